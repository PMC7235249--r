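# Independent oracles used to cross-check the implementation. These are
# deliberately written from first principles and share no code with the
# package internals.

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Exhaustive global-alignment score under affine gaps (gap of length L
# costs open + L*ext). Enumerates every set of aligned residue pairs
# (any monotone pairing, matches and mismatches alike); for a given set,
# the optimal gap arrangement is one gap per unmatched run, so the
# maximum over sets is the optimal alignment score. No dynamic
# programming and no memoization: every chain is visited.
align_score_oracle <- function(a, b, mat = blosum62, open = 11, ext = 1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  m <- length(ac)
  n <- length(bc)
  gapcost <- function(L) if (L > 0) open + L * ext else 0
  S <- matrix(mat[ac, bc], m, n)
  best <- -Inf
  rec <- function(i, j, acc) {
    total <- acc - gapcost(m - i) - gapcost(n - j)
    if (total > best) best <<- total
    if (i < m && j < n) {
      for (i2 in (i + 1):m) {
        for (j2 in (j + 1):n) {
          rec(i2, j2,
              acc + S[i2, j2] - gapcost(i2 - i - 1) - gapcost(j2 - j - 1))
        }
      }
    }
  }
  rec(0L, 0L, 0)
  best
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Brute-force sliding-window Hamming scan over every offset and strand,
# 0-based half-open forward coordinates.
hamming_scan_oracle <- function(spacer, genome, max_mm) {
  gc <- strsplit(genome, "")[[1]]
  L <- length(gc)
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else revcomp_chr(spacer)
    pc <- strsplit(pat, "")[[1]]
    l <- length(pc)
    n_win <- L - l + 1L
    mm <- integer(n_win)
    for (k in seq_len(l)) {
      mm <- mm + (gc[k:(k + n_win - 1L)] != pc[k])
    }
    hit <- which(mm <= max_mm)
    if (length(hit) > 0) {
      rows[[strand]] <- data.frame(start = hit - 1L, end = hit - 1L + l,
                                   strand = strand,
                                   mismatches = mm[hit],
                                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0))
  }
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

# Independent overlapping-dinucleotide tally (N windows excluded).
dinuc_tally_oracle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  pairs <- paste0(chars[-length(chars)], chars[-1])
  pairs <- pairs[!grepl("N", pairs)]
  bases <- c("A", "C", "G", "T")
  keys <- paste0(rep(bases, each = 4), bases)
  counts <- vapply(keys, function(k) sum(pairs == k), numeric(1))
  counts / sum(counts)
}

random_dna_string <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein_string <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# Standard synthetic study conditions reused across tests: a 300-residue
# reference and the two divergence tiers whose percent scores straddle
# the 70% retention threshold (~55% and ~85%).
make_reference <- function(len = 300, seed = 42) {
  set.seed(seed)
  protein_record("ref", random_protein_string(len))
}
TIER_LOW <- 0.35
TIER_HIGH <- 0.12
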