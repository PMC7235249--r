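#' Find protospacer matches of a spacer in a genome
#'
#' Mismatch-tolerant (Hamming, no indels) search for a CRISPR spacer on
#' both strands of a genome, via [Biostrings::matchPattern()]. Coordinates
#' are 0-based half-open on the forward strand regardless of strand, the
#' BED convention; a minus-strand hit means the spacer matches the reverse
#' complement of that interval.
#'
#' @param spacer a `spacer_record` (or plain sequence).
#' @param genome a `dna_record` (or plain sequence).
#' @param max_mismatches maximum Hamming distance (default 2). Must be
#'   below half the spacer length; more tolerant matches are unreliable.
#' @return A data.frame with columns `spacer_id`, `genome_id`, `start`,
#'   `end`, `strand`, `mismatches` (zero rows when there is no hit).
#' @export
find_protospacers <- function(spacer, genome, max_mismatches = 2) {
  if (!inherits(spacer, "spacer_record")) spacer <- spacer_record("spacer", spacer)
  if (!inherits(genome, "dna_record")) genome <- dna_record("genome", genome)
  slen <- nchar(spacer$sequence)
  if (max_mismatches >= slen / 2) {
    stop("max_mismatches (", max_mismatches, ") must be < spacer length/2",
         call. = FALSE)
  }
  if (slen >= nchar(genome$sequence)) {
    stop("spacer must be shorter than the genome", call. = FALSE)
  }
  subject <- Biostrings::DNAString(genome$sequence)
  hit_rows <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subject,
                                  max.mismatch = max_mismatches,
                                  with.indels = FALSE)
    if (length(m) == 0) return(NULL)
    mm <- vapply(as.character(m), function(s) {
      sum(strsplit(s, "")[[1]] != strsplit(as.character(pattern), "")[[1]])
    }, numeric(1), USE.NAMES = FALSE)
    data.frame(spacer_id = spacer$id, genome_id = genome$id,
               start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
               strand = strand, mismatches = as.integer(mm),
               stringsAsFactors = FALSE)
  }
  fwd <- hit_rows(Biostrings::DNAString(spacer$sequence), "+")
  rev <- hit_rows(Biostrings::reverseComplement(
    Biostrings::DNAString(spacer$sequence)), "-")
  out <- rbind(fwd, rev)
  if (is.null(out)) {
    out <- data.frame(spacer_id = character(0), genome_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Extract the PAM-side flank of a protospacer hit
#'
#' Returns the sequence immediately 3' of the protospacer on the
#' spacer-matching strand (the type II-A PAM side; 5'-NGG-3' for SpyCas9
#' lies here): `genome[end, end+flank_len)` for a plus-strand hit, the
#' reverse complement of `genome[start-flank_len, start)` for a minus
#' strand hit. Hits whose flank would run past the genome boundary return
#' `NA`.
#'
#' @param hit one row of the data.frame from [find_protospacers()].
#' @param genome the `dna_record` the hit refers to.
#' @param flank_len flank length (default 8, the randomized PAM library
#'   width).
#' @return The flank sequence, or `NA_character_` if out of bounds.
#' @export
extract_pam_flank <- function(hit, genome, flank_len = 8) {
  if (!inherits(genome, "dna_record")) genome <- dna_record("genome", genome)
  L <- nchar(genome$sequence)
  stopifnot(hit$start >= 0, hit$end <= L, hit$start < hit$end)
  if (hit$strand == "+") {
    if (hit$end + flank_len > L) return(NA_character_)
    substr(genome$sequence, hit$end + 1L, hit$end + flank_len)
  } else {
    if (hit$start - flank_len < 0) return(NA_character_)
    reverse_complement(
      substr(genome$sequence, hit$start - flank_len + 1L, hit$start))
  }
}

#' Build a PAM position frequency matrix from flanks
#'
#' @param flanks character vector of equal-length flank sequences (NA
#'   entries, e.g. boundary-excluded flanks, are dropped).
#' @param weights optional per-flank weights (e.g. `1 / hits-per-spacer`
#'   to keep repetitive regions from dominating); default 1. With
#'   non-unit weights the counts are non-negative reals.
#' @return A list of class `pam_matrix` with `counts` (4 x length,
#'   rows A/C/G/T), `length` and `n_observations` (sum of weights); each
#'   position's counts sum to `n_observations`.
#' @export
build_pam_matrix <- function(flanks, weights = NULL) {
  keep <- !is.na(flanks)
  flanks <- toupper(flanks[keep])
  if (is.null(weights)) weights <- rep(1, length(flanks)) else {
    stopifnot(length(weights) == length(keep))
    weights <- weights[keep]
  }
  if (length(flanks) == 0) stop("no flanks provided", call. = FALSE)
  lens <- nchar(flanks)
  if (length(unique(lens)) != 1) {
    stop("flanks have ragged lengths: ",
         paste(unique(lens), collapse = ","), call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(flanks, ""))
  bad <- setdiff(unique(as.vector(mat)), bases)
  if (length(bad) > 0) {
    stop("flanks contain non-ACGT base(s): ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  counts <- sapply(seq_len(ncol(mat)), function(j) {
    vapply(bases, function(b) sum(weights[mat[, j] == b]), numeric(1))
  })
  counts <- matrix(counts, nrow = 4, dimnames = list(bases, NULL))
  structure(list(counts = counts, length = ncol(counts),
                 n_observations = sum(weights)),
            class = "pam_matrix")
}

#' Per-position information content of a PAM matrix
#'
#' Schneider information content against a uniform DNA background:
#' `IC_j = 2 - H_j` bits, where `H_j` is the Shannon entropy of position
#' j's base frequencies. No small-sample correction is applied.
#'
#' @param m a `pam_matrix`.
#' @return Numeric vector of bits, one per position, each in `[0, 2]`.
#' @export
information_content <- function(m) {
  stopifnot(inherits(m, "pam_matrix"))
  if (m$n_observations <= 0) stop("pam_matrix has no observations",
                                  call. = FALSE)
  apply(m$counts, 2, function(counts) {
    p <- counts / sum(counts)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Call an IUPAC consensus from a PAM matrix
#'
#' Per position, the consensus covers every base whose frequency is at
#' least `include_threshold` times the most frequent base's frequency;
#' positions carrying less than `ic_floor` bits of information are forced
#' to N. This is the motif-calling convention that turns protospacer-flank
#' counts into a consensus such as 5'-NAAN-3'.
#'
#' @param m a `pam_matrix`.
#' @param include_threshold relative-frequency inclusion rule (default
#'   0.25 of the max base).
#' @param ic_floor positions below this information content (bits) are
#'   called N (default 0.2).
#' @param min_observations below this effective sample size the call is
#'   still emitted but flagged low-confidence with a warning (default 10).
#' @return A list of class `consensus_call` with `iupac` (string),
#'   `ic_bits` (per-position) and `low_confidence` (flag).
#' @export
call_consensus <- function(m, include_threshold = 0.25, ic_floor = 0.2,
                           min_observations = 10) {
  stopifnot(inherits(m, "pam_matrix"))
  low_confidence <- m$n_observations < min_observations
  if (low_confidence) {
    warning("call_consensus: only ", signif(m$n_observations, 4),
            " observations (< ", min_observations,
            "); consensus is low-confidence")
  }
  ic <- information_content(m)
  letters <- vapply(seq_len(m$length), function(j) {
    if (ic[j] < ic_floor) return("N")
    counts <- m$counts[, j]
    keep <- counts >= include_threshold * max(counts)
    iupac_code(rownames(m$counts)[keep])
  }, character(1))
  structure(list(iupac = paste(letters, collapse = ""), ic_bits = ic,
                 low_confidence = low_confidence),
            class = "consensus_call")
}

#' Infer a PAM consensus from spacers and phage genomes
#'
#' The full spacer-to-PAM stage: map every spacer to every genome on both
#' strands, extract the PAM-side flanks of all hits, build the position
#' frequency matrix and call the consensus. Flanks of multi-hit spacers
#' can be down-weighted by `1 / n_hits` so repetitive regions do not
#' dominate the logo (`weight_multi_hits`, off by default).
#'
#' @param spacers list of `spacer_record` objects.
#' @param genomes list of `dna_record` objects.
#' @param max_mismatches Hamming tolerance for protospacer matching.
#' @param flank_len PAM flank length.
#' @param weight_multi_hits logical; weight each flank by `1/n_hits` of
#'   its spacer.
#' @param ... passed to [call_consensus()].
#' @return A list with `hits` (data.frame incl. `pam_flank`), `matrix`
#'   (`pam_matrix`), `consensus` (`consensus_call`) and
#'   `n_excluded_boundary` flanks.
#' @export
infer_pam <- function(spacers, genomes, max_mismatches = 2, flank_len = 8,
                      weight_multi_hits = FALSE, ...) {
  genome_ids <- vapply(genomes, function(g) g$id, character(1))
  hits <- list()
  for (sp in spacers) {
    for (g in genomes) {
      h <- find_protospacers(sp, g, max_mismatches = max_mismatches)
      if (nrow(h) > 0) hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0) stop("no protospacer hits found", call. = FALSE)
  hits <- do.call(rbind, hits)
  hits$pam_flank <- vapply(seq_len(nrow(hits)), function(i) {
    g <- genomes[[match(hits$genome_id[i], genome_ids)]]
    fl <- extract_pam_flank(hits[i, ], g, flank_len = flank_len)
    if (is.na(fl)) NA_character_ else fl
  }, character(1))
  n_excluded <- sum(is.na(hits$pam_flank))
  if (n_excluded > 0) {
    message("infer_pam: ", n_excluded,
            " hit(s) excluded (flank past genome boundary)")
  }
  weights <- NULL
  if (weight_multi_hits) {
    weights <- as.numeric(1 / table(hits$spacer_id)[hits$spacer_id])
  }
  m <- build_pam_matrix(hits$pam_flank, weights = weights)
  list(hits = hits, matrix = m, consensus = call_consensus(m, ...),
       n_excluded_boundary = n_excluded)
}
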