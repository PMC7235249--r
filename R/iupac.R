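# IUPAC degenerate nucleotide alphabet: code -> set of matching bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' IUPAC code for a set of bases
#'
#' Returns the single degenerate-alphabet letter covering exactly the given
#' set of bases; the empty set maps to `"N"` by convention (no call).
#'
#' @param bases character vector, subset of A/C/G/T.
#' @return A single IUPAC letter.
#' @examples
#' iupac_code(c("A", "G"))  # "R"
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0) return("N")
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  key <- paste(bases, collapse = "")
  codes <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""),
                  character(1))
  names(codes)[match(key, codes)]
}

# Validate an IUPAC motif string; returns a list of per-position base sets.
iupac_motif_sets <- function(motif) {
  letters <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("invalid IUPAC letter(s) in motif '", motif, "': ",
         paste(unique(bad), collapse = ","), call. = FALSE)
  }
  lapply(letters, function(l) IUPAC_SETS[[l]])
}

# Reverse complement of an IUPAC motif.
iupac_reverse_complement <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  letters <- rev(strsplit(toupper(motif), "")[[1]])
  paste(comp[letters], collapse = "")
}

# Vectorized IUPAC window matcher over a plain DNA string.
# Returns a list with:
#   match : logical, one per window start (1-based), TRUE where the window
#           matches the motif (subject N never matches).
#   has_n : logical, TRUE where the window contains an N.
# Window semantics are explicit here (rather than delegated) so that
# assembly-gap Ns are excluded identically in scanning and density.
iupac_window_scan <- function(sequence, motif) {
  sets <- iupac_motif_sets(motif)
  m <- length(sets)
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < m) return(list(match = logical(0), has_n = logical(0)))
  n_win <- L - m + 1L
  match <- rep(TRUE, n_win)
  has_n <- rep(FALSE, n_win)
  is_n <- chars == "N"
  for (k in seq_len(m)) {
    window_chars <- chars[k:(k + n_win - 1L)]
    match <- match & (window_chars %in% sets[[k]])
    has_n <- has_n | is_n[k:(k + n_win - 1L)]
  }
  list(match = match & !has_n, has_n = has_n)
}
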