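#' Normalize raw trace peak heights to base fractions
#'
#' Converts a nonnegative position x base table of Sanger-trace peak
#' heights over the randomized PAM region into per-position base
#' fractions (each row sums to 1). Traces enter the analysis as such
#' tables; chromatogram peak quantification is upstream.
#'
#' @param raw numeric matrix or data.frame, positions in rows, columns
#'   A/C/G/T (a `position` column is accepted and dropped).
#' @return A list of class `trace_profile` with `fractions` (matrix) and
#'   `region_length`.
#' @export
normalize_trace <- function(raw) {
  m <- as_trace_matrix(raw)
  if (any(m < 0)) stop("negative peak heights", call. = FALSE)
  totals <- rowSums(m)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    stop("all-zero trace at position(s) ", paste(zero, collapse = ","),
         call. = FALSE)
  }
  structure(list(fractions = m / totals, region_length = nrow(m)),
            class = "trace_profile")
}

as_trace_matrix <- function(raw) {
  if (inherits(raw, "trace_profile")) return(raw$fractions)
  if (is.data.frame(raw)) {
    raw <- raw[, setdiff(names(raw), "position"), drop = FALSE]
    raw <- as.matrix(raw)
  }
  bases <- c("A", "C", "G", "T")
  if (is.null(colnames(raw))) colnames(raw) <- bases
  stopifnot(all(bases %in% colnames(raw)))
  m <- raw[, bases, drop = FALSE]
  storage.mode(m) <- "double"
  m
}

#' Post- vs pre-sort enrichment of a randomized PAM library
#'
#' Per-position, per-base log2 ratio of the sorted (reporter-positive)
#' population's base fraction to the pre-sort library's, with a
#' pseudocount on both fractions so ratios stay finite and an identical
#' pre/post pair gives exactly zero.
#'
#' @param pre,post `trace_profile` objects (or raw tables, normalized on
#'   the fly) of equal region length.
#' @param pseudocount added to both numerator and denominator fractions
#'   (default 0.01).
#' @return A list of class `enrichment_result` with `log2_ratio`
#'   (position x base matrix) and `pseudocount`.
#' @export
compute_enrichment <- function(pre, post, pseudocount = 0.01) {
  if (!inherits(pre, "trace_profile")) pre <- normalize_trace(pre)
  if (!inherits(post, "trace_profile")) post <- normalize_trace(post)
  if (pre$region_length != post$region_length) {
    stop("pre and post profiles have different region lengths",
         call. = FALSE)
  }
  ratio <- log2((post$fractions + pseudocount) /
                (pre$fractions + pseudocount))
  structure(list(log2_ratio = ratio, pseudocount = pseudocount),
            class = "enrichment_result")
}

#' Call per-position PAM preference from enrichment ratios
#'
#' A position is called as the IUPAC code covering every base whose log2
#' enrichment meets the threshold; positions with no base above threshold
#' are N. The default threshold of 1 log2 unit (2-fold enrichment) is this
#' pipeline's convention for reading a preference out of a trace pair.
#'
#' @param e an `enrichment_result`.
#' @param call_threshold log2-ratio cutoff (default 1.0).
#' @return A single IUPAC string, one letter per position.
#' @export
call_pam_preference <- function(e, call_threshold = 1.0) {
  stopifnot(inherits(e, "enrichment_result"))
  letters <- apply(e$log2_ratio, 1, function(r) {
    iupac_code(colnames(e$log2_ratio)[r >= call_threshold])
  })
  paste(letters, collapse = "")
}

#' Read / write trace tables
#'
#' TSV with columns `position`, `A`, `C`, `G`, `T` (fractions or raw peak
#' heights; [normalize_trace()] accepts either).
#'
#' @param path TSV path.
#' @return For `read_trace_tsv`, a data.frame.
#' @export
read_trace_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_trace_tsv
#' @param profile a `trace_profile`.
#' @export
write_trace_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "trace_profile"))
  df <- data.frame(position = seq_len(profile$region_length),
                   profile$fractions)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
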