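#' Enumerate PAM sites and candidate protospacers
#'
#' Scans a DNA sequence for windows matching an IUPAC PAM motif on one or
#' both strands and reports, for each site, the coordinates of the
#' spacer-length protospacer immediately 5' of the PAM on the PAM's
#' strand (type II-A geometry). Coordinates are 0-based half-open on the
#' forward strand. Sites whose protospacer would run outside the sequence
#' are excluded and counted separately; windows containing N never match.
#'
#' @param seq a `dna_record` (or plain sequence).
#' @param motif IUPAC motif, e.g. `"NAAN"`.
#' @param spacer_len protospacer length (default 20; 0 disables the
#'   protospacer-bounds requirement).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return A list with `sites` (data.frame: `genome_id`, `pam_start`,
#'   `pam_end`, `strand`, `pam_sequence`, `protospacer_start`,
#'   `protospacer_end`) and `n_excluded_bounds`.
#' @export
scan_pam_sites <- function(seq, motif, spacer_len = 20,
                           both_strands = TRUE) {
  if (!inherits(seq, "dna_record")) seq <- dna_record("seq", seq)
  m <- nchar(motif)
  L <- nchar(seq$sequence)
  if (L < m) stop("sequence shorter than motif", call. = FALSE)
  fwd <- iupac_window_scan(seq$sequence, motif)$match
  starts0 <- which(fwd) - 1L
  rows <- list(make_site_rows(seq, starts0, "+", m, spacer_len, L))
  if (both_strands) {
    # a minus-strand PAM at forward window [s, s+m) is a window whose
    # reverse complement matches the motif
    rev <- iupac_window_scan(seq$sequence,
                             iupac_reverse_complement(motif))$match
    rows[[2]] <- make_site_rows(seq, which(rev) - 1L, "-", m, spacer_len, L)
  }
  sites <- do.call(rbind, lapply(rows, `[[`, "sites"))
  sites <- sites[order(sites$pam_start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites,
       n_excluded_bounds = sum(vapply(rows, `[[`, numeric(1), "excluded")))
}

make_site_rows <- function(seq, starts0, strand, m, spacer_len, L) {
  if (strand == "+") {
    ps_start <- starts0 - spacer_len
    ps_end <- starts0
  } else {
    ps_start <- starts0 + m
    ps_end <- starts0 + m + spacer_len
  }
  ok <- ps_start >= 0 & ps_end <= L
  starts <- starts0[ok]
  pam_seq <- if (length(starts) == 0) character(0) else
    substring(seq$sequence, starts + 1L, starts + m)
  if (strand == "-") {
    pam_seq <- vapply(pam_seq, reverse_complement, character(1),
                      USE.NAMES = FALSE)
  }
  list(sites = data.frame(
    genome_id = rep(seq$id, length(starts)),
    pam_start = starts, pam_end = starts + m,
    strand = rep(strand, length(starts)),
    pam_sequence = pam_seq,
    protospacer_start = ps_start[ok], protospacer_end = ps_end[ok],
    stringsAsFactors = FALSE),
    excluded = sum(!ok))
}

#' Overlapping dinucleotide frequencies
#'
#' Counts all 16 dinucleotides over overlapping step-1 windows via
#' [Biostrings::oligonucleotideFrequency()]; windows containing N are
#' excluded from both numerator and denominator.
#'
#' @param seq a `dna_record` (or plain sequence), length >= 2.
#' @return A list of class `dinuc_stats` with `counts`, `frequencies`
#'   (named by dinucleotide) and `total_windows`.
#' @export
dinucleotide_frequencies <- function(seq) {
  if (!inherits(seq, "dna_record")) seq <- dna_record("seq", seq)
  if (nchar(seq$sequence) < 2) stop("sequence shorter than 2 nt",
                                    call. = FALSE)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(seq$sequence), width = 2, step = 1)
  total <- sum(counts)
  if (total == 0) stop("no N-free dinucleotide windows", call. = FALSE)
  structure(list(counts = counts, frequencies = counts / total,
                 total_windows = total),
            class = "dinuc_stats")
}

#' Genomic density of an IUPAC PAM motif
#'
#' The fraction of length-`|motif|` windows that match the motif on the
#' forward strand or (with `both_strands`) whose reverse complement
#' matches it. The denominator is the number of N-free windows of that
#' length (per record; multi-record densities aggregate match and window
#' counts across records without bridging junctions). This is the
#' convention under which adenine-dinucleotide PAM abundance in a genome
#' is measured.
#'
#' @param seq a `dna_record`, plain sequence, or list of records.
#' @param motif IUPAC motif string.
#' @param both_strands count reverse-strand matches too (default TRUE).
#' @return A list of class `pam_density` with `motif`, `window_count`,
#'   `match_count` and `density`.
#' @export
pam_density <- function(seq, motif, both_strands = TRUE) {
  records <- if (is.list(seq) && !inherits(seq, "dna_record")) seq else
    list(seq)
  match_count <- 0
  window_count <- 0
  for (r in records) {
    if (!inherits(r, "dna_record")) r <- dna_record("seq", r)
    if (nchar(r$sequence) < nchar(motif)) next
    fwd <- iupac_window_scan(r$sequence, motif)
    hit <- fwd$match
    if (both_strands) {
      hit <- hit | iupac_window_scan(
        r$sequence, iupac_reverse_complement(motif))$match
    }
    match_count <- match_count + sum(hit)
    window_count <- window_count + sum(!fwd$has_n)
  }
  if (window_count == 0) stop("no valid windows", call. = FALSE)
  structure(list(motif = motif, window_count = window_count,
                 match_count = match_count,
                 density = match_count / window_count),
            class = "pam_density")
}

#' Write PAM sites as a BED-like table
#'
#' @param sites the `sites` data.frame from [scan_pam_sites()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$genome_id, start = sites$pam_start,
                    end = sites$pam_end, name = sites$pam_sequence,
                    score = 0L, strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
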