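#' Residue-conservation profile around PAM-contact positions
#'
#' Aligns every ortholog to the reference, reads out the residues at an
#' odd-width window of reference positions around the given contact
#' positions (e.g. the 11 positions around the PAM-contacting arginines),
#' and tabulates per-position residue counts and information content
#' `IC_j = log2(20) - H_j` (Shannon entropy over the 20-residue alphabet,
#' gaps excluded from counts).
#'
#' @param records list of `protein_record` orthologs.
#' @param reference reference `protein_record`.
#' @param center_positions 1-based reference positions the window must
#'   cover (typically the PAM-contact residues).
#' @param window odd window width (total number of reference positions).
#' @param matrix,gap_open,gap_extend passed to [global_align()].
#' @return A list of class `divergence_profile` with `window_positions`,
#'   `residue_table` (ortholog x position character matrix, `"-"` at
#'   gaps), `frequency_table` (residue x position counts) and
#'   `information_content` (bits per position).
#' @export
build_residue_logo <- function(records, reference, center_positions,
                               window = 11, matrix = "BLOSUM62",
                               gap_open = 11, gap_extend = 1) {
  if (window < 1 || window %% 2 == 0) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  reference <- as_protein_record(reference, "ref")
  center_positions <- sort(as.integer(center_positions))
  half <- (window - 1L) %/% 2L
  mid <- floor((min(center_positions) + max(center_positions)) / 2)
  window_positions <- seq.int(mid - half, mid + half)
  if (!all(center_positions %in% window_positions)) {
    stop("window of width ", window, " cannot cover all center positions",
         call. = FALSE)
  }
  ref_len <- nchar(reference$sequence)
  if (min(window_positions) < 1 || max(window_positions) > ref_len) {
    stop("window extends outside the reference (1..", ref_len, ")",
         call. = FALSE)
  }

  ids <- vapply(records, function(r) r$id, character(1))
  residue_table <- matrix("-", nrow = length(records),
                          ncol = length(window_positions),
                          dimnames = list(ids, window_positions))
  for (i in seq_along(records)) {
    aln <- global_align(reference, records[[i]], matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend)
    mapped <- map_reference_positions(aln, window_positions)
    residue_table[i, ] <- mapped$query_residue
  }

  frequency_table <- apply(residue_table, 2, function(col) {
    col <- col[col != "-"]
    tabulate(factor(col, levels = AA_ALPHABET), nbins = length(AA_ALPHABET))
  })
  rownames(frequency_table) <- AA_ALPHABET

  coverage <- colSums(frequency_table) / length(records)
  low <- coverage < 0.5
  if (any(low)) {
    message("build_residue_logo: column(s) ",
            paste(window_positions[low], collapse = ","),
            " have < 50% non-gap coverage")
  }

  ic <- apply(frequency_table, 2, function(counts) {
    n <- sum(counts)
    if (n == 0) return(0)
    p <- counts[counts > 0] / n
    log2(20) + sum(p * log2(p))
  })

  structure(list(window_positions = window_positions,
                 residue_table = residue_table,
                 frequency_table = frequency_table,
                 information_content = ic),
            class = "divergence_profile")
}

#' Export a divergence profile as a logo-ready table
#'
#' @param profile a `divergence_profile`.
#' @param path optional TSV output path.
#' @return A data.frame with columns `ref_pos`, `residue`, `count`,
#'   `frequency`, `ic` (one row per position x observed residue).
#' @export
profile_table <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "divergence_profile"))
  rows <- do.call(rbind, lapply(seq_along(profile$window_positions),
    function(j) {
      counts <- profile$frequency_table[, j]
      counts <- counts[counts > 0]
      n <- sum(counts)
      if (n == 0) return(NULL)
      data.frame(ref_pos = profile$window_positions[j],
                 residue = names(counts), count = as.integer(counts),
                 frequency = as.numeric(counts) / n,
                 ic = profile$information_content[j],
                 stringsAsFactors = FALSE)
    }))
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  rows
}

#' Design a PID-graft hybrid protein
#'
#' Builds a hybrid by retaining the scaffold through a junction residue and
#' grafting the donor tail from the donor position aligned to the next
#' scaffold residue (the SpyMac construction: SpyCas9 scaffold with the
#' SmacCas9 PAM-interacting domain), then applies verified point mutations
#' (e.g. R221K/N394K for efficiency, R691A for fidelity).
#'
#' @param scaffold,donor `protein_record` objects.
#' @param junction_ref_pos 1-based last scaffold residue retained.
#' @param mutations list of `c(expected, position, new)` triplets, applied
#'   in product coordinates; each expected residue is checked against the
#'   pre-mutation product.
#' @param name name for the designed protein.
#' @param matrix,gap_open,gap_extend passed to [global_align()].
#' @return A list of class `hybrid_design` with the design bookkeeping and
#'   `product` (a `protein_record`).
#' @export
design_hybrid <- function(scaffold, donor, junction_ref_pos,
                          mutations = list(), name = "hybrid",
                          matrix = "BLOSUM62", gap_open = 11,
                          gap_extend = 1) {
  scaffold <- as_protein_record(scaffold, "scaffold")
  donor <- as_protein_record(donor, "donor")
  junction_ref_pos <- as.integer(junction_ref_pos)
  scaffold_len <- nchar(scaffold$sequence)
  if (junction_ref_pos < 1 || junction_ref_pos > scaffold_len) {
    stop("junction outside scaffold (1..", scaffold_len, ")", call. = FALSE)
  }

  if (junction_ref_pos == scaffold_len) {
    product_seq <- scaffold$sequence
  } else {
    aln <- global_align(scaffold, donor, matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend)
    mapped <- map_reference_positions(aln, junction_ref_pos + 1L)
    if (is.na(mapped$query_position)) {
      stop("junction+1 (scaffold position ", junction_ref_pos + 1L,
           ") aligns to a gap in the donor", call. = FALSE)
    }
    product_seq <- paste0(
      substr(scaffold$sequence, 1L, junction_ref_pos),
      substr(donor$sequence, mapped$query_position, nchar(donor$sequence)))
  }

  for (mut in mutations) {
    expected <- toupper(mut[[1]])
    pos <- as.integer(mut[[2]])
    new <- toupper(mut[[3]])
    if (pos < 1 || pos > nchar(product_seq)) {
      stop("mutation position ", pos, " outside product", call. = FALSE)
    }
    found <- substr(product_seq, pos, pos)
    if (found != expected) {
      stop("mutation ", expected, pos, new, ": product has '", found,
           "' at position ", pos, ", expected '", expected, "'",
           call. = FALSE)
    }
    substr(product_seq, pos, pos) <- new
  }

  structure(list(
    name = name, scaffold_id = scaffold$id, pid_donor_id = donor$id,
    junction_ref_pos = junction_ref_pos,
    point_mutations = mutations,
    product = protein_record(name, product_seq,
                             paste0("hybrid of ", scaffold$id, " and ",
                                    donor$id))),
    class = "hybrid_design")
}

#' Serialize a hybrid design
#'
#' Writes the product sequence as FASTA and the design bookkeeping as JSON.
#'
#' @param design a `hybrid_design`.
#' @param fasta_path,json_path output paths.
#' @return `design`, invisibly.
#' @export
write_hybrid_design <- function(design, fasta_path, json_path) {
  stopifnot(inherits(design, "hybrid_design"))
  write_fasta(list(design$product), fasta_path, type = "protein")
  meta <- design[c("name", "scaffold_id", "pid_donor_id",
                   "junction_ref_pos")]
  meta$point_mutations <- lapply(design$point_mutations, function(m) {
    list(expected = m[[1]], position = as.integer(m[[2]]), new = m[[3]])
  })
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(design)
}
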