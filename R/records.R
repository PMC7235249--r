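#' Sequence records and validation
#'
#' Protein and DNA records are the universal currency of the pipeline: a
#' record is a plain list with `id`, `description` and `sequence` fields.
#' Sequences are normalized to uppercase on construction and validated
#' against the appropriate alphabet (20 canonical amino acids plus X for
#' proteins; A/C/G/T plus N for DNA).
#'
#' @param id character identifier.
#' @param sequence sequence string.
#' @param description free-text description (default empty).
#' @return A list of class `protein_record` or `dna_record`.
#' @examples
#' protein_record("spy", "MDKKYSIGLD")
#' dna_record("phage1", "ACGTACGT")
#' @export
protein_record <- function(id, sequence, description = "") {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("protein_record: sequence for '", id, "' is empty", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(AA_ALPHABET, "X"))
  if (length(bad) > 0) {
    stop("protein_record: invalid residue(s) in '", id, "': ",
         paste(bad, collapse = ","), call. = FALSE)
  }
  structure(list(id = as.character(id), description = description,
                 sequence = sequence),
            class = "protein_record")
}

#' @rdname protein_record
#' @export
dna_record <- function(id, sequence, description = "") {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("dna_record: sequence for '", id, "' is empty", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop("dna_record: invalid base(s) in '", id, "': ",
         paste(bad, collapse = ","), call. = FALSE)
  }
  structure(list(id = as.character(id), description = description,
                 sequence = sequence),
            class = "dna_record")
}

#' Spacer record
#'
#' A CRISPR spacer: strict A/C/G/T alphabet and a minimum length of 15 nt,
#' below which protospacer matches are too unreliable to interpret.
#'
#' @param id character identifier.
#' @param sequence spacer sequence (A/C/G/T only).
#' @param array_id identifier of the source CRISPR cassette.
#' @return A list of class `spacer_record`.
#' @export
spacer_record <- function(id, sequence, array_id = NA_character_) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 15) {
    stop("spacer_record: spacer '", id, "' shorter than 15 nt", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    stop("spacer_record: invalid base(s) in '", id, "': ",
         paste(bad, collapse = ","), call. = FALSE)
  }
  structure(list(id = as.character(id), sequence = sequence,
                 array_id = array_id),
            class = "spacer_record")
}

# 20 canonical residues
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, paste0("(", nchar(x$sequence), " aa)"), "\n")
  invisible(x)
}

#' @export
print.dna_record <- function(x, ...) {
  cat("<dna_record>", x$id, paste0("(", nchar(x$sequence), " nt)"), "\n")
  invisible(x)
}

#' Read sequence records from FASTA
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] /
#' [Biostrings::readDNAStringSet()] returning lists of records.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return A list of `protein_record` / `dna_record` objects.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  desc <- sub("^\\S+\\s*", "", names(set))
  lapply(seq_along(set), function(i) {
    protein_record(ids[i], as.character(set[[i]]), desc[i])
  })
}

#' @rdname read_protein_fasta
#' @export
read_dna_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  desc <- sub("^\\S+\\s*", "", names(set))
  lapply(seq_along(set), function(i) {
    dna_record(ids[i], as.character(set[[i]]), desc[i])
  })
}

#' Write records to FASTA
#'
#' @param records list of `protein_record` / `dna_record` objects.
#' @param path output path.
#' @param type `"protein"` or `"dna"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, type = c("protein", "dna")) {
  type <- match.arg(type)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  names(seqs) <- vapply(records, function(r) r$id, character(1))
  set <- if (type == "protein") Biostrings::AAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
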