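#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed
#' with [Biostrings::pairwiseAlignment()]. A gap of length L costs
#' `gap_open + L * gap_extend`. Defaults (BLOSUM62, open 11, extend 1) are
#' the standard protein settings used when down-selecting Cas9 orthologs
#' against a reference.
#'
#' @param ref,query `protein_record` objects (or plain sequence strings).
#' @param matrix substitution matrix name; one of the matrices shipped with
#'   Biostrings (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return A list of class `protein_alignment` with fields `ref_id`,
#'   `query_id`, `aligned_ref`, `aligned_query`, `raw_score` and
#'   `percent_score` (raw score as a percentage of the reference
#'   self-alignment score, clamped below at 0).
#' @examples
#' a <- global_align(protein_record("r", "HEAGAWGHEE"),
#'                   protein_record("q", "PAWHEAE"))
#' a$raw_score
#' @export
global_align <- function(ref, query, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  ref <- as_protein_record(ref, "ref")
  query <- as_protein_record(query, "query")
  mat <- load_substitution_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref$sequence), Biostrings::AAString(query$sequence),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  self <- self_alignment_score(ref$sequence, mat)
  raw <- Biostrings::score(aln)
  structure(list(
    ref_id = ref$id, query_id = query$id,
    aligned_ref = as.character(Biostrings::alignedPattern(aln)),
    aligned_query = as.character(Biostrings::alignedSubject(aln)),
    raw_score = raw,
    percent_score = percent_blosum_score(raw, self),
    matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
    class = "protein_alignment")
}

as_protein_record <- function(x, role) {
  if (inherits(x, "protein_record")) return(x)
  protein_record(role, x)
}

load_substitution_matrix <- function(name) {
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = env)) {
    stop("unknown substitution matrix: '", name, "'", call. = FALSE)
  }
  get(name, envir = env)
}

# Self-alignment score: sum of diagonal substitution scores (no gaps can
# improve on aligning a sequence with itself under positive gap costs).
self_alignment_score <- function(sequence, mat) {
  chars <- strsplit(sequence, "")[[1]]
  sum(mat[cbind(chars, chars)])
}

#' Percent substitution-matrix score
#'
#' Normalizes a raw global-alignment score to the reference self-alignment
#' score: `100 * raw / self`, clamped below at 0. A self-alignment is
#' exactly 100. This is the agreement measure behind the 70% ortholog
#' retention threshold.
#'
#' @param raw_score raw alignment score, or a `protein_alignment`.
#' @param ref_self_score self-alignment score of the reference (> 0).
#' @return Percentage in `[0, 100]` (can exceed 100 only if the query
#'   outscores the reference against itself, which cannot happen for
#'   standard substitution matrices).
#' @export
percent_blosum_score <- function(raw_score, ref_self_score) {
  if (inherits(raw_score, "protein_alignment")) {
    raw_score <- raw_score$raw_score
  }
  if (!is.numeric(ref_self_score) || ref_self_score <= 0) {
    stop("ref_self_score must be positive", call. = FALSE)
  }
  max(0, 100 * raw_score / ref_self_score)
}

#' Filter orthologs by percent score against a reference
#'
#' Aligns every record to the reference and partitions the set at a percent
#' score threshold (boundary inclusive: `>= threshold` is kept). This is
#' the ortholog down-selection step: orthologs with less than 70% agreement
#' with the reference are discarded before residue-conservation analysis.
#'
#' @param records list of `protein_record` objects.
#' @param reference reference `protein_record`.
#' @param threshold percent score cutoff (default 70).
#' @param matrix,gap_open,gap_extend passed to [global_align()].
#' @return A list with `kept` and `discarded` record lists (input order
#'   preserved) and `percent_scores`, named by record id.
#' @export
filter_orthologs <- function(records, reference, threshold = 70,
                             matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1) {
  if (length(records) == 0) {
    warning("filter_orthologs: empty record list")
    return(list(kept = list(), discarded = list(),
                percent_scores = numeric(0)))
  }
  reference <- as_protein_record(reference, "ref")
  scores <- vapply(records, function(r) {
    global_align(reference, r, matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend)$percent_score
  }, numeric(1))
  names(scores) <- vapply(records, function(r) r$id, character(1))
  keep <- scores >= threshold
  list(kept = records[keep], discarded = records[!keep],
       percent_scores = scores)
}

#' Map reference positions through an alignment
#'
#' Transfers 1-based reference coordinates into query coordinates by
#' walking the alignment columns; this is how reference PAM-contact
#' positions (e.g. the SpyCas9 arginines R1333/R1335) are read out in an
#' ortholog. Positions falling in a query deletion are reported as gaps.
#'
#' @param aln a `protein_alignment` from [global_align()].
#' @param positions integer vector of 1-based reference positions.
#' @return A data.frame with columns `ref_position`, `ref_residue`,
#'   `query_position` (NA for gap) and `query_residue` (`"-"` for gap).
#' @export
map_reference_positions <- function(aln, positions) {
  stopifnot(inherits(aln, "protein_alignment"))
  rmap <- residue_map(aln)
  ref_len <- length(rmap$query_pos)
  positions <- as.integer(positions)
  if (any(positions < 1 | positions > ref_len)) {
    stop("position(s) out of reference range 1..", ref_len, call. = FALSE)
  }
  data.frame(
    ref_position = positions,
    ref_residue = rmap$ref_res[positions],
    query_position = rmap$query_pos[positions],
    query_residue = rmap$query_res[positions],
    stringsAsFactors = FALSE)
}

# Column walk: for every reference position, the aligned query position
# (NA at deletions) and residue ("-" at deletions). Mapped positions are
# strictly increasing by construction of a global alignment.
residue_map <- function(aln) {
  rc <- strsplit(aln$aligned_ref, "")[[1]]
  qc <- strsplit(aln$aligned_query, "")[[1]]
  stopifnot(length(rc) == length(qc))
  ref_i <- cumsum(rc != "-")
  query_i <- cumsum(qc != "-")
  keep <- rc != "-"
  query_pos <- ifelse(qc[keep] == "-", NA_integer_, query_i[keep])
  list(ref_res = rc[keep],
       query_pos = as.integer(query_pos),
       query_res = qc[keep])
}
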