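# Seeded generators with known truth for every pipeline stage. Each
# generator uses one private pseudo-random stream (the caller's global
# RNG state is saved and restored), so identical seed + parameters give
# identical output no matter what ran before.

with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

truth_record <- function(generator, seed, params) {
  structure(list(generator = generator, seed = seed, params = params),
            class = "truth_record")
}

#' Write a generator truth record as JSON
#'
#' @param truth a `truth_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic Cas9 ortholog family
#'
#' Mutated copies of a reference protein at a controlled substitution rate
#' per site, with designated members carrying planted residues (e.g. Q/Q)
#' at the PAM-contact positions. Emulates an ortholog set in which a small
#' number of members diverge at the PAM-contacting arginines.
#'
#' @param reference reference `protein_record`.
#' @param n number of orthologs.
#' @param divergence substitution probability per site, in `[0, 0.5]`;
#'   scalar or per-member vector (for mixed-divergence tiers).
#' @param contact_positions 1-based reference positions of the planted
#'   residues.
#' @param planted_residues named list: member index (as character) ->
#'   residue vector of `length(contact_positions)`.
#' @param seed integer seed.
#' @return A list with `records` (list of `protein_record`) and `truth`
#'   (`truth_record` carrying the per-member divergence and plants).
#' @export
gen_ortholog_family <- function(reference, n, divergence,
                                contact_positions = integer(0),
                                planted_residues = list(), seed = 1) {
  reference <- as_protein_record(reference, "ref")
  if (any(divergence < 0 | divergence > 0.5)) {
    stop("divergence must be in [0, 0.5]", call. = FALSE)
  }
  divergence <- rep_len(divergence, n)
  ref_chars <- strsplit(reference$sequence, "")[[1]]
  L <- length(ref_chars)
  contact_positions <- as.integer(contact_positions)
  if (any(contact_positions < 1 | contact_positions > L)) {
    stop("contact position(s) outside reference", call. = FALSE)
  }
  with_private_seed(seed, {
    records <- lapply(seq_len(n), function(i) {
      chars <- ref_chars
      hit <- stats::runif(L) < divergence[i]
      if (any(hit)) {
        chars[hit] <- vapply(chars[hit], function(orig) {
          sample(setdiff(AA_ALPHABET, orig), 1)
        }, character(1), USE.NAMES = FALSE)
      }
      planted <- planted_residues[[as.character(i)]]
      if (!is.null(planted)) {
        stopifnot(length(planted) == length(contact_positions))
        chars[contact_positions] <- toupper(planted)
      }
      protein_record(sprintf("ortho_%03d", i), paste(chars, collapse = ""))
    })
    list(records = records,
         truth = truth_record("ortholog_family", seed, list(
           reference_id = reference$id, n = n, divergence = divergence,
           contact_positions = contact_positions,
           planted_residues = planted_residues)))
  })
}

# Normalize one PAM-profile element to a prob vector over A/C/G/T.
# Accepts "N" (uniform), a fully named prob vector, or a partial one
# (remaining mass split over the unnamed bases).
profile_probs <- function(el) {
  bases <- c("A", "C", "G", "T")
  if (is.character(el) && length(el) == 1 && toupper(el) == "N") {
    return(stats::setNames(rep(0.25, 4), bases))
  }
  stopifnot(is.numeric(el), !is.null(names(el)),
            all(names(el) %in% bases), sum(el) <= 1 + 1e-9)
  p <- stats::setNames(rep(0, 4), bases)
  p[names(el)] <- el
  rest <- setdiff(bases, names(el))
  if (length(rest) > 0) p[rest] <- (1 - sum(el)) / length(rest)
  p / sum(p)
}

#' Generate a synthetic phage cohort with planted protospacers
#'
#' Random phage genomes carrying non-overlapping planted protospacers,
#' each on a random strand with a PAM-side flank drawn from a per-position
#' base profile; the matching spacers are emitted with per-base errors at
#' `mismatch_rate`. This is the with-truth analogue of mapping CRISPR
#' cassette spacers to phage genomes to read out a PAM motif.
#'
#' @param n_genomes,genome_len cohort shape.
#' @param n_protospacers total planted protospacers (distributed across
#'   genomes).
#' @param spacer_len spacer/protospacer length (default 20).
#' @param pam_profile list of per-position base distributions for the
#'   flank (see details in [gen_trace_pair()]; `"N"` = uniform, or named
#'   probabilities such as `c(A = 0.9)`); positions beyond the profile are
#'   uniform.
#' @param flank_len planted flank length (default 8).
#' @param mismatch_rate per-base substitution probability applied to the
#'   emitted spacer (default 0).
#' @param gc background GC content (default 0.5).
#' @param seed integer seed.
#' @return A list with `genomes` (list of `dna_record`), `spacers` (list
#'   of `spacer_record`) and `truth` (planted coordinates, strands and
#'   flanks).
#' @export
gen_phage_cohort <- function(n_genomes, genome_len, n_protospacers,
                             spacer_len = 20,
                             pam_profile = list("N", "N", "N", "N"),
                             flank_len = 8, mismatch_rate = 0, gc = 0.5,
                             seed = 1) {
  footprint <- spacer_len + flank_len
  if (n_protospacers * footprint > 0.5 * n_genomes * genome_len) {
    stop("overcrowded: planted material exceeds half the cohort",
         call. = FALSE)
  }
  probs <- lapply(seq_len(flank_len), function(j) {
    if (j <= length(pam_profile)) profile_probs(pam_profile[[j]])
    else profile_probs("N")
  })
  bases <- c("A", "C", "G", "T")
  with_private_seed(seed, {
    genome_seqs <- lapply(seq_len(n_genomes), function(i) {
      strsplit(random_dna(genome_len, gc = gc), "")[[1]]
    })
    occupied <- lapply(seq_len(n_genomes), function(i) integer(0))
    truth_rows <- vector("list", n_protospacers)
    spacers <- vector("list", n_protospacers)
    for (p in seq_len(n_protospacers)) {
      placed <- FALSE
      for (attempt in seq_len(1000)) {
        gi <- sample.int(n_genomes, 1)
        strand <- sample(c("+", "-"), 1)
        # footprint on the forward strand: flank is 3' of the protospacer
        # on the + strand, 5' (as reverse complement) on the - strand
        s <- sample.int(genome_len - footprint + 1L, 1) - 1L
        if (strand == "+") {
          ps_start <- s; flank_start <- s + spacer_len
        } else {
          flank_start <- s; ps_start <- s + flank_len
        }
        span <- (s + 1L):(s + footprint)
        if (length(intersect(span, occupied[[gi]])) == 0) {
          occupied[[gi]] <- c(occupied[[gi]], span)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place protospacer ", p,
                        " without overlap", call. = FALSE)
      protospacer <- random_dna(spacer_len, gc = gc)
      flank <- paste(vapply(probs, function(pr) sample(bases, 1, prob = pr),
                            character(1)), collapse = "")
      if (strand == "+") {
        genome_seqs[[gi]][(ps_start + 1L):(ps_start + spacer_len)] <-
          strsplit(protospacer, "")[[1]]
        genome_seqs[[gi]][(flank_start + 1L):(flank_start + flank_len)] <-
          strsplit(flank, "")[[1]]
      } else {
        genome_seqs[[gi]][(ps_start + 1L):(ps_start + spacer_len)] <-
          strsplit(reverse_complement(protospacer), "")[[1]]
        genome_seqs[[gi]][(flank_start + 1L):(flank_start + flank_len)] <-
          strsplit(reverse_complement(flank), "")[[1]]
      }
      spacer_seq <- strsplit(protospacer, "")[[1]]
      err <- stats::runif(spacer_len) < mismatch_rate
      if (any(err)) {
        spacer_seq[err] <- vapply(spacer_seq[err], function(orig) {
          sample(setdiff(bases, orig), 1)
        }, character(1), USE.NAMES = FALSE)
      }
      spacer_id <- sprintf("spacer_%03d", p)
      spacers[[p]] <- spacer_record(spacer_id,
                                    paste(spacer_seq, collapse = ""),
                                    array_id = "synthetic_array")
      truth_rows[[p]] <- data.frame(
        spacer_id = spacer_id, genome_id = sprintf("phage_%02d", gi),
        start = ps_start, end = ps_start + spacer_len, strand = strand,
        pam_flank = flank, n_spacer_errors = sum(err),
        stringsAsFactors = FALSE)
    }
    genomes <- lapply(seq_len(n_genomes), function(i) {
      dna_record(sprintf("phage_%02d", i),
                 paste(genome_seqs[[i]], collapse = ""))
    })
    list(genomes = genomes, spacers = spacers,
         truth = truth_record("phage_cohort", seed, list(
           n_genomes = n_genomes, genome_len = genome_len,
           spacer_len = spacer_len, flank_len = flank_len,
           mismatch_rate = mismatch_rate,
           planted = do.call(rbind, truth_rows))))
  })
}

#' Generate a pre/post-sort trace pair with a planted PAM preference
#'
#' The pre-sort profile is uniform base representation plus noise; the
#' post-sort profile reweights, at each position, the bases in that
#' position's IUPAC call by `fold_enrichment` before renormalizing (an
#' `N` call leaves the position uniform: no selection).
#'
#' @param region_len randomized-region length (default 8).
#' @param true_calls IUPAC string of length `region_len` (e.g.
#'   `"NAANNNNN"`).
#' @param fold_enrichment selection strength (> 0; 1 = no selection).
#' @param noise_sd multiplicative Gaussian noise on fractions before
#'   renormalization (a coefficient of variation, matching the gel-band
#'   noise convention of [gen_gel_data()]).
#' @param seed integer seed.
#' @return A list with `pre`, `post` (`trace_profile`s) and `truth`.
#' @export
gen_trace_pair <- function(region_len = 8, true_calls, fold_enrichment,
                           noise_sd = 0, seed = 1) {
  if (fold_enrichment <= 0) stop("fold_enrichment must be > 0",
                                 call. = FALSE)
  calls <- strsplit(toupper(true_calls), "")[[1]]
  if (length(calls) != region_len) {
    stop("true_calls must have length region_len", call. = FALSE)
  }
  sets <- iupac_motif_sets(true_calls)
  bases <- c("A", "C", "G", "T")
  with_private_seed(seed, {
    noisy <- function(m) {
      m <- m * (1 + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m)))
      m <- pmax(m, 1e-6)
      m / rowSums(m)
    }
    pre <- matrix(0.25, region_len, 4, dimnames = list(NULL, bases))
    post <- t(vapply(seq_len(region_len), function(j) {
      w <- rep(1, 4)
      if (calls[j] != "N") w[bases %in% sets[[j]]] <- fold_enrichment
      w / sum(w)
    }, numeric(4)))
    colnames(post) <- bases
    list(pre = normalize_trace(noisy(pre)),
         post = normalize_trace(noisy(post)),
         truth = truth_record("trace_pair", seed, list(
           region_len = region_len, true_calls = true_calls,
           fold_enrichment = fold_enrichment, noise_sd = noise_sd)))
  })
}

#' Generate synthetic gel lanes with known cleaved fractions
#'
#' Each lane gets a substrate band `total * (1 - f)` and a single product
#' band `total * f`, both perturbed by multiplicative Gaussian noise with
#' coefficient of variation `noise_cv` and floored at 0.
#'
#' @param true_fractions named numeric vector of cleaved fractions in
#'   `[0, 1]`; names become lane ids.
#' @param total_intensity lane total before noise (default 1000).
#' @param noise_cv coefficient of variation of the band noise (>= 0).
#' @param seed integer seed.
#' @return A list with `lanes` (data.frame: `lane_id`, `substrate`,
#'   `product_1`) and `truth`.
#' @export
gen_gel_data <- function(true_fractions, total_intensity = 1000,
                         noise_cv = 0, seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  stopifnot(all(true_fractions >= 0 & true_fractions <= 1))
  ids <- names(true_fractions)
  if (is.null(ids)) ids <- sprintf("lane_%02d", seq_along(true_fractions))
  with_private_seed(seed, {
    jitter <- function(x) {
      pmax(0, x * (1 + stats::rnorm(length(x), sd = noise_cv)))
    }
    lanes <- data.frame(
      lane_id = ids,
      substrate = jitter(total_intensity * (1 - true_fractions)),
      product_1 = jitter(total_intensity * true_fractions),
      stringsAsFactors = FALSE)
    list(lanes = lanes,
         truth = truth_record("gel_data", seed, list(
           true_fractions = as.list(stats::setNames(true_fractions, ids)),
           total_intensity = total_intensity, noise_cv = noise_cv)))
  })
}

#' Generate a synthetic cleavage time course
#'
#' `f(t) = plateau * (1 - exp(-k t))` plus Gaussian noise, clipped to
#' `[0, 1]`.
#'
#' @param k first-order rate (per minute, >= 0).
#' @param plateau amplitude in `[0, 1]`.
#' @param timepoints times in minutes, strictly increasing.
#' @param noise_sd Gaussian noise sd on fractions.
#' @param seed integer seed.
#' @return A list with `time`, `fraction` and `truth`.
#' @export
gen_timecourse <- function(k, plateau, timepoints, noise_sd = 0,
                           seed = 1) {
  if (length(timepoints) == 0) stop("empty timepoints", call. = FALSE)
  stopifnot(k >= 0, plateau >= 0, plateau <= 1)
  with_private_seed(seed, {
    f <- plateau * (1 - exp(-k * timepoints)) +
      stats::rnorm(length(timepoints), sd = noise_sd)
    f <- pmin(pmax(f, 0), 1)
    list(time = timepoints, fraction = f,
         truth = truth_record("timecourse", seed, list(
           k = k, plateau = plateau, timepoints = timepoints,
           noise_sd = noise_sd)))
  })
}
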