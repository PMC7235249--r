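#' Cleaved fraction of a gel lane
#'
#' The quantification behind in vitro digest readouts: cleaved fraction =
#' integrated intensity of product bands / integrated intensity of all
#' bands (substrate + products). Scale-invariant by construction.
#'
#' @param substrate_intensity uncleaved substrate band intensity (>= 0).
#' @param product_intensities numeric vector of product band intensities.
#' @param lane_id provenance label.
#' @return A list of class `cleavage_measurement` with `fraction` in
#'   `[0, 1]` and `lane_id`.
#' @examples
#' cleaved_fraction(50, 50)$fraction   # 0.5
#' cleaved_fraction(40, c(30, 30))$fraction  # 0.6
#' @export
cleaved_fraction <- function(substrate_intensity, product_intensities,
                             lane_id = NA_character_) {
  stopifnot(substrate_intensity >= 0, all(product_intensities >= 0))
  total <- substrate_intensity + sum(product_intensities)
  if (total <= 0) {
    stop("lane '", lane_id, "' has zero total intensity", call. = FALSE)
  }
  structure(list(fraction = sum(product_intensities) / total,
                 lane_id = lane_id),
            class = "cleavage_measurement")
}

#' Replicate mean and standard deviation
#'
#' Arithmetic mean and sample (n-1) standard deviation, the error-bar
#' convention for duplicate biochemical measurements; sd is `NA` for a
#' single value.
#'
#' @param values numeric vector (length >= 1).
#' @return A list with `mean`, `sd` and `n`.
#' @export
summarize_replicates <- function(values) {
  if (length(values) == 0) stop("no replicate values", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Assemble a 4x4 NAAN cleavage matrix
#'
#' Collects cleaved fractions of 5'-NAAN-3' substrates into a 4x4 matrix
#' keyed by the 5' and 3' bases flanking the adenine dinucleotide, with
#' replicate means and standard deviations per cell.
#'
#' @param fractions numeric vector of cleaved fractions.
#' @param pams character vector of matching PAM labels; each must be of
#'   the form xAAy with x, y in A/C/G/T (e.g. "TAAG").
#' @return A list of class `naan_matrix` with `mean`, `sd` and `n` (4x4
#'   matrices, rows = 5' base, cols = 3' base) and `missing_cells`
#'   (character vector of PAMs with no measurement).
#' @export
assemble_naan_matrix <- function(fractions, pams) {
  stopifnot(length(fractions) == length(pams))
  pams <- toupper(pams)
  ok <- grepl("^[ACGT]AA[ACGT]$", pams)
  if (!all(ok)) {
    stop("PAM label(s) not of NAAN form: ",
         paste(unique(pams[!ok]), collapse = ","), call. = FALSE)
  }
  stopifnot(all(fractions >= 0 & fractions <= 1))
  bases <- c("A", "C", "G", "T")
  mk <- function() matrix(NA_real_, 4, 4, dimnames = list(bases, bases))
  mean_m <- mk(); sd_m <- mk()
  n_m <- matrix(0L, 4, 4, dimnames = list(bases, bases))
  for (five in bases) for (three in bases) {
    vals <- fractions[pams == paste0(five, "AA", three)]
    n_m[five, three] <- length(vals)
    if (length(vals) > 0) {
      s <- summarize_replicates(vals)
      mean_m[five, three] <- s$mean
      sd_m[five, three] <- s$sd
    }
  }
  missing <- outer(bases, bases, function(f, t) paste0(f, "AA", t))[n_m == 0]
  if (length(missing) > 0) {
    message("assemble_naan_matrix: no measurement for ",
            paste(missing, collapse = ","))
  }
  structure(list(mean = mean_m, sd = sd_m, n = n_m,
                 missing_cells = missing),
            class = "naan_matrix")
}

#' Fit first-order cleavage kinetics
#'
#' Fits the single-exponential saturation model
#' `f(t) = A * (1 - exp(-k * t))`, the standard irreversible-cleavage
#' kinetic form, to a digestion time course by bounded Levenberg-Marquardt
#' least squares ([minpack.lm::nlsLM()]). Initialization is deterministic:
#' `A0 = max(fraction)`, `k0 = 1 / t_half-max` (first time at which the
#' fraction reaches half its maximum); bounds `A` in `[0, 1.05]`,
#' `k >= 0`.
#'
#' @param time numeric vector of times (minutes), strictly increasing,
#'   nonnegative.
#' @param fraction cleaved fractions in `[0, 1]`, same length.
#' @return A list of class `kinetics_fit` with `k` (per minute),
#'   `plateau`, `rss` and `converged`.
#' @export
fit_first_order <- function(time, fraction) {
  stopifnot(length(time) == length(fraction))
  if (length(time) < 3) stop("need at least 3 time points", call. = FALSE)
  if (any(diff(time) <= 0) || any(time < 0)) {
    stop("times must be nonnegative and strictly increasing", call. = FALSE)
  }
  stopifnot(all(fraction >= 0 & fraction <= 1))
  if (stats::sd(fraction) == 0) {
    return(structure(list(k = 0, plateau = fraction[1], rss = 0,
                          converged = FALSE),
                     class = "kinetics_fit"))
  }
  A0 <- max(fraction)
  t_half <- time[which(fraction >= A0 / 2)[1]]
  k0 <- if (is.na(t_half) || t_half <= 0) 1 else 1 / t_half
  fit <- tryCatch(
    minpack.lm::nlsLM(fraction ~ A * (1 - exp(-k * time)),
                      start = list(A = A0, k = k0),
                      lower = c(A = 0, k = 0), upper = c(A = 1.05, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(k = k0, plateau = A0, rss = NA_real_,
                          converged = FALSE),
                     class = "kinetics_fit"))
  }
  est <- stats::coef(fit)
  structure(list(k = unname(est["k"]), plateau = unname(est["A"]),
                 rss = sum(stats::residuals(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE),
            class = "kinetics_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify a table of gel lanes
#'
#' Applies [cleaved_fraction()] to every row of a lane table (the TSV
#' format: `lane_id`, metadata columns `enzyme`, `pam`, `time_min`,
#' `ratio`, then `substrate` and `product_1..product_k`).
#'
#' @param lanes data.frame of lanes.
#' @return The input with a `fraction` column appended.
#' @export
quantify_lanes <- function(lanes) {
  stopifnot(is.data.frame(lanes), "substrate" %in% names(lanes))
  prod_cols <- grep("^product_", names(lanes), value = TRUE)
  if (length(prod_cols) == 0) stop("no product_* columns", call. = FALSE)
  lanes$fraction <- vapply(seq_len(nrow(lanes)), function(i) {
    prods <- as.numeric(lanes[i, prod_cols])
    prods <- prods[!is.na(prods)]
    cleaved_fraction(lanes$substrate[i], prods,
                     lane_id = as.character(lanes$lane_id[i]))$fraction
  }, numeric(1))
  lanes
}
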