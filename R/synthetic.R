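#' Specify a synthetic two-class single-cell cohort
#'
#' The generator emulates the statistical regime the supercell framework is
#' designed for: per-class multivariate cell distributions whose mean
#' difference is much smaller than the within-class cell-to-cell spread (so
#' single cells are non-separable), patient-level variation within each
#' class, uninformative noise measurements (zero shift), and optionally
#' skewed noise or bimodal subpopulation structure.
#'
#' A cell's value on measurement i is
#' `class mean (+/- delta_i / 2) + patient offset + subpopulation offset +
#' sigma_i * noise`, with standard normal noise by default, optionally
#' transformed to a standardized log-normal with skewness controlled per
#' measurement.
#'
#' @param n_patients_per_class Pair of patient counts (class 1, class 2).
#' @param cells_per_patient Cells simulated per patient.
#' @param n_measurements Number of measurements.
#' @param class_shift Per-measurement class mean difference delta (recycled
#'   if scalar).  Class 1 means sit at `+delta/2`, class 2 at `-delta/2`.
#' @param cell_sd Per-measurement within-class cell SD sigma (recycled).
#' @param patient_effect_sd Per-measurement SD of the additive patient-level
#'   random mean offset (recycled; 0 disables patient effects).
#' @param subpopulations Optional bimodal/multimodal cell structure shared by
#'   both classes: a list with `weights` (mixture weights summing to 1) and
#'   `offsets` (components x measurements matrix of component mean offsets).
#' @param skew Optional per-measurement skew control `s` (recycled): noise is
#'   drawn as a standardized `exp(s * z)` log-normal; 0 keeps it Gaussian.
#' @param class_names Ordered pair of class names, default `c("A", "B")`.
#' @param seed Master seed; each patient gets an independent derived stream.
#' @return A `synthetic_spec` object for [generate_cohort()].
#' @export
synthetic_spec <- function(n_patients_per_class, cells_per_patient,
                           n_measurements, class_shift, cell_sd = 1,
                           patient_effect_sd = 0, subpopulations = NULL,
                           skew = NULL, class_names = c("A", "B"), seed = 1L) {
  n_patients_per_class <- as.integer(n_patients_per_class)
  stopifnot(length(n_patients_per_class) == 2L, all(n_patients_per_class >= 1L),
            cells_per_patient >= 1L, n_measurements >= 1L)
  p <- as.integer(n_measurements)
  expand <- function(v, what) {
    if (length(v) == 1L) v <- rep(v, p)
    if (length(v) != p)
      stop(sprintf("`%s` must have length 1 or %d", what, p), call. = FALSE)
    as.numeric(v)
  }
  class_shift <- expand(class_shift, "class_shift")
  cell_sd <- expand(cell_sd, "cell_sd")
  patient_effect_sd <- expand(patient_effect_sd, "patient_effect_sd")
  if (any(cell_sd < 0) || any(patient_effect_sd < 0))
    stop("SDs must be non-negative", call. = FALSE)
  if (!is.null(skew)) skew <- expand(skew, "skew")
  if (!is.null(subpopulations)) {
    if (!is.list(subpopulations) ||
        !all(c("weights", "offsets") %in% names(subpopulations)))
      stop("`subpopulations` must be a list with `weights` and `offsets`", call. = FALSE)
    w <- subpopulations$weights
    off <- as.matrix(subpopulations$offsets)
    if (abs(sum(w) - 1) > 1e-8)
      stop("subpopulation weights must sum to 1", call. = FALSE)
    if (nrow(off) != length(w) || ncol(off) != p)
      stop(sprintf("`offsets` must be %d x %d", length(w), p), call. = FALSE)
    subpopulations <- list(weights = as.numeric(w), offsets = off)
  }
  stopifnot(length(class_names) == 2L, !anyDuplicated(class_names))
  structure(list(n_patients_per_class = n_patients_per_class,
                 cells_per_patient = as.integer(cells_per_patient),
                 n_measurements = p, class_shift = class_shift,
                 cell_sd = cell_sd, patient_effect_sd = patient_effect_sd,
                 subpopulations = subpopulations, skew = skew,
                 class_names = as.character(class_names),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# internal: standardized (mean 0, SD 1) log-normal noise with skew control s
skewed_noise <- function(z, s) {
  if (s == 0) return(z)
  m <- exp(s^2 / 2)
  (exp(s * z) - m) / sqrt((exp(s^2) - 1) * exp(s^2))
}

#' Generate a synthetic cohort
#'
#' Draws the cohort described by a [synthetic_spec()].  Patient streams are
#' independent, derived from the spec seed and patient id, so cohorts are
#' reproducible and individual patients are stable under changes to the rest
#' of the spec's patient counts.
#'
#' @param spec A [synthetic_spec()].
#' @return A [cohort()].
#' @export
#' @examples
#' spec <- synthetic_spec(c(2, 2), cells_per_patient = 200, n_measurements = 3,
#'                        class_shift = c(1, 0, 0), seed = 42)
#' generate_cohort(spec)
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("`spec` must be a synthetic_spec", call. = FALSE)
  p <- spec$n_measurements
  nc <- spec$cells_per_patient
  meas <- paste0("m", seq_len(p))
  samples <- list()
  for (cls in 1:2) {
    sign <- if (cls == 1L) +0.5 else -0.5
    class_mean <- sign * spec$class_shift
    for (i in seq_len(spec$n_patients_per_class[cls])) {
      id <- sprintf("%s_p%02d", spec$class_names[cls], i)
      vals <- with_seed(derive_seed(spec$seed, "synthetic", id), {
        offset <- stats::rnorm(p, 0, spec$patient_effect_sd)
        z <- matrix(stats::rnorm(nc * p), nc, p)
        if (!is.null(spec$skew))
          for (j in seq_len(p)) z[, j] <- skewed_noise(z[, j], spec$skew[j])
        x <- sweep(z, 2L, spec$cell_sd, `*`)
        x <- sweep(x, 2L, class_mean + offset, `+`)
        if (!is.null(spec$subpopulations)) {
          comp <- sample.int(length(spec$subpopulations$weights), nc,
                             replace = TRUE, prob = spec$subpopulations$weights)
          x <- x + spec$subpopulations$offsets[comp, , drop = FALSE]
        }
        colnames(x) <- meas
        x
      })
      samples[[id]] <- cell_sample(id, spec$class_names[cls], vals)
    }
  }
  cohort(samples, spec$class_names)
}

#' Closed-form supercell accuracy for the 1-D two-Gaussian model
#'
#' For two equal-variance Gaussian classes separated by `delta`, a supercell
#' of size n has within-class SD `sigma / sqrt(n)`, and the midpoint
#' threshold classifies a supercell correctly with probability
#' `pnorm(sqrt(n) * delta / (2 * sigma))`.  This is the independent oracle
#' for accuracy-versus-N behaviour: 0.5 at `delta = 0`, rising monotonically
#' to 1 as n grows.
#'
#' @param delta Class mean difference.
#' @param sigma Within-class single-cell SD (> 0).
#' @param n Supercell size (>= 1).
#' @return Probability of correct classification.
#' @export
#' @examples
#' expected_accuracy_1d(1, 1, 30)  # ~0.997
expected_accuracy_1d <- function(delta, sigma, n) {
  stopifnot(sigma > 0, all(n >= 1))
  stats::pnorm(sqrt(n) * abs(delta) / (2 * sigma))
}
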