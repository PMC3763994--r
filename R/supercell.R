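#' Configure supercell construction
#'
#' A supercell of size N is the arithmetic mean of the measurement vectors of
#' N randomly selected cells from one sample.  K supercells drawn this way
#' form the sample's "supercell cloud" in measurement space.  By the central
#' limit theorem, supercell marginals narrow by roughly a factor 1/sqrt(N)
#' relative to the single-cell marginals, which is what turns overlapping
#' single-cell class distributions into separable supercell distributions.
#'
#' Cells are drawn without replacement within one supercell by default, so the
#' N cells of a supercell are distinct; different supercells are drawn
#' independently and may share cells.  Setting
#' `replacement = "within_supercell_allowed"` samples with replacement, which
#' also lifts the requirement that a sample have at least N cells.
#'
#' @param size_n Supercell size N (cells averaged per supercell), >= 1.
#' @param count_k Number K of supercells per sample (default 100).
#' @param replacement `"never"` (default) or `"within_supercell_allowed"`.
#' @param seed Master seed.  Each (sample, config) pair gets its own RNG
#'   stream derived from this seed and the sample id, so adding a sample to a
#'   cohort does not change the supercells drawn for the others.
#' @return A `supercell_config` object.
#' @export
#' @examples
#' supercell_config(size_n = 500, count_k = 100, seed = 7)
supercell_config <- function(size_n, count_k = 100L,
                             replacement = c("never", "within_supercell_allowed"),
                             seed = 1L) {
  replacement <- match.arg(replacement)
  size_n <- as.integer(size_n); count_k <- as.integer(count_k)
  stopifnot(length(size_n) == 1L, size_n >= 1L,
            length(count_k) == 1L, count_k >= 1L,
            length(seed) == 1L, is.finite(seed))
  structure(list(size_n = size_n, count_k = count_k,
                 replacement = replacement, seed = as.integer(seed)),
            class = "supercell_config")
}

# internal: a config with one field changed (used when sweeping N)
config_with <- function(config, size_n = config$size_n) {
  supercell_config(size_n, config$count_k, config$replacement, config$seed)
}

#' Build a supercell sample from one cell sample
#'
#' Draws `count_k` independent random subsets of `size_n` cells and averages
#' each into one supercell.  Reproducible: the RNG stream is derived from the
#' config seed, the sample id and the config geometry, independently of any
#' other sample.
#'
#' @param sample A [cell_sample()].
#' @param config A [supercell_config()].
#' @return A `supercell_sample`: fields `sample_id`, `class_label`,
#'   `measurement_names`, `values` (K x measurements matrix of supercell
#'   means) and `config`.
#' @export
build_supercells <- function(sample, config) {
  if (!inherits(sample, "cell_sample")) stop("`sample` must be a cell_sample", call. = FALSE)
  if (!inherits(config, "supercell_config")) stop("`config` must be a supercell_config", call. = FALSE)
  n <- nrow(sample$values)
  N <- config$size_n
  K <- config$count_k
  replace <- config$replacement != "never"
  if (!replace && N > n)
    stop(sprintf("sample '%s' has %d cells, fewer than supercell size %d (replacement = \"never\")",
                 sample$sample_id, n, N), call. = FALSE)
  p <- ncol(sample$values)
  x <- sample$values
  vals <- matrix(0, K, p, dimnames = list(NULL, sample$measurement_names))
  stream <- derive_seed(config$seed, sample$sample_id, N, K, config$replacement)
  with_seed(stream, {
    for (k in seq_len(K)) {
      rows <- sample.int(n, N, replace = replace)
      vals[k, ] <- .colMeans(x[rows, , drop = FALSE], N, p)
    }
  })
  structure(list(sample_id = sample$sample_id, class_label = sample$class_label,
                 measurement_names = sample$measurement_names,
                 values = vals, config = config),
            class = "supercell_sample")
}

#' @export
print.supercell_sample <- function(x, ...) {
  cat(sprintf("<supercell_sample> '%s' [%s]: K=%d supercells of size N=%d, %d measurements\n",
              x$sample_id, x$class_label, nrow(x$values), x$config$size_n,
              ncol(x$values)))
  invisible(x)
}

#' @export
as.data.frame.supercell_sample <- function(x, ...) {
  data.frame(sample_id = x$sample_id, class_label = x$class_label,
             supercell_size = x$config$size_n,
             as.data.frame(x$values), check.names = FALSE)
}

#' Width ratio of supercell to single-cell marginal distributions
#'
#' Returns `sd(supercell marginal) / sd(single-cell marginal)` for one named
#' measurement.  For i.i.d. cells with finite variance the central limit
#' theorem gives a ratio of about 1/sqrt(N): for example N = 30 narrows the
#' distribution by a factor of about 0.18.
#'
#' @param sample A [cell_sample()].
#' @param measurement Measurement name.
#' @param config A [supercell_config()].
#' @return The width ratio (a single number).
#' @export
width_ratio <- function(sample, measurement, config) {
  if (!measurement %in% sample$measurement_names)
    stop(sprintf("sample '%s' has no measurement '%s'",
                 sample$sample_id, measurement), call. = FALSE)
  s_cell <- stats::sd(sample$values[, measurement])
  if (s_cell == 0)
    stop(sprintf("measurement '%s' has zero single-cell SD; width ratio undefined",
                 measurement), call. = FALSE)
  sc <- build_supercells(sample, config)
  stats::sd(sc$values[, measurement]) / s_cell
}
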