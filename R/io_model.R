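#' Construct a single-sample table of cells by measurements
#'
#' A `cell_sample` holds the single-cell measurement matrix of one patient or
#' cell line: rows are cells, columns are continuous measurements (marker
#' intensities, scatter, shape metrics, ...), in arbitrary per-measurement
#' units.  Values must be finite: the downstream averaging works on raw
#' measurement vectors, and silent imputation would corrupt supercell
#' statistics, so any missing or non-finite value is a hard error.
#'
#' @param sample_id Unique sample identifier (string).
#' @param class_label Class the sample belongs to, e.g. `"healthy"`.
#' @param values Numeric matrix, cells x measurements.
#' @param measurement_names Column names; defaults to `colnames(values)`.
#'   Must be unique and non-empty.
#' @return An object of class `cell_sample` with fields `sample_id`,
#'   `class_label`, `measurement_names` and `values`.
#' @seealso [cohort()], [gate_subpopulation()], [build_supercells()]
#' @export
#' @examples
#' s <- cell_sample("p1", "healthy", matrix(rnorm(20), 10, 2,
#'                  dimnames = list(NULL, c("CD3", "CD4"))))
#' nrow(s$values)
cell_sample <- function(sample_id, class_label, values,
                        measurement_names = colnames(values)) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop("`sample_id` must be a single non-empty string", call. = FALSE)
  if (!is.character(class_label) || length(class_label) != 1L || !nzchar(class_label))
    stop("`class_label` must be a single non-empty string", call. = FALSE)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(measurement_names))
    stop("`measurement_names` must be given when `values` has no column names",
         call. = FALSE)
  measurement_names <- as.character(measurement_names)
  if (ncol(values) != length(measurement_names))
    stop(sprintf("sample '%s': %d measurement names for %d columns",
                 sample_id, length(measurement_names), ncol(values)), call. = FALSE)
  if (anyDuplicated(measurement_names))
    stop(sprintf("sample '%s': duplicate measurement names (%s)", sample_id,
                 paste(unique(measurement_names[duplicated(measurement_names)]),
                       collapse = ", ")), call. = FALSE)
  if (any(!nzchar(measurement_names)))
    stop(sprintf("sample '%s': empty measurement name", sample_id), call. = FALSE)
  if (nrow(values) < 1L)
    stop(sprintf("sample '%s' has no cells", sample_id), call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("sample '%s': non-finite value at cell %d, measurement '%s'",
                 sample_id, bad[[1L]], measurement_names[bad[[2L]]]), call. = FALSE)
  }
  colnames(values) <- measurement_names
  rownames(values) <- NULL
  structure(list(sample_id = sample_id, class_label = class_label,
                 measurement_names = measurement_names, values = values),
            class = "cell_sample")
}

#' @export
print.cell_sample <- function(x, ...) {
  cat(sprintf("<cell_sample> '%s' [%s]: %d cells x %d measurements\n",
              x$sample_id, x$class_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Number of cells in a sample
#' @param sample A [cell_sample()].
#' @return Integer cell count.
#' @export
n_cells <- function(sample) nrow(sample$values)

# internal: keep a subset of a sample's cells, preserving order
subset_cells <- function(sample, idx) {
  cell_sample(sample$sample_id, sample$class_label,
              sample$values[idx, , drop = FALSE], sample$measurement_names)
}

#' Assemble a labelled two-class cohort of cell samples
#'
#' All samples must share the same measurements in the same order, sample ids
#' must be unique, and both classes must be represented.  The first element of
#' `class_names` maps to the positive side of any boundary trained downstream.
#'
#' @param samples List of [cell_sample()] objects.
#' @param class_names Ordered pair of class names.  Defaults to the unique
#'   class labels in order of first appearance.
#' @return An object of class `cohort` with fields `samples` (named by sample
#'   id) and `class_names`.
#' @export
cohort <- function(samples, class_names = NULL) {
  if (!is.list(samples) || length(samples) == 0L ||
      !all(vapply(samples, inherits, logical(1), "cell_sample")))
    stop("`samples` must be a non-empty list of cell_sample objects", call. = FALSE)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  meas <- samples[[1L]]$measurement_names
  for (s in samples)
    if (!identical(s$measurement_names, meas))
      stop(sprintf("sample '%s' has different measurements than sample '%s'",
                   s$sample_id, ids[[1L]]), call. = FALSE)
  labels <- vapply(samples, `[[`, character(1), "class_label")
  if (is.null(class_names)) class_names <- unique(labels)
  class_names <- as.character(class_names)
  if (length(class_names) != 2L || anyDuplicated(class_names))
    stop("a cohort must have exactly two distinct classes", call. = FALSE)
  if (!all(labels %in% class_names))
    stop(sprintf("class label(s) outside class_names: %s",
                 paste(setdiff(labels, class_names), collapse = ", ")), call. = FALSE)
  if (!all(class_names %in% labels))
    stop(sprintf("class '%s' has no samples",
                 setdiff(class_names, labels)[[1L]]), call. = FALSE)
  names(samples) <- ids
  structure(list(samples = samples, class_names = class_names), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  labels <- vapply(x$samples, `[[`, character(1), "class_label")
  cells <- vapply(x$samples, n_cells, integer(1))
  cat(sprintf("<cohort> %d samples (%s), %d measurements, %d cells total\n",
              length(x$samples),
              paste(sprintf("%d %s", tabulate(factor(labels, x$class_names), 2L),
                            x$class_names), collapse = " / "),
              length(x$samples[[1L]]$measurement_names), sum(cells)))
  invisible(x)
}

#' Read a cohort from a plain-text cell table
#'
#' The canonical on-disk format is one long CSV with a header row and columns
#' `sample_id`, `class_label` (optional when `class_map` is given), followed by
#' one numeric column per measurement.  Alternatively `format = "per_sample"`
#' reads a directory of per-sample CSV files (file base name = sample id, no id
#' or label columns) and takes the labels from `class_map`.  Column order and
#' per-sample row order are preserved.  No fluorescence transform or
#' compensation is applied: values are read as-is.
#'
#' @param path File (long format) or directory (per-sample format).
#' @param format `"long"` (default) or `"per_sample"`.
#' @param class_map Named character vector mapping sample id to class label;
#'   overrides/replaces a `class_label` column.
#' @param class_names Optional ordered pair of class names passed to [cohort()].
#' @param sep Field separator, `","` by default (use `"\t"` for TSV).
#' @return A validated [cohort()].
#' @export
read_cell_table <- function(path, format = c("long", "per_sample"),
                            class_map = NULL, class_names = NULL, sep = ",") {
  format <- match.arg(format)
  if (format == "per_sample") {
    if (!dir.exists(path)) stop(sprintf("directory not found: %s", path), call. = FALSE)
    files <- sort(list.files(path, pattern = "\\.(csv|tsv)$", full.names = TRUE))
    if (length(files) == 0L) stop(sprintf("no table files in %s", path), call. = FALSE)
    if (is.null(class_map))
      stop("per-sample format needs `class_map` (sample_id -> class label)", call. = FALSE)
    samples <- lapply(files, function(f) {
      id <- sub("\\.(csv|tsv)$", "", basename(f))
      if (is.na(class_map[id]))
        stop(sprintf("sample '%s' missing from class_map", id), call. = FALSE)
      df <- read_table_checked(f, sep)
      cell_sample(id, unname(class_map[id]), as_numeric_matrix(df, f))
    })
    return(cohort(samples, class_names))
  }
  df <- read_table_checked(path, sep)
  if (!"sample_id" %in% names(df))
    stop(sprintf("%s: long format requires a 'sample_id' column", path), call. = FALSE)
  ids <- as.character(df$sample_id)
  if ("class_label" %in% names(df)) labels <- as.character(df$class_label)
  else if (!is.null(class_map)) labels <- unname(class_map[ids])
  else stop(sprintf("%s: no 'class_label' column and no class_map", path), call. = FALSE)
  if (anyNA(labels)) {
    miss <- unique(ids[is.na(labels)])
    stop(sprintf("no class label for sample(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  meas_df <- df[setdiff(names(df), c("sample_id", "class_label"))]
  if (ncol(meas_df) == 0L)
    stop(sprintf("%s: no measurement columns", path), call. = FALSE)
  mat <- as_numeric_matrix(meas_df, path)
  samples <- lapply(unique(ids), function(id) {
    rows <- which(ids == id)
    lab <- unique(labels[rows])
    if (length(lab) != 1L)
      stop(sprintf("sample '%s' has conflicting class labels: %s",
                   id, paste(lab, collapse = ", ")), call. = FALSE)
    cell_sample(id, lab, mat[rows, , drop = FALSE])
  })
  cohort(samples, class_names)
}

# internal: read.csv wrapper with empty-file / parse diagnostics
read_table_checked <- function(path, sep) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, sep = sep, check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("parse error in %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0L)
    stop(sprintf("parse error in %s: no data rows", path), call. = FALSE)
  df
}

# internal: coerce measurement columns to a double matrix, naming offenders
as_numeric_matrix <- function(df, path) {
  for (nm in names(df)) {
    col <- df[[nm]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      if (anyNA(parsed) & !anyNA(col)) {
        row <- which(is.na(parsed))[1L]
        stop(sprintf("parse error in %s: non-numeric value '%s' at data row %d, column '%s'",
                     path, col[row], row, nm), call. = FALSE)
      }
      df[[nm]] <- parsed
    }
  }
  as.matrix(df)
}

#' Write a cohort to the canonical long CSV format
#'
#' Writes one row per cell with columns `sample_id`, `class_label`, then the
#' measurements.  Numeric values are rendered with 17 significant digits so
#' that [read_cell_table()] reproduces the cohort bit for bit.
#'
#' @param cohort_obj A [cohort()].
#' @param path Output file path.
#' @param sep Field separator (default `","`).
#' @return Invisibly, `path`.
#' @export
write_cell_table <- function(cohort_obj, path, sep = ",") {
  if (!inherits(cohort_obj, "cohort")) stop("`cohort_obj` must be a cohort", call. = FALSE)
  meas <- cohort_obj$samples[[1L]]$measurement_names
  if (any(meas %in% c("sample_id", "class_label")))
    stop("measurement names may not be 'sample_id' or 'class_label'", call. = FALSE)
  blocks <- lapply(cohort_obj$samples, function(s) {
    vals <- apply(s$values, 2L, function(col) sprintf("%.17g", col))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)  # 1-cell sample
    data.frame(sample_id = s$sample_id, class_label = s$class_label,
               vals, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  names(out) <- c("sample_id", "class_label", meas)
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to %s", path), call. = FALSE)
  invisible(path)
}

#' Define one sequential gating rule
#'
#' A gate keeps cells whose value on one measurement is above (`positive`) or
#' at-or-below (`negative`) a threshold.  The two directions are exact
#' complements at the same threshold, so a positive and a negative gate on the
#' same measurement partition the cells.  Thresholds are user-supplied in the
#' measurement's own units; no automatic threshold inference is done.
#'
#' @param measurement Measurement name the rule applies to.
#' @param direction `"positive"` (keep value > threshold) or `"negative"`
#'   (keep value <= threshold).
#' @param threshold Numeric cut in the same units as the measurement.
#' @return A `gating_rule` object.
#' @export
#' @examples
#' gating_rule("CD3", "positive", 1000)
gating_rule <- function(measurement, direction = c("positive", "negative"),
                        threshold) {
  direction <- match.arg(direction)
  stopifnot(is.character(measurement), length(measurement) == 1L,
            is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  structure(list(measurement = measurement, direction = direction,
                 threshold = threshold), class = "gating_rule")
}

#' Gate a sample to a cell subpopulation
#'
#' Applies a conjunction of [gating_rule()]s, emulating standard sequential
#' gating (e.g. viability-/CD3+/CD4+/CD8- for CD4+ T cells).  Cells passing
#' every rule are kept in their original order with all measurement columns
#' unchanged; the rules are conjunctive, so their order does not affect the
#' result.  A gate that removes every cell is an error, signalling that the
#' thresholds are inappropriate for the sample.
#'
#' @param sample A [cell_sample()].
#' @param rules List of [gating_rule()]s (possibly empty, which returns the
#'   sample unchanged).
#' @return The gated [cell_sample()].
#' @export
gate_subpopulation <- function(sample, rules) {
  if (!inherits(sample, "cell_sample")) stop("`sample` must be a cell_sample", call. = FALSE)
  if (inherits(rules, "gating_rule")) rules <- list(rules)
  if (length(rules) == 0L) return(sample)
  keep <- rep(TRUE, nrow(sample$values))
  for (r in rules) {
    if (!inherits(r, "gating_rule")) stop("`rules` must contain gating_rule objects", call. = FALSE)
    if (!r$measurement %in% sample$measurement_names)
      stop(sprintf("sample '%s' has no measurement '%s'",
                   sample$sample_id, r$measurement), call. = FALSE)
    v <- sample$values[, r$measurement]
    keep <- keep & if (r$direction == "positive") v > r$threshold else v <= r$threshold
  }
  if (!any(keep))
    stop(sprintf("gate removed every cell of sample '%s'", sample$sample_id),
         call. = FALSE)
  subset_cells(sample, which(keep))
}

#' Gate every sample of a cohort
#'
#' @param cohort_obj A [cohort()].
#' @param rules List of [gating_rule()]s applied to each sample.
#' @return A [cohort()] of gated samples.
#' @export
gate_cohort <- function(cohort_obj, rules) {
  cohort(lapply(cohort_obj$samples, gate_subpopulation, rules = rules),
         cohort_obj$class_names)
}
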