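#' Train a linear max-margin boundary (perceptron amplitudes)
#'
#' Fits a soft-margin support vector machine with a linear kernel on
#' z-scored points.  The components of the unit normal to the separating
#' hyperplane are the "perceptron amplitudes": a positive amplitude means the
#' measurement is higher on the positive-class side, and its absolute value
#' measures that measurement's contribution to class separation relative to
#' the others.  Amplitudes are reported in standardized space so they are
#' comparable across measurements with different intensity scales.
#'
#' With the default `margin_cost = 1000` the fit is effectively a hard-margin
#' classifier on separable input (e.g. supercells of sufficient size) while
#' still converging on non-separable single-cell input.
#'
#' @param points Numeric matrix, rows x measurements (column names used as
#'   measurement names; `m1`, `m2`, ... if absent).
#' @param labels Class label per row (character or factor, exactly 2 classes).
#' @param positive_class Class mapped to the positive-distance side.
#' @param margin_cost Soft-margin cost C (default 1000).
#' @param standardize Z-score the columns before fitting (default `TRUE`).
#'   Measurements with zero variance cannot be standardized and are dropped
#'   with a warning (recorded in the result's `dropped` field).
#' @param tolerance Optimizer convergence tolerance (passed to the SVM
#'   solver; tighten for high-precision geometry on tiny point sets).
#' @return A `linear_boundary`: `measurement_names` (retained columns),
#'   `standardizer_mean`/`standardizer_sd`, unit-norm `amplitudes`,
#'   `intercept`, `margin` (half-width, standardized units),
#'   `positive_class`, `negative_class`, `margin_cost`, `dropped`.
#' @seealso [boundary_distances()], [rank_measurements()]
#' @export
train_linear <- function(points, labels, positive_class, margin_cost = 1000,
                         standardize = TRUE, tolerance = 0.001) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (is.null(colnames(points)))
    colnames(points) <- paste0("m", seq_len(ncol(points)))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(points))
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop("training points contain a single class; boundary undefined", call. = FALSE)
  if (length(classes) > 2L)
    stop("more than two classes in training labels", call. = FALSE)
  if (!positive_class %in% classes)
    stop(sprintf("positive_class '%s' not among training labels", positive_class),
         call. = FALSE)
  stopifnot(margin_cost > 0)

  mu <- colMeans(points)
  sdv <- apply(points, 2L, stats::sd)
  if (!standardize) {
    mu[] <- 0
    sdv[] <- 1
  }
  dropped <- colnames(points)[sdv < .Machine$double.eps]
  if (length(dropped) > 0L) {
    warning(sprintf("dropping zero-variance measurement(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    keep <- setdiff(colnames(points), dropped)
    if (length(keep) == 0L)
      stop("all measurements have zero variance", call. = FALSE)
    points <- points[, keep, drop = FALSE]
    mu <- mu[keep]
    sdv <- sdv[keep]
  }
  z <- scale(points, center = mu, scale = sdv)

  y <- factor(ifelse(labels == positive_class, "pos", "neg"),
              levels = c("pos", "neg"))
  fit <- e1071::svm(x = z, y = y, kernel = "linear", cost = margin_cost,
                    scale = FALSE, tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  # orient so that decision value = z.w - rho is positive for positive_class:
  # libsvm's internal +1 class is whichever it saw first, so check both the
  # reported decision values and their column label.
  dv <- attr(stats::predict(fit, z, decision.values = TRUE), "decision.values")
  dvm <- drop(z %*% w) - rho
  if (sum(abs(dvm - dv[, 1L])) > sum(abs(dvm + dv[, 1L]))) {
    w <- -w; rho <- -rho
  }
  if (strsplit(colnames(dv)[1L], "/")[[1L]][1L] != "pos") {
    w <- -w; rho <- -rho
  }
  wn <- sqrt(sum(w^2))
  if (wn == 0) stop("degenerate fit: zero normal vector", call. = FALSE)
  structure(list(measurement_names = colnames(points),
                 standardizer_mean = mu, standardizer_sd = sdv,
                 amplitudes = stats::setNames(w / wn, colnames(points)),
                 intercept = -rho / wn,
                 margin = 1 / wn,
                 positive_class = positive_class,
                 negative_class = setdiff(classes, positive_class),
                 margin_cost = margin_cost,
                 dropped = dropped),
            class = "linear_boundary")
}

#' @export
print.linear_boundary <- function(x, ...) {
  cat(sprintf("<linear_boundary> %s (+) vs %s (-), %d measurements, margin %.4g\n",
              x$positive_class, x$negative_class, length(x$amplitudes), x$margin))
  amps <- sort(abs(x$amplitudes), decreasing = TRUE)
  show <- utils::head(amps, 5L)
  cat("  top |amplitudes|:",
      paste(sprintf("%s=%.3f", names(show), show), collapse = ", "), "\n")
  invisible(x)
}

#' Signed Euclidean distances from the boundary
#'
#' Distances are measured in standardized space; points on the
#' `positive_class` side have positive distance.  A point exactly on the
#' hyperplane has distance 0 (and is counted on the negative side by the
#' classification rule `distance > 0`).
#'
#' @param boundary A [train_linear()] result.
#' @param points Matrix whose columns include the boundary's measurements.
#' @return Numeric vector of signed distances, one per row.
#' @export
boundary_distances <- function(boundary, points) {
  if (!inherits(boundary, "linear_boundary")) stop("`boundary` must be a linear_boundary", call. = FALSE)
  points <- as.matrix(points)
  if (is.null(colnames(points)) && ncol(points) == length(boundary$measurement_names))
    colnames(points) <- boundary$measurement_names
  missing <- setdiff(boundary$measurement_names, colnames(points))
  if (length(missing) > 0L)
    stop(sprintf("points lack boundary measurement(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  z <- scale(points[, boundary$measurement_names, drop = FALSE],
             center = boundary$standardizer_mean,
             scale = boundary$standardizer_sd)
  drop(z %*% boundary$amplitudes) + boundary$intercept
}

#' Rank measurements by perceptron amplitude
#'
#' Orders the boundary's measurements by decreasing absolute amplitude, i.e.
#' from most to least relevant for class separation.  Ties are broken by the
#' original column order (stable), for reproducibility.
#'
#' @param boundary A [train_linear()] result.
#' @return A `feature_ranking`: `ordered_measurements`, matching
#'   `abs_amplitudes` (non-increasing) and signed `amplitudes`.
#' @export
rank_measurements <- function(boundary) {
  if (!inherits(boundary, "linear_boundary")) stop("`boundary` must be a linear_boundary", call. = FALSE)
  a <- boundary$amplitudes
  ord <- order(-abs(a), seq_along(a))
  structure(list(ordered_measurements = names(a)[ord],
                 abs_amplitudes = unname(abs(a)[ord]),
                 amplitudes = unname(a[ord])),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("<feature_ranking>\n")
  print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' @export
as.data.frame.feature_ranking <- function(x, ...) {
  data.frame(rank = seq_along(x$ordered_measurements),
             measurement = x$ordered_measurements,
             amplitude = x$amplitudes,
             abs_amplitude = x$abs_amplitudes)
}

#' Classification accuracy over a grid of supercell sizes and measure counts
#'
#' For each supercell size N: build each sample's supercell cloud, fit the
#' linear boundary on all measurements, rank them by absolute amplitude, then
#' for each M refit using only the top M measurements and report the fraction
#' of evaluation supercells classified on their class's side.  The ranking is
#' recomputed at each N because it is size-dependent for small supercells.
#'
#' `evaluation = "held_out"` (default) randomly splits each sample's cells in
#' half before supercell construction, trains on supercells from one half and
#' evaluates on supercells from the other, so no cell contributes to both.
#' `evaluation = "training"` evaluates on the training supercells themselves.
#'
#' @param cohort_obj A [cohort()].
#' @param n_values Supercell sizes N to sweep.
#' @param m_values Numbers of top-ranked measurements M to sweep.
#' @param config A [supercell_config()] (its `size_n` is overridden by
#'   `n_values`).
#' @param evaluation `"held_out"` or `"training"`.
#' @param margin_cost Soft-margin cost passed to [train_linear()].
#' @return An `accuracy_grid`: `n_values`, `m_values`, `accuracy` matrix
#'   (rows = N, columns = M, fractions in \[0, 1\]), `evaluation`.
#' @export
accuracy_grid <- function(cohort_obj, n_values, m_values, config,
                          evaluation = c("held_out", "training"),
                          margin_cost = 1000) {
  evaluation <- match.arg(evaluation)
  if (!inherits(cohort_obj, "cohort")) stop("`cohort_obj` must be a cohort", call. = FALSE)
  n_values <- as.integer(n_values)
  m_values <- as.integer(m_values)
  p <- length(cohort_obj$samples[[1L]]$measurement_names)
  stopifnot(length(n_values) >= 1L, all(n_values >= 1L),
            length(m_values) >= 1L, all(m_values >= 1L), all(m_values <= p))

  samples <- cohort_obj$samples
  need <- max(n_values) * (if (evaluation == "held_out") 2L else 1L)
  if (config$replacement == "never") {
    for (s in samples)
      if (n_cells(s) < need)
        stop(sprintf("sample '%s' has %d cells; %d needed for N = %d (%s evaluation)",
                     s$sample_id, n_cells(s), need, max(n_values), evaluation),
             call. = FALSE)
  }

  if (evaluation == "held_out") {
    halves <- lapply(samples, function(s) {
      idx <- with_seed(derive_seed(config$seed, s$sample_id, "cellsplit"),
                       sample.int(n_cells(s)))
      cut <- floor(n_cells(s) / 2)
      list(train = subset_cells(s, sort(idx[seq_len(cut)])),
           eval = subset_cells(s, sort(idx[(cut + 1L):n_cells(s)])))
    })
  }

  pos <- cohort_obj$class_names[1L]
  acc <- matrix(NA_real_, length(n_values), length(m_values),
                dimnames = list(N = n_values, M = m_values))
  for (i in seq_along(n_values)) {
    cfg <- config_with(config, size_n = n_values[i])
    if (evaluation == "held_out") {
      sc_train <- lapply(halves, function(h) build_supercells(h$train, cfg))
      sc_eval <- lapply(halves, function(h) build_supercells(h$eval, cfg))
    } else {
      sc_train <- lapply(samples, build_supercells, config = cfg)
      sc_eval <- sc_train
    }
    xt <- do.call(rbind, lapply(sc_train, `[[`, "values"))
    yt <- rep(vapply(sc_train, `[[`, character(1), "class_label"),
              each = cfg$count_k)
    xe <- do.call(rbind, lapply(sc_eval, `[[`, "values"))
    ye <- rep(vapply(sc_eval, `[[`, character(1), "class_label"),
              each = cfg$count_k)
    fit_all <- train_linear(xt, yt, pos, margin_cost = margin_cost)
    ranking <- rank_measurements(fit_all)
    for (j in seq_along(m_values)) {
      cols <- ranking$ordered_measurements[seq_len(m_values[j])]
      fit <- if (m_values[j] >= length(fit_all$amplitudes)) fit_all
             else train_linear(xt[, cols, drop = FALSE], yt, pos,
                               margin_cost = margin_cost)
      d <- boundary_distances(fit, xe[, fit$measurement_names, drop = FALSE])
      acc[i, j] <- mean((d > 0) == (ye == pos))
    }
  }
  structure(list(n_values = n_values, m_values = m_values, accuracy = acc,
                 evaluation = evaluation), class = "accuracy_grid")
}

#' @export
print.accuracy_grid <- function(x, ...) {
  cat(sprintf("<accuracy_grid> (%s evaluation)\n", x$evaluation))
  print(round(x$accuracy, 3))
  invisible(x)
}

#' @export
as.data.frame.accuracy_grid <- function(x, ...) {
  data.frame(n = rep(x$n_values, times = length(x$m_values)),
             m = rep(x$m_values, each = length(x$n_values)),
             accuracy = as.vector(x$accuracy))
}

#' Project points onto their top singular directions
#'
#' Mean-centers the points and projects them onto the leading right singular
#' vectors, ordered by decreasing singular value.  This is the unsupervised
#' dimension-reduction baseline: the optimal axes it selects capture overall
#' variance, not class differences, so strongly overlapping classes typically
#' remain overlapping in the projection.
#'
#' @param points Numeric matrix, rows x measurements.
#' @param components Number of leading components (<= number of measurements;
#'   components beyond the matrix rank come back as ~0 columns).
#' @return Matrix rows x components of projection scores.
#' @export
svd_project <- function(points, components = 2L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  components <- as.integer(components)
  if (components < 1L || components > ncol(points))
    stop(sprintf("`components` must be between 1 and %d", ncol(points)), call. = FALSE)
  centered <- scale(points, center = TRUE, scale = FALSE)
  dec <- svd(centered, nu = 0L, nv = components)
  centered %*% dec$v
}
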