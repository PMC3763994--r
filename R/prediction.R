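#' Configure leave-one-patient-out jackknife prediction
#'
#' @param supercell A [supercell_config()] (N, K, replacement policy, seed).
#' @param threshold Prediction threshold theta in (0.5, 1], default 0.95: a
#'   patient is called for a class only when at least that fraction of their
#'   supercell cloud falls on the class's side of the boundary; otherwise the
#'   patient is left unclassified.  Values at or below 0.5 are rejected since
#'   both classes could then qualify at once.
#' @param m_values Numbers of top-ranked measurements to sweep (default: all
#'   prefixes, filled in at run time).
#' @param ranking_scope `"per_fold"` (default): the ranking is recomputed
#'   within each fold from the training patients only, so no information from
#'   the held-out patient leaks into measurement selection.  `"global"`: one
#'   cohort-wide ranking fitted on all patients is reused in every fold.
#' @param margin_cost Soft-margin cost for [train_linear()].
#' @return A `jackknife_config` object.
#' @export
jackknife_config <- function(supercell, threshold = 0.95, m_values = NULL,
                             ranking_scope = c("per_fold", "global"),
                             margin_cost = 1000) {
  ranking_scope <- match.arg(ranking_scope)
  if (!inherits(supercell, "supercell_config"))
    stop("`supercell` must be a supercell_config", call. = FALSE)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0.5, threshold <= 1)
  if (!is.null(m_values)) {
    m_values <- as.integer(m_values)
    stopifnot(all(m_values >= 1L))
  }
  structure(list(supercell = supercell, threshold = threshold,
                 m_values = m_values, ranking_scope = ranking_scope,
                 margin_cost = margin_cost),
            class = "jackknife_config")
}

#' Turn a positive-side fraction into a diagnostic call
#'
#' Implements the abstention rule: the first class is called when
#' `fraction_positive >= theta`, the second when
#' `1 - fraction_positive >= theta`, and `"unclassified"` otherwise.  The
#' comparison is `>=`, so a cloud exactly at the threshold is classified.
#'
#' @param fraction_positive Fraction(s) of a patient's supercells on the
#'   positive side of the boundary.
#' @param theta Prediction threshold in (0.5, 1].
#' @param class_names Ordered pair: positive-side class first.
#' @return Character vector of calls.
#' @export
#' @examples
#' call_from_fraction(c(1, 0.6, 0.02), 0.95, c("healthy", "diseased"))
call_from_fraction <- function(fraction_positive, theta, class_names) {
  stopifnot(theta > 0.5, theta <= 1, length(class_names) == 2L,
            all(fraction_positive >= 0 & fraction_positive <= 1))
  ifelse(fraction_positive >= theta, class_names[1L],
         ifelse(1 - fraction_positive >= theta, class_names[2L],
                "unclassified"))
}

# internal: per-patient positive-side fractions for every fold and M.
# The K supercells of each patient are built once and reused: across folds,
# and across M within a fold, so M-curves differ only by measure set.
jackknife_fractions <- function(cohort_obj, config) {
  samples <- cohort_obj$samples
  labels <- vapply(samples, `[[`, character(1), "class_label")
  for (cl in cohort_obj$class_names)
    if (sum(labels == cl) < 2L)
      stop(sprintf("class '%s' has fewer than 2 patients; a fold would lose the class",
                   cl), call. = FALSE)
  p <- length(samples[[1L]]$measurement_names)
  m_values <- config$m_values %||% seq_len(p)
  if (max(m_values) > p)
    stop(sprintf("m_values go up to %d but there are %d measurements",
                 max(m_values), p), call. = FALSE)
  pos <- cohort_obj$class_names[1L]
  scs <- lapply(samples, build_supercells, config = config$supercell)
  K <- config$supercell$count_k

  global_ranking <- NULL
  if (config$ranking_scope == "global") {
    x_all <- do.call(rbind, lapply(scs, `[[`, "values"))
    y_all <- rep(labels, each = K)
    global_ranking <- rank_measurements(
      train_linear(x_all, y_all, pos, margin_cost = config$margin_cost))
  }

  frac <- matrix(NA_real_, length(samples), length(m_values),
                 dimnames = list(names(samples), m_values))
  for (i in seq_along(samples)) {
    xt <- do.call(rbind, lapply(scs[-i], `[[`, "values"))
    yt <- rep(labels[-i], each = K)
    fit_all <- train_linear(xt, yt, pos, margin_cost = config$margin_cost)
    ranking <- global_ranking %||% rank_measurements(fit_all)
    for (j in seq_along(m_values)) {
      cols <- ranking$ordered_measurements[seq_len(m_values[j])]
      fit <- if (m_values[j] >= length(fit_all$amplitudes)) fit_all
             else train_linear(xt[, cols, drop = FALSE], yt, pos,
                               margin_cost = config$margin_cost)
      d <- boundary_distances(fit, scs[[i]]$values[, fit$measurement_names,
                                                   drop = FALSE])
      frac[i, j] <- mean(d > 0)
    }
  }
  list(fractions = frac, true_class = labels, m_values = m_values,
       class_names = cohort_obj$class_names)
}

# internal: apply the theta rule and tally cohort percentages
summarise_fractions <- function(fr, theta) {
  m_values <- fr$m_values
  n_pat <- length(fr$true_class)
  preds <- vector("list", length(m_values))
  summary <- data.frame(m = m_values, percent_correct = NA_real_,
                        percent_unclassified = NA_real_,
                        percent_incorrect = NA_real_)
  for (j in seq_along(m_values)) {
    call <- call_from_fraction(fr$fractions[, j], theta, fr$class_names)
    preds[[j]] <- data.frame(sample_id = rownames(fr$fractions),
                             true_class = unname(fr$true_class),
                             fraction_positive = unname(fr$fractions[, j]),
                             call = call, m = m_values[j],
                             row.names = NULL)
    summary$percent_correct[j] <- 100 * mean(call == fr$true_class)
    summary$percent_unclassified[j] <- 100 * mean(call == "unclassified")
    summary$percent_incorrect[j] <-
      100 * mean(call != "unclassified" & call != fr$true_class)
  }
  list(summary = summary, predictions = do.call(rbind, preds))
}

#' Leave-one-patient-out jackknife diagnosis
#'
#' For each patient: supercell clouds are built for all other patients, the
#' linear boundary is fitted on all measurements, measurements are ranked by
#' absolute amplitude, and for each M the boundary is refitted on the top M
#' measurements and the held-out patient's own supercell cloud is classified.
#' A patient is called for a class when at least `threshold` of their K
#' supercells fall on that class's side; clouds cut by the boundary are left
#' unclassified.  Cohort percentages of correct / unclassified / incorrect
#' patients are tallied per M and always sum to 100.
#'
#' @param cohort_obj A [cohort()] with at least 2 patients per class.
#' @param config A [jackknife_config()].
#' @return A `jackknife_summary`: `summary` data frame (per M: the three
#'   percentages), `predictions` data frame (per patient and M: positive-side
#'   fraction and call), `fractions` matrix (patients x M), `theta`,
#'   `m_values`, `class_names`, `config`.
#' @export
jackknife_predict <- function(cohort_obj, config) {
  if (!inherits(cohort_obj, "cohort")) stop("`cohort_obj` must be a cohort", call. = FALSE)
  if (!inherits(config, "jackknife_config")) stop("`config` must be a jackknife_config", call. = FALSE)
  fr <- jackknife_fractions(cohort_obj, config)
  out <- summarise_fractions(fr, config$threshold)
  structure(list(summary = out$summary, predictions = out$predictions,
                 fractions = fr$fractions, theta = config$threshold,
                 m_values = fr$m_values, class_names = fr$class_names,
                 config = config),
            class = "jackknife_summary")
}

#' @export
print.jackknife_summary <- function(x, ...) {
  cat(sprintf("<jackknife_summary> %d patients, theta = %.2f (%s ranking)\n",
              nrow(x$fractions), x$theta, x$config$ranking_scope))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Smallest number of top-ranked measurements meeting a jackknife criterion
#'
#' Runs the jackknife over `m_values` (all prefixes by default) and returns
#' the smallest M with no incorrect predictions
#' (`criterion = "zero_incorrect"`) or with neither incorrect nor
#' unclassified patients (`"zero_incorrect_and_unclassified"`).  When no M
#' meets the criterion the result is `NA` with attribute `achieved = FALSE`;
#' this is a reportable outcome, not an error.
#'
#' @param cohort_obj A [cohort()].
#' @param config A [jackknife_config()].
#' @param criterion `"zero_incorrect"` (default) or
#'   `"zero_incorrect_and_unclassified"`.
#' @return Integer M (with the full `jackknife_summary` attached as attribute
#'   `summary`), or `NA` if the criterion is never met.
#' @export
minimal_measures <- function(cohort_obj, config,
                             criterion = c("zero_incorrect",
                                           "zero_incorrect_and_unclassified")) {
  criterion <- match.arg(criterion)
  jk <- jackknife_predict(cohort_obj, config)
  s <- jk$summary[order(jk$summary$m), ]
  ok <- s$percent_incorrect == 0
  if (criterion == "zero_incorrect_and_unclassified")
    ok <- ok & s$percent_unclassified == 0
  m <- if (any(ok)) as.integer(s$m[which(ok)[1L]]) else NA_integer_
  structure(m, achieved = !is.na(m), summary = jk)
}

#' Smallest supercell size reaching an accuracy floor
#'
#' Sweeps candidate supercell sizes (ascending) at a fixed number of
#' top-ranked measurements M and returns the smallest N whose supercell
#' classification accuracy reaches `accuracy_floor`.  `NA` with attribute
#' `achieved = FALSE` when no candidate reaches the floor.
#'
#' @param cohort_obj A [cohort()].
#' @param config A [supercell_config()].
#' @param m Number of top-ranked measurements to use.
#' @param n_candidates Candidate supercell sizes, sorted ascending.
#' @param accuracy_floor Required fraction of correctly classified supercells
#'   (default 0.95).
#' @param evaluation Passed to [accuracy_grid()] (default `"held_out"`).
#' @param margin_cost Soft-margin cost for [train_linear()].
#' @return Integer N (with the [accuracy_grid()] attached as attribute
#'   `grid`), or `NA`.
#' @export
minimal_supercell_size <- function(cohort_obj, config, m, n_candidates,
                                   accuracy_floor = 0.95,
                                   evaluation = c("held_out", "training"),
                                   margin_cost = 1000) {
  evaluation <- match.arg(evaluation)
  n_candidates <- as.integer(n_candidates)
  if (is.unsorted(n_candidates))
    stop("`n_candidates` must be sorted ascending", call. = FALSE)
  grid <- accuracy_grid(cohort_obj, n_candidates, m, config,
                        evaluation = evaluation, margin_cost = margin_cost)
  hit <- which(grid$accuracy[, 1L] >= accuracy_floor)
  n <- if (length(hit) > 0L) n_candidates[hit[1L]] else NA_integer_
  structure(n, achieved = !is.na(n), grid = grid)
}

#' Sensitivity of jackknife outcomes to the prediction threshold
#'
#' Re-applies the abstention rule at each threshold to one fixed set of
#' jackknife positive-side fractions (the expensive fits are done once), and
#' reports, for each outcome, the largest change in its cohort percentage
#' across any pair of thresholds.  Raising the threshold can only move
#' patients from classified to unclassified, so percent_unclassified is
#' non-decreasing and percent_incorrect non-increasing in theta.
#'
#' @param cohort_obj A [cohort()].
#' @param config A [jackknife_config()] (its `threshold` is ignored here).
#' @param thetas Thresholds to sweep, each in (0.5, 1].
#' @return A `threshold_sweep`: `thetas`, `summaries` (long data frame with
#'   columns theta, m and the three percentages), `max_variation` (named
#'   vector: largest percentage-point range per outcome over thresholds and
#'   M), `fractions`.
#' @export
threshold_sweep <- function(cohort_obj, config, thetas) {
  stopifnot(length(thetas) >= 1L, all(thetas > 0.5), all(thetas <= 1))
  fr <- jackknife_fractions(cohort_obj, config)
  summaries <- do.call(rbind, lapply(thetas, function(th) {
    s <- summarise_fractions(fr, th)$summary
    cbind(theta = th, s)
  }))
  outcomes <- c("percent_correct", "percent_unclassified", "percent_incorrect")
  max_variation <- vapply(outcomes, function(oc) {
    per_m <- tapply(summaries[[oc]], summaries$m, function(v) diff(range(v)))
    max(per_m)
  }, numeric(1))
  structure(list(thetas = thetas, summaries = summaries,
                 max_variation = max_variation, fractions = fr$fractions),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> theta in [%.2f, %.2f] (%d values)\n",
              min(x$thetas), max(x$thetas), length(x$thetas)))
  cat("  max variation (percentage points of cohort):\n")
  print(round(x$max_variation, 2))
  invisible(x)
}
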