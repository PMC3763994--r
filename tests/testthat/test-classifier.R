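test_that("a symmetric 1-D pair is split at its midpoint", {
  X <- matrix(c(2, 0), 2, 1, dimnames = list(NULL, "x"))
  fit <- train_linear(X, c("healthy", "diseased"), "healthy",
                      margin_cost = 1e6, tolerance = 1e-8)
  d <- boundary_distances(fit, X)
  expect_equal(d[1], -d[2], tolerance = 1e-6)
  expect_gt(d[1], 0)
  # the raw-space midpoint lies on the hyperplane
  expect_equal(boundary_distances(fit, matrix(1, 1, 1,
                                              dimnames = list(NULL, "x")))[1],
               0, tolerance = 1e-6)
})

test_that("an axis-aligned 4-point set yields normal (1, 0) and unit margins", {
  X <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  colnames(X) <- c("m1", "m2")
  y <- c("neg", "neg", "pos", "pos")
  fit <- train_linear(X, y, "pos", margin_cost = 1e6, tolerance = 1e-10)

  expect_equal(abs(fit$amplitudes[["m1"]]), 1, tolerance = 1e-6)
  expect_equal(fit$amplitudes[["m2"]], 0, tolerance = 1e-6)

  # all four points are support vectors at +/- one margin width
  d <- boundary_distances(fit, X)
  expect_equal(abs(d), rep(fit$margin, 4), tolerance = 1e-6)
  expect_equal(sign(d), c(-1, -1, 1, 1))

  # reflecting a point through the hyperplane negates its distance
  pt <- matrix(c(1.7, 0.3), 1, 2, dimnames = list(NULL, c("m1", "m2")))
  z <- scale(pt, fit$standardizer_mean, fit$standardizer_sd)
  zr <- z - 2 * drop(z %*% fit$amplitudes + fit$intercept) * fit$amplitudes
  refl <- sweep(sweep(zr, 2, fit$standardizer_sd, `*`), 2,
                fit$standardizer_mean, `+`)
  colnames(refl) <- colnames(pt)
  expect_equal(boundary_distances(fit, refl), -boundary_distances(fit, pt),
               tolerance = 1e-8)

  expect_error(boundary_distances(fit, X[, 1, drop = FALSE]), "lack boundary")
})

test_that("the fitted margin matches an exhaustive max-margin search", {
  set.seed(91)
  for (rep in 1:40) {
    n1 <- sample(2:3, 1); n2 <- sample(2:3, 1)
    repeat {
      X <- rbind(matrix(rnorm(n1 * 2, 2.5), n1, 2),
                 matrix(rnorm(n2 * 2, -2.5), n2, 2))
      y <- c(rep(1, n1), rep(-1, n2))
      oracle <- brute_force_margin(X, y)
      if (oracle > 0.3) break  # keep clearly separable sets
    }
    colnames(X) <- c("a", "b")
    fit <- train_linear(X, ifelse(y > 0, "P", "N"), "P", margin_cost = 1e7,
                        standardize = FALSE, tolerance = 1e-9)
    expect_equal(fit$margin, oracle, tolerance = 1e-6)
  }
})

test_that("measurements are ranked by decreasing |amplitude| with stable ties", {
  mk_boundary <- function(a) {
    structure(list(measurement_names = names(a),
                   standardizer_mean = stats::setNames(rep(0, length(a)), names(a)),
                   standardizer_sd = stats::setNames(rep(1, length(a)), names(a)),
                   amplitudes = a, intercept = 0, margin = 1,
                   positive_class = "P", negative_class = "N",
                   margin_cost = 1000, dropped = character()),
              class = "linear_boundary")
  }
  r <- rank_measurements(mk_boundary(c(m1 = 0.1, m2 = -0.9, m3 = 0.3)))
  expect_identical(r$ordered_measurements, c("m2", "m3", "m1"))
  expect_identical(r$abs_amplitudes, c(0.9, 0.3, 0.1))
  expect_true(all(diff(r$abs_amplitudes) <= 0))

  tied <- rank_measurements(mk_boundary(c(m1 = 0.5, m2 = -0.5, m3 = 0.5)))
  expect_identical(tied$ordered_measurements, c("m1", "m2", "m3"))

  df <- as.data.frame(r)
  expect_identical(df$measurement, r$ordered_measurements)
  expect_identical(df$rank, 1:3)
})

test_that("a shift confined to one measurement dominates the ranking as N grows", {
  spec <- synthetic_spec(c(1, 1), cells_per_patient = 8000, n_measurements = 5,
                         class_shift = c(1, 0, 0, 0, 0), seed = 92)
  co <- generate_cohort(spec)
  amp_at <- function(n) {
    pool <- pool_supercells(co, supercell_config(n, 400, seed = 17))
    fit <- train_linear(pool$x, pool$y, co$class_names[1], margin_cost = 10)
    list(rank = rank_measurements(fit)$ordered_measurements[1],
         amp = abs(fit$amplitudes[["m1"]]))
  }
  a1 <- amp_at(1); a100 <- amp_at(100)
  expect_identical(a100$rank, "m1")
  expect_gt(a100$amp, 0.95)
  expect_gt(a100$amp, a1$amp)
})

test_that("amplitudes, ranking and accuracy are invariant to measurement rescaling", {
  spec <- synthetic_spec(c(2, 2), cells_per_patient = 500, n_measurements = 4,
                         class_shift = c(1, 0.5, 0, 0), seed = 93)
  co <- generate_cohort(spec)
  scaled <- cohort(lapply(co$samples, function(s) {
    v <- s$values
    v[, 2] <- v[, 2] * 1000   # e.g. a different fluorescence unit
    cell_sample(s$sample_id, s$class_label, v)
  }), co$class_names)

  cfg <- supercell_config(20, 100, seed = 94)
  p1 <- pool_supercells(co, cfg); p2 <- pool_supercells(scaled, cfg)
  f1 <- train_linear(p1$x, p1$y, co$class_names[1])
  f2 <- train_linear(p2$x, p2$y, co$class_names[1])
  expect_equal(f1$amplitudes, f2$amplitudes, tolerance = 1e-8)
  expect_identical(rank_measurements(f1)$ordered_measurements,
                   rank_measurements(f2)$ordered_measurements)

  g1 <- accuracy_grid(co, c(1, 20), c(1, 4), cfg, evaluation = "training",
                      margin_cost = 10)
  g2 <- accuracy_grid(scaled, c(1, 20), c(1, 4), cfg, evaluation = "training",
                      margin_cost = 10)
  expect_equal(g1$accuracy, g2$accuracy, tolerance = 1e-12)
})

test_that("swapping the positive class negates geometry but not accuracy", {
  spec <- synthetic_spec(c(2, 2), cells_per_patient = 400, n_measurements = 3,
                         class_shift = c(1, 0.4, 0), seed = 95)
  co <- generate_cohort(spec)
  pool <- pool_supercells(co, supercell_config(15, 100, seed = 96))
  fa <- train_linear(pool$x, pool$y, co$class_names[1])
  fb <- train_linear(pool$x, pool$y, co$class_names[2])
  expect_equal(fa$amplitudes, -fb$amplitudes, tolerance = 1e-6)
  expect_equal(boundary_distances(fa, pool$x), -boundary_distances(fb, pool$x),
               tolerance = 1e-6)
  acc_a <- mean((boundary_distances(fa, pool$x) > 0) == (pool$y == fa$positive_class))
  acc_b <- mean((boundary_distances(fb, pool$x) > 0) == (pool$y == fb$positive_class))
  expect_equal(acc_a, acc_b, tolerance = 1e-12)
})

test_that("degenerate training input is reported, not silently mangled", {
  X <- cbind(m1 = rnorm(20), m2 = rep(3, 20))
  y <- rep(c("a", "b"), 10)
  expect_warning(fit <- train_linear(X, y, "a"), "zero-variance.*m2")
  expect_identical(fit$dropped, "m2")
  expect_identical(fit$measurement_names, "m1")

  expect_error(train_linear(X, rep("a", 20), "a"), "single class")
  expect_error(train_linear(X, rep(c("a", "b", "c"), length.out = 20), "a"),
               "more than two")
  expect_error(train_linear(X, y, "zz"), "not among")
})

test_that("svd projection matches an eigendecomposition oracle", {
  set.seed(97)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  proj <- svd_project(X, 3)
  # oracle: eigenvectors of the covariance matrix of centered data
  C <- stats::cov(scale(X, scale = FALSE)) * (19 / 20)
  ev <- eigen(C, symmetric = TRUE)
  oracle <- scale(X, scale = FALSE) %*% ev$vectors
  for (j in 1:3)  # columns agree up to sign
    expect_equal(abs(proj[, j]), abs(oracle[, j]), tolerance = 1e-8)
  # variance ordered by decreasing singular value
  v <- apply(proj, 2, stats::var)
  expect_true(all(diff(v) <= 1e-12))

  # rank-1 input: everything beyond the first component is numerically zero
  r1 <- outer(rnorm(15), c(1, 2, 3))
  colnames(r1) <- c("a", "b", "c")
  p1 <- svd_project(r1, 3)
  expect_lt(stats::var(p1[, 2]), 1e-20)
  expect_error(svd_project(X, 4), "between 1 and 3")
})

test_that("variance-led projection fails where supercell classification succeeds", {
  # the class shift sits in a low-variance measurement, so the top-2 singular
  # directions chase the noisy measurements and the projection stays mixed
  spec <- synthetic_spec(c(1, 1), cells_per_patient = 3000, n_measurements = 5,
                         class_shift = c(1, 0, 0, 0, 0),
                         cell_sd = c(1, 2, 2, 2, 2), seed = 98)
  co <- generate_cohort(spec)
  cells <- do.call(rbind, lapply(co$samples, `[[`, "values"))
  labels <- rep(vapply(co$samples, `[[`, character(1), "class_label"), each = 3000)

  proj <- svd_project(cells, 2)
  colnames(proj) <- c("u1", "u2")
  fit <- train_linear(proj, labels, co$class_names[1], margin_cost = 10)
  acc_svd <- mean((boundary_distances(fit, proj) > 0) == (labels == co$class_names[1]))
  expect_lt(acc_svd, 0.62)  # near chance: projection never saw the labels

  g <- accuracy_grid(co, 100, 5, supercell_config(100, 300, seed = 99),
                     evaluation = "held_out", margin_cost = 10)
  expect_gt(g$accuracy[1, 1], 0.95)
})

test_that("accuracy sits at chance for identical classes and grows with N and M", {
  null_spec <- synthetic_spec(c(2, 2), cells_per_patient = 1000,
                              n_measurements = 3, class_shift = 0, seed = 100)
  g0 <- accuracy_grid(generate_cohort(null_spec), c(1, 25), c(1, 3),
                      supercell_config(1, 250, seed = 101),
                      evaluation = "held_out", margin_cost = 10)
  expect_true(all(abs(g0$accuracy - 0.5) < 0.08))

  # informative measurements of decreasing strength: accuracy should be
  # non-decreasing (within Monte-Carlo tolerance) along both axes
  spec <- synthetic_spec(c(1, 1), cells_per_patient = 12000, n_measurements = 4,
                         class_shift = c(0.8, 0.5, 0.3, 0.2), seed = 102)
  g <- accuracy_grid(generate_cohort(spec), c(1, 8, 40), c(1, 2, 4),
                     supercell_config(1, 500, seed = 103),
                     evaluation = "held_out", margin_cost = 10)
  expect_true(all(diff(g$accuracy) > -0.03))          # down the N axis
  expect_true(all(t(diff(t(g$accuracy))) > -0.03))    # along the M axis
  expect_true(all(g$accuracy >= 0 & g$accuracy <= 1))

  df <- as.data.frame(g)
  expect_identical(nrow(df), 9L)
  expect_equal(df$accuracy[df$n == 8 & df$m == 2],
               g$accuracy["8", "2"])
})

test_that("rank order fluctuates for single cells but stabilizes for large supercells", {
  # skewed, overlapping single-cell intensities: the hinge solution at N = 1
  # sees a very different geometry than the near-Gaussian large-N clouds
  rank_at <- function(co, n, seed) {
    pool <- pool_supercells(co, supercell_config(n, 1000, seed = seed))
    r <- rank_measurements(train_linear(pool$x, pool$y, co$class_names[1],
                                        margin_cost = 1))
    match(paste0("m", 1:10), r$ordered_measurements)
  }
  sp_large <- c(); sp_single <- c()
  for (seed in 1:6) {
    spec <- synthetic_spec(c(1, 1), cells_per_patient = 30000,
                           n_measurements = 10,
                           class_shift = seq(0.8, 0.08, length.out = 10),
                           skew = 2, seed = seed)
    co <- generate_cohort(spec)
    r1 <- rank_at(co, 1, seed + 100)
    r200 <- rank_at(co, 200, seed + 200)
    r500 <- rank_at(co, 500, seed + 300)
    sp_large <- c(sp_large, stats::cor(r200, r500, method = "spearman"))
    sp_single <- c(sp_single, stats::cor(r1, r500, method = "spearman"))
  }
  expect_gt(mean(sp_large), mean(sp_single))
  expect_gt(mean(sp_large), 0.7)
})

test_that("single cells are not classifiable where modest supercells are", {
  spec <- synthetic_spec(c(1, 1), cells_per_patient = 8000, n_measurements = 5,
                         class_shift = c(1, 0, 0, 0, 0), seed = 104)
  co <- generate_cohort(spec)
  g <- accuracy_grid(co, c(1, 100), 5, supercell_config(1, 3000, seed = 105),
                     evaluation = "training", margin_cost = 10)
  expect_lt(g$accuracy["1", 1], 0.7)
  expect_gt(g$accuracy["100", 1], 0.95)
})
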