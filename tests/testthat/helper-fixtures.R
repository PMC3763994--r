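# Shared fixtures and independent oracles, all built in code at test time.

# Exhaustive max-margin search for small 2-D separable sets (y in {+1, -1}).
# The optimal hard-margin boundary is supported by either one point per class
# (normal along their difference) or an edge of one class's hull plus one
# opposite point; enumerating both families and keeping the feasible
# candidate with the largest margin is exact for point sets this small.
brute_force_margin <- function(X, y) {
  cand <- list()
  pos <- which(y > 0)
  neg <- which(y < 0)
  for (i in pos) for (j in neg) {
    w <- X[i, ] - X[j, ]
    cand[[length(cand) + 1L]] <- c(w, -sum(w * (X[i, ] + X[j, ]) / 2))
  }
  for (cls in list(pos, neg)) {
    other <- if (identical(cls, pos)) neg else pos
    if (length(cls) < 2L) next
    pairs <- utils::combn(cls, 2L)
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1L, q]; j <- pairs[2L, q]
      e <- X[j, ] - X[i, ]
      for (k in other) {
        d <- X[k, ] - X[i, ]
        w <- d - e * sum(d * e) / sum(e * e)
        if (sum(w^2) < 1e-18) next
        cand[[length(cand) + 1L]] <- c(w, -sum(w * (X[i, ] + X[k, ]) / 2))
      }
    }
  }
  best <- -Inf
  for (cb in cand) {
    w <- cb[1:2]; b <- cb[3]
    f <- drop(X %*% w + b)
    mar <- max(min(y * f), min(-y * f)) / sqrt(sum(w^2))
    if (is.finite(mar) && mar > best) best <- mar
  }
  best
}

# Reassign class labels to a cohort's samples (for permutation nulls).
relabel_cohort <- function(co, labels) {
  cohort(Map(function(s, l) cell_sample(s$sample_id, l, s$values),
             co$samples, labels), co$class_names)
}

# Pool every sample's supercell cloud into one labelled training matrix.
pool_supercells <- function(co, cfg) {
  scs <- lapply(co$samples, build_supercells, config = cfg)
  list(x = do.call(rbind, lapply(scs, `[[`, "values")),
       y = rep(vapply(scs, `[[`, character(1), "class_label"),
               each = cfg$count_k))
}

# One hand-built sample with explicit per-measurement means.
fixed_mean_sample <- function(id, cls, mu, cells, sigma, names = NULL) {
  p <- length(mu)
  vals <- matrix(stats::rnorm(cells * p, mean = rep(mu, each = cells),
                              sd = sigma), cells, p)
  colnames(vals) <- names %||% paste0("m", seq_len(p))
  cell_sample(id, cls, vals)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-class cohort whose patient means are coordinate permutations of
# (1,1,0) vs (0,0,1) on three signal measurements plus pure-noise columns:
# the classes separate in the 3-D signal subspace (coordinate sums 2 vs 1)
# but collide in every 1-D or 2-D coordinate projection, which pins the
# minimal number of informative measurements at exactly 3.
permutation_cohort <- function(seed, p_noise = 7, cells = 600, sigma = 0.35) {
  A <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  B <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  samples <- list()
  set.seed(seed)
  for (i in 1:3) for (cls in c("A", "B")) {
    mu <- c(if (cls == "A") A[i, ] else B[i, ], rep(0, p_noise))
    id <- sprintf("%s%d", cls, i)
    samples[[id]] <- fixed_mean_sample(id, cls, mu, cells, sigma)
  }
  cohort(samples, c("A", "B"))
}
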