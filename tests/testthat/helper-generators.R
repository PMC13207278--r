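# Shared fixture builders for the property suites. All randomness is
# drawn from an explicit seed so every test is reproducible.

# A random valid TFN: three sorted draws from [lo, hi].
rand_tfn <- function(lo = 0.1, hi = 10) {
  sort(stats::runif(3, lo, hi))
}

# A random fuzzy decision matrix with the given directions; strictly
# positive cells so cost normalization is always defined.
rand_fuzzy_dm <- function(n_alt, directions, crisp = FALSE, lo = 0.5, hi = 10) {
  n_crit <- length(directions)
  cells <- array(NA_real_, dim = c(n_alt, n_crit, 3L))
  for (i in seq_len(n_alt)) {
    for (j in seq_len(n_crit)) {
      cells[i, j, ] <- if (crisp) rep(stats::runif(1, lo, hi), 3) else rand_tfn(lo, hi)
    }
  }
  fuzzy_decision_matrix(
    cells,
    data.frame(code = sprintf("A%d", seq_len(n_alt)),
               name = sprintf("alt %d", seq_len(n_alt))),
    data.frame(id = sprintf("C%d", seq_len(n_crit)),
               name = sprintf("crit %d", seq_len(n_crit)),
               units = "a.u.", direction = directions,
               target_lo = NA_real_, target_hi = NA_real_)
  )
}

# A random non-negative fuzzy weight vector over the given ids.
rand_weights <- function(ids, crisp = FALSE) {
  local <- t(vapply(ids, function(id) {
    if (crisp) rep(stats::runif(1, 0.05, 0.5), 3) else sort(stats::runif(3, 0.05, 0.5))
  }, numeric(3)))
  weight_vector(id = ids, local = local)
}

# Straight-line fuzzy TOPSIS recomputation used as the independent
# end-to-end oracle: explicit loops over plain arrays, no package
# pipeline calls.
oracle_fuzzy_topsis_cc <- function(cells, directions, w_local) {
  n_alt <- dim(cells)[1L]; n_crit <- dim(cells)[2L]
  r <- array(NA_real_, dim = dim(cells))
  for (j in seq_len(n_crit)) {
    if (directions[j] == "benefit") {
      ustar <- max(cells[, j, 3])
      for (i in seq_len(n_alt)) for (k in 1:3) r[i, j, k] <- cells[i, j, k] / ustar
    } else {
      lmin <- min(cells[, j, 1])
      for (i in seq_len(n_alt)) {
        r[i, j, 1] <- lmin / cells[i, j, 3]
        r[i, j, 2] <- lmin / cells[i, j, 2]
        r[i, j, 3] <- lmin / cells[i, j, 1]
      }
    }
  }
  v <- array(NA_real_, dim = dim(cells))
  for (i in seq_len(n_alt)) for (j in seq_len(n_crit)) for (k in 1:3) {
    v[i, j, k] <- r[i, j, k] * w_local[j, k]
  }
  dpos <- dneg <- numeric(n_alt)
  for (i in seq_len(n_alt)) {
    for (j in seq_len(n_crit)) {
      fp <- c(max(v[, j, 1]), max(v[, j, 2]), max(v[, j, 3]))
      fn <- c(min(v[, j, 1]), min(v[, j, 2]), min(v[, j, 3]))
      dpos[i] <- dpos[i] + sqrt(((v[i, j, 1] - fp[1])^2 + (v[i, j, 2] - fp[2])^2 +
                                   (v[i, j, 3] - fp[3])^2) / 3)
      dneg[i] <- dneg[i] + sqrt(((v[i, j, 1] - fn[1])^2 + (v[i, j, 2] - fn[2])^2 +
                                   (v[i, j, 3] - fn[3])^2) / 3)
    }
  }
  dneg / (dpos + dneg)
}
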