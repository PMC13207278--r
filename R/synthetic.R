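#' Specification of a synthetic decision problem
#'
#' Describes a randomly generated alternatives x criteria fuzzy decision
#' problem with known ground-truth structure, used to validate the
#' ranking pipeline: a designated alternative can be forced to weakly
#' dominate every other, which must earn it rank 1 under any non-negative
#' weighting.
#'
#' All generators are pure functions of their seed: the same spec yields
#' byte-identical output, and the caller's RNG state is left untouched.
#'
#' @param n_alternatives,n_criteria Problem size (at least 2 alternatives).
#' @param directions Character vector of per-criterion directions,
#'   `"benefit"` or `"cost"`; recycled defaults to all-benefit.
#' @param dominant Optional index of the alternative forced to weakly
#'   dominate (component-wise best on every criterion).
#' @param noise_scale Non-negative log-normal noise scale; 0 collapses
#'   every cell to a crisp criterion-level base value.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_alternatives, n_criteria,
                           directions = rep("benefit", n_criteria),
                           dominant = NULL, noise_scale = 0.25, seed = 1L) {
  if (n_alternatives < 2L) stop("need at least 2 alternatives", call. = FALSE)
  if (n_criteria < 1L) stop("need at least 1 criterion", call. = FALSE)
  directions <- rep_len(directions, n_criteria)
  if (!all(directions %in% c("benefit", "cost"))) {
    stop("directions must be 'benefit' or 'cost'", call. = FALSE)
  }
  if (!is.null(dominant) &&
      (dominant < 1L || dominant > n_alternatives)) {
    stop("dominant index out of range", call. = FALSE)
  }
  if (noise_scale < 0) stop("noise_scale must be non-negative", call. = FALSE)
  structure(list(n_alternatives = as.integer(n_alternatives),
                 n_criteria = as.integer(n_criteria),
                 directions = directions,
                 dominant = if (is.null(dominant)) NULL else as.integer(dominant),
                 noise_scale = as.numeric(noise_scale),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a fuzzy decision matrix with optional planted dominance
#'
#' Each cell is built from three sorted draws of
#' `base_j * exp(noise_scale * z)`, `z ~ N(0, 1)`, where `base_j` is a
#' criterion-level magnitude: multiplicative log-normal noise keeps all
#' values strictly positive (as the TFN product/reciprocal domains
#' require) and controls both the inter-alternative spread and the
#' fuzziness of each cell with a single knob. With `noise_scale = 0`
#' every cell is crisp and all rows are identical.
#'
#' If `spec$dominant` is set, that alternative's row is replaced, per
#' criterion, by the component-wise best envelope of all other rows
#' (maximum on benefit columns, minimum on cost columns) pushed 5%
#' past it, so the planted alternative strictly dominates in every
#' component and an incumbent best row cannot tie it.
#'
#' @param spec A [synthetic_spec()].
#' @return A [fuzzy_decision_matrix()].
#' @export
gen_dominant_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_a <- spec$n_alternatives
  n_c <- spec$n_criteria
  withr::with_seed(spec$seed, {
    base <- exp(stats::runif(n_c, log(1), log(100)))
    cells <- array(NA_real_, dim = c(n_a, n_c, 3L))
    for (i in seq_len(n_a)) {
      for (j in seq_len(n_c)) {
        draws <- base[j] * exp(spec$noise_scale * stats::rnorm(3L))
        cells[i, j, ] <- sort(draws)
      }
    }
  })
  if (!is.null(spec$dominant)) {
    d <- spec$dominant
    others <- setdiff(seq_len(n_a), d)
    for (j in seq_len(n_c)) {
      env <- if (spec$directions[j] == "benefit") {
        apply(cells[others, j, , drop = FALSE], 3L, max) * 1.05
      } else {
        apply(cells[others, j, , drop = FALSE], 3L, min) * 0.95
      }
      cells[d, j, ] <- env
    }
  }
  alternatives <- data.frame(code = sprintf("A%d", seq_len(n_a)),
                             name = sprintf("synthetic alternative %d", seq_len(n_a)))
  criteria <- data.frame(id = sprintf("C%d", seq_len(n_c)),
                         name = sprintf("synthetic criterion %d", seq_len(n_c)),
                         units = "a.u.", direction = spec$directions,
                         target_lo = NA_real_, target_hi = NA_real_)
  fuzzy_decision_matrix(cells, alternatives, criteria)
}

#' Simulate inter-study evidence for one property
#'
#' Emulates how a property interval arises in practice: `n_studies`
#' independent measurements of the same underlying value scatter
#' multiplicatively (fabrication parameters, loading fractions, test
#' protocols), and the reported evidence is their observed range. The
#' midpoint of the fuzzified interval converges to `true_value` as
#' `noise_scale` shrinks.
#'
#' @param true_value Positive underlying property value.
#' @param n_studies Number of simulated studies (>= 1).
#' @param noise_scale Log-normal measurement noise scale.
#' @param seed Integer seed.
#' @return An [evidence_interval()].
#' @export
gen_interval_evidence <- function(true_value, n_studies, noise_scale, seed = 1L) {
  if (n_studies < 1L) stop("n_studies must be >= 1", call. = FALSE)
  if (noise_scale < 0) stop("noise_scale must be non-negative", call. = FALSE)
  meas <- withr::with_seed(seed,
    true_value * exp(noise_scale * stats::rnorm(n_studies)))
  evidence_interval(min(meas), max(meas),
                    source_note = sprintf("simulated range over %d studies", n_studies))
}

#' Generate a near-consistent fuzzy comparison matrix
#'
#' Builds an `n x n` reciprocal TFN matrix whose upper-triangle entries
#' are centred on the true importance ratios `w_i / w_j` of a known
#' weight vector, jittered by multiplicative log-normal noise of scale
#' `perturbation`, and fuzzified symmetrically with relative half-width
#' `spread`: an entry with centre `r` becomes
#' `(r / (1 + spread), r, r * (1 + spread))`. Reciprocity is enforced
#' exactly by construction. With `perturbation = 0` and `spread = 0` the
#' matrix is crisp and perfectly consistent (CR = 0); this is the
#' ground-truth oracle for the extent-analysis weights and the
#' consistency ratio.
#'
#' @param weights Positive numeric vector of true criterion weights.
#' @param perturbation Log-normal noise scale on the ratios.
#' @param spread Relative fuzzy half-width (>= 0).
#' @param seed Integer seed.
#' @return A [fuzzy_comparison_matrix()].
#' @export
gen_consistent_comparison_matrix <- function(weights, perturbation = 0,
                                             spread = 0, seed = 1L) {
  if (any(weights <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (perturbation < 0 || spread < 0) {
    stop("perturbation and spread must be non-negative", call. = FALSE)
  }
  n <- length(weights)
  arr <- array(NA_real_, dim = c(n, n, 3L))
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      arr[i, i, ] <- c(1, 1, 1)
      for (j in seq_len(n)) {
        if (j <= i) next
        centre <- (weights[i] / weights[j]) *
          exp(perturbation * stats::rnorm(1L))
        entry <- c(centre / (1 + spread), centre, centre * (1 + spread))
        arr[i, j, ] <- entry
        arr[j, i, ] <- rev(1 / entry)
      }
    }
  })
  dimnames(arr) <- list(sprintf("C%d", seq_len(n)), sprintf("C%d", seq_len(n)),
                        c("l", "m", "u"))
  fuzzy_comparison_matrix(arr)
}
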