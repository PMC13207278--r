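#' Desirability transform for target-range criteria
#'
#' Some criteria are best inside a window rather than maximal or minimal:
#' scaffold degradation, for instance, should track the bone-healing
#' timetable -- too fast leaves the defect unsupported, too slow leaves a
#' foreign body. The transform maps a raw TFN onto a `[0, 1]` desirability
#' scale through the piecewise-linear function
#' `g(t) = t / lo` for `t < lo`; `1` inside `[lo, hi]`; and
#' `max(0, 1 - (t - hi) / (decay_anchor - hi))` beyond `hi`, reaching 0 at
#' the decay anchor. `g` is not monotone, so the transformed vertices are
#' sorted ascending to restore TFN ordering; the result is treated
#' downstream as a benefit value.
#'
#' @param x A non-negative TFN in criterion units.
#' @param window Numeric `c(lo, hi)`, the fully-desirable band.
#' @param decay_anchor Value above `hi` at which desirability hits zero.
#' @return A [tfn()] with components in `[0, 1]`.
#' @examples
#' target_range_transform(tfn(24, 48, 100), c(12, 26), 200)
#' @export
target_range_transform <- function(x, window, decay_anchor = 200) {
  x <- as_tfn(x)
  if (length(window) != 2L || !all(is.finite(window)) || window[1L] >= window[2L]) {
    stop("window must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  if (!is.finite(decay_anchor) || decay_anchor <= window[2L]) {
    stop("decay_anchor must exceed the window's upper edge", call. = FALSE)
  }
  if (x[[1L]] < 0) stop("target-range transform expects non-negative values", call. = FALSE)
  g <- desirability_fun(window[1L], window[2L], decay_anchor)
  new_tfn(sort(g(unclass(x))))
}

desirability_fun <- function(lo, hi, anchor) {
  function(t) {
    ifelse(t < lo, t / lo,
           ifelse(t <= hi, 1, pmax(0, 1 - (t - hi) / (anchor - hi))))
  }
}

# Replace target-range columns by their desirability, marking them benefit.
transform_target_columns <- function(dm, decay_anchor = 200) {
  crit <- dm$criteria
  idx <- which(crit$direction == "target_range")
  if (length(idx) == 0L) return(dm)
  cells <- dm$cells
  for (j in idx) {
    g <- desirability_fun(crit$target_lo[j], crit$target_hi[j], decay_anchor)
    if (decay_anchor <= crit$target_hi[j]) {
      stop("decay_anchor must exceed the target window of ", crit$id[j],
           call. = FALSE)
    }
    for (i in seq_len(dim(cells)[1L])) {
      cells[i, j, ] <- sort(g(cells[i, j, ]))
    }
    crit$direction[j] <- "benefit"
    crit$units[j] <- "desirability"
    crit$target_lo[j] <- NA_real_
    crit$target_hi[j] <- NA_real_
  }
  fuzzy_decision_matrix(cells, dm$alternatives, crit)
}

#' Linear-scale normalization of a fuzzy decision matrix
#'
#' Brings all criteria onto a common dimensionless `[0, 1]` scale. For a
#' benefit column with column maximum upper bound `u*`, each cell becomes
#' `(l/u*, m/u*, u/u*)`; for a cost column with minimum lower bound `l-`,
#' each cell becomes `(l-/u, l-/m, l-/l)` (larger is better after the
#' flip). Target-range columns must be transformed to the benefit scale
#' first (see [target_range_transform()]).
#'
#' @param matrix A [fuzzy_decision_matrix()] without target-range columns.
#' @return A [fuzzy_decision_matrix()] of dimensionless cells in `[0, 1]`.
#' @export
normalize_matrix <- function(matrix) {
  crit <- matrix$criteria
  if (any(crit$direction == "target_range")) {
    stop("transform target_range columns to the benefit scale before ",
         "normalization", call. = FALSE)
  }
  cells <- matrix$cells
  out <- cells
  for (j in seq_len(nrow(crit))) {
    if (crit$direction[j] == "benefit") {
      ustar <- max(cells[, j, 3L])
      if (ustar <= 0) {
        stop("benefit column ", crit$id[j], " has non-positive maximum",
             call. = FALSE)
      }
      out[, j, ] <- cells[, j, ] / ustar
    } else {
      if (any(cells[, j, ] == 0)) {
        stop("cost column ", crit$id[j], " contains a zero component",
             call. = FALSE)
      }
      lminus <- min(cells[, j, 1L])
      out[, j, 1L] <- lminus / cells[, j, 3L]
      out[, j, 2L] <- lminus / cells[, j, 2L]
      out[, j, 3L] <- lminus / cells[, j, 1L]
    }
    crit$units[j] <- ""
  }
  fuzzy_decision_matrix(out, matrix$alternatives, crit)
}

#' Weight a normalized fuzzy decision matrix
#'
#' Multiplies every normalized cell by its criterion's fuzzy local weight
#' (component-wise TFN product), yielding the weighted normalized matrix
#' from which the ideal solutions are read.
#'
#' @param normalized A normalized [fuzzy_decision_matrix()].
#' @param weights A [weight_vector()] whose `id`s match the matrix's
#'   criteria (order-insensitive).
#' @return A [fuzzy_decision_matrix()].
#' @export
apply_weights <- function(normalized, weights) {
  crit <- normalized$criteria
  pos <- match(crit$id, weights$id)
  if (anyNA(pos)) {
    stop("weights missing for criteria: ",
         paste(crit$id[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  cells <- normalized$cells
  out <- cells
  for (j in seq_len(nrow(crit))) {
    w <- c(weights$l[pos[j]], weights$m[pos[j]], weights$u[pos[j]])
    if (any(w < 0)) stop("negative fuzzy weight for ", crit$id[j], call. = FALSE)
    out[, j, 1L] <- cells[, j, 1L] * w[1L]
    out[, j, 2L] <- cells[, j, 2L] * w[2L]
    out[, j, 3L] <- cells[, j, 3L] * w[3L]
  }
  fuzzy_decision_matrix(out, normalized$alternatives, crit)
}

#' Fuzzy positive and negative ideal solutions
#'
#' Per criterion, the FPIS is the component-wise maximum of the weighted
#' normalized TFNs across alternatives and the FNIS the component-wise
#' minimum: the ideals are data-driven envelopes of the observed
#' performance, not the fixed `(1,1,1)` / `(0,0,0)` convention.
#'
#' @param weighted A weighted normalized [fuzzy_decision_matrix()] with at
#'   least two alternatives.
#' @return A list with `fpis` and `fnis`, each an `n_crit x 3` matrix
#'   (rows named by criterion id).
#' @export
ideal_solutions <- function(weighted) {
  cells <- weighted$cells
  if (dim(cells)[1L] < 2L) {
    stop("ideal solutions need at least 2 alternatives", call. = FALSE)
  }
  fpis <- apply(cells, c(2L, 3L), max)
  fnis <- apply(cells, c(2L, 3L), min)
  rownames(fpis) <- rownames(fnis) <- weighted$criteria$id
  list(fpis = fpis, fnis = fnis)
}

#' Closeness coefficient
#'
#' `CC = d_neg / (d_pos + d_neg)`, the relative closeness of an
#' alternative to the positive ideal: 1 when it coincides with the FPIS,
#' 0 when it coincides with the FNIS. Vectorized over alternatives.
#'
#' @param d_pos,d_neg Non-negative distances to the positive/negative
#'   ideal solution.
#' @return Values in `[0, 1]`.
#' @examples
#' closeness(3.82, 8.01)   # 0.677 to 3 d.p.
#' @export
closeness <- function(d_pos, d_neg) {
  if (any(d_pos < 0) || any(d_neg < 0)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  if (any(d_pos + d_neg == 0)) {
    stop("closeness undefined: an alternative coincides with both ideals ",
         "(degenerate problem)", call. = FALSE)
  }
  d_neg / (d_pos + d_neg)
}

#' Rank alternatives by fuzzy TOPSIS
#'
#' The full four-step procedure: (i) target-range columns are mapped to
#' the benefit scale, the matrix is normalized and multiplied by the
#' fuzzy criterion weights; (ii) the fuzzy positive and negative ideal
#' solutions are taken as the per-criterion component-wise extrema of the
#' weighted normalized cells; (iii) each alternative's separations
#' `d_pos` / `d_neg` are the sums over criteria of vertex distances to
#' the two ideals; (iv) alternatives are ranked by descending closeness
#' coefficient, ties broken by ascending alternative code.
#'
#' @param matrix A [fuzzy_decision_matrix()] with at least 2 alternatives.
#' @param weights A [weight_vector()] covering the matrix's criteria.
#' @param decay_anchor Passed to the target-range transform.
#' @param labels Optional named character vector (`code -> label`) of
#'   free-text classification annotations for the report; defaults to a
#'   `label` column on `matrix$alternatives` when present.
#' @return An object of class `ranking_result`: a data frame (one row per
#'   alternative, ordered by rank) with columns `rank`, `code`, `name`,
#'   `cc`, `d_pos`, `d_neg`, `label`, carrying the intermediate matrices
#'   (`normalized`, `weighted`, `fpis`, `fnis`) as attributes for audit.
#' @examples
#' rr <- run_fuzzy_topsis(load_study_fixture(), study_weights())
#' rr$code[rr$rank == 1]
#' @export
run_fuzzy_topsis <- function(matrix, weights, decay_anchor = 200,
                             labels = NULL) {
  transformed <- transform_target_columns(matrix, decay_anchor = decay_anchor)
  normalized <- normalize_matrix(transformed)
  weighted <- apply_weights(normalized, weights)
  ideals <- ideal_solutions(weighted)

  n_alt <- nrow(matrix$alternatives)
  n_crit <- nrow(matrix$criteria)
  d_pos <- d_neg <- numeric(n_alt)
  for (i in seq_len(n_alt)) {
    for (j in seq_len(n_crit)) {
      v <- weighted$cells[i, j, ]
      d_pos[i] <- d_pos[i] + sqrt(sum((v - ideals$fpis[j, ])^2) / 3)
      d_neg[i] <- d_neg[i] + sqrt(sum((v - ideals$fnis[j, ])^2) / 3)
    }
  }
  cc <- closeness(d_pos, d_neg)
  build_ranking(matrix$alternatives, cc, d_pos, d_neg, labels,
                method = "fuzzy",
                extras = list(normalized = normalized, weighted = weighted,
                              fpis = ideals$fpis, fnis = ideals$fnis,
                              weights = weights))
}

#' Rank alternatives by crisp midpoint TOPSIS
#'
#' The comparison arm for the fuzzy analysis: every cell and weight is
#' collapsed to its modal value `m` and classical TOPSIS is run on the
#' resulting crisp matrix -- linear-scale normalization (`x / max` for
#' benefit, `min / x` for cost, the same formulas the fuzzy route uses,
#' degenerated to crisp ratios), modal-weight multiplication, data-driven
#' crisp ideals, city-block distances (absolute differences summed over
#' criteria) and the same closeness coefficient. Comparing its ranking
#' with [run_fuzzy_topsis()] shows what the fuzzy treatment of
#' inter-study spread changes: a candidate with strong modal values but
#' wide uncertainty can win the crisp analysis yet lose the fuzzy one.
#'
#' @inheritParams run_fuzzy_topsis
#' @return A `ranking_result`, as for [run_fuzzy_topsis()].
#' @export
run_crisp_topsis <- function(matrix, weights, decay_anchor = 200,
                             labels = NULL) {
  crit <- matrix$criteria
  n_alt <- nrow(matrix$alternatives)
  n_crit <- nrow(crit)
  if (n_alt < 2L) stop("need at least 2 alternatives", call. = FALSE)

  x <- matrix$cells[, , 2L, drop = FALSE]
  dim(x) <- c(n_alt, n_crit)
  direction <- crit$direction
  for (j in seq_len(n_crit)) {
    if (direction[j] == "target_range") {
      g <- desirability_fun(crit$target_lo[j], crit$target_hi[j], decay_anchor)
      x[, j] <- g(x[, j])
      direction[j] <- "benefit"
    }
  }
  r <- x
  for (j in seq_len(n_crit)) {
    if (direction[j] == "benefit") {
      mx <- max(x[, j])
      if (mx <= 0) stop("benefit column ", crit$id[j], " has non-positive maximum",
                        call. = FALSE)
      r[, j] <- x[, j] / mx
    } else {
      if (any(x[, j] == 0)) stop("cost column ", crit$id[j], " contains zero",
                                 call. = FALSE)
      r[, j] <- min(x[, j]) / x[, j]
    }
  }
  pos <- match(crit$id, weights$id)
  if (anyNA(pos)) {
    stop("weights missing for criteria: ",
         paste(crit$id[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  v <- sweep(r, 2L, weights$m[pos], `*`)
  best <- apply(v, 2L, max)
  worst <- apply(v, 2L, min)
  d_pos <- rowSums(abs(sweep(v, 2L, best)))
  d_neg <- rowSums(abs(sweep(v, 2L, worst)))
  cc <- closeness(d_pos, d_neg)
  build_ranking(matrix$alternatives, cc, d_pos, d_neg, labels,
                method = "crisp",
                extras = list(crisp_matrix = x, crisp_normalized = r,
                              crisp_weighted = v, weights = weights))
}

build_ranking <- function(alternatives, cc, d_pos, d_neg, labels, method,
                          extras = list()) {
  code <- as.character(alternatives$code)
  if (is.null(labels)) {
    labels <- if (!is.null(alternatives$label)) {
      stats::setNames(as.character(alternatives$label), code)
    } else {
      stats::setNames(rep(NA_character_, length(code)), code)
    }
  }
  ord <- order(-cc, code)
  rank <- integer(length(cc))
  rank[ord] <- seq_along(cc)
  df <- data.frame(
    rank = rank, code = code, name = as.character(alternatives$name),
    cc = cc, d_pos = d_pos, d_neg = d_neg,
    label = unname(labels[code]),
    row.names = NULL
  )
  df <- df[order(df$rank), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ranking_result", "data.frame"),
            method = method, intermediates = extras)
}

#' @export
print.ranking_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s TOPSIS ranking\n",
              if (identical(attr(x, "method"), "crisp")) "Crisp" else "Fuzzy"))
  df <- data.frame(
    rank = x$rank, code = x$code, name = x$name,
    cc = round(x$cc, digits),
    d_pos = round(x$d_pos, digits), d_neg = round(x$d_neg, digits),
    label = ifelse(is.na(x$label), "", x$label)
  )
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
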