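#' Fuzzy pairwise-comparison matrix
#'
#' An `n x n` reciprocal grid of TFN importance judgements: entry `(i, j)`
#' states how much more important criterion `i` is than criterion `j` on
#' the 1-9 fuzzy scale. The diagonal is the crisp identity `(1, 1, 1)` and
#' the lower triangle is the TFN reciprocal of the upper triangle.
#'
#' @param entries An `n x n x 3` numeric array, or an `n x n` list-matrix
#'   of TFNs/coercibles. Lower-triangle entries may be `NULL`/`NA`, in
#'   which case they are filled as reciprocals of the upper triangle.
#' @param ids Optional character vector of criterion ids (dimnames).
#' @return An object of class `fuzzy_comparison_matrix` wrapping the
#'   validated array.
#' @export
fuzzy_comparison_matrix <- function(entries, ids = NULL) {
  if (is.list(entries)) {
    n <- length(entries)
    arr <- array(NA_real_, dim = c(n, n, 3L))
    for (i in seq_len(n)) {
      if (length(entries[[i]]) != n) stop("ragged comparison matrix", call. = FALSE)
      for (j in seq_len(n)) {
        e <- entries[[i]][[j]]
        if (is.null(e) || (length(e) == 1L && is.na(e))) next
        if (is.character(e)) e <- tfn_from_linguistic(e)
        arr[i, j, ] <- unclass(as_tfn(e))
      }
    }
    # fill omitted entries from their transpose partner
    for (i in seq_len(n)) {
      arr[i, i, ] <- c(1, 1, 1)
      for (j in seq_len(n)) {
        if (i != j && anyNA(arr[i, j, ]) && !anyNA(arr[j, i, ])) {
          arr[i, j, ] <- unclass(tfn_reciprocal(as_tfn(arr[j, i, ])))
        }
      }
    }
    entries <- arr
  }
  if (!is.array(entries) || length(dim(entries)) != 3L ||
      dim(entries)[1L] != dim(entries)[2L] || dim(entries)[3L] != 3L) {
    stop("entries must be an n x n x 3 array", call. = FALSE)
  }
  n <- dim(entries)[1L]
  if (!is.null(ids)) dimnames(entries) <- list(ids, ids, c("l", "m", "u"))
  obj <- structure(list(entries = entries, n = n),
                   class = "fuzzy_comparison_matrix")
  validate_comparison_matrix(obj)
  obj
}

#' Validate a fuzzy comparison matrix
#'
#' Checks that every entry is a positive valid TFN, the diagonal is
#' `(1, 1, 1)` and the matrix is reciprocal (`entries[j, i] ==
#' 1 / entries[i, j]` component-reversed) within tolerance `1e-9`.
#'
#' @param fcm A [fuzzy_comparison_matrix()].
#' @param tol Reciprocity tolerance.
#' @return `fcm`, invisibly.
#' @export
validate_comparison_matrix <- function(fcm, tol = 1e-9) {
  a <- fcm$entries
  n <- fcm$n
  for (i in seq_len(n)) {
    if (any(abs(a[i, i, ] - 1) > tol)) {
      stop("diagonal entry (", i, ",", i, ") is not (1, 1, 1)", call. = FALSE)
    }
    for (j in seq_len(n)) {
      v <- a[i, j, ]
      if (anyNA(v) || any(!is.finite(v)) || v[1L] <= 0) {
        stop("entry (", i, ",", j, ") must be a positive finite TFN", call. = FALSE)
      }
      if (v[1L] > v[2L] + tol || v[2L] > v[3L] + tol) {
        stop("entry (", i, ",", j, ") violates l <= m <= u", call. = FALSE)
      }
      if (j > i) {
        recip <- rev(1 / v)
        if (any(abs(a[j, i, ] - recip) > tol)) {
          stop("entries (", i, ",", j, ") and (", j, ",", i,
               ") are not reciprocal", call. = FALSE)
        }
      }
    }
  }
  invisible(fcm)
}

#' @export
print.fuzzy_comparison_matrix <- function(x, ...) {
  cat(sprintf("Fuzzy comparison matrix (%d x %d)\n", x$n, x$n))
  lab <- dimnames(x$entries)[[1L]]
  if (is.null(lab)) lab <- paste0("c", seq_len(x$n))
  for (i in seq_len(x$n)) {
    row <- vapply(seq_len(x$n), function(j) {
      sprintf("(%.3g,%.3g,%.3g)", x$entries[i, j, 1L], x$entries[i, j, 2L],
              x$entries[i, j, 3L])
    }, character(1))
    cat(sprintf("  %-4s %s\n", lab[i], paste(row, collapse = " ")))
  }
  invisible(x)
}

#' Consolidate an expert panel into one comparison matrix
#'
#' Entry-wise component geometric mean of the experts' matrices. The
#' geometric mean of reciprocal entries is reciprocal in exact arithmetic,
#' but floating error accumulates, so the lower triangle is recomputed as
#' the exact reciprocal of the aggregated upper triangle to restore the
#' type invariant.
#'
#' @param judgments A non-empty list of [fuzzy_comparison_matrix()] of
#'   equal dimension.
#' @return A [fuzzy_comparison_matrix()].
#' @export
aggregate_panel <- function(judgments) {
  if (length(judgments) == 0L) stop("empty panel", call. = FALSE)
  ns <- vapply(judgments, function(m) m$n, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("panel matrices have mismatched dimensions", call. = FALSE)
  }
  n <- ns[1L]
  out <- array(NA_real_, dim = c(n, n, 3L))
  for (i in seq_len(n)) {
    out[i, i, ] <- c(1, 1, 1)
    for (j in seq_len(n)) {
      if (j <= i) next
      stack <- do.call(rbind, lapply(judgments, function(m) m$entries[i, j, ]))
      agg <- unclass(tfn_geometric_mean(stack))
      out[i, j, ] <- agg
      out[j, i, ] <- rev(1 / agg)
    }
  }
  dimnames(out) <- dimnames(judgments[[1L]]$entries)
  fuzzy_comparison_matrix(out)
}

#' Criterion weights by Chang's extent analysis
#'
#' Converts a fuzzy comparison matrix into crisp weights. Per criterion
#' the fuzzy synthetic extent is
#' `S_i = (sum_j M_ij) (x) (sum_k sum_j M_kj)^(-1)`; the possibility
#' degree that one extent exceeds another is
#' `V(S2 >= S1) = 1` if `m2 >= m1`, `0` if `l1 >= u2`, else
#' `(l1 - u2) / ((m2 - u2) - (m1 - l1))`; each criterion scores
#' `d_i = min_{k != i} V(S_i >= S_k)` and the crisp weights are the
#' normalised scores. The fuzzy synthetic extents are returned as the
#' fuzzy local weights.
#'
#' Extent analysis assigns weight zero to a criterion whose extent lies
#' wholly below some other extent; this is surfaced as a warning (the
#' zero is genuine output of the method, not renormalised away). A matrix
#' on which every criterion scores zero is rejected as degenerate.
#'
#' @param matrix A [fuzzy_comparison_matrix()].
#' @return A [weight_vector()] whose `global` column holds the Chang
#'   weights and whose TFN columns hold the synthetic extents.
#' @export
chang_extent_weights <- function(matrix) {
  a <- matrix$entries
  n <- matrix$n
  # row fuzzy sums and grand total
  rows <- t(vapply(seq_len(n), function(i) {
    m <- matrix(a[i, , ], nrow = n, ncol = 3L)
    colSums(m)
  }, numeric(3)))
  total <- colSums(rows)
  # S_i = rows_i (x) total^(-1), with the reversed-component inverse
  s <- cbind(rows[, 1L] / total[3L], rows[, 2L] / total[2L], rows[, 3L] / total[1L])

  v_ge <- function(i, k) {
    # possibility degree V(S_i >= S_k)
    l1 <- s[k, 1L]; m1 <- s[k, 2L]
    m2 <- s[i, 2L]; u2 <- s[i, 3L]
    if (m2 >= m1) return(1)
    if (l1 >= u2) return(0)
    (l1 - u2) / ((m2 - u2) - (m1 - l1))
  }

  d <- vapply(seq_len(n), function(i) {
    min(vapply(setdiff(seq_len(n), i), function(k) v_ge(i, k), numeric(1)))
  }, numeric(1))

  if (all(d <= 0)) {
    stop("degenerate comparison matrix: every extent is dominated, ",
         "all Chang scores are zero", call. = FALSE)
  }
  if (any(d <= 0)) {
    warning("extent analysis assigned zero weight to ",
            sum(d <= 0), " criterion/criteria (disjoint extents)",
            call. = FALSE)
  }
  ids <- dimnames(a)[[1L]]
  if (is.null(ids)) ids <- paste0("C", seq_len(n))
  weight_vector(id = ids, local = s, global = d / sum(d))
}

# Saaty random-consistency indices for n = 3..10
.saaty_ri <- c(`3` = 0.58, `4` = 0.90, `5` = 1.12, `6` = 1.24,
               `7` = 1.32, `8` = 1.41, `9` = 1.45, `10` = 1.49)

#' Consistency ratio of a fuzzy comparison matrix
#'
#' Defuzzifies every entry, extracts the principal eigenvalue
#' `lambda_max` of the resulting crisp positive matrix by power iteration
#' (convergence tolerance 1e-10), and reports
#' `CI = (lambda_max - n) / (n - 1)` and `CR = CI / RI` with Saaty's
#' random-index constants. Judgements pass when `CR < 0.10`.
#'
#' @param matrix A [fuzzy_comparison_matrix()] with `3 <= n <= 10` (the
#'   range covered by the RI table).
#' @param method Defuzzification convention, see [defuzzify()].
#' @return An object of class `consistency_report`: a list with
#'   `lambda_max`, `CI`, `RI`, `CR`, `pass`, `n`, `method`.
#' @export
consistency_ratio <- function(matrix, method = c("centroid", "graded_mean")) {
  method <- match.arg(method)
  n <- matrix$n
  if (n < 3L || n > 10L) {
    stop("consistency ratio is defined here for 3 <= n <= 10", call. = FALSE)
  }
  crisp <- apply(matrix$entries, c(1L, 2L),
                 function(v) defuzzify(as_tfn(v), method = method))
  lambda_max <- principal_eigenvalue(crisp)
  ci <- (lambda_max - n) / (n - 1)
  ri <- .saaty_ri[[as.character(n)]]
  cr <- ci / ri
  structure(
    list(lambda_max = lambda_max, CI = ci, RI = ri, CR = cr,
         pass = cr < 0.10, n = n, method = method),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Consistency: lambda_max = %.6f (n = %d), CI = %.6f, RI = %.2f, CR = %.4f -> %s\n",
    x$lambda_max, x$n, x$CI, x$RI, x$CR,
    if (x$pass) "PASS (CR < 0.10)" else "FAIL (CR >= 0.10)"))
  invisible(x)
}

# Perron root of a positive matrix by power iteration.
principal_eigenvalue <- function(a, tol = 1e-10, max_iter = 100000L) {
  n <- nrow(a)
  x <- rep(1, n)
  lambda <- 0
  for (iter in seq_len(max_iter)) {
    y <- as.vector(a %*% x)
    lambda_new <- sqrt(sum(y^2)) / sqrt(sum(x^2))
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol && abs(lambda_new - lambda) < tol) {
      return(lambda_new)
    }
    x <- y
    lambda <- lambda_new
  }
  lambda
}
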