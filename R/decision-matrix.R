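#' Fuzzy decision matrix
#'
#' The central container of the pipeline: an alternatives x criteria grid
#' of TFNs plus criterion metadata. Cells hold raw performance values in
#' criterion units; [normalize_matrix()] and [apply_weights()] return the
#' same class with transformed cells.
#'
#' @param cells A numeric array of dimension `n_alt x n_crit x 3` (last
#'   margin `(l, m, u)`), or a list of rows of TFNs.
#' @param alternatives A data frame with at least columns `code` and
#'   `name`; extra columns (e.g. report labels) are carried along.
#' @param criteria A data frame with columns `id`, `name`, `units`,
#'   `direction` (`"benefit"`, `"cost"` or `"target_range"`) and, for
#'   target-range criteria, `target_lo` / `target_hi` (the desirability
#'   window in criterion units).
#'
#' @return An object of class `fuzzy_decision_matrix` with fields
#'   `cells`, `alternatives`, `criteria`.
#' @export
fuzzy_decision_matrix <- function(cells, alternatives, criteria) {
  alternatives <- as.data.frame(alternatives)
  criteria <- as.data.frame(criteria)
  if (!all(c("code", "name") %in% names(alternatives))) {
    stop("alternatives needs columns 'code' and 'name'", call. = FALSE)
  }
  if (!all(c("id", "direction") %in% names(criteria))) {
    stop("criteria needs columns 'id' and 'direction'", call. = FALSE)
  }
  if (is.null(criteria$name)) criteria$name <- criteria$id
  if (is.null(criteria$units)) criteria$units <- ""
  if (is.null(criteria$target_lo)) criteria$target_lo <- NA_real_
  if (is.null(criteria$target_hi)) criteria$target_hi <- NA_real_

  if (is.list(cells) && !is.array(cells)) {
    n_alt <- length(cells)
    n_crit <- length(cells[[1L]])
    arr <- array(NA_real_, dim = c(n_alt, n_crit, 3L))
    for (i in seq_len(n_alt)) {
      for (j in seq_len(n_crit)) arr[i, j, ] <- unclass(as_tfn(cells[[i]][[j]]))
    }
    cells <- arr
  }
  if (!is.array(cells) || length(dim(cells)) != 3L || dim(cells)[3L] != 3L) {
    stop("cells must be an n_alt x n_crit x 3 array", call. = FALSE)
  }
  dimnames(cells) <- list(alternatives$code, criteria$id, c("l", "m", "u"))

  obj <- structure(
    list(cells = cells, alternatives = alternatives, criteria = criteria),
    class = "fuzzy_decision_matrix"
  )
  validate_decision_matrix(obj)
  obj
}

#' Validate a fuzzy decision matrix
#'
#' Checks the container invariants: rectangular shape, every cell a valid
#' finite TFN, directions drawn from the closed vocabulary, a valid
#' `lo < hi` window on every target-range criterion, and non-negative
#' cells on benefit/cost criteria. Errors name the offending cell or
#' criterion.
#'
#' @param dm A [fuzzy_decision_matrix()].
#' @return `dm`, invisibly, if valid; otherwise an error.
#' @export
validate_decision_matrix <- function(dm) {
  cells <- dm$cells
  alt <- dm$alternatives
  crit <- dm$criteria
  if (nrow(alt) != dim(cells)[1L] || nrow(crit) != dim(cells)[2L]) {
    stop("cells dimensions do not match alternatives/criteria", call. = FALSE)
  }
  ok_dir <- crit$direction %in% c("benefit", "cost", "target_range")
  if (!all(ok_dir)) {
    stop("criterion ", crit$id[!ok_dir][1L], ": unknown direction '",
         crit$direction[!ok_dir][1L], "'", call. = FALSE)
  }
  for (j in seq_len(nrow(crit))) {
    if (crit$direction[j] == "target_range") {
      lo <- crit$target_lo[j]; hi <- crit$target_hi[j]
      if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
        stop("criterion ", crit$id[j],
             ": target_range needs a window with target_lo < target_hi",
             call. = FALSE)
      }
    }
    for (i in seq_len(nrow(alt))) {
      v <- cells[i, j, ]
      if (anyNA(v) || !all(is.finite(v))) {
        stop("cell ", alt$code[i], "/", crit$id[j], ": non-finite component",
             call. = FALSE)
      }
      if (v[1L] > v[2L] || v[2L] > v[3L]) {
        stop(sprintf("cell %s/%s: invalid TFN (%g, %g, %g), need l <= m <= u",
                     alt$code[i], crit$id[j], v[1L], v[2L], v[3L]),
             call. = FALSE)
      }
      if (crit$direction[j] %in% c("benefit", "cost") && v[1L] < 0) {
        stop("cell ", alt$code[i], "/", crit$id[j],
             ": negative component on a ", crit$direction[j], " criterion",
             call. = FALSE)
      }
    }
  }
  invisible(dm)
}

#' @export
print.fuzzy_decision_matrix <- function(x, ...) {
  cat(sprintf("Fuzzy decision matrix: %d alternatives x %d criteria\n",
              nrow(x$alternatives), nrow(x$criteria)))
  cat("Criteria:\n")
  for (j in seq_len(nrow(x$criteria))) {
    cr <- x$criteria[j, ]
    extra <- if (cr$direction == "target_range") {
      sprintf(" [window %g-%g]", cr$target_lo, cr$target_hi)
    } else ""
    cat(sprintf("  %s %s (%s, %s%s)\n", cr$id, cr$name, cr$units,
                cr$direction, extra))
  }
  cat("Alternatives:", paste(x$alternatives$code, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one cell as a TFN
#'
#' @param dm A [fuzzy_decision_matrix()].
#' @param alt Alternative code or row index.
#' @param crit Criterion id or column index.
#' @return A [tfn()].
#' @export
dm_cell <- function(dm, alt, crit) {
  as_tfn(dm$cells[alt, crit, ])
}

#' Per-criterion fuzzy weights
#'
#' Couples each criterion's fuzzy local weight (a dimensionless TFN) with
#' its crisp global weight. If global weights are not supplied they are
#' derived by defuzzifying the local TFNs and normalising to sum 1.
#'
#' @param id Character vector of criterion ids.
#' @param local An `n x 3` numeric matrix of local-weight TFNs (or a list
#'   of TFNs).
#' @param global Optional numeric vector of crisp global weights; must be
#'   non-negative and is normalised to sum exactly 1.
#' @param method Defuzzification used when `global` is absent; see
#'   [defuzzify()].
#' @return An object of class `weight_vector`: a data frame with columns
#'   `id`, `l`, `m`, `u`, `global`.
#' @export
weight_vector <- function(id, local, global = NULL,
                          method = c("centroid", "graded_mean")) {
  method <- match.arg(method)
  if (!is.matrix(local)) {
    local <- do.call(rbind, lapply(local, function(x) unclass(as_tfn(x))))
  }
  id <- as.character(id)
  if (length(id) != nrow(local)) {
    stop("id and local weights disagree in length", call. = FALSE)
  }
  if (any(local < 0)) stop("fuzzy weight components must be non-negative", call. = FALSE)
  bad <- local[, 1L] > local[, 2L] | local[, 2L] > local[, 3L]
  if (any(bad)) {
    stop("weight ", id[bad][1L], ": invalid TFN ordering", call. = FALSE)
  }
  if (is.null(global)) {
    crisp <- apply(local, 1L, function(v) defuzzify(as_tfn(v), method = method))
    global <- crisp / sum(crisp)
  } else {
    global <- as.numeric(global)
    if (length(global) != length(id)) stop("global weights wrong length", call. = FALSE)
    if (any(global < 0)) stop("global weights must be non-negative", call. = FALSE)
    s <- sum(global)
    if (s <= 0) stop("global weights sum to zero", call. = FALSE)
    if (abs(s - 1) > 1e-9) global <- global / s
  }
  structure(
    data.frame(id = id, l = local[, 1L], m = local[, 2L], u = local[, 3L],
               global = global, row.names = NULL),
    class = c("weight_vector", "data.frame")
  )
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("Fuzzy criterion weights\n")
  df <- data.frame(
    id = x$id,
    local = sprintf("(%.3g, %.3g, %.3g)", x$l, x$m, x$u),
    global = sprintf("%.1f%%", 100 * x$global)
  )
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

weight_tfn <- function(w, j) as_tfn(c(w$l[j], w$m[j], w$u[j]))
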