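#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) is an ordered triple `(l, m, u)` --
#' pessimistic bound, modal (most likely) value, optimistic bound -- whose
#' membership function rises linearly from `l` to 1 at `m` and falls back to
#' zero at `u`. TFNs are the atom of this package: property evidence,
#' pairwise-comparison judgements and criterion weights are all TFNs. A
#' "crisp" TFN has `l = m = u` and behaves exactly like the ordinary real
#' number it collapses to.
#'
#' @param l Lower bound.
#' @param m Modal value; defaults to `l`.
#' @param u Upper bound; defaults to `m`.
#'
#' @return An object of class `tfn`: a named numeric vector `c(l, m, u)`.
#'
#' @examples
#' tfn(1, 3, 5)
#' tfn(4)          # crisp 4
#' @export
tfn <- function(l, m = l, u = m) {
  x <- c(as.numeric(l), as.numeric(m), as.numeric(u))
  if (length(x) != 3L || anyNA(x) || !all(is.finite(x))) {
    stop("a TFN needs three finite components (l, m, u)", call. = FALSE)
  }
  if (x[1L] > x[2L] || x[2L] > x[3L]) {
    stop(sprintf("invalid TFN (%g, %g, %g): components must satisfy l <= m <= u",
                 x[1L], x[2L], x[3L]), call. = FALSE)
  }
  new_tfn(x)
}

new_tfn <- function(x) {
  structure(as.numeric(x), names = c("l", "m", "u"), class = "tfn")
}

#' Coerce to a TFN
#'
#' @param x A `tfn`, or a numeric vector of length 3 (taken as `(l, m, u)`)
#'   or length 1 (taken as crisp).
#' @return A `tfn`.
#' @export
as_tfn <- function(x) {
  if (inherits(x, "tfn")) return(x)
  x <- as.numeric(x)
  if (length(x) == 1L) return(tfn(x))
  if (length(x) == 3L) return(tfn(x[1L], x[2L], x[3L]))
  stop("cannot coerce length-", length(x), " vector to a TFN", call. = FALSE)
}

#' @export
print.tfn <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.tfn <- function(x, digits = 4, ...) {
  sprintf("TFN(%s, %s, %s)",
          format(x[[1L]], digits = digits),
          format(x[[2L]], digits = digits),
          format(x[[3L]], digits = digits))
}

#' Is a TFN crisp?
#'
#' @param a A `tfn`.
#' @param tol Absolute tolerance on `u - l`.
#' @return `TRUE` if `l = m = u` within `tol`.
#' @export
is_crisp <- function(a, tol = 0) {
  a <- as_tfn(a)
  (a[[3L]] - a[[1L]]) <= tol
}

#' TFN addition
#'
#' Component-wise sum, the standard extension-principle result for
#' triangular numbers.
#'
#' @param a,b TFNs (or coercible).
#' @return The sum, a `tfn`.
#' @export
tfn_add <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  new_tfn(unclass(a) + unclass(b))
}

#' TFN multiplication (non-negative operands)
#'
#' Component-wise product `(l1*l2, m1*m2, u1*u2)`. This is the usual
#' triangular approximation: the exact product of two TFNs is not
#' triangular, but on non-negative operands the component-wise form
#' preserves ordering and is the convention used throughout fuzzy
#' AHP/TOPSIS. Negative components are rejected because the approximation
#' (and this pipeline) is only valid on the non-negative domain.
#'
#' @param a,b Non-negative TFNs.
#' @return The approximate product, a `tfn`.
#' @export
tfn_mul <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  if (a[[1L]] < 0 || b[[1L]] < 0) {
    stop("tfn_mul is defined only for non-negative TFNs", call. = FALSE)
  }
  new_tfn(unclass(a) * unclass(b))
}

#' TFN reciprocal
#'
#' `(1/u, 1/m, 1/l)` -- the standard triangular approximation of the
#' inverse, used for reciprocal pairwise-comparison entries and for the
#' normalising inverse in Chang's extent analysis.
#'
#' @param a A TFN with strictly positive lower bound.
#' @return The reciprocal, a `tfn`.
#' @export
tfn_reciprocal <- function(a) {
  a <- as_tfn(a)
  if (a[[1L]] <= 0) {
    stop("tfn_reciprocal requires a strictly positive lower bound", call. = FALSE)
  }
  new_tfn(rev(1 / unclass(a)))
}

#' Component-wise geometric mean of TFNs
#'
#' Consolidates several fuzzy judgements of the same quantity (e.g. a panel
#' of experts rating one pairwise comparison) into one TFN:
#' `((prod l)^(1/K), (prod m)^(1/K), (prod u)^(1/K))`.
#'
#' @param items A list of TFNs (or coercibles), or a K x 3 numeric matrix
#'   with one judgement per row.
#' @return A `tfn`.
#' @export
tfn_geometric_mean <- function(items) {
  if (is.matrix(items)) {
    m <- items
  } else {
    if (length(items) == 0L) stop("empty collection of TFNs", call. = FALSE)
    m <- do.call(rbind, lapply(items, function(x) unclass(as_tfn(x))))
  }
  if (nrow(m) == 0L) stop("empty collection of TFNs", call. = FALSE)
  if (any(m <= 0)) {
    stop("geometric mean requires strictly positive components", call. = FALSE)
  }
  new_tfn(exp(colMeans(log(m))))
}

#' Vertex distance between two TFNs
#'
#' `d(A, B) = sqrt((1/3) * ((l1-l2)^2 + (m1-m2)^2 + (u1-u2)^2))`. On crisp
#' numbers this reduces to the absolute difference; it is the distance used
#' to measure separation from the fuzzy ideal solutions in TOPSIS.
#'
#' @param a,b TFNs.
#' @return A non-negative scalar.
#' @export
vertex_distance <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  sqrt(sum((unclass(a) - unclass(b))^2) / 3)
}

#' Defuzzify a TFN to a single representative value
#'
#' Two conventions are offered: the centroid `(l + m + u) / 3` (default)
#' and the graded mean `(l + 4m + u) / 6`, which weights the modal value
#' more heavily. Both are documented so that any crisp summary derived
#' from fuzzy quantities is auditable.
#'
#' @param a A TFN.
#' @param method `"centroid"` or `"graded_mean"`.
#' @return A scalar.
#' @examples
#' defuzzify(tfn(20, 45, 65))                        # 43.33
#' defuzzify(tfn(1, 3, 5), method = "graded_mean")   # 3
#' @export
defuzzify <- function(a, method = c("centroid", "graded_mean")) {
  a <- as_tfn(a)
  method <- match.arg(method)
  switch(method,
         centroid    = (a[[1L]] + a[[2L]] + a[[3L]]) / 3,
         graded_mean = (a[[1L]] + 4 * a[[2L]] + a[[3L]]) / 6)
}
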