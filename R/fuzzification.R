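#' Literature evidence intervals
#'
#' Quantitative material properties reported across independent studies
#' rarely agree: fabrication route, filler loading and testing protocol
#' all shift the measured value. An `evidence_interval` records the range
#' `[low, high]` observed across studies, plus a free-form provenance note.
#'
#' @param low,high Interval bounds in criterion units, `low <= high`.
#' @param source_note Free-form provenance text.
#' @return An object of class `evidence_interval`.
#' @export
evidence_interval <- function(low, high, source_note = "") {
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high)) {
    stop("interval bounds must be finite", call. = FALSE)
  }
  if (low > high) {
    stop(sprintf("invalid interval [%g, %g]: low > high", low, high),
         call. = FALSE)
  }
  structure(list(low = low, high = high, source_note = as.character(source_note)),
            class = "evidence_interval")
}

#' @export
print.evidence_interval <- function(x, ...) {
  cat(sprintf("[%g, %g]", x$low, x$high))
  if (nzchar(x$source_note)) cat(" —", x$source_note)
  cat("\n")
  invisible(x)
}

#' Fuzzify an evidence interval
#'
#' An interval `[a, b]` becomes the TFN `(a, (a + b) / 2, b)`: the bounds
#' are kept as the pessimistic/optimistic vertices and the midpoint is
#' taken as the modal value. This retains the spread that a single crisp
#' midpoint would discard.
#'
#' @param iv An [evidence_interval()] (or a numeric length-2 vector).
#' @return A [tfn()].
#' @examples
#' tfn_from_interval(evidence_interval(4, 12))   # TFN(4, 8, 12)
#' @export
tfn_from_interval <- function(iv) {
  if (is.numeric(iv) && length(iv) == 2L) iv <- evidence_interval(iv[1L], iv[2L])
  if (!inherits(iv, "evidence_interval")) {
    stop("expected an evidence_interval", call. = FALSE)
  }
  tfn(iv$low, (iv$low + iv$high) / 2, iv$high)
}

# Five-point linguistic scale for expert judgements. VH is deliberately
# right-saturated at 9 (the scale ceiling), VL left-saturated at 1.
.linguistic_scale <- list(
  VL = c(1, 1, 3),
  L  = c(1, 3, 5),
  M  = c(3, 5, 7),
  H  = c(5, 7, 9),
  VH = c(7, 9, 9)
)

#' The linguistic judgement scale
#'
#' @return A data frame mapping the five linguistic labels (VL, L, M, H,
#'   VH) to their TFNs on the 1-9 importance scale.
#' @export
linguistic_scale <- function() {
  data.frame(
    label = names(.linguistic_scale),
    l = vapply(.linguistic_scale, `[`, numeric(1), 1L),
    m = vapply(.linguistic_scale, `[`, numeric(1), 2L),
    u = vapply(.linguistic_scale, `[`, numeric(1), 3L),
    row.names = NULL
  )
}

#' Fuzzify a linguistic term
#'
#' Maps the closed five-label vocabulary used for expert ratings onto the
#' 1-9 fuzzy importance scale: VL (1,1,3), L (1,3,5), M (3,5,7), H (5,7,9),
#' VH (7,9,9).
#'
#' @param term One of `"VL"`, `"L"`, `"M"`, `"H"`, `"VH"`.
#' @return A [tfn()].
#' @export
tfn_from_linguistic <- function(term) {
  term <- as.character(term)
  if (length(term) != 1L || !term %in% names(.linguistic_scale)) {
    stop(sprintf("unknown linguistic term %s; expected one of %s",
                 deparse(term), paste(names(.linguistic_scale), collapse = ", ")),
         call. = FALSE)
  }
  as_tfn(.linguistic_scale[[term]])
}

#' Load the packaged composite-scaffold case study
#'
#' Returns the package's five-alternative, six-criterion fuzzy decision
#' matrix for load-bearing bone-tissue-engineering scaffold selection:
#' five polymer-matrix composites (PLA/HA, PCL/HA, PLGA/BG, PLA/CNT,
#' PLA/Mg) scored on compressive strength, elastic modulus, porosity,
#' degradation rate (target window 12-26 weeks), cell viability and a 1-9
#' manufacturing-cost index.
#'
#' The five property criteria carry literature-derived TFNs. The
#' cost-index column is a package default: linguistic cost ratings mapped
#' through the 1-9 scale (PLA/HA L, PCL/HA L, PLGA/BG M, PLA/CNT H,
#' PLA/Mg M), flagged as an assumption in the fixture file and
#' overridable by supplying your own matrix. Any headline result that
#' depends on the cost column holds under this documented assumption.
#'
#' @param path Path to a fixture JSON; defaults to the packaged study.
#' @return A [fuzzy_decision_matrix()].
#' @seealso [study_weights()], [published_ranking()]
#' @export
load_study_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scaffold_study.json",
                        package = "scaffoldmcdm", mustWork = TRUE)
  }
  read_decision_matrix_json(path)
}

#' Criterion weights for the packaged case study
#'
#' The fuzzy local weights and crisp global weights used in the packaged
#' study (derived by a fuzzy-AHP expert panel; shipped here as fixture
#' inputs). Global weights are fractions summing to 1.
#'
#' @param path Path to a fixture JSON; defaults to the packaged study.
#' @return A [weight_vector()].
#' @export
study_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scaffold_study.json",
                        package = "scaffoldmcdm", mustWork = TRUE)
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$weights)) stop("fixture has no weights block", call. = FALSE)
  parse_weights_block(doc$weights)
}

#' Published reference ranking for the packaged case study
#'
#' The reference ranking table shipped with the case study: per
#' alternative, the reported closeness coefficient, distances to the fuzzy
#' positive/negative ideal solutions, rank and classification label.
#' These printed values serve as comparison data for the package's own
#' recomputation; they are inputs, not outputs.
#'
#' @param path Path to a fixture JSON; defaults to the packaged study.
#' @return A data frame with columns `rank`, `code`, `name`, `cc`,
#'   `d_pos`, `d_neg`, `label`.
#' @export
published_ranking <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scaffold_study.json",
                        package = "scaffoldmcdm", mustWork = TRUE)
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$published_ranking)) {
    stop("fixture has no published_ranking block", call. = FALSE)
  }
  rows <- doc$published_ranking
  data.frame(
    rank  = vapply(rows, function(r) as.integer(r$rank), integer(1)),
    code  = vapply(rows, function(r) as.character(r$code), character(1)),
    name  = vapply(rows, function(r) as.character(r$name), character(1)),
    cc    = vapply(rows, function(r) as.numeric(r$cc), numeric(1)),
    d_pos = vapply(rows, function(r) as.numeric(r$d_pos), numeric(1)),
    d_neg = vapply(rows, function(r) as.numeric(r$d_neg), numeric(1)),
    label = vapply(rows, function(r) as.character(r$label), character(1)),
    row.names = NULL
  )
}
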