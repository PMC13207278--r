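#' Weighting scenario
#'
#' A declarative perturbation of a baseline weight vector, expressed as
#' per-criterion directives: `multiply` scales a criterion's weight by a
#' factor; `set_global` pins a criterion's crisp global weight to an
#' absolute share, with the unpinned criteria scaled proportionally into
#' the remaining share. After the directives are applied the crisp
#' weights are renormalized to sum exactly 1, and each criterion's fuzzy
#' local triple is scaled by the same overall factor as its crisp weight
#' so the fuzzy ranking reflects the scenario.
#'
#' @param name Scenario name.
#' @param multiply Named numeric vector of multiplicative factors
#'   (criterion id -> factor); unnamed criteria keep factor 1.
#' @param set_global Named numeric vector of absolute crisp shares
#'   (criterion id -> share, shares summing to at most 1). A pinned
#'   criterion's fuzzy local weight becomes the crisp share itself.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, multiply = NULL, set_global = NULL) {
  if (!is.null(multiply) && (is.null(names(multiply)) || any(multiply < 0))) {
    stop("multiply must be a named non-negative vector", call. = FALSE)
  }
  if (!is.null(set_global)) {
    if (is.null(names(set_global)) || any(set_global < 0) ||
        sum(set_global) > 1 + 1e-12) {
      stop("set_global must be named, non-negative, and sum to at most 1",
           call. = FALSE)
    }
  }
  structure(list(name = as.character(name), multiply = multiply,
                 set_global = set_global),
            class = "scenario_spec")
}

#' Apply a scenario to a baseline weight vector
#'
#' @param baseline A [weight_vector()].
#' @param scenario A [scenario_spec()].
#' @return A [weight_vector()] with crisp weights summing exactly to 1.
#' @export
apply_scenario <- function(baseline, scenario) {
  ids <- baseline$id
  w <- stats::setNames(baseline$global, ids)
  new_w <- w

  if (!is.null(scenario$multiply)) {
    unknown <- setdiff(names(scenario$multiply), ids)
    if (length(unknown)) stop("unknown criteria in multiply: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    new_w[names(scenario$multiply)] <-
      new_w[names(scenario$multiply)] * scenario$multiply
  }
  pinned <- character(0)
  if (!is.null(scenario$set_global)) {
    pinned <- names(scenario$set_global)
    unknown <- setdiff(pinned, ids)
    if (length(unknown)) stop("unknown criteria in set_global: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    rest <- setdiff(ids, pinned)
    rest_mass <- sum(new_w[rest])
    new_w[pinned] <- scenario$set_global[pinned]
    if (length(rest) > 0L && rest_mass > 0) {
      new_w[rest] <- new_w[rest] * (1 - sum(scenario$set_global)) / rest_mass
    }
  }

  z <- sum(new_w)
  if (z <= 0) stop("scenario produces an all-zero weight vector", call. = FALSE)
  new_w <- new_w / z
  # scale each fuzzy triple by the same overall factor its crisp weight
  # received; pinned criteria get the crisp share itself as their fuzzy
  # weight (the directive states an absolute share, not a rescaling)
  scale <- ifelse(w > 0, new_w / w, 0)
  local <- cbind(baseline$l * scale, baseline$m * scale, baseline$u * scale)
  for (p in pinned) {
    local[match(p, ids), ] <- new_w[[p]]
  }
  weight_vector(id = ids, local = local, global = new_w)
}

#' The five standard weighting scenarios
#'
#' Builds the default sensitivity battery around a baseline weight
#' vector over criteria `C1..C6`:
#' \itemize{
#'   \item Baseline -- the input weights unchanged;
#'   \item Biological Focus -- cell viability (C5) and degradation rate
#'     (C4) doubled, mechanical criteria (C1, C2) halved;
#'   \item Mechanical Focus -- compressive strength (C1) and elastic
#'     modulus (C2) doubled, biological criteria (C5, C4) halved;
#'   \item Equal Weights -- every criterion pinned to 1/6 (16.7%);
#'   \item Cost Focus -- manufacturing cost (C6) raised to 40%, the
#'     remaining weight distributed proportionally.
#' }
#' Porosity (C3) stays at baseline in both focus scenarios (cost C6 too),
#' entering only through the final renormalization.
#'
#' @param baseline A [weight_vector()] covering ids C1..C6.
#' @return A list of five [scenario_spec()]s.
#' @export
build_default_scenarios <- function(baseline) {
  need <- paste0("C", 1:6)
  if (!all(need %in% baseline$id)) {
    stop("default scenarios need criteria ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  list(
    scenario_spec("Baseline"),
    scenario_spec("Biological Focus",
                  multiply = c(C5 = 2, C4 = 2, C1 = 0.5, C2 = 0.5)),
    scenario_spec("Mechanical Focus",
                  multiply = c(C1 = 2, C2 = 2, C5 = 0.5, C4 = 0.5)),
    scenario_spec("Equal Weights",
                  set_global = stats::setNames(rep(1 / 6, 6), paste0("C", 1:6))),
    scenario_spec("Cost Focus", set_global = c(C6 = 0.40))
  )
}

#' Rank stability across weighting scenarios
#'
#' Reruns the fuzzy TOPSIS ranking under each scenario and summarises how
#' stable every alternative's position is: its closeness coefficient per
#' scenario, its best and worst rank, and how often it takes rank 1.
#'
#' @param matrix A [fuzzy_decision_matrix()].
#' @param scenarios A list of [scenario_spec()]s, e.g. from
#'   [build_default_scenarios()].
#' @param baseline A [weight_vector()] the scenarios perturb.
#' @param decay_anchor Passed to [run_fuzzy_topsis()].
#' @param labels Optional report labels, see [run_fuzzy_topsis()].
#' @return An object of class `stability_report`: a list with
#'   `rankings` (one `ranking_result` per scenario), `cc_grid`
#'   (scenario x alternative matrix of closeness coefficients),
#'   `rank_grid`, and `stability` (per alternative: `min_rank`,
#'   `max_rank`, `top_count`).
#' @export
run_sensitivity <- function(matrix, scenarios, baseline,
                            decay_anchor = 200, labels = NULL) {
  if (length(scenarios) == 0L) stop("no scenarios supplied", call. = FALSE)
  names(scenarios) <- vapply(scenarios, function(s) s$name, character(1))
  rankings <- lapply(scenarios, function(s) {
    w <- apply_scenario(baseline, s)
    run_fuzzy_topsis(matrix, w, decay_anchor = decay_anchor, labels = labels)
  })
  codes <- sort(rankings[[1L]]$code)
  cc_grid <- t(vapply(rankings, function(r) {
    stats::setNames(r$cc, r$code)[codes]
  }, numeric(length(codes))))
  rank_grid <- t(vapply(rankings, function(r) {
    stats::setNames(r$rank, r$code)[codes]
  }, numeric(length(codes))))
  colnames(cc_grid) <- colnames(rank_grid) <- codes
  stability <- data.frame(
    code = codes,
    min_rank = apply(rank_grid, 2L, min),
    max_rank = apply(rank_grid, 2L, max),
    top_count = apply(rank_grid, 2L, function(r) sum(r == 1L)),
    row.names = NULL
  )
  structure(list(rankings = rankings, cc_grid = cc_grid,
                 rank_grid = rank_grid, stability = stability),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, digits = 3, ...) {
  cat(sprintf("Sensitivity analysis: %d scenarios x %d alternatives\n",
              nrow(x$cc_grid), ncol(x$cc_grid)))
  cat("\nCloseness coefficients by scenario:\n")
  print(round(x$cc_grid, digits))
  cat("\nRank stability:\n")
  print.data.frame(x$stability, row.names = FALSE)
  invisible(x)
}
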