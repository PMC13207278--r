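#' Read a fuzzy decision matrix from JSON
#'
#' The JSON schema mirrors the in-memory container: an `alternatives`
#' list (objects with `code`, `name` and optional extras such as `label`),
#' a `criteria` list (`id`, `name`, `units`, `direction`, optional
#' `target` window `[lo, hi]`), and a `matrix` object keyed by
#' alternative code then criterion id, each cell a 3-element `[l, m, u]`
#' array.
#'
#' @param path Path to a JSON file.
#' @return A [fuzzy_decision_matrix()].
#' @export
read_decision_matrix_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$alternatives) || is.null(doc$criteria) || is.null(doc$matrix)) {
    stop("decision-matrix JSON needs 'alternatives', 'criteria' and 'matrix' ",
         "blocks: ", path, call. = FALSE)
  }
  alt <- do.call(rbind, lapply(doc$alternatives, function(a) {
    data.frame(code = as.character(a$code), name = as.character(a$name),
               label = if (is.null(a$label)) NA_character_ else as.character(a$label))
  }))
  crit <- do.call(rbind, lapply(doc$criteria, function(cr) {
    tw <- if (is.null(cr$target)) c(NA_real_, NA_real_) else as.numeric(unlist(cr$target))
    data.frame(id = as.character(cr$id),
               name = if (is.null(cr$name)) as.character(cr$id) else as.character(cr$name),
               units = if (is.null(cr$units)) "" else as.character(cr$units),
               direction = as.character(cr$direction),
               target_lo = tw[1L], target_hi = tw[2L])
  }))
  cells <- array(NA_real_, dim = c(nrow(alt), nrow(crit), 3L))
  for (i in seq_len(nrow(alt))) {
    row <- doc$matrix[[alt$code[i]]]
    if (is.null(row)) stop("matrix block missing alternative ", alt$code[i],
                           call. = FALSE)
    for (j in seq_len(nrow(crit))) {
      cell <- row[[crit$id[j]]]
      if (is.null(cell)) stop("matrix cell missing: ", alt$code[i], "/",
                              crit$id[j], call. = FALSE)
      v <- as.numeric(unlist(cell))
      if (length(v) != 3L) stop("cell ", alt$code[i], "/", crit$id[j],
                                " is not a [l, m, u] triple", call. = FALSE)
      cells[i, j, ] <- v
    }
  }
  fuzzy_decision_matrix(cells, alt, crit)
}

#' Write a fuzzy decision matrix to JSON
#'
#' @param dm A [fuzzy_decision_matrix()].
#' @param path Output path.
#' @param weights Optional [weight_vector()] embedded as a `weights` block.
#' @param extra Optional named list of additional top-level blocks
#'   (e.g. notes), written as-is.
#' @return `path`, invisibly.
#' @export
write_decision_matrix_json <- function(dm, path, weights = NULL, extra = NULL) {
  alt_list <- lapply(seq_len(nrow(dm$alternatives)), function(i) {
    a <- dm$alternatives[i, ]
    out <- list(code = a$code, name = a$name)
    if (!is.null(a$label) && !is.na(a$label)) out$label <- a$label
    out
  })
  crit_list <- lapply(seq_len(nrow(dm$criteria)), function(j) {
    cr <- dm$criteria[j, ]
    out <- list(id = cr$id, name = cr$name, units = cr$units,
                direction = cr$direction)
    if (cr$direction == "target_range") out$target <- c(cr$target_lo, cr$target_hi)
    out
  })
  mat <- stats::setNames(lapply(seq_len(nrow(dm$alternatives)), function(i) {
    stats::setNames(lapply(seq_len(nrow(dm$criteria)), function(j) {
      as.numeric(dm$cells[i, j, ])
    }), dm$criteria$id)
  }), dm$alternatives$code)
  doc <- list(alternatives = alt_list, criteria = crit_list, matrix = mat)
  if (!is.null(weights)) doc$weights <- weights_block(weights)
  if (!is.null(extra)) doc <- c(doc, extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

weights_block <- function(w) {
  lapply(seq_len(nrow(w)), function(j) {
    list(id = w$id[j], local = c(w$l[j], w$m[j], w$u[j]), global = w$global[j])
  })
}

parse_weights_block <- function(block) {
  ids <- vapply(block, function(x) as.character(x$id), character(1))
  local <- do.call(rbind, lapply(block, function(x) as.numeric(unlist(x$local))))
  global <- vapply(block, function(x) {
    if (!is.null(x$global)) as.numeric(x$global)
    else if (!is.null(x$global_pct)) as.numeric(x$global_pct) / 100
    else NA_real_
  }, numeric(1))
  if (anyNA(global)) {
    weight_vector(id = ids, local = local)
  } else {
    weight_vector(id = ids, local = local, global = global)
  }
}

#' Read / write a weight vector (JSON)
#'
#' JSON weights are a list of objects with `id`, `local` (`[l, m, u]`)
#' and either `global` (fraction) or `global_pct` (percentage); with
#' neither, crisp weights are derived by centroid defuzzification.
#'
#' @param path File path.
#' @return [read_weight_vector_json()] returns a [weight_vector()].
#' @export
read_weight_vector_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  block <- if (!is.null(doc$weights)) doc$weights else doc
  parse_weights_block(block)
}

#' @rdname read_weight_vector_json
#' @param w A [weight_vector()].
#' @export
write_weight_vector_json <- function(w, path) {
  jsonlite::write_json(list(weights = weights_block(w)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a weight vector (CSV)
#'
#' Columns: `id`, `l`, `m`, `u`, `global` (fraction). Comma-separated,
#' UTF-8, `.` decimal, header row mandatory, full precision.
#'
#' @param path File path.
#' @return [read_weight_vector_csv()] returns a [weight_vector()].
#' @export
read_weight_vector_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "l", "m", "u", "global")
  if (!all(need %in% names(df))) {
    stop("weights CSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  weight_vector(id = df$id, local = as.matrix(df[, c("l", "m", "u")]),
                global = df$global)
}

#' @rdname read_weight_vector_csv
#' @param w A [weight_vector()].
#' @export
write_weight_vector_csv <- function(w, path) {
  utils::write.csv(as.data.frame(unclass(w)), path, row.names = FALSE)
  invisible(path)
}

#' Write a decision matrix as CSV (matrix + criteria metadata)
#'
#' The cell grid goes to `path` with columns `code`, `name` and three
#' adjacent columns `<id>_l, <id>_m, <id>_u` per criterion; criterion
#' metadata goes to `criteria_path` (`id`, `name`, `units`, `direction`,
#' `target_lo`, `target_hi`).
#'
#' @param dm A [fuzzy_decision_matrix()].
#' @param path Matrix CSV path.
#' @param criteria_path Criteria CSV path; default derives
#'   `<path>_criteria.csv`.
#' @return `path`, invisibly.
#' @export
write_decision_matrix_csv <- function(dm, path,
                                      criteria_path = sub("\\.csv$", "_criteria.csv", path)) {
  df <- data.frame(code = dm$alternatives$code, name = dm$alternatives$name)
  for (j in seq_len(nrow(dm$criteria))) {
    id <- dm$criteria$id[j]
    df[[paste0(id, "_l")]] <- dm$cells[, j, 1L]
    df[[paste0(id, "_m")]] <- dm$cells[, j, 2L]
    df[[paste0(id, "_u")]] <- dm$cells[, j, 3L]
  }
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(dm$criteria, criteria_path, row.names = FALSE)
  invisible(path)
}

#' Read a decision matrix from CSV (matrix + criteria metadata)
#'
#' @param path Matrix CSV path (schema of [write_decision_matrix_csv()]).
#' @param criteria_path Criteria CSV path.
#' @return A [fuzzy_decision_matrix()].
#' @export
read_decision_matrix_csv <- function(path,
                                     criteria_path = sub("\\.csv$", "_criteria.csv", path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  crit <- utils::read.csv(criteria_path, stringsAsFactors = FALSE)
  cells <- array(NA_real_, dim = c(nrow(df), nrow(crit), 3L))
  for (j in seq_len(nrow(crit))) {
    for (k in 1:3) {
      col <- paste0(crit$id[j], "_", c("l", "m", "u")[k])
      if (is.null(df[[col]])) stop("matrix CSV missing column ", col, call. = FALSE)
      cells[, j, k] <- df[[col]]
    }
  }
  fuzzy_decision_matrix(cells, df[, c("code", "name")], crit)
}

#' Write a ranking report as CSV
#'
#' One row per alternative: `rank`, `code`, `name`, `cc`, `d_pos`,
#' `d_neg`, `label` at full precision, plus a rounded `cc_display`
#' column (3 d.p.) for report tables.
#'
#' @param rr A `ranking_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(rr, path) {
  df <- as.data.frame(unclass(rr))[, c("rank", "code", "name", "cc",
                                       "d_pos", "d_neg", "label")]
  df$cc_display <- sprintf("%.3f", df$cc)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read scenario specifications from YAML or JSON
#'
#' The file holds a list of scenarios, each with a `name` and optional
#' `multiply` / `set_global` maps from criterion id to factor/share (see
#' [scenario_spec()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of [scenario_spec()]s.
#' @export
read_scenarios <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  lapply(raw, function(s) {
    scenario_spec(
      name = s$name,
      multiply = if (is.null(s$multiply)) NULL else unlist(s$multiply),
      set_global = if (is.null(s$set_global)) NULL else unlist(s$set_global)
    )
  })
}

#' Read an expert panel of fuzzy comparison matrices from JSON
#'
#' Schema: `criteria` (list of ids) and `experts`, each with a `name`
#' and an `n x n` `matrix` whose entries are `[l, m, u]` triples,
#' linguistic labels (`"VL"`, `"L"`, `"M"`, `"H"`, `"VH"`), crisp
#' numbers, or `null` in the lower triangle (filled as reciprocals).
#'
#' @param path Path to a JSON file.
#' @return A list of [fuzzy_comparison_matrix()], one per expert.
#' @export
read_panel_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$experts)) stop("panel JSON needs an 'experts' block", call. = FALSE)
  ids <- if (is.null(doc$criteria)) NULL else as.character(unlist(doc$criteria))
  lapply(doc$experts, function(ex) {
    rows <- lapply(ex$matrix, function(row) {
      lapply(row, function(cell) {
        if (is.null(cell)) NULL
        else if (is.character(cell)) cell
        else as.numeric(unlist(cell))
      })
    })
    fuzzy_comparison_matrix(rows, ids = ids)
  })
}

#' Write a machine-readable provenance record
#'
#' Every pipeline run emits, next to its results, a JSON record of the
#' package version, R version, timestamp and the full configuration that
#' produced the outputs, so any result file can be traced to its inputs.
#'
#' @param path Output path.
#' @param config Named list echoed verbatim into the record.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config = list()) {
  rec <- list(
    package = "scaffoldmcdm",
    version = as.character(utils::packageVersion("scaffoldmcdm")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
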