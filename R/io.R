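#' @section File formats:
#' All writers emit deterministic output: fixed column order and an exact
#' shortest-decimal rendering of doubles (no locale effects), so repeated
#' runs are byte-identical and outputs are diffable. All readers accept the
#' writers' output, so every file round-trips.
#' @name markovprev-io
NULL

# shortest decimal string that parses back to exactly x
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    for (d in 1:17) {
      s <- format(v, digits = d, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == v) return(s)
    }
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
}

write_lines_deterministic <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

csv_cell <- function(x) {
  if (is.numeric(x)) fmt_num(x) else as.character(x)
}

write_csv_deterministic <- function(df, path) {
  cells <- lapply(df, csv_cell)
  body <- do.call(paste, c(cells, sep = ","))
  write_lines_deterministic(c(paste(names(df), collapse = ","), body), path)
}

# base read.csv keeps strtod parsing, which round-trips fmt_num output
# bit-exactly; `classes` maps column name -> colClass for the typed columns
read_csv_checked <- function(path, required, classes = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path))
  }
  header <- tryCatch(
    utils::read.csv(path, nrows = 1, check.names = FALSE),
    error = function(e) {
      rlang::abort(paste0("Failed to parse ", path, ": ", conditionMessage(e)))
    })
  missing <- setdiff(required, names(header))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      path, ": missing required column(s): ", paste(missing, collapse = ", "),
      " (header must contain ", paste(required, collapse = ","), ")"))
  }
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = classes),
    error = function(e) {
      rlang::abort(paste0("Failed to parse ", path, ": ", conditionMessage(e)))
    })
  tibble::as_tibble(df)
}

#' Read and write prevalence tables
#'
#' CSV with header `state,prevalence`, one row per state.
#'
#' @param path File path.
#' @param prevalence Data frame with columns `state`, `prevalence`.
#' @return `read_prevalence_csv()` returns a tibble `state`, `prevalence`;
#'   `write_prevalence_csv()` returns `path` invisibly.
#' @export
read_prevalence_csv <- function(path) {
  df <- read_csv_checked(path, c("state", "prevalence"),
                         classes = c(state = "character",
                                     prevalence = "numeric"))
  df[c("state", "prevalence")]
}

#' @rdname read_prevalence_csv
#' @export
write_prevalence_csv <- function(prevalence, path) {
  write_csv_deterministic(prevalence[c("state", "prevalence")], path)
  invisible(path)
}

#' Read and write the model-structure JSON
#'
#' One JSON document describing everything but the prevalences: `states`
#' (ordered list), `absorbing` (list), `edges` (list of `[from, to]` pairs),
#' `death_rates` (map state -> probability) and `exponent` (number).
#'
#' @param path File path.
#' @param model A list with elements `states`, `absorbing`, `moves` (tibble
#'   `from`, `to`), `deaths` (tibble `state`, `death_prob`) and `exponent`,
#'   as returned by [rwanda_inputs()] or [generate_model()].
#' @return `read_model_json()` returns such a list; `write_model_json()`
#'   returns `path` invisibly.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    rlang::abort(paste0("Failed to parse ", path, ": ",
                                        conditionMessage(e)))
                  })
  for (key in c("states", "absorbing", "edges", "death_rates", "exponent")) {
    if (!key %in% names(doc)) {
      rlang::abort(paste0(path, ": missing required key `", key, "`"))
    }
  }
  edges <- doc$edges
  moves <- if (length(edges) == 0) {
    tibble::tibble(from = character(), to = character())
  } else if (is.matrix(edges)) {
    tibble::tibble(from = edges[, 1], to = edges[, 2])
  } else {
    tibble::tibble(from = vapply(edges, `[`, character(1), 1),
                   to = vapply(edges, `[`, character(1), 2))
  }
  dr <- unlist(doc$death_rates)
  deaths <- if (length(dr) == 0) {
    tibble::tibble(state = character(), death_prob = numeric())
  } else {
    tibble::tibble(state = names(dr), death_prob = unname(dr))
  }
  list(states = as.character(doc$states),
       absorbing = as.character(doc$absorbing),
       moves = moves, deaths = deaths,
       exponent = as.numeric(doc$exponent))
}

#' @rdname read_model_json
#' @export
write_model_json <- function(model, path) {
  edges <- purrr::map2(model$moves$from, model$moves$to, ~ c(.x, .y))
  doc <- list(
    states = model$states,
    absorbing = model$absorbing,
    edges = edges,
    death_rates = stats::setNames(as.list(model$deaths$death_prob),
                                  model$deaths$state),
    exponent = model$exponent
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_lines_deterministic(json, path)
  invisible(path)
}

#' Read and write transition matrices as CSV
#'
#' State labels form the header row and the first column; values are written
#' at full precision.
#'
#' @param matrix A `transition_matrix`.
#' @param path File path.
#' @param absorbing Absorbing state labels to attach on read (the CSV itself
#'   carries only the probabilities).
#' @return `read_matrix_csv()` returns a `transition_matrix`;
#'   `write_matrix_csv()` returns `path` invisibly.
#' @export
write_matrix_csv <- function(matrix, path) {
  mat <- as.matrix(matrix)
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = ",")
  }, character(1))
  write_lines_deterministic(
    c(paste(c("state", colnames(mat)), collapse = ","), rows), path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path, absorbing = character()) {
  df <- read_csv_checked(path, "state", classes = c(state = "character"))
  states <- df$state
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- states
  if (!identical(colnames(mat), states)) {
    rlang::abort(paste0(path, ": column labels do not match row labels."))
  }
  suppressWarnings(as_transition_matrix(mat, absorbing = absorbing))
}

#' Read and write projection trajectories
#'
#' Long format is `year,state,prevalence` at full precision; the optional
#' wide format has one column per state.
#'
#' @param trajectory A `prevalence_trajectory`.
#' @param path,path_wide File paths (`path_wide = NULL` skips the wide file).
#' @return `read_trajectory_csv()` returns a tibble `year`, `state`,
#'   `prevalence`; `write_trajectory_csv()` returns `path` invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, path_wide = NULL) {
  long <- dplyr::select(tibble::as_tibble(trajectory),
                        "year", "state", "prevalence")
  write_csv_deterministic(long, path)
  if (!is.null(path_wide)) {
    write_csv_deterministic(trajectory_wide(trajectory), path_wide)
  }
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read_csv_checked(path, c("year", "state", "prevalence"),
                         classes = c(year = "numeric", state = "character",
                                     prevalence = "numeric"))
  df[c("year", "state", "prevalence")]
}

#' Write a simulated cohort with its provenance sidecar
#'
#' The CSV holds `step,state,count`; the JSON sidecar records the seed, the
#' cohort size and a checksum of the transition matrix used, so a simulation
#' can be traced back to its exact inputs.
#'
#' @param cohort A `cohort_trajectory` from [simulate_cohort()].
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @param matrix The `transition_matrix` used for the simulation (for the
#'   checksum); optional.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, matrix = NULL) {
  write_csv_deterministic(
    dplyr::select(tibble::as_tibble(cohort), "step", "state", "count"), path)
  sidecar <- list(
    seed = attr(cohort, "seed"),
    n_subjects = attr(cohort, "n_subjects"),
    matrix_checksum = if (is.null(matrix)) NULL else matrix_checksum(matrix)
  )
  write_lines_deterministic(
    jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read_csv_checked(path, c("step", "state", "count"),
                         classes = c(step = "integer", state = "character",
                                     count = "integer"))
  df[c("step", "state", "count")]
}

#' MD5 checksum of a transition matrix's exact contents
#'
#' @param matrix A `transition_matrix` or plain matrix.
#' @return A length-1 character MD5 digest over the labels and the exact
#'   decimal rendering of every entry, row-major.
#' @export
matrix_checksum <- function(matrix) {
  mat <- as.matrix(matrix)
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  write_lines_deterministic(
    c(paste(colnames(mat), collapse = ","), fmt_num(as.vector(t(mat)))), tmp)
  unname(tools::md5sum(tmp))
}
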