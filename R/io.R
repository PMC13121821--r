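#' Read a CSV response matrix
#'
#' Expects a header row of item ids and one row of 0/1 cells per examinee;
#' an optional first identifier column (named `id` or `examinee_id`, or
#' any non-numeric first column) supplies examinee labels. File order
#' defines arrival order. In strict mode any empty or non-binary cell is
#' rejected with its row and column; in masked mode empty cells become
#' `NA` (item not presented).
#'
#' @param path CSV file path.
#' @param masked Allow missing cells?
#' @return List with `responses` (`N x J` numeric matrix, item ids as
#'   column names), `item_ids`, and `examinee_ids` (or `NULL`).
#' @export
read_response_matrix <- function(path, masked = FALSE) {
  if (!file.exists(path)) stop(sprintf("response file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, colClasses = NA,
                 na.strings = if (masked) c("", "NA") else character(0))
  if (nrow(df) == 0L || ncol(df) == 0L) stop(sprintf("empty response file: %s", path))
  examinee_ids <- NULL
  first <- names(df)[1L]
  if (tolower(first) %in% c("id", "examinee_id") ||
      (!is.numeric(df[[1L]]) && !all(as.character(df[[1L]]) %in% c("0", "1", NA)))) {
    examinee_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  bad <- which(!(is.na(mat) & masked) & !(mat %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-binary cell '%s' at row %d, column '%s' of %s",
                 format(mat[bad[1L, 1L], bad[1L, 2L]]), bad[1L, 1L],
                 colnames(mat)[bad[1L, 2L]], path))
  }
  list(responses = mat, item_ids = colnames(mat), examinee_ids = examinee_ids)
}

#' Write a response matrix as CSV
#'
#' Inverse of [read_response_matrix()].
#'
#' @param responses `N x J` 0/1 matrix with item ids as column names.
#' @param path Output path.
#' @param examinee_ids Optional labels written as a leading `id` column.
#' @export
write_response_matrix <- function(responses, path, examinee_ids = NULL) {
  df <- as.data.frame(responses)
  if (!is.null(examinee_ids)) df <- cbind(id = examinee_ids, df)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Stream examinee records from a JSONL file
#'
#' One JSON object per line: `{"id": "...", "y": [0, 1, ...]}`. Returns a
#' lazy iterator holding only an open connection, so memory use is
#' constant in the number of records.
#'
#' @param path JSONL file path.
#' @param J Expected item count; each record's `y` is validated against it
#'   when given.
#' @return A function; each call returns the next record as a
#'   [response_vector()] or `NULL` at end of file. The iterator carries a
#'   `close` attribute to release the connection early.
#' @export
stream_responses <- function(path, J = NULL) {
  if (!file.exists(path)) stop(sprintf("response stream not found: %s", path))
  con <- file(path, open = "r")
  line_no <- 0L
  done <- FALSE
  nxt <- function() {
    if (done) return(NULL)
    repeat {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (length(line) == 0L) {
        done <<- TRUE
        close(con)
        return(NULL)
      }
      line_no <<- line_no + 1L
      if (nzchar(trimws(line))) break
    }
    rec <- tryCatch(jsonlite::fromJSON(line), error = function(e) {
      stop(sprintf("malformed JSONL at line %d of %s: %s",
                   line_no, path, conditionMessage(e)))
    })
    if (is.null(rec$y)) stop(sprintf("record at line %d of %s has no 'y' field", line_no, path))
    y <- as.numeric(rec$y)
    if (!is.null(J) && length(y) != J) {
      stop(sprintf("record at line %d of %s has %d responses; expected J = %d",
                   line_no, path, length(y), J))
    }
    response_vector(y, examinee_id = rec$id, masked = TRUE)
  }
  attr(nxt, "close") <- function() if (!done) { done <<- TRUE; close(con) }
  nxt
}

#' Streaming fit from a JSONL record stream
#'
#' Drives [fit_online()] over a [stream_responses()] iterator in fixed-size
#' chunks, so arbitrarily long streams are fitted in constant memory.
#'
#' @param path JSONL file path.
#' @param J Item count.
#' @param config [estimator_config()].
#' @param chunk_size Records per engine call.
#' @param ... Passed to [fit_online()] (e.g. `start`, `checkpoints`).
#' @return An `irtstream_fit`; its `eap` matrix covers the whole stream.
#' @export
fit_stream <- function(path, J, config = estimator_config(),
                       chunk_size = 1000L, ...) {
  it <- stream_responses(path, J = J)
  fit <- NULL
  eap_all <- list()
  ids <- character(0)
  repeat {
    chunk <- matrix(NA_real_, chunk_size, J)
    cids <- character(chunk_size)
    m <- 0L
    while (m < chunk_size) {
      rec <- it()
      if (is.null(rec)) break
      m <- m + 1L
      chunk[m, ] <- rec$values
      cids[m] <- if (is.null(rec$examinee_id)) "" else rec$examinee_id
    }
    if (m == 0L) break
    chunk <- chunk[seq_len(m), , drop = FALSE]
    fit <- if (is.null(fit)) {
      fit_online(chunk, config, ...)
    } else {
      fit_online(chunk, config, resume = fit, ...)
    }
    eap_all[[length(eap_all) + 1L]] <- fit$eap
    ids <- c(ids, cids[seq_len(m)])
    if (m < chunk_size) break
  }
  if (is.null(fit)) stop(sprintf("no records in %s", path))
  fit$eap <- do.call(rbind, eap_all)
  fit$examinee_ids <- ids
  fit
}

#' Write / read a trajectory of real-time estimates as JSONL
#'
#' Each record is one line holding the examinee index `n`, the averaged
#' item-parameter snapshot, the step size in force, and the examinee's EAP
#' score. Numbers are serialized at 17 significant digits so a read-back
#' reproduces the estimates exactly.
#'
#' @param records List of `trajectory_record` objects (from
#'   [process_examinee()]) or an `irtstream_fit` (its checkpoints are
#'   written).
#' @param path Output path.
#' @export
write_trajectory <- function(records, path) {
  if (inherits(records, "irtstream_fit")) {
    fit <- records
    records <- lapply(seq_along(fit$checkpoints), function(i) {
      structure(list(n = fit$checkpoints[i],
                     beta_avg = fit$checkpoint_avg[, , i, drop = FALSE][, , 1L],
                     eap = NULL, step = step_size(fit$checkpoints[i], fit$config),
                     examinee_id = NULL),
                class = "trajectory_record")
    })
  }
  con <- file(path, open = "w")
  on.exit(close(con))
  # numbers serialized at 17 significant digits: the shortest length
  # guaranteeing exact binary round-trip for doubles
  num <- function(x) sprintf("%.17g", x)
  arr <- function(x) paste0("[", paste(num(x), collapse = ","), "]")
  for (rec in records) {
    dims <- dim(as.matrix(rec$beta_avg))
    fields <- c(
      sprintf('"n":%d', as.integer(rec$n)),
      sprintf('"beta_avg":%s', arr(as.vector(rec$beta_avg))),
      sprintf('"dim":[%d,%d]', dims[1L], dims[2L]),
      sprintf('"step":%s', num(rec$step)))
    if (!is.null(rec$eap)) fields <- c(fields, sprintf('"eap":%s', arr(rec$eap)))
    if (!is.null(rec$examinee_id)) {
      fields <- c(fields,
                  sprintf('"id":%s', jsonlite::toJSON(rec$examinee_id, auto_unbox = TRUE)))
    }
    writeLines(paste0("{", paste(fields, collapse = ","), "}"), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory()`: list of `trajectory_record` objects.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], function(line) {
    obj <- jsonlite::fromJSON(line)
    structure(
      list(n = obj$n,
           beta_avg = matrix(obj$beta_avg, obj$dim[1L], obj$dim[2L]),
           eap = obj$eap, step = obj$step, examinee_id = obj$id),
      class = "trajectory_record")
  })
}

#' Write final parameter estimates (and standard errors) as CSV
#'
#' One row per item parameter, columns `item_id, parameter, estimate,
#' standard_error, anchored`. For a unidimensional fit the classical
#' `(a, b)` parameterization is reported alongside the slope-intercept
#' entries.
#'
#' @param fit An `irtstream_fit` (or an [item_param_set()] with `ses`
#'   supplied separately).
#' @param path Output path.
#' @param ses Optional `(Q+1) x J` matrix of standard errors.
#' @return The table, invisibly written to `path`.
#' @export
write_parameter_table <- function(fit, path, ses = NULL) {
  if (inherits(fit, "irtstream_fit")) {
    params <- fit$params
    if (is.null(ses)) ses <- fit$se
  } else {
    params <- fit
  }
  stopifnot(inherits(params, "item_param_set"))
  B <- param_matrix(params)
  Q <- params$Q
  free <- free_matrix(params)
  pn <- c(sprintf("a%d", seq_len(Q)), "d")
  if (Q == 1L) pn <- c("a", "d")
  rows <- list()
  for (j in seq_len(params$J)) {
    for (p in seq_len(Q + 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        item_id = params$item_ids[j], parameter = pn[p],
        estimate = B[p, j],
        standard_error = if (is.null(ses)) NA_real_ else ses[p, j],
        anchored = !free[p, j])
    }
    if (Q == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        item_id = params$item_ids[j], parameter = "b",
        estimate = difficulty(params$items[[j]]),
        standard_error = NA_real_, anchored = !any(free[, j]))
    }
  }
  tab <- do.call(rbind, rows)
  write.csv(format(tab, digits = 17, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Load and validate a run configuration from YAML or JSON
#'
#' Recognized keys: `model` (`2pl`/`m2pl`), `estimator`
#' (`tasna`/`tsna`/`em`), `Q`, `K`, the [estimator_config()] schedule
#' fields, `input`, `out_dir`, `seed`, and `checkpoints`. Unknown keys are
#' rejected by name.
#'
#' @param path `.yaml`/`.yml`/`.json` file.
#' @return List of class `run_config` with an `estimator_config` element
#'   built from the schedule fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("model", "estimator", "Q", "K", "gamma", "c_nu", "n0",
               "c_lambda", "alpha_lambda", "avg_mode", "avg_w",
               "gradient_at", "s0", "input", "out_dir", "seed",
               "checkpoints", "chunk_size")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  model <- match.arg(tolower(raw$model %||% "2pl"), c("2pl", "m2pl"))
  estimator <- match.arg(tolower(raw$estimator %||% "tasna"),
                         c("tasna", "tsna", "em"))
  Q <- as.integer(raw$Q %||% if (model == "2pl") 1L else 2L)
  if (model == "2pl" && Q != 1L) stop("model '2pl' requires Q = 1")
  ec_args <- raw[intersect(names(raw), c("gamma", "c_nu", "n0", "c_lambda",
                                         "alpha_lambda", "avg_mode", "avg_w",
                                         "gradient_at", "s0"))]
  ec <- NULL
  if (estimator != "em") {
    ec <- do.call(estimator_config,
                  c(list(method = estimator, K = as.integer(raw$K %||% 11L),
                         Q = Q, seed = as.integer(raw$seed %||% 1L)),
                    ec_args))
  }
  structure(
    list(model = model, estimator = estimator, Q = Q,
         K = as.integer(raw$K %||% 11L),
         estimator_config = ec,
         input = raw$input, out_dir = raw$out_dir %||% ".",
         seed = as.integer(raw$seed %||% 1L),
         checkpoints = as.integer(raw$checkpoints %||% integer(0)),
         chunk_size = as.integer(raw$chunk_size %||% 1000L)),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a response matrix as a JSONL record stream
#'
#' Inverse of [stream_responses()]: one `{"id": ..., "y": [...]}` object
#' per line, preserving row order.
#'
#' @param responses `N x J` 0/1 matrix.
#' @param path Output path.
#' @param examinee_ids Optional labels (defaults to `e1 ... eN`).
#' @export
write_responses_jsonl <- function(responses, path, examinee_ids = NULL) {
  responses <- as.matrix(responses)
  N <- nrow(responses)
  if (is.null(examinee_ids)) examinee_ids <- sprintf("e%d", seq_len(N))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(N)) {
    writeLines(jsonlite::toJSON(list(id = examinee_ids[i],
                                     y = unname(responses[i, ])),
                                auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' Read a parameter table written by [write_parameter_table()]
#'
#' Reconstructs the [item_param_set()] from the slope-intercept rows
#' (`a1..aQ`/`a` and `d`); derived `b` rows are ignored.
#'
#' @param path CSV path.
#' @return An [item_param_set()].
#' @export
read_parameter_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  need <- c("item_id", "parameter", "estimate")
  if (!all(need %in% names(tab))) {
    stop(sprintf("parameter table %s lacks columns: %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  tab <- tab[tab$parameter != "b", , drop = FALSE]
  ids <- unique(tab$item_id)
  slopes <- sort(unique(tab$parameter[tab$parameter != "d"]))
  Q <- length(slopes)
  items <- lapply(ids, function(id) {
    rows <- tab[tab$item_id == id, , drop = FALSE]
    a <- vapply(slopes, function(p) rows$estimate[rows$parameter == p][1L], numeric(1L))
    d <- rows$estimate[rows$parameter == "d"][1L]
    free <- if ("anchored" %in% names(rows)) {
      !vapply(c(slopes, "d"), function(p) {
        isTRUE(as.logical(rows$anchored[rows$parameter == p][1L]))
      }, logical(1L))
    } else rep(TRUE, Q + 1L)
    item_param(a, d, free = free, id = id)
  })
  item_param_set(items, item_ids = as.character(ids))
}
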