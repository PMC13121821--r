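#' Item parameters for a single 2PL/M2PL item
#'
#' An item is stored in slope-intercept form: a loading (discrimination)
#' vector `a` of length `Q` and a scalar intercept `d`, giving the correct
#' response probability `plogis(a . theta + d)`. The classical 2PL
#' difficulty parameterization `a (theta - b)` is the `Q = 1` case with
#' `d = -a b`; use [item_2pl()] to construct from `(a, b)` and
#' [difficulty()] to convert back.
#'
#' @param loadings Numeric vector of `Q` discrimination values.
#' @param intercept Scalar intercept on the logit scale.
#' @param free Logical vector of length `Q + 1` marking which entries
#'   (loadings then intercept) are estimable; anchored (`FALSE`) entries are
#'   never changed by any estimator.
#' @param id Optional item label.
#'
#' @return An object of class `item_param`.
#' @export
item_param <- function(loadings, intercept, free = NULL, id = NULL) {
  loadings <- as.numeric(loadings)
  stopifnot(length(intercept) == 1L, is.finite(intercept), all(is.finite(loadings)))
  Q <- length(loadings)
  if (is.null(free)) free <- rep(TRUE, Q + 1L)
  free <- as.logical(free)
  if (length(free) != Q + 1L) {
    stop(sprintf("free mask has length %d; expected Q + 1 = %d", length(free), Q + 1L))
  }
  structure(
    list(loadings = loadings, intercept = as.numeric(intercept),
         free = free, id = id),
    class = "item_param"
  )
}

#' @rdname item_param
#' @param a,b 2PL discrimination and difficulty.
#' @export
item_2pl <- function(a, b, free = NULL, id = NULL) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  item_param(loadings = a, intercept = -a * b, free = free, id = id)
}

#' An ordered collection of item parameters
#'
#' @param items List of [item_param()] objects sharing a common dimension
#'   count `Q`.
#' @param item_ids Optional character vector of labels (defaults to ids
#'   stored on the items, else `item1 ... itemJ`).
#'
#' @return An object of class `item_param_set`: a list with `items`, `J`,
#'   `Q`, `item_ids`.
#' @export
item_param_set <- function(items, item_ids = NULL) {
  stopifnot(is.list(items), length(items) >= 1L)
  ok <- vapply(items, inherits, logical(1L), what = "item_param")
  if (!all(ok)) stop("all elements must be item_param objects")
  Qs <- vapply(items, function(it) length(it$loadings), integer(1L))
  if (length(unique(Qs)) != 1L) stop("all items must share the same dimension count Q")
  J <- length(items)
  if (is.null(item_ids)) {
    item_ids <- vapply(seq_len(J), function(j) {
      id <- items[[j]]$id
      if (is.null(id)) sprintf("item%d", j) else as.character(id)
    }, character(1L))
  }
  stopifnot(length(item_ids) == J)
  structure(
    list(items = items, J = J, Q = Qs[[1L]], item_ids = item_ids),
    class = "item_param_set"
  )
}

#' @export
print.item_param_set <- function(x, ...) {
  cat(sprintf("item_param_set: J = %d items, Q = %d dimension(s), %d anchored\n",
              x$J, x$Q, sum(!vapply(x$items, function(it) any(it$free), logical(1L)))))
  invisible(x)
}

#' @rdname item_param
#' @param x An `item_param` with `Q = 1`.
#' @export
difficulty <- function(x) {
  stopifnot(inherits(x, "item_param"), length(x$loadings) == 1L)
  if (x$loadings == 0) return(NA_real_)
  -x$intercept / x$loadings
}

# --- internal matrix views ----------------------------------------------

# (Q+1) x J matrix of stacked (loadings, intercept) columns
param_matrix <- function(params) {
  vapply(params$items, function(it) c(it$loadings, it$intercept),
         numeric(params$Q + 1L))
}

# (Q+1) x J logical matrix of free masks
free_matrix <- function(params) {
  vapply(params$items, function(it) it$free, logical(params$Q + 1L))
}

# rebuild an item_param_set from a (Q+1) x J matrix, preserving masks/ids
set_param_matrix <- function(params, B) {
  B <- as.matrix(B)
  stopifnot(nrow(B) == params$Q + 1L, ncol(B) == params$J)
  items <- lapply(seq_len(params$J), function(j) {
    it <- params$items[[j]]
    item_param(B[seq_len(params$Q), j], B[params$Q + 1L, j],
               free = it$free, id = it$id)
  })
  item_param_set(items, item_ids = params$item_ids)
}

#' A single examinee's binary response record
#'
#' @param values Length-`J` vector of 0/1 responses. In masked mode
#'   (`masked = TRUE`) entries may be `NA`, meaning the item was not
#'   presented; in strict mode any `NA` is rejected.
#' @param examinee_id Optional label.
#' @param masked Allow missing entries?
#'
#' @return An object of class `response_vector`.
#' @export
response_vector <- function(values, examinee_id = NULL, masked = FALSE) {
  values <- as.numeric(values)
  obs <- !is.na(values)
  if (!masked && !all(obs)) {
    stop("missing responses are not allowed in strict mode (use masked = TRUE)")
  }
  bad <- obs & !(values %in% c(0, 1))
  if (any(bad)) {
    stop(sprintf("non-binary response value %s at position %d",
                 format(values[which(bad)[1L]]), which(bad)[1L]))
  }
  structure(
    list(values = values, observed = obs, examinee_id = examinee_id),
    class = "response_vector"
  )
}
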