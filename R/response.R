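#' Index scores of individuals
#'
#' Scores every individual as the linear combination of its GEBVs with the
#' index weights: `score_i = sum_j b_j * gebv_ij`.
#'
#' @param gebv m-by-n numeric matrix of GEBVs (rows = individuals, columns
#'   = traits), optionally with row names as individual ids.
#' @param b index weight vector of length n.
#' @return Numeric vector of m scores, named after the individuals when
#'   `gebv` has row names.
#' @export
index_scores <- function(gebv, b) {
  gebv <- as.matrix(gebv)
  b <- as.numeric(b)
  if (ncol(gebv) != length(b)) {
    stop("gebv has ", ncol(gebv), " trait columns but b has length ",
         length(b), call. = FALSE)
  }
  drop(gebv %*% b)
}

#' Select the top-scoring individuals
#'
#' Returns the row indices of the `n_select` highest scores. Ties at the
#' selection cutoff are broken deterministically by input order (earlier
#' rows win), so a run is reproducible for any score vector.
#'
#' @param scores numeric score vector.
#' @param n_select number of individuals to keep, between 1 and
#'   `length(scores)`.
#' @return Integer vector of `n_select` row indices, ordered by decreasing
#'   score (input order within ties).
#' @export
select_top <- function(scores, n_select) {
  m <- length(scores)
  if (!is.numeric(n_select) || length(n_select) != 1 || is.na(n_select) ||
      n_select < 1 || n_select > m) {
    stop("n_select must be a single integer in [1, ", m, "]", call. = FALSE)
  }
  # order() with the radix method is stable: ties keep input order
  order(-scores, method = "radix")[seq_len(as.integer(n_select))]
}

#' Standardized selection response
#'
#' The realised selection response of a selected subset, expressed per
#' trait as the number of standard deviations by which the subset's mean
#' GEBV differs from the whole population's mean:
#' `g_j = (mean(selected_j) - mean(all_j)) / sd(all_j)`,
#' with the sample standard deviation (denominator m - 1). The response is
#' invariant to rescaling a trait and is zero for every trait when the
#' whole population is selected.
#'
#' @inheritParams index_scores
#' @param selected integer row indices (or logical mask, or row names) of
#'   the selected individuals; must be a non-empty subset.
#' @return Named numeric vector `g` of per-trait standardized responses.
#' @export
selection_response <- function(gebv, selected) {
  gebv <- as.matrix(gebv)
  if (is.character(selected)) {
    selected <- match(selected, rownames(gebv))
    if (anyNA(selected)) stop("selected ids not found in gebv", call. = FALSE)
  }
  sub <- gebv[selected, , drop = FALSE]
  if (nrow(sub) == 0) stop("selected subset is empty", call. = FALSE)
  mu <- colMeans(gebv)
  sdv <- apply(gebv, 2, sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    bad <- colnames(gebv)[zero]
    if (is.null(bad)) bad <- which(zero)
    stop("zero-variance trait(s): ", paste(bad, collapse = ", "),
         "; the standardized response is undefined", call. = FALSE)
  }
  (colMeans(sub) - mu) / sdv
}

#' Apply an index to a candidate population
#'
#' Composes [index_scores()], [select_top()] and [selection_response()]:
#' ranks the candidates with the index weights, keeps the top `n_select`,
#' and standardizes the response against the candidate population's own
#' means and standard deviations.
#'
#' @inheritParams index_scores
#' @inheritParams select_top
#' @param n_select number of individuals to select.
#' @return An object of class `"dg_selection"`: a list with elements
#'   `selected_ids` (character or integer, length `n_select`, ranked),
#'   `selected` (integer row indices), `scores` (length m) and `response`
#'   (named per-trait standardized response).
#' @export
apply_index <- function(gebv, b, n_select) {
  gebv <- as.matrix(gebv)
  scores <- index_scores(gebv, b)
  sel <- select_top(scores, n_select)
  ids <- rownames(gebv)
  structure(
    list(
      selected_ids = if (is.null(ids)) sel else ids[sel],
      selected = sel,
      scores = scores,
      response = selection_response(gebv, sel)
    ),
    class = "dg_selection"
  )
}

#' @export
print.dg_selection <- function(x, ...) {
  cat("Selection of", length(x$selected), "of", length(x$scores),
      "individuals\n")
  cat("Standardized response (population SD units):\n")
  print(round(x$response, 3))
  invisible(x)
}
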