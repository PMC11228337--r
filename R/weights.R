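#' Desired-gain index weights
#'
#' Computes the weights `b` of a desired-gain selection index from a
#' phenotypic (co)variance or correlation matrix `P`, a genetic
#' variance-covariance matrix `G`, and a vector of desired gains `d`:
#' \deqn{b = P^{-1} G (G P^{-1} G)^{-1} d}
#' so that the expected per-trait gain `G b` equals `d` exactly. The product
#' is evaluated with two linear solves (`P X = G`, then `(G' X) y = d`,
#' `b = X y`) rather than explicit inversions, for numerical stability.
#'
#' `P` is typically the correlation matrix of the reference population's
#' GEBVs (see [empirical_P()]); `G` the REML genetic covariance matrix, used
#' on whatever scale it is supplied.
#'
#' @param G n-by-n symmetric genetic variance-covariance matrix.
#' @param P n-by-n symmetric positive-definite phenotypic matrix (here
#'   usually the correlation between GEBVs).
#' @param d numeric vector of desired gains, length n, in population-SD
#'   units. Only its direction affects the ranking of individuals: scaling
#'   `d` scales `b` by the same factor.
#' @param jitter if `TRUE`, add `1e-8` to the diagonal of a matrix whose
#'   condition number exceeds `max_cond` instead of failing.
#' @param max_cond condition-number ceiling above which a matrix is
#'   considered numerically singular.
#'
#' @return Numeric vector `b` of length n, named after the traits when
#'   `G` has dimnames.
#' @seealso [expected_gains()] for the identity `G b = d`.
#' @examples
#' P <- diag(2); G <- diag(2)
#' dg_weights(G, P, c(1, -1))  # identity matrices: b = d
#' @export
dg_weights <- function(G, P, d, jitter = FALSE, max_cond = 1e12) {
  cv <- check_cov_pair(G, P)
  G <- cv$G
  P <- cv$P
  n <- nrow(G)
  d <- as.numeric(d)
  if (length(d) != n) {
    stop("length of d (", length(d), ") does not match the ", n,
         "-trait covariance matrices", call. = FALSE)
  }
  if (any(!is.finite(d))) stop("d contains non-finite entries", call. = FALSE)

  P <- guard_condition(P, "P", jitter, max_cond)
  X <- solve(P, G)                       # P X = G
  A <- crossprod(G, X)                   # G P^-1 G  (G symmetric)
  A <- guard_condition(A, "G P^-1 G", jitter, max_cond)
  b <- as.numeric(X %*% solve(A, d))
  names(b) <- rownames(G)
  b
}

#' Expected per-trait gain of an index
#'
#' Returns `G b`, the gain vector implied by index weights `b` under the
#' genetic covariance `G`. For weights computed by [dg_weights()] this
#' reproduces the desired-gain vector `d` exactly (an algebraic identity of
#' the index equation), which makes it a useful diagnostic; the *realised*
#' response of a selected subset is a different quantity, measured by
#' [selection_response()].
#'
#' @inheritParams dg_weights
#' @param b numeric index weight vector, length n.
#' @return Numeric vector `G b` of length n.
#' @examples
#' expected_gains(diag(2), c(2, 3))
#' @export
expected_gains <- function(G, b) {
  G <- as.matrix(G)
  b <- as.numeric(b)
  if (nrow(G) != ncol(G)) stop("G must be square", call. = FALSE)
  if (length(b) != nrow(G)) {
    stop("length of b (", length(b), ") does not match G (", nrow(G),
         " traits)", call. = FALSE)
  }
  g <- as.numeric(G %*% b)
  names(g) <- rownames(G)
  g
}

# Validate a (G, P) pair: square, matching dimension, symmetric to 1e-10
# (measured relative to the largest entry), consistent trait labels.
check_cov_pair <- function(G, P, tol = 1e-10) {
  G <- as.matrix(G)
  P <- as.matrix(P)
  for (nm in c("G", "P")) {
    M <- if (nm == "G") G else P
    if (nrow(M) != ncol(M)) stop(nm, " must be square", call. = FALSE)
    asym <- max(abs(M - t(M)))
    scale <- max(abs(M), 1)
    if (asym > tol * scale) {
      stop(nm, " is not symmetric (max asymmetry ", format(asym), ")",
           call. = FALSE)
    }
  }
  if (nrow(G) != nrow(P)) {
    stop("G (", nrow(G), " traits) and P (", nrow(P),
         " traits) have different dimensions", call. = FALSE)
  }
  if (!is.null(rownames(G)) && !is.null(rownames(P)) &&
      !identical(rownames(G), rownames(P))) {
    stop("trait labels of G and P differ", call. = FALSE)
  }
  # symmetrise exactly so downstream solves see clean inputs
  list(G = (G + t(G)) / 2, P = (P + t(P)) / 2)
}

# Refuse (or jitter) matrices whose 2-norm condition number exceeds max_cond.
guard_condition <- function(M, label, jitter, max_cond) {
  cn <- kappa(M, exact = TRUE)
  if (!is.finite(cn) || cn > max_cond) {
    if (jitter) {
      M <- M + diag(1e-8, nrow(M))
      cn2 <- kappa(M, exact = TRUE)
      if (!is.finite(cn2) || cn2 > max_cond) {
        stop(label, " is numerically singular even after jitter ",
             "(condition number ", format(cn2), ")", call. = FALSE)
      }
      return(M)
    }
    stop(label, " is ill-conditioned (condition number ", format(cn),
         " > ", format(max_cond), "); supply better-conditioned matrices ",
         "or set jitter = TRUE", call. = FALSE)
  }
  M
}
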