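#' Goodness of fit of a realised response against its target
#'
#' Scores how well a realised standardized response `g` matches the
#' targeted response `dg` for one trait. With the default `"canonical"`
#' form, let `r = g/dg` (so `r = 1` means the target is hit exactly, and
#' `r <= 0` means the response went in the wrong direction):
#' \itemize{
#'   \item `r >= 1/e`: `gof = ln(x)/x` with `x = e*r` — the classical
#'     unimodal `ln(x)/x` curve, maximised at `x = e` (`g = dg`) with value
#'     `1/e`, decaying slowly for overshoot and steeply for undershoot;
#'   \item `0 < r < 1/e`: the linear ramp `gof = -1/e + r`, which joins
#'     `ln(x)/x` continuously at `x = 1` and keeps every
#'     correct-direction response strictly above `-1/e`;
#'   \item `r <= 0`: `gof = -(1/e) * (1 + |r|)`, so any wrong-direction
#'     response scores strictly below every correct-direction response,
#'     and more so the further it goes.
#' }
#' The maximum `1/e` is attained exactly at `g = dg`, for either sign of
#' the target.
#'
#' The `"literal"` form evaluates
#' `log(base^2 |g|, base) / (base^2 |g|)` with `base = |e*dg|`. It is kept
#' for comparison only: it does not peak at `g = dg` and ignores the sign
#' of the response, so it is unsuitable for optimisation.
#'
#' @param g realised standardized response(s), numeric.
#' @param dg targeted response(s), numeric, no entry exactly zero (leave a
#'   trait effectively unconstrained with a large-magnitude target, e.g.
#'   4, rather than 0). Recycled against `g`.
#' @param form `"canonical"` (default) or `"literal"`.
#' @return Numeric vector of goodness-of-fit values.
#' @seealso [theta_penalty()] for the multi-trait aggregate.
#' @examples
#' gof(0.5, 0.5)            # exactly on target: 1/e
#' gof(0.25, 0.5)           # undershoot
#' gof(-0.5, 0.5)           # wrong direction: below any correct response
#' @export
gof <- function(g, dg, form = c("canonical", "literal")) {
  form <- match.arg(form)
  if (any(dg == 0)) {
    stop("dg contains a zero target; use a large-magnitude target ",
         "(e.g. +4 or -4) for traits you do not wish to constrain",
         call. = FALSE)
  }
  n <- max(length(g), length(dg))
  g <- rep_len(as.numeric(g), n)
  dg <- rep_len(as.numeric(dg), n)

  if (form == "literal") {
    base <- abs(exp(1) * dg)
    x <- base^2 * abs(g)
    return(log(x, base = base) / x)
  }

  r <- g / dg
  out <- numeric(n)
  wrong <- r <= 0
  ramp <- r > 0 & r < exp(-1)
  main <- r >= exp(-1)
  out[wrong] <- -exp(-1) * (1 + abs(r[wrong]))
  out[ramp] <- -exp(-1) + r[ramp]
  x <- exp(1) * r[main]
  out[main] <- log(x) / x
  out
}

#' Maximum attainable goodness of fit
#'
#' The value of [gof()] at `g = dg`. Under the canonical form this is
#' `1/e` for any nonzero target, of either sign.
#'
#' @inheritParams gof
#' @return Numeric vector, `gof(dg, dg, form)`.
#' @examples
#' gof_max(0.5)   # 1/e
#' gof_max(-4)    # also 1/e
#' @export
gof_max <- function(dg, form = c("canonical", "literal")) {
  form <- match.arg(form)
  gof(dg, dg, form = form)
}

#' Penalty of a sampled desired-gain vector
#'
#' Aggregates per-trait goodness of fit into the deviation measure
#' \deqn{\theta = \sum_j (gofMAX_j - gof_j) / gofMAX_j}
#' between a realised response vector `g` and the targeted response `dg`.
#' Under the canonical form, `theta >= 0` always, and `theta = 0` exactly
#' when `g = dg` componentwise; a smaller `theta` means better alignment.
#'
#' @param g realised standardized response vector.
#' @param dg targeted response vector, same length, no zero entries.
#' @inheritParams gof
#' @return A single non-negative number (canonical form).
#' @examples
#' theta_penalty(c(0.5, 0.5), c(0.5, 0.5))    # 0
#' theta_penalty(c(0.25, 0.5), c(0.5, 0.5))   # ~0.386
#' @export
theta_penalty <- function(g, dg, form = c("canonical", "literal")) {
  form <- match.arg(form)
  if (length(g) != length(dg)) {
    stop("g and dg must have the same length", call. = FALSE)
  }
  gm <- gof_max(dg, form = form)
  sum((gm - gof(g, dg, form = form)) / gm)
}
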