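#' Fit an iterative desired-gain selection index
#'
#' Optimises a desired-gain selection index so that the *realised*
#' standardized response of the top `n_select` individuals of a reference
#' GEBV population matches a user-specified target response `target` as
#' closely as possible.
#'
#' The desired-gain vector `d` fed into the index equation
#' `b = P^-1 G (G P^-1 G)^-1 d` guarantees the *expected* gain `G b = d`,
#' but not the realised response of a truncation-selected subset. `dgi()`
#' therefore treats `d` as a free parameter and searches it stochastically:
#' starting from `d = target`, each iteration draws a proposal for every
#' trait from a normal distribution centred on the most recently accepted
#' `d` (SD `proposal_sd`), computes the index weights, ranks the reference
#' population, selects the top `n_select`, measures their standardized
#' response `g` ([selection_response()]), and scores the proposal with the
#' penalty `theta` ([theta_penalty()]). A proposal is accepted only if it
#' strictly lowers `theta`, so the accepted `theta` sequence is
#' non-increasing and the final fit is never worse than the classical
#' single-pass method ([dgi_baseline()]).
#'
#' @param reference m-by-n numeric matrix (or data frame) of reference
#'   GEBVs; rows are individuals (row names used as ids), columns are
#'   traits in the same order as `G`, `P` and `target`.
#' @param target numeric vector of targeted standardized responses, one
#'   per trait, in population-SD units; the sign gives the desired
#'   direction and no entry may be zero (use a large magnitude such as
#'   +-4 to leave a trait effectively unconstrained).
#' @param G n-by-n genetic variance-covariance matrix.
#' @param P n-by-n phenotypic matrix; defaults to the correlation matrix
#'   of the reference GEBVs ([empirical_P()]).
#' @param n_select number of individuals selected each iteration
#'   (default 100).
#' @param iterations number of optimisation iterations (default 1000);
#'   `0` reproduces the classical no-iteration method.
#' @param proposal_sd standard deviation of the proposal distribution in
#'   desired-gain units (default 0.5).
#' @param seed optional integer seed; fixing it makes the fit
#'   bit-reproducible.
#' @param jitter,gof_form passed to [dg_weights()] and [gof()].
#'
#' @return An object of class `"dgi"`, a list with components
#'   \describe{
#'     \item{d}{the best accepted desired-gain vector,}
#'     \item{b}{its index weights (also via [coef()]),}
#'     \item{response}{the realised standardized response of the selected
#'       reference subset (targets minus this via [residuals()]),}
#'     \item{theta}{the final penalty,}
#'     \item{selected_ids, scores}{the final reference selection,}
#'     \item{trajectory}{a data frame (iteration, theta, accepted) with
#'       iteration 0 the starting state `d = target`,}
#'     \item{baseline}{the no-iteration fit at `d = target`.}
#'   }
#' @seealso [predict.dgi()], [summary.dgi()], [dgi_replicates()]
#' @examples
#' p <- wheat_params(m_ref = 400, m_cand = 300)
#' pop <- simulate_gebv(p, m = 400, seed = 1)
#' fit <- dgi(pop$gebv, target = wheat_targets()$equal,
#'            G = genetic_covariance(p), n_select = 20,
#'            iterations = 50, seed = 2)
#' fit
#' @export
dgi <- function(reference, target, G, P = NULL, n_select = 100,
                iterations = 1000, proposal_sd = 0.5, seed = NULL,
                jitter = FALSE, gof_form = c("canonical", "literal")) {
  cl <- match.call()
  gof_form <- match.arg(gof_form)
  reference <- as_gebv_matrix(reference)
  if (is.null(P)) P <- empirical_P(reference)
  cv <- check_cov_pair(G, P)
  G <- cv$G
  P <- cv$P
  n <- nrow(G)
  traits <- trait_names(reference, G, P, target)
  target <- as.numeric(target)
  if (length(target) != n) {
    stop("target has length ", length(target), " but there are ", n,
         " traits", call. = FALSE)
  }
  if (any(target == 0)) {
    stop("target contains a zero entry; use a large-magnitude target ",
         "for unconstrained traits", call. = FALSE)
  }
  if (ncol(reference) != n) {
    stop("reference has ", ncol(reference), " trait columns but the ",
         "matrices have ", n, call. = FALSE)
  }
  stopifnot(iterations >= 0, proposal_sd > 0)
  if (!is.null(seed)) set.seed(seed)

  # fixed pieces of the per-iteration evaluation
  P <- guard_condition(P, "P", jitter, 1e12)
  X <- solve(P, G)
  A <- guard_condition(crossprod(G, X), "G P^-1 G", jitter, 1e12)
  M <- reference %*% X                 # scores for d are M solve(A, d)
  mu <- colMeans(reference)
  sdv <- apply(reference, 2, sd)
  if (any(sdv == 0)) {
    stop("zero-variance trait(s) in the reference population: ",
         paste(traits[sdv == 0], collapse = ", "), call. = FALSE)
  }

  evaluate <- function(d) {
    y <- solve(A, d)
    scores <- drop(M %*% y)
    sel <- select_top(scores, n_select)
    g <- (colMeans(reference[sel, , drop = FALSE]) - mu) / sdv
    list(d = d, y = y, g = g, theta = theta_penalty(g, target, gof_form),
         sel = sel, scores = scores)
  }

  best <- evaluate(target)
  accepted_d <- target
  theta_trace <- numeric(iterations + 1)
  accept_trace <- logical(iterations + 1)
  theta_trace[1] <- best$theta
  accept_trace[1] <- TRUE
  baseline <- best

  for (i in seq_len(iterations)) {
    d <- rnorm(n, mean = accepted_d, sd = proposal_sd)
    cand <- tryCatch(
      evaluate(d),
      error = function(e) {
        stop("iteration ", i, " failed for d = (",
             paste(signif(d, 6), collapse = ", "), "): ",
             conditionMessage(e), call. = FALSE)
      }
    )
    theta_trace[i + 1] <- cand$theta
    if (cand$theta < best$theta) {
      best <- cand
      accepted_d <- d
      accept_trace[i + 1] <- TRUE
    }
  }

  ids <- rownames(reference)
  finish <- function(st) {
    b <- as.numeric(X %*% st$y)
    names(b) <- traits
    list(
      d = setNames(st$d, traits),
      b = b,
      response = setNames(st$g, traits),
      theta = st$theta,
      selected_ids = if (is.null(ids)) st$sel else ids[st$sel],
      scores = setNames(st$scores, ids)
    )
  }
  out <- finish(best)
  structure(
    c(out,
      list(
        baseline = finish(baseline),
        trajectory = data.frame(
          iteration = 0:iterations,
          theta = theta_trace,
          accepted = accept_trace
        ),
        target = setNames(target, traits),
        traits = traits,
        m = nrow(reference),
        n_select = n_select,
        iterations = iterations,
        proposal_sd = proposal_sd,
        seed = seed,
        gof_form = gof_form,
        G = G, P = P,
        call = cl
      )),
    class = "dgi"
  )
}

#' Classical (no-iteration) desired-gain index
#'
#' The single-pass desired-gain method: the index is computed directly at
#' `d = target` and applied once, with no optimisation of the sampled
#' desired gains. Equivalent to `dgi(..., iterations = 0)`.
#'
#' @inheritParams dgi
#' @return An object of class `"dgi"` (see [dgi()]) whose fit equals its
#'   own `baseline`.
#' @export
dgi_baseline <- function(reference, target, G, P = NULL, n_select = 100,
                         jitter = FALSE,
                         gof_form = c("canonical", "literal")) {
  dgi(reference, target, G, P = P, n_select = n_select, iterations = 0,
      jitter = jitter, gof_form = match.arg(gof_form))
}

as_gebv_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("GEBVs must be numeric", call. = FALSE)
  if (anyNA(x)) stop("GEBVs contain missing values", call. = FALSE)
  x
}

# Reconcile trait labels across the inputs; first non-NULL wins, any other
# labelled input must agree.
trait_names <- function(reference, G, P, target) {
  cand <- list(colnames(reference), rownames(G), rownames(P),
               names(target))
  cand <- Filter(Negate(is.null), cand)
  if (length(cand) == 0) return(paste0("trait", seq_len(nrow(G))))
  for (x in cand[-1]) {
    if (!identical(x, cand[[1]])) {
      stop("trait labels disagree across inputs: ",
           paste(cand[[1]], collapse = ","), " vs ",
           paste(x, collapse = ","), call. = FALSE)
    }
  }
  cand[[1]]
}

#' @export
print.dgi <- function(x, digits = 3, ...) {
  cat("Iterative desired-gain selection index\n")
  cat("  ", length(x$traits), " traits, ", x$m, " reference individuals, ",
      "top ", x$n_select, " selected\n", sep = "")
  cat("  iterations: ", x$iterations, " (", sum(x$trajectory$accepted) - 1,
      " accepted), theta: ", format(x$theta, digits = digits),
      " (no-iteration: ", format(x$baseline$theta, digits = digits), ")\n",
      sep = "")
  tab <- rbind(target = x$target, response = x$response, d = x$d, b = x$b)
  colnames(tab) <- x$traits
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.dgi <- function(object, ...) object$b

#' @export
fitted.dgi <- function(object, ...) object$scores

#' @export
residuals.dgi <- function(object, ...) object$response - object$target

#' Apply a fitted desired-gain index to new individuals
#'
#' Scores a candidate GEBV table with the fitted index weights and,
#' unless `type = "scores"`, selects the top `n_select` candidates and
#' measures their standardized response against the candidate
#' population's own means and standard deviations.
#'
#' @param object a fitted `"dgi"` object.
#' @param newdata m-by-n GEBV matrix or data frame with the same trait
#'   columns as the reference population.
#' @param n_select number of candidates to select (defaults to the fitted
#'   value).
#' @param type `"selection"` (default) for the full [apply_index()] result,
#'   `"scores"` for the score vector only.
#' @param ... unused.
#' @return A `"dg_selection"` object or a numeric score vector.
#' @export
predict.dgi <- function(object, newdata, n_select = object$n_select,
                        type = c("selection", "scores"), ...) {
  type <- match.arg(type)
  newdata <- as_gebv_matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$traits)) {
    stop("candidate trait columns (", paste(colnames(newdata), collapse = ","),
         ") do not match the fitted traits (",
         paste(object$traits, collapse = ","), ")", call. = FALSE)
  }
  if (type == "scores") return(index_scores(newdata, object$b))
  apply_index(newdata, object$b, n_select)
}

#' Summarise a desired-gain index fit
#'
#' Builds the standard per-trait report: the sampled desired gain `d`, the
#' index weights `b`, the targeted response `dg`, the no-iteration
#' response, the realised reference response and (when `candidates` is
#' supplied) the realised candidate response.
#'
#' @param object a fitted `"dgi"` object.
#' @param candidates optional candidate GEBV matrix; adds a
#'   `Response_Cand` column via [predict.dgi()].
#' @param ... unused.
#' @return An object of class `"summary.dgi"` whose `table` element is the
#'   per-trait report data frame.
#' @export
summary.dgi <- function(object, candidates = NULL, ...) {
  tab <- data.frame(
    Trait = object$traits,
    Sampled_d = unname(object$d),
    Index_b = unname(object$b),
    Target_dg = unname(object$target),
    Response_NoIteration = unname(object$baseline$response),
    Response_Ref = unname(object$response),
    stringsAsFactors = FALSE
  )
  if (!is.null(candidates)) {
    tab$Response_Cand <- unname(predict(object, candidates)$response)
  }
  structure(
    list(table = tab, theta = object$theta,
         theta_baseline = object$baseline$theta,
         iterations = object$iterations,
         accepted = sum(object$trajectory$accepted) - 1L,
         n_select = object$n_select, m = object$m),
    class = "summary.dgi"
  )
}

#' @export
print.summary.dgi <- function(x, digits = 3, ...) {
  cat("Desired-gain index fit: ", x$m, " individuals, top ", x$n_select,
      " selected\n", sep = "")
  cat("theta = ", format(x$theta, digits = digits), " after ",
      x$iterations, " iterations (", x$accepted, " accepted); ",
      "no-iteration theta = ", format(x$theta_baseline, digits = digits),
      "\n\n", sep = "")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot the penalty trajectory of a fit
#'
#' Shows the proposed penalty `theta` at every iteration (points) and the
#' running best accepted `theta` (step line), with the no-iteration
#' baseline marked.
#'
#' @param x a fitted `"dgi"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dgi <- function(x, ...) {
  tr <- x$trajectory
  best <- cummin(ifelse(tr$accepted, tr$theta, Inf))
  best <- cummin(pmin(best, tr$theta[1]))
  plot(tr$iteration, pmin(tr$theta, stats::quantile(tr$theta, 0.98)),
       pch = 16, cex = 0.4, col = "grey60",
       xlab = "iteration", ylab = expression(theta), ...)
  lines(tr$iteration, best, type = "s", col = "firebrick", lwd = 2)
  abline(h = x$baseline$theta, lty = 3)
  legend("topright", bty = "n", lwd = c(NA, 2, 1), pch = c(16, NA, NA),
         lty = c(NA, 1, 3), col = c("grey60", "firebrick", "black"),
         legend = c("proposed", "best accepted", "no iteration"))
  invisible(x)
}
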