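#' Replicate runs of the iterative desired-gain index
#'
#' Runs [dgi()] `replicates` times with seeds `seed + 1, ..., seed +
#' replicates`, applies every replicate's final index to the candidate
#' population, and measures how consistent the replicates are as the mean
#' pairwise correlation between their candidate score vectors (scores,
#' rather than weight vectors, determine who gets selected, and are
#' invariant to the scale ambiguity of `b`). Use
#' `cor_method = "spearman"` to correlate candidate rankings instead.
#'
#' @inheritParams dgi
#' @param candidates candidate GEBV matrix scored by every replicate.
#' @param replicates number of replicate runs (default 20, minimum 2).
#' @param seed base seed; replicate k runs with `seed + k`.
#' @param cor_method correlation between replicate score vectors:
#'   `"pearson"` (default) or `"spearman"`.
#' @param ... further arguments to [dgi()] (`n_select`, `iterations`,
#'   `proposal_sd`, ...).
#' @return An object of class `"dgi_replicates"`: a list with `fits` (the
#'   replicate `"dgi"` objects), `scores` (candidates-by-replicates score
#'   matrix), `cor` (replicate-by-replicate correlation matrix),
#'   `mean_cor`, and `response_ref` / `response_cand`
#'   (replicates-by-traits realised response matrices).
#' @export
dgi_replicates <- function(reference, candidates, target, G, P = NULL,
                           replicates = 20, seed = 0,
                           cor_method = c("pearson", "spearman"), ...) {
  cor_method <- match.arg(cor_method)
  if (replicates < 2) stop("replicates must be at least 2", call. = FALSE)
  candidates <- as_gebv_matrix(candidates)
  fits <- vector("list", replicates)
  for (k in seq_len(replicates)) {
    fits[[k]] <- dgi(reference, target, G, P = P, seed = seed + k, ...)
  }
  scores <- vapply(fits, function(f) predict(f, candidates, type = "scores"),
                   numeric(nrow(candidates)))
  colnames(scores) <- paste0("rep", seq_len(replicates))
  cc <- cor(scores, method = cor_method)
  response_ref <- t(vapply(fits, `[[`, numeric(length(fits[[1]]$traits)),
                           "response"))
  response_cand <- t(vapply(fits,
                            function(f) predict(f, candidates)$response,
                            numeric(length(fits[[1]]$traits))))
  colnames(response_ref) <- colnames(response_cand) <- fits[[1]]$traits
  structure(
    list(fits = fits, scores = scores, cor = cc,
         mean_cor = mean(cc[upper.tri(cc)]),
         response_ref = response_ref, response_cand = response_cand,
         target = fits[[1]]$target, seed = seed,
         cor_method = cor_method),
    class = "dgi_replicates"
  )
}

#' @export
print.dgi_replicates <- function(x, digits = 3, ...) {
  cat("Desired-gain index:", length(x$fits), "replicates\n")
  cat("Mean pairwise", x$cor_method, "correlation of candidate scores:",
      format(x$mean_cor, digits = digits), "\n")
  tab <- rbind(
    target = x$target,
    `mean response (ref)` = colMeans(x$response_ref),
    `mean response (cand)` = colMeans(x$response_cand)
  )
  print(round(tab, digits))
  invisible(x)
}
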