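#' Score gene pairs for genetic interactions
#'
#' From a fitted model, lets `T_gh = y_g + y_h + s_gh` be the model-implied
#' full-efficacy double-knockdown effect and computes two additive
#' deviations per gene pair:
#' \itemize{
#'   \item sensitive: `T_gh - lambda * (y_g + y_h)` (deviation from the
#'     lambda-scaled additive expectation; equal to `s_gh` at `lambda = 1`),
#'   \item strong: `T_gh - min(y_g, y_h)` (deviation beyond the stronger
#'     single knockdown).
#' }
#' Deviations toward synthetic lethality are negative. Following the
#' screen's reporting convention, non-lethal (non-negative) deviations are
#' clipped to 0 and scores are reported as values <= 0, so that more
#' negative means a stronger interaction. Pairs with a sensitive score at or
#' below `cutoff` are flagged synthetic lethal.
#'
#' @param fit a \linkS4class{ModelFit} (a warning is emitted when the fit
#'   did not converge).
#' @param lambda scaling of the additive expectation (default 1).
#' @param cutoff synthetic-lethal flag threshold on the sensitive score
#'   (default -1).
#' @return an \linkS4class{InteractionScores}
#' @export
scoreGenePairs <- function(fit, lambda = 1, cutoff = -1) {
  stopifnot(is(fit, "ModelFit"), lambda >= 0)
  if (!fit@converged) {
    warning("scoring a model fit that did not converge")
  }
  sdf <- fit@s
  known <- sdf$gene_a %in% names(fit@y) & sdf$gene_b %in% names(fit@y)
  if (any(!known)) {
    warning(sprintf("skipping %d pair(s) with gene effects absent from the fit",
                    sum(!known)))
    sdf <- sdf[known, , drop = FALSE]
  }
  ya <- fit@y[sdf$gene_a]
  yb <- fit@y[sdf$gene_b]
  tt <- ya + yb + sdf$s
  rawSens <- tt - lambda * (ya + yb)
  rawStrong <- tt - pmin(ya, yb)
  tab <- data.frame(gene_a = sdf$gene_a, gene_b = sdf$gene_b,
                    raw_sensitive = unname(rawSens),
                    raw_strong = unname(rawStrong),
                    sensitive_score = pmin(unname(rawSens), 0),
                    strong_score = pmin(unname(rawStrong), 0),
                    stringsAsFactors = FALSE)
  tab$is_synthetic_lethal <- tab$sensitive_score <= cutoff
  new("InteractionScores", table = tab, lambda = lambda, cutoff = cutoff)
}
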