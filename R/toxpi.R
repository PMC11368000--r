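#' ToxPi scores and ranks from a POD matrix
#'
#' Integrates per-chemical PODs across the five phenotypes into a 0-1
#' toxicological priority index. Within each phenotype slice, scores are
#' linear in -log10(POD) between the slice's observed extremes:
#' \deqn{score = \frac{\log_{10} POD_{max} - \log_{10} POD}
#'                    {\log_{10} POD_{max} - \log_{10} POD_{min}}}
#' so 0 marks the highest POD (least bioactive) and 1 the lowest POD.
#' Censored or inactive entries score 0, as does every chemical in a
#' constant slice. The overall score is the weighted mean of slice scores;
#' ranking is descending, ties broken by `chemical_id`.
#'
#' @param pod_matrix Tibble with `chemical_id` and one POD column (µM) per
#'   phenotype; `Inf`/`NA` mean censored or inactive. The conventional input
#'   is the most sensitive (minimum) donor-specific POD per chemical and
#'   phenotype.
#' @param weights Named slice weights (default equal); normalized internally.
#' @return Tibble: `chemical_id`, `score_<phenotype>` slice scores,
#'   `overall_score`, `rank`, sorted by rank.
#' @export
toxpi_scores <- function(pod_matrix, weights = NULL) {
  check_columns(pod_matrix, "chemical_id", "pod_matrix")
  slices <- setdiff(names(pod_matrix), "chemical_id")
  if (nrow(pod_matrix) < 2) stop("need >= 2 chemicals for ToxPi scaling")
  if (is.null(weights)) weights <- setNames(rep(1, length(slices)), slices)
  stopifnot(all(slices %in% names(weights)), all(weights >= 0))
  w <- weights[slices] / sum(weights[slices])
  score1 <- function(pod) {
    lp <- log10(pod)
    ok <- is.finite(lp)
    out <- rep(0, length(pod))
    if (sum(ok) == 0) return(out)
    lo <- min(lp[ok]); hi <- max(lp[ok])
    if (hi > lo) out[ok] <- (hi - lp[ok]) / (hi - lo)
    out
  }
  scores <- vapply(slices, function(s) score1(pod_matrix[[s]]),
                   numeric(nrow(pod_matrix)))
  scores <- matrix(scores, nrow = nrow(pod_matrix),
                   dimnames = list(NULL, slices))
  overall <- as.numeric(scores %*% w)
  out <- tibble::tibble(chemical_id = pod_matrix$chemical_id)
  for (s in slices) out[[paste0("score_", s)]] <- scores[, s]
  out$overall_score <- overall
  out <- out[order(-out$overall_score, out$chemical_id), ]
  out$rank <- seq_len(nrow(out))
  out
}
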