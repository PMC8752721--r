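# Final regulator score: min-max-normalised -log p from the differential
# channel (P_D) and the enrichment channel (P_E), summed.

#' Min-max normalisation
#'
#' \eqn{f(x) = (x - \min x) / (\max x - \min x)}; a constant vector maps
#' to all zeros (documented convention), so an uninformative channel
#' contributes nothing to the combined score.
#'
#' @param x finite numeric vector.
#' @return numeric vector in [0, 1].
#' @export
minmax <- function(x) {
  if (length(x) == 0) stopf("minmax of an empty vector")
  if (any(!is.finite(x))) stopf("minmax requires finite values")
  rng <- max(x) - min(x)
  if (rng == 0) return(rep(0, length(x)))
  (x - min(x)) / rng
}

#' Combined regulator ranking score
#'
#' \eqn{score = f(-\log P_E) + f(-\log P_D)} with \eqn{f} the min-max map
#' over regulators; the log base is immaterial because min-max absorbs
#' positive scaling. Regulators are ordered by score descending, ties
#' broken by smaller \eqn{P_E}, then smaller \eqn{P_D}, then regulator ID;
#' ranks are the resulting 1-based positions.
#'
#' @param p_d named vector of per-regulator differential p-values; NAs are
#'   set to 1.
#' @param p_e named vector of per-regulator enrichment p-values on the
#'   same IDs; NAs are set to 1.
#' @return an object of class \code{regulator_ranking}: data.frame with
#'   columns \code{rank}, \code{regulator}, \code{p_d}, \code{p_e},
#'   \code{score}.
#' @export
rank_regulators <- function(p_d, p_e) {
  if (is.null(names(p_d)) || is.null(names(p_e)))
    stopf("p_d and p_e must be named by regulator ID")
  only_d <- setdiff(names(p_d), names(p_e))
  only_e <- setdiff(names(p_e), names(p_d))
  if (length(only_d) || length(only_e))
    stopf("regulator ID mismatch; only in p_d: {%s}; only in p_e: {%s}",
          paste(only_d, collapse = ", "), paste(only_e, collapse = ", "))
  ids <- names(p_d)
  p_e <- p_e[ids]
  na_d <- sum(is.na(p_d)); na_e <- sum(is.na(p_e))
  if (na_d) message(sprintf("%d regulator(s) without DE p-value set to p_d = 1", na_d))
  if (na_e) message(sprintf("%d regulator(s) without enrichment p set to p_e = 1", na_e))
  p_d[is.na(p_d)] <- 1
  p_e[is.na(p_e)] <- 1
  p_d <- clamp_p(p_d); p_e <- clamp_p(p_e)
  score <- minmax(-log(p_e)) + minmax(-log(p_d))
  ord <- order(-score, p_e, p_d, ids, method = "radix")
  out <- data.frame(rank = seq_along(ids), regulator = ids[ord],
                    p_d = unname(p_d[ord]), p_e = unname(p_e[ord]),
                    score = unname(score[ord]), stringsAsFactors = FALSE)
  class(out) <- c("regulator_ranking", "data.frame")
  out
}
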