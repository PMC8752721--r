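# Regulator enrichment: hypergeometric over-representation of a
# differential gene set in each regulator's targets, or a weighted GSEA
# enrichment score with a gene-permutation empirical null. Produces the
# P_E channel of the final regulator score.

enrichment_result <- function(regulator, method, n_targets, overlap, es,
                              p_value) {
  p_adj <- rep(NA_real_, length(p_value))
  ok <- !is.na(p_value)
  p_adj[ok] <- clamp_p(stats::p.adjust(p_value[ok], "BH"))
  out <- data.frame(regulator = regulator, method = method,
                    n_targets = n_targets, overlap = overlap, es = es,
                    p_value = p_value, p_adjusted = p_adj,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# Upper hypergeometric tail P(X >= K) for X ~ Hypergeom(N, M, s), summed
# term by term in log space.
hyper_tail <- function(K, s, M, N) {
  if (K <= 0) return(1)
  ks <- K:min(s, M)
  if (length(ks) == 0 || K > min(s, M)) return(clamp_p(0))
  lt <- lchoose(M, ks) + lchoose(N - M, s - ks) - lchoose(N, s)
  lt <- lt[is.finite(lt)]
  if (!length(lt)) return(clamp_p(0))
  mx <- max(lt)
  clamp_p(exp(mx + log(sum(exp(lt - mx)))))
}

#' Hypergeometric (Fisher's exact) regulator enrichment
#'
#' For each regulator with target set of size \eqn{s_i} in the network,
#' the p-value is the probability of observing at least the realised
#' overlap \eqn{K} between its targets and the differential gene set by
#' chance: \eqn{P_i = \sum_{k=K}^{s_i} C(M,k) C(N-M, s_i-k) / C(N, s_i)},
#' where \eqn{N} is the universe size (all network nodes by default) and
#' \eqn{M} the number of differential genes inside the universe.
#' Differential genes outside the universe are excluded. Computed in log
#' space; BH-adjusted across regulators.
#'
#' @param net a \code{\link{regulator_network}}.
#' @param de_genes character vector of differential gene IDs.
#' @param universe gene universe; defaults to all network nodes.
#' @param min_set_size regulators whose target set (within the universe)
#'   has fewer genes are reported NA.
#' @return an \code{enrichment_result} data.frame (method "FET"; the
#'   \code{es} column is NA).
#' @export
fet_enrich <- function(net, de_genes, universe = NULL, min_set_size = 3L) {
  stopifnot(inherits(net, "regulator_network"))
  universe <- universe %||% net$nodes
  de_u <- intersect(unique(de_genes), universe)
  M <- length(de_u)
  N <- length(universe)
  tsets <- target_sets(net)
  regs <- names(tsets)
  if (M == 0)
    warnf("no differential genes inside the universe; all enrichment p = 1")
  s_i <- integer(length(regs)); K <- integer(length(regs))
  pval <- rep(NA_real_, length(regs))
  for (i in seq_along(regs)) {
    tg <- intersect(unique(tsets[[i]]), universe)
    s_i[i] <- length(tg)
    K[i] <- length(intersect(tg, de_u))
    if (s_i[i] < min_set_size) next
    pval[i] <- if (M == 0) 1 else hyper_tail(K[i], s_i[i], M, N)
  }
  enrichment_result(regs, "FET", s_i, K, NA_real_, pval)
}

#' Ranking metric for GSEA: z-scaled negative log p-values
#'
#' Transforms per-gene differential p-values to \eqn{-\log p}, standardises
#' to zero mean and unit sample SD, and sorts decreasingly (ties broken by
#' gene ID). The log base is immaterial: standardisation absorbs any
#' positive rescaling. If all p-values are equal the metric is all zeros
#' (with a warning).
#'
#' @param de a \code{de_result} data.frame (or any data.frame with
#'   \code{gene_id} and \code{p_value} columns).
#' @param genes optional subset of genes to restrict the metric to (e.g.
#'   the network's gene universe).
#' @return named numeric vector sorted decreasingly.
#' @export
make_ranking_metric <- function(de, genes = NULL) {
  if (!all(c("gene_id", "p_value") %in% names(de)))
    stopf("`de` must have gene_id and p_value columns")
  ids <- as.character(de$gene_id)
  p <- clamp_p(de$p_value)
  if (!is.null(genes)) {
    keep <- ids %in% genes
    ids <- ids[keep]; p <- p[keep]
  }
  if (length(ids) < 2) stopf("need at least 2 genes for a ranking metric")
  nlp <- -log(p)
  s <- stats::sd(nlp)
  r <- if (s > 0) (nlp - mean(nlp)) / s else {
    warnf("all p-values equal; ranking metric is identically zero")
    rep(0, length(nlp))
  }
  names(r) <- ids
  r[order(-r, ids, method = "radix")]
}

# Enrichment score from sorted hit positions. h: strictly increasing
# positions of the set's genes in the sorted metric; w: |r| at every
# position; N: universe size. The running sum Phit - Pmiss attains its
# maxima at hit positions and its minima just before hits (or 0 at the
# end), so only O(|S|) evaluations are needed.
es_from_positions <- function(h, w, N) {
  K <- length(h)
  wh <- w[h]
  denom <- sum(wh)
  if (denom <= 0 || K == 0 || K >= N) return(NA_real_)
  cw <- cumsum(wh) / denom
  j <- seq_len(K)
  miss_at <- (h - j) / (N - K)
  miss_before <- (h - j) / (N - K)   # at index h_j - 1: (h_j-1)-(j-1) misses
  dP_hit <- cw - miss_at
  dP_before <- c(0, cw[-K]) - miss_before
  mx <- max(dP_hit, 0)
  mn <- min(dP_before, 0)
  if (mx >= -mn) mx else mn
}

#' Weighted GSEA enrichment score of a target set
#'
#' Walks down the decreasingly sorted ranking metric accumulating
#' \eqn{P_{hit}} (weighted by \eqn{|r_j|} normalised over the set) and
#' \eqn{P_{miss}} (uniform \eqn{1/(N-N_H)}); the enrichment score is
#' \eqn{\max(\Delta P)} if \eqn{\max(\Delta P) \ge \max(-\Delta P)}, else
#' \eqn{\min(\Delta P)}.
#'
#' @param metric named, decreasingly sorted ranking metric (see
#'   \code{\link{make_ranking_metric}}).
#' @param S character vector: the target set.
#' @return the enrichment score in [-1, 1], or NA (with a warning) when
#'   the set is empty, covers the whole universe, or the set's total
#'   weight is zero.
#' @export
gsea_es <- function(metric, S) {
  N <- length(metric)
  hit <- names(metric) %in% S
  N_H <- sum(hit)
  if (N_H == 0 || N_H >= N) {
    warnf("target set empty or equal to the universe; ES undefined")
    return(NA_real_)
  }
  w <- abs(metric)
  denom <- sum(w[hit])
  if (denom <= 0) {
    warnf("target set has zero total metric weight; ES undefined")
    return(NA_real_)
  }
  p_hit <- cumsum(w * hit) / denom
  p_miss <- cumsum(!hit) / (N - N_H)
  dP <- p_hit - p_miss
  mx <- max(dP); mn <- min(dP)
  if (mx >= -mn) mx else mn
}

#' GSEA enrichment with a gene-permutation empirical null
#'
#' Computes each regulator's observed enrichment score, then shuffles the
#' assignment of genes to ranking-metric positions \code{n_perm} times
#' (one shared permutation stream for all regulators) and re-computes the
#' score. The empirical p-value is one-sided on the sign-matched side of
#' the null with a +1 pseudo-count: for ES >= 0,
#' \eqn{p = (1 + \#\{ES^{null} \ge ES, ES^{null} \ge 0\}) /
#' (1 + \#\{ES^{null} \ge 0\})}, and symmetrically for negative scores.
#' BH-adjusted across regulators.
#'
#' @param metric named, decreasingly sorted ranking metric.
#' @param tsets named list: regulator -> target gene IDs.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the shared permutation stream.
#' @param min_set_size regulators whose target set intersects fewer than
#'   this many metric genes are reported NA.
#' @param n_jobs parallel workers over regulators; the permutation stream
#'   is pre-generated, so results are identical for any worker count.
#' @return an \code{enrichment_result} data.frame (method "GSEA";
#'   \code{n_targets} and \code{overlap} both report \eqn{N_H}).
#' @export
gsea_empirical_p <- function(metric, tsets, n_perm = 1000L, seed = 1L,
                             min_set_size = 3L, n_jobs = 1L) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  N <- length(metric)
  w <- abs(metric)
  gene_pos <- stats::setNames(seq_len(N), names(metric))
  perm <- with_seed(seed, {
    matrix(unlist(lapply(seq_len(n_perm), function(b) sample.int(N))), N, n_perm)
  })
  regs <- names(tsets)
  score_one <- function(i) {
    idx <- gene_pos[intersect(unique(tsets[[i]]), names(metric))]
    K <- length(idx)
    if (K < min_set_size || K >= N)
      return(list(n = K, es = NA_real_, p = NA_real_))
    es_obs <- es_from_positions(sort.int(idx), w, N)
    if (is.na(es_obs)) return(list(n = K, es = NA_real_, p = NA_real_))
    null_es <- numeric(n_perm)
    pm <- perm[idx, , drop = FALSE]
    for (b in seq_len(n_perm))
      null_es[b] <- es_from_positions(sort.int(pm[, b]), w, N)
    null_es <- null_es[!is.na(null_es)]
    if (es_obs >= 0) {
      side <- null_es[null_es >= 0]
      if (!length(side)) {
        warnf("no permuted ES of matching sign for %s; p floored", regs[i])
        p <- 1 / (n_perm + 1)
      } else p <- (1 + sum(side >= es_obs)) / (1 + length(side))
    } else {
      side <- null_es[null_es < 0]
      if (!length(side)) {
        warnf("no permuted ES of matching sign for %s; p floored", regs[i])
        p <- 1 / (n_perm + 1)
      } else p <- (1 + sum(side <= es_obs)) / (1 + length(side))
    }
    list(n = K, es = es_obs, p = p)
  }
  res <- if (n_jobs > 1L)
    parallel::mclapply(seq_along(regs), score_one, mc.cores = n_jobs)
  else lapply(seq_along(regs), score_one)
  enrichment_result(regs, "GSEA",
                    vapply(res, `[[`, integer(1), "n"),
                    vapply(res, `[[`, integer(1), "n"),
                    vapply(res, `[[`, numeric(1), "es"),
                    vapply(res, `[[`, numeric(1), "p"))
}

#' Write enrichment results as TSV
#' @param enr an \code{enrichment_result} data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_enrichment <- function(enr, path) {
  utils::write.table(enr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
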