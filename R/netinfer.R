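# Regulator-target network inference: co-expression (soft-threshold
# adjacency -> topological overlap) or random-forest importances, top-edge
# extraction, and directed hub metrics.

drop_constant_genes <- function(mat) {
  v <- apply(mat, 1, stats::var)
  bad <- !is.finite(v) | v == 0
  if (any(bad)) {
    warnf("dropping %d constant gene(s) before correlation: %s",
          sum(bad), paste(utils::head(rownames(mat)[bad], 5), collapse = ", "))
    mat <- mat[!bad, , drop = FALSE]
  }
  mat
}

scale_free_r2 <- function(k, n_bins = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < 3L) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  if (length(unique(breaks)) < 3L) return(NA_real_)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = nlevels(bin))
  km <- tapply(k, bin, mean)
  keep <- cnt > 0 & !is.na(km) & km > 0
  if (sum(keep) < 3L) return(NA_real_)
  p_k <- cnt[keep] / sum(cnt)
  fit <- stats::lm(log10(p_k) ~ log10(as.numeric(km[keep])))
  summary(fit)$r.squared
}

#' Choose the soft-threshold power by the approximate scale-free criterion
#'
#' For each candidate power beta, the unsigned adjacency
#' \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} is formed, per-gene connectivity
#' \eqn{k_i = \sum_{j \ne i} a_{ij}} is computed, and the fit of
#' \eqn{\log_{10} p(k)} vs \eqn{\log_{10} k} over equal-width connectivity
#' bins is summarised by plain R-squared. The chosen beta is the smallest
#' power whose fit reaches \code{r2_target}; if none does, the power with
#' the maximal fit is returned with a warning.
#'
#' @param ed an \code{\link{expression_data}} object with >= 4 samples.
#' @param powers increasing integer candidate powers.
#' @param r2_target scale-free fit target in (0, 1).
#' @param n_bins number of connectivity bins for the fit.
#' @param block_size genes per block for blockwise correlation (memory
#'   control on large matrices).
#' @return list with \code{beta} (chosen power) and \code{fit_table}
#'   (data.frame: power, r2, mean_k, max_k).
#' @export
pick_soft_power <- function(ed, powers = c(1:10, seq(12L, 20L, 2L)),
                            r2_target = 0.85, n_bins = 10L,
                            block_size = 2000L) {
  stopifnot(inherits(ed, "ExpressionData"))
  if (ncol(ed$matrix) < 4) stopf("need at least 4 samples")
  powers <- sort(unique(as.integer(powers)))
  if (length(powers) < 1 || any(powers < 1)) stopf("powers must be >= 1")
  if (!(r2_target > 0 && r2_target < 1)) stopf("r2_target must be in (0,1)")
  mat <- drop_constant_genes(ed$matrix)
  xs <- scale_rows_cor(mat)
  G <- nrow(xs)
  maxp <- max(powers)
  ksum <- matrix(0, G, length(powers))
  starts <- seq(1L, G, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, G)
    cb <- abs(tcrossprod(xs, xs[idx, , drop = FALSE]))  # G x b
    cur <- cb
    pw <- 1L
    for (pi in seq_along(powers)) {
      while (pw < powers[pi]) { cur <- cur * cb; pw <- pw + 1L }
      ksum[, pi] <- ksum[, pi] + rowSums(cur)
    }
  }
  # remove the self term a_ii = 1 present at every power
  ksum <- ksum - 1
  fit_table <- data.frame(power = powers,
                          r2 = NA_real_,
                          mean_k = colMeans(ksum),
                          max_k = apply(ksum, 2, max))
  for (pi in seq_along(powers))
    fit_table$r2[pi] <- scale_free_r2(ksum[, pi], n_bins)
  ok <- which(!is.na(fit_table$r2) & fit_table$r2 >= r2_target)
  if (length(ok)) {
    beta <- powers[ok[1]]
  } else {
    if (all(is.na(fit_table$r2)))
      stopf("scale-free fit undefined for all powers (too few genes?)")
    beta <- powers[which.max(fit_table$r2)]
    warnf("no power reached scale-free R^2 >= %.2f; using power %d (R^2 = %.3f)",
          r2_target, beta, max(fit_table$r2, na.rm = TRUE))
  }
  list(beta = beta, fit_table = fit_table)
}

#' Topological overlap from an adjacency matrix
#'
#' \eqn{TOM_{ij} = (l_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})} with
#' \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1.
#'
#' @param A symmetric adjacency matrix with entries in [0, 1]; the
#'   diagonal is ignored.
#' @return symmetric matrix of topological overlaps in [0, 1].
#' @export
tom_from_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stopf("A must be square")
  if (any(A < 0 | A > 1)) stopf("adjacency entries must lie in [0, 1]")
  if (max(abs(A - t(A))) > 1e-12) stopf("A must be symmetric")
  diag(A) <- 0
  L <- A %*% A
  k <- rowSums(A)
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Topological overlap matrix of an expression dataset
#'
#' Builds the unsigned adjacency \eqn{|cor|^\beta} (Pearson) and returns
#' its topological overlap matrix.
#'
#' @param ed an \code{\link{expression_data}} object.
#' @param beta soft-threshold power, >= 1.
#' @return symmetric gene x gene TOM.
#' @export
compute_tom <- function(ed, beta) {
  stopifnot(inherits(ed, "ExpressionData"))
  if (beta < 1) stopf("beta must be >= 1")
  mat <- drop_constant_genes(ed$matrix)
  A <- elem_power(abs(stats::cor(t(mat))), beta)
  diag(A) <- 0
  tom_from_adjacency(A)
}

#' Regulator-row TOM weight matrix (co-expression network weights)
#'
#' Computes the topological overlap between each regulator and every gene
#' without materialising the full gene x gene matrix (blockwise), giving
#' the candidate edge-weight matrix of the co-expression network. Each
#' regulator's self-entry is masked NA.
#'
#' @param ed an \code{\link{expression_data}} object.
#' @param regulators character vector of regulator gene IDs; must overlap
#'   the expression genes.
#' @param beta soft-threshold power; \code{NULL} picks it via
#'   \code{\link{pick_soft_power}}.
#' @param powers,r2_target passed to \code{\link{pick_soft_power}} when
#'   \code{beta} is NULL.
#' @param block_size genes per block.
#' @return regulators x genes weight matrix in [0, 1] with attribute
#'   \code{beta}.
#' @export
coen_weight_matrix <- function(ed, regulators, beta = NULL,
                               powers = c(1:10, seq(12L, 20L, 2L)),
                               r2_target = 0.85, block_size = 2000L) {
  stopifnot(inherits(ed, "ExpressionData"))
  mat <- drop_constant_genes(ed$matrix)
  regulators <- intersect(regulators, rownames(mat))
  if (length(regulators) == 0)
    stopf("regulator set is disjoint from the expression genes")
  if (is.null(beta)) {
    pick <- suppressWarnings(
      pick_soft_power(expression_data(mat, ed$annotations, ed$kind),
                      powers, r2_target, block_size = block_size))
    beta <- pick$beta
  }
  if (beta < 1) stopf("beta must be >= 1")
  xs <- scale_rows_cor(mat)
  G <- nrow(xs)
  genes <- rownames(xs)
  ridx <- match(regulators, genes)
  A_reg <- elem_power(abs(tcrossprod(xs[ridx, , drop = FALSE], xs)), beta)
  A_reg[cbind(seq_along(ridx), ridx)] <- 0  # zero self-adjacency
  k <- numeric(G)
  L <- matrix(0, length(ridx), G)
  starts <- seq(1L, G, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, G)
    A_blk <- elem_power(abs(tcrossprod(xs, xs[idx, , drop = FALSE])), beta)
    A_blk[cbind(idx, seq_along(idx))] <- 0
    k[idx] <- colSums(A_blk)
    L[, idx] <- A_reg %*% A_blk
  }
  k_reg <- k[ridx]
  denom <- outer(k_reg, k, pmin) + 1 - A_reg
  W <- (L + A_reg) / denom
  dimnames(W) <- list(regulators, genes)
  W[cbind(seq_along(ridx), ridx)] <- NA  # mask self edges
  attr(W, "beta") <- beta
  attr(W, "method") <- "coen"
  W
}

#' Random-forest importance weight matrix (GRN network weights)
#'
#' Each gene j is regressed on the regulators (excluding itself when j is
#' a regulator) with a random forest on standardised expression. The
#' weight \eqn{W_{ij}} is regulator i's impurity importance, normalised so
#' the column sums to the model's fraction of variance explained
#' (out-of-bag R-squared, floored at 0). Deterministic given \code{seed};
#' parallel workers do not change the result because per-target seeds are
#' drawn up front.
#'
#' @param ed an \code{\link{expression_data}} object with >= 5 samples.
#' @param regulators regulator gene IDs (>= 2 present in the data).
#' @param n_trees trees per forest.
#' @param seed master RNG seed.
#' @param n_jobs parallel workers over target genes (forked; results are
#'   identical for any worker count).
#' @param mtry predictors sampled per split; default
#'   \code{floor(sqrt(#regulators))}.
#' @return list with \code{weights} (regulators x genes matrix, self
#'   entries NA) and \code{quality} (named out-of-bag R-squared per gene).
#' @export
grn_importances <- function(ed, regulators, n_trees = 1000L, seed = 1L,
                            n_jobs = 1L, mtry = NULL) {
  stopifnot(inherits(ed, "ExpressionData"))
  if (ncol(ed$matrix) < 5) stopf("need at least 5 samples for random forests")
  mat <- drop_constant_genes(ed$matrix)
  genes <- rownames(mat)
  regulators <- intersect(regulators, genes)
  if (length(regulators) < 2)
    stopf("need at least 2 regulators present in the expression data")
  xs <- t(scale(t(mat)))  # per-gene z-scores
  pred_df <- as.data.frame(t(xs[regulators, , drop = FALSE]))
  colnames(pred_df) <- regulators
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(genes)))
  fit_one <- function(ji) {
    j <- genes[ji]
    preds <- setdiff(regulators, j)
    if (length(preds) < 1) return(list(w = numeric(0), preds = character(0),
                                       q = NA_real_))
    m_try <- min(mtry %||% max(1L, floor(sqrt(length(preds)))),
                 length(preds))
    fit <- ranger::ranger(x = pred_df[, preds, drop = FALSE], y = xs[j, ],
                          num.trees = n_trees, mtry = m_try,
                          min.node.size = 1L, importance = "impurity",
                          seed = seeds[ji], num.threads = 1L)
    imp <- fit$variable.importance
    q <- fit$r.squared
    tot <- sum(imp)
    w <- if (tot > 0) imp / tot * max(q, 0) else imp * 0
    list(w = w, preds = preds, q = q)
  }
  res <- if (n_jobs > 1L)
    parallel::mclapply(seq_along(genes), fit_one, mc.cores = n_jobs)
  else lapply(seq_along(genes), fit_one)
  W <- matrix(NA_real_, length(regulators), length(genes),
              dimnames = list(regulators, genes))
  quality <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (ji in seq_along(genes)) {
    r <- res[[ji]]
    if (length(r$preds)) {
      W[, genes[ji]] <- 0
      W[r$preds, genes[ji]] <- r$w
      if (genes[ji] %in% regulators) W[genes[ji], genes[ji]] <- NA
    }
    quality[ji] <- r$q
  }
  attr(W, "method") <- "grn"
  list(weights = W, quality = quality)
}

#' Remove targets whose expression the forest failed to predict
#'
#' Columns (target genes) with model quality at or below \code{threshold}
#' (default 0, i.e. out-of-bag R-squared non-positive) are masked so they
#' contribute no candidate edges.
#'
#' @param W regulators x genes weight matrix.
#' @param quality per-gene model quality aligned with the columns of
#'   \code{W}.
#' @param threshold quality cutoff.
#' @return the filtered weight matrix.
#' @export
filter_poor_models <- function(W, quality, threshold = 0) {
  if (is.null(names(quality))) {
    if (length(quality) != ncol(W)) stopf("quality does not align with W")
    names(quality) <- colnames(W)
  }
  q <- quality[colnames(W)]
  bad <- !is.na(q) & q <= threshold
  W[, bad] <- NA
  W
}

#' Extract the directed regulator-target network from a weight matrix
#'
#' Ranks all unmasked regulator-to-gene entries by weight and retains the
#' top \code{ceiling(edge_fraction * n_candidates)}. Ties at the cutoff are
#' broken deterministically: weight descending, then regulator ID, then
#' target ID ascending. Nodes with no retained incident edge are dropped.
#'
#' @param W regulators x genes weight matrix (NA = masked).
#' @param edge_fraction fraction of candidate edges to keep, in (0, 1].
#' @return an object of class \code{regulator_network}: list with
#'   \code{edges} (data.frame regulator/target/weight), \code{nodes},
#'   \code{regulators} (regulator nodes present) and
#'   \code{regulator_universe} (all rows of \code{W}).
#' @export
extract_topology <- function(W, edge_fraction = 0.05) {
  if (!(edge_fraction > 0 && edge_fraction <= 1))
    stopf("edge_fraction must lie in (0, 1]")
  cand <- which(!is.na(W))
  if (length(cand) == 0) stopf("no candidate edges in the weight matrix")
  idx <- arrayInd(cand, dim(W))
  regs <- rownames(W)[idx[, 1]]
  tgts <- colnames(W)[idx[, 2]]
  w <- W[cand]
  n_keep <- ceiling(edge_fraction * length(cand))
  ord <- order(-w, regs, tgts, method = "radix")
  keep <- ord[seq_len(n_keep)]
  edges <- data.frame(regulator = regs[keep], target = tgts[keep],
                      weight = w[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  regulator_network(edges, regulator_universe = rownames(W))
}

#' Construct a regulator network from a directed edge list
#'
#' @param edges data.frame with columns \code{regulator}, \code{target},
#'   \code{weight}.
#' @param regulator_universe all candidate regulator IDs (defaults to the
#'   regulators appearing in \code{edges}).
#' @return a \code{regulator_network} object.
#' @export
regulator_network <- function(edges, regulator_universe = NULL) {
  need <- c("regulator", "target", "weight")
  if (!all(need %in% names(edges)))
    stopf("edges must have columns regulator, target, weight")
  if (any(edges$regulator == edges$target)) stopf("self-loops are not allowed")
  if (any(edges$weight < 0)) stopf("edge weights must be non-negative")
  regulator_universe <- regulator_universe %||% unique(edges$regulator)
  if (!all(edges$regulator %in% regulator_universe))
    stopf("every edge source must be a regulator")
  nodes <- union(unique(edges$regulator), unique(edges$target))
  structure(list(edges = edges,
                 nodes = nodes,
                 regulators = intersect(regulator_universe, nodes),
                 regulator_universe = regulator_universe),
            class = "regulator_network")
}

#' @export
print.regulator_network <- function(x, ...) {
  cat(sprintf("regulator_network: %d edges, %d nodes (%d regulators)\n",
              nrow(x$edges), length(x$nodes), length(x$regulators)))
  invisible(x)
}

#' Target sets (regulons) of a network
#' @param net a \code{regulator_network}.
#' @return named list: regulator -> character vector of its targets.
#' @export
target_sets <- function(net) {
  stopifnot(inherits(net, "regulator_network"))
  split(net$edges$target, factor(net$edges$regulator,
                                 levels = unique(net$edges$regulator)))
}

#' Directed hub metrics: out-degree and out-closeness
#'
#' Out-degree is the number of distinct nodes a node points to.
#' Out-closeness is reachable-set closeness with the Wasserman-Faust size
#' correction: \eqn{(n_r / \sum d) \cdot (n_r / (n - 1))} over the
#' \eqn{n_r} reachable nodes (unit edge lengths); nodes reaching nothing
#' get 0.
#'
#' @param net a \code{regulator_network}.
#' @return data.frame with columns \code{node}, \code{out_degree},
#'   \code{out_closeness}.
#' @export
hub_metrics <- function(net) {
  stopifnot(inherits(net, "regulator_network"))
  if (nrow(net$edges) == 0) stopf("empty network")
  g <- igraph::graph_from_data_frame(net$edges[, c("regulator", "target")],
                                     directed = TRUE,
                                     vertices = net$nodes)
  outdeg <- igraph::degree(g, mode = "out")
  d <- igraph::distances(g, mode = "out", weights = NA)
  n <- length(net$nodes)
  cl <- vapply(seq_len(n), function(i) {
    dv <- d[i, -i]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0) return(0)
    nr <- length(dv)
    (nr / sum(dv)) * (nr / (n - 1))
  }, numeric(1))
  data.frame(node = net$nodes,
             out_degree = as.integer(outdeg[net$nodes]),
             out_closeness = cl,
             stringsAsFactors = FALSE)
}

#' Write / read a network edge list as TSV
#'
#' Format: header line \code{regulator<TAB>target<TAB>weight}, weights
#' written with \code{\%.6g}.
#'
#' @param net a \code{regulator_network}.
#' @param path file path.
#' @return \code{write_network}: invisibly, \code{path}.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "regulator_network"))
  df <- net$edges
  df$weight <- sprintf("%.6g", df$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @param regulator_universe optional full regulator universe for the
#'   loaded network.
#' @return \code{read_network}: a \code{regulator_network}.
#' @export
read_network <- function(path, regulator_universe = NULL) {
  if (!file.exists(path)) stopf("network file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("regulator", "target", "weight") %in% names(df)))
    stopf("network TSV must have columns regulator, target, weight")
  df$weight <- as.numeric(df$weight)
  regulator_network(df, regulator_universe %||% unique(df$regulator))
}
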