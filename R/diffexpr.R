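# Differential expression: per-gene p-values (the P_D channel of the
# final regulator score) and effect sizes, for count and continuous data.

de_result <- function(gene_id, log_fc, statistic, p_value) {
  p_value <- clamp_p(p_value)
  out <- data.frame(gene_id = gene_id, log_fc = log_fc,
                    statistic = statistic, p_value = p_value,
                    p_adjusted = clamp_p(stats::p.adjust(p_value, "BH")),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

get_groups <- function(ed, two = TRUE, min_per_group = 2L) {
  ann <- ed$annotations
  if (!"group" %in% names(ann)) stopf("annotations lack a 'group' column")
  g <- factor(ann$group)
  if (two && nlevels(g) != 2L)
    stopf("exactly two groups required, found %d", nlevels(g))
  if (any(table(g) < min_per_group))
    stopf("each group needs at least %d samples", min_per_group)
  g
}

#' Median-of-ratios size factors for count data
#'
#' For each sample j, the factor is the median over reference genes g
#' (those with a positive geometric mean across samples) of
#' \eqn{x_{gj} / \mathrm{geomean}_g}. Genes with a zero anywhere are
#' excluded from the reference set.
#'
#' @param ed counts-kind \code{\link{expression_data}}.
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(ed) {
  stopifnot(inherits(ed, "ExpressionData"))
  if (ed$kind != "counts") stopf("size factors are defined for counts data")
  x <- ed$matrix
  ok <- rowSums(x <= 0) == 0
  if (!any(ok))
    stopf(paste("no gene has positive counts in every sample;",
                "size factors undefined (filter low-coverage samples or",
                "supply deeper data)"))
  lg <- log(x[ok, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - loggeo)))
  names(sf) <- colnames(x)
  sf
}

# Method-of-moments NB dispersion per gene with geometric-mean shrinkage
# toward a binned trend. cells: factor defining replicate groups.
estimate_dispersions <- function(nc, cells, sf, floor = 1e-8, ceiling = 10,
                                 shrink = 0.5, n_bins = 10L) {
  base_mean <- rowMeans(nc)
  lev <- levels(cells)
  wss <- 0; dfree <- 0
  for (l in lev) {
    idx <- which(cells == l)
    if (length(idx) >= 2) {
      mu <- rowMeans(nc[, idx, drop = FALSE])
      wss <- wss + rowSums((nc[, idx, drop = FALSE] - mu)^2)
      dfree <- dfree + length(idx) - 1L
    }
  }
  v <- wss / max(dfree, 1L)
  xi <- mean(1 / sf)
  disp <- (v - xi * base_mean) / base_mean^2
  disp[!is.finite(disp)] <- floor
  disp <- pmin(pmax(disp, floor), ceiling)
  # trend: mean log-dispersion within expression-level bins
  pos <- base_mean > 0
  if (sum(pos) >= 2L) {
    lb <- log(base_mean[pos])
    bins <- cut(lb, breaks = max(2L, min(n_bins, length(unique(lb)))),
                include.lowest = TRUE)
    trend <- stats::ave(log(disp[pos]), bins)
    disp[pos] <- exp((1 - shrink) * log(disp[pos]) + shrink * trend)
  }
  pmin(pmax(disp, floor), ceiling)
}

#' Negative binomial Wald test for a two-group comparison of counts
#'
#' Per gene, fits a negative binomial GLM (log link) with group as the
#' single covariate and log size factors as offset, using a
#' method-of-moments gene-wise dispersion shrunk toward a trend. The Wald
#' statistic is the group coefficient over its standard error; two-sided
#' p-values come from the standard normal, adjusted across genes by
#' Benjamini-Hochberg. Reported \code{log_fc} is the log2 ratio of
#' normalised group means with a 0.5 pseudo-count.
#'
#' @param ed counts-kind \code{\link{expression_data}} whose annotations
#'   contain a two-level \code{group} column with >= 2 samples per group.
#' @return a \code{de_result} data.frame with columns \code{gene_id},
#'   \code{log_fc}, \code{statistic}, \code{p_value}, \code{p_adjusted}.
#' @export
nb_wald_test <- function(ed) {
  stopifnot(inherits(ed, "ExpressionData"))
  if (ed$kind != "counts") stopf("nb_wald_test requires counts data")
  g <- get_groups(ed)
  x <- ed$matrix
  sf <- estimate_size_factors(ed)
  nc <- sweep(x, 2, sf, "/")
  disp <- estimate_dispersions(nc, g, sf)
  X <- stats::model.matrix(~g)
  off <- log(sf)
  mA <- rowMeans(nc[, g == levels(g)[1], drop = FALSE])
  mB <- rowMeans(nc[, g == levels(g)[2], drop = FALSE])
  lfc <- log2((mB + 0.5) / (mA + 0.5))
  n_genes <- nrow(x)
  stat <- numeric(n_genes); pval <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    y <- x[i, ]
    if (all(y == 0)) { stat[i] <- 0; pval[i] <- 1; lfc[i] <- 0; next }
    z <- tryCatch({
      fam <- MASS::negative.binomial(theta = 1 / disp[i])
      f <- suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off))
      p <- ncol(X)
      R <- f$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
      R[lower.tri(R)] <- 0
      cov <- chol2inv(R)
      f$coefficients[2] / sqrt(cov[2, 2])
    }, error = function(e) NA_real_)
    if (!is.finite(z)) { stat[i] <- 0; pval[i] <- 1 }
    else { stat[i] <- z; pval[i] <- 2 * stats::pnorm(-abs(z)) }
  }
  de_result(rownames(x), lfc, stat, pval)
}

# Newton inversion of trigamma, as used when matching moments of the
# log residual variances to a scaled inverse-chi-square prior.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Moderated t-test with empirical-Bayes variance shrinkage
#'
#' Per gene, an ordinary two-sample linear model fit; residual variances
#' are shrunk toward a common prior estimated by matching moments of the
#' log variances to a scaled inverse-chi-square distribution, and the
#' moderated t uses the augmented degrees of freedom. With
#' \code{prior_df = 0} this reduces exactly to the ordinary two-sample
#' (equal-variance) t-test.
#'
#' @param ed continuous-kind \code{\link{expression_data}} (values assumed
#'   log scale) with a two-level \code{group} annotation, >= 2 samples per
#'   group.
#' @param prior_df prior degrees of freedom; \code{NULL} (default)
#'   estimates them from the data, \code{0} disables shrinkage,
#'   \code{Inf} forces full shrinkage to the prior variance.
#' @return a \code{de_result} data.frame; \code{log_fc} is the group-B
#'   minus group-A mean difference (log2 fold change for log2 data).
#' @export
moderated_t_test <- function(ed, prior_df = NULL) {
  stopifnot(inherits(ed, "ExpressionData"))
  if (ed$kind != "continuous") stopf("moderated_t_test requires continuous data")
  g <- get_groups(ed)
  x <- ed$matrix
  iA <- g == levels(g)[1]; iB <- g == levels(g)[2]
  nA <- sum(iA); nB <- sum(iB)
  d <- nA + nB - 2L
  if (d <= 0) stopf("zero residual degrees of freedom")
  mA <- rowMeans(x[, iA, drop = FALSE]); mB <- rowMeans(x[, iB, drop = FALSE])
  rss <- rowSums((x[, iA, drop = FALSE] - mA)^2) +
         rowSums((x[, iB, drop = FALSE] - mB)^2)
  s2 <- rss / d
  if (is.null(prior_df)) {
    pos <- s2 > 0
    if (sum(pos) >= 2L) {
      e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
      evar <- stats::var(e)
      resid_tri <- evar - trigamma(d / 2)
      if (is.finite(resid_tri) && resid_tri > 0) {
        d0 <- 2 * trigamma_inverse(resid_tri)
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      } else {
        d0 <- Inf
        s02 <- exp(mean(e))
      }
    } else { d0 <- 0; s02 <- mean(s2) }
  } else if (is.infinite(prior_df)) {
    d0 <- Inf; s02 <- exp(mean(log(s2[s2 > 0])))
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) exp(mean(log(s2[s2 > 0]))) else 0
  }
  s2_mod <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_mod * (1 / nA + 1 / nB))
  tstat <- (mB - mA) / se
  tstat[!is.finite(tstat)] <- 0
  df_total <- d + d0
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  res <- de_result(rownames(x), mB - mA, tstat, pval)
  attr(res, "prior_df") <- d0
  attr(res, "prior_var") <- s02
  res
}

#' Likelihood-ratio test for nested designs (multi-group / time series)
#'
#' Per gene, twice the log-likelihood difference between a full and a
#' nested reduced model is compared to a chi-square with df equal to the
#' rank difference. Counts use a negative binomial likelihood with
#' size-factor offsets and a dispersion estimated from the full design's
#' replicate cells; continuous data use a Gaussian likelihood (profiled
#' variance), for which the statistic is \eqn{n \log(RSS_0 / RSS_1)}.
#'
#' @param ed an \code{\link{expression_data}} object.
#' @param full,reduced model formulas over the annotation columns, e.g.
#'   \code{~ group} and \code{~ 1}; \code{reduced} must be nested in
#'   \code{full}.
#' @return a \code{de_result} data.frame. \code{log_fc} is the largest
#'   absolute pairwise log2 contrast between group means when the full
#'   design is a single factor, NA otherwise.
#' @export
likelihood_ratio_test <- function(ed, full = ~group, reduced = ~1) {
  stopifnot(inherits(ed, "ExpressionData"))
  ann <- ed$annotations
  X1 <- stats::model.matrix(full, data = ann)
  X0 <- stats::model.matrix(reduced, data = ann)
  r1 <- qr(X1)$rank; r0 <- qr(X0)$rank
  if (qr(cbind(X0, X1))$rank > r1)
    stopf("reduced design is not nested in the full design")
  df <- r1 - r0
  n <- ncol(ed$matrix)
  if (n - r1 <= 0) stopf("full model has no residual degrees of freedom")
  x <- ed$matrix
  n_genes <- nrow(x)
  # effect size for single-factor designs: max pairwise contrast
  vars <- all.vars(full)
  lfc <- rep(NA_real_, n_genes)
  if (ed$kind == "continuous") {
    fit1 <- stats::lm.fit(X1, t(x))
    fit0 <- stats::lm.fit(X0, t(x))
    rss1 <- colSums(as.matrix(fit1$residuals)^2)
    rss0 <- colSums(as.matrix(fit0$residuals)^2)
    stat <- ifelse(rss1 > 0, n * log(rss0 / rss1),
                   ifelse(rss0 > rss1, Inf, 0))
    stat <- pmax(stat, 0)
    pval <- if (df == 0) rep(1, n_genes) else
      stats::pchisq(stat, df = df, lower.tail = FALSE)
    if (length(vars) == 1 && is.character(ann[[vars]]) ||
        (length(vars) == 1 && is.factor(ann[[vars]]))) {
      gg <- factor(ann[[vars]])
      gm <- sapply(levels(gg), function(l)
        rowMeans(x[, gg == l, drop = FALSE]))
      lfc <- apply(gm, 1, function(v) max(v) - min(v))
    }
  } else {
    sf <- estimate_size_factors(ed)
    nc <- sweep(x, 2, sf, "/")
    cells <- factor(apply(X1, 1, paste, collapse = "/"))
    disp <- estimate_dispersions(nc, cells, sf)
    off <- log(sf)
    stat <- numeric(n_genes)
    for (i in seq_len(n_genes)) {
      y <- x[i, ]
      if (all(y == 0)) { stat[i] <- 0; next }
      ll <- tryCatch({
        fam <- MASS::negative.binomial(theta = 1 / disp[i])
        f1 <- suppressWarnings(stats::glm.fit(X1, y, family = fam, offset = off))
        f0 <- suppressWarnings(stats::glm.fit(X0, y, family = fam, offset = off))
        sz <- 1 / disp[i]
        l1 <- sum(stats::dnbinom(y, size = sz, mu = f1$fitted.values, log = TRUE))
        l0 <- sum(stats::dnbinom(y, size = sz, mu = f0$fitted.values, log = TRUE))
        2 * (l1 - l0)
      }, error = function(e) NA_real_)
      stat[i] <- if (is.finite(ll)) max(ll, 0) else 0
    }
    pval <- if (df == 0) rep(1, n_genes) else
      stats::pchisq(stat, df = df, lower.tail = FALSE)
    if (length(vars) == 1 &&
        (is.character(ann[[vars]]) || is.factor(ann[[vars]]))) {
      gg <- factor(ann[[vars]])
      gm <- sapply(levels(gg), function(l)
        rowMeans(nc[, gg == l, drop = FALSE]))
      lg <- log2(gm + 0.5)
      lfc <- apply(lg, 1, function(v) max(v) - min(v))
    }
  }
  de_result(rownames(x), lfc, stat, pval)
}

#' Write differential-expression results as TSV
#' @param de a \code{de_result} data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_de_results <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
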