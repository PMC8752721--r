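# Shared fixture builders; everything is generated in code at test time.

# Random two-group continuous expression matrix.
random_ed <- function(n_genes = 20, n_samples = 10, seed = 1, sd = 1,
                      kind = "continuous") {
  set.seed(seed)
  mat <- matrix(rnorm(n_genes * n_samples, mean = 8, sd = sd), n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
  ann <- data.frame(sample_id = colnames(mat),
                    group = rep(c("A", "B"), c(ceiling(n_samples / 2),
                                               floor(n_samples / 2))),
                    stringsAsFactors = FALSE)
  expression_data(mat, ann, kind)
}

# Two-group NB counts with a planted fold change on the first genes.
nb_counts_ed <- function(n_genes = 100, n_per_group = 10, n_de = 0,
                         fold = 4, mu0 = 100, size = 10, seed = 1) {
  set.seed(seed)
  mat <- t(sapply(seq_len(n_genes), function(i) {
    muB <- if (i <= n_de) mu0 * fold else mu0
    c(rnbinom(n_per_group, mu = mu0, size = size),
      rnbinom(n_per_group, mu = muB, size = size))
  }))
  rownames(mat) <- sprintf("g%03d", seq_len(n_genes))
  colnames(mat) <- sprintf("s%03d", seq_len(2 * n_per_group))
  ann <- data.frame(sample_id = colnames(mat),
                    group = rep(c("A", "B"), each = n_per_group),
                    stringsAsFactors = FALSE)
  expression_data(mat, ann, "counts")
}

# A sorted ranking metric from explicit values (names a, b, c, ...).
metric_from <- function(vals, ids = NULL) {
  ids <- ids %||% sprintf("gene%02d", seq_along(vals))
  names(vals) <- ids
  sort(vals, decreasing = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force weighted GSEA ES: recompute P_hit and P_miss from scratch
# at every index of the sorted metric (O(N * N_H) oracle).
es_bruteforce <- function(metric, S) {
  N <- length(metric)
  hit <- names(metric) %in% S
  N_H <- sum(hit)
  denom <- sum(abs(metric)[hit])
  dP <- numeric(N)
  for (i in seq_len(N)) {
    p_hit <- sum(abs(metric)[seq_len(i)][hit[seq_len(i)]]) / denom
    p_miss <- sum(!hit[seq_len(i)]) / (N - N_H)
    dP[i] <- p_hit - p_miss
  }
  if (max(dP) >= max(-dP)) max(dP) else min(dP)
}

# Exact hypergeometric upper tail by plain binomial-coefficient sums;
# exact in doubles for N <= 30 since every term is bounded by C(N, s).
hyper_tail_exact <- function(K, s, M, N) {
  if (K <= 0) return(1)
  ks <- K:s
  num <- choose(M, ks) * choose(N - M, s - ks)
  sum(num) / choose(N, s)
}

# Triple-loop topological overlap oracle.
tom_bruteforce <- function(A) {
  diag(A) <- 0
  n <- nrow(A)
  out <- matrix(1, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    out[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  out
}

# Expression whose co-expression network has a planted scale-free
# (preferential-attachment) backbone: correlation decays with graph
# distance on a Barabasi-Albert tree.
ba_expression <- function(n_genes = 60, n_samples = 100, rho = 0.75,
                          seed = 1) {
  set.seed(seed)
  g <- igraph::sample_pa(n_genes, m = 1, directed = FALSE)
  D <- igraph::distances(g)
  Sigma <- rho^D
  x <- t(chol(Sigma)) %*% matrix(rnorm(n_genes * n_samples), n_genes)
  rownames(x) <- sprintf("G%03d", seq_len(n_genes))
  colnames(x) <- sprintf("S%03d", seq_len(n_samples))
  expression_data(x, kind = "continuous")
}
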