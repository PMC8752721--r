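test_that("topological overlap reproduces the forced hand cases", {
  # two genes with unit adjacency
  A2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(tom_from_adjacency(A2)["a", "b"], 1)
  # three genes, all adjacencies 0.5: (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  A3 <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(A3) <- 0
  t3 <- tom_from_adjacency(A3)
  expect_equal(unname(t3[upper.tri(t3)]), rep(0.5, 3))
  # zero adjacency -> zero overlap off the diagonal
  A0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  t0 <- tom_from_adjacency(A0)
  expect_equal(unname(t0[upper.tri(t0)]), rep(0, 6))
  expect_equal(unname(diag(t0)), rep(1, 4))
})

test_that("matrix TOM agrees with the triple-loop oracle", {
  for (s in 1:5) {
    set.seed(s)
    n <- 10
    A <- matrix(runif(n * n, 0, 0.9), n, n)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    dimnames(A) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
    expect_equal(tom_from_adjacency(A), tom_bruteforce(A), tolerance = 1e-12)
  }
})

test_that("TOM entries live in [0,1], are symmetric, and rise with adjacency", {
  set.seed(4)
  A <- matrix(runif(64, 0, 0.8), 8, 8); A <- (A + t(A)) / 2; diag(A) <- 0
  dimnames(A) <- list(sprintf("g%d", 1:8), sprintf("g%d", 1:8))
  tm <- tom_from_adjacency(A)
  expect_true(all(tm >= 0 & tm <= 1 + 1e-12))
  expect_equal(tm, t(tm))
  A2 <- A
  A2[1, 2] <- A2[2, 1] <- min(A[1, 2] + 0.15, 1)
  expect_gt(tom_from_adjacency(A2)[1, 2], tm[1, 2])
})

test_that("compute_tom is the TOM of the soft-thresholded correlation", {
  ed <- random_ed(n_genes = 12, n_samples = 20, seed = 6)
  beta <- 4
  A <- abs(cor(t(ed$matrix)))^beta
  diag(A) <- 0
  expect_equal(compute_tom(ed, beta), tom_from_adjacency(A), tolerance = 1e-12)
  expect_error(compute_tom(ed, 0.5), "beta")
})

test_that("blockwise regulator-row TOM matches the full computation", {
  ed <- random_ed(n_genes = 25, n_samples = 15, seed = 8)
  regs <- gene_ids(ed)[c(2, 9, 17)]
  W <- coen_weight_matrix(ed, regs, beta = 3, block_size = 7)
  full <- compute_tom(ed, 3)
  expect_equal(attr(W, "beta"), 3)
  for (r in regs) {
    expect_true(is.na(W[r, r]))
    cols <- setdiff(colnames(W), r)
    expect_equal(W[r, cols], full[r, cols], tolerance = 1e-12)
  }
})

test_that("soft power selection follows the first-hit rule and warns on noise", {
  ed <- ba_expression(seed = 2)
  # a tiny target makes every power pass: smallest candidate wins
  pick1 <- pick_soft_power(ed, powers = c(2, 4, 6), r2_target = 0.01)
  expect_equal(pick1$beta, 2)
  # independent noise cannot reach a near-1 target: argmax + warning
  noise <- random_ed(n_genes = 40, n_samples = 30, seed = 3)
  expect_warning(pick2 <- pick_soft_power(noise, powers = 1:6,
                                          r2_target = 0.999),
                 "no power reached")
  ft <- pick2$fit_table
  expect_equal(pick2$beta, ft$power[which.max(ft$r2)])
})

test_that("a planted preferential-attachment backbone yields a scale-free fit", {
  for (s in 1:3) {
    ed <- ba_expression(n_genes = 60, n_samples = 100, seed = s)
    pick <- suppressWarnings(pick_soft_power(ed))
    r2_at_beta <- pick$fit_table$r2[pick$fit_table$power == pick$beta]
    expect_gte(r2_at_beta, 0.85)
  }
})

test_that("constant genes are dropped with a warning before correlation", {
  ed <- random_ed(n_genes = 10, n_samples = 12, seed = 10)
  mat <- ed$matrix
  mat[3, ] <- 5
  ed2 <- expression_data(mat, ed$annotations, "continuous")
  expect_warning(W <- coen_weight_matrix(ed2, gene_ids(ed2)[1:2], beta = 2),
                 "constant")
  expect_false("g003" %in% colnames(W))
})

test_that("random-forest importances find the true driver of a copied target", {
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    A <- rnorm(n); B <- rnorm(n)
    mat <- rbind(A = A, B = B, tgt = A)
    colnames(mat) <- sprintf("s%02d", 1:n)
    ed <- expression_data(mat, kind = "continuous")
    g <- grn_importances(ed, c("A", "B"), n_trees = 300, seed = s, mtry = 2)
    w <- g$weights[, "tgt"]
    expect_gt(w["A"], w["B"])
    expect_gt(w["A"] / (w["A"] + w["B"]), 0.9)
    expect_gt(g$quality["tgt"], 0.5)
  }
})

test_that("unpredictable targets get non-positive out-of-bag quality", {
  neg <- sapply(1:50, function(s) {
    set.seed(s)
    mat <- matrix(rnorm(6 * 100), 6, 100,
                  dimnames = list(LETTERS[1:6], sprintf("s%03d", 1:100)))
    ed <- expression_data(mat, kind = "continuous")
    g <- grn_importances(ed, LETTERS[1:5], n_trees = 300, seed = s)
    g$quality["F"] <= 0
  })
  expect_gte(mean(neg), 0.9)
})

test_that("forest weights are deterministic across runs and worker counts", {
  ed <- random_ed(n_genes = 8, n_samples = 20, seed = 12)
  regs <- gene_ids(ed)[1:4]
  g1 <- grn_importances(ed, regs, n_trees = 100, seed = 3, n_jobs = 1)
  g2 <- grn_importances(ed, regs, n_trees = 100, seed = 3, n_jobs = 2)
  expect_identical(g1$weights, g2$weights)
  g3 <- grn_importances(ed, regs, n_trees = 100, seed = 4)
  expect_false(identical(g1$weights, g3$weights))
  expect_error(grn_importances(ed, c("zz", "yy")), "regulators")
})

test_that("poor-model filtering removes exactly the failing targets", {
  W <- matrix(runif(12), 3, 4,
              dimnames = list(c("r1", "r2", "r3"), c("t1", "t2", "t3", "t4")))
  q <- c(t1 = 0.5, t2 = -0.3, t3 = 0, t4 = 0.1)
  Wf <- filter_poor_models(W, q, threshold = 0)
  expect_equal(sum(colSums(is.na(Wf)) == 3), sum(q <= 0))
  expect_true(all(is.na(Wf[, "t2"])) && all(is.na(Wf[, "t3"])))
  expect_equal(Wf[, "t1"], W[, "t1"])
  # all qualities above threshold: unchanged
  expect_equal(filter_poor_models(W, q, threshold = -1), W)
})

test_that("topology extraction keeps exactly the top-ranked edge fraction", {
  set.seed(20)
  W <- matrix(runif(20), 4, 5,
              dimnames = list(sprintf("r%d", 1:4), sprintf("t%d", 1:5)))
  # 20 candidates at fraction 0.05 -> exactly the single max edge
  net1 <- extract_topology(W, 0.05)
  expect_equal(nrow(net1$edges), 1)
  top <- arrayInd(which.max(W), dim(W))
  expect_equal(net1$edges$regulator, rownames(W)[top[1]])
  expect_equal(net1$edges$target, colnames(W)[top[2]])
  # fraction 1 keeps everything
  net_all <- extract_topology(W, 1)
  expect_equal(nrow(net_all$edges), 20)
  expect_setequal(net_all$nodes, c(rownames(W), colnames(W)))
  # exact ceiling count on random masks
  for (s in 1:5) {
    set.seed(s)
    Wm <- W; Wm[sample(20, 6)] <- NA
    f <- runif(1, 0.05, 0.9)
    expect_equal(nrow(extract_topology(Wm, f)$edges), ceiling(f * 14))
  }
  expect_error(extract_topology(W, 0), "edge_fraction")
  expect_error(extract_topology(W, 1.2), "edge_fraction")
})

test_that("ties at the cutoff break by regulator then target ID", {
  W <- matrix(0.1, 2, 2, dimnames = list(c("rB", "rA"), c("t1", "t2")))
  W["rB", "t1"] <- 0.9
  # 4 candidates, fraction 0.5 -> 2 edges; three tie at 0.1, rA/t1 wins
  net <- extract_topology(W, 0.5)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$regulator, c("rB", "rA"))
  expect_equal(net$edges$target, c("t1", "t1"))
})

test_that("network edges always originate from regulators, no self-loops", {
  ed <- random_ed(n_genes = 20, n_samples = 16, seed = 30)
  regs <- gene_ids(ed)[1:5]
  W <- coen_weight_matrix(ed, regs, beta = 2)
  net <- extract_topology(W, 0.1)
  expect_true(all(net$edges$regulator %in% regs))
  expect_false(any(net$edges$regulator == net$edges$target))
  # every node touches a retained edge
  expect_setequal(net$nodes, union(net$edges$regulator, net$edges$target))
})

test_that("strong planted networks recover most true targets per regulator", {
  recall_coen <- recall_grn <- numeric(0)
  for (s in 1:3) {
    ds <- simulate_regulators(simulation_spec(
      n_samples = 60, n_regulators = 10, n_bona_fide = 5, effect_size = 3,
      target_noise_sd = 0.5, targets_min = 3, targets_max = 6, seed = s))
    ed <- ds$expression
    true_edges <- sum(lengths(ds$target_map))
    n_cand <- length(ds$regulators) * (nrow(ed$matrix) - 1)
    frac <- true_edges / n_cand
    rec_of <- function(net) {
      ts <- target_sets(net)
      mean(vapply(ds$regulators, function(r) {
        tr <- ds$target_map[[r]]
        length(intersect(ts[[r]], tr)) / length(tr)
      }, numeric(1)))
    }
    Wc <- suppressWarnings(coen_weight_matrix(ed, ds$regulators))
    recall_coen <- c(recall_coen, rec_of(extract_topology(Wc, frac)))
    g <- grn_importances(ed, ds$regulators, n_trees = 300, seed = s)
    Wg <- filter_poor_models(g$weights, g$quality)
    recall_grn <- c(recall_grn, rec_of(extract_topology(Wg, frac)))
  }
  expect_gte(mean(recall_coen), 0.8)
  expect_gte(mean(recall_grn), 0.8)
})

test_that("hub metrics match hand-computed digraph cases", {
  star <- regulator_network(data.frame(
    regulator = "c", target = sprintf("l%d", 1:5), weight = 1))
  hm <- hub_metrics(star)
  expect_equal(hm$out_degree[hm$node == "c"], 5L)
  expect_true(all(hm$out_degree[hm$node != "c"] == 0L))
  expect_true(all(hm$out_closeness[hm$node != "c"] == 0))
  # chain a -> b -> c: closeness(a) = (2/3) * (2/2), b = (1/1) * (1/2)
  chain <- regulator_network(data.frame(
    regulator = c("a", "b"), target = c("b", "c"), weight = 1),
    regulator_universe = c("a", "b"))
  hm2 <- hub_metrics(chain)
  cl <- setNames(hm2$out_closeness, hm2$node)
  expect_equal(cl[["a"]], (2 / 3) * (2 / 2))
  expect_equal(cl[["b"]], (1 / 1) * (1 / 2))
  expect_equal(cl[["c"]], 0)
})

test_that("edge lists round-trip through TSV at %.6g precision", {
  set.seed(44)
  W <- matrix(runif(30), 5, 6,
              dimnames = list(sprintf("r%d", 1:5), sprintf("t%d", 1:6)))
  net <- extract_topology(W, 0.4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  net2 <- read_network(path, regulator_universe = net$regulator_universe)
  expect_equal(net2$edges$regulator, net$edges$regulator)
  expect_equal(net2$edges$target, net$edges$target)
  expect_equal(net2$edges$weight, net$edges$weight, tolerance = 1e-5)
  expect_error(regulator_network(data.frame(regulator = "a", target = "a",
                                            weight = 1)), "self-loops")
})
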