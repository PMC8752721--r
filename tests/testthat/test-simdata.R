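test_that("gene count is conserved and targets partition cleanly", {
  for (s in 1:5) {
    spec <- simulation_spec(n_samples = 10, n_regulators = 10, n_bona_fide = 3,
                            targets_min = 3, targets_max = 8, seed = s)
    ds <- simulate_regulators(spec)
    t_i <- lengths(ds$target_map)
    expect_equal(nrow(ds$expression$matrix), 10 + sum(t_i))
    expect_true(all(t_i >= 3 & t_i <= 8))
    # every target appears in exactly one regulator's list
    all_targets <- unlist(ds$target_map, use.names = FALSE)
    expect_false(anyDuplicated(all_targets) > 0)
    expect_setequal(c(ds$regulators, all_targets), gene_ids(ds$expression))
    # group sizes differ by at most one
    tab <- table(ds$expression$annotations$group)
    expect_lte(abs(tab[["A"]] - tab[["B"]]), 1)
  }
})

test_that("degenerate spec with one regulator and fixed targets is exact", {
  spec <- simulation_spec(n_samples = 4, n_regulators = 1, n_bona_fide = 0,
                          targets_min = 3, targets_max = 3, seed = 1)
  ds <- simulate_regulators(spec)
  expect_equal(nrow(ds$expression$matrix), 4)
  expect_equal(length(ds$truth), 0)
})

test_that("spec validation rejects impossible parameters", {
  expect_error(simulation_spec(n_samples = 3), "n_samples")
  expect_error(simulation_spec(n_bona_fide = 11, n_regulators = 10),
               "n_bona_fide")
  expect_error(simulation_spec(targets_min = 5, targets_max = 3), "targets")
  expect_error(simulation_spec(reg_sd = 0), "deviations")
})

test_that("bona fide regulators carry the planted group shift, others do not", {
  spec <- simulation_spec(n_samples = 2000, n_regulators = 6, n_bona_fide = 3,
                          targets_min = 3, targets_max = 3, effect_size = 2,
                          seed = 42)
  ds <- simulate_regulators(spec)
  grp <- ds$expression$annotations$group
  x <- ds$expression$matrix
  dmeans <- rowMeans(x[ds$regulators, grp == "B"]) -
            rowMeans(x[ds$regulators, grp == "A"])
  expect_equal(unname(dmeans[1:3]), rep(2, 3), tolerance = 0.15)
  expect_equal(unname(dmeans[4:6]), rep(0, 3), tolerance = 0.15)
})

test_that("targets track their regulator with the predicted correlation", {
  # corr(x, x + eps) = sd_x / sqrt(sd_x^2 + sd_eps^2); with reg_sd 1,
  # noise 0.5 and a 3-unit group shift the within-dataset correlation
  # exceeds 0.8 by a wide margin
  cors <- unlist(lapply(1:20, function(s) {
    ds <- simulate_regulators(simulation_spec(
      n_samples = 50, n_regulators = 10, n_bona_fide = 5, effect_size = 3,
      target_noise_sd = 0.5, targets_min = 3, targets_max = 8, seed = s))
    x <- ds$expression$matrix
    unlist(lapply(ds$regulators, function(r)
      cor(x[r, ], t(x[ds$target_map[[r]], , drop = FALSE]))))
  }))
  expect_gt(mean(cors), 0.8)
})

test_that("simulation is byte-identical under the same seed", {
  spec <- simulation_spec(n_samples = 12, n_regulators = 8, n_bona_fide = 2,
                          seed = 99)
  d1 <- simulate_regulators(spec)
  d2 <- simulate_regulators(spec)
  expect_identical(d1$expression$matrix, d2$expression$matrix)
  spec2 <- simulation_spec(n_samples = 12, n_regulators = 8, n_bona_fide = 2,
                           seed = 100)
  expect_false(identical(simulate_regulators(spec2)$expression$matrix,
                         d1$expression$matrix))
})

test_that("counts mode produces valid integer count data", {
  ds <- simulate_regulators(simulation_spec(
    n_samples = 8, n_regulators = 5, n_bona_fide = 1, targets_min = 3,
    targets_max = 5, counts = TRUE, seed = 5))
  x <- ds$expression$matrix
  expect_identical(ds$expression$kind, "counts")
  expect_true(all(x >= 0) && all(x == floor(x)))
})

test_that("non-bona-fide regulators are null: t-test p-values are uniform", {
  ps <- unlist(lapply(1:300, function(s) {
    ds <- simulate_regulators(simulation_spec(
      n_samples = 20, n_regulators = 50, n_bona_fide = 10,
      targets_min = 3, targets_max = 3, seed = s))
    grp <- ds$expression$annotations$group
    nulls <- setdiff(ds$regulators, ds$truth)
    x <- ds$expression$matrix[nulls[1:2], , drop = FALSE]
    apply(x, 1, function(row)
      t.test(row[grp == "A"], row[grp == "B"])$p.value)
  }))
  expect_gt(ks.test(ps, punif)$p.value, 0.01)
})

test_that("downsampling preserves genes and truth and balances groups", {
  ds <- simulate_regulators(simulation_spec(
    n_samples = 100, n_regulators = 10, n_bona_fide = 2, targets_min = 3,
    targets_max = 6, seed = 3))
  full <- downsample_dataset(ds, 100, seed = 1)
  expect_identical(full$expression$matrix, ds$expression$matrix)
  small <- downsample_dataset(ds, 6, seed = 1)
  expect_equal(ncol(small$expression$matrix), 6)
  expect_equal(as.vector(table(small$expression$annotations$group)), c(3L, 3L))
  expect_identical(small$truth, ds$truth)
  expect_identical(rownames(small$expression$matrix),
                   rownames(ds$expression$matrix))
  expect_error(downsample_dataset(ds, 7), "even")
  expect_error(downsample_dataset(ds, 102), "available")
})

test_that("knockdown scales the regulator and re-propagates its targets", {
  ds <- simulate_regulators(simulation_spec(
    n_samples = 400, n_regulators = 4, n_bona_fide = 0, targets_min = 5,
    targets_max = 5, seed = 11))
  expect_error(simulate_knockdown(ds, "R1", 1.0), "knock_fraction")
  expect_error(simulate_knockdown(ds, "nope", 0.5), "unknown")
  kd <- simulate_knockdown(ds, "R1", 0.2, seed = 2)
  grp <- ds$expression$annotations$group
  reg_b_before <- mean(ds$expression$matrix["R1", grp == "B"])
  tg <- ds$target_map[["R1"]]
  tg_b_after <- mean(kd$expression$matrix[tg, grp == "B"])
  # targets re-propagate from the reduced regulator values
  expect_equal(tg_b_after, 0.2 * reg_b_before, tolerance = 0.05)
  # group A and unrelated genes untouched
  expect_identical(kd$expression$matrix[, grp == "A"],
                   ds$expression$matrix[, grp == "A"])
  other <- ds$target_map[["R2"]]
  expect_identical(kd$expression$matrix[other, ], ds$expression$matrix[other, ])
})

test_that("simulated datasets round-trip through the TSV writers", {
  ds <- simulate_regulators(simulation_spec(
    n_samples = 6, n_regulators = 3, n_bona_fide = 1, targets_min = 3,
    targets_max = 4, seed = 8))
  dir <- withr::local_tempdir()
  write_simulated_dataset(ds, dir)
  ed <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "metadata.tsv"))
  expect_equal(ed$matrix, ds$expression$matrix, tolerance = 1e-12)
  expect_identical(readLines(file.path(dir, "truth_regulators.txt")), ds$truth)
})
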