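#' Specification of a planted-regulator simulation
#'
#' Describes a two-group expression simulation with planted ("bona fide")
#' key regulators. Each of \code{n_regulators} regulators gets a baseline
#' mean drawn from Gaussian(\code{baseline_mean}, \code{baseline_sd}); the
#' first \code{n_bona_fide} regulators additionally have their group-B mean
#' shifted by \code{effect_size}, so only they are differential by
#' construction. Every regulator drives \code{t} targets with
#' \code{t ~ Uniform\{targets_min..targets_max\}}; a target's expression is
#' its regulator's expression plus i.i.d. Gaussian(0, \code{target_noise_sd})
#' noise, giving regulator-target correlation
#' \eqn{\sigma_x / \sqrt{\sigma_x^2 + \sigma_\epsilon^2}}.
#'
#' @param n_samples total number of samples (two groups, sizes differing by
#'   at most one); must be at least 4.
#' @param n_regulators number of regulators (m).
#' @param n_bona_fide number of planted differential regulators (k),
#'   \code{0 <= k <= m}.
#' @param targets_min,targets_max bounds of the per-regulator target count.
#' @param reg_sd per-regulator Gaussian standard deviation.
#' @param effect_size group mean shift for bona fide regulators, in
#'   expression units (default two regulator SDs).
#' @param target_noise_sd SD of the Gaussian noise added when propagating a
#'   regulator's expression to its targets.
#' @param baseline_mean,baseline_sd distribution of per-regulator baseline
#'   means.
#' @param counts if TRUE, expression values x are converted to integer
#'   counts by Poisson sampling with rate 2^x (exercises the negative
#'   binomial analysis path).
#' @param seed RNG seed; the realisation is a deterministic function of the
#'   spec including the seed.
#' @return an object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_samples = 100L, n_regulators = 500L,
                            n_bona_fide = 20L,
                            targets_min = 3L, targets_max = 50L,
                            reg_sd = 1, effect_size = 2 * reg_sd,
                            target_noise_sd = 1,
                            baseline_mean = 10, baseline_sd = 2,
                            counts = FALSE, seed = 1L) {
  if (n_samples < 4) stopf("n_samples must be >= 4 to form two usable groups")
  if (n_regulators < 1) stopf("n_regulators must be positive")
  if (n_bona_fide < 0 || n_bona_fide > n_regulators)
    stopf("n_bona_fide must be between 0 and n_regulators")
  if (targets_min < 1 || targets_max < targets_min)
    stopf("need 1 <= targets_min <= targets_max")
  if (reg_sd <= 0 || target_noise_sd <= 0 || baseline_sd <= 0)
    stopf("all standard deviations must be > 0")
  structure(list(n_samples = as.integer(n_samples),
                 n_regulators = as.integer(n_regulators),
                 n_bona_fide = as.integer(n_bona_fide),
                 targets_min = as.integer(targets_min),
                 targets_max = as.integer(targets_max),
                 reg_sd = reg_sd, effect_size = effect_size,
                 target_noise_sd = target_noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 counts = isTRUE(counts), seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a two-group expression dataset with planted key regulators
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return an object of class \code{simulated_dataset}: a list with
#'   \code{expression} (an \code{\link{expression_data}} object, two groups
#'   "A"/"B"), \code{truth} (IDs of the planted bona fide regulators),
#'   \code{target_map} (named list regulator ID -> target IDs) and
#'   \code{spec}. The total gene count is exactly
#'   \code{n_regulators + sum(t_i)}.
#' @export
simulate_regulators <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  m <- spec$n_regulators; N <- spec$n_samples; k <- spec$n_bona_fide
  with_seed(spec$seed, {
    t_rng <- seq.int(spec$targets_min, spec$targets_max)
    t_i <- if (length(t_rng) == 1L) rep.int(t_rng, m) else
      sample(t_rng, m, replace = TRUE)
    mu <- stats::rnorm(m, spec$baseline_mean, spec$baseline_sd)
    n_a <- ceiling(N / 2)
    grp <- rep(c("A", "B"), c(n_a, N - n_a))
    shift <- c(rep(spec$effect_size, k), rep(0, m - k))
    mean_mat <- outer(mu, rep(1, N)) + outer(shift, as.numeric(grp == "B"))
    reg_expr <- mean_mat + matrix(stats::rnorm(m * N, 0, spec$reg_sd), m, N)
    total_t <- sum(t_i)
    parent <- rep(seq_len(m), t_i)
    tar_expr <- reg_expr[parent, , drop = FALSE] +
      matrix(stats::rnorm(total_t * N, 0, spec$target_noise_sd), total_t, N)
    reg_ids <- sprintf("R%0*d", nchar(m), seq_len(m))
    tar_ids <- sprintf("%s_T%02d", reg_ids[parent], sequence(t_i))
    mat <- rbind(reg_expr, tar_expr)
    rownames(mat) <- c(reg_ids, tar_ids)
    colnames(mat) <- sprintf("S%0*d", max(3L, nchar(N)), seq_len(N))
    kind <- "continuous"
    if (spec$counts) {
      lambda <- 2^pmin(pmax(mat, 0), 30)
      mat[] <- stats::rpois(length(mat), lambda)
      kind <- "counts"
    }
    ann <- data.frame(sample_id = colnames(mat), group = grp,
                      stringsAsFactors = FALSE)
    ed <- expression_data(mat, ann, kind)
    tm <- split(tar_ids, factor(parent, levels = seq_len(m)))
    names(tm) <- reg_ids
    structure(list(expression = ed,
                   truth = reg_ids[seq_len(k)],
                   target_map = tm,
                   regulators = reg_ids,
                   spec = spec),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d genes (%d regulators, %d bona fide) x %d samples\n",
              nrow(x$expression$matrix), length(x$regulators),
              length(x$truth), ncol(x$expression$matrix)))
  invisible(x)
}

#' Down-sample a simulated dataset preserving group balance
#'
#' Draws \code{n/2} samples without replacement from each group; the gene
#' set, planted truth and target map are unchanged.
#'
#' @param ds a \code{simulated_dataset}.
#' @param n even number of samples to retain, \code{n <=} current count.
#' @param seed RNG seed for the draw.
#' @return a \code{simulated_dataset} with \code{n} samples.
#' @export
downsample_dataset <- function(ds, n, seed = 1L) {
  stopifnot(inherits(ds, "simulated_dataset"))
  N <- ncol(ds$expression$matrix)
  if (n %% 2 != 0) stopf("n must be even to preserve group balance (got %d)", n)
  if (n > N) stopf("cannot draw %d samples from %d available", n, N)
  grp <- ds$expression$annotations$group
  with_seed(seed, {
    keep <- unlist(lapply(unique(grp), function(g) {
      idx <- which(grp == g)
      if (length(idx) < n / 2)
        stopf("group %s has only %d samples, need %d", g, length(idx), n / 2)
      sort(sample(idx, n / 2))
    }))
  })
  keep <- sort(keep)
  ed <- expression_data(ds$expression$matrix[, keep, drop = FALSE],
                        ds$expression$annotations[keep, , drop = FALSE],
                        ds$expression$kind)
  out <- ds
  out$expression <- ed
  out
}

#' Simulate an in-silico knockdown of one regulator
#'
#' In the silenced group the regulator's expression is multiplied by
#' \code{knock_fraction} and its targets are re-propagated from the reduced
#' values (target = reduced regulator expression + fresh Gaussian noise with
#' the spec's \code{target_noise_sd}); all other genes are untouched. This
#' emulates a gene-silencing experiment contrasted against controls.
#'
#' @param ds a \code{simulated_dataset} of kind continuous.
#' @param regulator_id the regulator to silence.
#' @param knock_fraction multiplicative knockdown factor in (0, 1).
#' @param seed RNG seed for the re-propagation noise.
#' @param silenced_group which group label is silenced (default "B").
#' @return a modified \code{simulated_dataset}.
#' @export
simulate_knockdown <- function(ds, regulator_id, knock_fraction,
                               seed = 1L, silenced_group = "B") {
  stopifnot(inherits(ds, "simulated_dataset"))
  if (ds$expression$kind != "continuous")
    stopf("knockdown simulation requires a continuous dataset")
  if (!regulator_id %in% ds$regulators)
    stopf("unknown regulator: %s", regulator_id)
  if (!(knock_fraction > 0 && knock_fraction < 1))
    stopf("knock_fraction must lie strictly in (0, 1)")
  grp <- ds$expression$annotations$group
  if (!silenced_group %in% grp) stopf("no samples in group %s", silenced_group)
  cols <- which(grp == silenced_group)
  mat <- ds$expression$matrix
  mat[regulator_id, cols] <- mat[regulator_id, cols] * knock_fraction
  targets <- ds$target_map[[regulator_id]]
  with_seed(seed, {
    if (length(targets)) {
      base <- matrix(mat[regulator_id, cols], nrow = length(targets),
                     ncol = length(cols), byrow = TRUE)
      mat[targets, cols] <- base +
        matrix(stats::rnorm(length(targets) * length(cols), 0,
                            ds$spec$target_noise_sd),
               nrow = length(targets))
    }
  })
  out <- ds
  out$expression <- expression_data(mat, ds$expression$annotations, "continuous")
  out$knocked <- list(regulator = regulator_id, fraction = knock_fraction,
                      group = silenced_group)
  out
}

#' Write a simulated dataset to a directory
#'
#' Writes \code{expression.tsv}, \code{metadata.tsv},
#' \code{truth_regulators.txt} (one planted regulator per line),
#' \code{regulators.txt} (full regulator universe) and
#' \code{target_map.tsv} (regulator, target).
#'
#' @param ds a \code{simulated_dataset}.
#' @param dir output directory (created if missing).
#' @return invisibly, \code{dir}.
#' @export
write_simulated_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(ds$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "metadata.tsv"))
  writeLines(ds$truth, file.path(dir, "truth_regulators.txt"))
  writeLines(ds$regulators, file.path(dir, "regulators.txt"))
  tm <- data.frame(regulator = rep(names(ds$target_map),
                                   lengths(ds$target_map)),
                   target = unlist(ds$target_map, use.names = FALSE))
  utils::write.table(tm, file.path(dir, "target_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
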