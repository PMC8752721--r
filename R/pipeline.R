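# Orchestration: regulator list loading, the in-memory four-stage
# pipeline, and the file-based runner with config + manifest.

#' Load a regulator list
#'
#' Plain text, one ID per line; \code{#} starts a comment; duplicates are
#' dropped keeping first occurrence. With \code{path = NULL} (or
#' \code{"default"}) the bundled default list is used - a synthetic
#' stand-in of widely studied human transcription-factor symbols, intended
#' to be replaced by the user's own list for real analyses.
#'
#' @param path file path, \code{"default"}, or NULL.
#' @return character vector of regulator IDs.
#' @export
load_regulators <- function(path = NULL) {
  if (is.null(path) || identical(path, "default"))
    path <- system.file("extdata", "default_regulators_synthetic.txt",
                        package = "keyreg", mustWork = TRUE)
  if (!file.exists(path)) stopf("regulator file not found: %s", path)
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  x <- x[!duplicated(x)]
  if (!length(x)) stopf("regulator list is empty after parsing: %s", path)
  x
}

#' Run the four-stage key-regulator pipeline in memory
#'
#' Stages: differential expression -> regulator-target network inference
#' (unless a network is supplied) -> regulator enrichment -> combined
#' ranking. Fully deterministic given \code{seed}.
#'
#' @param ed an \code{\link{expression_data}} object with a \code{group}
#'   annotation.
#' @param regulators character vector of candidate regulator IDs.
#' @param network optional pre-built \code{\link{regulator_network}}; when
#'   supplied the inference stage is skipped.
#' @param network_method \code{"coen"} (soft-threshold TOM co-expression)
#'   or \code{"grn"} (random-forest importances with poor-model filter).
#' @param enrich_method \code{"fet"} (hypergeometric over-representation
#'   of the FDR-significant gene set) or \code{"gsea"} (weighted
#'   enrichment score with permutation null).
#' @param de_method \code{"auto"} picks the NB Wald test for counts and
#'   the moderated t for continuous data (likelihood-ratio test when more
#'   than two groups); or one of \code{"wald"}, \code{"mod_t"},
#'   \code{"lrt"}.
#' @param de_fdr BH-adjusted cutoff defining the differential gene set for
#'   FET.
#' @param edge_fraction fraction of top-weighted candidate edges retained.
#' @param beta fixed soft-threshold power (NULL = pick by scale-free fit).
#' @param powers,r2_target soft-power selection parameters.
#' @param n_trees,filter_threshold GRN forest size and poor-model cutoff.
#' @param n_perm,min_set_size GSEA permutations and minimum target-set
#'   size.
#' @param seed seed for all stochastic stages.
#' @param n_jobs parallel workers (results independent of the count).
#' @param block_size blockwise correlation chunk for COEN.
#' @return list with elements \code{de}, \code{network},
#'   \code{enrichment}, \code{ranking} (a \code{regulator_ranking} whose
#'   table also carries log_fc, es, n_targets, overlap).
#' @export
run_keyreg <- function(ed, regulators, network = NULL,
                       network_method = c("coen", "grn"),
                       enrich_method = c("fet", "gsea"),
                       de_method = "auto", de_fdr = 0.05,
                       edge_fraction = 0.05, beta = NULL,
                       powers = c(1:10, seq(12L, 20L, 2L)), r2_target = 0.85,
                       n_trees = 1000L, filter_threshold = 0,
                       n_perm = 1000L, min_set_size = 3L,
                       seed = 1L, n_jobs = 1L, block_size = 2000L) {
  stopifnot(inherits(ed, "ExpressionData"))
  network_method <- match.arg(network_method)
  enrich_method <- match.arg(enrich_method)
  # stage 1: differential expression
  n_groups <- length(unique(ed$annotations$group))
  if (de_method == "auto")
    de_method <- if (n_groups > 2) "lrt"
                 else if (ed$kind == "counts") "wald" else "mod_t"
  de <- switch(de_method,
    wald = nb_wald_test(ed),
    mod_t = moderated_t_test(ed),
    lrt = likelihood_ratio_test(ed, ~group, ~1),
    stopf("unknown de_method: %s", de_method))
  # stage 2: network
  if (is.null(network)) {
    regs_in <- intersect(regulators, gene_ids(ed))
    if (!length(regs_in))
      stopf("regulator set is disjoint from the expression genes")
    if (length(regs_in) < length(regulators))
      message(sprintf("%d of %d regulators absent from the expression data",
                      length(regulators) - length(regs_in), length(regulators)))
    if (network_method == "coen") {
      W <- coen_weight_matrix(ed, regs_in, beta = beta, powers = powers,
                              r2_target = r2_target, block_size = block_size)
    } else {
      g <- grn_importances(ed, regs_in, n_trees = n_trees, seed = seed,
                           n_jobs = n_jobs)
      W <- filter_poor_models(g$weights, g$quality, filter_threshold)
    }
    network <- extract_topology(W, edge_fraction)
  } else {
    stopifnot(inherits(network, "regulator_network"))
  }
  # stage 3: enrichment
  if (enrich_method == "fet") {
    de_genes <- de$gene_id[de$p_adjusted < de_fdr]
    enr <- fet_enrich(network, de_genes, min_set_size = min_set_size)
  } else {
    metric <- make_ranking_metric(de, genes = network$nodes)
    enr <- gsea_empirical_p(metric, target_sets(network), n_perm = n_perm,
                            seed = seed, min_set_size = min_set_size,
                            n_jobs = n_jobs)
  }
  # stage 4: ranking
  regs <- enr$regulator
  p_d <- stats::setNames(de$p_value[match(regs, de$gene_id)], regs)
  p_e <- stats::setNames(enr$p_value, regs)
  ranking <- suppressMessages(rank_regulators(p_d, p_e))
  extra <- de[match(ranking$regulator, de$gene_id), c("log_fc"), drop = FALSE]
  ei <- match(ranking$regulator, enr$regulator)
  ranking$log_fc <- extra$log_fc
  ranking$es <- enr$es[ei]
  ranking$n_targets <- enr$n_targets[ei]
  ranking$overlap <- enr$overlap[ei]
  ranking <- ranking[, c("rank", "regulator", "p_d", "log_fc", "p_e", "es",
                         "n_targets", "overlap", "score")]
  class(ranking) <- c("regulator_ranking", "data.frame")
  list(de = de, network = network, enrichment = enr, ranking = ranking)
}

#' Default pipeline configuration
#'
#' @return a nested list of defaults; see \code{\link{run_pipeline}} for
#'   the fields.
#' @export
default_config <- function() {
  list(paths = list(expr = NULL, meta = NULL, regulators = "default",
                    network = NULL, out_dir = "keyreg_out"),
       data = list(kind = "continuous", log2_transform = FALSE),
       de = list(method = "auto", de_fdr = 0.05),
       network = list(method = "coen", edge_fraction = 0.05, beta = NULL,
                      powers = c(1:10, seq(12L, 20L, 2L)), r2_target = 0.85,
                      n_trees = 1000L, filter_threshold = 0),
       enrichment = list(method = "fet", n_perm = 1000L, min_set_size = 3L),
       seed = 1L, n_jobs = 1L)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML (or JSON)
#'
#' Unspecified fields fall back to \code{\link{default_config}}.
#'
#' @param path YAML/JSON file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the full pipeline from a configuration, writing all outputs
#'
#' Executes differential expression, network inference (or loads a
#' user-supplied edge list), enrichment and ranking, persisting
#' \code{de_results.tsv}, \code{network_edges.tsv}, \code{enrichment.tsv},
#' \code{ranking.tsv}, \code{regulator_targets.tsv} and
#' \code{run_manifest.json} (the fully resolved configuration plus package
#' version) under \code{paths$out_dir}. Outputs are written with a
#' \code{.partial} suffix and renamed on successful completion, so an
#' aborted run leaves its partial files identifiable.
#'
#' @param config configuration list (see \code{\link{default_config}}).
#' @return invisibly, the \code{regulator_ranking} table.
#' @export
run_pipeline <- function(config) {
  cfg <- merge_config(default_config(), config)
  p <- cfg$paths
  if (is.null(p$expr)) stopf("config paths$expr is required")
  out_dir <- p$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  part <- function(f) file.path(out_dir, paste0(f, ".partial"))
  final <- function(f) file.path(out_dir, f)
  stage <- "input"
  res <- tryCatch({
    ed <- read_expression(p$expr, p$meta, cfg$data$kind)
    if (isTRUE(cfg$data$log2_transform)) {
      ed <- expression_data(log2(ed$matrix + 1), ed$annotations, "continuous")
    }
    regulators <- load_regulators(p$regulators)
    network <- if (!is.null(p$network)) read_network(p$network) else NULL
    stage <- "pipeline"
    run_keyreg(ed, regulators, network = network,
               network_method = cfg$network$method,
               enrich_method = cfg$enrichment$method,
               de_method = cfg$de$method, de_fdr = cfg$de$de_fdr,
               edge_fraction = cfg$network$edge_fraction,
               beta = cfg$network$beta, powers = cfg$network$powers,
               r2_target = cfg$network$r2_target,
               n_trees = cfg$network$n_trees,
               filter_threshold = cfg$network$filter_threshold,
               n_perm = cfg$enrichment$n_perm,
               min_set_size = cfg$enrichment$min_set_size,
               seed = cfg$seed, n_jobs = cfg$n_jobs)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  write_de_results(res$de, part("de_results.tsv"))
  write_network(res$network, part("network_edges.tsv"))
  write_enrichment(res$enrichment, part("enrichment.tsv"))
  utils::write.table(res$ranking, part("ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # companion export: per-edge table with differential flag
  de_set <- res$de$gene_id[res$de$p_adjusted < cfg$de$de_fdr]
  rt <- res$network$edges
  rt$target_in_de_set <- rt$target %in% de_set
  utils::write.table(rt, part("regulator_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(package = "keyreg",
                   version = as.character(utils::packageVersion("keyreg")),
                   config = cfg)
  jsonlite::write_json(manifest, part("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  for (f in c("de_results.tsv", "network_edges.tsv", "enrichment.tsv",
              "ranking.tsv", "regulator_targets.tsv", "run_manifest.json"))
    file.rename(part(f), final(f))
  invisible(res$ranking)
}
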