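# End-to-end pipeline: orchestrates fit, null, significance, enrichment,
# tissue context, capacity and validation stages, writing one TSV per stage
# plus a manifest with input hashes and parameters.

#' Default pipeline configuration
#'
#' Paths may point at files written by [write_sim_bundle()] or any data in
#' the same formats; when `paths` is `NULL` a synthetic bundle is generated
#' in memory from `sim` (a [sim_config()]).
#'
#' @param paths optional named list: `dependency`, `expression`,
#'   `annotation`, and optionally `duplicated`, `gi`, `prognosis`,
#'   `tissue_map`.
#' @param sim a [sim_config()] used when `paths` is `NULL`.
#' @param b,alpha,cscore_threshold C-score fit parameters.
#' @param n_shuffles,seed null-model parameters.
#' @param percentile capacity reference percentile.
#' @param enrichment_cutoffs ascending cutoffs for the enrichment curve.
#' @param network_cutoff cutoff for network construction.
#' @param region_cutoff,region_p_adj,region_max_pairs region-analysis knobs.
#' @param prognosis_cutoffs cutoffs for prognosis AUC.
#' @param log_base enrichment log base.
#' @return list of class `cebu_config`.
#' @export
cebu_config <- function(paths = NULL, sim = sim_config(),
                        b = 1, alpha = 0.05, cscore_threshold = 0.25,
                        n_shuffles = 5L, seed = 1L, percentile = 25,
                        enrichment_cutoffs = c(0.05, 0.1, 0.15, 0.2, 0.25),
                        network_cutoff = 0.25,
                        region_cutoff = 0.25, region_p_adj = 0.05,
                        region_max_pairs = 200L,
                        prognosis_cutoffs = c(0.1, 0.25),
                        log_base = 2) {
  cfg <- as.list(environment())
  stopifnot(alpha > 0, alpha < 1, n_shuffles >= 1L,
            !is.unsorted(enrichment_cutoffs))
  class(cfg) <- "cebu_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [cebu_config()]; `paths` is a
#' mapping of input-file paths, and `sim` a mapping of [sim_config()]
#' overrides.
#'
#' @param path YAML file.
#' @return list of class `cebu_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- if (!is.null(y$sim)) y$sim else list()
  y$sim <- do.call(sim_config, sim_args)
  do.call(cebu_config, y)
}

#' Run the full buffering-inference pipeline
#'
#' Stages: load-or-simulate, C-score fit, shuffled null + significance,
#' duplicated/annotation enrichment, buffering network, tissue specificity
#' and tau contrast, region x tissue enrichment, buffering capacity and
#' tissue means, GI validation (assignment, ROC/AUC, capacity correlation)
#' and prognosis AUC.  Every stage's output is written as TSV under
#' `out_dir`, with a `manifest.yaml` recording parameters, input hashes and
#' record counts.  Deterministic given `config$seed`.
#'
#' @param config a [cebu_config()] (or path to a YAML file).
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the fitted objects and result tables.
#' @export
run_pipeline <- function(config = cebu_config(), out_dir = tempfile("cebu_run_"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "cebu_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  t0 <- Sys.time()
  manifest <- list(parameters = config[setdiff(names(config), c("paths", "sim"))],
                   inputs = list(), outputs = list())

  # --- inputs ------------------------------------------------------------
  truths <- NULL; truth <- NULL
  if (is.null(config$paths)) {
    say("data", "generating synthetic bundle (seed %d)", config$sim$seed)
    sim <- sim_cebu(config$sim)
    data <- sim$data
    truth <- sim$truth
    truths <- sim_ground_truths(sim)
    manifest$inputs$synthetic <- unclass(config$sim)
  } else {
    p <- config$paths
    say("data", "reading %s", p$dependency)
    dep <- read_matrix(p$dependency, "dependency")
    expr <- read_matrix(p$expression, "expression")
    ann <- read_cell_annotation(p$annotation)
    data <- align_datasets(dep, expr, ann)
    truths <- list(
      duplicated = if (!is.null(p$duplicated))
        read_pair_table(p$duplicated, "duplicated"),
      gi = if (!is.null(p$gi)) read_pair_table(p$gi, "gi"),
      prognosis = if (!is.null(p$prognosis))
        read.table(p$prognosis, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE),
      tissue_map = if (!is.null(p$tissue_map))
        read.table(p$tissue_map, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE))
    manifest$inputs <- lapply(p, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  }

  out <- list(data = data, truth = truth)

  # --- C-score fit, null, significance ----------------------------------
  say("cscore", "fitting screen (b=%g, alpha=%g, threshold=%g)",
      config$b, config$alpha, config$cscore_threshold)
  fit <- cebu(data, b = config$b, alpha = config$alpha,
              threshold = min(config$cscore_threshold,
                              config$enrichment_cutoffs,
                              config$prognosis_cutoffs))
  say("cscore", "slope_min = %.5g; %d records kept", fit$slope_min,
      nrow(fit$records))
  null <- cebu_null(fit, n_shuffles = config$n_shuffles, seed = config$seed)
  say("null", "mu = %.4g, sigma = %.4g", null$mu, null$sigma)
  fit <- cebu_significance(fit, null)
  out$fit <- fit; out$null <- null
  .write_stage <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs[[name]] <<- list(md5 = unname(tools::md5sum(path)),
                                      rows = nrow(df))
    path
  }
  .write_stage(fit$records, "pairs.tsv")
  .write_stage(null$per_shuffle, "null.tsv")

  # --- enrichment --------------------------------------------------------
  if (!is.null(truths$duplicated) && nrow(truths$duplicated)) {
    dup <- duplicated_enrichment(fit, truths$duplicated,
                                 config$cscore_threshold)
    say("enrich", "duplicated pairs: %d/%d above cutoff, p = %.3g",
        dup$e_ac, dup$e_a, dup$p)
    curve <- enrichment_curve(fit, truths$duplicated,
                              config$enrichment_cutoffs, config$log_base)
    curve$hypergeom_p <- vapply(config$enrichment_cutoffs, function(ct)
      duplicated_enrichment(fit, truths$duplicated, ct)$p, numeric(1))
    out$duplicated <- dup; out$enrichment <- curve
    .write_stage(curve, "enrichment.tsv")
  }

  # --- network -----------------------------------------------------------
  net <- build_network(fit, config$network_cutoff)
  say("network", "%d nodes, %d edges", igraph::vcount(net$graph),
      igraph::ecount(net$graph))
  write_network(net, file.path(out_dir, "network.sif"), "sif")
  manifest$outputs[["network.sif"]] <-
    list(md5 = unname(tools::md5sum(file.path(out_dir, "network.sif"))),
         rows = igraph::ecount(net$graph))
  out$network <- net

  # --- tissue specificity ------------------------------------------------
  tau <- compute_tau(data$expression, data$annotation)
  high <- fit$records[fit$records$c_score >= config$cscore_threshold, ]
  contrast <- NULL
  tau_g1 <- tau$tau[match(high$g1, tau$gene)]
  tau_g2 <- tau$tau[match(high$g2, tau$gene)]
  ok <- is.finite(tau_g1) & is.finite(tau_g2)
  if (sum(ok) >= 2L) {
    contrast <- tau_contrast(tau_g1[ok], tau_g2[ok])
  } else {
    # G1 genes without expression profiles (synthetic panels): contrast each
    # high-pair G2 against its own shuffled-expression control instead
    contrast <- tryCatch(shuffled_tau_contrast(fit, high, tau,
                                               seed = config$seed),
                         error = function(e) NULL)
  }
  out$tau <- tau; out$tau_contrast <- contrast
  .write_stage(tau, "tau.tsv")

  # --- regions -----------------------------------------------------------
  reg <- region_tissue_enrichment(fit, config$region_cutoff,
                                  p_adj = config$region_p_adj,
                                  max_pairs = config$region_max_pairs)
  out$regions <- reg
  .write_stage(data.frame(region = rownames(reg$share), reg$share,
                          check.names = FALSE), "regions.tsv")

  # --- capacity ----------------------------------------------------------
  caps <- buffering_capacity(fit, pairs = high, percentile = config$percentile)
  tiss_cap <- tissue_mean_capacity(caps, data$annotation)
  say("capacity", "top tissue: %s (mean %.3g)", tiss_cap$tissue_type[1L],
      tiss_cap$mean_capacity[1L])
  out$capacity <- caps; out$tissue_capacity <- tiss_cap
  .write_stage(tiss_cap, "tissue_capacity.tsv")

  # --- GI validation -----------------------------------------------------
  if (!is.null(truths$gi)) {
    gi <- assign_pair_cscore(truths$gi, fit)
    roc <- roc_auc(gi$assigned_cscore, gi$label)
    say("validate", "GI ROC AUC = %.3f (p = %.3g)", roc$auc, roc$p)
    out$gi <- gi; out$gi_auc <- roc
    gi_pairs <- unique(data.frame(g1 = gi$gene_a, g2 = gi$gene_b,
                                  stringsAsFactors = FALSE))
    gi_pairs <- merge(gi_pairs, fit$records[c("g1", "g2")],
                      by = c("g1", "g2"), sort = FALSE)
    out$gi_correlation <- if (nrow(gi_pairs)) tryCatch({
      gi_caps <- buffering_capacity(fit, pairs = gi_pairs,
                                    percentile = config$percentile)
      capacity_gi_correlation(gi_caps, gi, config$cscore_threshold)
    }, error = function(e) NULL)
    .write_stage(gi, "gi_validation.tsv")
  }

  # --- prognosis ---------------------------------------------------------
  if (!is.null(truths$prognosis) && !is.null(truths$tissue_map)) {
    prog <- prognosis_auc(truths$prognosis, fit, truths$tissue_map,
                          cutoffs = config$prognosis_cutoffs,
                          percentile = config$percentile)
    say("prognosis", "%d (cancer, cutoff) AUCs; median %.3f", nrow(prog),
        if (nrow(prog)) stats::median(prog$auc) else NA)
    out$prognosis <- prog
    .write_stage(prog, "prognosis.tsv")
  }

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  out$manifest <- manifest
  out$out_dir <- out_dir
  invisible(out)
}
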