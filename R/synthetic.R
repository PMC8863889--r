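# Synthetic DepMap-like panel generator with planted buffering structure.
#
# The generator emulates the statistical geometry the C-score screen relies
# on: tissue-blocked cell lines, tissue-specific G2 expression with strongly
# heterogeneous per-gene variability (a lognormal bulk plus a few
# near-invariant "housekeeping-like" transcripts, which are what anchor the
# minimum regression slope in real panels), and planted pairs in which G1
# dependency is a linear function of G2 expression plus Gaussian noise, so
# that the expression-on-dependency slope is a directly recoverable
# parameter.

#' Configuration for the synthetic panel generator
#'
#' Defaults define the package's reference study conditions: 200 cell lines
#' in 8 tissues, a 50 x 200 gene universe (10,000 pairs) with 50 planted
#' buffering pairs of true slope 0.01 log2 TPM per dependency unit, and
#' noise standard deviations 0.1 (dependency) and 0.5 (expression).
#'
#' @param n_cell_lines number of cell lines.
#' @param n_tissues number of tissue labels (cells assigned near-uniformly).
#' @param n_g1 number of dependency-profiled (buffered candidate) genes.
#' @param n_g2 number of expression-profiled (buffering candidate) genes.
#' @param n_planted_pairs planted buffering pairs (`<= min(n_g1, n_g2)`).
#' @param planted_slope true expression-on-dependency slope of planted pairs
#'   (log2 TPM per dependency-score unit).
#' @param dependency_noise_sd Gaussian noise sd on dependency scores.
#' @param expression_noise_sd baseline within-tissue expression noise sd
#'   (log2 TPM); scaled per gene by `expr_sd_mult` draws.
#' @param tissue_effect_sd baseline sd of tissue-specific expression offsets;
#'   scaled per gene by the same variability multiplier as the noise.
#' @param baseline_dependency mean dependency score of G1 genes (< 0, i.e.
#'   essential on average so they pass candidate filtering).
#' @param expression_mean_range range of per-gene baseline expression means
#'   (log2 TPM), drawn uniformly.
#' @param expr_sd_mult lognormal meanlog/sdlog and truncation bounds
#'   (`sdlog`, `lo`, `hi`) of the per-gene expression variability multiplier.
#' @param n_flat_genes number of near-invariant transcripts.
#' @param flat_sd_mult loguniform range of the variability multiplier for the
#'   near-invariant class.
#' @param dep_sd_mult loguniform range of the per-gene dependency noise
#'   multiplier for background G1s.
#' @param boost_tissue index of the tissue with elevated planted-G2
#'   expression (a high-buffering tissue); `0` disables.
#' @param tissue_boost log2 TPM added to planted G2 means in `boost_tissue`.
#' @param seed integer seed governing every draw.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cell_lines = 200L, n_tissues = 8L,
                       n_g1 = 50L, n_g2 = 200L, n_planted_pairs = 50L,
                       planted_slope = 0.01,
                       dependency_noise_sd = 0.1,
                       expression_noise_sd = 0.5,
                       tissue_effect_sd = 1,
                       baseline_dependency = -1,
                       expression_mean_range = c(1.5, 7),
                       expr_sd_mult = c(sdlog = 1.2, lo = 0.05, hi = 8),
                       n_flat_genes = 4L,
                       flat_sd_mult = c(0.004, 0.015),
                       dep_sd_mult = c(0.8, 1.25),
                       boost_tissue = 1L, tissue_boost = 1.5,
                       seed = 1L) {
  cfg <- list(n_cell_lines = as.integer(n_cell_lines),
              n_tissues = as.integer(n_tissues),
              n_g1 = as.integer(n_g1), n_g2 = as.integer(n_g2),
              n_planted_pairs = as.integer(n_planted_pairs),
              planted_slope = planted_slope,
              dependency_noise_sd = dependency_noise_sd,
              expression_noise_sd = expression_noise_sd,
              tissue_effect_sd = tissue_effect_sd,
              baseline_dependency = baseline_dependency,
              expression_mean_range = expression_mean_range,
              expr_sd_mult = expr_sd_mult,
              n_flat_genes = as.integer(n_flat_genes),
              flat_sd_mult = flat_sd_mult,
              dep_sd_mult = dep_sd_mult,
              boost_tissue = as.integer(boost_tissue),
              tissue_boost = tissue_boost,
              seed = as.integer(seed))
  stopifnot(cfg$n_planted_pairs <= min(cfg$n_g1, cfg$n_g2),
            cfg$dependency_noise_sd >= 0, cfg$expression_noise_sd >= 0,
            cfg$tissue_effect_sd >= 0, cfg$baseline_dependency < 0,
            cfg$planted_slope != 0,
            cfg$n_flat_genes + cfg$n_planted_pairs <= cfg$n_g2)
  if (cfg$expression_noise_sd == 0 && cfg$tissue_effect_sd == 0) {
    stop("degenerate configuration: expression has zero variance everywhere")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic aligned panel with planted buffering pairs
#'
#' Expression of each G2 gene is its per-tissue mean plus Gaussian noise,
#' floored at 0 (log2(TPM+1) is non-negative).  For each planted pair the G1
#' dependency profile is generated conditional on the (floored) G2
#' expression:
#' `D = intercept + (E - mean(E)) / slope + noise`, so regressing expression
#' on dependency recovers `slope`.  Background G1 profiles are independent
#' of every G2.  Identical seeds give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list of class `cebu_sim` with elements `data` (a `cebu_data`) and
#'   `truth` (planted pairs with true slope/intercept, tissue assignment,
#'   per-gene tissue means and config).
#' @export
sim_cebu <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_c <- config$n_cell_lines
  cells <- sprintf("CL%04d", seq_len(n_c))
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  tissue_of <- sample(rep_len(tissues, n_c))
  g1 <- sprintf("G1_%04d", seq_len(config$n_g1))
  g2 <- sprintf("G2_%04d", seq_len(config$n_g2))

  # per-gene expression variability multiplier: near-invariant class first,
  # lognormal bulk for the rest
  em <- config$expr_sd_mult
  mult <- pmin(pmax(exp(rnorm(config$n_g2, 0, em[["sdlog"]])), em[["lo"]]),
               em[["hi"]])
  if (config$n_flat_genes > 0L) {
    fr <- config$flat_sd_mult
    mult[seq_len(config$n_flat_genes)] <-
      exp(runif(config$n_flat_genes, log(fr[1L]), log(fr[2L])))
  }
  base <- runif(config$n_g2, config$expression_mean_range[1L],
                config$expression_mean_range[2L])
  tiss_means <- base +
    matrix(rnorm(config$n_g2 * config$n_tissues, 0, config$tissue_effect_sd),
           config$n_g2, config$n_tissues,
           dimnames = list(g2, tissues)) * mult

  # planted G2s sit after the near-invariant block
  planted_g2_idx <- config$n_flat_genes + seq_len(config$n_planted_pairs)
  if (config$boost_tissue > 0L && config$n_planted_pairs > 0L) {
    tiss_means[planted_g2_idx, config$boost_tissue] <-
      tiss_means[planted_g2_idx, config$boost_tissue] + config$tissue_boost
  }

  expr <- tiss_means[, match(tissue_of, tissues), drop = FALSE] +
    matrix(rnorm(config$n_g2 * n_c, 0, config$expression_noise_sd),
           config$n_g2, n_c) * mult
  expr[expr < 0] <- 0
  dimnames(expr) <- list(g2, cells)

  dep_mult <- exp(runif(config$n_g1, log(config$dep_sd_mult[1L]),
                        log(config$dep_sd_mult[2L])))
  dep <- config$baseline_dependency +
    matrix(rnorm(config$n_g1 * n_c, 0, config$dependency_noise_sd),
           config$n_g1, n_c) * dep_mult
  dimnames(dep) <- list(g1, cells)

  planted <- data.frame(g1 = character(0), g2 = character(0),
                        true_slope = numeric(0), true_intercept = numeric(0))
  if (config$n_planted_pairs > 0L) {
    for (i in seq_len(config$n_planted_pairs)) {
      e <- expr[planted_g2_idx[i], ]
      dep[i, ] <- config$baseline_dependency +
        (e - mean(e)) / config$planted_slope +
        rnorm(n_c, 0, config$dependency_noise_sd)
    }
    planted <- data.frame(g1 = g1[seq_len(config$n_planted_pairs)],
                          g2 = g2[planted_g2_idx],
                          true_slope = config$planted_slope,
                          true_intercept = config$baseline_dependency,
                          stringsAsFactors = FALSE)
  }

  ann <- data.frame(cell_line = cells, tissue_type = tissue_of,
                    stringsAsFactors = FALSE)
  data <- align_datasets(dep, expr, ann)
  truth <- structure(list(planted = planted,
                          tissue_means = tiss_means,
                          expr_sd_mult = setNames(mult, g2),
                          boost_tissue = if (config$boost_tissue > 0L)
                            tissues[config$boost_tissue] else NA_character_,
                          config = config),
                     class = "cebu_sim_truth")
  structure(list(data = data, truth = truth), class = "cebu_sim")
}

#' @export
print.cebu_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Synthetic buffering panel: %d x %d genes, %d cell lines, %d planted pairs (seed %d)\n",
              cfg$n_g1, cfg$n_g2, cfg$n_cell_lines, cfg$n_planted_pairs,
              cfg$seed))
  invisible(x)
}

#' Companion ground-truth tables for a synthetic panel
#'
#' Emits the external evidence tables the validation stages consume:
#' a duplicated-pair list (a configurable fraction of planted pairs flagged),
#' a genetic-interaction table (planted pairs receive negative GI scores in
#' their high-expression cell lines, background pairs scores centred on 0),
#' and a per-cancer prognosis table in which the planted G2s are the genes
#' whose higher expression associates with poorer prognosis (positive Cox
#' coefficient sign, adjusted p below 0.1).
#'
#' @param sim a [sim_cebu()] result.
#' @param fraction_duplicated fraction of planted pairs flagged duplicated.
#' @param gi_effect GI score per standardized unit of G2 expression excess
#'   in planted pairs (negative: more expression, stronger buffering, more
#'   negative interaction).
#' @param gi_sd Gaussian sd of GI scores.
#' @param n_background_gi_pairs background (unplanted) pairs given GI rows.
#' @param expression_quantile planted GI rows are emitted for cell lines with
#'   G2 expression above this quantile (the high-expression lines).
#' @param seed seed for the ground-truth draws.
#' @return list with data.frames `duplicated`, `gi`, `prognosis` and a
#'   `tissue_map` (cancer type to tissue).  Prognosis positives (positive
#'   Cox sign, adjusted p < 0.1) are the planted G2s in the cancer matched
#'   to the high-buffering (boosted) tissue, where their capacity is
#'   genuinely elevated; other cancers carry too few positives and are
#'   skipped by [prognosis_auc()].
#' @export
sim_ground_truths <- function(sim, fraction_duplicated = 0.5,
                              gi_effect = -0.5, gi_sd = 0.1,
                              n_background_gi_pairs = 10L,
                              expression_quantile = 0.75,
                              seed = sim$truth$config$seed + 1L) {
  stopifnot(inherits(sim, "cebu_sim"))
  set.seed(seed)
  planted <- sim$truth$planted
  expr <- sim$data$expression
  dep_genes <- rownames(sim$data$dependency)
  expr_genes <- rownames(expr)

  n_dup <- round(fraction_duplicated * nrow(planted))
  duplicated <- planted[sample.int(nrow(planted), n_dup), c("g1", "g2")]
  rownames(duplicated) <- NULL
  if (nrow(duplicated)) duplicated$key <- pair_key(duplicated$g1, duplicated$g2)

  gi <- list()
  for (i in seq_len(nrow(planted))) {
    e <- expr[planted$g2[i], ]
    hi <- names(e)[e > quantile(e, expression_quantile)]
    if (!length(hi)) next
    # standardized excess above the high-expression threshold, plus a base
    # effect so interactions in high-expression lines are genuinely negative
    excess <- (e[hi] - quantile(e, expression_quantile)) / sd(e)
    gi[[length(gi) + 1L]] <- data.frame(
      cell_line = hi, gene_a = planted$g1[i], gene_b = planted$g2[i],
      score = gi_effect * (0.5 + excess) + rnorm(length(hi), 0, gi_sd),
      stringsAsFactors = FALSE)
  }
  planted_keys <- pair_key(planted$g1, planted$g2)
  n_bg <- 0L
  while (n_bg < n_background_gi_pairs) {
    a <- sample(dep_genes, 1L); b <- sample(expr_genes, 1L)
    if (a == b || pair_key(a, b) %in% planted_keys) next
    cl <- sample(colnames(expr), min(50L, ncol(expr)))
    gi[[length(gi) + 1L]] <- data.frame(
      cell_line = cl, gene_a = a, gene_b = b,
      score = rnorm(length(cl), 0, gi_sd), stringsAsFactors = FALSE)
    n_bg <- n_bg + 1L
  }
  gi <- do.call(rbind, gi)
  attr(gi, "kind") <- "gi"

  tissues <- unique(sim$data$annotation$tissue_type)
  tissue_map <- data.frame(cancer_type = paste0("cancer_", tissues),
                           tissue = tissues, stringsAsFactors = FALSE)
  boosted_cancer <- tissue_map$cancer_type[
    match(sim$truth$boost_tissue, tissue_map$tissue)]
  prognosis <- do.call(rbind, lapply(tissue_map$cancer_type, function(ca) {
    if (identical(ca, boosted_cancer)) {
      # poorer prognosis with higher expression, exactly the planted G2s
      pos <- planted$g2
      neg <- setdiff(expr_genes, pos)
      data.frame(cancer_type = ca,
                 gene = c(pos, neg),
                 cox_sign = c(rep(1L, length(pos)),
                              sample(c(1L, -1L), length(neg), replace = TRUE)),
                 adjusted_p = c(runif(length(pos), 0, 0.0999),
                                runif(length(neg), 0.1, 1)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cancer_type = ca,
                 gene = expr_genes,
                 cox_sign = sample(c(1L, -1L), length(expr_genes),
                                   replace = TRUE),
                 adjusted_p = runif(length(expr_genes), 0.05, 1),
                 stringsAsFactors = FALSE)
    }
  }))
  prognosis$significant <- prognosis$adjusted_p < 0.1
  rownames(prognosis) <- NULL

  list(duplicated = duplicated, gi = gi, prognosis = prognosis,
       tissue_map = tissue_map)
}

#' Write a synthetic bundle to disk in the package's file formats
#'
#' @param sim a [sim_cebu()] result.
#' @param truths optional [sim_ground_truths()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_bundle <- function(sim, truths = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dependency = file.path(dir, "dependency.csv"),
             expression = file.path(dir, "expression.csv"),
             annotation = file.path(dir, "annotation.csv"))
  write_matrix(sim$data$dependency, paths[["dependency"]])
  write_matrix(sim$data$expression, paths[["expression"]])
  write.table(sim$data$annotation, paths[["annotation"]], sep = ",",
              quote = FALSE, row.names = FALSE)
  write_pair_table(sim$truth$planted, file.path(dir, "planted_truth.tsv"))
  paths["planted_truth"] <- file.path(dir, "planted_truth.tsv")
  if (!is.null(truths)) {
    dup <- truths$duplicated
    if (!is.null(dup) && nrow(dup)) {
      names(dup)[match(c("g1", "g2"), names(dup))] <- c("gene_a", "gene_b")
    } else {
      dup <- data.frame(gene_a = character(0), gene_b = character(0))
    }
    tabs <- list(duplicated = dup, gi = truths$gi,
                 prognosis = truths$prognosis, tissue_map = truths$tissue_map)
    for (nm in names(tabs)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      write_pair_table(tabs[[nm]], p)
      paths[nm] <- p
    }
  }
  invisible(paths)
}
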