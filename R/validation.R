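# Validation against genetic-interaction and prognosis ground truths:
# orientation-max C-score assignment, rank-based ROC/AUC, capacity-GI
# correlation, and per-cancer prognosis AUC.

#' Assign the orientation-maximum C-score to genetic-interaction pairs
#'
#' Either gene of an experimentally measured pair could act as the buffered
#' gene, so both orientations are scored and the higher C-score is assigned.
#' An orientation outside the candidate universe counts as `-Inf`; pairs
#' absent in both orientations are dropped (count reported as attribute
#' `n_dropped`).  The buffering label is `TRUE` for strictly negative GI
#' scores (synthetic-sick/lethal), `FALSE` otherwise (0 included).
#'
#' @param gi data.frame with `gene_a`, `gene_b`, `cell_line`, `score`.
#' @param fit a [cebu()] object.
#' @return data.frame `cell_line, gene_a, gene_b, gi_score, assigned_cscore,
#'   label`.
#' @export
assign_pair_cscore <- function(gi, fit) {
  stopifnot(inherits(fit, "cebu"))
  upairs <- unique(gi[c("gene_a", "gene_b")])
  fwd <- score_pairs(fit, upairs$gene_a, upairs$gene_b)$c_score
  rev <- score_pairs(fit, upairs$gene_b, upairs$gene_a)$c_score
  assigned <- pmax(ifelse(is.na(fwd), -Inf, fwd),
                   ifelse(is.na(rev), -Inf, rev))
  upairs$assigned_cscore <- assigned
  out <- merge(gi, upairs, by = c("gene_a", "gene_b"), sort = FALSE)
  dropped <- !is.finite(out$assigned_cscore)
  n_dropped <- sum(dropped)
  if (n_dropped) out <- out[!dropped, , drop = FALSE]
  res <- data.frame(cell_line = out$cell_line, gene_a = out$gene_a,
                    gene_b = out$gene_b, gi_score = out$score,
                    assigned_cscore = out$assigned_cscore,
                    label = out$score < 0, stringsAsFactors = FALSE)
  attr(res, "n_dropped") <- n_dropped
  res
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is computed from average ranks (tie-corrected):
#' `(sum of positive ranks - n1(n1+1)/2) / (n1 * n0)`.  The p-value is a
#' one-sided Mann-Whitney test of positives scoring higher than negatives
#' (AUC > 0.5).
#'
#' @param scores numeric predictor.
#' @param labels logical (TRUE = positive class).
#' @return list with `auc`, `p`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  p <- suppressWarnings(
    wilcox.test(scores[labels], scores[!labels],
                alternative = "greater", exact = FALSE)$p.value)
  list(auc = auc, p = p, n_pos = n1, n_neg = n0)
}

#' Correlation of buffering capacity with genetic-interaction strength
#'
#' Pearson correlation of cell-specific capacity against the measured GI
#' score over matched (pair, cell line) records with assigned C-score at or
#' above the cutoff; buffering predicts a negative correlation (stronger
#' capacity, more negative GI).
#'
#' @param capacities data.frame from [buffering_capacity()] (the pair is
#'   matched on the buffered/buffering orientation actually scored).
#' @param gi data.frame from [assign_pair_cscore()].
#' @param cutoff minimum assigned C-score.
#' @return list with `r`, `p`, `n`.
#' @export
capacity_gi_correlation <- function(capacities, gi, cutoff) {
  gi <- gi[gi$assigned_cscore >= cutoff, , drop = FALSE]
  key_cap <- paste(pair_key(capacities$g1, capacities$g2),
                   capacities$cell_line)
  key_gi <- paste(pair_key(gi$gene_a, gi$gene_b), gi$cell_line)
  idx <- match(key_gi, key_cap)
  ok <- !is.na(idx)
  if (sum(ok) < 3L) stop("fewer than 3 matched (pair, cell line) records")
  cap <- capacities$capacity[idx[ok]]
  sc <- gi$gi_score[ok]
  if (sd(sc) == 0 || sd(cap) == 0) stop("zero variance in matched records")
  ct <- stats::cor.test(cap, sc)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Per-cancer prognosis AUC from buffering capacity
#'
#' For each cancer type and C-score cutoff: a gene's predictor score is its
#' buffering capacity in the matched tissue (aggregated over qualifying
#' pairs in which it is the buffering gene, `max` by default), and its label
#' is whether higher expression significantly associates with poorer
#' prognosis (positive Cox coefficient sign and adjusted p < 0.1 in the
#' supplied ground-truth table).  Cancers with fewer than `min_positives`
#' positive genes are skipped.  AUC and one-sided Mann-Whitney p per
#' (cancer, cutoff); q is Benjamini-Hochberg across all evaluated
#' combinations.
#'
#' @param prognosis data.frame with `cancer_type, gene, cox_sign,
#'   adjusted_p`.
#' @param fit a [cebu()] object (records must cover the smallest cutoff).
#' @param tissue_map data.frame `cancer_type, tissue` matching cancers to
#'   panel tissues.
#' @param cutoffs C-score cutoffs to evaluate.
#' @param percentile capacity reference percentile.
#' @param aggregate `"max"` (default) or `"mean"` over a gene's qualifying
#'   pairs.
#' @param min_positives minimum positive genes per cancer.
#' @return data.frame `cancer_type, cutoff, auc, p, q, n_pos, n_neg` (one
#'   row per evaluated combination) with skipped cancers in attribute
#'   `skipped`.
#' @export
prognosis_auc <- function(prognosis, fit, tissue_map, cutoffs = c(0.1, 0.25),
                          percentile = 25, aggregate = c("max", "mean"),
                          min_positives = 50L) {
  stopifnot(inherits(fit, "cebu"))
  aggregate <- match.arg(aggregate)
  ann <- fit$data$annotation
  if (!"significant" %in% names(prognosis)) {
    prognosis$significant <- prognosis$adjusted_p < 0.1
  }
  rows <- list(); skipped <- list()
  for (ca in unique(prognosis$cancer_type)) {
    tissue <- tissue_map$tissue[match(ca, tissue_map$cancer_type)]
    cells <- ann$cell_line[ann$tissue_type %in% tissue]
    pr <- prognosis[prognosis$cancer_type == ca, , drop = FALSE]
    if (is.na(tissue) || length(cells) == 0L) {
      skipped[[ca]] <- "no matched tissue"
      next
    }
    n_pos_table <- sum(pr$cox_sign > 0 & pr$significant)
    if (n_pos_table < min_positives) {
      skipped[[ca]] <- sprintf("fewer than %d positive genes (%d)",
                               min_positives, n_pos_table)
      next
    }
    for (ct in cutoffs) {
      recs <- fit$records[fit$records$c_score >= ct, , drop = FALSE]
      recs <- recs[recs$g2 %in% pr$gene, , drop = FALSE]
      if (nrow(recs) == 0L) next
      caps <- buffering_capacity(fit, pairs = recs, cell_lines = cells,
                                 percentile = percentile)
      per_pair <- aggregate_mean(caps)
      fun <- if (aggregate == "max") max else mean
      gene_score <- tapply(per_pair$capacity, per_pair$g2, fun)
      genes <- intersect(names(gene_score), pr$gene)
      lab <- pr$cox_sign[match(genes, pr$gene)] > 0 &
        pr$significant[match(genes, pr$gene)]
      if (sum(lab) == 0L || sum(!lab) == 0L) next
      ra <- roc_auc(unname(gene_score[genes]), lab)
      rows[[length(rows) + 1L]] <- data.frame(
        cancer_type = ca, cutoff = ct, auc = ra$auc, p = ra$p,
        n_pos = ra$n_pos, n_neg = ra$n_neg, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cancer_type = character(0), cutoff = numeric(0),
               auc = numeric(0), p = numeric(0), n_pos = integer(0),
               n_neg = integer(0))
  out$q <- if (nrow(out)) p.adjust(out$p, method = "BH") else numeric(0)
  attr(out, "skipped") <- skipped
  out
}

# mean capacity per (g1, g2) pair over the evaluated cell lines
aggregate_mean <- function(caps) {
  agg <- aggregate(caps$capacity,
                   by = list(g1 = caps$g1, g2 = caps$g2), FUN = mean)
  names(agg)[3L] <- "capacity"
  agg
}
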