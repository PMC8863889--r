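# Tissue context: tissue-specificity tau, normalized dependency-expression
# plots, the nine angular regions R1-R9, and region x tissue enrichment.

#' Tissue-specificity index tau
#'
#' Cell lines are grouped by tissue and each gene's expression is averaged
#' per tissue; tissue means below `floor_at` log2 TPM are set to 0, and
#' \deqn{\tau = \sum_i (1 - x_i/x_{max}) / (N - 1)} over the `N` tissue
#' means.  `tau = 0` for uniform expression, `1` for single-tissue
#' expression; genes whose thresholded means are all 0 get `NA` (undefined).
#'
#' @param expression gene x cell-line matrix (log2 TPM).
#' @param annotation data.frame with `cell_line`, `tissue_type`.
#' @param floor_at tissue means below this are treated as 0.
#' @return data.frame with `gene`, `tau`, `n_tissues`, `x_max`, plus the
#'   thresholded tissue-mean matrix as attribute `tissue_means`.
#' @export
compute_tau <- function(expression, annotation, floor_at = 1) {
  stopifnot(is.matrix(expression))
  ann <- annotation[match(colnames(expression), annotation$cell_line), ]
  if (anyNA(ann$tissue_type)) stop("cell line(s) missing tissue annotation")
  tissues <- sort(unique(ann$tissue_type))
  if (length(tissues) < 2L) stop("tau requires at least 2 tissues (N - 1 > 0)")
  means <- vapply(tissues, function(tt) {
    rowMeans(expression[, ann$tissue_type == tt, drop = FALSE])
  }, numeric(nrow(expression)))
  means <- matrix(means, nrow = nrow(expression),
                  dimnames = list(rownames(expression), tissues))
  means[means < floor_at] <- 0
  x_max <- apply(means, 1L, max)
  tau <- ifelse(x_max > 0,
                rowSums(1 - means / ifelse(x_max > 0, x_max, 1)) /
                  (length(tissues) - 1),
                NA_real_)
  out <- data.frame(gene = rownames(expression), tau = tau,
                    n_tissues = length(tissues), x_max = x_max,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "tissue_means") <- means
  out
}

#' Paired contrast of G1 versus G2 tissue specificity
#'
#' Paired t-test of tau(G2) - tau(G1) over high C-score pairs; a positive
#' mean difference says buffering genes are more tissue-specific than the
#' genes they buffer.
#'
#' @param tau_g1,tau_g2 paired numeric vectors (same pairs, same order).
#' @return list with `mean_diff`, `t`, `p`, `n`.
#' @export
tau_contrast <- function(tau_g1, tau_g2) {
  if (length(tau_g1) != length(tau_g2)) stop("paired vectors differ in length")
  ok <- is.finite(tau_g1) & is.finite(tau_g2)
  d <- tau_g2[ok] - tau_g1[ok]
  if (length(d) < 2L) stop("need at least 2 complete pairs")
  if (sd(d) <= 1e-10 * max(abs(d), 1)) {
    # degenerate paired test: identical differences
    return(list(mean_diff = mean(d),
                t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else 0, n = length(d)))
  }
  tt <- t.test(tau_g2[ok], tau_g1[ok], paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       p = tt$p.value, n = length(d))
}

#' Tissue-specificity contrast against a shuffled-expression control
#'
#' For each distinct buffering gene among the supplied pairs, tau is
#' recomputed after permuting that gene's expression across cell lines
#' (destroying any tissue structure while preserving the expression
#' multiset) and the real tau is contrasted against the shuffled control
#' with [tau_contrast()].  A positive mean difference says the buffering
#' genes' expression is more tissue-structured than chance.
#'
#' @param fit a [cebu()] object.
#' @param pairs data.frame with a `g2` column (e.g. high C-score records).
#' @param tau optional precomputed [compute_tau()] table.
#' @param seed seed for the permutations.
#' @return list as from [tau_contrast()].
#' @export
shuffled_tau_contrast <- function(fit, pairs, tau = NULL, seed = 1L) {
  stopifnot(inherits(fit, "cebu"))
  set.seed(seed)
  g2s <- unique(pairs$g2)
  if (is.null(tau)) tau <- compute_tau(fit$data$expression,
                                       fit$data$annotation)
  expr <- fit$data$expression[g2s, , drop = FALSE]
  perm <- t(apply(expr, 1L, sample))
  colnames(perm) <- colnames(expr)
  tau_perm <- compute_tau(perm, fit$data$annotation)
  tau_contrast(tau_perm$tau, tau$tau[match(g2s, tau$gene)])
}

#' Rank-normalize a pair's profiles onto the unit square
#'
#' Dependency scores are rank-mapped onto \[-1, 0\] (most negative score,
#' i.e. strongest essentiality, maps to -1) and expression onto \[0, 1\]
#' (highest expression maps to 1); ties get average ranks.
#'
#' @param g1_profile dependency vector across cell lines.
#' @param g2_profile expression vector across the same cell lines.
#' @return data.frame with `cell_line`, `x_norm`, `y_norm`.
#' @export
normalize_pair_plot <- function(g1_profile, g2_profile) {
  n <- length(g1_profile)
  if (length(g2_profile) != n) stop("profiles have different lengths")
  if (length(unique(g1_profile)) < 2L || length(unique(g2_profile)) < 2L) {
    stop("constant profile cannot be rank-normalized")
  }
  x_norm <- -(n - rank(g1_profile, ties.method = "average")) / (n - 1)
  y_norm <- (rank(g2_profile, ties.method = "average") - 1) / (n - 1)
  data.frame(cell_line = if (!is.null(names(g1_profile))) names(g1_profile)
             else seq_len(n),
             x_norm = x_norm, y_norm = y_norm,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign normalized points to the nine angular regions
#'
#' The normalized quadrant (x in \[-1, 0\], y in \[0, 1\]) is divided into
#' nine equal 10-degree sectors radiating from the origin; the angle is
#' measured from the positive-y (expression) axis toward the negative-x
#' (dependency) axis, so R1 abuts the expression axis and R9 the dependency
#' axis.  Boundary angles (exact multiples of 10 degrees) go to the
#' lower-index region; the origin returns `NA`.
#'
#' @param x_norm,y_norm numeric vectors in \[-1, 0\] and \[0, 1\].
#' @param boundary_tol angles within this many degrees above a sector
#'   boundary are treated as on the boundary (absorbs floating-point jitter
#'   in the angle computation).
#' @return integer vector of regions 1..9 (`NA` for origin points).
#' @export
assign_region <- function(x_norm, y_norm, boundary_tol = 1e-9) {
  stopifnot(length(x_norm) == length(y_norm))
  if (any(x_norm < -1 | x_norm > 0 | y_norm < 0 | y_norm > 1, na.rm = TRUE)) {
    stop("points outside the normalized quadrant")
  }
  theta <- atan2(-x_norm, y_norm) * 180 / pi
  reg <- pmax(1L, as.integer(ceiling(theta / 10 - boundary_tol)))
  reg[x_norm == 0 & y_norm == 0] <- NA_integer_
  reg
}

#' Region x tissue enrichment of high C-score pairs
#'
#' For every pair at or above the cutoff, each cell line is placed in a
#' region of the pair's normalized plot; for each (pair, region, tissue) a
#' hypergeometric test asks whether that tissue's cell lines are
#' over-represented among the cell lines falling in the region (universe =
#' all cell lines).  Within each region, p-values are Benjamini-Hochberg
#' adjusted across pairs and tissues, and a (pair, tissue) event is
#' "enriched" at adjusted p below `p_adj`.  The returned table gives, per
#' region, each tissue's percentage share of enriched events (each region's
#' shares sum to 100 where any event exists).
#'
#' @param fit a [cebu()] object.
#' @param cutoff C-score cutoff selecting pairs.
#' @param p_adj BH-adjusted significance level per region.
#' @param min_cells tissues with fewer cell lines are excluded (warning).
#' @param max_pairs optional cap on the number of top pairs analyzed.
#' @return list with `share` (9 x tissues percentage matrix), `counts`
#'   (enriched events per region x tissue) and `n_pairs`.
#' @export
region_tissue_enrichment <- function(fit, cutoff, p_adj = 0.05,
                                     min_cells = 3L, max_pairs = Inf) {
  stopifnot(inherits(fit, "cebu"))
  ann <- fit$data$annotation
  tab <- table(ann$tissue_type)
  small <- names(tab)[tab < min_cells]
  if (length(small)) {
    warning("tissue(s) with fewer than ", min_cells, " cell lines excluded: ",
            paste(small, collapse = ", "))
  }
  tissues <- sort(names(tab)[tab >= min_cells])
  pairs <- fit$records[fit$records$c_score >= cutoff, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no pairs at or above the cutoff")
  if (nrow(pairs) > max_pairs) pairs <- head(pairs, max_pairs)

  n_cells <- fit$n_cells
  tissue_of <- ann$tissue_type[match(colnames(fit$data$dependency),
                                     ann$cell_line)]
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    np <- normalize_pair_plot(fit$data$dependency[pairs$g1[i], ],
                              fit$data$expression[pairs$g2[i], ])
    reg <- assign_region(np$x_norm, np$y_norm)
    rows <- list()
    for (r in unique(reg[!is.na(reg)])) {
      in_r <- !is.na(reg) & reg == r
      for (tt in tissues) {
        k <- sum(in_r & tissue_of == tt)
        p <- phyper(k - 1L, tab[[tt]], n_cells - tab[[tt]], sum(in_r),
                    lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          pair = i, region = r, tissue = tt, k = k, p = p)
      }
    }
    res[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, res)
  res$p_adj <- NA_real_
  for (r in unique(res$region)) {
    sel <- res$region == r
    res$p_adj[sel] <- p.adjust(res$p[sel], method = "BH")
  }
  res$enriched <- res$p_adj < p_adj

  counts <- matrix(0L, nrow = 9L, ncol = length(tissues),
                   dimnames = list(paste0("R", 1:9), tissues))
  agg <- res[res$enriched, , drop = FALSE]
  if (nrow(agg)) {
    t2 <- table(factor(agg$region, levels = 1:9),
                factor(agg$tissue, levels = tissues))
    counts[] <- as.integer(t2)
  }
  share <- counts
  tot <- rowSums(counts)
  for (r in seq_len(9L)) {
    share[r, ] <- if (tot[r] > 0) 100 * counts[r, ] / tot[r] else 0
  }
  list(share = share, counts = counts, n_pairs = nrow(pairs), detail = res)
}
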