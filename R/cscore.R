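# C-score engine: candidate filtering, per-pair regression, slope_min,
# genome-wide C-scores.  The screen regresses G2 expression (y) on G1
# dependency (x): shallow slopes mean near-flat expression against a wide
# dependency range, and slope_min (the shallowest significantly positive
# slope in the pair universe) rescales each pair's slope so that
# flat-expression buffering pairs are up-weighted.

#' Filter candidate buffered (G1) and buffering (G2) genes
#'
#' G1 candidates are dependency genes whose mean dependency score is
#' negative (knockout slows proliferation on average); genes with mean
#' score > 0, or exactly 0, are discarded.  G2 candidates are expression
#' genes with mean expression >= `min_expression` log2 TPM.
#'
#' @param data a `cebu_data` from [align_datasets()] or [sim_cebu()].
#' @param min_expression minimum mean log2 TPM for G2 candidates.
#' @return list with character vectors `g1` and `g2`.
#' @export
filter_candidates <- function(data, min_expression = 0.5) {
  stopifnot(inherits(data, "cebu_data"))
  g1 <- rownames(data$dependency)[rowMeans(data$dependency) < 0]
  g2 <- rownames(data$expression)[rowMeans(data$expression) >= min_expression]
  if (length(g1) == 0L) stop("no G1 candidates: all mean dependency scores >= 0")
  if (length(g2) == 0L) stop("no G2 candidates: all mean expressions below threshold")
  list(g1 = g1, g2 = g2)
}

#' Per-pair regression of expression on dependency
#'
#' @param x G1 dependency profile across cell lines.
#' @param y G2 expression profile across the same cell lines.
#' @return list with `rho` (Pearson correlation), `slope` and `intercept`
#'   (least-squares fit of `y ~ x`), `se_slope`, `p_rho` (two-sided
#'   correlation test) and `n`.
#' @export
pair_regression <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("profiles have different lengths")
  if (n < 3L) stop("need at least 3 cell lines")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("zero-variance profile: correlation undefined")
  cxy <- stats::cov(x, y)
  rho <- cxy / sqrt(vx * vy)
  slope <- cxy / vx
  tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), n - 2)
  se <- sqrt(vy * max(1 - rho^2, 0) / ((n - 2) * vx))
  list(rho = rho, slope = slope, intercept = mean(y) - slope * mean(x),
       se_slope = se, p_rho = p, n = n)
}

#' Minimum slope among significantly positively correlated pairs
#'
#' @param slope,rho,p parallel numeric vectors over the considered pairs.
#' @param alpha significance level on the unadjusted two-sided correlation p.
#' @return the minimum qualifying slope.
#' @export
compute_slope_min <- function(slope, rho, p, alpha = 0.05) {
  ok <- is.finite(slope) & rho > 0 & p < alpha
  if (!any(ok)) stop("no pair with a significant positive correlation; slope_min undefined")
  min(slope[ok])
}

#' The C-score index
#'
#' `rho * (1 + b * slope_min / slope)`.  With `b = 0` this is the Pearson
#' correlation; for the pair attaining `slope_min` (with positive rho) it is
#' `rho * (1 + b)`.
#'
#' @param rho Pearson correlation of G1 dependency with G2 expression.
#' @param slope expression-on-dependency regression slope (non-zero).
#' @param slope_min minimum qualifying slope of the pair universe.
#' @param b slope weight; 1 for a pan-cell/pan-cancer analysis.
#' @return numeric C-score(s).
#' @export
compute_cscore <- function(rho, slope, slope_min, b = 1) {
  if (any(slope == 0)) stop("slope = 0: C-score undefined")
  rho * (1 + b * slope_min / slope)
}

# blockwise pair statistics against pre-scaled expression; returns rho and
# slope matrices for a block of G1 rows
.block_stats <- function(dep_block, exprs_scaled, sd_dep, sd_expr, n) {
  dep_scaled <- (dep_block - rowMeans(dep_block)) / sd_dep
  rho <- tcrossprod(dep_scaled, exprs_scaled) / (n - 1)
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  slope <- rho * outer(1 / sd_dep, sd_expr)
  list(rho = rho, slope = slope)
}

#' Fit the C-score screen on an aligned panel
#'
#' Computes C-scores for every candidate G1 x G2 pair (self-pairs excluded),
#' streaming over blocks of G1 genes: a first pass establishes `slope_min`
#' over the whole pair universe, a second pass scores pairs and materializes
#' those with `c_score >= threshold`.
#'
#' @param data a `cebu_data` from [align_datasets()] or `sim_cebu()$data`.
#' @param b slope weight in the C-score (default 1).
#' @param alpha significance level for the `slope_min` qualifying set.
#' @param threshold report threshold: only pairs with `c_score >= threshold`
#'   are kept in `records` (`-Inf` keeps every pair).
#' @param slope_min optionally override the fitted minimum slope (e.g. to
#'   score new pairs on an existing calibration).
#' @param min_expression G2 candidate filter, see [filter_candidates()].
#' @param block_size G1 rows per block.
#' @return An object of class `cebu`: list with `records` (data.frame
#'   `g1, g2, rho, slope, c_score`), `slope_min`, `b`, `alpha`, `threshold`,
#'   `n_cells`, `n_pairs`, candidate gene sets, per-gene summary statistics
#'   and the aligned data (for downstream null/capacity computations).
#' @seealso [cebu_null()], [cebu_significance()], [buffering_capacity()]
#' @export
cebu <- function(data, b = 1, alpha = 0.05, threshold = 0.25,
                 slope_min = NULL, min_expression = 0.5, block_size = 2000L) {
  stopifnot(inherits(data, "cebu_data"))
  cand <- filter_candidates(data, min_expression)
  dep <- data$dependency[cand$g1, , drop = FALSE]
  expr <- data$expression[cand$g2, , drop = FALSE]
  n <- ncol(dep)
  if (n < 3L) stop("need at least 3 cell lines")

  sd_dep <- apply(dep, 1L, sd)
  sd_expr <- apply(expr, 1L, sd)
  if (any(sd_dep == 0)) stop("zero-variance dependency profile(s): ",
                             paste(head(cand$g1[sd_dep == 0], 3L), collapse = ", "))
  if (any(sd_expr == 0)) stop("zero-variance expression profile(s): ",
                              paste(head(cand$g2[sd_expr == 0], 3L), collapse = ", "))
  exprs_scaled <- (expr - rowMeans(expr)) / sd_expr
  blocks <- split(seq_along(cand$g1),
                  ceiling(seq_along(cand$g1) / block_size))

  # pass 1: slope_min over the full pair universe (self-pairs excluded)
  if (is.null(slope_min)) {
    smin <- Inf
    any_qual <- FALSE
    for (idx in blocks) {
      st <- .block_stats(dep[idx, , drop = FALSE], exprs_scaled,
                         sd_dep[idx], sd_expr, n)
      tval <- st$rho * sqrt((n - 2) / pmax(1 - st$rho^2, .Machine$double.eps))
      p <- 2 * pt(-abs(tval), n - 2)
      qual <- st$rho > 0 & p < alpha
      self <- outer(cand$g1[idx], cand$g2, "==")
      qual[self] <- FALSE
      if (any(qual)) {
        any_qual <- TRUE
        smin <- min(smin, min(st$slope[qual]))
      }
    }
    if (!any_qual) stop("no pair with a significant positive correlation; slope_min undefined")
    slope_min <- smin
  }

  # pass 2: C-scores, materialize records above threshold
  recs <- vector("list", length(blocks))
  n_pairs <- 0L
  for (k in seq_along(blocks)) {
    idx <- blocks[[k]]
    st <- .block_stats(dep[idx, , drop = FALSE], exprs_scaled,
                       sd_dep[idx], sd_expr, n)
    cs <- st$rho * (1 + b * slope_min / st$slope)
    self <- outer(cand$g1[idx], cand$g2, "==")
    cs[self] <- NA_real_
    n_pairs <- n_pairs + sum(!self)
    keep <- which(!is.na(cs) & cs >= threshold, arr.ind = TRUE)
    if (nrow(keep)) {
      recs[[k]] <- data.frame(
        g1 = cand$g1[idx][keep[, 1L]],
        g2 = cand$g2[keep[, 2L]],
        rho = st$rho[keep],
        slope = st$slope[keep],
        c_score = cs[keep],
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) {
    records <- data.frame(g1 = character(0), g2 = character(0),
                          rho = numeric(0), slope = numeric(0),
                          c_score = numeric(0))
  }
  records <- records[order(-records$c_score), , drop = FALSE]
  rownames(records) <- NULL

  structure(list(records = records, slope_min = slope_min, b = b,
                 alpha = alpha, threshold = threshold,
                 n_cells = n, n_pairs = n_pairs,
                 g1 = cand$g1, g2 = cand$g2,
                 sd_dep = sd_dep, sd_expr = sd_expr,
                 data = data, call = match.call()),
            class = "cebu")
}

#' Score an arbitrary set of gene pairs under a fitted screen
#'
#' Returns the full pair statistics (rho, slope, C-score with the fit's
#' `slope_min` and `b`) for given (g1, g2) pairs, whether or not they passed
#' the report threshold.  Pairs outside the candidate universe get `NA`.
#'
#' @param fit a [cebu()] object.
#' @param g1,g2 character vectors (recycled to equal length).
#' @return data.frame `g1, g2, rho, slope, c_score`.
#' @export
score_pairs <- function(fit, g1, g2) {
  stopifnot(inherits(fit, "cebu"))
  k <- max(length(g1), length(g2))
  g1 <- rep_len(g1, k); g2 <- rep_len(g2, k)
  out <- data.frame(g1 = g1, g2 = g2, rho = NA_real_, slope = NA_real_,
                    c_score = NA_real_, stringsAsFactors = FALSE)
  ok <- g1 %in% fit$g1 & g2 %in% fit$g2 & g1 != g2
  for (i in which(ok)) {
    pr <- pair_regression(fit$data$dependency[g1[i], ],
                          fit$data$expression[g2[i], ])
    out$rho[i] <- pr$rho
    out$slope[i] <- pr$slope
    out$c_score[i] <- compute_cscore(pr$rho, pr$slope, fit$slope_min, fit$b)
  }
  out
}

#' @export
print.cebu <- function(x, ...) {
  cat("C-score screen\n")
  cat(sprintf("  %d G1 x %d G2 candidates, %d cell lines, %d pairs scored\n",
              length(x$g1), length(x$g2), x$n_cells, x$n_pairs))
  cat(sprintf("  slope_min = %.5g, b = %g, report threshold = %g\n",
              x$slope_min, x$b, x$threshold))
  cat(sprintf("  %d pair(s) at c_score >= %g\n", nrow(x$records), x$threshold))
  invisible(x)
}

#' @export
summary.cebu <- function(object, n_top = 10L, ...) {
  out <- list(fit = object,
              top = head(object$records, n_top),
              frac_above = nrow(object$records) / max(object$n_pairs, 1L))
  class(out) <- "summary.cebu"
  out
}

#' @export
print.summary.cebu <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  fraction of universe above threshold: %.3g%%\n",
              100 * x$frac_above))
  if (nrow(x$top)) {
    cat("  top pairs:\n")
    print(x$top, digits = 3)
  }
  invisible(x)
}

#' @export
coef.cebu <- function(object, ...) {
  setNames(object$records$c_score,
           paste(object$records$g1, object$records$g2, sep = ":"))
}

#' Plot method for a C-score screen
#'
#' With `pair` given, draws the dependency-expression scatter for one gene
#' pair (the "C-score plot": G1 dependency on x, G2 expression on y) with its
#' regression line; otherwise a histogram of all materialized C-scores.
#'
#' @param x a [cebu()] object.
#' @param pair optional `c(g1, g2)`.
#' @param ... passed to the underlying plot.
#' @export
plot.cebu <- function(x, pair = NULL, ...) {
  if (is.null(pair)) {
    graphics::hist(x$records$c_score, breaks = 50,
                   main = "C-score distribution",
                   xlab = "C-score", ...)
    return(invisible(x))
  }
  xs <- x$data$dependency[pair[1L], ]
  ys <- x$data$expression[pair[2L], ]
  pr <- pair_regression(xs, ys)
  graphics::plot(xs, ys, xlab = paste(pair[1L], "dependency score"),
                 ylab = paste(pair[2L], "expression (log2 TPM)"),
                 main = sprintf("%s:%s  rho=%.2f slope=%.3g", pair[1L],
                                pair[2L], pr$rho, pr$slope), ...)
  graphics::abline(pr$intercept, pr$slope, col = "red3")
  invisible(x)
}
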