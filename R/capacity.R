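# Cell-specific buffering capacity, Bliss independence synergy, and
# exponential growth-rate fitting.

#' Cell-specific buffering capacity
#'
#' For a scored pair and cell line,
#' `capacity = (expression - q)/slope_mod` with `q` the `percentile`-th
#' percentile of the G2 gene's expression over all cell lines and
#' `slope_mod = c_score * sd(G2 expression)/sd(G1 dependency)` (sample
#' standard deviations over all aligned cell lines; percentiles use linear
#' interpolation between order statistics).  Capacity is 0 at the reference
#' percentile and increases with the cell line's G2 expression when
#' `slope_mod > 0`.
#'
#' @param fit a [cebu()] object.
#' @param pairs data.frame with `g1`, `g2` (and optionally `c_score`);
#'   default: the fit's materialized records.
#' @param cell_lines cell lines to evaluate (default all).
#' @param percentile reference expression percentile (default 25).
#' @return data.frame with one row per pair x cell line: `g1, g2,
#'   cell_line, expression, q_ref, slope_mod, capacity`.
#' @export
buffering_capacity <- function(fit, pairs = NULL, cell_lines = NULL,
                               percentile = 25) {
  stopifnot(inherits(fit, "cebu"))
  if (is.null(pairs)) pairs <- fit$records
  if (is.null(pairs$c_score)) {
    pairs <- merge(pairs[c("g1", "g2")], fit$records[c("g1", "g2", "c_score")],
                   by = c("g1", "g2"), sort = FALSE)
  }
  if (is.null(cell_lines)) cell_lines <- colnames(fit$data$dependency)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    e_all <- fit$data$expression[pairs$g2[i], ]
    d_all <- fit$data$dependency[pairs$g1[i], ]
    cs <- pairs$c_score[i]
    if (is.na(cs) || cs == 0) stop("c_score missing or zero for pair ",
                                   pairs$g1[i], ":", pairs$g2[i])
    slope_mod <- cs * sd(e_all) / sd(d_all)
    if (slope_mod == 0) stop("slope_mod = 0 for pair ",
                             pairs$g1[i], ":", pairs$g2[i])
    q_ref <- unname(quantile(e_all, percentile / 100, type = 7))
    out[[i]] <- data.frame(
      g1 = pairs$g1[i], g2 = pairs$g2[i], cell_line = cell_lines,
      expression = unname(e_all[cell_lines]), q_ref = q_ref,
      slope_mod = slope_mod,
      capacity = unname((e_all[cell_lines] - q_ref) / slope_mod),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean buffering capacity per tissue
#'
#' Averages capacity records over all (pair, cell line) observations whose
#' cell line belongs to each tissue.
#'
#' @param capacities data.frame from [buffering_capacity()].
#' @param annotation data.frame with `cell_line`, `tissue_type`.
#' @return data.frame `tissue_type, mean_capacity, n`, sorted by decreasing
#'   mean capacity.
#' @export
tissue_mean_capacity <- function(capacities, annotation) {
  tt <- annotation$tissue_type[match(capacities$cell_line,
                                     annotation$cell_line)]
  if (anyNA(tt)) stop("capacity record(s) with unannotated cell line")
  agg <- aggregate(capacities$capacity, by = list(tissue_type = tt),
                   FUN = mean)
  names(agg)[2L] <- "mean_capacity"
  agg$n <- as.integer(table(tt)[agg$tissue_type])
  agg[order(-agg$mean_capacity), , drop = FALSE]
}

#' Bliss independence score
#'
#' `(e_a + e_b - e_a*e_b) / e_ab`, the ratio of the Bliss-expected combined
#' effect to the observed combined effect, where effects are relative cell
#' growth (fold-change of confluence) under suppression of gene A, gene B,
#' or both.  Values below 1 flag potential synergy.
#'
#' @param e_a,e_b relative growth under single suppression.
#' @param e_ab relative growth under combined suppression (non-zero).
#' @return numeric Bliss score(s).
#' @export
bliss_score <- function(e_a, e_b, e_ab) {
  if (any(e_ab == 0)) stop("e_ab = 0: Bliss ratio undefined")
  (e_a + e_b - e_a * e_b) / e_ab
}

#' Fit an exponential growth rate to confluence measurements
#'
#' Least-squares fit of `log(confluence) ~ time`; the rate is the slope per
#' hour and the fold-change is the fitted ratio over the observation window.
#'
#' @param times hours (length >= 3).
#' @param confluence positive confluence values (percent).
#' @return list with `rate` (per hour), `fold_change` (fitted, over the
#'   window), `log_intercept` and `n`.
#' @export
fit_growth_rate <- function(times, confluence) {
  if (length(times) != length(confluence)) stop("lengths differ")
  if (length(times) < 3L) stop("need at least 3 time points")
  if (any(confluence <= 0)) stop("confluence must be positive")
  fitted <- lm(log(confluence) ~ times)
  rate <- unname(coef(fitted)[2L])
  list(rate = rate,
       fold_change = exp(rate * (max(times) - min(times))),
       log_intercept = unname(coef(fitted)[1L]),
       n = length(times))
}
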