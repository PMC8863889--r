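# Shuffled-expression null calibration and significance.

#' Shuffled-expression null model for C-scores
#'
#' For each shuffle, every G2 expression profile is independently permuted
#' across cell lines (preserving each gene's expression multiset while
#' destroying its pairing with dependency), the full pair universe is
#' re-scored with the real-data `slope_min`, and a normal distribution is
#' fitted to the pooled shuffled C-scores.
#'
#' @param fit a [cebu()] object.
#' @param n_shuffles number of shuffled expression datasets (default 5).
#' @param seed integer seed for the permutations.
#' @param block_size G1 rows per block.
#' @return An object of class `cebu_null`: `mu`, `sigma` (pooled normal
#'   fit), `per_shuffle` (data.frame of per-shuffle mean/sd), `n_shuffles`,
#'   `n_scores`, `seed`.
#' @export
cebu_null <- function(fit, n_shuffles = 5L, seed = 1L, block_size = 2000L) {
  stopifnot(inherits(fit, "cebu"), n_shuffles >= 1L)
  set.seed(seed)
  dep <- fit$data$dependency[fit$g1, , drop = FALSE]
  expr <- fit$data$expression[fit$g2, , drop = FALSE]
  n <- ncol(dep)
  sd_dep <- fit$sd_dep
  blocks <- split(seq_along(fit$g1), ceiling(seq_along(fit$g1) / block_size))

  per <- data.frame(shuffle = seq_len(n_shuffles), mu = NA_real_, sigma = NA_real_)
  tot_s <- 0; tot_ss <- 0; tot_n <- 0
  for (s in seq_len(n_shuffles)) {
    perm <- t(apply(expr, 1L, sample))
    sd_perm <- fit$sd_expr  # permutation preserves each gene's sd
    perm_scaled <- (perm - rowMeans(perm)) / sd_perm
    s_sum <- 0; s_ss <- 0; s_n <- 0
    for (idx in blocks) {
      st <- .block_stats(dep[idx, , drop = FALSE], perm_scaled,
                         sd_dep[idx], sd_perm, n)
      cs <- st$rho * (1 + fit$b * fit$slope_min / st$slope)
      cs[outer(fit$g1[idx], fit$g2, "==")] <- NA_real_
      cs <- cs[!is.na(cs)]
      s_sum <- s_sum + sum(cs); s_ss <- s_ss + sum(cs^2); s_n <- s_n + length(cs)
    }
    per$mu[s] <- s_sum / s_n
    per$sigma[s] <- sqrt((s_ss - s_sum^2 / s_n) / (s_n - 1))
    tot_s <- tot_s + s_sum; tot_ss <- tot_ss + s_ss; tot_n <- tot_n + s_n
  }
  mu <- tot_s / tot_n
  sigma <- sqrt((tot_ss - tot_s^2 / tot_n) / (tot_n - 1))
  if (!is.finite(sigma) || sigma <= 0) stop("degenerate null: sigma <= 0")
  structure(list(mu = mu, sigma = sigma, per_shuffle = per,
                 n_shuffles = n_shuffles, n_scores = tot_n, seed = seed),
            class = "cebu_null")
}

#' @export
print.cebu_null <- function(x, ...) {
  cat(sprintf("Shuffled-expression C-score null: normal(mu = %.4g, sigma = %.4g)\n",
              x$mu, x$sigma))
  cat(sprintf("  %d shuffle(s), %d scores pooled, seed %d\n",
              x$n_shuffles, x$n_scores, x$seed))
  invisible(x)
}

#' Upper-tail p-values of C-scores under a fitted null
#'
#' @param c_score numeric vector.
#' @param null a [cebu_null()] object.
#' @return numeric vector of upper-tail normal probabilities.
#' @export
cscore_pvalues <- function(c_score, null) {
  stopifnot(inherits(null, "cebu_null"))
  if (null$sigma <= 0) stop("null sigma must be positive")
  pnorm(c_score, mean = null$mu, sd = null$sigma, lower.tail = FALSE)
}

#' Attach p- and q-values to a fitted screen
#'
#' p is the upper-tail probability of each materialized C-score under the
#' shuffled null; q applies Benjamini-Hochberg over the evaluated pair
#' universe.  When the screen kept only pairs above its report threshold
#' (which are exactly the smallest p-values, since p is monotone decreasing
#' in C-score), the step-up uses the full universe size `m = n_pairs`, which
#' is conservative for the retained tail.
#'
#' @param fit a [cebu()] object.
#' @param null a [cebu_null()] object.
#' @return `fit` with `records$p`, `records$q` and `null` attached.
#' @export
cebu_significance <- function(fit, null) {
  stopifnot(inherits(fit, "cebu"))
  p <- cscore_pvalues(fit$records$c_score, null)
  if (is.finite(fit$threshold) && fit$n_pairs > nrow(fit$records)) {
    q <- bh_adjust(p, m = fit$n_pairs)
  } else {
    q <- p.adjust(p, method = "BH")
  }
  fit$records$p <- p
  fit$records$q <- q
  fit$null <- null
  fit
}

#' Benjamini-Hochberg adjustment with an explicit universe size
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) * m / j` computed over the
#' supplied p-values, with the total number of tests `m` allowed to exceed
#' `length(p)` (the remaining tests are assumed to have larger p-values, as
#' holds when `p` is the lower tail of a thresholded screen).
#'
#' @param p numeric vector of the smallest `length(p)` p-values.
#' @param m total number of tests (`>= length(p)`).
#' @return adjusted q-values, capped at 1, in the input order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  stopifnot(m >= length(p))
  o <- order(p)
  ro <- order(o)
  q <- pmin(1, cummin(rev(p[o] * m / seq_along(p))))
  rev(q)[ro]
}
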