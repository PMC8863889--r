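test_that("candidate filtering keeps essential G1s and expressed G2s", {
  data <- toy_data()
  cand <- filter_candidates(data)
  expect_identical(cand$g1, c("d1", "d2"))   # d3 has positive mean score
  expect_identical(cand$g2, c("e1", "e2"))   # e3 mean expression < 0.5
  # boundary: mean exactly zero is excluded
  data$dependency["d3", ] <- c(-1, 1, -2, 2)
  expect_identical(filter_candidates(data)$g1, c("d1", "d2"))
})

test_that("pair regression matches exact lines and an lm/cor.test oracle", {
  pr <- pair_regression(c(-3, -2, -1), c(1, 2, 3))
  expect_equal(pr$rho, 1, tolerance = 1e-12)
  expect_equal(pr$slope, 1, tolerance = 1e-12)
  pr <- pair_regression(c(-3, -2, -1), c(3, 2, 1))
  expect_equal(pr$rho, -1, tolerance = 1e-12)
  expect_equal(pr$slope, -1, tolerance = 1e-12)

  x <- c(-0.9, -0.5, -0.2, -0.1); y <- c(2.0, 3.1, 3.9, 4.2)
  pr <- pair_regression(x, y)
  fit <- lm(y ~ x)
  ct <- cor.test(x, y)
  expect_equal(pr$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(pr$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
  expect_equal(pr$se_slope, summary(fit)$coefficients[2, 2], tolerance = 1e-12)
  expect_equal(pr$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pr$p_rho, ct$p.value, tolerance = 1e-12)

  expect_error(pair_regression(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pair_regression(1:2, 1:2), "at least 3")
})

test_that("slope_min filters on significant positive correlation", {
  slopes <- c(0.2, 0.05, -0.1)
  rhos <- c(0.8, 0.3, -0.9)
  ps <- c(0.01, 0.2, 0.001)
  expect_equal(compute_slope_min(slopes, rhos, ps), 0.2)
  expect_equal(compute_slope_min(0.5, 0.9, 0.01), 0.5)
  expect_error(compute_slope_min(0.5, -0.9, 0.01), "slope_min undefined")
})

test_that("the C-score formula reproduces its worked arithmetic", {
  expect_equal(compute_cscore(0.5, 0.1, 0.1, b = 1), 1.0)
  expect_equal(compute_cscore(0.6, 0.37, 0.02, b = 0), 0.6)
  expect_equal(compute_cscore(0.5, 0.2, 0.1, b = 1), 0.75)
  expect_error(compute_cscore(0.5, 0, 0.1), "slope = 0")
})

test_that("C-score is strictly decreasing in slope for positive rho and b", {
  slopes <- seq(0.01, 2, length.out = 50)
  cs <- compute_cscore(0.5, slopes, 0.01, b = 1)
  expect_true(all(diff(cs) < 0))
})

test_that("the screen excludes self-pairs and matches per-pair recomputation", {
  set.seed(55)
  dep <- matrix(rnorm(5 * 30), 5, 30,
                dimnames = list(paste0("g", 1:5), paste0("CL", 1:30)))
  dep <- dep - 1
  expr <- matrix(abs(rnorm(6 * 30)) + 1, 6, 30,
                 dimnames = list(paste0("g", c(1:3, 7:9)), paste0("CL", 1:30)))
  # ensure a significantly positive pair exists so slope_min is defined
  expr["g7", ] <- pmax(3 + 0.5 * dep["g4", ] + rnorm(30, 0, 0.2), 0)
  ann <- data.frame(cell_line = paste0("CL", 1:30), tissue_type = "t1")
  fit <- cebu(align_datasets(dep, expr, ann), threshold = -Inf)
  expect_equal(fit$n_pairs, 5L * 6L - 3L)  # g1..g3 shared => self-pairs out
  expect_false(any(fit$records$g1 == fit$records$g2))
  # every record agrees with a direct pair regression + formula evaluation
  for (i in sample(nrow(fit$records), 10)) {
    r <- fit$records[i, ]
    pr <- pair_regression(dep[r$g1, ], expr[r$g2, ])
    expect_equal(r$rho, pr$rho, tolerance = 1e-12)
    expect_equal(r$slope, pr$slope, tolerance = 1e-12)
    expect_equal(r$c_score,
                 compute_cscore(pr$rho, pr$slope, fit$slope_min, fit$b),
                 tolerance = 1e-12)
  }
  # slope_min agrees with a brute-force enumeration over all pairs
  all_slopes <- c(); all_rhos <- c(); all_ps <- c()
  for (a in rownames(dep)) for (b in rownames(expr)) {
    if (a == b) next
    pr <- pair_regression(dep[a, ], expr[b, ])
    all_slopes <- c(all_slopes, pr$slope)
    all_rhos <- c(all_rhos, pr$rho)
    all_ps <- c(all_ps, pr$p_rho)
  }
  expect_equal(fit$slope_min,
               compute_slope_min(all_slopes, all_rhos, all_ps, fit$alpha),
               tolerance = 1e-12)
})

test_that("with b = 0 the screen collapses to a Pearson correlation screen", {
  fit <- cebu(small_sim()$data, b = 0, threshold = -Inf)
  expect_equal(fit$records$c_score, fit$records$rho, tolerance = 1e-12)
})

test_that("the screen is directional: swapping roles changes C-scores", {
  # both genes carry a dependency and an expression profile; the pair's
  # C-score depends on which gene plays the buffered (G1) role
  set.seed(21)
  n <- 40L
  dep <- rbind(a = rnorm(n, -1, 0.3), b = rnorm(n, -1, 1.2))
  expr <- rbind(a = pmax(3 + 0.2 * dep["b", ] + rnorm(n, 0, 0.1), 0),
                b = pmax(3 + 0.8 * dep["a", ] + rnorm(n, 0, 0.1), 0))
  colnames(dep) <- colnames(expr) <- paste0("CL", seq_len(n))
  ann <- data.frame(cell_line = colnames(dep), tissue_type = "t1")
  fit <- cebu(align_datasets(dep, expr, ann), threshold = -Inf)
  ab <- fit$records[fit$records$g1 == "a" & fit$records$g2 == "b", ]
  ba <- fit$records[fit$records$g1 == "b" & fit$records$g2 == "a", ]
  expect_equal(nrow(ab), 1L)
  expect_equal(nrow(ba), 1L)
  expect_false(isTRUE(all.equal(ab$c_score, ba$c_score)))
})

test_that("planted pairs occupy the top ranks of the screen", {
  sim <- small_sim()
  fit <- small_fit()
  keys <- pair_key(sim$truth$planted$g1, sim$truth$planted$g2)
  rks <- match(keys, pair_key(fit$records$g1, fit$records$g2))
  expect_lte(stats::median(rks), nrow(sim$truth$planted))
})

test_that("blockwise streaming is invariant to block size", {
  sim <- small_sim()
  f1 <- cebu(sim$data, threshold = 0.1, block_size = 3L)
  f2 <- cebu(sim$data, threshold = 0.1, block_size = 1000L)
  expect_equal(f1$records, f2$records, tolerance = 1e-14)
  expect_equal(f1$slope_min, f2$slope_min, tolerance = 1e-14)
})

test_that("score_pairs returns the same statistics as the screen records", {
  fit <- small_fit()
  r <- fit$records[3, ]
  sp <- score_pairs(fit, r$g1, r$g2)
  expect_equal(sp$c_score, r$c_score, tolerance = 1e-12)
  expect_true(is.na(score_pairs(fit, "nope", r$g2)$c_score))
})
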