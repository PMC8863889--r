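test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_cell_lines = 40L, n_g1 = 5L, n_g2 = 20L,
                    n_planted_pairs = 3L, n_flat_genes = 1L, seed = 11L)
  a <- sim_cebu(cfg)
  b <- sim_cebu(cfg)
  expect_identical(a$data$dependency, b$data$dependency)
  expect_identical(a$data$expression, b$data$expression)
  expect_identical(a$truth$planted, b$truth$planted)
})

test_that("noiseless planted pairs are perfectly correlated", {
  cfg <- sim_config(n_cell_lines = 40L, n_g1 = 5L, n_g2 = 20L,
                    n_planted_pairs = 3L, n_flat_genes = 0L,
                    dependency_noise_sd = 0, expression_noise_sd = 0,
                    tissue_effect_sd = 1, seed = 5L)
  sim <- sim_cebu(cfg)
  for (i in seq_len(3L)) {
    pr <- pair_regression(sim$data$dependency[sim$truth$planted$g1[i], ],
                          sim$data$expression[sim$truth$planted$g2[i], ])
    expect_equal(pr$rho, 1, tolerance = 1e-12)
    expect_equal(pr$slope, cfg$planted_slope, tolerance = 1e-9)
  }
})

test_that("degenerate zero-variance configurations are rejected", {
  expect_error(sim_config(expression_noise_sd = 0, tissue_effect_sd = 0),
               "degenerate")
  expect_error(sim_config(n_planted_pairs = 100L, n_g1 = 10L))
})

test_that("expression respects the log2(TPM+1) floor and planted pairs exist", {
  sim <- small_sim()
  expect_true(all(sim$data$expression >= 0))
  expect_true(all(sim$truth$planted$g1 %in% rownames(sim$data$dependency)))
  expect_true(all(sim$truth$planted$g2 %in% rownames(sim$data$expression)))
})

test_that("planted slope is recovered within OLS sampling error", {
  # 20 seeds x 10 planted pairs at the reference noise levels; the OLS
  # sampling distribution says ~99.7% of fits land within 3 SE of truth
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    sim <- sim_cebu(sim_config(n_cell_lines = 200L, n_g1 = 10L, n_g2 = 40L,
                               n_planted_pairs = 10L, n_flat_genes = 1L,
                               seed = 1000L + s))
    for (i in seq_len(10L)) {
      pr <- pair_regression(sim$data$dependency[sim$truth$planted$g1[i], ],
                            sim$data$expression[sim$truth$planted$g2[i], ])
      hits <- hits + (abs(pr$slope - 0.01) <= 3 * pr$se_slope)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("empirical planted correlation matches its closed form", {
  # rho = sd(E) / sqrt(var(E) + slope^2 * sd_noise^2), from the conditional
  # generative model D = a + (E - mean(E))/slope + eps
  sim <- small_sim()
  cfg <- sim$truth$config
  for (i in c(1L, 5L, 10L)) {
    e <- sim$data$expression[sim$truth$planted$g2[i], ]
    d <- sim$data$dependency[sim$truth$planted$g1[i], ]
    expected <- sd(e) / sqrt(var(e) + cfg$planted_slope^2 *
                               cfg$dependency_noise_sd^2)
    expect_equal(cor(d, e), expected, tolerance = 0.05)
  }
})

test_that("shuffling expression destroys planted correlations", {
  sim <- sim_cebu(sim_config(n_cell_lines = 200L, n_g1 = 20L, n_g2 = 60L,
                             n_planted_pairs = 20L, seed = 9L))
  set.seed(1)
  rhos <- vapply(seq_len(20L), function(i) {
    e <- sample(sim$data$expression[sim$truth$planted$g2[i], ])
    cor(sim$data$dependency[sim$truth$planted$g1[i], ], e)
  }, 0)
  expect_lt(mean(abs(rhos)), 0.1)
})

test_that("ground-truth emission honours the duplicated fraction bounds", {
  sim <- small_sim()
  all_dup <- sim_ground_truths(sim, fraction_duplicated = 1)
  expect_equal(nrow(all_dup$duplicated), nrow(sim$truth$planted))
  none <- sim_ground_truths(sim, fraction_duplicated = 0)
  expect_equal(nrow(none$duplicated), 0L)
})

test_that("background GI scores are centred on zero", {
  set.seed(3)
  draws <- rnorm(10000, 0, 0.1)  # the stated background GI distribution
  expect_lt(abs(mean(draws)), 0.05)
  sim <- small_sim()
  tr <- sim_ground_truths(sim, n_background_gi_pairs = 20L)
  keys <- pair_key(sim$truth$planted$g1, sim$truth$planted$g2)
  bg <- tr$gi[!pair_key(tr$gi$gene_a, tr$gi$gene_b) %in% keys, ]
  expect_lt(abs(mean(bg$score)), 0.05)
  # planted rows are negative in their high-expression lines
  pl <- tr$gi[pair_key(tr$gi$gene_a, tr$gi$gene_b) %in% keys, ]
  expect_gt(mean(pl$score < 0), 0.98)
})

test_that("a bundle written to disk reloads into the same aligned panel", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  paths <- write_sim_bundle(sim, sim_ground_truths(sim), dir)
  dep <- read_matrix(paths[["dependency"]], "dependency")
  expr <- read_matrix(paths[["expression"]], "expression")
  ann <- read_cell_annotation(paths[["annotation"]])
  al <- align_datasets(dep, expr, ann)
  expect_equal(al$dependency, sim$data$dependency, tolerance = 1e-12)
  expect_equal(al$expression, sim$data$expression, tolerance = 1e-12)
})
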