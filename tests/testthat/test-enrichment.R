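test_that("hypergeometric enrichment agrees with exhaustive enumeration", {
  # N=10 pairs, K=4 annotated, n=5 above cutoff, k=4 hits: p = 6/252
  expect_equal(phyper(4 - 1, 4, 6, 5, lower.tail = FALSE), 6 / 252,
               tolerance = 1e-12)
  # all N <= 12 configurations against the enumeration oracle
  set.seed(2)
  for (i in 1:25) {
    N <- sample(4:12, 1); K <- sample(1:(N - 1), 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 enum_hyper_upper(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("duplicated-pair enrichment runs against the fitted screen", {
  sim <- small_sim(); fit <- small_fit()
  tr <- sim_ground_truths(sim, fraction_duplicated = 1)
  dup <- duplicated_enrichment(fit, tr$duplicated, cutoff = 0.5)
  expect_equal(dup$e_a, nrow(sim$truth$planted))
  expect_lt(dup$p, 1e-6)   # planted pairs are all above the cutoff
  # full draw: n = N => k = K, p = 1
  full <- duplicated_enrichment(fit, tr$duplicated, cutoff = min(fit$records$c_score))
  expect_equal(full$e_c, fit$n_pairs)
  expect_equal(full$e_ac, full$e_a)
  expect_equal(full$p, 1, tolerance = 1e-12)
})

test_that("log-enrichment evaluates its formula and is symmetric in labels", {
  # direct formula evaluation via a hand-built fit stub
  stub <- structure(list(
    records = data.frame(g1 = c("a", "a", "b"), g2 = c("x", "y", "x"),
                         c_score = c(0.9, 0.4, 0.1)),
    g1 = c("a", "b"), g2 = c("x", "y"), n_pairs = 4L, threshold = -Inf),
    class = "cebu")
  ann <- data.frame(gene_a = "x", gene_b = "a")  # reversed labels
  e <- pair_set_enrichment(stub, ann, cutoff = 0.5)
  # e_ac = 1 (a-x), e_a = 1, e_c = 1, e_t = 4 -> log2((1/1)/(1/4)) = 2
  expect_equal(e$enrichment, 2, tolerance = 1e-12)
  ann2 <- data.frame(gene_a = "a", gene_b = "x")
  expect_equal(pair_set_enrichment(stub, ann2, 0.5)$enrichment,
               e$enrichment, tolerance = 1e-12)
  # ratio arithmetic: e_ac=10, e_a=100, e_c=1000, e_t=100000 -> log2(10)
  expect_equal(log((10 / 100) / (1000 / 100000), base = 2), log2(10),
               tolerance = 1e-12)
  # doubling e_ac adds exactly one bit
  e1 <- log((10 / 100) / (1000 / 1e5), 2)
  e2 <- log((20 / 100) / (1000 / 1e5), 2)
  expect_equal(e2 - e1, 1, tolerance = 1e-12)
})

test_that("enrichment of planted pairs increases with the C-score cutoff", {
  sim <- default_sim(); fit <- default_fit()
  annotated <- data.frame(gene_a = sim$truth$planted$g1,
                          gene_b = sim$truth$planted$g2)
  curve <- enrichment_curve(fit, annotated, c(0.05, 0.1, 0.15, 0.2, 0.25))
  expect_true(all(diff(curve$enrichment) > 0))
  # single cutoff consistency
  single <- enrichment_curve(fit, annotated, 0.15)
  expect_equal(single$enrichment,
               pair_set_enrichment(fit, annotated, 0.15)$enrichment)
})

test_that("annotation independent of the score gives a flat curve near zero", {
  fit <- default_fit()
  set.seed(13)
  annotated <- data.frame(gene_a = sample(fit$g1, 400, replace = TRUE),
                          gene_b = sample(fit$g2, 400, replace = TRUE))
  annotated <- annotated[annotated$gene_a != annotated$gene_b, ]
  curve <- enrichment_curve(fit, annotated, c(0.05, 0.15, 0.25))
  # Monte-Carlo spread of log2 enrichment with e_ac ~ Binom: sd ~ 1/sqrt(e_ac)
  mc_sd <- 1.45 / sqrt(pmax(curve$e_ac, 1))
  expect_true(all(abs(curve$enrichment) < 4 * mc_sd + 0.2))
})

test_that("network construction classifies nodes and conserves edges", {
  stub <- structure(list(
    records = data.frame(g1 = c("a", "b", "a"), g2 = c("x", "x", "y"),
                         c_score = c(0.9, 0.8, 0.7))),
    class = "cebu")
  net <- build_network(stub, cutoff = 0.5)
  expect_equal(igraph::vcount(net$graph), 4)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_identical(unname(net$node_class[c("x", "y")]),
                   c("buffering", "buffering"))
  expect_identical(unname(net$node_class[c("a", "b")]),
                   c("buffered", "buffered"))
  # a gene appearing on both sides is classed "both"
  stub$records <- rbind(stub$records,
                        data.frame(g1 = "x", g2 = "y", c_score = 0.6))
  net2 <- build_network(stub, 0.5)
  expect_identical(unname(net2$node_class["x"]), "both")
  # edge conservation at an arbitrary cutoff on a real fit
  fit <- small_fit()
  net3 <- build_network(fit, 0.3)
  expect_equal(igraph::ecount(net3$graph),
               sum(fit$records$c_score >= 0.3))
})

test_that("network export writes SIF and GraphML", {
  fit <- small_fit()
  net <- build_network(fit, 0.5)
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, sif, "sif")
  expect_equal(length(readLines(sif)), igraph::ecount(net$graph))
  write_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), igraph::ecount(net$graph))
})
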