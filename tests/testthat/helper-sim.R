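# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

# small planted panel + fit: 80 cells, 20 x 60 genes, 10 planted pairs
small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- sim_cebu(sim_config(
      n_cell_lines = 80L, n_tissues = 4L, n_g1 = 20L, n_g2 = 60L,
      n_planted_pairs = 10L, n_flat_genes = 2L, seed = 42L))
  }
  .fixtures$sim
}

small_fit <- function() {
  if (is.null(.fixtures$fit)) {
    .fixtures$fit <- cebu(small_sim()$data, threshold = -Inf)
  }
  .fixtures$fit
}

# default-scale panel (the reference study conditions) and its fit
default_sim <- function() {
  if (is.null(.fixtures$dsim)) .fixtures$dsim <- sim_cebu(sim_config(seed = 7L))
  .fixtures$dsim
}

default_fit <- function() {
  if (is.null(.fixtures$dfit)) {
    .fixtures$dfit <- cebu(default_sim()$data, threshold = 0.05)
  }
  .fixtures$dfit
}

# tiny hand-buildable aligned dataset
toy_data <- function() {
  dep <- matrix(c(-3, -2, -1, -0.5,
                  -1, -1.5, -0.2, -0.8,
                  0.5, 0.2, 0.1, 0.4), nrow = 3, byrow = TRUE,
                dimnames = list(c("d1", "d2", "d3"),
                                c("A", "B", "C", "D")))
  expr <- matrix(c(1, 2, 3, 3.5,
                   4, 3, 5, 4.2,
                   0.1, 0.2, 0.1, 0.3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("e1", "e2", "e3"),
                                 c("A", "B", "C", "D")))
  ann <- data.frame(cell_line = c("A", "B", "C", "D"),
                    tissue_type = c("t1", "t1", "t2", "t2"),
                    stringsAsFactors = FALSE)
  align_datasets(dep, expr, ann)
}

# a minimal hand-built screen whose statistics are fully known
capacity_stub <- function(e, d, c_score = 0.5) {
  cells <- paste0("CL", seq_along(e))
  structure(list(
    records = data.frame(g1 = "d", g2 = "e", c_score = c_score),
    data = list(dependency = matrix(d, 1, dimnames = list("d", cells)),
                expression = matrix(e, 1, dimnames = list("e", cells)))),
    class = "cebu")
}

# trapezoidal ROC integration, an oracle independent of the rank formula
trapezoid_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!labels] >= t), 0), 1)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# exhaustive hypergeometric upper tail by enumerating all draws (N <= 12)
enum_hyper_upper <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}
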