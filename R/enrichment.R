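# Pair-annotation enrichment: duplicated-pair hypergeometric test,
# annotation/PPI log-enrichment ratio, and the directed buffering network.

#' Enrichment counts for an annotated pair set at a C-score cutoff
#'
#' @param fit a [cebu()] object whose `records` cover the cutoff (fit with
#'   `threshold <= cutoff`).
#' @param annotated pair data.frame (unordered membership; see
#'   [read_pair_table()]).
#' @param cutoff C-score cutoff defining "buffering" pairs.
#' @return list with `e_ac` (annotated and buffering), `e_a` (annotated
#'   pairs within the scored universe), `e_c` (buffering pairs), `e_t`
#'   (total pair universe, self-pairs excluded).
#' @export
enrichment_counts <- function(fit, annotated, cutoff) {
  stopifnot(inherits(fit, "cebu"))
  if (cutoff < fit$threshold) {
    stop("cutoff below the fit's report threshold; refit with a lower threshold")
  }
  keys <- unique(if (!is.null(annotated$key)) annotated$key
                 else pair_key(annotated$gene_a, annotated$gene_b))
  # annotated pairs restricted to the scored universe
  in_universe <- function(a, b) {
    (a %in% fit$g1 & b %in% fit$g2) | (b %in% fit$g1 & a %in% fit$g2)
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  e_a <- if (length(keys)) sum(in_universe(parts[, 1L], parts[, 2L]) &
                               parts[, 1L] != parts[, 2L]) else 0L
  buf <- fit$records[fit$records$c_score >= cutoff, , drop = FALSE]
  e_c <- nrow(buf)
  e_ac <- if (e_c) sum(pair_key(buf$g1, buf$g2) %in% keys) else 0L
  list(e_ac = e_ac, e_a = e_a, e_c = e_c, e_t = fit$n_pairs)
}

#' Hypergeometric enrichment of duplicated pairs above a C-score cutoff
#'
#' Upper-tail probability of observing at least `e_ac` duplicated pairs
#' among the `e_c` pairs above the cutoff, drawing from a universe of `e_t`
#' pairs that contains `e_a` duplicated pairs.
#'
#' @inheritParams enrichment_counts
#' @param duplicated duplicated-pair data.frame.
#' @return list with the counts and `p` (hypergeometric upper tail).
#' @export
duplicated_enrichment <- function(fit, duplicated, cutoff) {
  ct <- enrichment_counts(fit, duplicated, cutoff)
  if (ct$e_a == 0L) stop("no duplicated pairs in the scored universe")
  ct$p <- phyper(ct$e_ac - 1L, ct$e_a, ct$e_t - ct$e_a, ct$e_c,
                 lower.tail = FALSE)
  ct
}

#' Log-ratio enrichment of an annotated pair set above a C-score cutoff
#'
#' `log((e_ac / e_a) / (e_c / e_t))` in the given log base (default 2).
#' Annotation membership is symmetric in (g1, g2).  `e_ac = 0` yields
#' `-Inf` with the counts attached.
#'
#' @inheritParams enrichment_counts
#' @param log_base base of the logarithm.
#' @return list with the counts and `enrichment`.
#' @export
pair_set_enrichment <- function(fit, annotated, cutoff, log_base = 2) {
  ct <- enrichment_counts(fit, annotated, cutoff)
  if (ct$e_a == 0L) stop("no annotated pairs in the scored universe")
  if (ct$e_c == 0L) stop("no buffering pairs at this cutoff")
  ct$enrichment <- log((ct$e_ac / ct$e_a) / (ct$e_c / ct$e_t), base = log_base)
  ct
}

#' Enrichment across an ascending ladder of C-score cutoffs
#'
#' @inheritParams pair_set_enrichment
#' @param cutoffs ascending numeric vector of cutoffs.
#' @return data.frame with one row per cutoff: counts and `enrichment`.
#' @export
enrichment_curve <- function(fit, annotated, cutoffs, log_base = 2) {
  stopifnot(!is.unsorted(cutoffs))
  do.call(rbind, lapply(cutoffs, function(ct) {
    e <- pair_set_enrichment(fit, annotated, ct, log_base)
    data.frame(cutoff = ct, e_ac = e$e_ac, e_a = e$e_a, e_c = e$e_c,
               e_t = e$e_t, enrichment = e$enrichment)
  }))
}

#' Directed buffering gene network
#'
#' One directed edge g2 -> g1 per pair at or above the cutoff.  Nodes are
#' classed `buffered` (appear only as G1), `buffering` (only as G2) or
#' `both`.
#'
#' @inheritParams enrichment_counts
#' @param cutoff C-score cutoff for edge inclusion.
#' @return object of class `cebu_network`: list with `graph` (igraph),
#'   `node_class` (named character) and `edges` (the contributing records).
#' @export
build_network <- function(fit, cutoff) {
  stopifnot(inherits(fit, "cebu"))
  edges <- fit$records[fit$records$c_score >= cutoff, , drop = FALSE]
  if (nrow(edges) == 0L) {
    warning("no pairs at or above the cutoff; empty network")
    g <- igraph::make_empty_graph(directed = TRUE)
    return(structure(list(graph = g, node_class = character(0),
                          edges = edges, cutoff = cutoff),
                     class = "cebu_network"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$g2, to = edges$g1, c_score = edges$c_score),
    directed = TRUE)
  as_g1 <- unique(edges$g1)
  as_g2 <- unique(edges$g2)
  nodes <- igraph::V(g)$name
  cls <- ifelse(nodes %in% as_g1 & nodes %in% as_g2, "both",
                ifelse(nodes %in% as_g1, "buffered", "buffering"))
  names(cls) <- nodes
  igraph::V(g)$class <- unname(cls)
  structure(list(graph = g, node_class = cls, edges = edges, cutoff = cutoff),
            class = "cebu_network")
}

#' @export
print.cebu_network <- function(x, ...) {
  tab <- table(factor(x$node_class,
                      levels = c("buffered", "buffering", "both")))
  cat(sprintf("Buffering network (C-score >= %g): %d nodes, %d edges\n",
              x$cutoff, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  cat(sprintf("  buffered-only %d, buffering-only %d, both %d\n",
              tab[["buffered"]], tab[["buffering"]], tab[["both"]]))
  invisible(x)
}

#' Export a buffering network
#'
#' SIF lines are `g2 buffers g1`; GraphML export preserves edge C-scores
#' and node classes.
#'
#' @param network a [build_network()] result.
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- if (nrow(network$edges))
      sprintf("%s\tbuffers\t%s", network$edges$g2, network$edges$g1)
    else character(0)
    writeLines(lines, path)
  } else {
    igraph::write_graph(network$graph, path, format = "graphml")
  }
  invisible(path)
}
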