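#' Build a protein-complex hierarchy DAG end to end
#'
#' Runs the full pipeline: read/accept evidence and PPI tables, group
#' equivalent evidences into initial complex nodes, calibrate the corpus
#' floor c (weighted median of complexes per protein), the PPI pseudocount
#' kappa (median degree) and the walk damping alpha (so the mean walk time
#' equals `target_time`), compute the scheme's protein weights, merge
#' near-identical nodes by agglomerative clustering at tolerance `epsilon`,
#' verify acyclicity of the resulting part-of graph, filter nodes with
#' participation ratio below `pr_threshold`, classify the kept nodes and
#' decompose them into connected components.
#'
#' Scheme codes follow the weighting used: `"P"` support weights, `"A"`
#' adjusted weights, `"N4"` information-flow weights with the mean walk time
#' set by `target_time` (default 4 steps), and `"Z"` the baseline (support
#' weights with epsilon forced to 0, whose nodes are exactly the
#' non-redundant complexes).
#'
#' @param evidence an `evidence_table` (see [read_complex_evidence()]) or a
#'   path to a canonical evidence TSV.
#' @param ppi a pair data frame (see [read_ppi_pairs()]), a path, or NULL
#'   when no direct-interaction data is used (schemes `"P"`, `"A"`, `"Z"`).
#' @param scheme weighting scheme, one of `"N4"`, `"A"`, `"P"`, `"Z"`.
#' @param epsilon embedding tolerance (default 0.15: about one mismatching
#'   protein in seven); ignored (forced 0) for scheme `"Z"`.
#' @param target_time mean random-walk steps before termination for `"N4"`
#'   (default 4).
#' @param min_size minimum distinct proteins per evidence record (default 4).
#' @param pr_threshold participation-ratio filter cutoff (default 2.5).
#' @return a `complex_hierarchy` object: list with node table `nodes`
#'   (`node_id`, `class`, `n_evidences`, `n_members`, `participation_ratio`,
#'   `total_weight`, `component_id`), kept `edges` and pre-filter
#'   `edges_prefilter` (`from`, `to`, `d_forward`, `d_backward`), the merge
#'   `trace`, calibration `params`, per-node weight matrices (`support`,
#'   `adjusted`, `flow` when applicable), member sets, constituent
#'   non-redundant ids, and the final `corpus`.
#' @examples
#' truth <- generate_truth(synth_params(n_complexes = 8, n_proteins = 120),
#'                         seed = 1)
#' ev <- sample_evidence_corpus(truth, seed = 1)
#' ppi <- sample_ppi(truth, seed = 1)
#' h <- build_hierarchy(ev, ppi, scheme = "N4")
#' h
#' score_recovery(h, truth)[c("edge_precision", "edge_recall")]
#' @export
build_hierarchy <- function(evidence, ppi = NULL,
                            scheme = c("N4", "A", "P", "Z"),
                            epsilon = 0.15, target_time = 4, min_size = 4,
                            pr_threshold = 2.5) {
  scheme <- match.arg(scheme)
  if (is.character(evidence)) evidence <- read_complex_evidence(evidence)
  if (is.character(ppi)) ppi <- read_ppi_pairs(ppi)
  corpus <- group_evidences(evidence, min_size = min_size)
  if (length(corpus$nodes) == 0L) {
    stop("no evidence records with at least ", min_size, " proteins")
  }
  stats0 <- corpus_stats(corpus)
  net <- NULL
  alpha <- 0
  kappa <- NA_integer_
  if (!is.null(ppi) && nrow(ppi) > 0L) {
    net <- build_ppi_network(ppi, proteins = corpus$proteins)
    kappa <- net$kappa
  }
  if (scheme == "N4") {
    if (is.null(net)) {
      stop("scheme N4 needs a non-empty PPI table to calibrate alpha; ",
           "use scheme A to run without direct-interaction data")
    }
    alpha <- solve_alpha(target_time, net)
  }
  eps_use <- if (scheme == "Z") 0 else epsilon
  cl <- iterative_clustering(corpus, scheme = scheme, epsilon = eps_use,
                             net = net, alpha = alpha,
                             floor_c = stats0$median_c)
  edges <- relationship_graph(distances = cl$distance, epsilon = eps_use)
  totals <- colSums(cl$weights)
  assert_acyclic(edges, totals)

  final <- cl$corpus
  stats_final <- structure(list(counts = rowSums(cl$support),
                                total_mass = sum(cl$support),
                                median_c = cl$floor_c),
                           class = "corpus_stats")
  adjusted <- adjusted_weights(final, stats_final, support = cl$support)
  flow <- if (scheme == "N4")
    flow_weights(final, net, alpha, stats_final, support = cl$support)
  else NULL

  ids <- vapply(final$nodes, `[[`, character(1), "id")
  members <- lapply(seq_along(final$nodes), function(g) {
    rownames(cl$support)[cl$support[, g] > 0]
  })
  names(members) <- ids
  constituents <- lapply(final$nodes, `[[`, "constituents")
  names(constituents) <- ids

  h <- structure(list(
    scheme = scheme,
    params = list(scheme = scheme, epsilon = eps_use,
                  target_time = if (scheme == "N4") target_time else NA_real_,
                  min_size = min_size, pr_threshold = pr_threshold,
                  c = stats0$median_c, kappa = kappa, alpha = alpha,
                  n_ppi_proteins = if (is.null(net)) 0L else
                    length(net$ppi_proteins),
                  downweighted_fraction =
                    mean(stats0$counts > stats0$median_c)),
    corpus = final,
    members = members,
    constituents = constituents,
    support = cl$support,
    adjusted = adjusted,
    flow = flow,
    weights = cl$weights,
    totals = totals,
    trace = cl$trace,
    edges_prefilter = edges,
    pr_threshold = pr_threshold
  ), class = "complex_hierarchy")
  finalize_hierarchy(h)
}

# Apply the participation-ratio filter, classify kept nodes and assign
# components; idempotent so the filter threshold can be changed afterwards.
finalize_hierarchy <- function(h) {
  ids <- names(h$members)
  pr <- vapply(seq_along(ids), function(g) participation_ratio(h$weights[, g]),
               numeric(1))
  names(pr) <- ids
  filtered <- ids[pr < h$pr_threshold]
  kept <- setdiff(ids, filtered)
  edges <- h$edges_prefilter
  edges <- edges[edges$from %in% kept & edges$to %in% kept, , drop = FALSE]
  rownames(edges) <- NULL
  h$edges <- edges
  cls <- as.character(classify_nodes(kept, edges))
  names(cls) <- kept
  n_ev <- vapply(h$corpus$nodes, function(nd) length(nd$ev), integer(1))
  names(n_ev) <- vapply(h$corpus$nodes, `[[`, character(1), "id")
  nodes <- data.frame(
    node_id = ids,
    class = ifelse(ids %in% filtered, "filtered", cls[ids]),
    n_evidences = as.integer(n_ev[ids]),
    n_members = lengths(h$members[ids]),
    participation_ratio = pr[ids],
    total_weight = h$totals[ids],
    stringsAsFactors = FALSE)
  comp <- hierarchy_components(structure(list(edges = edges),
                                         class = "complex_hierarchy"))
  nodes$component_id <- comp$component_id[match(nodes$node_id, comp$node_id)]
  rownames(nodes) <- NULL
  h$nodes <- nodes
  h
}

#' @export
print.complex_hierarchy <- function(x, ...) {
  p <- x$params
  cat(sprintf("complex_hierarchy (scheme %s, epsilon %.3g)\n", p$scheme,
              p$epsilon))
  cat(sprintf("  calibration: c = %.6g, kappa = %s, alpha = %.6g%s\n",
              p$c, format(p$kappa),
              p$alpha,
              if (!is.na(p$target_time))
                sprintf(" (mean walk time %g)", p$target_time) else ""))
  tab <- table(factor(x$nodes$class,
                      levels = c("filtered", "isolated", "minimum", "inner",
                                 "maximum")))
  cat(sprintf("  nodes: %d (%s)\n", nrow(x$nodes),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  edges: %d kept (%d before filtering); merges: %d\n",
              nrow(x$edges), nrow(x$edges_prefilter), nrow(x$trace)))
  n_comp <- length(unique(stats::na.omit(x$nodes$component_id)))
  cat(sprintf("  connected components: %d\n", n_comp))
  invisible(x)
}

#' Write hierarchy result tables and graph exports
#'
#' Writes, under `dir`: `nodes.tsv`, `edges.tsv` (kept edges with both
#' directed distances), `merge_trace.tsv`, `weights.tsv` (per node and
#' protein: support, adjusted and, when computed, flow weights),
#' `params.tsv`, plus `dag.dot`/`dag.graphml` for the full kept graph and
#' `dag_reduced.dot` for its transitive reduction (display form). Every
#' table starts with a `#` provenance header carrying the full parameter
#' set.
#'
#' @param hierarchy a `complex_hierarchy`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, dir) {
  stopifnot(inherits(hierarchy, "complex_hierarchy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- hierarchy$params
  stamp <- sprintf(
    "# complexHier %s | scheme=%s epsilon=%g target_time=%s min_size=%d pr_threshold=%g c=%g kappa=%s alpha=%g",
    as.character(utils::packageVersion("complexHier")),
    p$scheme, p$epsilon, format(p$target_time), p$min_size, p$pr_threshold,
    p$c, format(p$kappa), p$alpha)
  write_stamped <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  write_stamped(hierarchy$nodes, "nodes.tsv")
  write_stamped(hierarchy$edges, "edges.tsv")
  write_stamped(hierarchy$trace, "merge_trace.tsv")
  wdump <- weight_dump(hierarchy)
  write_stamped(wdump, "weights.tsv")
  params_df <- data.frame(parameter = names(p),
                          value = vapply(p, function(v) format(v, digits = 12),
                                         character(1)),
                          stringsAsFactors = FALSE)
  write_stamped(params_df, "params.tsv")
  g <- igraph::graph_from_data_frame(
    hierarchy$edges[, c("from", "to")],
    vertices = hierarchy$nodes$node_id[hierarchy$nodes$class != "filtered"],
    directed = TRUE)
  igraph::write_graph(g, file.path(dir, "dag.dot"), format = "dot")
  igraph::write_graph(g, file.path(dir, "dag.graphml"), format = "graphml")
  red <- transitive_reduction(hierarchy$edges)
  gr <- igraph::graph_from_data_frame(
    red[, c("from", "to")],
    vertices = hierarchy$nodes$node_id[hierarchy$nodes$class != "filtered"],
    directed = TRUE)
  igraph::write_graph(gr, file.path(dir, "dag_reduced.dot"), format = "dot")
  invisible(dir)
}

weight_dump <- function(hierarchy) {
  out <- list()
  ids <- colnames(hierarchy$support)
  for (g in seq_along(ids)) {
    m <- which(hierarchy$support[, g] > 0)
    out[[g]] <- data.frame(
      node_id = ids[[g]],
      protein = rownames(hierarchy$support)[m],
      w_support = hierarchy$support[m, g],
      w_adjusted = hierarchy$adjusted[m, g],
      w_flow = if (is.null(hierarchy$flow)) NA_real_ else hierarchy$flow[m, g],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
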