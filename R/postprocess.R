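#' Participation ratio (effective size) of a weight vector
#'
#' PR(w) = (sum w)^2 / sum w^2: the effective number of meaningfully
#' weighted members. Equals n for n equal weights and 1 when a single entry
#' dominates; always between 1 and the support size. A nominally large
#' complex dominated by one regular-weight bait plus down-weighted sticky
#' proteins has a small participation ratio and behaves like a binary
#' interaction rather than a complex.
#'
#' @param w numeric weight vector (zeros allowed; total must be positive).
#' @return the participation ratio.
#' @export
participation_ratio <- function(w) {
  w <- w[w != 0]
  if (length(w) == 0L || sum(w) <= 0) stop("weight vector with zero total")
  sum(w)^2 / sum(w^2)
}

#' Remove nodes with small effective size
#'
#' Drops, together with their incident edges, all nodes whose participation
#' ratio under the hierarchy's own weighting scheme is below `threshold`
#' (default 2.5, below which a node reflects binary interactions or a single
#' protein more than a complex). Filtered nodes are reported separately and
#' keep their merge history; classification and component analysis operate
#' on the kept graph.
#'
#' @param hierarchy a `complex_hierarchy` from [build_hierarchy()].
#' @param threshold participation-ratio cutoff.
#' @return the hierarchy with `nodes`, `edges`, classes and components
#'   recomputed under the new threshold.
#' @export
filter_by_effective_size <- function(hierarchy, threshold = 2.5) {
  stopifnot(inherits(hierarchy, "complex_hierarchy"))
  hierarchy$pr_threshold <- threshold
  finalize_hierarchy(hierarchy)
}

#' Classify DAG nodes by their incident part-of edges
#'
#' An edge X -> Y reads "X is approximately a part of Y", so maxima (only
#' incoming edges) are the largest assemblies, minima (only outgoing) the
#' smallest parts, inner nodes have both, and isolated nodes have neither.
#' Filtered nodes form their own class.
#'
#' @param node_ids character vector of kept node ids.
#' @param edges data frame with columns `from`, `to` restricted to kept
#'   nodes.
#' @return a factor, named by node id, with levels
#'   `isolated`, `minimum`, `inner`, `maximum`.
#' @export
classify_nodes <- function(node_ids, edges) {
  outdeg <- table(factor(edges$from, levels = node_ids))
  indeg <- table(factor(edges$to, levels = node_ids))
  cls <- ifelse(outdeg == 0 & indeg == 0, "isolated",
         ifelse(outdeg > 0 & indeg == 0, "minimum",
         ifelse(outdeg == 0 & indeg > 0, "maximum", "inner")))
  factor(stats::setNames(cls, node_ids),
         levels = c("isolated", "minimum", "inner", "maximum"))
}

#' Connected components of the undirected part-of relation
#'
#' Two nodes belong to one component when either is approximately a part of
#' the other, directly or through intermediates. Isolated nodes are reported
#' as a class of their own (see [classify_nodes()]) and excluded here, so
#' every component has at least two nodes.
#'
#' @param hierarchy a `complex_hierarchy`.
#' @return a data frame `node_id`, `component_id` for connected nodes, with
#'   components numbered by decreasing size (`K001` the largest).
#' @export
hierarchy_components <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "complex_hierarchy"))
  edges <- hierarchy$edges
  connected <- sort(unique(c(edges$from, edges$to)))
  if (length(connected) == 0L) {
    return(data.frame(node_id = character(0), component_id = character(0),
                      stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = connected, directed = FALSE)
  comp <- igraph::components(g)
  size_rank <- rank(-comp$csize, ties.method = "first")
  data.frame(node_id = names(comp$membership),
             component_id = sprintf("K%03d", size_rank[comp$membership]),
             stringsAsFactors = FALSE)
}

#' Subgraph of the hierarchy induced by one protein
#'
#' Returns the part of the DAG consisting of all kept nodes whose member set
#' contains the given protein, with node classes recomputed within the
#' subgraph. Filtered nodes containing the protein are reported separately.
#'
#' @param hierarchy a `complex_hierarchy`.
#' @param protein a protein identifier.
#' @return a list with `nodes` (subset of the hierarchy node table, classes
#'   local to the subgraph), `edges`, and `filtered` (ids of filtered nodes
#'   containing the protein). Unknown proteins yield an empty subgraph with
#'   a warning.
#' @export
protein_subgraph <- function(hierarchy, protein) {
  stopifnot(inherits(hierarchy, "complex_hierarchy"))
  has <- vapply(hierarchy$members, function(m) protein %in% m, logical(1))
  if (!any(has)) warning("protein ", protein, " occurs in no node")
  ids <- intersect(hierarchy$nodes$node_id[
    hierarchy$nodes$class != "filtered"], names(has)[has])
  edges <- hierarchy$edges
  edges <- edges[edges$from %in% ids & edges$to %in% ids, , drop = FALSE]
  nodes <- hierarchy$nodes[match(ids, hierarchy$nodes$node_id), , drop = FALSE]
  nodes$class <- as.character(classify_nodes(ids, edges))[match(ids, ids)]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges,
       filtered = intersect(hierarchy$nodes$node_id[
         hierarchy$nodes$class == "filtered"], names(has)[has]))
}

#' Transitive reduction of a DAG edge set
#'
#' Removes every edge that can be replaced by a directed path of two or more
#' remaining edges, giving the unique minimal edge set with the same
#' reachability. Intended for display and export only; all analyses operate
#' on the full edge set.
#'
#' @param edges data frame with columns `from`, `to` describing an acyclic
#'   graph.
#' @return the reduced edge data frame (other columns preserved).
#' @export
transitive_reduction <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  ids <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = ids, directed = TRUE)
  if (!igraph::is_dag(g)) stop("transitive reduction requires an acyclic graph")
  reach <- igraph::distances(g, mode = "out") < Inf  # includes self
  from_i <- match(edges$from, ids)
  to_i <- match(edges$to, ids)
  redundant <- vapply(seq_len(nrow(edges)), function(r) {
    # u -> v is redundant iff some other successor w of u reaches v
    succ <- setdiff(which(reach[from_i[[r]], ]),
                    c(from_i[[r]], to_i[[r]]))
    any(reach[succ, to_i[[r]]])
  }, logical(1))
  out <- edges[!redundant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand a hierarchy to edges over the non-redundant complex set
#'
#' Every merged node is expanded into its constituent non-redundant
#' complexes (the nodes obtained after step-0 merging of compositionally
#' identical evidences), linked pairwise in both directions
#' (`within_node`, k(k-1) ordered pairs for k constituents); every DAG edge
#' X -> Y is expanded into all ordered pairs between the constituents of X
#' and of Y (`between_nodes`). Expansion is computed on the pre-filter
#' graph; pairs whose source or destination node was filtered are labelled
#' `filtered`. This representation is independent of the weighting scheme
#' and is the common currency for comparing hierarchies.
#'
#' @param hierarchy a `complex_hierarchy`.
#' @return a data frame `from_nr`, `to_nr`, `provenance`.
#' @export
expand_edges <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "complex_hierarchy"))
  cons <- hierarchy$constituents
  filtered <- hierarchy$nodes$node_id[hierarchy$nodes$class == "filtered"]
  out <- list()
  for (id in names(cons)) {
    k <- length(cons[[id]])
    if (k < 2L) next
    pairs <- expand.grid(from_nr = cons[[id]], to_nr = cons[[id]],
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from_nr != pairs$to_nr, , drop = FALSE]
    pairs$provenance <- if (id %in% filtered) "filtered" else "within_node"
    out[[length(out) + 1L]] <- pairs
  }
  edges <- hierarchy$edges_prefilter
  for (r in seq_len(nrow(edges))) {
    pairs <- expand.grid(from_nr = cons[[edges$from[[r]]]],
                         to_nr = cons[[edges$to[[r]]]],
                         stringsAsFactors = FALSE)
    pairs$provenance <-
      if (edges$from[[r]] %in% filtered || edges$to[[r]] %in% filtered)
        "filtered" else "between_nodes"
    out[[length(out) + 1L]] <- pairs
  }
  if (length(out) == 0L) {
    return(data.frame(from_nr = character(0), to_nr = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$from_nr, res$to_nr), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare two hierarchies over their shared non-redundant complex set
#'
#' Hierarchies built from the same initial evidence corpus under different
#' weighting schemes contain different merged nodes and edges; they become
#' comparable after [expand_edges()] maps both onto ordered pairs of
#' non-redundant complexes. Reports the sizes of the intersection and the
#' two differences, optionally after removing a baseline edge set (typically
#' the Z scheme, whose edges are the composition-identical embeddings shared
#' by every scheme).
#'
#' @param a,b `complex_hierarchy` objects built from the same corpus.
#' @param baseline optional third hierarchy whose expanded edges are removed
#'   from both sides before comparison.
#' @param include_filtered keep expanded pairs with `filtered` provenance
#'   (default FALSE: compare the analysed graphs).
#' @return a list with counts `n_common`, `n_only_a`, `n_only_b` and the
#'   corresponding edge data frames.
#' @export
compare_dags <- function(a, b, baseline = NULL, include_filtered = FALSE) {
  stopifnot(inherits(a, "complex_hierarchy"), inherits(b, "complex_hierarchy"))
  if (!identical(a$corpus$signature, b$corpus$signature) ||
      !identical(sort(unique(unlist(a$constituents))),
                 sort(unique(unlist(b$constituents))))) {
    stop("hierarchies were not built from the same non-redundant complex set")
  }
  key <- function(h) {
    e <- expand_edges(h)
    if (!include_filtered) e <- e[e$provenance != "filtered", , drop = FALSE]
    unique(paste(e$from_nr, e$to_nr, sep = "\r"))
  }
  ka <- key(a); kb <- key(b)
  if (!is.null(baseline)) {
    kz <- key(baseline)
    ka <- setdiff(ka, kz)
    kb <- setdiff(kb, kz)
  }
  unkey <- function(k) {
    if (length(k) == 0L) {
      return(data.frame(from_nr = character(0), to_nr = character(0),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(k, "\r", fixed = TRUE)
    data.frame(from_nr = vapply(parts, `[`, character(1), 1L),
               to_nr = vapply(parts, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  }
  common <- intersect(ka, kb)
  list(n_common = length(common),
       n_only_a = length(setdiff(ka, kb)),
       n_only_b = length(setdiff(kb, ka)),
       common = unkey(sort(common)),
       only_a = unkey(sort(setdiff(ka, kb))),
       only_b = unkey(sort(setdiff(kb, ka))))
}
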