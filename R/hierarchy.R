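#' Weighted-overlap similarity of two complexes
#'
#' sigma(X, Y) = sum_i min(wX(i), wY(i)). For indicator weights this is the
#' size of the set intersection; in general it generalizes it to weighted
#' membership. Symmetric, and sigma(X, X) equals the total weight
#' (self-similarity) of X.
#'
#' @param wx,wy named numeric weight vectors (or unnamed vectors of equal
#'   length over the same index).
#' @return a single number in [0, min(sigma(X,X), sigma(Y,Y))].
#' @export
similarity <- function(wx, wy) {
  if (is.null(names(wx)) || is.null(names(wy))) {
    stopifnot(length(wx) == length(wy))
    return(sum(pmin(wx, wy)))
  }
  common <- intersect(names(wx), names(wy))
  if (length(common) == 0L) return(0)
  sum(pmin(wx[common], wy[common]))
}

#' Relative distance between complexes
#'
#' d(X -> Y) = 1 - sigma(X, Y) / sigma(X, X), the fraction of X's weight not
#' covered by Y. It lies in [0, 1], is asymmetric, does not satisfy the
#' triangle inequality, and is 0 exactly when Y dominates X entrywise
#' (X is a part of Y).
#'
#' @param wx,wy named numeric weight vectors; `wx` must have positive total.
#' @return a single number in [0, 1].
#' @export
relative_distance <- function(wx, wy) {
  tot <- sum(wx)
  if (!is.finite(tot) || tot <= 0) stop("weight vector with zero total")
  1 - similarity(wx, wy) / tot
}

#' Approximate part-of relationship graph
#'
#' Connects X -> Y whenever d(X -> Y) <= epsilon, i.e. all but a fraction
#' epsilon of X's weight is covered by Y. At epsilon = 0 this is the
#' dominance partial order and the graph is a transitively closed DAG; for
#' epsilon > 0 bidirectional pairs may occur before clustering has merged
#' near-identical nodes.
#'
#' @param weights proteins-by-nodes weight matrix (one column per complex),
#'   or a precomputed forward distance matrix via `distances`.
#' @param epsilon embedding tolerance in [0, 1).
#' @param distances optional precomputed forward distance matrix
#'   (`distances[i, j]` = d(i -> j)); overrides `weights`.
#' @return a data frame with columns `from`, `to`, `d_forward`, `d_backward`.
#' @export
relationship_graph <- function(weights = NULL, epsilon = 0.15,
                               distances = NULL) {
  if (is.null(distances)) distances <- distance_matrix(weights)
  ids <- rownames(distances)
  hit <- which(distances <= epsilon & row(distances) != col(distances),
               arr.ind = TRUE)
  out <- data.frame(from = ids[hit[, 1]], to = ids[hit[, 2]],
                    d_forward = distances[hit],
                    d_backward = distances[hit[, c(2, 1), drop = FALSE]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two complex nodes
#'
#' Replaces nodes X and Y by a single node associated with the union of
#' their evidence sets. The kept identifier is the lexicographically smaller
#' of the two. Evidence weights implicitly reset to uniform 1/|E| over the
#' union, which changes n(i) for every protein in the union; dependent
#' weights must be recomputed afterwards (as [iterative_clustering()] does).
#'
#' @param corpus a `complex_corpus`.
#' @param id_x,id_y distinct node identifiers.
#' @return the updated `complex_corpus`.
#' @export
merge_nodes <- function(corpus, id_x, id_y) {
  stopifnot(inherits(corpus, "complex_corpus"), id_x != id_y)
  ids <- vapply(corpus$nodes, `[[`, character(1), "id")
  ix <- match(id_x, ids); iy <- match(id_y, ids)
  if (is.na(ix) || is.na(iy)) stop("unknown node id")
  if (ids[[ix]] <= ids[[iy]]) { kept <- ix; gone <- iy }
  else { kept <- iy; gone <- ix }
  corpus$nodes[[kept]]$ev <- sort(union(corpus$nodes[[kept]]$ev,
                                        corpus$nodes[[gone]]$ev))
  corpus$nodes[[kept]]$constituents <-
    sort(union(corpus$nodes[[kept]]$constituents,
               corpus$nodes[[gone]]$constituents))
  corpus$nodes[[gone]] <- NULL
  corpus
}

#' Iterative agglomerative merging of near-identical complexes
#'
#' Resembles hierarchical agglomerative clustering under the symmetrized
#' distance d_sym = max(d(X -> Y), d(Y -> X)). Step 0 merges all nodes with
#' identical support weight vectors, yielding the non-redundant set. Then,
#' while any pair has d_sym <= epsilon, the closest pair (ties broken by the
#' lexicographically smallest id pair) is replaced by the union of its
#' evidences; evidence weights, occurrence counts n(i) and the scheme's
#' weight vectors of every affected node are recomputed before the next
#' merge. The floor c and the damping alpha are calibrated once from the
#' initial corpus and held fixed throughout.
#'
#' @param corpus a `complex_corpus` from [group_evidences()].
#' @param scheme weighting scheme: `"P"`/`"Z"` support, `"A"` adjusted,
#'   `"N4"` information flow (requires `net` and `alpha`).
#' @param epsilon merge/edge tolerance in [0, 0.5).
#' @param net a `ppi_network` (required for `"N4"`).
#' @param alpha damping parameter for `"N4"` (see [solve_alpha()]).
#' @param floor_c frozen occurrence floor c; defaults to the weighted median
#'   of the initial corpus.
#' @param recompute `"affected"` recomputes, after each merge, only the
#'   weight vectors and distances of nodes sharing a protein with the merged
#'   union (exact, since nothing else changes); `"full"` recomputes
#'   everything and exists to validate the bookkeeping.
#' @return a list with the clustered `corpus`, the merge `trace` (data frame
#'   `step`, `kept_id`, `absorbed_id`, `d_sym`), final weight matrices
#'   (`support` and scheme `weights`), the forward `distance` matrix, and the
#'   calibration constants.
#' @export
iterative_clustering <- function(corpus, scheme = c("P", "A", "N4", "Z"),
                                 epsilon = 0.15, net = NULL, alpha = 0,
                                 floor_c = NULL,
                                 recompute = c("affected", "full")) {
  scheme <- match.arg(scheme)
  recompute <- match.arg(recompute)
  stopifnot(epsilon >= 0, epsilon < 0.5)
  if (length(corpus$nodes) == 0L) {
    return(list(corpus = corpus,
                trace = empty_trace(), support = NULL, weights = NULL,
                distance = NULL, scheme = scheme, epsilon = epsilon,
                floor_c = floor_c, alpha = alpha))
  }
  if (is.null(floor_c)) floor_c <- corpus_stats(corpus)$median_c
  P <- if (scheme == "N4" && alpha > 0) transition_operator(net) else NULL

  ## step 0: collapse nodes with identical support weight vectors
  W_S <- support_weights(corpus)
  sig <- apply(W_S, 2L, function(w) {
    pos <- which(w > 0)
    paste(pos, sprintf("%.15g", w[pos]), collapse = " ")
  })
  trace <- list()
  step <- 0L
  for (group in split(colnames(W_S), sig)) {
    if (length(group) < 2L) next
    group <- sort(group)
    for (absorbed in group[-1L]) {
      corpus <- merge_nodes(corpus, group[[1L]], absorbed)
      trace[[length(trace) + 1L]] <-
        data.frame(step = 0L, kept_id = group[[1L]], absorbed_id = absorbed,
                   d_sym = 0, stringsAsFactors = FALSE)
    }
  }

  state <- cluster_state(corpus, scheme, floor_c, net, alpha, P)
  D <- distance_matrix(state$W)

  ## agglomerative phase
  repeat {
    if (nrow(D) < 2L) break
    Dsym <- pmax(D, t(D))
    diag(Dsym) <- Inf
    dmin <- min(Dsym)
    if (dmin > epsilon) break
    cand <- which(Dsym == dmin & upper.tri(Dsym), arr.ind = TRUE)
    ids <- rownames(D)
    lo <- pmin(ids[cand[, 1]], ids[cand[, 2]])
    hi <- pmax(ids[cand[, 1]], ids[cand[, 2]])
    pick <- order(lo, hi)[[1L]]
    step <- step + 1L
    kept_id <- lo[[pick]]; absorbed_id <- hi[[pick]]
    corpus <- merge_nodes(corpus, kept_id, absorbed_id)
    trace[[length(trace) + 1L]] <-
      data.frame(step = step, kept_id = kept_id, absorbed_id = absorbed_id,
                 d_sym = dmin, stringsAsFactors = FALSE)
    if (recompute == "full") {
      state <- cluster_state(corpus, scheme, floor_c, net, alpha, P)
      D <- distance_matrix(state$W)
      next
    }
    ## affected-set update: the merged node's support changed, and n(i)
    ## changed exactly for proteins in the merged union, so only nodes
    ## containing such proteins can see their weight vectors move.
    drop_col <- match(absorbed_id, colnames(state$W_S))
    kept_col <- match(kept_id, colnames(state$W_S))
    members <- which(state$W_S[, kept_col] > 0 | state$W_S[, drop_col] > 0)
    state$W_S <- state$W_S[, -drop_col, drop = FALSE]
    state$W <- state$W[, -drop_col, drop = FALSE]
    D <- D[-drop_col, -drop_col, drop = FALSE]
    kept_col <- match(kept_id, colnames(state$W_S))
    node <- corpus$nodes[[match(kept_id,
                                vapply(corpus$nodes, `[[`, character(1), "id"))]]
    state$W_S[, kept_col] <- support_column(corpus, node)
    state$counts <- rowSums(state$W_S)
    affected <- if (scheme %in% c("P", "Z")) kept_col else
      which(colSums(state$W_S[members, , drop = FALSE] > 0) > 0)
    state$W[, affected] <- scheme_columns(state, affected, scheme, floor_c,
                                          net, alpha, P)
    tot <- colSums(state$W)
    for (a in affected) {
      sims <- colSums(pmin(state$W, state$W[, a]))
      D[a, ] <- 1 - sims / tot[[a]]
      D[, a] <- 1 - sims / tot
    }
  }

  trace <- if (length(trace) > 0L) do.call(rbind, trace) else empty_trace()
  list(corpus = corpus, trace = trace, support = state$W_S,
       weights = state$W, distance = D, scheme = scheme, epsilon = epsilon,
       floor_c = floor_c, alpha = alpha)
}

#' Verify acyclicity and produce a topological order
#'
#' After clustering has removed every pair with d_sym <= epsilon, the
#' relationship graph has no bidirectional edges, and every surviving edge
#' X -> Y forces sigma(X, X) < sigma(Y, Y): total weight strictly increases
#' along edges, which rules out cycles. This checks both the absence of
#' bidirectional pairs and the strict total-weight increase (the constructive
#' witness), then returns a topological order of the node ids.
#'
#' @param edges data frame with columns `from`, `to` (as produced by
#'   [relationship_graph()]).
#' @param totals named numeric vector of self-similarities sigma(X, X),
#'   covering every node (including isolated ones).
#' @return a character vector: the node ids in topological order.
#' @export
assert_acyclic <- function(edges, totals) {
  ids <- names(totals)
  if (nrow(edges) > 0L) {
    fwd <- paste(edges$from, edges$to, sep = "\r")
    rev <- paste(edges$to, edges$from, sep = "\r")
    bad <- fwd %in% rev
    if (any(bad)) {
      stop("bidirectional edge(s) found: ",
           paste(utils::head(paste(edges$from[bad], edges$to[bad], sep = " <-> "), 3),
                 collapse = ", "))
    }
    nonmono <- totals[edges$from] >= totals[edges$to]
    if (any(nonmono)) {
      stop("total weight does not increase along edge(s): ",
           paste(utils::head(paste(edges$from[nonmono], edges$to[nonmono],
                                   sep = " -> "), 3), collapse = ", "))
    }
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = ids, directed = TRUE)
  ord <- igraph::topo_sort(g, mode = "out")
  if (length(ord) != length(ids)) stop("cycle found in relationship graph")
  names(ord)
}

# --- internal engine -------------------------------------------------------

empty_trace <- function() {
  data.frame(step = integer(0), kept_id = character(0),
             absorbed_id = character(0), d_sym = numeric(0),
             stringsAsFactors = FALSE)
}

# forward distances d[i, j] = 1 - sigma(i, j) / sigma(i, i) for all columns
distance_matrix <- function(W) {
  n <- ncol(W)
  tot <- colSums(W)
  S <- matrix(0, n, n, dimnames = list(colnames(W), colnames(W)))
  for (i in seq_len(n)) {
    S[i, ] <- colSums(pmin(W, W[, i]))
  }
  D <- 1 - S / tot
  dimnames(D) <- list(colnames(W), colnames(W))
  diag(D) <- 0
  D
}

support_column <- function(corpus, node) {
  prot_idx <- lapply(corpus$evidences$proteins[node$ev], match,
                     table = corpus$proteins)
  tabulate(unlist(prot_idx), nbins = length(corpus$proteins)) / length(node$ev)
}

cluster_state <- function(corpus, scheme, floor_c, net, alpha, P) {
  W_S <- support_weights(corpus)
  counts <- rowSums(W_S)
  state <- list(W_S = W_S, counts = counts)
  state$W <- scheme_columns(state, seq_len(ncol(W_S)), scheme, floor_c,
                            net, alpha, P)
  colnames(state$W) <- colnames(W_S)
  rownames(state$W) <- rownames(W_S)
  state
}

scheme_columns <- function(state, cols, scheme, floor_c, net, alpha, P) {
  Wsub <- state$W_S[, cols, drop = FALSE]
  if (scheme %in% c("P", "Z")) return(Wsub)
  factor <- pmin(1, floor_c / state$counts)
  if (scheme == "A" || alpha == 0) return(Wsub * factor)
  FF <- expected_visits(Wsub, alpha, P)[rownames(state$W_S), , drop = FALSE]
  out <- FF * (floor_c / pmax(state$counts, floor_c))
  out[Wsub == 0] <- 0
  out
}
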