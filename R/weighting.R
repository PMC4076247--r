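#' Per-evidence redundancy weights
#'
#' Each evidence in a complex node of k evidences carries weight u(e) = 1/k,
#' so that every node contributes one unit of total evidence mass regardless
#' of how often its complex was reported. Weights are recomputed whenever
#' nodes are merged.
#'
#' @param corpus a `complex_corpus`.
#' @return a numeric vector of weights named by `evidence_id`, covering every
#'   evidence assigned to a node.
#' @export
evidence_weights <- function(corpus) {
  stopifnot(inherits(corpus, "complex_corpus"))
  idx <- unlist(lapply(corpus$nodes, `[[`, "ev"))
  u <- unlist(lapply(corpus$nodes, function(nd) {
    rep(1 / length(nd$ev), length(nd$ev))
  }))
  names(u) <- corpus$evidences$evidence_id[idx]
  u
}

#' Support weight matrix
#'
#' The support weight of protein i in complex node C is the fraction of the
#' node's (redundancy-weighted) evidences that contain i:
#' w_S(i) = sum over evidences e containing i of u(e), with u(e) = 1/k inside
#' a node of k evidences. It equals 1 exactly when every evidence of the node
#' contains the protein, and is positive exactly on the node's member set.
#'
#' @param corpus a `complex_corpus`.
#' @return a dense numeric matrix, proteins (rows) by nodes (columns), with
#'   dimnames; entries in (0, 1] on members and 0 elsewhere.
#' @export
support_weights <- function(corpus) {
  stopifnot(inherits(corpus, "complex_corpus"))
  proteins <- corpus$proteins
  W <- matrix(0, nrow = length(proteins), ncol = length(corpus$nodes),
              dimnames = list(proteins,
                              vapply(corpus$nodes, `[[`, character(1), "id")))
  prot_idx <- lapply(corpus$evidences$proteins, match, table = proteins)
  for (g in seq_along(corpus$nodes)) {
    nd <- corpus$nodes[[g]]
    counts <- tabulate(unlist(prot_idx[nd$ev]), nbins = length(proteins))
    W[, g] <- counts / length(nd$ev)
  }
  W
}

#' Corpus-wide protein occurrence statistics
#'
#' Computes, for every member protein, the weighted number of complexes it
#' occurs in, n(i) = sum over all evidences e containing i of u(e), and the
#' weighted median c: the largest attained value m of n such that proteins
#' with n(i) >= m account for at least half of the total mass N = sum n(i).
#' Proteins with n(i) > c are the globally "sticky" ones that get
#' down-weighted; by construction they carry less than 50% of the mass.
#'
#' @param corpus a `complex_corpus` (with at least one node).
#' @param support optional precomputed [support_weights()] matrix.
#' @return a `corpus_stats` list with `counts` (named numeric n(i)),
#'   `total_mass` (N) and `median_c` (c).
#' @export
corpus_stats <- function(corpus, support = NULL) {
  stopifnot(inherits(corpus, "complex_corpus"))
  if (length(corpus$nodes) == 0L) stop("empty corpus: no complex nodes")
  if (is.null(support)) support <- support_weights(corpus)
  # n(i) = sum_e u(e) over evidences containing i = sum over nodes of w_S(i)
  counts <- rowSums(support)
  structure(list(counts = counts,
                 total_mass = sum(counts),
                 median_c = weighted_median_count(counts)),
            class = "corpus_stats")
}

weighted_median_count <- function(counts) {
  n_total <- sum(counts)
  values <- sort(unique(counts), decreasing = TRUE)
  mass <- vapply(values, function(m) sum(counts[counts >= m]), numeric(1))
  values[[which(mass >= n_total / 2)[[1]]]]
}

#' Adjusted weight matrix
#'
#' Down-weights globally over-represented proteins: w_A(i) = w_S(i) *
#' min(1, c / n(i)). Proteins occurring in at most the weighted-median number
#' c of complexes keep their support weight unchanged; the rest are reduced
#' proportionally by c / n(i).
#'
#' @param corpus a `complex_corpus`.
#' @param stats a `corpus_stats` object; by default computed from `corpus`.
#'   During clustering the floor c is held at its initial-corpus value while
#'   n(i) is recomputed, so callers may pass a `stats` with a frozen
#'   `median_c`.
#' @param support optional precomputed [support_weights()] matrix.
#' @return a matrix of the same shape as [support_weights()], entrywise
#'   <= the support matrix.
#' @export
adjusted_weights <- function(corpus, stats = corpus_stats(corpus, support),
                             support = NULL) {
  if (is.null(support)) support <- support_weights(corpus)
  factor <- pmin(1, stats$median_c / stats$counts[rownames(support)])
  support * factor
}

#' Random-walk transition operator on the PPI network
#'
#' P(i, j) = A(i, j) / (deg(i) + kappa), where A is the boolean adjacency of
#' direct interactions and kappa the median degree pseudocount. Rows sum to
#' deg(i) / (deg(i) + kappa) < 1: the missing mass is the per-step
#' probability that a walker leaves the protein-protein layer (jumps to a
#' complex node and terminates). Degree-0 proteins have all-zero rows.
#'
#' @param net a `ppi_network` with defined kappa.
#' @return a sparse substochastic matrix (`dgCMatrix`) with protein dimnames.
#' @export
transition_operator <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.na(net$kappa)) {
    stop("kappa undefined: the PPI pair list is empty, so the transition operator cannot be built")
  }
  P <- Matrix::Diagonal(x = 1 / (net$degree + net$kappa)) %*% net$adjacency
  dimnames(P) <- dimnames(net$adjacency)
  methods::as(P, "CsparseMatrix")
}

#' Expected random-walk visits (Green's function applied to a source)
#'
#' For a damped walk with transition operator P and continuation probability
#' alpha, the Green's function G = sum_{k>=0} (alpha P)^k = (I - alpha P)^{-1}
#' gives expected visit counts. This evaluates F(i) = sum_j source(j) G(j, i),
#' the expected number of visits to protein i by walkers placed according to
#' `source`, via one sparse linear solve of the transposed system
#' (I - alpha P)' F = source.
#'
#' @param source numeric vector of initial walker mass, named by protein
#'   (proteins missing from the operator index are not allowed), or a matrix
#'   with one source per column whose rownames index the operator.
#' @param alpha damping parameter in [0, 1).
#' @param P transition operator from [transition_operator()].
#' @return visits in the same shape as `source`, aligned to the operator
#'   index (vector input: named vector over all operator proteins).
#'   Everywhere `F >= source`; at alpha = 0, `F == source`.
#' @export
expected_visits <- function(source, alpha, P) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop("alpha must be a single value in [0, 1)")
  }
  idx <- rownames(P)
  vec_in <- is.null(dim(source))
  if (vec_in) source <- matrix(source, ncol = 1,
                               dimnames = list(names(source), NULL))
  if (is.null(rownames(source))) {
    if (nrow(source) != nrow(P)) stop("unnamed source must match operator size")
  } else {
    unknown <- setdiff(rownames(source), idx)
    if (length(unknown) > 0L) {
      stop("source proteins absent from the operator index: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    full <- matrix(0, nrow = nrow(P), ncol = ncol(source),
                   dimnames = list(idx, colnames(source)))
    full[rownames(source), ] <- source
    source <- full
  }
  A <- Matrix::Diagonal(nrow(P)) - alpha * Matrix::t(P)
  FF <- as.matrix(Matrix::solve(A, source))
  rownames(FF) <- idx
  if (vec_in) FF[, 1] else FF
}

#' Information-flow (ITM) weight matrix
#'
#' Generalizes the adjusted weights by letting evidence mass diffuse over the
#' network of direct interactions. Walkers are placed on the member proteins
#' of a complex node C proportionally to its support weights, wander with
#' damping alpha under the substochastic operator P (possibly visiting
#' non-members), and their expected visit counts F_C are retained on the
#' member set only. Visits are rescaled by the termination-jump factor
#' c / max(n(i), c), which both puts the weights on the support-weight scale
#' and down-weights globally sticky proteins:
#' w_N(i) = c * F_C(i) / max(n(i), c) for i in Supp(C), 0 otherwise.
#' At alpha = 0 no diffusion occurs and w_N coincides exactly with w_A.
#'
#' @param corpus a `complex_corpus`.
#' @param net a `ppi_network` indexing at least every corpus protein.
#' @param alpha damping parameter in [0, 1); see [solve_alpha()].
#' @param stats a `corpus_stats` (the floor c may be frozen; see
#'   [adjusted_weights()]).
#' @param support optional precomputed [support_weights()] matrix.
#' @param P optional precomputed [transition_operator()].
#' @return a matrix of the same shape as [support_weights()].
#' @export
flow_weights <- function(corpus, net, alpha,
                         stats = corpus_stats(corpus, support),
                         support = NULL, P = NULL) {
  if (is.null(support)) support <- support_weights(corpus)
  if (alpha == 0 && (is.null(net) || is.na(net$kappa))) {
    # no diffusion and no network: the walk visits only its starting protein
    return(adjusted_weights(corpus, stats, support = support))
  }
  if (is.null(P)) P <- transition_operator(net)
  missing <- setdiff(rownames(support), rownames(P))
  if (length(missing) > 0L) {
    stop("PPI network does not index corpus protein(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         "; pass them via build_ppi_network(pairs, proteins = ...)")
  }
  FF <- expected_visits(support, alpha, P)[rownames(support), , drop = FALSE]
  factor <- stats$median_c / pmax(stats$counts[rownames(support)],
                                  stats$median_c)
  W <- FF * factor
  W[support == 0] <- 0  # weights live on the member set only
  W
}

#' Mean random-walk time before termination
#'
#' The expected total number of protein-node visits of a damped walk,
#' averaged over starting proteins drawn uniformly from the interaction
#' network: T(alpha) = (1/|V|) sum_i [G 1](i), where G = (I - alpha P)^{-1}
#' and V is the set of proteins occurring in the PPI pair list. T(0) = 1
#' (only the starting node is visited) and T increases monotonically with
#' alpha; on a k-regular network with kappa = k it equals 1/(1 - alpha/2).
#'
#' @param alpha damping parameter in [0, 1).
#' @param net a `ppi_network`.
#' @param P optional precomputed transition operator.
#' @return the mean walk time, a single number >= 1.
#' @export
mean_walk_time <- function(alpha, net, P = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.null(P)) P <- transition_operator(net)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop("alpha must be a single value in [0, 1)")
  }
  A <- Matrix::Diagonal(nrow(P)) - alpha * P
  x <- as.numeric(Matrix::solve(A, rep(1, nrow(P))))
  names(x) <- rownames(P)
  mean(x[net$ppi_proteins])
}

#' Calibrate the walk damping parameter from a target mean walk time
#'
#' Solves T(alpha) = target for alpha in [0, 1) by Newton's method with the
#' derivative obtained from a second linear solve (dT/dalpha involves
#' G P G 1), safeguarded by bisection on the monotone bracket. Because the
#' transition operator is strictly substochastic, T remains finite as
#' alpha -> 1; a target above that supremum is unreachable and reported as
#' such (e.g. on a k-regular network with kappa = k, T < 2 for every alpha).
#'
#' @param target_time desired mean walk time, >= 1 (1 gives alpha = 0).
#' @param net a `ppi_network`.
#' @param tol convergence tolerance on |T(alpha) - target| (default 1e-9).
#' @return the calibrated alpha.
#' @export
solve_alpha <- function(target_time, net, tol = 1e-9) {
  stopifnot(inherits(net, "ppi_network"))
  if (!is.numeric(target_time) || length(target_time) != 1L || target_time < 1) {
    stop("target_time must be a single value >= 1")
  }
  if (target_time == 1) return(0)
  P <- transition_operator(net)
  n <- nrow(P)
  I <- Matrix::Diagonal(n)
  ppi <- match(net$ppi_proteins, rownames(P))
  walk_time <- function(a) {
    x <- as.numeric(Matrix::solve(I - a * P, rep(1, n)))
    list(t = mean(x[ppi]), x = x)
  }
  sup_t <- walk_time(1)$t  # limit of T(alpha) as alpha -> 1
  if (target_time >= sup_t) {
    stop(sprintf("target unreachable: sup of the mean walk time on this network is %.6g < requested %g",
                 sup_t, target_time))
  }
  lo <- 0; hi <- 1 - 1e-12
  a <- min(max(1 - 1 / target_time, 1e-3), hi)  # crude initial guess
  for (iter in seq_len(100L)) {
    wt <- walk_time(a)
    f <- wt$t - target_time
    if (abs(f) <= tol) return(a)
    if (f < 0) lo <- a else hi <- a
    # dT/dalpha = mean over PPI proteins of [G P G 1]
    y <- as.numeric(Matrix::solve(I - a * P, as.numeric(P %*% wt$x)))
    deriv <- mean(y[ppi])
    a_new <- a - f / deriv
    if (!is.finite(a_new) || a_new <= lo || a_new >= hi) {
      a_new <- (lo + hi) / 2
    }
    a <- a_new
  }
  stop("solve_alpha failed to converge within 100 iterations")
}
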