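test_that("similarity generalizes set intersection and self-similarity", {
  wx <- stats::setNames(rep(1, 4), c("a", "b", "c", "d"))
  wy <- stats::setNames(rep(1, 4), c("b", "c", "d", "e"))
  expect_equal(similarity(wx, wy), 3)
  expect_equal(similarity(wx, stats::setNames(1, "z")), 0)
  for (seed in 1:5) {
    w <- random_weights(sprintf("u%02d", 1:40), 12, seed)
    expect_equal(similarity(w, w), sum(w))
    w2 <- random_weights(sprintf("u%02d", 1:40), 15, seed + 50)
    expect_lte(similarity(w, w2), min(sum(w), sum(w2)))
    expect_equal(similarity(w, w2), similarity(w2, w))
  }
})

test_that("relative distance is the uncovered weight fraction", {
  X <- stats::setNames(rep(1, 7), sprintf("p%d", 1:7))
  Y <- stats::setNames(rep(1, 8), sprintf("p%d", 1:8))
  expect_equal(relative_distance(X, Y), 0)
  expect_equal(relative_distance(Y, X), 1 / 8)
  expect_equal(relative_distance(X, X), 0)
  expect_error(relative_distance(stats::setNames(numeric(0), character(0)), X),
               "zero total")
})

test_that("distance matches a per-protein brute-force oracle on random vectors", {
  universe <- sprintf("u%02d", 1:30)
  for (seed in 1:10) {
    wx <- random_weights(universe, 10, seed)
    wy <- random_weights(universe, 14, seed + 200)
    oracle <- 1 - sum(vapply(names(wx), function(p) {
      min(wx[[p]], if (p %in% names(wy)) wy[[p]] else 0)
    }, numeric(1))) / sum(wx)
    expect_equal(relative_distance(wx, wy), unname(oracle), tolerance = 1e-12)
  }
})

test_that("zero distance is equivalent to entrywise dominance", {
  universe <- sprintf("u%02d", 1:25)
  for (seed in 1:10) {
    wy <- random_weights(universe, 12, seed)
    wx <- wy[sample(names(wy), 7)] * stats::runif(7, 0.3, 1)  # dominated
    expect_equal(relative_distance(wx, wy), 0)
    wx2 <- wx
    wx2[[1]] <- wy[[names(wx2)[[1]]]] * 1.5  # break dominance in one entry
    expect_gt(relative_distance(wx2, wy), 0)
  }
})

test_that("epsilon = 0 on nested sets yields the transitively closed order", {
  W <- matrix(0, 6, 3, dimnames = list(sprintf("p%d", 1:6), c("A", "B", "C")))
  W[1:3, "A"] <- 1; W[1:4, "B"] <- 1; W[1:6, "C"] <- 1
  g <- relationship_graph(W, epsilon = 0)
  expect_setequal(paste(g$from, g$to),
                  c("A B", "A C", "B C"))
})

test_that("a near-superset pair is bidirectional at epsilon 0.15", {
  W <- matrix(0, 8, 2, dimnames = list(sprintf("p%d", 1:8), c("X", "Y")))
  W[1:7, "X"] <- 1; W[1:8, "Y"] <- 1
  g <- relationship_graph(W, epsilon = 0.15)
  expect_setequal(paste(g$from, g$to), c("X Y", "Y X"))
})

test_that("edge sets equal an all-pairs threshold oracle on random instances", {
  universe <- sprintf("u%02d", 1:20)
  for (seed in 1:5) {
    set.seed(seed)
    W <- matrix(0, 20, 8, dimnames = list(universe, sprintf("n%d", 1:8)))
    for (j in 1:8) {
      picked <- sample(20, sample(4:9, 1))
      W[picked, j] <- stats::runif(length(picked), 0.2, 1)
    }
    eps <- 0.3
    g <- relationship_graph(W, epsilon = eps)
    oracle <- character(0)
    for (x in colnames(W)) for (y in colnames(W)) {
      if (x != y && relative_distance(W[W[, x] > 0, x], W[W[, y] > 0, y]) <= eps)
        oracle <- c(oracle, paste(x, y))
    }
    expect_setequal(paste(g$from, g$to), oracle)
  }
})

test_that("epsilon = 0 edge relation is transitive on random subset families", {
  universe <- sprintf("u%02d", 1:30)
  for (seed in 1:10) {
    set.seed(seed)
    sets <- list()
    for (j in 1:4) {
      big <- sample(universe, sample(12:18, 1))
      mid <- sample(big, sample(6:9, 1))
      sets[[length(sets) + 1L]] <- big
      sets[[length(sets) + 1L]] <- mid
      sets[[length(sets) + 1L]] <- sample(mid, sample(3:5, 1))
    }
    W <- matrix(0, 30, length(sets),
                dimnames = list(universe, sprintf("n%02d", seq_along(sets))))
    for (j in seq_along(sets)) W[sets[[j]], j] <- 1
    g <- relationship_graph(W, epsilon = 0)
    edges <- paste(g$from, g$to)
    chains <- 0L
    for (r1 in seq_len(nrow(g))) for (r2 in seq_len(nrow(g))) {
      if (g$to[[r1]] == g$from[[r2]] && g$from[[r1]] != g$to[[r2]]) {
        chains <- chains + 1L
        expect_true(paste(g$from[[r1]], g$to[[r2]]) %in% edges)
      }
    }
    expect_gt(chains, 0L)
  }
})

test_that("merging unions evidence and rescues false-negative members", {
  ev <- ev_table(list(c("a", "b", "c", "d"), c("a", "b", "c", "e")))
  corpus <- group_evidences(ev)
  ids <- vapply(corpus$nodes, `[[`, character(1), "id")
  merged <- merge_nodes(corpus, ids[[1]], ids[[2]])
  expect_equal(length(merged$nodes), 1L)
  W <- support_weights(merged)
  expect_equal(unname(W[c("a", "b", "c", "d", "e"), 1]),
               c(1, 1, 1, 0.5, 0.5))

  # identical protein sets: support stays all-ones after merging
  ev2 <- ev_table(list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  corpus2 <- group_evidences(ev2)
  ids2 <- vapply(corpus2$nodes, `[[`, character(1), "id")
  W2 <- support_weights(merge_nodes(corpus2, ids2[[1]], ids2[[2]]))
  expect_true(all(W2[c("a", "b", "c", "d"), 1] == 1))
})

test_that("corpus mass stays consistent with a from-scratch oracle after merges", {
  bundle <- small_noisy_bundle(9)
  corpus <- group_evidences(bundle$ev)
  set.seed(9)
  for (k in 1:10) {
    ids <- vapply(corpus$nodes, `[[`, character(1), "id")
    pick <- sample(ids, 2)
    corpus <- merge_nodes(corpus, pick[[1]], pick[[2]])
  }
  st <- corpus_stats(corpus)
  # oracle: N = sum over nodes of sum over evidences |proteins|/k
  oracle <- sum(vapply(corpus$nodes, function(nd) {
    sum(lengths(corpus$evidences$proteins[nd$ev])) / length(nd$ev)
  }, numeric(1)))
  expect_equal(st$total_mass, oracle, tolerance = 1e-12)
  u <- evidence_weights(corpus)
  for (nd in corpus$nodes) {
    expect_equal(sum(u[corpus$evidences$evidence_id[nd$ev]]), 1)
  }
})

test_that("step 0 merges compositionally identical complexes", {
  ev <- ev_table(list(c("a", "b", "c", "d"), c("a", "b", "c", "d"),
                      c("q", "r", "s", "t")))
  cl <- iterative_clustering(group_evidences(ev), scheme = "P",
                             epsilon = 0.15)
  expect_equal(length(cl$corpus$nodes), 2L)
  expect_equal(nrow(cl$trace), 1L)
  expect_equal(cl$trace$step, 0L)
  expect_equal(cl$trace$d_sym, 0)
})

test_that("a seven-member set merges into its eight-member superset at 0.15", {
  ev <- ev_table(list(sprintf("p%d", 1:7), sprintf("p%d", 1:8)))
  cl <- iterative_clustering(group_evidences(ev), scheme = "P",
                             epsilon = 0.15)
  expect_equal(length(cl$corpus$nodes), 1L)
  expect_equal(nrow(cl$trace), 1L)
  expect_equal(cl$trace$d_sym, 1 / 8)
  # at epsilon = 0.1 the pair stays separate
  cl2 <- iterative_clustering(group_evidences(ev), scheme = "P",
                              epsilon = 0.1)
  expect_equal(length(cl2$corpus$nodes), 2L)
})

test_that("planted duplicate evidences collapse to the distinct complexes", {
  params <- synth_params(n_proteins = 300, n_complexes = 8)
  truth <- generate_truth(params, seed = 21)
  ev <- sample_evidence_corpus(truth, seed = 21)
  cl <- iterative_clustering(group_evidences(ev), scheme = "P",
                             epsilon = 0.15)
  expect_equal(length(cl$corpus$nodes), length(truth$complexes))
  expect_equal(nrow(cl$trace),
               nrow(group_evidences(ev)$evidences) - length(truth$complexes))
  expect_true(all(cl$trace$step == 0L))
})

test_that("affected-set distance bookkeeping matches full recomputation", {
  for (scheme in c("A", "N4")) {
    bundle <- small_noisy_bundle(13)
    corpus <- group_evidences(bundle$ev)
    net <- build_ppi_network(bundle$ppi, proteins = corpus$proteins)
    alpha <- if (scheme == "N4") solve_alpha(4, net) else 0
    lazy <- iterative_clustering(corpus, scheme = scheme, epsilon = 0.15,
                                 net = net, alpha = alpha,
                                 recompute = "affected")
    full <- iterative_clustering(corpus, scheme = scheme, epsilon = 0.15,
                                 net = net, alpha = alpha,
                                 recompute = "full")
    expect_equal(lazy$trace, full$trace)
    expect_equal(lazy$distance, full$distance, tolerance = 1e-10)
    expect_equal(lazy$weights, full$weights, tolerance = 1e-10)
  }
})

test_that("clustering is invariant under permutation of the input records", {
  bundle <- small_noisy_bundle(17)
  ev <- bundle$ev
  set.seed(17)
  shuffled <- ev[sample(nrow(ev)), , drop = FALSE]
  rownames(shuffled) <- NULL
  h1 <- iterative_clustering(group_evidences(ev), scheme = "A",
                             epsilon = 0.15)
  h2 <- iterative_clustering(group_evidences(shuffled), scheme = "A",
                             epsilon = 0.15)
  sets1 <- lapply(h1$corpus$nodes, function(nd)
    sort(unique(unlist(h1$corpus$evidences$proteins[nd$ev]))))
  sets2 <- lapply(h2$corpus$nodes, function(nd)
    sort(unique(unlist(h2$corpus$evidences$proteins[nd$ev]))))
  expect_setequal(vapply(sets1, paste, character(1), collapse = " "),
                  vapply(sets2, paste, character(1), collapse = " "))
  expect_equal(h1$trace$d_sym, h2$trace$d_sym)
})

test_that("no pair within epsilon survives clustering", {
  for (seed in 1:4) {
    bundle <- small_noisy_bundle(seed)
    cl <- iterative_clustering(group_evidences(bundle$ev), scheme = "A",
                               epsilon = 0.15)
    if (nrow(cl$distance) >= 2L) {
      Dsym <- pmax(cl$distance, t(cl$distance))
      diag(Dsym) <- Inf
      expect_gt(min(Dsym), 0.15)
    }
  }
})

test_that("acyclicity check accepts clustered graphs and rejects 2-cycles", {
  bundle <- small_noisy_bundle(23)
  cl <- iterative_clustering(group_evidences(bundle$ev), scheme = "A",
                             epsilon = 0.15)
  edges <- relationship_graph(distances = cl$distance, epsilon = 0.15)
  totals <- colSums(cl$weights)
  ord <- assert_acyclic(edges, totals)
  expect_setequal(ord, colnames(cl$weights))
  pos <- match(colnames(cl$weights), ord)
  if (nrow(edges) > 0L) {
    expect_true(all(pos[match(edges$from, colnames(cl$weights))] <
                    pos[match(edges$to, colnames(cl$weights))]))
    expect_true(all(totals[edges$from] < totals[edges$to]))
  }
  bad <- data.frame(from = c("A", "B"), to = c("B", "A"),
                    stringsAsFactors = FALSE)
  expect_error(assert_acyclic(bad, c(A = 1, B = 2)), "bidirectional")
})
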