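#' Parameters for the synthetic complex universe
#'
#' Bundles and validates the knobs of the generator. The defaults describe a
#' small interactome with nested complexes and redundant reporting: a pool
#' of proteins, a set of true complexes of 4-8 members some of which are
#' core subassemblies shared by one or two larger parents (so the planted
#' part-of relations form a DAG, not a tree), three independent evidences
#' per complex, and a PPI layer much denser within true complexes than in
#' the background. Noise channels are off by default and switched on per
#' experiment: per-evidence false negatives (`fn_rate`) and false-positive
#' contaminants (`fp_rate`), plus a designated pool of globally sticky
#' proteins that attach to any evidence with probability
#' `sticky_attach_prob` (systematic noise, distinct from sporadic
#' contaminants).
#'
#' @param n_proteins size of the protein pool.
#' @param n_complexes number of true complexes (cores + parents +
#'   independent ones).
#' @param nesting_depth 1 for no nesting, 2 to plant core-inside-parent
#'   relations.
#' @param size_range inclusive range for core/independent complex sizes and
#'   for the number of extra proteins a parent adds on top of its core;
#'   minimum 4.
#' @param fp_rate expected contaminants per evidence, as a fraction of the
#'   true complex size.
#' @param fn_rate probability that a true member is missed by an evidence.
#' @param redundancy evidences drawn per complex.
#' @param sticky_count number of globally sticky proteins.
#' @param sticky_attach_prob probability a sticky protein joins an evidence.
#' @param ppi_within_prob probability of a direct-interaction edge between
#'   two members of the same true complex.
#' @param ppi_background_prob probability of a sporadic background edge
#'   between any two pool proteins.
#' @param peripheral_fraction fraction of non-member proteins that carry a
#'   single binary-interaction partner (randomly matched pairs). This
#'   emulates the degree-1-dominated periphery of curated interactomes: it
#'   pins the median degree (kappa) at 1 while complex members sit in dense
#'   within-complex neighborhoods of much higher degree, the degree skew
#'   that makes a mean-walk-time target of several steps attainable.
#' @return a validated `synth_params` list.
#' @export
synth_params <- function(n_proteins = 600, n_complexes = 16,
                         nesting_depth = 2, size_range = c(8, 14),
                         fp_rate = 0, fn_rate = 0, redundancy = 3,
                         sticky_count = 0, sticky_attach_prob = 0.5,
                         ppi_within_prob = 0.95,
                         ppi_background_prob = 0.0002,
                         peripheral_fraction = 1) {
  p <- list(n_proteins = as.integer(n_proteins),
            n_complexes = as.integer(n_complexes),
            nesting_depth = as.integer(nesting_depth),
            size_range = as.integer(size_range),
            fp_rate = fp_rate, fn_rate = fn_rate,
            redundancy = as.integer(redundancy),
            sticky_count = as.integer(sticky_count),
            sticky_attach_prob = sticky_attach_prob,
            ppi_within_prob = ppi_within_prob,
            ppi_background_prob = ppi_background_prob,
            peripheral_fraction = peripheral_fraction)
  probs <- c(p$fp_rate, p$fn_rate, p$sticky_attach_prob, p$ppi_within_prob,
             p$ppi_background_prob, p$peripheral_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$size_range[[1]] < 4 || p$size_range[[2]] < p$size_range[[1]]) {
    stop("size_range must be an increasing range with minimum >= 4")
  }
  if (p$nesting_depth < 1 || p$n_complexes < 1 || p$redundancy < 1) {
    stop("n_complexes, nesting_depth and redundancy must be positive")
  }
  structure(p, class = "synth_params")
}

#' Generate a ground-truth complex universe
#'
#' Plants `n_complexes` true protein sets. With `nesting_depth >= 2`, about
#' a quarter of them are core subassemblies, each embedded in one or two
#' larger parent complexes (core plus extra module), mirroring the pattern
#' of a stable core shared by several larger assemblies; the remaining
#' complexes are independent. Independent complexes and distinct cores draw
#' disjoint protein sets, so the planted subset relations are the only true
#' containments; sticky proteins live in a reserved pool outside all
#' complexes and enter only through the evidence-sampling noise channels.
#'
#' @param params a [synth_params()] list.
#' @param seed integer seed; the same seed reproduces the universe exactly.
#' @return a `synth_truth` list: `complexes` (named list of protein sets),
#'   `edges` (planted part-of relations, data frame `child`, `parent`),
#'   `sticky` (sticky protein ids), `params`, `seed`.
#' @export
generate_truth <- function(params = synth_params(), seed = 1) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(seed, {
    pool <- sprintf("P%04d", seq_len(params$n_proteins))
    sticky <- if (params$sticky_count > 0)
      pool[seq_len(params$sticky_count)] else character(0)
    avail <- setdiff(pool, sticky)
    cursor <- 0L
    draw <- function(k) {
      if (cursor + k > length(avail)) {
        stop("infeasible size constraints: protein pool exhausted; ",
             "increase n_proteins or reduce n_complexes/size_range")
      }
      out <- avail[(cursor + 1L):(cursor + k)]
      cursor <<- cursor + k
      out
    }
    rsize <- function() sample(params$size_range[[1]]:params$size_range[[2]], 1L)
    n_cores <- if (params$nesting_depth >= 2)
      max(1L, params$n_complexes %/% 4L) else 0L
    complexes <- list()
    edges <- list()
    slots <- params$n_complexes
    for (k in seq_len(n_cores)) {
      if (slots < 2L) break
      n_par <- min(sample(1:2, 1L), slots - 1L)
      core <- draw(rsize())
      core_id <- sprintf("T%03d", length(complexes) + 1L)
      complexes[[core_id]] <- core
      slots <- slots - 1L
      for (j in seq_len(n_par)) {
        parent <- c(core, draw(rsize()))
        parent_id <- sprintf("T%03d", length(complexes) + 1L)
        complexes[[parent_id]] <- parent
        edges[[length(edges) + 1L]] <-
          data.frame(child = core_id, parent = parent_id,
                     stringsAsFactors = FALSE)
        slots <- slots - 1L
      }
    }
    while (slots > 0L) {
      id <- sprintf("T%03d", length(complexes) + 1L)
      complexes[[id]] <- draw(rsize())
      slots <- slots - 1L
    }
    edges <- if (length(edges) > 0L) do.call(rbind, edges) else
      data.frame(child = character(0), parent = character(0),
                 stringsAsFactors = FALSE)
    structure(list(complexes = complexes, edges = edges, sticky = sticky,
                   pool = pool, params = params, seed = seed),
              class = "synth_truth")
  })
}

#' Sample a noisy evidence corpus from a planted truth
#'
#' Draws `redundancy` evidences per true complex. Each evidence keeps every
#' true member with probability 1 - `fn_rate`, attaches each sticky protein
#' independently with probability `sticky_attach_prob`, and adds
#' Binomial(|complex|, `fp_rate`) uniform non-member contaminants. Each
#' evidence receives its own publication identifier and a bait drawn from
#' its surviving members, so initial grouping keeps redundant evidences as
#' separate nodes and all merging is left to the clustering. The originating
#' complex id is recorded in the `source` column (used by
#' [score_recovery()]). Evidences reduced below two proteins by false
#' negatives are dropped.
#'
#' @param truth a `synth_truth`.
#' @param seed integer seed.
#' @return an `evidence_table`.
#' @export
sample_evidence_corpus <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synth_truth"))
  p <- truth$params
  with_seed(seed, {
    rows <- list()
    counter <- 0L
    for (cid in names(truth$complexes)) {
      members <- truth$complexes[[cid]]
      eligible_fp <- setdiff(truth$pool, c(members, truth$sticky))
      for (r in seq_len(p$redundancy)) {
        counter <- counter + 1L
        kept <- members[stats::runif(length(members)) >= p$fn_rate]
        stuck <- truth$sticky[stats::runif(length(truth$sticky)) <
                                p$sticky_attach_prob]
        n_fp <- stats::rbinom(1L, length(members), p$fp_rate)
        contaminants <- if (n_fp > 0L)
          sample(eligible_fp, min(n_fp, length(eligible_fp))) else character(0)
        proteins <- unique(c(kept, stuck, contaminants))
        if (length(kept) < 1L || length(proteins) < 2L) next
        rows[[length(rows) + 1L]] <- list(
          evidence_id = sprintf("ev%05d", counter),
          publication = sprintf("PUB%05d", counter),
          method = "MI:0676",
          bait = sample(kept, 1L),
          proteins = proteins,
          source = cid)
      }
    }
    new_evidence_table(
      vapply(rows, `[[`, character(1), "evidence_id"),
      vapply(rows, `[[`, character(1), "publication"),
      vapply(rows, `[[`, character(1), "method"),
      vapply(rows, `[[`, character(1), "bait"),
      lapply(rows, `[[`, "proteins"),
      vapply(rows, `[[`, character(1), "source"))
  })
}

#' Sample a PPI network consistent with a planted truth
#'
#' Pairs of proteins belonging to the same true complex interact with
#' probability `ppi_within_prob`; any pair of pool proteins with probability
#' `ppi_background_prob`; and a `peripheral_fraction` of the proteins
#' outside all complexes are randomly matched into degree-1 pairs (the
#' single-partner periphery typical of curated interactomes, which keeps
#' the median degree low relative to within-complex degrees). The result is
#' symmetric, self-free and deduplicated.
#'
#' @param truth a `synth_truth`.
#' @param seed integer seed.
#' @return a data frame `protein_a`, `protein_b`.
#' @export
sample_ppi <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synth_truth"))
  p <- truth$params
  with_seed(seed, {
    a <- character(0); b <- character(0)
    for (members in truth$complexes) {
      if (length(members) < 2L) next
      pairs <- utils::combn(sort(members), 2L)
      hit <- stats::runif(ncol(pairs)) < p$ppi_within_prob
      a <- c(a, pairs[1L, hit]); b <- c(b, pairs[2L, hit])
    }
    if (p$ppi_background_prob > 0) {
      pool <- truth$pool
      n <- length(pool)
      n_pairs <- n * (n - 1L) / 2
      hits <- which(stats::runif(n_pairs) < p$ppi_background_prob)
      if (length(hits) > 0L) {
        all_pairs <- utils::combn(n, 2L)
        a <- c(a, pool[all_pairs[1L, hits]])
        b <- c(b, pool[all_pairs[2L, hits]])
      }
    }
    if (p$peripheral_fraction > 0) {
      members <- unique(unlist(truth$complexes))
      periph <- setdiff(truth$pool, members)
      periph <- periph[stats::runif(length(periph)) < p$peripheral_fraction]
      periph <- sample(periph)
      if (length(periph) %% 2L == 1L) periph <- periph[-1L]
      if (length(periph) >= 2L) {
        m <- matrix(periph, ncol = 2L)
        a <- c(a, m[, 1L]); b <- c(b, m[, 2L])
      }
    }
    dedup_pairs(a, b)
  })
}

#' Score recovery of the planted hierarchy
#'
#' Maps each final node of a built hierarchy to the true complex with the
#' largest weighted overlap of its support vector (ties to the smaller true
#' id), then compares containment relations. Recovered relations are the
#' mapped kept edges with distinct endpoints; precision is the fraction of
#' recovered relations within the transitive closure of the planted ones,
#' recall the fraction of planted relations within the transitive closure of
#' the recovered ones (so chains recovered via intermediates count). Merge
#' purity is the fraction of final nodes whose evidences all originate from
#' one true complex.
#'
#' @param hierarchy a `complex_hierarchy` built from a corpus sampled from
#'   `truth`.
#' @param truth the `synth_truth` the corpus was sampled from.
#' @return a list with `edge_precision`, `edge_recall`, `merge_purity` and
#'   the node-to-truth `mapping` data frame.
#' @export
score_recovery <- function(hierarchy, truth) {
  stopifnot(inherits(hierarchy, "complex_hierarchy"),
            inherits(truth, "synth_truth"))
  ids <- colnames(hierarchy$support)
  true_ids <- names(truth$complexes)
  overlap <- vapply(true_ids, function(t) {
    members <- truth$complexes[[t]]
    colSums(hierarchy$support[rownames(hierarchy$support) %in% members, ,
                              drop = FALSE])
  }, numeric(length(ids)))
  if (length(ids) == 1L) overlap <- matrix(overlap, nrow = 1L,
                                           dimnames = list(ids, true_ids))
  mapped <- true_ids[apply(overlap, 1L, which.max)]  # ties: first = smaller id
  names(mapped) <- ids

  kept <- hierarchy$nodes$node_id[hierarchy$nodes$class != "filtered"]
  edges <- hierarchy$edges
  rec <- unique(data.frame(child = mapped[edges$from],
                           parent = mapped[edges$to],
                           stringsAsFactors = FALSE))
  rec <- rec[rec$child != rec$parent, , drop = FALSE]

  closure <- function(e) {
    if (nrow(e) == 0L) return(character(0))
    g <- igraph::graph_from_data_frame(e, directed = TRUE,
                                       vertices = true_ids)
    reach <- igraph::distances(g, mode = "out") < Inf
    diag(reach) <- FALSE
    hit <- which(reach, arr.ind = TRUE)
    paste(true_ids[hit[, 1]], true_ids[hit[, 2]], sep = "\r")
  }
  rec_keys <- paste(rec$child, rec$parent, sep = "\r")
  planted_keys <- paste(truth$edges$child, truth$edges$parent, sep = "\r")
  precision <- if (length(rec_keys) == 0L) 1 else
    mean(rec_keys %in% closure(truth$edges))
  recall <- if (length(planted_keys) == 0L) 1 else
    mean(planted_keys %in% closure(rec))

  purity <- mean(vapply(hierarchy$corpus$nodes, function(nd) {
    length(unique(hierarchy$corpus$evidences$source[nd$ev])) == 1L
  }, logical(1)))

  list(edge_precision = precision, edge_recall = recall,
       merge_purity = purity,
       mapping = data.frame(node_id = ids, true_id = unname(mapped),
                            stringsAsFactors = FALSE))
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
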