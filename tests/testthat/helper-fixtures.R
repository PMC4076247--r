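# Small in-code fixtures shared across test files.

# Build an evidence table directly (bypassing file IO).
ev_table <- function(proteins, ids = sprintf("ev%02d", seq_along(proteins)),
                     pubs = sprintf("PUB%02d", seq_along(proteins)),
                     methods = "MI:0676", baits = "-", sources = "") {
  n <- length(proteins)
  complexHier:::new_evidence_table(
    ids, rep_len(pubs, n), rep_len(methods, n), rep_len(baits, n),
    proteins, rep_len(sources, n))
}

# Write an evidence table to a temp TSV and return the path.
ev_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("evidence_id\tpublication\tmethod\tbait\tproteins", lines),
             path)
  path
}

ppi_table <- function(a, b) {
  data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
}

# Simple named graphs used in weighting tests.
path_ppi <- function() ppi_table(c("a", "b"), c("b", "c"))

clique_ppi <- function(k, prefix = "v") {
  v <- paste0(prefix, seq_len(k))
  pairs <- utils::combn(v, 2)
  ppi_table(pairs[1, ], pairs[2, ])
}

cycle_ppi <- function(n) {
  v <- sprintf("c%02d", seq_len(n))
  ppi_table(v, v[c(2:n, 1)])
}

# Random simple graph on n labelled proteins with edge probability p.
random_ppi <- function(n, p, seed) {
  set.seed(seed)
  v <- sprintf("r%03d", seq_len(n))
  pairs <- utils::combn(v, 2)
  hit <- stats::runif(ncol(pairs)) < p
  ppi_table(pairs[1, hit], pairs[2, hit])
}

# Random sparse nonnegative weight vector over a protein universe.
random_weights <- function(universe, k, seed) {
  set.seed(seed)
  picked <- sample(universe, k)
  stats::setNames(stats::runif(k, 0.05, 1), picked)
}

# A noisy synthetic corpus bundle at reduced scale (fast to cluster).
small_noisy_bundle <- function(seed, fp = 0.1, fn = 0.1, sticky = 3) {
  params <- synth_params(n_proteins = 300, n_complexes = 8,
                         fp_rate = fp, fn_rate = fn, sticky_count = sticky)
  truth <- generate_truth(params, seed = seed)
  list(truth = truth,
       ev = sample_evidence_corpus(truth, seed = seed),
       ppi = sample_ppi(truth, seed = seed))
}
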