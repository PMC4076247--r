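#' Read a protein-complex evidence table
#'
#' Reads the canonical tab-delimited evidence format: one row per experimental
#' evidence of a protein association, with columns `evidence_id`,
#' `publication`, `method`, `bait` (`"-"` when no bait was annotated) and
#' `proteins` (semicolon-separated protein identifiers). Lines starting with
#' `#` are ignored. Duplicate proteins within a row are collapsed with a
#' warning; a bait listed outside the member list is kept with a warning
#' (membership is defined solely by the protein list).
#'
#' @param path path to a UTF-8, tab-delimited evidence file.
#' @return an `evidence_table`: a data frame with character columns
#'   `evidence_id`, `publication`, `method`, `bait`, `source` and a list
#'   column `proteins` of character vectors (each of length >= 2).
#' @seealso [write_complex_evidence()], [group_evidences()]
#' @export
read_complex_evidence <- function(path) {
  parsed <- read_tsv_lines(path)
  required <- c("evidence_id", "publication", "method", "bait", "proteins")
  missing <- setdiff(required, parsed$header)
  if (length(missing) > 0L) {
    stop("evidence table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  col <- function(name) vapply(parsed$fields, `[`, character(1),
                               match(name, parsed$header))
  if (length(parsed$fields) == 0L) {
    return(empty_evidence_table())
  }
  prot_raw <- col("proteins")
  proteins <- vector("list", length(prot_raw))
  bait <- col("bait")
  for (r in seq_along(prot_raw)) {
    p <- strsplit(prot_raw[[r]], ";", fixed = TRUE)[[1]]
    p <- p[nzchar(p)]
    if (length(p) == 0L) {
      stop(sprintf("empty protein list at line %d of %s",
                   parsed$lines[[r]], path), call. = FALSE)
    }
    if (anyDuplicated(p)) {
      warning(sprintf("duplicate proteins collapsed at line %d of %s",
                      parsed$lines[[r]], path), call. = FALSE)
      p <- unique(p)
    }
    if (!identical(bait[[r]], "-") && !(bait[[r]] %in% p)) {
      warning(sprintf("bait %s not in protein list at line %d of %s",
                      bait[[r]], parsed$lines[[r]], path), call. = FALSE)
    }
    proteins[[r]] <- p
  }
  src <- if ("source" %in% parsed$header) col("source") else
    rep("", length(prot_raw))
  new_evidence_table(col("evidence_id"), col("publication"), col("method"),
                     bait, proteins, src)
}

#' Write a protein-complex evidence table
#'
#' @param x an `evidence_table` as returned by [read_complex_evidence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_complex_evidence <- function(x, path) {
  stopifnot(is.data.frame(x))
  lines <- c(
    paste(c("evidence_id", "publication", "method", "bait", "proteins",
            "source"), collapse = "\t"),
    vapply(seq_len(nrow(x)), function(r) {
      paste(c(x$evidence_id[[r]], x$publication[[r]], x$method[[r]],
              x$bait[[r]], paste(x$proteins[[r]], collapse = ";"),
              if (is.null(x$source)) "" else x$source[[r]]),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a table of direct binary protein-protein interactions
#'
#' Reads a tab-delimited table with columns `protein_a` and `protein_b`
#' (extra columns are ignored, `#` comment lines skipped). Self-interactions
#' are removed and duplicate pairs (in either order) are collapsed.
#'
#' @param path path to the PPI pair file.
#' @return a data frame with character columns `protein_a`, `protein_b`;
#'   one row per distinct unordered, non-self pair.
#' @export
read_ppi_pairs <- function(path) {
  parsed <- read_tsv_lines(path)
  required <- c("protein_a", "protein_b")
  missing <- setdiff(required, parsed$header)
  if (length(missing) > 0L) {
    stop("PPI table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ia <- match("protein_a", parsed$header)
  ib <- match("protein_b", parsed$header)
  a <- vapply(parsed$fields, `[`, character(1), ia)
  b <- vapply(parsed$fields, `[`, character(1), ib)
  dedup_pairs(a, b)
}

#' @export
#' @rdname read_ppi_pairs
#' @param x data frame with columns `protein_a`, `protein_b`.
write_ppi_pairs <- function(x, path) {
  writeLines(c("protein_a\tprotein_b",
               paste(x$protein_a, x$protein_b, sep = "\t")), path)
  invisible(path)
}

#' Best-effort reader for PSI-MI TAB 2.6 complex-expansion rows
#'
#' Maps MITAB 2.6 rows onto evidence records: interactor identifier columns
#' 1 and 2, detection method column 7, publication identifiers column 9 and
#' experimental roles columns 19/20 (a participant annotated as `bait`
#' becomes the evidence bait). Rows sharing (publication, method, bait) are
#' collected into one evidence record whose protein set is the union of
#' their interactors. This adapter is intentionally lossy: it is meant for
#' spoke/matrix-expanded complex records, not for faithful MITAB round-trips.
#'
#' @param path path to a MITAB 2.6 file (uncompressed).
#' @return an `evidence_table` (see [read_complex_evidence()]).
#' @export
read_psimi_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && startsWith(lines[[1]], "#")) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) return(empty_evidence_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  strip_db <- function(s) sub("^[^:]*:", "", sub("\\|.*$", "", s))
  first_mi <- function(s) {
    m <- regmatches(s, regexpr("MI:[0-9]{4}", s))
    if (length(m) == 0L) "-" else m
  }
  first_pmid <- function(s) {
    m <- regmatches(s, regexpr("pubmed:[0-9]+", s))
    if (length(m) == 0L) "-" else sub("pubmed:", "", m)
  }
  n <- length(fields)
  ua <- character(n); ub <- character(n); meth <- character(n)
  pub <- character(n); bait <- character(n)
  for (r in seq_len(n)) {
    f <- fields[[r]]
    if (length(f) < 9L) {
      stop(sprintf("malformed MITAB row at line %d of %s", r, path),
           call. = FALSE)
    }
    ua[[r]] <- strip_db(f[[1]])
    ub[[r]] <- strip_db(f[[2]])
    meth[[r]] <- first_mi(f[[7]])
    pub[[r]] <- first_pmid(f[[9]])
    role_a <- if (length(f) >= 19L) f[[19]] else ""
    role_b <- if (length(f) >= 20L) f[[20]] else ""
    bait[[r]] <- if (grepl("bait", role_a, fixed = TRUE)) ua[[r]]
      else if (grepl("bait", role_b, fixed = TRUE)) ub[[r]] else "-"
  }
  key <- paste(pub, meth, bait, sep = "\r")
  groups <- split(seq_len(n), key)
  groups <- groups[order(names(groups))]
  proteins <- lapply(groups, function(idx) sort(unique(c(ua[idx], ub[idx]))))
  k <- length(groups)
  first <- vapply(groups, `[`, integer(1), 1L)
  new_evidence_table(sprintf("mitab%05d", seq_len(k)), pub[first],
                     meth[first], bait[first], proteins,
                     rep("psimi-tab", k))
}

#' Group equivalent evidences into initial complex nodes
#'
#' Evidences reporting the same complex redundantly -- sharing publication,
#' detection-method annotation and bait protein -- are grouped into a single
#' initial complex node. Records with fewer than `min_size` distinct proteins
#' are excluded before grouping (the method targets heteromeric complexes;
#' small records reflect binary interactions more than complexes). Within a
#' group of k equivalent evidences each evidence carries redundancy weight
#' u(e) = 1/k.
#'
#' @param x an `evidence_table`.
#' @param min_size minimum number of distinct proteins per record
#'   (default 4, i.e. complexes with more than three different proteins).
#' @return a `complex_corpus`: list with elements `evidences` (the surviving
#'   `evidence_table`), `nodes` (list of nodes, each with `id`, integer
#'   evidence indices `ev` and constituent ids `constituents`) and
#'   `proteins` (sorted union of member proteins).
#' @export
group_evidences <- function(x, min_size = 4) {
  stopifnot(is.data.frame(x), min_size >= 2)
  sizes <- lengths(x$proteins)
  keep <- sizes >= min_size
  ev <- x[keep, , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) == 0L) {
    corpus <- structure(list(evidences = ev, nodes = list(),
                             proteins = character(0), min_size = min_size,
                             n_excluded = sum(!keep)),
                        class = "complex_corpus")
    return(corpus)
  }
  key <- paste(ev$publication, ev$method, ev$bait, sep = "\r")
  groups <- split(seq_len(nrow(ev)), key)
  groups <- groups[order(names(groups))]
  nodes <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    id <- sprintf("N%05d", g)
    nodes[[g]] <- list(id = id, ev = as.integer(groups[[g]]),
                       constituents = id)
  }
  # corpus fingerprint: identifies the evidence content (and hence the
  # non-redundant complex set) independently of node bookkeeping
  signature <- paste(sort(paste(ev$publication, ev$method, ev$bait,
                                vapply(ev$proteins,
                                       function(p) paste(sort(p),
                                                         collapse = ";"),
                                       character(1)),
                                sep = "\r")), collapse = "\n")
  structure(list(evidences = ev,
                 nodes = nodes,
                 proteins = sort(unique(unlist(ev$proteins))),
                 min_size = min_size,
                 n_excluded = sum(!keep),
                 signature = signature),
            class = "complex_corpus")
}

#' Build a PPI network object
#'
#' Represents the set of direct binary interactions as a symmetric boolean
#' adjacency operator with empty diagonal. The pseudocount kappa is the
#' median number of direct interactions per protein (lower median over the
#' proteins appearing in the pair list, so that the attained integer value is
#' reported). Proteins supplied via `proteins` but absent from the pair list
#' are included with degree 0, so that the transition operator is defined on
#' the union of complex-evidence and interaction proteins.
#'
#' @param pairs data frame with columns `protein_a`, `protein_b`
#'   (deduplicated and self-free, as produced by [read_ppi_pairs()]);
#'   may have zero rows.
#' @param proteins additional protein identifiers to index (typically the
#'   member proteins of a complex corpus).
#' @return a `ppi_network`: list with `proteins` (index), sparse symmetric
#'   `adjacency`, named integer `degree`, `kappa` (NA when the pair list is
#'   empty) and `ppi_proteins` (proteins occurring in the pair list).
#' @export
build_ppi_network <- function(pairs, proteins = NULL) {
  a <- as.character(pairs$protein_a)
  b <- as.character(pairs$protein_b)
  if (any(a == b)) stop("self-pairs must be removed before building the network")
  ppi_proteins <- sort(unique(c(a, b)))
  all_proteins <- sort(unique(c(ppi_proteins, proteins)))
  n <- length(all_proteins)
  if (length(a) > 0L) {
    i <- match(a, all_proteins)
    j <- match(b, all_proteins)
    adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                                dims = c(n, n),
                                dimnames = list(all_proteins, all_proteins))
    adj@x[] <- 1  # collapse accidental duplicates to boolean
  } else {
    adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n),
                                dimnames = list(all_proteins, all_proteins))
  }
  degree <- Matrix::rowSums(adj)
  storage.mode(degree) <- "integer"
  kappa <- if (length(ppi_proteins) == 0L) NA_integer_ else {
    d <- sort(degree[ppi_proteins])
    as.integer(d[[ceiling(length(d) / 2)]])
  }
  structure(list(proteins = all_proteins, adjacency = adj, degree = degree,
                 kappa = kappa, ppi_proteins = ppi_proteins),
            class = "ppi_network")
}

#' @export
print.complex_corpus <- function(x, ...) {
  cat(sprintf("complex_corpus: %d evidences in %d nodes over %d proteins (%d record(s) below min_size %d excluded)\n",
              nrow(x$evidences), length(x$nodes), length(x$proteins),
              x$n_excluded, x$min_size))
  invisible(x)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins indexed (%d with interactions), %d edges, kappa = %s\n",
              length(x$proteins), length(x$ppi_proteins),
              as.integer(Matrix::nnzero(x$adjacency) / 2),
              format(x$kappa)))
  invisible(x)
}

# --- internal helpers ------------------------------------------------------

new_evidence_table <- function(evidence_id, publication, method, bait,
                               proteins, source) {
  out <- data.frame(evidence_id = as.character(evidence_id),
                    publication = as.character(publication),
                    method = as.character(method),
                    bait = as.character(bait),
                    source = as.character(source),
                    stringsAsFactors = FALSE)
  out$proteins <- unname(proteins)
  rownames(out) <- NULL
  class(out) <- c("evidence_table", "data.frame")
  out
}

empty_evidence_table <- function() {
  new_evidence_table(character(0), character(0), character(0), character(0),
                     list(), character(0))
}

# Parse a UTF-8 TSV with '#' comments, tracking original line numbers.
read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0L) stop("no header row found in ", path, call. = FALSE)
  header <- strsplit(lines[[keep[[1]]]], "\t", fixed = TRUE)[[1]]
  data_idx <- keep[-1L]
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  for (r in seq_along(fields)) {
    if (length(fields[[r]]) < length(header)) {
      stop(sprintf("malformed row at line %d of %s (%d of %d columns)",
                   data_idx[[r]], path, length(fields[[r]]), length(header)),
           call. = FALSE)
    }
  }
  list(header = header, fields = fields, lines = data_idx)
}

dedup_pairs <- function(a, b) {
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  out <- data.frame(protein_a = lo[!dup], protein_b = hi[!dup],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
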