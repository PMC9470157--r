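#' Per-LCR amino-acid composition matrix
#'
#' Each LCR becomes a 20-dimensional vector of residue frequencies over
#' the standard amino acids. Non-standard letters (X, U, O, B, Z) are
#' excluded from both numerator and denominator; an LCR consisting only of
#' non-standard letters is dropped with a warning. Rows sum to 1.
#'
#' @param calls LCR calls (needs `protein_id`, `lcr_index`, `sequence`).
#' @param species optional species/proteome tag, recycled to one per call.
#' @return object of class `lcr_composition`: list with `matrix`
#'   (n x 20, columns the 20 amino acids, rownames
#'   `species|protein_id|lcr_index`) and `meta` (data.frame with
#'   protein_id, lcr_index, species).
#' @export
composition_matrix <- function(calls, species = "proteome") {
  stopifnot(nrow(calls) >= 1L)
  species <- rep_len(as.character(species), nrow(calls))
  counts <- t(vapply(calls$sequence, function(s) {
    ch <- seq_chars(s)
    tabulate(factor(ch, levels = AA20), nbins = 20L)
  }, integer(20L), USE.NAMES = FALSE))
  colnames(counts) <- AA20
  tot <- rowSums(counts)
  drop <- tot == 0L
  if (any(drop)) {
    warning(sum(drop), " LCR(s) with no standard residues dropped")
    counts <- counts[!drop, , drop = FALSE]
    calls <- calls[!drop, , drop = FALSE]
    species <- species[!drop]
    tot <- tot[!drop]
  }
  if (nrow(counts) == 0L) stop("no LCRs with standard residues")
  comp <- counts / tot
  meta <- data.frame(protein_id = calls$protein_id,
                     lcr_index = calls$lcr_index,
                     species = species, stringsAsFactors = FALSE)
  rownames(comp) <- paste(meta$species, meta$protein_id, meta$lcr_index,
                          sep = "|")
  structure(list(matrix = comp, meta = meta), class = "lcr_composition")
}

#' Merge composition matrices from several proteomes
#' @param ... `lcr_composition` objects (e.g. one per species)
#' @return a single `lcr_composition` with rows stacked in argument order
#' @export
merge_compositions <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L,
            all(vapply(xs, inherits, logical(1L), "lcr_composition")))
  structure(list(matrix = do.call(rbind, lapply(xs, `[[`, "matrix")),
                 meta = do.call(rbind, lapply(xs, `[[`, "meta"))),
            class = "lcr_composition")
}

check_composition <- function(comp) {
  stopifnot(inherits(comp, "lcr_composition"),
            ncol(comp$matrix) == 20L,
            nrow(comp$matrix) == nrow(comp$meta),
            all(abs(rowSums(comp$matrix) - 1) < 1e-9),
            all(comp$matrix >= 0), all(comp$matrix <= 1))
  invisible(comp)
}

#' Embed LCR compositions in two dimensions with UMAP
#'
#' Deterministic given (input, parameters, seed, uwot version); run
#' parameters are recorded in the result's attributes. Single-threaded so
#' that results do not depend on the host.
#'
#' @param comp an `lcr_composition`.
#' @param n_neighbors UMAP neighbourhood size, default 15; 200 reproduces
#'   the large multi-species map setting.
#' @param seed RNG seed, default 73.
#' @param min_dist UMAP min_dist, default 0.1.
#' @return n x 2 matrix of coordinates (columns `umap1`, `umap2`, rownames
#'   as in `comp$matrix`)
#' @export
embed_lcrs <- function(comp, n_neighbors = 15, seed = 73, min_dist = 0.1) {
  check_composition(comp)
  n <- nrow(comp$matrix)
  if (n < n_neighbors + 1L)
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1L,
         " LCRs, got ", n)
  coords <- withr::with_seed(as.integer(seed), {
    uwot::umap(comp$matrix, n_neighbors = n_neighbors, n_components = 2,
               min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
  })
  stopifnot(all(is.finite(coords)))
  dimnames(coords) <- list(rownames(comp$matrix), c("umap1", "umap2"))
  attr(coords, "params") <- list(n_neighbors = n_neighbors,
                                 seed = as.integer(seed),
                                 min_dist = min_dist,
                                 uwot_version =
                                   as.character(utils::packageVersion("uwot")))
  coords
}

#' Cluster LCR compositions with the Leiden algorithm
#'
#' Communities are found on a shared-nearest-neighbour graph built from
#' the 20-dimensional composition vectors themselves, never from the 2-D
#' embedding (which would bake in projection artifacts). Edges of the
#' k-nearest-neighbour graph are weighted by the Jaccard overlap of the
#' two endpoints' neighbour sets, and Leiden optimises modularity on that
#' weighted graph.
#'
#' Degenerate input in which every composition is identical yields a
#' single cluster by definition.
#'
#' @param comp an `lcr_composition`.
#' @param k neighbours for the kNN graph, default 15.
#' @param seed RNG seed, default 73.
#' @param resolution Leiden resolution (modularity objective), default 0.1:
#'   coarse enough to identify composition islands; raise it to subdivide
#'   clusters by finer composition differences.
#' @return integer vector of cluster labels (1..C, ordered by first
#'   appearance), one per row of `comp$matrix`
#' @export
cluster_lcrs <- function(comp, k = 15, seed = 73, resolution = 0.1) {
  check_composition(comp)
  X <- comp$matrix
  n <- nrow(X)
  if (n < k + 1L)
    stop("need at least k + 1 = ", k + 1L, " LCRs, got ", n)
  # collapse exact duplicates: they are one point in composition space
  key <- apply(X, 1L, paste, collapse = ",")
  uniq <- !duplicated(key)
  U <- X[uniq, , drop = FALSE]
  map <- match(key, key[uniq])
  m <- nrow(U)
  if (m == 1L) return(rep(1L, n))
  ku <- min(k, m - 1L)
  nn <- FNN::get.knn(U, k = ku)$nn.index
  # SNN: Jaccard overlap of neighbour sets (self included)
  nbr <- cbind(seq_len(m), nn)
  a <- rep(seq_len(m), each = ku); b <- as.vector(t(nn))
  edges <- cbind(pmin(a, b), pmax(a, b))
  edges <- edges[!duplicated(edges[, 1L] * (m + 1) + edges[, 2L]), ,
                 drop = FALSE]
  jac <- vapply(seq_len(nrow(edges)), function(e) {
    a <- nbr[edges[e, 1L], ]; b <- nbr[edges[e, 2L], ]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1L))
  keep <- jac > 0
  g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
  cl <- withr::with_seed(as.integer(seed), {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution,
                           weights = jac[keep], n_iterations = 5)
  })
  memb_u <- igraph::membership(cl)
  memb <- memb_u[map]
  # relabel 1..C by first appearance
  lab <- match(memb, unique(memb))
  as.integer(lab)
}

#' Name clusters by their dominant residues
#'
#' For each cluster the mean composition is computed; the name joins, by
#' "/", every residue whose mean frequency is at least `frac` times the
#' cluster's maximum mean frequency, in descending frequency order. This
#' is a reproducible proxy for eyeballing the dominant amino acids of a
#' cluster.
#'
#' @param comp an `lcr_composition`.
#' @param labels cluster labels from [cluster_lcrs()].
#' @param frac inclusion fraction relative to the top residue, default 0.5.
#' @return named character vector: cluster label -> name (e.g. "K", "G/P")
#' @export
label_clusters <- function(comp, labels, frac = 0.5) {
  check_composition(comp)
  stopifnot(length(labels) == nrow(comp$matrix), frac > 0, frac <= 1)
  out <- vapply(sort(unique(labels)), function(l) {
    mu <- colMeans(comp$matrix[labels == l, , drop = FALSE])
    keep <- mu >= frac * max(mu)
    paste(names(sort(mu[keep], decreasing = TRUE)), collapse = "/")
  }, character(1L))
  names(out) <- sort(unique(labels))
  out
}

#' Select residue-enriched LCRs from a reference set
#'
#' Marks the reference rows in the top `1 - q` fraction (default the top
#' quartile) of the given residue's frequency, i.e. rows whose frequency
#' is at least the q-quantile of that frequency within the reference set.
#' When all reference frequencies are equal, all rows are selected.
#' "Both"-enrichment (e.g. K/E) is the AND of two such masks.
#'
#' @param comp an `lcr_composition`.
#' @param residue one-letter amino-acid code.
#' @param reference_rows integer or logical index of the reference rows.
#' @param q quantile, default 0.75.
#' @return logical vector over all rows of `comp$matrix`; TRUE only for
#'   selected reference rows
#' @export
quartile_enriched <- function(comp, residue, reference_rows, q = 0.75) {
  check_composition(comp)
  stopifnot(residue %in% AA20)
  n <- nrow(comp$matrix)
  ref <- seq_len(n) %in% seq_len(n)[reference_rows]
  if (!any(ref)) stop("empty reference set")
  f <- comp$matrix[, residue]
  cut <- stats::quantile(f[ref], probs = q, names = FALSE)
  ref & f >= cut
}

#' Per-species cluster occupancy
#'
#' @param labels cluster labels (one per LCR).
#' @param species species tags aligned with `labels`.
#' @return contingency table (species x cluster) of LCR counts
#' @export
cluster_occupancy <- function(labels, species) {
  stopifnot(length(labels) == length(species))
  table(species = species, cluster = labels)
}
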