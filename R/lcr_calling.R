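#' Segment a convolved dotplot at an intensity threshold
#'
#' Pixels with intensity >= threshold form the foreground; maximal
#' connected sets of foreground pixels are labelled 1..K (8-connectivity by
#' default, so diagonally adjacent pixels join — dotplot repeat signatures
#' run diagonally and 4-connectivity would fracture them).
#'
#' @param im an `intensity_matrix` from [convolve_dotplot()].
#' @param threshold integer threshold in `[1, kernel_size^2]`.
#' @param connectivity 8 (default) or 4.
#' @return object of class `segmented_mask`: list with `protein_id`,
#'   `matrix` (integer N x N of component labels, 0 = background),
#'   `threshold`, `connectivity`.
#' @export
segment_matrix <- function(im, threshold, connectivity = 8) {
  stopifnot(inherits(im, "intensity_matrix"),
            threshold >= 1, threshold <= im$kernel_size^2)
  lab <- .cc_label(im$matrix >= threshold, as.integer(connectivity))
  structure(list(protein_id = im$protein_id, matrix = lab,
                 threshold = as.integer(threshold),
                 connectivity = as.integer(connectivity)),
            class = "segmented_mask")
}

#' Call LCRs from a segmented dotplot
#'
#' Only components that touch the diagonal are LCRs. For each such
#' component the raw extent is the min..max of its diagonal indices (an
#' off-diagonal lobe does not extend the call); the extent is then widened
#' by `-pad_left`/`+pad_right` residues to undo the convolution kernel's
#' erosion of boundaries, and clamped to the protein. Expanded intervals
#' that overlap or abut are merged into one LCR.
#'
#' @param mask a `segmented_mask`.
#' @param sequence the protein's residue string (length must match mask).
#' @param pad_left,pad_right boundary expansion, defaults 4 and 5 (matching
#'   the default kernel anchor).
#' @return data.frame with columns protein_id, lcr_index, start, stop,
#'   length, sequence (coordinates 1-based inclusive, rows in N-to-C
#'   order); zero rows if no component touches the diagonal.
#' @export
call_lcrs <- function(mask, sequence, pad_left = 4, pad_right = 5) {
  stopifnot(inherits(mask, "segmented_mask"))
  sequence <- unname(sequence)
  n <- nrow(mask$matrix)
  if (nchar(sequence) != n)
    stop("sequence length does not match mask for ", mask$protein_id)
  diag_lab <- mask$matrix[cbind(seq_len(n), seq_len(n))]
  labs <- unique(diag_lab[diag_lab > 0L])
  if (length(labs) == 0L) return(empty_lcr_calls(mask$protein_id))
  iv <- t(vapply(labs, function(l) {
    idx <- which(diag_lab == l)
    c(min(idx), max(idx))
  }, integer(2L)))
  start <- pmax(1L, iv[, 1L] - as.integer(pad_left))
  stop_ <- pmin(n, iv[, 2L] + as.integer(pad_right))
  o <- order(start, stop_)
  start <- start[o]; stop_ <- stop_[o]
  # merge overlapping or abutting expanded intervals
  ms <- start[1L]; me <- stop_[1L]; outs <- integer(0); oute <- integer(0)
  for (k in seq_along(start)[-1L]) {
    if (start[k] <= me + 1L) {
      me <- max(me, stop_[k])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[k]; me <- stop_[k]
    }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  data.frame(protein_id = mask$protein_id,
             lcr_index = seq_along(outs),
             start = outs, stop = oute,
             length = oute - outs + 1L,
             sequence = substring(sequence, outs, oute),
             stringsAsFactors = FALSE)
}

empty_lcr_calls <- function(protein_id = character(0)) {
  data.frame(protein_id = character(0), lcr_index = integer(0),
             start = integer(0), stop = integer(0), length = integer(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' Find off-diagonal intersections between called LCRs
#'
#' LCRs a and b (a != b) intersect if any segmented (foreground) pixel lies
#' in the rectangle rows(interval_a) x cols(interval_b) of the mask, using
#' the expanded intervals. Intersections mean the two LCRs' sequences match
#' each other, i.e. they are compositionally the same kind of repeat.
#'
#' @param mask a `segmented_mask`.
#' @param calls LCR calls for the same protein from [call_lcrs()].
#' @return integer matrix with two columns (`a`, `b`), one row per
#'   unordered intersecting pair of `lcr_index` values; zero rows if none.
#' @export
find_type_edges <- function(mask, calls) {
  stopifnot(inherits(mask, "segmented_mask"))
  m <- nrow(calls)
  edges <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("a", "b")))
  if (m < 2L) return(edges)
  if (!all(calls$protein_id == mask$protein_id))
    stop("calls do not belong to mask protein")
  for (a in seq_len(m - 1L)) {
    for (b in seq((a + 1L), m)) {
      block <- mask$matrix[calls$start[a]:calls$stop[a],
                           calls$start[b]:calls$stop[b], drop = FALSE]
      if (any(block > 0L))
        edges <- rbind(edges, c(calls$lcr_index[a], calls$lcr_index[b]))
    }
  }
  edges
}

#' Assign LCR types and copy numbers from intersection edges
#'
#' The per-protein LCR graph has LCRs as nodes and off-diagonal
#' intersections as edges. Its connected components are the distinct LCR
#' types; the size of a component is the copy number of every LCR in it.
#' Types are numbered 1..C by their first (most N-terminal) member.
#'
#' @param calls LCR calls of one protein.
#' @param edges edge matrix from [find_type_edges()].
#' @return list with `calls` (the input with `type_id` and
#'   `type_copy_number` filled in) and `graph` (class `lcr_type_graph`:
#'   protein_id, nodes, edges, components).
#' @export
assign_types <- function(calls, edges) {
  m <- nrow(calls)
  if (m == 0L) {
    calls$type_id <- integer(0); calls$type_copy_number <- integer(0)
    g <- structure(list(protein_id = character(0), nodes = integer(0),
                        edges = edges, components = list()),
                   class = "lcr_type_graph")
    return(list(calls = calls, graph = g))
  }
  if (nrow(edges) > 0L &&
      !all(c(edges) %in% calls$lcr_index))
    stop("edge references unknown lcr_index")
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  # order components by smallest member lcr_index (== node index here)
  first <- vapply(seq_len(comp$no),
                  function(c) min(which(comp$membership == c)), integer(1L))
  rank <- order(order(first))
  type_id <- rank[comp$membership]
  calls$type_id <- as.integer(type_id)
  calls$type_copy_number <- as.integer(comp$csize[comp$membership])
  components <- lapply(seq_len(comp$no)[order(first)],
                       function(c) calls$lcr_index[comp$membership == c])
  graph <- structure(list(protein_id = calls$protein_id[1L],
                          nodes = calls$lcr_index,
                          edges = edges,
                          components = components),
                     class = "lcr_type_graph")
  list(calls = calls, graph = graph)
}

#' Classify a protein by its total and distinct LCR counts
#'
#' @param total total number of LCRs in the protein (>= 1).
#' @param distinct number of distinct LCR types (1 <= distinct <= total).
#' @return one of "single", "multiple-same", "multiple-distinct",
#'   "multiple-mixed". A protein like RPA43 with three copies of one type
#'   is "multiple-same"; one like TCOF with 22 LCRs across 4 types is
#'   "multiple-mixed".
#' @export
classify_protein <- function(total, distinct) {
  stopifnot(length(total) == length(distinct))
  if (any(distinct < 1L) || any(distinct > total))
    stop("need 1 <= distinct <= total")
  ifelse(total == 1L, "single",
         ifelse(distinct == 1L, "multiple-same",
                ifelse(distinct == total, "multiple-distinct",
                       "multiple-mixed")))
}

#' Cross-tabulate total vs distinct LCR counts over a proteome
#'
#' @param calls typed LCR calls (several proteins).
#' @return data.frame with columns `total`, `distinct`, `n_proteins`; one
#'   row per occupied cell. `sum(n_proteins)` equals the number of
#'   LCR-containing proteins.
#' @export
total_vs_distinct_table <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(total = integer(0), distinct = integer(0),
                      n_proteins = integer(0)))
  stopifnot(all(!is.na(calls$type_id)))
  per <- do.call(rbind, lapply(split(calls, calls$protein_id), function(x) {
    data.frame(total = nrow(x), distinct = length(unique(x$type_id)))
  }))
  agg <- stats::aggregate(list(n_proteins = rep(1L, nrow(per))),
                          by = per[c("total", "distinct")], FUN = sum)
  agg <- agg[order(agg$total, agg$distinct), ]
  rownames(agg) <- NULL
  agg
}

#' Export a per-protein LCR type graph to JSON
#'
#' Nodes carry `lcr_index`, `start`, `stop` and `type_id`; edges are pairs
#' of `lcr_index`. The file round-trips losslessly through
#' [import_protein_graph()].
#'
#' @param graph an `lcr_type_graph` from [assign_types()].
#' @param calls the typed calls of the same protein (interval source).
#' @param path output JSON path.
#' @return `path`, invisibly
#' @export
export_protein_graph <- function(graph, calls, path) {
  stopifnot(inherits(graph, "lcr_type_graph"))
  nodes <- if (nrow(calls) > 0L)
    calls[, c("lcr_index", "start", "stop", "type_id")]
  else
    data.frame(lcr_index = integer(0), start = integer(0),
               stop = integer(0), type_id = integer(0))
  edges <- if (nrow(graph$edges) > 0L)
    as.data.frame(graph$edges)
  else
    data.frame(a = integer(0), b = integer(0))
  obj <- list(protein_id = if (length(graph$protein_id)) graph$protein_id
              else NA_character_,
              nodes = nodes, edges = edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a per-protein LCR type graph from JSON
#' @param path JSON written by [export_protein_graph()].
#' @return list with `protein_id`, `nodes` (data.frame), `edges`
#'   (data.frame with columns a, b)
#' @export
import_protein_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  edges <- as.data.frame(obj$edges)
  if (nrow(nodes) == 0L)
    nodes <- data.frame(lcr_index = integer(0), start = integer(0),
                        stop = integer(0), type_id = integer(0))
  if (nrow(edges) == 0L)
    edges <- data.frame(a = integer(0), b = integer(0))
  list(protein_id = obj$protein_id, nodes = nodes, edges = edges)
}

#' Call, type and annotate all LCRs of a proteome
#'
#' Runs per protein: convolve the dotplot, segment at `threshold`, call
#' LCRs, detect off-diagonal intersections, assign types, and compute
#' Shannon entropy of each LCR sequence.
#'
#' @param proteome a [proteome()].
#' @param threshold integer segmentation threshold (from
#'   [lcr_threshold()]).
#' @param kernel_size kernel width, default 10.
#' @param connectivity component connectivity, default 8.
#' @param pad_left,pad_right boundary expansion, defaults 4/5.
#' @param entropy_base logarithm base for entropy, default 2 (bits).
#' @param keep_graphs if TRUE, attach the per-protein type graphs as the
#'   `graphs` attribute (named list).
#' @return data.frame of typed calls (columns of [write_lcr_table()]),
#'   sorted by (protein_id, start).
#' @export
call_proteome <- function(proteome, threshold, kernel_size = 10,
                          connectivity = 8, pad_left = 4, pad_right = 5,
                          entropy_base = 2, keep_graphs = FALSE) {
  stopifnot(inherits(proteome, "proteome"))
  res <- vector("list", length(proteome$sequences))
  graphs <- if (keep_graphs) list() else NULL
  ids <- names(proteome$sequences)
  for (k in seq_along(ids)) {
    s <- proteome$sequences[[k]]
    im <- convolve_dotplot(build_dotplot(s, protein_id = ids[k]), kernel_size)
    mask <- segment_matrix(im, threshold, connectivity)
    calls <- call_lcrs(mask, s, pad_left, pad_right)
    if (nrow(calls) == 0L) next
    typed <- assign_types(calls, find_type_edges(mask, calls))
    calls <- typed$calls
    calls$entropy_bits <- vapply(calls$sequence, shannon_entropy,
                                 numeric(1L), base = entropy_base,
                                 USE.NAMES = FALSE)
    res[[k]] <- calls
    if (keep_graphs) graphs[[ids[k]]] <- typed$graph
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(out)) {
    out <- empty_lcr_calls()
    out$type_id <- integer(0); out$type_copy_number <- integer(0)
    out$entropy_bits <- numeric(0)
  } else {
    out <- out[order(out$protein_id, out$start), ]
    rownames(out) <- NULL
  }
  out <- out[, lcr_table_cols]
  if (keep_graphs) attr(out, "graphs") <- graphs
  out
}
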