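#' Brute-force LCR-calling oracle
#'
#' Recomputes the whole per-protein calling path by naive loops: the
#' dotplot by pairwise character comparison, window counts by explicit
#' submatrix sums, components by flood fill, diagonal extraction,
#' boundary expansion, interval merging and off-diagonal intersection
#' checks. Intended for testing the optimised path against; O(N^2 k^2),
#' so keep N <= 2000.
#'
#' @param sequence residue string (N <= 2000).
#' @param threshold segmentation threshold.
#' @param kernel_size kernel width, default 10.
#' @param pad_left,pad_right boundary expansion, defaults 4/5.
#' @param connectivity 8 (default) or 4.
#' @return list with `labels` (labelled component matrix), `intervals`
#'   (data.frame start/stop of called LCRs, N-to-C) and `edges` (integer
#'   matrix of intersecting call-index pairs)
#' @export
brute_force_lcr_oracle <- function(sequence, threshold, kernel_size = 10,
                                   pad_left = 4, pad_right = 5,
                                   connectivity = 8) {
  sequence <- unname(sequence)
  ch <- seq_chars(sequence)
  n <- length(ch)
  stopifnot(n <= 2000L)
  dot <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (ch[i] == ch[j]) dot[i, j] <- 1L
  lo <- -(as.integer(ceiling(kernel_size / 2)) - 1L)
  hi <- as.integer(floor(kernel_size / 2))
  conv <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    r <- max(1L, i + lo):min(n, i + hi)
    for (j in seq_len(n)) {
      cset <- max(1L, j + lo):min(n, j + hi)
      conv[i, j] <- sum(dot[r, cset])
    }
  }
  mask <- conv >= threshold
  # flood fill, labels by first appearance in column-major order
  labels <- matrix(0L, n, n)
  nextlab <- 0L
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  }
  for (j0 in seq_len(n)) for (i0 in seq_len(n)) {
    if (!mask[i0, j0] || labels[i0, j0] > 0L) next
    nextlab <- nextlab + 1L
    queue <- matrix(c(i0, j0), ncol = 2L)
    labels[i0, j0] <- nextlab
    while (nrow(queue) > 0L) {
      cur <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (d in seq_along(dr)) {
        ii <- cur[1L] + dr[d]; jj <- cur[2L] + dc[d]
        if (ii >= 1L && ii <= n && jj >= 1L && jj <= n &&
            mask[ii, jj] && labels[ii, jj] == 0L) {
          labels[ii, jj] <- nextlab
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  # diagonal components -> raw extents -> expanded, clamped, merged
  diag_lab <- labels[cbind(seq_len(n), seq_len(n))]
  raw <- list()
  for (l in unique(diag_lab[diag_lab > 0L])) {
    idx <- which(diag_lab == l)
    raw[[length(raw) + 1L]] <- c(min(idx), max(idx))
  }
  iv <- list()
  if (length(raw) > 0L) {
    ex <- lapply(raw, function(r)
      c(max(1L, r[1L] - pad_left), min(n, r[2L] + pad_right)))
    ex <- ex[order(vapply(ex, `[`, numeric(1L), 1L),
                   vapply(ex, `[`, numeric(1L), 2L))]
    cur <- ex[[1L]]
    for (e in ex[-1L]) {
      if (e[1L] <= cur[2L] + 1L) cur[2L] <- max(cur[2L], e[2L])
      else { iv[[length(iv) + 1L]] <- cur; cur <- e }
    }
    iv[[length(iv) + 1L]] <- cur
  }
  intervals <- if (length(iv) > 0L)
    data.frame(start = as.integer(vapply(iv, `[`, numeric(1L), 1L)),
               stop = as.integer(vapply(iv, `[`, numeric(1L), 2L)))
  else data.frame(start = integer(0), stop = integer(0))
  edges <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("a", "b")))
  m <- nrow(intervals)
  if (m >= 2L) for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    found <- FALSE
    for (i in intervals$start[a]:intervals$stop[a]) {
      for (j in intervals$start[b]:intervals$stop[b]) {
        if (labels[i, j] > 0L) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) edges <- rbind(edges, c(a, b))
  }
  list(labels = labels, intervals = intervals, edges = edges)
}
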