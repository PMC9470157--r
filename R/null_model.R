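#' Simulate a length-matched null proteome
#'
#' One sequence per input length, in the same order, with residues drawn
#' i.i.d. uniformly from the 20 standard amino acids. The null proteome is
#' the background model against which the segmentation threshold is
#' calibrated: under it, any dotplot density is what chance alone produces.
#'
#' @param lengths integer vector of sequence lengths (all >= 1).
#' @param seed integer seed; the same seed always yields the same proteome.
#' @param name proteome label.
#' @return a [proteome()] with ids `null_1`, `null_2`, ...
#' @export
generate_null_proteome <- function(lengths, seed, name = "null") {
  if (length(lengths) == 0L) stop("empty length list")
  lengths <- as.integer(lengths)
  if (any(lengths < 1L)) stop("all lengths must be >= 1")
  seqs <- withr::with_seed(seed, {
    vapply(lengths,
           function(L) paste(sample(AA20, L, replace = TRUE), collapse = ""),
           character(1L))
  })
  names(seqs) <- paste0("null_", seq_along(seqs))
  p <- proteome(seqs, name = name)
  attr(p, "seed") <- as.integer(seed)
  p
}

#' Pooled histogram of convolved dotplot intensities over a proteome
#'
#' Counts every pixel of every protein's convolved dotplot (full N x N
#' matrix: diagonal and both symmetric halves). Bin b holds the number of
#' pixels with intensity b, b = 0..kernel_size^2.
#'
#' Matrices are streamed row-by-row, so memory stays O(N) per protein even
#' for titin-scale sequences.
#'
#' @param proteome a [proteome()].
#' @param kernel_size convolution window width, default 10.
#' @return object of class `intensity_histogram`: list with `counts`
#'   (integer vector, index i = intensity i-1), `n_pixels`, `kernel_size`.
#' @export
proteome_intensity_histogram <- function(proteome, kernel_size = 10) {
  stopifnot(inherits(proteome, "proteome"))
  kmax <- as.integer(kernel_size)^2
  counts <- numeric(kmax + 1L)
  for (s in proteome$sequences) {
    stream_intensity_rows(s, kernel_size, function(row, i) {
      t <- tabulate(row + 1L, nbins = kmax + 1L)
      counts <<- counts + t
    })
  }
  intensity_histogram(counts, kernel_size = kernel_size)
}

#' Construct an intensity histogram from counts
#' @param counts numeric vector of pixel counts, index i = intensity i-1.
#' @param kernel_size kernel width the intensities came from.
#' @return an `intensity_histogram`
#' @export
intensity_histogram <- function(counts, kernel_size = 10) {
  kmax <- as.integer(kernel_size)^2
  stopifnot(length(counts) == kmax + 1L, all(counts >= 0))
  structure(list(counts = as.numeric(counts), n_pixels = sum(counts),
                 kernel_size = as.integer(kernel_size)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity histogram: %.0f pixels, kernel %d, max intensity %d>\n",
              x$n_pixels, x$kernel_size,
              max(which(x$counts > 0)) - 1L))
  invisible(x)
}

#' FDR-calibrated segmentation threshold
#'
#' For each candidate integer threshold t, the false discovery rate is the
#' number of null-proteome pixels with intensity >= t divided by the total
#' number of passing pixels from the real and null sets combined:
#' `fdr(t) = null_ge(t) / (real_ge(t) + null_ge(t))`, defined as 0 when no
#' pixel passes. The selected threshold is the smallest t >= 1 with
#' `fdr(t) <= target_fdr`.
#'
#' @param real intensity histogram of the real proteome.
#' @param null intensity histogram of the matched null proteome.
#' @param target_fdr target false discovery rate, default 0.002.
#' @return object of class `threshold_result`: list with `threshold`,
#'   `fdr_at_threshold`, `fdr_curve` (named vector over t = 1..kmax),
#'   `target_fdr`, and pass counts.
#' @export
threshold_from_fdr <- function(real, null, target_fdr = 0.002) {
  stopifnot(inherits(real, "intensity_histogram"),
            inherits(null, "intensity_histogram"),
            real$kernel_size == null$kernel_size,
            target_fdr > 0, target_fdr < 1)
  if (real$n_pixels == 0 || null$n_pixels == 0)
    stop("empty histogram")
  kmax <- real$kernel_size^2
  # counts with intensity >= t, t = 0..kmax (cumulative from above)
  real_ge <- rev(cumsum(rev(real$counts)))
  null_ge <- rev(cumsum(rev(null$counts)))
  stopifnot(!is.unsorted(rev(real_ge)), !is.unsorted(rev(null_ge)))
  t <- seq_len(kmax)                  # candidate thresholds 1..kmax
  denom <- real_ge[t + 1L] + null_ge[t + 1L]
  fdr <- ifelse(denom == 0, 0, null_ge[t + 1L] / denom)
  names(fdr) <- t
  # a threshold no pixel passes is meaningless, so require denom > 0
  ok <- which(fdr <= target_fdr & denom > 0)
  if (length(ok) == 0L) {
    cond <- structure(
      class = c("dotlcr_no_threshold", "error", "condition"),
      list(message = sprintf("no threshold satisfies FDR <= %g", target_fdr),
           call = sys.call(), fdr_curve = fdr))
    stop(cond)
  }
  thr <- ok[1L]
  structure(list(threshold = as.integer(thr),
                 fdr_at_threshold = unname(fdr[thr]),
                 fdr_curve = fdr,
                 target_fdr = target_fdr,
                 n_real_pass = unname(real_ge[thr + 1L]),
                 n_null_pass = unname(null_ge[thr + 1L])),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold %d: FDR %.3g (target %g); %d real / %d null pixels pass>\n",
              x$threshold, x$fdr_at_threshold, x$target_fdr,
              x$n_real_pass, x$n_null_pass))
  invisible(x)
}

#' Derive the segmentation threshold for a proteome
#'
#' Convenience wrapper: simulates the length-matched null proteome, pools
#' intensity histograms for both proteomes, and calibrates the threshold at
#' `target_fdr`. With `n_null_reps > 1` the null histogram is averaged over
#' that many independent null proteomes (seeds `seed`, `seed+1`, ...).
#'
#' @param proteome a [proteome()].
#' @param target_fdr target FDR, default 0.002.
#' @param kernel_size kernel width, default 10.
#' @param seed seed for the null proteome simulation.
#' @param n_null_reps number of null replicates to average, default 1.
#' @return a `threshold_result` with the seed recorded in `$seed`.
#' @export
lcr_threshold <- function(proteome, target_fdr = 0.002, kernel_size = 10,
                          seed = 1L, n_null_reps = 1L) {
  lens <- unname(protein_lengths(proteome))
  real_h <- proteome_intensity_histogram(proteome, kernel_size)
  counts <- numeric(as.integer(kernel_size)^2 + 1L)
  for (r in seq_len(n_null_reps)) {
    nullp <- generate_null_proteome(lens, seed = seed + r - 1L)
    counts <- counts + proteome_intensity_histogram(nullp, kernel_size)$counts
  }
  null_h <- intensity_histogram(counts / n_null_reps, kernel_size)
  res <- threshold_from_fdr(real_h, null_h, target_fdr)
  res$seed <- as.integer(seed)
  res$kernel_size <- as.integer(kernel_size)
  res
}
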