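#' Build a binary self-comparison dotplot
#'
#' `matrix[i, j] = 1` iff residues i and j of the sequence are the same
#' character (exact equality, so non-standard letters such as X match
#' themselves). The result is symmetric with an all-ones diagonal.
#'
#' @param sequence a residue string, or a single-element named character
#'   vector (the name is kept as the protein id).
#' @param protein_id optional id; defaults to the name of `sequence`.
#' @return object of class `dotplot`: list with `protein_id` and `matrix`
#'   (integer N x N of 0/1).
#' @export
build_dotplot <- function(sequence, protein_id = NULL) {
  if (is.null(protein_id)) protein_id <- names(sequence) %||% "protein"
  sequence <- unname(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L)
  ch <- seq_chars(sequence)
  m <- outer(ch, ch, "==")
  storage.mode(m) <- "integer"
  structure(list(protein_id = protein_id, matrix = m), class = "dotplot")
}

# kernel window offsets: a width-k window anchored so that for k = 10 the
# window at pixel i spans i-4 .. i+5 (this anchor is what makes the -4/+5
# boundary expansion of called LCRs exact)
kernel_offsets <- function(kernel_size) {
  if (!is.numeric(kernel_size) || kernel_size < 1)
    stop("kernel_size must be a positive integer")
  k <- as.integer(kernel_size)
  c(lo = -(as.integer(ceiling(k / 2)) - 1L), hi = as.integer(floor(k / 2)))
}

#' Convolve a dotplot with a uniform kernel
#'
#' Each output pixel is the number of dots inside a `kernel_size` x
#' `kernel_size` window centred (for the default 10) on offsets -4..+5 in
#' both axes, with zero padding outside the matrix ("same" shape). Values
#' are integers in `[0, kernel_size^2]` (0..100 for the default).
#'
#' Implemented with a summed-area table, so it is exact integer counting,
#' not floating-point convolution.
#'
#' @param dp a `dotplot` from [build_dotplot()].
#' @param kernel_size window width, default 10.
#' @return object of class `intensity_matrix`: list with `protein_id`,
#'   `matrix` (integer N x N), `kernel_size`.
#' @export
convolve_dotplot <- function(dp, kernel_size = 10) {
  stopifnot(inherits(dp, "dotplot"))
  off <- kernel_offsets(kernel_size)
  m <- dp$matrix
  n <- nrow(m)
  # summed-area table: P[i+1, j+1] = sum(m[1..i, 1..j])
  P <- matrix(0, n + 1L, n + 1L)
  cs <- matrix(apply(m, 2L, cumsum), n, n)
  P[-1L, -1L] <- t(matrix(apply(cs, 1L, cumsum), n, n))
  i <- seq_len(n)
  r1 <- pmax(1L, i + off["lo"]); r2 <- pmin(n, i + off["hi"])
  out <- P[r2 + 1L, r2 + 1L, drop = FALSE] - P[r1, r2 + 1L, drop = FALSE] -
    P[r2 + 1L, r1, drop = FALSE] + P[r1, r1, drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  structure(list(protein_id = dp$protein_id, matrix = out,
                 kernel_size = as.integer(kernel_size)),
            class = "intensity_matrix")
}

# Stream the rows of the convolved intensity matrix of one sequence without
# materialising the dotplot or the intensity matrix: O(N) memory. Calls
# `row_fun(intensities, i)` for each row i. Exact same numbers as
# convolve_dotplot (asserted in the tests).
stream_intensity_rows <- function(sequence, kernel_size, row_fun) {
  ch <- seq_chars(sequence)
  n <- length(ch)
  off <- kernel_offsets(kernel_size)
  lo <- off[["lo"]]; hi <- off[["hi"]]
  # band = per-column dot counts over dotplot rows max(1,i+lo)..min(n,i+hi)
  band <- integer(n)
  for (r in seq_len(min(n, 1L + hi))) band <- band + (ch == ch[r])
  j <- seq_len(n)
  j1 <- pmax(1L, j + lo); j2 <- pmin(n, j + hi)
  for (i in seq_len(n)) {
    if (i > 1L) {
      add <- i + hi; drop <- i + lo - 1L
      if (add <= n) band <- band + (ch == ch[add])
      if (drop >= 1L) band <- band - (ch == ch[drop])
    }
    cs <- c(0L, cumsum(band))
    row_fun(cs[j2 + 1L] - cs[j1], i)
  }
  invisible(NULL)
}
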