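#' Shannon entropy of a residue sequence
#'
#' `H = -sum(f_a * log(f_a))` over the frequencies of the characters
#' present in the sequence. Base 2 gives bits; the comparison tests in this
#' package are base-invariant.
#'
#' @param sequence residue string, length >= 1.
#' @param base logarithm base, default 2.
#' @return entropy (0 for a homopolymer, up to `log(min(20, L), base)`).
#' @export
shannon_entropy <- function(sequence, base = 2) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 1L) stop("empty sequence")
  f <- table(seq_chars(sequence))
  f <- f / sum(f)
  -sum(f * log(f, base = base))
}

#' Sample a length-matched random sequence from a proteome
#'
#' All proteins are concatenated in file order into one string of length T;
#' a start position is drawn uniformly from the valid starts and the
#' substring of length `L` is returned. Draws may span protein boundaries,
#' which is exactly what uniform position sampling over the concatenation
#' allows; set `span_boundaries = FALSE` to redraw until the sample lies
#' within one protein.
#'
#' @param proteome a [proteome()].
#' @param L sample length, `1 <= L <= total_length(proteome)`.
#' @param seed optional seed; omit to use the current RNG state (so that a
#'   caller can draw many samples under one seed).
#' @param span_boundaries allow samples crossing protein boundaries
#'   (default TRUE).
#' @return a residue string of length L
#' @export
sample_length_matched <- function(proteome, L, seed = NULL,
                                  span_boundaries = TRUE) {
  stopifnot(inherits(proteome, "proteome"))
  L <- as.integer(L)
  concat <- paste(proteome$sequences, collapse = "")
  total <- nchar(concat)
  if (L > total) stop("sample length ", L, " exceeds proteome length ", total)
  draw <- function() {
    if (span_boundaries) {
      start <- sample.int(total - L + 1L, 1L)
      return(substr(concat, start, start + L - 1L))
    }
    ends <- cumsum(nchar(proteome$sequences))
    starts <- c(1L, head(ends, -1L) + 1L)
    repeat {
      start <- sample.int(total - L + 1L, 1L)
      prot <- findInterval(start, starts)
      if (start + L - 1L <= ends[prot])
        return(substr(concat, start, start + L - 1L))
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Compare called-LCR entropy with length-matched random samples
#'
#' For each LCR one random length-matched sequence is sampled from the
#' proteome and both entropies are computed; a one-sided Wilcoxon rank-sum
#' test asks whether LCR entropies are lower. Truly low-complexity calls
#' give a small p-value; random calls do not.
#'
#' @param calls LCR calls (needs `sequence`), >= 2 rows.
#' @param proteome the proteome the calls came from.
#' @param seed seed for the sampling.
#' @param base entropy logarithm base, default 2.
#' @return object of class `entropy_comparison`: list with
#'   `lcr_entropies`, `matched_entropies`, `test_statistic` (rank-sum W),
#'   `p_value`.
#' @export
entropy_validation <- function(calls, proteome, seed = 1L, base = 2) {
  if (nrow(calls) < 2L) stop("need at least 2 LCR calls")
  lcr_h <- vapply(calls$sequence, shannon_entropy, numeric(1L),
                  base = base, USE.NAMES = FALSE)
  matched <- withr::with_seed(seed, {
    vapply(nchar(calls$sequence),
           function(L) sample_length_matched(proteome, L),
           character(1L))
  })
  matched_h <- vapply(matched, shannon_entropy, numeric(1L),
                      base = base, USE.NAMES = FALSE)
  wt <- stats::wilcox.test(lcr_h, matched_h, alternative = "less",
                           exact = FALSE, correct = TRUE)
  structure(list(lcr_entropies = lcr_h, matched_entropies = matched_h,
                 test_statistic = unname(wt$statistic),
                 p_value = wt$p.value, seed = as.integer(seed)),
            class = "entropy_comparison")
}

#' @export
print.entropy_comparison <- function(x, ...) {
  cat(sprintf(
    "<entropy comparison: %d LCRs, mean %.3f vs %.3f bits, rank-sum p = %.3g>\n",
    length(x$lcr_entropies), mean(x$lcr_entropies),
    mean(x$matched_entropies), x$p_value))
  invisible(x)
}
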