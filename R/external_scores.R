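#' Mean per-LCR value of an external per-position score
#'
#' Predictors such as disorder or binding-propensity tools score every
#' residue of a protein; this attaches their mean over each LCR interval
#' to the calls, without re-implementing the predictor.
#'
#' @param scores named list: protein_id -> numeric vector spanning the
#'   full protein (one value per residue), or a long-format data.frame
#'   with columns protein_id, position, score.
#' @param calls LCR calls (needs protein_id, lcr_index, start, stop).
#' @param score_name label for the score column, default "score".
#' @return data.frame: protein_id, lcr_index, score_name, value
#' @export
mean_score_per_lcr <- function(scores, calls, score_name = "score") {
  if (is.data.frame(scores)) {
    stopifnot(all(c("protein_id", "position", "score") %in% names(scores)))
    scores <- lapply(split(scores, scores$protein_id), function(x) {
      v <- numeric(max(x$position))
      v[] <- NA_real_
      v[x$position] <- x$score
      v
    })
  }
  vals <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    pid <- calls$protein_id[i]
    v <- scores[[pid]]
    if (is.null(v)) stop("no scores for protein ", pid)
    if (calls$stop[i] > length(v))
      stop("score vector for ", pid, " shorter than protein (",
           length(v), " < ", calls$stop[i], ")")
    vals[i] <- mean(v[calls$start[i]:calls$stop[i]])
  }
  data.frame(protein_id = calls$protein_id, lcr_index = calls$lcr_index,
             score_name = score_name, value = vals,
             stringsAsFactors = FALSE)
}

#' Read a per-position score table
#' @param path TSV with columns protein_id, position, score.
#' @return data.frame suitable for [mean_score_per_lcr()]
#' @export
read_score_table <- function(path) {
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "position", "score") %in% names(x)))
  x
}
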