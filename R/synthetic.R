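#' Generate a synthetic proteome with planted low-entropy blocks
#'
#' Background residues are drawn i.i.d. from a configurable composition
#' (uniform over the 20 standard amino acids by default, so a uniform null
#' proteome is exactly composition-matched to the background). Into each
#' protein, low-entropy blocks are planted at random positions with at
#' least `spacing` background residues between blocks and from the
#' protein ends. Blocks built from the same alphabet share a planted type
#' label, giving ground truth for type/copy-number recovery.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer length range, inclusive; each protein's
#'   length is drawn uniformly from it.
#' @param blocks per-protein block specification: a list of block specs,
#'   each a list with `len` (block length) and `alphabet` (one or two
#'   residue letters; at most two so planted entropy is <= 1 bit), applied
#'   to every protein; or a list of such lists, one per protein (recycled).
#' @param background "uniform20" or a named numeric composition over
#'   residues (normalised internally).
#' @param seed RNG seed.
#' @param spacing minimum background run between blocks and protein ends,
#'   default 10.
#' @return object of class `planted_proteome`: list with `proteome` (a
#'   [proteome()], ids `syn_1`...) and `truth` (data.frame: protein_id,
#'   start, stop, block_composition, planted_type_label)
#' @export
make_planted_proteome <- function(n_proteins, length_range = c(300L, 500L),
                                  blocks = list(list(len = 20L,
                                                     alphabet = "K")),
                                  background = "uniform20", seed = 1L,
                                  spacing = 10L) {
  stopifnot(n_proteins >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L])
  per_protein <- if (length(blocks) > 0L && is.list(blocks[[1L]]) &&
                     !is.null(blocks[[1L]]$len)) {
    rep(list(blocks), n_proteins)           # one spec for all proteins
  } else {
    rep(blocks, length.out = n_proteins)    # one spec per protein
  }
  if (identical(background, "uniform20")) {
    bg_letters <- AA20; bg_prob <- rep(1 / 20, 20L)
  } else {
    stopifnot(is.numeric(background), !is.null(names(background)))
    bg_letters <- names(background); bg_prob <- background / sum(background)
  }
  withr::with_seed(as.integer(seed), {
    seqs <- character(n_proteins)
    truth <- vector("list", n_proteins)
    for (p in seq_len(n_proteins)) {
      L <- length_range[1L] +
        sample.int(length_range[2L] - length_range[1L] + 1L, 1L) - 1L
      spec <- per_protein[[p]]
      lens <- vapply(spec, function(b) as.integer(b$len), integer(1L))
      alphabets <- lapply(spec, function(b) {
        a <- b$alphabet
        if (length(a) == 1L && nchar(a) > 1L) a <- seq_chars(a)
        if (length(a) > 2L)
          stop("block alphabet larger than 2 letters (entropy > 1 bit)")
        toupper(a)
      })
      m <- length(lens)
      extra <- L - sum(lens) - spacing * (m + 1L)
      if (extra < 0L)
        stop("blocks do not fit in protein of length ", L,
             " with spacing ", spacing)
      gap_extra <- if (m >= 0L && extra > 0L)
        tabulate(sample.int(m + 1L, extra, replace = TRUE), m + 1L)
      else rep(0L, m + 1L)
      gaps <- spacing + gap_extra
      bg <- function(n) if (n == 0L) character(0) else
        sample(bg_letters, n, replace = TRUE, prob = bg_prob)
      pieces <- character(0)
      starts <- integer(m); pos <- 0L
      for (b in seq_len(m + 1L)) {
        pieces <- c(pieces, bg(gaps[b])); pos <- pos + gaps[b]
        if (b <= m) {
          block <- sample(alphabets[[b]], lens[b], replace = TRUE)
          pieces <- c(pieces, block)
          starts[b] <- pos + 1L
          pos <- pos + lens[b]
        }
      }
      seqs[p] <- paste(pieces, collapse = "")
      stopifnot(nchar(seqs[p]) == L)
      if (m > 0L) {
        labels <- vapply(alphabets, function(a)
          paste(sort(a), collapse = ""), character(1L))
        truth[[p]] <- data.frame(
          protein_id = paste0("syn_", p),
          start = starts, stop = starts + lens - 1L,
          block_composition = labels,
          planted_type_label = labels,
          stringsAsFactors = FALSE)
      }
    }
    names(seqs) <- paste0("syn_", seq_len(n_proteins))
    truth_df <- do.call(rbind, truth[!vapply(truth, is.null, logical(1L))])
    if (is.null(truth_df))
      truth_df <- data.frame(protein_id = character(0), start = integer(0),
                             stop = integer(0),
                             block_composition = character(0),
                             planted_type_label = character(0))
    structure(list(proteome = proteome(seqs, name = "synthetic"),
                   truth = truth_df, seed = as.integer(seed)),
              class = "planted_proteome")
  })
}

#' Write the planted truth table
#' @param planted a `planted_proteome`
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_truth_table <- function(planted, path) {
  stopifnot(inherits(planted, "planted_proteome"))
  write.table(planted$truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Compare called LCRs with planted truth
#'
#' A planted block is recovered if exactly one call overlaps it; coverage
#' is the fraction of the planted interval inside that call.
#'
#' @param calls LCR calls.
#' @param truth truth table from [make_planted_proteome()].
#' @return data.frame: one row per planted block with `n_overlapping`
#'   (calls overlapping it), `recovered` (exactly one), `coverage`
#' @export
score_planted_recovery <- function(calls, truth) {
  out <- truth
  out$n_overlapping <- 0L
  out$coverage <- 0
  for (i in seq_len(nrow(truth))) {
    cc <- calls[calls$protein_id == truth$protein_id[i], , drop = FALSE]
    if (nrow(cc) == 0L) next
    ov_len <- pmin(cc$stop, truth$stop[i]) - pmax(cc$start, truth$start[i]) + 1L
    hit <- ov_len > 0L
    out$n_overlapping[i] <- sum(hit)
    if (any(hit))
      out$coverage[i] <- max(ov_len[hit]) /
        (truth$stop[i] - truth$start[i] + 1L)
  }
  out$recovered <- out$n_overlapping == 1L
  out
}
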