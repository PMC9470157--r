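# shared fixtures, all generated in code

# write a FASTA file from a named character vector, return the path
write_fasta_tmp <- function(seqs, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = env)
  lines <- unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]])))
  writeLines(lines, path)
  path
}

# LCR calls for a clean two-island composition set: n_per planted poly-K
# proteins and n_per planted poly-E proteins, one 25-mer block each, with
# the pipeline's -4/+5 flank attached so compositions vary within islands
two_island_calls <- function(seed, n_per = 250) {
  pp <- make_planted_proteome(
    2L * n_per, c(60L, 80L),
    blocks = list(list(list(len = 25L, alphabet = "K")),
                  list(list(len = 25L, alphabet = "E"))),
    seed = seed)
  tr <- pp$truth
  seqs <- pp$proteome$sequences[tr$protein_id]
  lens <- nchar(seqs)
  st <- pmax(1L, tr$start - 4L)
  en <- pmin(lens, tr$stop + 5L)
  data.frame(protein_id = tr$protein_id, lcr_index = 1L,
             start = st, stop = en, length = en - st + 1L,
             sequence = unname(substring(seqs, st, en)),
             island = tr$planted_type_label,
             stringsAsFactors = FALSE)
}

# integer identity matrix
int_diag <- function(n) {
  d <- diag(n)
  storage.mode(d) <- "integer"
  d
}

# purity of a clustering against a reference partition
cluster_purity <- function(labels, truth) {
  tab <- table(labels, truth)
  sum(apply(tab, 1L, max)) / sum(tab)
}

# brute-force 2-D window-count oracle for the convolution contract
naive_window_counts <- function(m, kernel_size) {
  n <- nrow(m)
  lo <- -(ceiling(kernel_size / 2) - 1L)
  hi <- floor(kernel_size / 2)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    rs <- max(1L, i + lo):min(n, i + hi)
    cs <- max(1L, j + lo):min(n, j + hi)
    out[i, j] <- sum(m[rs, cs])
  }
  out
}
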