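#' Construct a proteome object
#'
#' A proteome is an ordered set of uniquely identified protein sequences.
#' Order is preserved everywhere (it defines the concatenation used by
#' [sample_length_matched()]).
#'
#' @param sequences named character vector of uppercase residue strings;
#'   names are protein ids, unique and non-empty.
#' @param name short label for the proteome (used as species tag downstream).
#' @return An object of class `proteome`: a list with elements `sequences`
#'   and `name`.
#' @export
proteome <- function(sequences, name = "proteome") {
  if (length(sequences) == 0L) stop("no records")
  ids <- names(sequences)
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop("all sequences must be named by a protein id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  sequences <- toupper(sequences)
  if (any(grepl("[[:space:]]", sequences)))
    stop("sequences must not contain whitespace")
  if (any(nchar(sequences) < 1L)) stop("zero-length sequence")
  structure(list(sequences = sequences, name = name), class = "proteome")
}

#' @export
length.proteome <- function(x) length(x$sequences)

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome '%s': %d proteins, %d residues>\n",
              x$name, length(x$sequences), total_length(x)))
  invisible(x)
}

#' Total residue count of a proteome
#' @param x a `proteome`
#' @return integer, sum of sequence lengths
#' @export
total_length <- function(x) sum(nchar(x$sequences))

#' Protein sequence lengths
#' @param x a `proteome`
#' @return named integer vector of lengths, in file order
#' @export
protein_lengths <- function(x) {
  stats::setNames(nchar(x$sequences), names(x$sequences))
}

#' Read a proteome from a FASTA file
#'
#' One record per protein. The protein id is the first whitespace-delimited
#' token of the header; with `uniprot_accession = TRUE` the accession between
#' the pipes of a UniProt-style `db|ACCESSION|NAME` id is extracted instead.
#' Sequences are uppercased and a trailing stop character `*` is stripped;
#' non-standard residue letters (X, U, O, B, Z) are retained, because
#' dotplot matching is defined on characters.
#'
#' @param path FASTA file, plain or gzipped.
#' @param name proteome label; defaults to the file name without extension.
#' @param uniprot_accession if TRUE, extract the accession from
#'   `db|ACC|NAME` ids.
#' @return a [proteome()] object
#' @export
read_proteome <- function(path, name = NULL,
                          uniprot_accession = FALSE) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  if (uniprot_accession) {
    piped <- grepl("^[^|]+\\|[^|]+\\|", ids)
    ids[piped] <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", ids[piped])
  }
  descr <- ifelse(grepl("[[:space:]]", headers),
                  sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence in ", path)
  names(seqs) <- ids
  p <- proteome(seqs, name = name %||%
                  sub("\\.(fa|fasta|faa)(\\.gz)?$", "", basename(path)))
  attr(p, "descriptions") <- stats::setNames(descr, ids)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a proteome to a FASTA file
#' @param x a `proteome`
#' @param path output file (plain FASTA)
#' @return `path`, invisibly
#' @export
write_proteome <- function(x, path) {
  stopifnot(inherits(x, "proteome"))
  set <- Biostrings::AAStringSet(x$sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an annotation set (a FASTA subset of the proteome)
#'
#' Annotation files list the proteins belonging to some group (for example a
#' subcellular location export). Ids are matched exactly against the
#' proteome; ids absent from the proteome are counted, reported with a
#' message, and dropped.
#'
#' @param path FASTA file of annotated proteins.
#' @param proteome the reference [proteome()].
#' @param name annotation label; defaults to the file name.
#' @param uniprot_accession as in [read_proteome()].
#' @return object of class `annotation_set`: list with `name` and
#'   `protein_ids` (character vector, unique, all present in `proteome`).
#' @export
read_annotation <- function(path, proteome, name = NULL,
                            uniprot_accession = FALSE) {
  stopifnot(inherits(proteome, "proteome"))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  ids <- sub("[[:space:]].*$", "", names(set))
  if (uniprot_accession) {
    piped <- grepl("^[^|]+\\|[^|]+\\|", ids)
    ids[piped] <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", ids[piped])
  }
  ids <- unique(ids)
  keep <- ids %in% names(proteome$sequences)
  if (!any(keep)) stop("annotation does not match proteome: ",
                       "0 of ", length(ids), " ids found")
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(n_drop, " annotation id(s) not in proteome; dropped")
  annotation_set(ids[keep],
                 name = name %||%
                   sub("\\.(fa|fasta|faa)(\\.gz)?$", "", basename(path)))
}

#' Construct an annotation set from protein ids
#' @param protein_ids character vector of protein ids
#' @param name label, e.g. "nucleolus"
#' @return an `annotation_set`
#' @export
annotation_set <- function(protein_ids, name = "annotation") {
  stopifnot(is.character(protein_ids))
  structure(list(name = name, protein_ids = unique(protein_ids)),
            class = "annotation_set")
}

# ---- LCR table IO ----------------------------------------------------------

lcr_table_cols <- c("protein_id", "lcr_index", "start", "stop", "length",
                    "sequence", "type_id", "type_copy_number", "entropy_bits")

#' Write a table of LCR calls to TSV
#'
#' Coordinates are 1-based inclusive. Rows must be sorted by
#' (protein_id, start) with per-protein non-overlapping intervals and
#' `lcr_index` numbering 1..n from N- to C-terminus.
#'
#' @param calls data.frame of LCR calls as produced by [call_proteome()].
#' @param path output TSV path.
#' @return `path`, invisibly
#' @export
write_lcr_table <- function(calls, path) {
  calls <- validate_lcr_calls(calls)
  write.table(calls[, lcr_table_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a table of LCR calls from TSV
#' @param path TSV written by [write_lcr_table()].
#' @return data.frame of LCR calls
#' @export
read_lcr_table <- function(path) {
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(protein_id = "character",
                                 sequence = "character"))
  missing <- setdiff(lcr_table_cols, names(x))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(x) > 0L) validate_lcr_calls(x) else x
}

# shared invariants for LCR call tables; returns the table sorted check passed
validate_lcr_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  missing <- setdiff(lcr_table_cols, names(calls))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(calls) == 0L) return(calls)
  if (any(calls$start < 1L) || any(calls$stop < calls$start))
    stop("invalid interval: need 1 <= start <= stop")
  if (any(calls$length != calls$stop - calls$start + 1L))
    stop("length column inconsistent with start/stop")
  ord <- order(calls$protein_id, calls$start)
  if (!identical(ord, seq_len(nrow(calls))))
    stop("calls must be sorted by (protein_id, start)")
  by_prot <- split(seq_len(nrow(calls)), calls$protein_id)
  for (idx in by_prot) {
    if (!identical(calls$lcr_index[idx], seq_along(idx)))
      stop("lcr_index must number 1..n in N-to-C order within each protein")
    if (length(idx) > 1L) {
      s <- calls$start[idx]; e <- calls$stop[idx]
      if (any(s[-1L] <= e[-length(e)]))
        stop("overlapping LCR intervals within protein ",
             calls$protein_id[idx[1L]])
    }
  }
  calls
}
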