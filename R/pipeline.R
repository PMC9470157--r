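#' Default pipeline configuration
#'
#' All tunable constants of the pipeline in one place. Values are recorded
#' verbatim in the metadata of every pipeline run.
#'
#' @param ... overrides for individual fields.
#' @return named list of parameters (class `pipeline_config`)
#' @export
pipeline_config <- function(...) {
  cfg <- list(kernel_size = 10L, target_fdr = 0.002, pad_left = 4L,
              pad_right = 5L, connectivity = 8L, null_seed = 1L,
              n_null_reps = 1L, entropy_base = 2, embed_seed = 73L,
              cluster_seed = 73L, n_neighbors = 15L, cluster_k = 15L,
              resolution = 0.1, quartile_q = 0.75, enrichment_alpha = 0.001,
              min_map_size = 50L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(all(vapply(cfg, function(v) is.numeric(v) && v > 0, logical(1L))))
  structure(cfg, class = "pipeline_config")
}

#' Run the full LCR pipeline
#'
#' Per proteome: simulate its own length-matched null, calibrate the FDR
#' threshold, call and type LCRs, validate entropy. Across proteomes: one
#' pooled composition map (embedding + clustering, when at least
#' `min_map_size` LCRs exist) and per-annotation enrichment tables.
#' Thresholds are independent per proteome, so adding a species never
#' changes another species' calls.
#'
#' @param proteomes a [proteome()] or list of them.
#' @param annotations optional list of `annotation_set`s (enrichment is
#'   computed for each against all other LCRs).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the LCR tables, map CSV,
#'   enrichment TSVs and a `run_metadata.json` are written there.
#' @return list with `thresholds`, `calls` (named by proteome), `entropy`
#'   (comparison per proteome), `composition`, `embedding`, `clusters`,
#'   `cluster_names`, `enrichment` (per annotation), `metadata`
#' @export
run_pipeline <- function(proteomes, annotations = list(),
                         config = pipeline_config(), out_dir = NULL) {
  if (inherits(proteomes, "proteome")) proteomes <- list(proteomes)
  stopifnot(length(proteomes) >= 1L,
            all(vapply(proteomes, inherits, logical(1L), "proteome")))
  names(proteomes) <- vapply(proteomes, `[[`, character(1L), "name")
  cfg <- config

  thresholds <- list(); calls <- list(); entropy <- list()
  for (nm in names(proteomes)) {
    p <- proteomes[[nm]]
    thr <- tryCatch(
      lcr_threshold(p, target_fdr = cfg$target_fdr,
                    kernel_size = cfg$kernel_size, seed = cfg$null_seed,
                    n_null_reps = cfg$n_null_reps),
      error = function(e) stop("threshold stage failed for proteome '", nm,
                               "': ", conditionMessage(e), call. = FALSE))
    cl <- tryCatch(
      call_proteome(p, thr$threshold, kernel_size = cfg$kernel_size,
                    connectivity = cfg$connectivity,
                    pad_left = cfg$pad_left, pad_right = cfg$pad_right,
                    entropy_base = cfg$entropy_base),
      error = function(e) stop("calling stage failed for proteome '", nm,
                               "': ", conditionMessage(e), call. = FALSE))
    thresholds[[nm]] <- thr
    calls[[nm]] <- cl
    entropy[[nm]] <- if (nrow(cl) >= 2L)
      entropy_validation(cl, p, seed = cfg$null_seed,
                         base = cfg$entropy_base)
    else NULL
  }

  comp <- NULL; coords <- NULL; labels <- NULL; cnames <- NULL
  with_calls <- names(calls)[vapply(calls, nrow, integer(1L)) > 0L]
  if (length(with_calls) > 0L) {
    comps <- lapply(with_calls, function(nm)
      composition_matrix(calls[[nm]], species = nm))
    comp <- do.call(merge_compositions, comps)
    if (nrow(comp$matrix) >= cfg$min_map_size) {
      coords <- embed_lcrs(comp, n_neighbors = cfg$n_neighbors,
                           seed = cfg$embed_seed)
      labels <- cluster_lcrs(comp, k = cfg$cluster_k,
                             seed = cfg$cluster_seed,
                             resolution = cfg$resolution)
      cnames <- label_clusters(comp, labels)
    }
  }

  enrich <- list()
  if (length(annotations) > 0L && !is.null(comp)) {
    for (ann in annotations) {
      mask <- annotation_mask(comp, ann)
      enrich[[ann$name]] <- tryCatch(
        rank_sum_enrichment(comp, mask, alpha = cfg$enrichment_alpha),
        error = function(e) {
          message("enrichment skipped for '", ann$name, "': ",
                  conditionMessage(e))
          NULL
        })
    }
  }

  metadata <- list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("dotlcr")),
    proteomes = lapply(proteomes, function(p)
      list(name = p$name, n_proteins = length(p),
           total_length = total_length(p))),
    thresholds = lapply(thresholds, function(t)
      list(threshold = t$threshold, fdr_at_threshold = t$fdr_at_threshold,
           seed = t$seed)),
    n_lcrs = lapply(calls, nrow))

  result <- list(thresholds = thresholds, calls = calls, entropy = entropy,
                 composition = comp, embedding = coords, clusters = labels,
                 cluster_names = cnames, enrichment = enrich,
                 metadata = metadata)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result$calls))
    write_lcr_table(result$calls[[nm]],
                    file.path(out_dir, paste0(nm, "_lcrs.tsv")))
  if (!is.null(result$embedding)) {
    map <- data.frame(result$composition$meta,
                      umap1 = result$embedding[, 1L],
                      umap2 = result$embedding[, 2L],
                      cluster = result$clusters,
                      cluster_name =
                        result$cluster_names[as.character(result$clusters)],
                      stringsAsFactors = FALSE)
    write.table(map, file.path(out_dir, "lcr_map.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  }
  for (nm in names(result$enrichment)) {
    if (is.null(result$enrichment[[nm]])) next
    write.table(result$enrichment[[nm]],
                file.path(out_dir, paste0("enrichment_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$metadata,
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
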