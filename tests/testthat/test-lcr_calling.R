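# a segmented mask built directly from an intensity-like matrix
mask_from <- function(m, threshold = 1L, connectivity = 8L,
                      protein_id = "p") {
  im <- structure(list(protein_id = protein_id, matrix = m,
                       kernel_size = 10L), class = "intensity_matrix")
  segment_matrix(im, threshold, connectivity)
}

test_that("segmentation labels components under the chosen connectivity", {
  m <- matrix(0L, 8L, 8L)
  m[1:3, 1:3] <- 50L
  expect_identical(max(mask_from(m)$matrix), 1L)

  m2 <- m; m2[6:8, 6:8] <- 50L                # >= 2-pixel gap: 2 components
  expect_identical(max(mask_from(m2)$matrix), 2L)

  m3 <- m; m3[4:6, 4:6] <- 50L                # corner contact
  expect_identical(max(mask_from(m3)$matrix), 1L)
  expect_identical(max(mask_from(m3, connectivity = 4L)$matrix), 2L)
})

test_that("labels agree with the flood-fill oracle on random masks", {
  set.seed(21)
  for (rep in 1:6) {
    s <- paste(sample(c("K", "E", "A"), 60, replace = TRUE), collapse = "")
    thr <- sample(20:60, 1L)
    or <- brute_force_lcr_oracle(s, thr)
    im <- convolve_dotplot(build_dotplot(s, "p"))
    expect_identical(segment_matrix(im, thr)$matrix, or$labels)
  }
})

test_that("LCR calls are diagonal components, expanded and clamped", {
  n <- 100L
  m <- matrix(0L, n, n)
  m[20:40, 20:40] <- 99L
  calls <- call_lcrs(mask_from(m), strrep("K", n))
  expect_identical(calls$start, 16L)
  expect_identical(calls$stop, 45L)
  expect_identical(calls$length, 30L)

  # component reaching the protein start clamps to residue 1
  m2 <- matrix(0L, 20L, 20L)
  m2[1:12, 1:12] <- 99L
  calls2 <- call_lcrs(mask_from(m2), strrep("K", 20L))
  expect_identical(calls2$start, 1L)
  expect_identical(calls2$stop, 17L)

  # an entirely off-diagonal component contributes no LCR
  m3 <- matrix(0L, 30L, 30L)
  m3[1:5, 20:25] <- 99L
  m3[20:25, 1:5] <- 99L
  expect_identical(nrow(call_lcrs(mask_from(m3), strrep("K", 30L))), 0L)

  # an off-diagonal lobe does not extend the diagonal extent
  m4 <- matrix(0L, 40L, 40L)
  m4[10:20, 10:20] <- 99L
  m4[10:20, 21:35] <- 99L   # lobe of same component, off diagonal
  calls4 <- call_lcrs(mask_from(m4), strrep("K", 40L))
  expect_identical(calls4$start, 6L)
  expect_identical(calls4$stop, 25L)
})

test_that("colliding expanded intervals merge into one call", {
  m <- matrix(0L, 60L, 60L)
  m[10:20, 10:20] <- 99L
  m[24:30, 24:30] <- 99L    # gap 3 < pad_left + pad_right
  calls <- call_lcrs(mask_from(m), strrep("K", 60L))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$start, 6L)
  expect_identical(calls$stop, 35L)
  expect_identical(calls$lcr_index, 1L)
})

test_that("off-diagonal intersections define type edges", {
  pp <- make_planted_proteome(
    1L, c(120L, 120L),
    blocks = list(list(len = 18L, alphabet = "K"),
                  list(len = 18L, alphabet = "K")), seed = 31L)
  s <- pp$proteome$sequences[[1L]]
  im <- convolve_dotplot(build_dotplot(s, "syn_1"))
  mask <- segment_matrix(im, 45L)
  calls <- call_lcrs(mask, s)
  expect_identical(nrow(calls), 2L)
  edges <- find_type_edges(mask, calls)
  expect_identical(unname(edges), matrix(c(1L, 2L), ncol = 2L))

  # disjoint alphabets: no cross matches, no edge
  pp2 <- make_planted_proteome(
    1L, c(120L, 120L),
    blocks = list(list(len = 18L, alphabet = "K"),
                  list(len = 18L, alphabet = "E")), seed = 32L)
  s2 <- pp2$proteome$sequences[[1L]]
  im2 <- convolve_dotplot(build_dotplot(s2, "syn_1"))
  mask2 <- segment_matrix(im2, 45L)
  calls2 <- call_lcrs(mask2, s2)
  expect_identical(nrow(calls2), 2L)
  expect_identical(nrow(find_type_edges(mask2, calls2)), 0L)

  # single call: empty edge set
  expect_identical(nrow(find_type_edges(mask2, calls2[1L, ])), 0L)
})

test_that("types are connected components with copy numbers", {
  calls <- data.frame(protein_id = "p", lcr_index = 1:2,
                      start = c(1L, 30L), stop = c(10L, 40L),
                      length = c(10L, 11L), sequence = c("A", "B"),
                      stringsAsFactors = FALSE)
  one_edge <- matrix(c(1L, 2L), ncol = 2L,
                     dimnames = list(NULL, c("a", "b")))
  ty <- assign_types(calls, one_edge)
  expect_identical(ty$calls$type_id, c(1L, 1L))
  expect_identical(ty$calls$type_copy_number, c(2L, 2L))

  no_edge <- matrix(integer(0), ncol = 2L)
  ty2 <- assign_types(calls, no_edge)
  expect_identical(ty2$calls$type_id, c(1L, 2L))
  expect_identical(ty2$calls$type_copy_number, c(1L, 1L))

  # transitivity: 3 nodes chained -> one type of size 3
  calls3 <- rbind(calls, data.frame(protein_id = "p", lcr_index = 3L,
                                    start = 60L, stop = 70L, length = 11L,
                                    sequence = "C"))
  chain <- matrix(c(1L, 2L, 2L, 3L), ncol = 2L, byrow = TRUE)
  ty3 <- assign_types(calls3, chain)
  expect_identical(ty3$calls$type_id, rep(1L, 3L))
  expect_identical(ty3$calls$type_copy_number, rep(3L, 3L))
  expect_identical(length(ty3$graph$components), 1L)
})

test_that("protein groups follow the total/distinct scheme", {
  expect_identical(classify_protein(1L, 1L), "single")
  expect_identical(classify_protein(3L, 1L), "multiple-same")
  expect_identical(classify_protein(22L, 4L), "multiple-mixed")
  expect_identical(classify_protein(3L, 3L), "multiple-distinct")
  expect_error(classify_protein(2L, 3L), "distinct")
  expect_error(classify_protein(2L, 0L), "distinct")
})

test_that("total-vs-distinct table counts proteins consistently", {
  calls <- data.frame(
    protein_id = c("a", "b", "c", "c"),
    lcr_index = c(1L, 1L, 1L, 2L),
    type_id = c(1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  tab <- total_vs_distinct_table(calls)
  expect_identical(tab$n_proteins[tab$total == 1L & tab$distinct == 1L], 2L)
  expect_identical(tab$n_proteins[tab$total == 2L & tab$distinct == 1L], 1L)
  expect_identical(sum(tab$n_proteins), length(unique(calls$protein_id)))
  expect_identical(nrow(total_vs_distinct_table(calls[0, ])), 0L)
})

test_that("protein graphs round-trip through JSON", {
  pp <- make_planted_proteome(
    3L, c(150L, 200L),
    blocks = list(list(len = 18L, alphabet = "K"),
                  list(len = 18L, alphabet = "K")), seed = 77L)
  calls <- call_proteome(pp$proteome, 45L, keep_graphs = TRUE)
  graphs <- attr(calls, "graphs")
  expect_gte(length(graphs), 1L)
  for (nm in names(graphs)) {
    path <- withr::local_tempfile(fileext = ".json")
    cc <- calls[calls$protein_id == nm, ]
    export_protein_graph(graphs[[nm]], cc, path)
    back <- import_protein_graph(path)
    expect_identical(back$protein_id, nm)
    expect_identical(back$nodes$lcr_index, cc$lcr_index)
    expect_identical(back$nodes$start, cc$start)
    expect_identical(back$nodes$type_id, cc$type_id)
    expect_identical(back$edges$a, unname(graphs[[nm]]$edges[, "a"]))
    expect_identical(back$edges$b, unname(graphs[[nm]]$edges[, "b"]))
  }
  # empty graph is valid JSON with empty lists
  ty <- assign_types(calls[0, c("protein_id", "lcr_index", "start", "stop",
                                "length", "sequence")],
                     matrix(integer(0), ncol = 2L))
  path <- withr::local_tempfile(fileext = ".json")
  export_protein_graph(ty$graph, ty$calls, path)
  back <- import_protein_graph(path)
  expect_identical(nrow(back$nodes), 0L)
  expect_identical(nrow(back$edges), 0L)
})

test_that("calling is deterministic and writes byte-identical tables", {
  pp <- make_planted_proteome(10L, c(100L, 160L),
                              blocks = list(list(len = 16L,
                                                 alphabet = "KE")),
                              seed = 12L)
  c1 <- call_proteome(pp$proteome, 40L)
  c2 <- call_proteome(pp$proteome, 40L)
  expect_identical(c1, c2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_lcr_table(c1, f1); write_lcr_table(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
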