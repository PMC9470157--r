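test_that("composition rows are frequencies over standard residues", {
  calls <- data.frame(protein_id = c("p1", "p2", "p3"),
                      lcr_index = 1L,
                      sequence = c("KKKK", "KKEE", "KKXK"),
                      stringsAsFactors = FALSE)
  comp <- composition_matrix(calls)
  expect_equal(unname(comp$matrix[1L, "K"]), 1)
  expect_equal(unname(comp$matrix[2L, c("K", "E")]), c(0.5, 0.5))
  expect_equal(unname(comp$matrix[3L, "K"]), 1)     # X dropped from denom
  expect_equal(unname(rowSums(comp$matrix)), rep(1, 3L))

  allx <- data.frame(protein_id = "p", lcr_index = 1L, sequence = "XXX",
                     stringsAsFactors = FALSE)
  expect_error(suppressWarnings(composition_matrix(allx)), "no LCRs")
  mixed <- rbind(calls, allx)
  expect_warning(comp2 <- composition_matrix(mixed), "dropped")
  expect_identical(nrow(comp2$matrix), 3L)
})

test_that("embedding is deterministic and separates planted islands", {
  calls <- two_island_calls(seed = 51L, n_per = 120L)
  comp <- composition_matrix(calls)
  co1 <- embed_lcrs(comp, seed = 73L)
  co2 <- embed_lcrs(comp, seed = 73L)
  expect_identical(co1, co2)
  expect_true(all(is.finite(co1)))
  expect_identical(rownames(co1), rownames(comp$matrix))

  # two-group silhouette on the 2-D coordinates
  isl <- calls$island
  d <- as.matrix(dist(co1))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- setdiff(which(isl == isl[i]), i)
    a <- mean(d[i, own])
    b <- mean(d[i, isl != isl[i]])
    (b - a) / max(a, b)
  }, numeric(1L))
  expect_gt(mean(sil), 0.8)

  expect_error(embed_lcrs(composition_matrix(calls[1:10, ])),
               "n_neighbors")
})

test_that("clustering recovers planted islands and handles degeneracy", {
  calls <- two_island_calls(seed = 52L, n_per = 150L)
  comp <- composition_matrix(calls)
  lab <- cluster_lcrs(comp)
  expect_length(lab, nrow(comp$matrix))
  expect_identical(length(unique(lab)), 2L)
  expect_gt(cluster_purity(lab, calls$island), 0.99)

  # all-identical compositions: one cluster by definition
  same <- data.frame(protein_id = paste0("p", 1:30), lcr_index = 1L,
                     sequence = strrep("K", 20L), stringsAsFactors = FALSE)
  expect_identical(unique(cluster_lcrs(composition_matrix(same))), 1L)
})

test_that("cluster outputs are invariant to row permutation", {
  calls <- two_island_calls(seed = 53L, n_per = 100L)
  comp <- composition_matrix(calls)
  lab <- cluster_lcrs(comp)
  perm <- withr::with_seed(3L, sample(nrow(comp$matrix)))
  comp_p <- comp
  comp_p$matrix <- comp$matrix[perm, ]
  comp_p$meta <- comp$meta[perm, ]
  lab_p <- cluster_lcrs(comp_p)
  # same partition (labels renumbered by first appearance)
  expect_gt(cluster_purity(lab_p, lab[perm]), 0.999)
  expect_identical(length(unique(lab_p)), length(unique(lab)))
})

test_that("cluster names join dominant residues by mean frequency", {
  mk <- function(freqs) {
    m <- matrix(rep(freqs, each = 4L), nrow = 4L,
                dimnames = list(NULL,
                                c("A", "C", "D", "E", "F", "G", "H", "I",
                                  "K", "L", "M", "N", "P", "Q", "R", "S",
                                  "T", "V", "W", "Y")))
    structure(list(matrix = m,
                   meta = data.frame(protein_id = paste0("p", 1:4),
                                     lcr_index = 1L,
                                     species = "s")),
              class = "lcr_composition")
  }
  pure_k <- numeric(20L); names(pure_k) <- colnames(mk(numeric(20L))$matrix)
  pure_k["K"] <- 1
  expect_identical(unname(label_clusters(mk(pure_k), rep(1L, 4L))), "K")

  gp <- numeric(20L); names(gp) <- names(pure_k)
  gp["G"] <- 0.30; gp["P"] <- 0.25         # P/G = 0.83: in at 0.5, out at 0.9
  rest <- setdiff(names(gp), c("G", "P"))
  gp[rest] <- (1 - 0.55) / length(rest)    # all < 0.1
  expect_identical(unname(label_clusters(mk(gp), rep(1L, 4L))), "G/P")
  expect_identical(unname(label_clusters(mk(gp), rep(1L, 4L), frac = 0.9)),
                   "G")
})

test_that("quartile enrichment selects the top fraction with ties", {
  f <- c(0.0, 0.1, 0.2, 0.9)
  m <- matrix(0, 4L, 20L, dimnames = list(NULL, colnames(
    composition_matrix(data.frame(protein_id = "p", lcr_index = 1L,
                                  sequence = "K"))$matrix)))
  m[, "E"] <- f
  m[, "K"] <- 1 - f
  comp <- structure(list(matrix = m,
                         meta = data.frame(protein_id = paste0("p", 1:4),
                                           lcr_index = 1L,
                                           species = "s")),
                    class = "lcr_composition")
  sel <- quartile_enriched(comp, "E", reference_rows = 1:4)
  expect_identical(unname(which(sel)), 4L)

  m2 <- m; m2[, "E"] <- 0.5; m2[, "K"] <- 0.5
  comp2 <- comp; comp2$matrix <- m2
  expect_identical(sum(quartile_enriched(comp2, "E", 1:4)), 4L)

  expect_error(quartile_enriched(comp, "E", integer(0)), "empty")

  # both-enrichment is the AND of two masks
  both <- quartile_enriched(comp, "E", 1:4) &
    quartile_enriched(comp, "K", 1:4)
  expect_identical(sum(both), 0L)
})

test_that("cluster occupancy is a consistent contingency table", {
  labels <- c(rep(1L, 10L), rep(2L, 10L))
  species <- c(rep("human", 10L), rep("yeast", 10L))
  tab <- cluster_occupancy(labels, species)
  expect_identical(unname(tab["human", "1"]), 10L)
  expect_identical(unname(tab["yeast", "2"]), 10L)
  expect_identical(sum(tab), 20L)
  shuf <- withr::with_seed(4L, sample(species))
  tab2 <- cluster_occupancy(labels, shuf)
  expect_identical(rowSums(tab2), rowSums(tab))  # marginals preserved
})
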