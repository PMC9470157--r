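# dotlcr

Low complexity regions (LCRs) — protein segments dominated by one or a few
residue types, such as poly-K stretches or G/P-rich repeats — are central to
higher order assemblies like the nucleolus, nuclear speckles, the
extracellular matrix and the fungal cell wall. `dotlcr` detects LCRs in any
proteome, determines how many *types* of LCR each protein carries and in how
many copies, and places every LCR on a 2-D amino-acid-composition map with
clustering and annotation enrichment. It is aimed at anyone studying
compositionally biased regions: no external predictors or databases are
needed, and the whole pipeline can be exercised on synthetic proteomes with
planted ground truth.

## Method

The core idea is to treat a protein's self-comparison dotplot as an image:

1. **Dotplot** — for a sequence of length N, build the N×N binary matrix
   with `D[i,j] = 1` iff residues i and j are identical. Repeats and
   compositional bias appear as dense blocks.
2. **Convolution** — convolve `D` with a uniform 10×10 kernel, giving each
   pixel an integer intensity 0–100: the number of dots in the window
   spanning offsets −4..+5 around it.
3. **FDR threshold** — simulate a length-matched *null proteome* with
   residues drawn i.i.d. uniformly over the 20 amino acids, pool convolved
   intensities from real and null proteomes, and pick the smallest
   intensity t with

   FDR(t) = null≥t / (real≥t + null≥t) ≤ 0.002.

4. **Segmentation & calling** — threshold every protein's convolved dotplot
   and label connected components (8-connectivity). Components touching the
   diagonal are LCRs: the call spans the component's diagonal extent,
   widened by −4/+5 to undo the kernel's boundary erosion and clamped to
   the protein.
5. **Types and copy numbers** — an off-diagonal component at the
   intersection of two called LCRs means their sequences match each other.
   In the per-protein graph (LCRs = nodes, intersections = edges) each
   connected component is one LCR *type*; its size is the copy number.
   Proteins are grouped as `single`, `multiple-same`, `multiple-distinct`
   or `multiple-mixed` from their total and distinct LCR counts.
6. **Validation & mapping** — called LCRs are confirmed low complexity by
   comparing their Shannon entropies against length-matched sequences
   sampled from the proteome (one-sided rank-sum test). Each LCR's residue
   frequencies give a 20-dimensional composition vector; UMAP provides 2-D
   coordinates, Leiden clustering on a shared-nearest-neighbour composition
   graph gives clusters, and per-residue Wilcoxon rank-sum tests (BH
   corrected across the 20 residues) test annotated protein sets for
   compositional enrichment.

## Worked example

```r
library(dotlcr)

# a 100-protein synthetic proteome; every protein carries one planted
# 20-residue poly-K block, and every second protein a second identical one
pp <- make_planted_proteome(
  n_proteins = 100, length_range = c(150, 250),
  blocks = list(list(list(len = 20, alphabet = "K")),
                list(list(len = 20, alphabet = "K"),
                     list(len = 20, alphabet = "K"))),
  seed = 7, spacing = 25)

thr <- lcr_threshold(pp$proteome, target_fdr = 0.002, seed = 11)
print(thr)
#> <threshold 25: FDR 0.00174 (target 0.002); 161065 real / 280 null pixels pass>
```

Chance alone (the null proteome) produces almost no windows with 25 or more
matching residue pairs, so pixels at that intensity are trusted as real
low-complexity signal: of the 161,345 pixels passing the threshold, only
0.17% come from the null.

```r
calls <- call_proteome(pp$proteome, thr$threshold)
head(calls[, c("protein_id", "start", "stop", "type_id",
               "type_copy_number", "entropy_bits")])
#>   protein_id start stop type_id type_copy_number entropy_bits
#> 1      syn_1    71  100       1                1     1.892272
#> 2     syn_10    65   96       1                2     1.843951
#> 3     syn_10   152  181       1                2     1.892272
#> 4    syn_100    14   23       1                1     2.121928
#> 5    syn_100    53   86       2                2     1.769910
#> 6    syn_100   121  151       2                2     1.849723
```

`syn_10`'s two calls share `type_id = 1` with copy number 2: the planted
identical poly-K pair was recognised as two copies of one LCR type via
their off-diagonal intersection.

```r
rec <- score_planted_recovery(calls, pp$truth)
mean(rec$recovered)
#> [1] 1

print(entropy_validation(calls, pp$proteome, seed = 13))
#> <entropy comparison: 180 LCRs, mean 1.945 vs 3.274 bits, rank-sum p = 6.09e-44>
```

Every planted block is recovered, and the called LCRs carry about 1.3 bits
less sequence entropy than length-matched random samples — they are indeed
low complexity.

```r
table(classify_protein(
  total = tapply(calls$lcr_index, calls$protein_id, length),
  distinct = tapply(calls$type_id, calls$protein_id,
                    function(x) length(unique(x)))))
#> multiple-distinct    multiple-mixed     multiple-same            single
#>                13                11                40                36
```

For composition maps, see `composition_matrix()`, `embed_lcrs()`,
`cluster_lcrs()`, `label_clusters()` and `rank_sum_enrichment()`; the
vignette walks through a planted two-island example.

## Command line

A thin CLI over the same functions lives at `inst/cli/lcr.R`:

```sh
Rscript inst/cli/lcr.R call --proteome proteome.fasta --fdr 0.002 --seed 1 --out calls.tsv
Rscript inst/cli/lcr.R map --calls calls.tsv --out map.csv
Rscript inst/cli/lcr.R enrich --proteome proteome.fasta --calls calls.tsv \
    --annotation nucleolus.fasta --out enrichment.tsv
```

Subcommands: `simulate`, `threshold`, `call`, `entropy`, `map`, `enrich`,
`run`.

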