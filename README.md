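# sigma54scan

Genome-wide analysis of binding sites of the bacterial alternative sigma
factor **σ54 (RpoN)** from ChIP-seq coverage tracks.

σ54 is unusual among sigma factors: RNA polymerase holoenzyme carrying σ54
binds its −24/−12 promoter elements in a transcriptionally inactive state and
waits for an enhancer-binding protein to act, so its binding is largely
condition-independent and ChIP-seq yields a near-complete census of sites —
including the majority that lie *inside* genes. This package is for
microbial genomicists who want to run or re-examine such a census: it takes
genome FASTA, gene annotation (GFF3/BED) and coverage (bedGraph/wiggle), and
produces called peaks, motif calls, site classifications, occupancy
meta-profiles and cross-species conservation scores. A transcription of the
135 published *E. coli* σ54 binding sites ships as a fixture, and a
synthetic-data module makes the whole pipeline testable offline.

## What it computes

* **FAT peak calling** — coverage is normalized to genome-wide mean 1, the
  threshold is a trimmed `mean + 4·SD`, and each peak's Fold-Above-Threshold
  score is `max height / threshold` (FAT = 1 at the calling threshold;
  low-stringency mode divides the effective threshold by 5).
* **PSSM motif model** — a 17-column log₂-odds matrix
  `log2((n_ib + 0.5)/(N + 2)/0.25)` built from aligned site 17-mers
  (consensus `CTGGCACGAATTTTGCA`, with the strong GG/TGC core at positions
  3,4 and 14–16), scanned on both strands in 150-bp windows around peaks,
  plus a one-sided binomial test for central enrichment of motif offsets.
* **Site classification** — OS/OA/IS/IA (Outside/Inside a gene,
  Sense/Antisense), predicted TSS = motif center + 19 bp on the motif
  strand, distance to the next available downstream gene start, an exact
  binomial orientation-bias test `P(X ≥ n_sense | n, ½)`, and enrichment of
  distances in the 360–760 bp band against an exhaustively computed
  genome-wide background.
* **RNAP occupancy** — strand-resolved median meta-profile over ±500 bp,
  each site's window flipped into motif orientation and normalized at
  offset 0, with a random-position control.
* **Conservation** — anchored ±100 bp PSSM rescans in query genomes (BLAST
  tabular anchors at E ≤ 1e−4, or a naive seed-and-extend matcher for
  substitution-only orthologs), a site × species score matrix, and the
  substitution-rate contrast between important (3,4,14,15,16) and
  unimportant (1,8,9,10,12) motif positions,
  `fold = (s_u/e_u)/(s_i/e_i)`.

## Worked example

Statistics of the packaged 135-site table:

```r
library(sigma54scan)
sites <- read_site_table()
table(sites$class)
#> IA IS OA OS
#> 27 58  8 42

sigma54_pssm()
#> <pssm> width 17, built from 135 sites, consensus CTGGCACGAATTTTGCA

intra <- sites[sites$class %in% c("IS", "IA"), ]
nrow(intra) / nrow(sites)                      # 0.63: 85/135 sites inside genes
orientation_bias_test(sum(intra$class == "IS"), nrow(intra))
#> 0.00051                                     # 58/85 sense is no accident
spearman_fat_vs_score(sites, "OS")             # 0.67
spearman_fat_vs_score(sites, c("OA","IS","IA"))# 0.38
fold_ratio(substitution_tally(35, 1603, 309, 1640))
#> 8.6        # substitutions hit low-information motif positions 8.6x more
```

The numbers mean: two thirds of σ54 sites are intragenic, their orientation
is strongly biased toward the sense strand of the host gene, ChIP strength
correlates with motif quality (most tightly for classic intergenic
promoters), and across species the motif's information-rich positions are
conserved far beyond their surroundings — together the signature of
functional, selected binding sites rather than sequence accidents.

A full simulated run (generate a 2-Mb genome with 135 planted sites, call
peaks, associate motifs, classify) is shown in the vignette
(`vignettes/sigma54-binding-site-analysis.Rmd`), which also documents every
model, parameter and design decision.

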