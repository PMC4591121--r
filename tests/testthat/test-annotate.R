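# Site classification, predicted TSS, distances, and positional statistics.

test_that("predicted TSS sits 19 bp downstream of the motif center", {
  expect_equal(predict_tss(2689382, "-"), 2689363L)
  expect_equal(predict_tss(100, "+"), 119L)
  expect_equal(predict_tss(5, "-", genome_length = 1000), 986L)
  # bijection: the opposite strand undoes the offset
  for (x in c(1L, 57L, 999L)) {
    expect_equal(predict_tss(predict_tss(x, "+", 1000), "-", 1000), x)
  }
})

test_that("toy sites classify into the four classes with correct distances", {
  ann <- toy_annotation(list("A", 1000, 2000, "+"))
  r <- classify_sites(500, "+", ann, genome_length = 10000)
  expect_equal(r$class, "OS")
  expect_equal(r$downstream_gene, "A")
  expect_equal(r$distance, 1000L - 519L)   # TSS 519 to start 1000

  expect_equal(classify_sites(1500, "+", ann, 10000)$class, "IS")
  r2 <- classify_sites(1500, "-", ann, 10000)
  expect_equal(r2$class, "IA")
  expect_equal(r2$overlapping_gene, "A")

  # boundary positions count as intragenic (inclusive convention)
  expect_equal(classify_sites(1000, "+", ann, 10000)$class, "IS")
  expect_equal(classify_sites(2000, "+", ann, 10000)$class, "IS")
  # a '-' motif in the gap upstream of a '+' gene points away from it: OA
  expect_equal(classify_sites(500, "-", ann, 10000)$class, "OA")
  expect_error(classify_sites(500, "+", ann[0, ], 10000), "empty annotation")
})

test_that("downstream search skips unavailable starts and overlapping genes", {
  # B's start (3000) is upstream of the TSS from a site inside B, so the
  # next available start is C's
  ann <- toy_annotation(list("B", 3000, 4000, "+"), list("C", 5000, 5600, "+"))
  r <- classify_sites(3500, "+", ann, 10000)
  expect_equal(r$class, "IS")
  expect_equal(r$downstream_gene, "C")
  expect_equal(r$distance, 5000L - 3519L)
  # intergenic site whose TSS lands inside the downstream gene: that gene's
  # start is behind the TSS (not available), so the search falls through to C
  r2 <- classify_sites(2990, "+", ann, 10000)
  expect_equal(r2$class, "OS")
  expect_equal(r2$downstream_gene, "C")
  expect_equal(r2$distance, 5000L - 3009L)
})

test_that("distance is invariant to genes on the opposite strand", {
  ann1 <- toy_annotation(list("A", 1000, 2000, "+"))
  ann2 <- toy_annotation(list("A", 1000, 2000, "+"), list("X", 600, 900, "-"))
  d1 <- classify_sites(100, "+", ann1, 10000)$distance
  d2 <- classify_sites(100, "+", ann2, 10000)$distance
  expect_equal(d1, d2)
})

test_that("classification agrees with a brute-force oracle on random draws", {
  set.seed(77)
  L <- 20000L
  for (rep in 1:5) {
    ng <- sample(5:12, 1)
    starts <- sort(sample.int(L - 400L, ng))
    ends <- pmin(starts + sample(100:2000, ng, replace = TRUE), L)
    ann <- gene_annotation(sprintf("g%02d", seq_len(ng)), starts, ends,
                           sample(c("+", "-"), ng, replace = TRUE))
    centers <- sample.int(L, 200)
    strands <- sample(c("+", "-"), 200, replace = TRUE)
    got <- classify_sites(centers, strands, ann, L)
    for (i in seq_len(200)) {
      oracle <- brute_classify(centers[i], strands[i], ann, L)
      expect_equal(got$class[i], oracle$class,
                   info = sprintf("rep %d center %d %s", rep, centers[i],
                                  strands[i]))
      expect_equal(got$distance[i], oracle$distance,
                   info = sprintf("rep %d center %d %s", rep, centers[i],
                                  strands[i]))
    }
  }
})

test_that("orientation bias test reproduces published and hand-computed tails", {
  expect_equal(orientation_bias_test(58, 85), 5e-4, tolerance = 0.05)
  expect_equal(orientation_bias_test(79, 129), 0.007, tolerance = 0.05)
  # exact tail sum for 5 of 10: sum_{k>=5} C(10,k)/2^10 = 638/1024
  expect_equal(orientation_bias_test(5, 10), 638 / 1024)
  expect_equal(orientation_bias_test(0, 10), 1)
  expect_error(orientation_bias_test(5, 0), "positive")
})

test_that("orientation test p-values are uniform-dominated under the null", {
  set.seed(123)
  x <- rbinom(10000, 85, 0.5)
  p <- pbinom(x - 1, 85, 0.5, lower.tail = FALSE)
  expect_lte(mean(p <= 0.05), 0.05 + 0.01)
  expect_lte(mean(p <= 0.01), 0.01 + 0.01)
})

test_that("interval enrichment counts distances in the band", {
  expect_equal(interval_enrichment(rep(500, 20))$observed_fraction, 1)
  set.seed(9)
  u <- interval_enrichment(runif(20000, 0, 5000))
  expect_equal(u$observed_fraction, 401 / 5001, tolerance = 0.08)
  expect_error(interval_enrichment(numeric(0)), "no distances")
  expect_error(interval_enrichment(c(-5, 10)), ">= 0")
})

test_that("fixture intragenic distances are enriched in the 360-760 band", {
  sites <- fixture_sites()
  intra <- sites[sites$class %in% c("IS", "IA"), ]
  obs <- interval_enrichment(intra$distance)$observed_fraction
  expect_gte(obs, 0.30)
  expect_lte(obs, 0.40)
})

test_that("genome background fraction matches brute force and closed form", {
  # single gene spanning the whole genome, unbounded interval -> 1
  ann <- toy_annotation(list("A", 1, 500, "+"), list("B", 501, 1000, "+"))
  expect_equal(genome_background_fraction(ann, 1000, 0, Inf), 1)

  # exhaustive equality with per-position brute force on a 10 kb toy
  set.seed(55)
  starts <- sort(sample.int(9000L, 8L))
  ends <- pmin(starts + sample(200:1500, 8L, replace = TRUE), 10000L)
  ok <- c(TRUE, starts[-1] > ends[-8])  # keep it simple: non-overlapping
  ann <- gene_annotation(sprintf("g%d", which(ok)), starts[ok], ends[ok],
                         sample(c("+", "-"), sum(ok), replace = TRUE))
  got <- genome_background_fraction(ann, 10000L, 360, 760)
  brute <- brute_background_fraction(ann, 10000L, 360, 760)
  expect_equal(got, brute)

  # contiguous tiling of same-strand genes: closed form (hi-lo+1)/1000
  ann <- gene_annotation(sprintf("t%d", 1:10), seq(1, 9001, by = 1000),
                         seq(1000, 10000, by = 1000), rep("+", 10))
  frac <- genome_background_fraction(ann, 10000L, 100, 349,
                                     intragenic_only = FALSE)
  expect_equal(frac, 250 / 1000)
})

test_that("cumulative distance curves are deterministic and dominated by sites", {
  sim <- paper_sim()
  cls <- classify_sites(sim$truth$position, sim$truth$strand, sim$annotation,
                        sim$cfg$genome_length, site_id = sim$truth$site_id)
  c1 <- cumulative_distance_curve(cls, sim$annotation, sim$cfg$genome_length,
                                  n_random = 500, seed = 5)
  c2 <- cumulative_distance_curve(cls, sim$annotation, sim$cfg$genome_length,
                                  n_random = 500, seed = 5)
  expect_identical(c1$random, c2$random)
  expect_equal(length(c1$intergenic) + length(c1$intragenic), nrow(cls))
  # sites are planted near gene starts, so their distances are
  # stochastically smaller than those of random positions (site CDF above
  # the random CDF; ks.test "greater" tests exactly that)
  ks <- suppressWarnings(ks.test(c1$all, c1$random, alternative = "greater"))
  expect_lt(ks$p.value, 0.01)
})

test_that("Spearman FAT-versus-score reproduces the published correlations", {
  sites <- fixture_sites()
  expect_equal(round(spearman_fat_vs_score(sites, "OS"), 2), 0.67)
  expect_equal(round(spearman_fat_vs_score(sites, c("OA", "IS", "IA")), 2),
               0.38)
  mono <- data.frame(fat = 1:10, pssm_score = (1:10)^2)
  expect_equal(spearman_fat_vs_score(mono), 1)
  const <- data.frame(fat = rep(1, 5), pssm_score = 1:5)
  expect_error(spearman_fat_vs_score(const), "constant")
})
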