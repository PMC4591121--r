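# Anchored conservation rescans, the site-by-species matrix, and the
# important/unimportant substitution contrast.

make_anchor <- function(site_id, pos, strand, species = "sp1") {
  data.frame(site_id = site_id, species = species, mapped_position = pos,
             mapped_strand = strand, evalue = 1e-20, stringsAsFactors = FALSE)
}

test_that("scanning an identical genome returns the site's own score at offset 0", {
  p <- sigma54_pssm()
  g <- plant_motif(random_genome(3000, seed = 41), p$consensus, 1500, "+")
  own <- score_sequence(p, p$consensus)
  cell <- conservation_scan("s1", g, make_anchor("s1", 1500, "+"), p)
  expect_true(cell$homolog_found)
  expect_equal(cell$exact_score, own)
  expect_equal(cell$best_score, own)
  expect_equal(cell$best_offset, 0L)
  expect_true(cell$aligned)
  expect_equal(cell$best_seq, p$consensus)
})

test_that("a shifted planted motif is recovered at its exact offset", {
  p <- sigma54_pssm()
  base <- random_genome(5000, seed = 43)
  g <- plant_motif(base, p$consensus, 2537, "+")   # shifted +37 in the query
  cell <- conservation_scan("s1", g, make_anchor("s1", 2500, "+"), p)
  expect_equal(cell$best_offset, 37L)
  expect_equal(cell$best_score, score_sequence(p, p$consensus))
  expect_false(cell$aligned)
  # on a minus-strand anchor the offset is reported in site orientation
  gm <- plant_motif(base, p$consensus, 2463, "-")
  cellm <- conservation_scan("s1", gm, make_anchor("s1", 2500, "-"), p)
  expect_equal(cellm$best_offset, 37L)
})

test_that("missing anchors give all-missing cells", {
  p <- sigma54_pssm()
  g <- random_genome(2000, seed = 45)
  cell <- conservation_scan("s1", g, NULL, p)
  expect_false(cell$homolog_found)
  expect_true(is.na(cell$best_score))
  expect_true(is.na(cell$exact_score))
})

test_that("best score is monotone non-decreasing in window size", {
  p <- sigma54_pssm()
  g <- random_genome(4000, seed = 47)
  a <- make_anchor("s1", 2000, "+")
  scores <- vapply(c(20, 50, 100, 200), function(w)
    conservation_scan("s1", g, a, p, window = w)$best_score, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("conservation matrix declines with divergence and handles edge cases", {
  cfg <- sim_config(genome_length = 400000L, n_sites = 40L, seed = 51L)
  gen <- generate_genome(cfg)
  p <- sigma54_pssm()
  pl <- plant_sites(gen$genome, gen$annotation, p, cfg)
  sites <- data.frame(site_id = pl$truth$site_id, stringsAsFactors = FALSE)

  divs <- c(0, 0.02, 0.05, 0.1, 0.2)
  genomes <- list(); anchors <- list()
  for (k in seq_along(divs)) {
    sp <- sprintf("sp%d", k)
    ort <- mutate_ortholog(pl$genome, pl$truth, divs[k], seed = 60L + k,
                           species = sp)
    genomes[[sp]] <- ort$genome
    anchors[[k]] <- ort$anchors
  }
  anchors <- do.call(rbind, anchors)
  cm <- build_conservation_matrix(sites, genomes, anchors, p)
  expect_equal(dim(cm$matrix), c(40L, 5L))
  col_means <- colMeans(cm$matrix)
  expect_true(all(diff(col_means) <= 0))   # more divergence, lower scores
  # identity species: the exact-position rescans equal the sites' own
  # scores, and the window best can only improve on them
  own <- vapply(pl$truth$motif, function(m) score_sequence(p, m), numeric(1))
  sp1 <- cm$cells[cm$cells$species == "sp1", ]
  sp1 <- sp1[match(pl$truth$site_id, sp1$site_id), ]
  expect_equal(sp1$exact_score, unname(own))
  # best >= exact up to float noise from the sliding-sum scan order
  expect_true(all(sp1$best_score >= sp1$exact_score - 1e-9))
  expect_true(all(cm$matrix[pl$truth$site_id, "sp1"] >= unname(own) - 1e-9))

  empty <- build_conservation_matrix(sites, setNames(list(), character(0)),
                                     anchors[0, ], p)
  expect_equal(ncol(empty$matrix), 0L)
  dup <- rbind(anchors[1, ], anchors[1, ])
  expect_error(build_conservation_matrix(sites, genomes, dup, p), "duplicate")
})

test_that("substitution counting applies the consensus-match restriction", {
  p <- sigma54_pssm()
  cons <- p$consensus
  cell <- function(seq, score = 10, offset = 0L, aligned = TRUE) {
    data.frame(site_id = "s1", species = "spX", homolog_found = TRUE,
               exact_score = score, best_score = score, best_offset = offset,
               best_strand = "+", aligned = aligned, best_seq = seq,
               stringsAsFactors = FALSE)
  }
  motifs <- c(s1 = cons)

  # identical pair: no substitutions, 5 + 5 positions examined
  t0 <- substitution_stats(motifs, cell(cons), p)
  expect_equal(t0$important_substitutions, 0L)
  expect_equal(t0$important_examined, 5L)
  expect_equal(t0$unimportant_examined, 5L)

  # pair differing only at (unimportant) positions 8 and 9
  hom <- cons
  for (pos in c(8, 9)) {
    substr(hom, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(cons, pos, pos))[1]
  }
  t1 <- substitution_stats(motifs, cell(hom), p)
  expect_equal(t1$important_substitutions, 0L)
  expect_equal(t1$unimportant_substitutions, 2L)
  expect_equal(t1$unimportant_examined, 5L)

  # E. coli site deviating from the consensus at important position 16:
  # that position is excluded, leaving 4 examined
  dev <- cons
  substr(dev, 16, 16) <- setdiff(c("A", "C", "G", "T"),
                                 substr(cons, 16, 16))[1]
  t2 <- substitution_stats(c(s1 = dev), cell(cons), p)
  expect_equal(t2$important_examined, 4L)

  # pairs failing the score or alignment filter are not counted
  t3 <- substitution_stats(motifs, cell(cons, score = 5), p)
  expect_equal(t3$n_pairs, 0L)
  t4 <- substitution_stats(motifs, cell(cons, offset = 3L, aligned = FALSE), p)
  expect_equal(t4$n_pairs, 0L)
})

test_that("fold ratio reproduces the published 8.6 and simple arithmetic", {
  expect_equal(round(fold_ratio(substitution_tally(35, 1603, 309, 1640)), 1),
               8.6)
  expect_equal(fold_ratio(substitution_tally(10, 100, 10, 100)), 1)
  expect_equal(fold_ratio(substitution_tally(1, 100, 10, 100)), 10)
  expect_equal(fold_ratio(substitution_tally(0, 100, 10, 100)), Inf)
  expect_error(substitution_tally(10, 5, 0, 5), "exceed")
})

test_that("naive anchoring locates fragments in substitution-only orthologs", {
  cfg <- sim_config(genome_length = 400000L, n_sites = 60L,
                    site_spacing = 3000L, seed = 71L)
  gen <- generate_genome(cfg)
  p <- sigma54_pssm()
  pl <- plant_sites(gen$genome, gen$annotation, p, cfg)
  sites <- data.frame(site_id = pl$truth$site_id,
                      motif_center = pl$truth$position,
                      motif_strand = pl$truth$strand, stringsAsFactors = FALSE)

  # divergence 0: anchored at the identical coordinate
  a0 <- anchor_from_alignment(sites[1, ], pl$genome, pl$genome, mode = "naive")
  expect_equal(a0$mapped_position, sites$motif_center[1])

  # divergence 0.05: anchor within 2 bp of truth for >= 95% of sites
  ort <- mutate_ortholog(pl$genome, pl$truth, 0.05, seed = 72L)
  hit <- vapply(seq_len(nrow(sites)), function(i) {
    a <- anchor_from_alignment(sites[i, ], pl$genome, ort$genome,
                               mode = "naive")
    !is.na(a$mapped_position) &&
      abs(a$mapped_position - sites$motif_center[i]) <= 2
  }, logical(1))
  expect_gte(mean(hit), 0.95)

  # a scrambled genome yields no anchor
  set.seed(73)
  scram <- genome_record("scram", paste(sample(strsplit(pl$genome$sequence,
    "")[[1]]), collapse = ""))
  a_sc <- anchor_from_alignment(sites[1, ], pl$genome, scram, mode = "naive")
  expect_true(is.na(a_sc$mapped_position))

  # provided mode passes anchors through
  ap <- anchor_from_alignment(sites[2, ], pl$genome, ort$genome,
                              mode = "provided", anchors = ort$anchors,
                              species = "sp1")
  expect_equal(ap$mapped_position, sites$motif_center[2])
})
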