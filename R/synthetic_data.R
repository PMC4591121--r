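# Synthetic E. coli-like data: genomes with a gene tiling at ~88% coding
# density, planted 17-bp motifs drawn from a PWM, bimodal ChIP coverage,
# symmetric RNAP footprints, and neutrally diverged ortholog genomes with
# known anchors. Every generator is a pure function of (config, seed): each
# stage seeds its own RNG stream at config$seed + a stage offset, so stages
# can be re-run independently.

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults mirror the published E. coli study conditions: 135 sites split
#' 42/8/58/27 across the OS/OA/IS/IA classes, a 68% sense bias among
#' intragenic sites, an enriched band of promoter-to-gene-start distances at
#' 360-760 bp, ~88% coding density, and per-site ChIP strengths spanning the
#' printed FAT range 1-201.
#'
#' @param genome_length Genome size in bp.
#' @param coding_fraction Target fraction of coding bases, in (0, 1).
#' @param n_sites Number of binding sites to plant.
#' @param class_proportions Probabilities of classes OS, OA, IS, IA
#'   (must sum to 1).
#' @param sense_bias Probability that an intragenic site is in the sense
#'   orientation of its host gene.
#' @param tss_distance_mix List `(lo, hi, weight)`: with probability
#'   `weight` an intragenic site is placed so its predicted TSS falls
#'   `lo`-`hi` bp upstream of the next available gene start.
#' @param read_depth Mean background depth (reads per position).
#' @param peak_height Enrichment multiple of a strength-1 site over
#'   background.
#' @param peak_halfwidth Half-width of the ChIP peak in bp; the two lobes of
#'   the bimodal sigma peak sit at `+/- peak_halfwidth/2`.
#' @param rnap_height Enrichment multiple of the symmetric RNAP footprint.
#' @param gene_length_mean Mean simulated gene length in bp.
#' @param site_spacing Minimum spacing between planted sites in bp.
#' @param seed Integer seed; all generator stages derive their streams from
#'   it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 2000000L,
                       coding_fraction = 0.88,
                       n_sites = 135L,
                       class_proportions = c(OS = 42, OA = 8, IS = 58, IA = 27) / 135,
                       sense_bias = 0.68,
                       tss_distance_mix = list(lo = 360, hi = 760, weight = 0.365),
                       read_depth = 50,
                       peak_height = 3,
                       peak_halfwidth = 100L,
                       rnap_height = 5,
                       gene_length_mean = 900,
                       site_spacing = 5000L,
                       seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1")
  }
  if (coding_fraction <= 0 || coding_fraction >= 1) {
    stop("coding_fraction must be in (0, 1)")
  }
  if (read_depth <= 0 || peak_height < 0 || rnap_height < 0) {
    stop("depth parameters must be positive")
  }
  if (genome_length <= 10 * peak_halfwidth) {
    stop("genome_length must exceed 10 x peak_halfwidth")
  }
  structure(list(genome_length = as.integer(genome_length),
                 coding_fraction = coding_fraction,
                 n_sites = as.integer(n_sites),
                 class_proportions = class_proportions,
                 sense_bias = sense_bias,
                 tss_distance_mix = tss_distance_mix,
                 read_depth = read_depth, peak_height = peak_height,
                 peak_halfwidth = as.integer(peak_halfwidth),
                 rnap_height = rnap_height,
                 gene_length_mean = gene_length_mean,
                 site_spacing = as.integer(site_spacing),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random genome with a gene tiling
#'
#' The background sequence is i.i.d. uniform over A/C/G/T. Non-overlapping
#' genes of gamma-distributed length are tiled with geometric intergenic
#' gaps sized so the realized coding fraction approximates
#' `config$coding_fraction`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [genome_record()]) and `annotation`
#'   (a [gene_annotation()]).
#' @export
generate_genome <- function(config) {
  L <- config$genome_length
  cf <- config$coding_fraction
  glen_mean <- config$gene_length_mean
  gap_mean <- glen_mean * (1 - cf) / cf
  if (gap_mean < 2) stop("coding_fraction infeasible: intergenic gaps < 2 bp")
  if (L < 5 * glen_mean) {
    stop("genome_length too small to tile genes of mean length ", glen_mean)
  }
  with_seed(config$seed + 1L, {
    seq <- paste(sample(BASES, L, replace = TRUE), collapse = "")
    pos <- 1L
    starts <- integer(); ends <- integer(); strands <- character()
    repeat {
      gap <- 2L + stats::rgeom(1L, 1 / max(gap_mean - 2, 1))
      glen <- max(120L, round(stats::rgamma(1L, shape = 4, scale = glen_mean / 4)))
      s <- pos + gap
      e <- s + glen - 1L
      if (e > L - 2L) break
      starts <- c(starts, s); ends <- c(ends, e)
      strands <- c(strands, sample(c("+", "-"), 1L))
      pos <- e + 1L
    }
    if (length(starts) == 0L) stop("could not place any gene")
    ann <- gene_annotation(
      gene_id = sprintf("sg%04d", seq_along(starts)),
      start = starts, end = ends, strand = strands,
      b_number = sprintf("b%04d", seq_along(starts)))
    list(genome = genome_record("sim_genome", seq), annotation = ann)
  })
}

# sample one sequence of pssm width column-wise from its probability matrix
sample_from_pwm <- function(pssm) {
  paste(vapply(seq_len(pssm$width), function(i)
    sample(BASES, 1L, prob = pssm$probs[i, ]), character(1)), collapse = "")
}

# genome coordinates occupied by a 17-mer with top-strand center `center`
motif_span <- function(center, width = 17L) {
  half <- (width - 1L) %/% 2L
  seq.int(center - half, center + half)
}

# top-strand coordinate of motif position i (1-based, read on `strand`)
motif_pos_coord <- function(center, strand, i, width = 17L) {
  mid <- (width + 1L) %/% 2L
  if (strand == "+") center + (i - mid) else center - (i - mid)
}

#' Plant binding sites into a genome
#'
#' Each site's 17-mer is sampled column-wise from the PWM and written into
#' the genome (reverse-complemented for minus-strand sites). Classes and
#' orientations are drawn from the configuration: intergenic sites are
#' placed in gaps oriented toward (OS) or away from (OA) the neighboring
#' gene, intragenic sites inside a gene in sense (probability `sense_bias`)
#' or antisense orientation, with a fraction of sense sites placed so that
#' the predicted TSS lands in the configured distance band upstream of the
#' next available gene start.
#'
#' @param genome A [genome_record()] from [generate_genome()].
#' @param annotation The matching [gene_annotation()].
#' @param pssm A `pssm` supplying the motif model (see [build_pssm()]).
#' @param config A [sim_config()].
#' @return List with `genome` (sequence with motifs written in) and `truth`,
#'   a data frame of planted sites: `site_id`, `position` (motif center),
#'   `strand`, `class`, `motif` (as read on the site strand), `gene_id` of
#'   the host gene (NA for intergenic sites) and `strength` (per-site
#'   ChIP strength factor, log-uniform on [1, 200] to mimic the printed FAT
#'   range).
#' @export
plant_sites <- function(genome, annotation, pssm, config) {
  L <- genome$length
  n <- config$n_sites
  w <- pssm$width
  half <- (w - 1L) %/% 2L
  spacing <- config$site_spacing
  mix <- config$tss_distance_mix
  with_seed(config$seed + 2L, {
    classes <- sample(VALID_CLASSES, n, replace = TRUE,
                      prob = config$class_proportions)
    # reserve sense/antisense choice for intragenic sites
    placed_centers <- integer()
    gaps <- intergenic_gaps(annotation, L)
    genes_ok <- annotation[annotation$end - annotation$start + 1L >= 300L, ]
    rows <- vector("list", n)
    chars <- strsplit(genome$sequence, "")[[1L]]
    for (i in seq_len(n)) {
      cls <- classes[i]
      ok <- FALSE
      for (try in seq_len(200L)) {
        if (cls %in% c("OS", "OA")) {
          g <- gaps[sample.int(nrow(gaps), 1L), ]
          if (g$width < 60L) next
          pick <- place_intergenic(g, annotation, cls, half)
        } else {
          sense <- stats::runif(1L) < config$sense_bias
          cls <- if (sense) "IS" else "IA"
          gene <- genes_ok[sample.int(nrow(genes_ok), 1L), ]
          pick <- place_intragenic(gene, annotation, L, sense, mix, half)
        }
        if (is.null(pick)) next
        if (length(placed_centers) &&
            min(circ_dist(pick$center, placed_centers, L)) < spacing) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place site ", i, " without overlap")
      motif <- sample_from_pwm(pssm)
      top <- if (pick$strand == "+") motif else revcomp(motif)
      chars[wrap_pos(motif_span(pick$center, w), L)] <- strsplit(top, "")[[1L]]
      placed_centers <- c(placed_centers, pick$center)
      rows[[i]] <- data.frame(
        site_id = sprintf("sim%03d", i), position = pick$center,
        strand = pick$strand, class = cls,
        motif = motif, gene_id = pick$gene_id, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    truth$strength <- exp(stats::runif(n, log(1), log(200)))
    list(genome = genome_record(genome$id, paste(chars, collapse = ""),
                                genome$circular),
         truth = truth)
  })
}

# shortest circular distance between a position and a vector of positions
circ_dist <- function(p, q, L) {
  d <- abs(p - q)
  pmin(d, L - d)
}

# table of intergenic gaps (between consecutive genes in top-strand order)
intergenic_gaps <- function(annotation, L) {
  n <- nrow(annotation)
  gap_start <- annotation$end + 1L
  gap_end <- c(annotation$start[-1L] - 1L, L)
  left <- seq_len(n)
  right <- c(seq_len(n)[-1L], NA_integer_)   # NA: gap after last gene
  keep <- gap_end >= gap_start
  data.frame(start = gap_start[keep], end = gap_end[keep],
             width = (gap_end - gap_start + 1L)[keep],
             left_gene = left[keep], right_gene = right[keep])
}

# choose center+strand in an intergenic gap yielding the requested class
place_intergenic <- function(gap, annotation, cls, half) {
  lo <- gap$start + half + 2L
  hi <- gap$end - half - 2L
  if (hi < lo) return(NULL)
  right_strand <- if (is.na(gap$right_gene)) NA_character_
                  else annotation$strand[gap$right_gene]
  left_strand <- annotation$strand[gap$left_gene]
  # a '+' motif in the gap points at the right flanking gene, a '-' motif at
  # the left one; sense (OS) means the flanking gene shares the motif strand
  opts <- character()
  if (!is.na(right_strand)) {
    if ((cls == "OS") == (right_strand == "+")) opts <- c(opts, "+")
  }
  if ((cls == "OS") == (left_strand == "-")) opts <- c(opts, "-")
  if (length(opts) == 0L) return(NULL)
  strand <- sample(opts, 1L)
  if (cls == "OS") {
    # place the TSS 20-250 bp upstream of the flanking gene start
    d <- sample(20:250, 1L)
    center <- if (strand == "+") annotation$start[gap$right_gene] - d - 19L
              else annotation$end[gap$left_gene] + d + 19L
    if (center < lo || center > hi) center <- sample(lo:hi, 1L)
  } else {
    center <- sample(lo:hi, 1L)
  }
  list(center = as.integer(center), strand = strand, gene_id = NA_character_)
}

# choose center inside a gene; optionally target the enriched distance band
place_intragenic <- function(gene, annotation, L, sense, mix, half) {
  lo <- gene$start + half + 2L
  hi <- gene$end - half - 2L
  if (hi < lo) return(NULL)
  strand <- if (sense) gene$strand else setdiff(c("+", "-"), gene$strand)
  center <- NA_integer_
  if (stats::runif(1L) < mix$weight) {
    d <- sample(seq.int(mix$lo, mix$hi), 1L)
    ns <- next_available_start(gene, annotation, strand, L)
    if (!is.na(ns)) {
      cand <- if (strand == "+") ns - d - 19L else ns + d + 19L
      cand <- wrap_pos(cand, L)
      if (cand >= lo && cand <= hi) center <- cand
    }
  }
  if (is.na(center)) center <- sample(lo:hi, 1L)
  list(center = as.integer(center), strand = strand, gene_id = gene$gene_id)
}

# strand-aware start of the nearest same-strand gene downstream of `gene`,
# excluding the gene itself (used only for band-targeted placement)
next_available_start <- function(gene, annotation, strand, L) {
  cand <- annotation[annotation$strand == strand &
                     annotation$gene_id != gene$gene_id, ]
  if (nrow(cand) == 0L) return(NA_integer_)
  starts <- gene_tx_start(cand)
  ref <- if (strand == "+") gene$end else gene$start
  d <- if (strand == "+") (starts - ref) %% L else (ref - starts) %% L
  starts[which.min(d)]
}

#' Simulate ChIP coverage tracks over a genome with planted sites
#'
#' Produces four Poisson tracks of mean background `read_depth`: a sigma
#' ChIP track where each site adds a two-lobed (bimodal) enrichment with
#' Gaussian lobes of sd `peak_halfwidth/2` offset at `+/- peak_halfwidth/2`
#' and amplitude `read_depth * peak_height * strength`; plus- and
#' minus-strand RNAP tracks each gaining a symmetric Gaussian footprint
#' centered on the motif; and an input track with no planted enrichment.
#'
#' @param genome A [genome_record()] (supplies the length).
#' @param truth Truth table from [plant_sites()].
#' @param config A [sim_config()].
#' @return List of [coverage_track()]s: `sigma`, `rnap_plus`, `rnap_minus`,
#'   `input`.
#' @export
simulate_chip_coverage <- function(genome, truth, config) {
  if (is.null(truth)) {
    truth <- data.frame(position = integer(), strand = character(),
                        strength = numeric())
  }
  L <- genome$length
  depth <- config$read_depth
  hw <- config$peak_halfwidth
  lam_sigma <- rep(depth, L)
  lam_rnap <- rep(depth, L)
  win <- seq.int(-4L * hw, 4L * hw)
  lobe_sd <- hw / 2
  bimodal <- stats::dnorm(win, -hw / 2, lobe_sd) + stats::dnorm(win, hw / 2, lobe_sd)
  bimodal <- bimodal / max(bimodal)
  footprint <- stats::dnorm(win, 0, hw)
  footprint <- footprint / max(footprint)
  for (i in seq_len(nrow(truth))) {
    idx <- wrap_pos(truth$position[i] + win, L)
    amp <- depth * config$peak_height * truth$strength[i]
    lam_sigma[idx] <- lam_sigma[idx] + amp * bimodal
    lam_rnap[idx] <- lam_rnap[idx] + depth * config$rnap_height * footprint
  }
  with_seed(config$seed + 3L, {
    list(sigma = coverage_track(stats::rpois(L, lam_sigma), genome$id, "*"),
         rnap_plus = coverage_track(stats::rpois(L, lam_rnap), genome$id, "+"),
         rnap_minus = coverage_track(stats::rpois(L, lam_rnap), genome$id, "-"),
         input = coverage_track(stats::rpois(L, depth), genome$id, "*"))
  })
}

#' Generate a neutrally diverged ortholog genome
#'
#' Applies independent per-base substitutions at rate `divergence`, except
#' at planted-motif positions listed in `constrained_positions`, which
#' mutate at rate `divergence * relaxation` (purifying selection on the
#' motif core). Coordinates are preserved (substitutions only), so the
#' returned anchor table maps every planted site to its true ortholog
#' coordinate.
#'
#' @param genome Genome with planted sites (from [plant_sites()]).
#' @param truth Matching truth table.
#' @param divergence Per-base substitution rate, in \[0, 0.5).
#' @param constrained_positions Motif positions (1-17, read on the site
#'   strand) under constraint; default the strong-consensus core positions.
#' @param relaxation Rate multiplier at constrained positions (default 0.1).
#' @param seed RNG seed for this ortholog.
#' @param species Species label for the anchor table.
#' @return List with `genome` (the ortholog [genome_record()]) and
#'   `anchors` (5-column anchor `data.frame`).
#' @export
mutate_ortholog <- function(genome, truth, divergence,
                            constrained_positions = IMPORTANT_POSITIONS,
                            relaxation = 0.1, seed = 1L, species = "sp1") {
  if (divergence < 0 || divergence >= 0.5) stop("divergence must be in [0, 0.5)")
  L <- genome$length
  rate <- rep(divergence, L)
  if (nrow(truth) > 0L && length(constrained_positions)) {
    for (i in seq_len(nrow(truth))) {
      coords <- vapply(constrained_positions, function(p)
        motif_pos_coord(as.integer(truth$position[i]), truth$strand[i],
                        as.integer(p)), integer(1))
      rate[wrap_pos(coords, L)] <- divergence * relaxation
    }
  }
  with_seed(seed, {
    mut <- which(stats::runif(L) < rate)
    chars <- strsplit(genome$sequence, "")[[1L]]
    if (length(mut)) {
      # substitute with one of the three other bases, uniformly
      idx <- match(chars[mut], BASES)
      step <- sample.int(3L, length(mut), replace = TRUE)
      chars[mut] <- BASES[((idx - 1L + step) %% 4L) + 1L]
    }
    anchors <- data.frame(site_id = truth$site_id, species = species,
                          mapped_position = truth$position,
                          mapped_strand = truth$strand,
                          evalue = 1e-30, stringsAsFactors = FALSE)
    list(genome = genome_record(paste0(genome$id, "_", species),
                                paste(chars, collapse = ""), genome$circular),
         anchors = anchors)
  })
}
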