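# Classification of binding sites against a gene annotation (OS/OA/IS/IA),
# predicted transcription start sites, downstream-gene distances, and the
# positional and orientation statistics built on them.
#
# Conventions (documented tie-breaks):
#  * intragenic means motif center within [start, end] inclusive; a center
#    exactly on a boundary counts as intragenic;
#  * when several genes contain the center, the one with the smallest start
#    wins and the site is flagged ambiguous;
#  * the "available" downstream gene start is the first strand-aware start
#    coordinate at or downstream of the TSS on the motif strand; a gene
#    whose start lies upstream but whose body overlaps the TSS is thereby
#    skipped automatically (its start is not available);
#  * for intergenic sites, sense (OS) versus antisense (OA) is decided by
#    the first gene body encountered moving downstream from the motif:
#    sense when that neighboring gene is on the motif strand.

TSS_OFFSET <- 19L   # predicted TSS is 19 bp downstream of the motif center

#' Predict the transcription start site of a sigma54 motif
#'
#' The TSS is placed 19 bp downstream of the motif center on the motif
#' strand, reflecting the -24/-12 geometry of the element (the motif center
#' sits between the two promoter boxes).
#'
#' @param motif_center Motif center coordinate(s), 1-based.
#' @param strand Motif strand(s), `"+"` or `"-"`.
#' @param genome_length Optional genome length for circular wrap-around.
#' @return Integer TSS coordinate(s).
#' @export
predict_tss <- function(motif_center, strand, genome_length = NULL) {
  n <- max(length(motif_center), length(strand))
  motif_center <- rep_len(as.integer(motif_center), n)
  strand <- rep_len(strand, n)
  tss <- motif_center + ifelse(strand == "+", TSS_OFFSET, -TSS_OFFSET)
  if (!is.null(genome_length)) tss <- wrap_pos(tss, genome_length)
  as.integer(tss)
}

#' Classify binding sites relative to a gene annotation
#'
#' Each site is classified as intergenic or intragenic (motif center inside
#' a gene, boundaries inclusive) and as sense or antisense: relative to the
#' overlapping gene for intragenic sites, and relative to the first
#' neighboring gene downstream of the motif for intergenic sites. The
#' predicted TSS, the closest appropriately oriented downstream gene
#' (excluding the overlapping gene), and the TSS-to-gene-start distance are
#' computed per site.
#'
#' @param motif_center Motif center coordinates.
#' @param strand Motif strands (`"+"`/`"-"`).
#' @param annotation A [gene_annotation()].
#' @param genome_length Genome length (circular coordinates).
#' @param site_id Optional site identifiers.
#' @return `data.frame` with columns `site_id`, `motif_center`, `strand`,
#'   `class` (OS/OA/IS/IA), `tss`, `overlapping_gene` (NA for intergenic),
#'   `downstream_gene`, `distance` (bp, >= 0), and `ambiguous_overlap`.
#' @export
classify_sites <- function(motif_center, strand, annotation, genome_length,
                           site_id = NULL) {
  if (is.null(annotation) || nrow(annotation) == 0L) {
    stop("empty annotation: cannot classify sites")
  }
  n <- length(motif_center)
  strand <- rep_len(strand, n)
  if (is.null(site_id)) site_id <- sprintf("site%03d", seq_len(n))
  L <- as.integer(genome_length)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- classify_one(as.integer(motif_center[i]), strand[i],
                             annotation, L)
  }
  res <- do.call(rbind, out)
  res$site_id <- site_id
  res[, c("site_id", "motif_center", "strand", "class", "tss",
          "overlapping_gene", "downstream_gene", "distance",
          "ambiguous_overlap")]
}

classify_one <- function(center, strand, ann, L) {
  containing <- which(ann$start <= center & ann$end >= center)
  ambiguous <- length(containing) > 1L
  tss <- predict_tss(center, strand, L)
  if (length(containing) >= 1L) {
    host <- containing[which.min(ann$start[containing])]
    sense <- ann$strand[host] == strand
    cls <- if (sense) "IS" else "IA"
    host_gene <- ann$gene_id[host]
  } else {
    # intergenic: orientation relative to the first gene body downstream
    d_body <- if (strand == "+") (ann$start - center) %% L
              else (center - ann$end) %% L
    neighbor <- which.min(d_body)
    cls <- if (ann$strand[neighbor] == strand) "OS" else "OA"
    host <- NA_integer_
    host_gene <- NA_character_
  }
  ds <- downstream_gene(tss, strand, ann, L,
                        exclude = if (is.na(host)) integer() else host)
  data.frame(motif_center = center, strand = strand, class = cls, tss = tss,
             overlapping_gene = host_gene, downstream_gene = ds$gene_id,
             distance = ds$distance, ambiguous_overlap = ambiguous,
             stringsAsFactors = FALSE)
}

# first same-strand, strand-aware gene start at or downstream of the TSS
downstream_gene <- function(tss, strand, ann, L, exclude = integer()) {
  cand <- which(ann$strand == strand)
  cand <- setdiff(cand, exclude)
  if (length(cand) == 0L) {
    return(list(gene_id = NA_character_, distance = NA_integer_))
  }
  starts <- gene_tx_start(ann)[cand]
  d <- if (strand == "+") (starts - tss) %% L else (tss - starts) %% L
  j <- which.min(d)
  list(gene_id = ann$gene_id[cand[j]], distance = as.integer(d[j]))
}

#' One-sided binomial test for sense-orientation bias
#'
#' Tests whether intragenic sites fall in the sense orientation of their
#' host gene more often than the 50% expected under random orientation:
#' exact one-sided tail `P(X >= n_sense | n_total, 0.5)`.
#'
#' @param n_sense Number of sense-oriented sites.
#' @param n_total Total number of sites.
#' @return The one-sided exact binomial p-value.
#' @export
orientation_bias_test <- function(n_sense, n_total) {
  if (n_total <= 0L) stop("n_total must be positive")
  if (n_sense < 0L || n_sense > n_total) stop("n_sense out of range")
  stats::pbinom(n_sense - 1L, n_total, 0.5, lower.tail = FALSE)
}

#' Enrichment of distances in an interval
#'
#' Fraction of TSS-to-gene-start distances inside `[lo, hi]` compared with
#' a background fraction (supplied, or computed genome-wide with
#' [genome_background_fraction()]).
#'
#' @param distances Non-negative distances in bp.
#' @param lo,hi Interval bounds in bp (defaults 360 and 760).
#' @param background_fraction Optional background fraction for the ratio.
#' @return List with `observed_fraction`, `background_fraction` (may be
#'   NA), `ratio` and `n`.
#' @export
interval_enrichment <- function(distances, lo = 360, hi = 760,
                                background_fraction = NULL) {
  distances <- distances[!is.na(distances)]
  if (length(distances) == 0L) stop("no distances supplied")
  if (any(distances < 0)) stop("distances must be >= 0")
  obs <- mean(distances >= lo & distances <= hi)
  bg <- if (is.null(background_fraction)) NA_real_ else background_fraction
  list(observed_fraction = obs, background_fraction = bg,
       ratio = if (is.na(bg) || bg == 0) NA_real_ else obs / bg,
       n = length(distances))
}

#' Genome-wide background fraction of distances in an interval
#'
#' For every genome coordinate (optionally restricted to intragenic
#' coordinates), the distance to the next available same-strand gene start
#' is computed exhaustively under both strand conventions (a hypothetical
#' site on `+` and on `-`), and the fraction of distances in `[lo, hi]` is
#' returned, pooling both conventions. Intragenic coordinates exclude the
#' containing gene's own start, mirroring the site classification rule.
#'
#' @param annotation A [gene_annotation()].
#' @param genome_length Genome length in bp.
#' @param lo,hi Interval bounds in bp.
#' @param intragenic_only Restrict to coordinates inside genes
#'   (default `TRUE`, matching the intragenic-site comparison).
#' @return Fraction in `[0, 1]`.
#' @export
genome_background_fraction <- function(annotation, genome_length, lo = 360,
                                       hi = 760, intragenic_only = TRUE) {
  L <- as.integer(genome_length)
  pos <- seq_len(L)
  host <- containing_gene_index(annotation, L)
  if (intragenic_only) pos <- pos[!is.na(host)]
  if (length(pos) == 0L) return(NaN)
  inside <- 0; total <- 0
  for (s in c("+", "-")) {
    d <- distance_to_next_start(pos, s, annotation, L,
                                exclude_gene = host[pos])
    d <- d[!is.na(d)]
    inside <- inside + sum(d >= lo & d <= hi)
    total <- total + length(d)
  }
  inside / total
}

# index of the containing gene per position (smallest start wins), NA where
# intergenic; vectorized over the whole genome
containing_gene_index <- function(ann, L) {
  host <- rep(NA_integer_, L)
  # later (larger-start) genes are written first so smaller starts win
  for (i in rev(order(ann$start))) {
    host[ann$start[i]:ann$end[i]] <- i
  }
  host
}

# vectorized distance from hypothetical TSS positions to the next available
# same-strand gene start, excluding per-position a containing gene
distance_to_next_start <- function(pos, strand, ann, L, exclude_gene = NULL) {
  tss <- as.numeric(predict_tss(pos, strand, L))
  idx <- which(ann$strand == strand)
  if (length(idx) == 0L) return(rep(NA_integer_, length(pos)))
  ss <- sort.int(gene_tx_start(ann)[idx], index.return = TRUE)
  sv <- ss$x
  gi <- idx[ss$ix]
  m <- length(sv)
  pick <- function(i, t) {        # distance from tss values t to slot i
    i <- ((i - 1L) %% m) + 1L
    d <- if (strand == "+") sv[i] - t else t - sv[i]
    d[d < 0] <- d[d < 0] + L
    list(i = i, d = d)
  }
  i0 <- if (strand == "+") findInterval(tss - 0.5, sv) + 1L
        else findInterval(tss + 0.5, sv)
  res <- pick(i0, tss)
  if (!is.null(exclude_gene)) {
    bad <- !is.na(exclude_gene) & gi[res$i] == exclude_gene
    if (any(bad)) {
      step <- if (strand == "+") 1L else -1L
      fix <- pick(res$i[bad] + step, tss[bad])
      res$d[bad] <- if (m == 1L) NA_real_ else fix$d
    }
  }
  as.integer(round(res$d))
}

#' Cumulative distance curves for sites and random positions
#'
#' Empirical cumulative distributions of the TSS-to-next-available-start
#' distance for intergenic sites, intragenic sites, all sites, and `n_random`
#' uniformly drawn random positions with random orientation.
#'
#' @param classified Output of [classify_sites()] (or the packaged site
#'   table with `class` and `distance` columns).
#' @param annotation A [gene_annotation()].
#' @param genome_length Genome length in bp.
#' @param n_random Number of random control positions (default 4000).
#' @param seed RNG seed for the random positions.
#' @return List of numeric distance vectors: `intergenic`, `intragenic`,
#'   `all`, `random`.
#' @export
cumulative_distance_curve <- function(classified, annotation, genome_length,
                                      n_random = 4000L, seed = 1L) {
  if (nrow(classified) == 0L) stop("no sites supplied")
  L <- as.integer(genome_length)
  d_all <- classified$distance
  inter <- classified$class %in% c("OS", "OA")
  rnd <- with_seed(seed, {
    p <- sample.int(L, n_random, replace = TRUE)
    s <- sample(c("+", "-"), n_random, replace = TRUE)
    host <- containing_gene_index(annotation, L)
    d <- integer(n_random)
    for (str in c("+", "-")) {
      k <- s == str
      d[k] <- distance_to_next_start(p[k], str, annotation, L,
                                     exclude_gene = host[p[k]])
    }
    d
  })
  list(intergenic = d_all[inter], intragenic = d_all[!inter], all = d_all,
       random = rnd[!is.na(rnd)])
}

#' Spearman correlation of ChIP enrichment and motif score
#'
#' Rank correlation (average ranks on ties) between FAT scores and PSSM
#' scores of a site table, optionally restricted to given classes.
#'
#' @param sites Site `data.frame` with `fat` and `pssm_score` columns (and
#'   `class` when filtering).
#' @param classes Optional class subset, e.g. `"OS"` or
#'   `c("OA","IS","IA")`.
#' @return Spearman's rho.
#' @export
spearman_fat_vs_score <- function(sites, classes = NULL) {
  if (!is.null(classes)) sites <- sites[sites$class %in% classes, ]
  if (nrow(sites) < 3L) stop("need at least 3 sites")
  if (length(unique(sites$fat)) < 2L || length(unique(sites$pssm_score)) < 2L) {
    stop("correlation undefined for a constant column")
  }
  stats::cor(sites$fat, sites$pssm_score, method = "spearman")
}
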