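# Cross-species conservation of binding sites: anchored +/-100 bp PSSM
# rescans in query genomes, the site x species score matrix, and the
# important/unimportant-position substitution-rate contrast.

#' Rescan a site's neighborhood in a query genome
#'
#' Given an anchor mapping the E. coli site into a query genome, scores the
#' 17-mer at the exact mapped position on the mapped strand (`exact_score`)
#' and the best-scoring 17-mer on either strand whose center lies within
#' `+/- window` bp of the mapped position (`best_score`, with its signed
#' offset in site orientation and its sequence as read on the hit strand).
#' A missing anchor yields an all-missing cell.
#'
#' @param site_id Site identifier for the cell.
#' @param query_genome [genome_record()] of the query species.
#' @param anchor One-row anchor `data.frame` (`mapped_position`,
#'   `mapped_strand`, `species`), or `NULL` when no homolog was found.
#' @param pssm A `pssm`.
#' @param window Rescan half-width in bp (default 100).
#' @return One-row `data.frame`: `site_id`, `species`, `homolog_found`,
#'   `exact_score`, `best_score`, `best_offset`, `best_strand`,
#'   `aligned` (best hit at offset 0 on the anchored strand), `best_seq`.
#' @export
conservation_scan <- function(site_id, query_genome, anchor, pssm,
                              window = 100L) {
  missing_cell <- data.frame(
    site_id = site_id, species = NA_character_, homolog_found = FALSE,
    exact_score = NA_real_, best_score = NA_real_, best_offset = NA_integer_,
    best_strand = NA_character_, aligned = FALSE, best_seq = NA_character_,
    exact_seq = NA_character_, stringsAsFactors = FALSE)
  if (is.null(anchor) || nrow(anchor) == 0L ||
      is.na(anchor$mapped_position[1L])) {
    return(missing_cell)
  }
  pos <- as.integer(anchor$mapped_position[1L])
  strand <- anchor$mapped_strand[1L]
  w <- pssm$width
  half <- (w - 1L) %/% 2L
  L <- query_genome$length
  if (!query_genome$circular &&
      (pos - window - half < 1L || pos + window + half > L)) {
    warning("scan window truncated at a contig end for site ", site_id)
    window <- min(window, pos - half - 1L, L - pos - half)
    if (window < 0L) return(missing_cell)
  }
  exact_seq <- extract_seq(query_genome, pos - half, w)
  if (strand == "-") exact_seq <- revcomp(exact_seq)
  exact <- score_sequence(pssm, exact_seq)
  hit <- scan_window(pssm, query_genome, pos, window)
  # offset in site orientation: positive = downstream of the anchored point
  off <- if (strand == "+") hit$position - pos else pos - hit$position
  data.frame(site_id = site_id, species = anchor$species[1L],
             homolog_found = TRUE, exact_score = as.numeric(exact),
             best_score = hit$score, best_offset = as.integer(off),
             best_strand = hit$strand,
             aligned = off == 0L && hit$strand == strand,
             best_seq = hit$sequence, exact_seq = exact_seq,
             stringsAsFactors = FALSE)
}

#' Build the site-by-species conservation matrix
#'
#' Runs [conservation_scan()] for every (site, species) pair. The long-form
#' cell table and a wide best-score matrix (sites as rows ordered by class
#' then id, species as columns, `NA` where no homolog was found) are
#' returned.
#'
#' @param sites Site table with `site_id` and (optionally) `class` columns.
#' @param species_genomes Named list of query [genome_record()]s.
#' @param anchors Anchor `data.frame` from [read_anchor_table()] or
#'   [mutate_ortholog()], with one row per (site, species) at most.
#' @param pssm A `pssm`.
#' @param window Rescan half-width in bp.
#' @return List with `cells` (long form) and `matrix` (sites x species
#'   best scores).
#' @export
build_conservation_matrix <- function(sites, species_genomes, anchors, pssm,
                                      window = 100L) {
  species <- names(species_genomes)
  if (is.null(species) && length(species_genomes) > 0L) {
    stop("species_genomes must be a named list")
  }
  key <- paste(anchors$site_id, anchors$species, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate anchors for a (site, species) pair")
  ord <- order(match(substr(sites$site_id, 1L, 2L), VALID_CLASSES),
               sites$site_id)
  sites <- sites[ord, , drop = FALSE]
  cells <- vector("list", nrow(sites) * length(species))
  k <- 0L
  for (sp in species) {
    for (i in seq_len(nrow(sites))) {
      sid <- sites$site_id[i]
      a <- anchors[anchors$site_id == sid & anchors$species == sp, ,
                   drop = FALSE]
      k <- k + 1L
      cell <- conservation_scan(sid, species_genomes[[sp]],
                                if (nrow(a)) a else NULL, pssm, window)
      cell$species <- sp
      cells[[k]] <- cell
    }
  }
  cells <- if (k == 0L) {
    conservation_scan("none", genome_record("empty", "A"), NULL,
                      pssm)[0, , drop = FALSE]
  } else {
    do.call(rbind, cells)
  }
  mat <- matrix(NA_real_, nrow(sites), length(species),
                dimnames = list(sites$site_id, species))
  for (j in seq_len(nrow(cells))) {
    mat[cells$site_id[j], cells$species[j]] <- cells$best_score[j]
  }
  list(cells = cells, matrix = mat)
}

#' Substitution tally constructor
#'
#' @param important_substitutions,important_examined Counts at
#'   strong-consensus motif positions.
#' @param unimportant_substitutions,unimportant_examined Counts at
#'   low-information motif positions.
#' @return A `substitution_tally` list.
#' @export
substitution_tally <- function(important_substitutions, important_examined,
                               unimportant_substitutions,
                               unimportant_examined) {
  if (important_substitutions > important_examined ||
      unimportant_substitutions > unimportant_examined) {
    stop("substitutions cannot exceed examined positions")
  }
  structure(list(important_substitutions = important_substitutions,
                 important_examined = important_examined,
                 unimportant_substitutions = unimportant_substitutions,
                 unimportant_examined = unimportant_examined),
            class = "substitution_tally")
}

#' Count substitutions at important versus unimportant motif positions
#'
#' For every qualifying (site, homolog) pair -- homolog found, best hit
#' perfectly aligned (offset 0 on the anchored strand) and scoring above
#' `min_score` -- compares the E. coli 17-mer with the homolog 17-mer at
#' the five strong-consensus ("important") positions, skipping positions
#' where the E. coli base itself deviates from the PSSM consensus, and at
#' the five low-information ("unimportant") positions.
#'
#' @param ecoli_motifs Named character vector of E. coli 17-mers, names are
#'   site ids.
#' @param cells Cell table from [build_conservation_matrix()] or rows from
#'   [conservation_scan()].
#' @param pssm The `pssm` supplying consensus and position sets.
#' @param min_score Minimum homolog score (default 6). Set to `-Inf` to
#'   disable the strong-site filter, e.g. for neutral calibration.
#' @param alignment `"best"` qualifies pairs on the best rescan hit sitting
#'   exactly at the anchored coordinate ("perfectly aligned"); `"exact"`
#'   compares the 17-mer at the anchored coordinate itself, regardless of
#'   where the window maximum lies.
#' @return A `substitution_tally` with an extra `n_pairs` and
#'   `n_skipped_missing` field.
#' @export
substitution_stats <- function(ecoli_motifs, cells, pssm, min_score = 6,
                               alignment = c("best", "exact")) {
  alignment <- match.arg(alignment)
  cons <- strsplit(pssm$consensus, "")[[1L]]
  imp <- pssm$important_positions
  unimp <- pssm$unimportant_positions
  is_sub <- ie <- us <- ue <- 0L
  n_pairs <- 0L; n_missing <- 0L
  for (j in seq_len(nrow(cells))) {
    sid <- cells$site_id[j]
    ec <- ecoli_motifs[[sid]]
    if (is.null(ec) || is.na(ec)) next
    if (!isTRUE(cells$homolog_found[j])) next
    hom_seq <- if (alignment == "exact" && "exact_seq" %in% names(cells))
      cells$exact_seq[j] else cells$best_seq[j]
    hom_score <- if (alignment == "exact") cells$exact_score[j]
                 else cells$best_score[j]
    if (is.na(hom_seq)) { n_missing <- n_missing + 1L; next }
    if (alignment == "best" && !isTRUE(cells$aligned[j])) next
    if (is.na(hom_score) || hom_score <= min_score) next
    n_pairs <- n_pairs + 1L
    e <- strsplit(ec, "")[[1L]]
    h <- strsplit(hom_seq, "")[[1L]]
    imp_use <- imp[e[imp] == cons[imp]]   # consensus-match restriction
    ie <- ie + length(imp_use)
    is_sub <- is_sub + sum(e[imp_use] != h[imp_use])
    ue <- ue + length(unimp)
    us <- us + sum(e[unimp] != h[unimp])
  }
  tally <- substitution_tally(is_sub, ie, us, ue)
  tally$n_pairs <- n_pairs
  tally$n_skipped_missing <- n_missing
  tally
}

#' Fold ratio of substitution rates (unimportant over important)
#'
#' @param tally A [substitution_tally()].
#' @return `(unimportant rate) / (important rate)`; `Inf` when no
#'   substitutions occurred at important positions.
#' @export
fold_ratio <- function(tally) {
  if (tally$important_examined <= 0L) stop("no important positions examined")
  imp_rate <- tally$important_substitutions / tally$important_examined
  unimp_rate <- tally$unimportant_substitutions / tally$unimportant_examined
  if (imp_rate == 0) return(Inf)
  unimp_rate / imp_rate
}

#' Anchor a site into a query genome
#'
#' In `provided` mode the anchor is taken from a pre-read anchor table. In
#' `naive` mode -- valid for substitution-only orthologs where coordinates
#' are preserved, as produced by [mutate_ortholog()] -- a 300-nt fragment
#' centered on the E. coli motif is located in the query genome by exact
#' 20-bp seeds extended to a full-fragment Hamming score; the anchor is the
#' implied fragment center.
#'
#' @param site One row of a site table (needs `site_id`, `motif_center`,
#'   `motif_strand`).
#' @param ecoli_genome The E. coli [genome_record()].
#' @param query_genome The query [genome_record()].
#' @param mode `"provided"` or `"naive"`.
#' @param anchors Anchor table for `provided` mode.
#' @param species Species label recorded in the result.
#' @param fragment Fragment length for naive anchoring (default 300).
#' @param min_identity Minimum full-fragment identity to accept a naive
#'   anchor (default 0.5).
#' @return One-row anchor `data.frame`; `mapped_position` is `NA` when no
#'   anchor was found.
#' @export
anchor_from_alignment <- function(site, ecoli_genome, query_genome,
                                  mode = c("provided", "naive"),
                                  anchors = NULL, species = "query",
                                  fragment = 300L, min_identity = 0.5) {
  mode <- match.arg(mode)
  if (mode == "provided") {
    if (is.null(anchors)) stop("provided mode needs an anchor table")
    a <- anchors[anchors$site_id == site$site_id &
                 anchors$species == species, , drop = FALSE]
    if (nrow(a) == 0L) {
      return(data.frame(site_id = site$site_id, species = species,
                        mapped_position = NA_integer_,
                        mapped_strand = NA_character_, evalue = NA_real_,
                        stringsAsFactors = FALSE))
    }
    return(a[1L, , drop = FALSE])
  }
  center <- as.integer(site$motif_center)
  frag_start <- center - fragment %/% 2L
  frag <- extract_seq(ecoli_genome, frag_start, fragment)
  qseq <- query_genome$sequence
  qchars <- strsplit(qseq, "")[[1L]]
  fchars <- strsplit(frag, "")[[1L]]
  seed_offsets <- seq.int(1L, fragment - 19L, by = 20L)
  best <- NULL
  for (so in seed_offsets) {
    seed <- substr(frag, so, so + 19L)
    hits <- gregexpr(seed, qseq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    for (h in hits) {
      qstart <- h - so + 1L           # implied fragment start in the query
      if (qstart < 1L || qstart + fragment - 1L > query_genome$length) next
      ident <- mean(qchars[qstart:(qstart + fragment - 1L)] == fchars)
      if (is.null(best) || ident > best$ident) {
        best <- list(qstart = qstart, ident = ident)
      }
    }
  }
  if (is.null(best) || best$ident < min_identity) {
    return(data.frame(site_id = site$site_id, species = species,
                      mapped_position = NA_integer_,
                      mapped_strand = NA_character_, evalue = NA_real_,
                      stringsAsFactors = FALSE))
  }
  data.frame(site_id = site$site_id, species = species,
             mapped_position = best$qstart + (center - frag_start),
             mapped_strand = site$motif_strand,
             evalue = NA_real_, match_fraction = best$ident,
             stringsAsFactors = FALSE)
}
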