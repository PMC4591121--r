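# Readers/writers for external formats and the packaged site-table fixture.
# This file is the single home for coordinate conventions: internally all
# coordinates are 1-based inclusive positions on a (by default) circular
# chromosome; BED's half-open 0-based intervals are converted at the boundary.

VALID_CLASSES <- c("OS", "OA", "IS", "IA")

#' Construct a genome record
#'
#' A genome record holds a single chromosome as an upper-case DNA string on a
#' 1-based, by default circular, coordinate system.
#'
#' @param id Sequence identifier.
#' @param sequence DNA string (A/C/G/T/N).
#' @param circular Is the chromosome circular? Bacterial chromosomes are.
#' @return An object of class `genome_record` with fields `id`, `sequence`,
#'   `length` and `circular`.
#' @export
genome_record <- function(id, sequence, circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("genome sequence must have length >= 1")
  if (grepl("[^ACGTN]", sequence)) {
    stop("genome sequence contains characters outside A/C/G/T/N")
  }
  structure(
    list(id = as.character(id), sequence = sequence,
         length = nchar(sequence), circular = isTRUE(circular)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp (%s)\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a gene annotation table
#'
#' @param gene_id Gene names.
#' @param start,end 1-based inclusive top-strand coordinates, `start <= end`.
#' @param strand `"+"` or `"-"` per gene.
#' @param b_number Optional systematic identifiers (b-numbers).
#' @return A `gene_annotation` data frame sorted by `start` with columns
#'   `gene_id`, `b_number`, `start`, `end`, `strand`.
#' @export
gene_annotation <- function(gene_id, start, end, strand, b_number = gene_id) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start)) stop("gene end < start")
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  ann <- data.frame(gene_id = as.character(gene_id),
                    b_number = as.character(b_number),
                    start = start, end = end, strand = as.character(strand),
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Strand-aware transcription-relevant gene start
#'
#' The "start" used in downstream-distance logic is the first coding base in
#' transcription order: the `start` field for `+` genes and the `end` field
#' for `-` genes.
#'
#' @param annotation A [gene_annotation()].
#' @return Integer vector of strand-aware start coordinates.
#' @export
gene_tx_start <- function(annotation) {
  ifelse(annotation$strand == "+", annotation$start, annotation$end)
}

#' Construct a coverage track
#'
#' @param values Non-negative per-position depth, one slot per genome position.
#' @param genome_id Genome the track belongs to.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded).
#' @return A numeric vector of class `coverage_track` with attributes
#'   `genome_id` and `strand`.
#' @export
coverage_track <- function(values, genome_id = "genome", strand = "*") {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("coverage values must be finite and >= 0")
  }
  structure(values, genome_id = genome_id, strand = strand,
            class = "coverage_track")
}

# keep attributes through arithmetic-free subsetting elsewhere; tracks are
# otherwise treated as plain numeric vectors.

## ---- coordinate helpers (shared across modules) ----

# wrap a 1-based position onto a circular chromosome of length L
wrap_pos <- function(pos, len) {
  ((pos - 1L) %% len) + 1L
}

# extract a subsequence with circular wrap-around
extract_seq <- function(genome, start, width) {
  len <- genome$length
  idx <- wrap_pos(seq.int(start, length.out = width), len)
  if (all(diff(idx) == 1L)) {
    substr(genome$sequence, idx[1L], idx[width])
  } else {
    paste(strsplit(genome$sequence, "")[[1L]][idx], collapse = "")
  }
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

## ---- FASTA ----

#' Read genome sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param circular Mark chromosomes as circular (default `TRUE`).
#' @return A list of [genome_record()] objects in file order.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA: ", conditionMessage(e)))
  if (length(set) == 0L) stop("malformed FASTA: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    genome_record(ids[i], as.character(set[[i]]), circular = circular))
}

#' Write genome records to a FASTA file
#'
#' @param genomes A [genome_record()] or list of them.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## ---- gene annotation (GFF3 / BED6) ----

#' Read a gene annotation from GFF3 or BED
#'
#' GFF3 `gene` features (or all features when none are typed `gene`) are used
#' directly; BED intervals are converted from half-open 0-based to 1-based
#' inclusive coordinates at this boundary.
#'
#' @param path Annotation file.
#' @param dialect `"gff3"`, `"bed"`, or `"auto"` (by file extension).
#' @return A [gene_annotation()] sorted by start.
#' @export
read_annotation <- function(path, dialect = c("auto", "gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "bed") "bed" else "gff3"),
    error = function(e) stop("malformed ", dialect, ": ", conditionMessage(e)))
  df <- as.data.frame(gr)
  if (dialect == "gff3" && "type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no gene records in ", path)
  strand <- as.character(df$strand)
  if (any(!strand %in% c("+", "-"))) stop("unknown strand in ", path)
  name <- if ("Name" %in% names(df) && !all(is.na(df$Name))) df$Name
          else if ("name" %in% names(df)) df$name
          else if ("ID" %in% names(df)) df$ID
          else paste0("gene", seq_len(nrow(df)))
  bnum <- if ("locus_tag" %in% names(df) && !all(is.na(df$locus_tag))) df$locus_tag else name
  gene_annotation(gene_id = name, start = df$start, end = df$end,
                  strand = strand, b_number = bnum)
}

#' Write a gene annotation as GFF3
#'
#' @param annotation A [gene_annotation()].
#' @param path Output file.
#' @param genome_id Sequence identifier to write in column 1.
#' @export
write_annotation <- function(annotation, path, genome_id = "genome") {
  lines <- c("##gff-version 3",
             sprintf("%s\tsigma54scan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;locus_tag=%s",
                     genome_id, annotation$start, annotation$end,
                     annotation$strand, annotation$gene_id,
                     annotation$gene_id, annotation$b_number))
  writeLines(lines, path)
  invisible(path)
}

## ---- coverage (bedGraph / fixed-step wiggle) ----

#' Read a coverage track from bedGraph or fixed-step wiggle
#'
#' Positions not covered by any interval get depth 0; bedGraph intervals
#' (half-open, 0-based) are expanded per base.
#'
#' @param path Coverage file.
#' @param genome_length Genome length in bp; defines the track length.
#' @param strand Track strand (`"+"`, `"-"`, `"*"`).
#' @return A [coverage_track()] of length `genome_length`.
#' @export
read_coverage <- function(path, genome_length, strand = "*") {
  if (!file.exists(path)) stop("file not found: ", path)
  genome_length <- as.integer(genome_length)
  values <- numeric(genome_length)
  info <- file.info(path)
  gid <- "genome"
  if (is.na(info$size) || info$size > 0L) {
    fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedGraph"
    gr <- tryCatch(rtracklayer::import(path, format = fmt),
                   error = function(e) stop("malformed coverage file: ",
                                            conditionMessage(e)))
    if (length(gr) > 0L) {
      df <- as.data.frame(gr)
      if (max(df$end) > genome_length) {
        stop("coverage interval beyond genome_length (", max(df$end), " > ",
             genome_length, ")")
      }
      gid <- as.character(df$seqnames[1L])
      for (i in seq_len(nrow(df))) {
        values[df$start[i]:df$end[i]] <- df$score[i]
      }
    }
  }
  coverage_track(values, genome_id = gid, strand = strand)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth are collapsed into intervals; zero runs are omitted.
#'
#' @param track A [coverage_track()] (or numeric vector).
#' @param path Output file.
#' @param genome_id Sequence name for column 1.
#' @export
write_coverage <- function(track, path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- attr(track, "genome_id")
    if (is.null(genome_id)) genome_id <- "genome"
  }
  r <- rle(as.numeric(track))
  ends <- cumsum(r$lengths)
  starts0 <- ends - r$lengths          # bedGraph is 0-based half-open
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", genome_id, starts0[keep], ends[keep],
                   format(r$values[keep], trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

## ---- site table (packaged fixture schema) ----

#' Read a sigma54 binding-site table
#'
#' Reads the tab-separated site-table schema used by the packaged fixture:
#' one row per binding site with its ChIP-seq peak center, FAT score, 17-bp
#' motif and motif center/strand, overlapping and downstream genes, distance
#' to the downstream gene start, and PSSM score. The site class (OS/OA/IS/IA)
#' is derivable from the `site_id` prefix.
#'
#' @param path TSV file; defaults to the packaged transcription of the 135
#'   published E. coli sites.
#' @return A `data.frame` of validated site records.
#' @export
read_site_table <- function(path = sigma54_sites_path()) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  required <- c("site_id", "peak_center", "fat", "motif", "motif_center",
                "motif_strand", "downstream_gene", "distance", "pssm_score")
  missing <- setdiff(required, names(x))
  if (length(missing)) stop("site table missing columns: ",
                            paste(missing, collapse = ", "))
  if (!"class" %in% names(x)) x$class <- substr(x$site_id, 1L, 2L)
  if (any(!x$class %in% VALID_CLASSES)) {
    stop("site_id prefixes must be one of ", paste(VALID_CLASSES, collapse = "/"))
  }
  bad <- nchar(x$motif) != 17L | grepl("[^ACGT]", x$motif)
  if (any(bad)) {
    stop("motifs must be 17-mers over ACGT; offending: ",
         paste(x$site_id[bad], collapse = ", "))
  }
  if (any(x$fat < 1)) stop("FAT scores must be >= 1")
  if (any(!x$motif_strand %in% c("+", "-"))) stop("motif_strand must be +/-")
  intra <- x$class %in% c("IS", "IA")
  if ("overlapping_gene" %in% names(x) &&
      any(intra & (is.na(x$overlapping_gene) | x$overlapping_gene == ""))) {
    stop("intragenic (IS/IA) rows must name an overlapping gene")
  }
  x
}

#' Path to the packaged 135-site fixture
#' @return File path of the packaged site table.
#' @export
sigma54_sites_path <- function() {
  system.file("extdata", "sigma54_sites.tsv", package = "sigma54scan",
              mustWork = TRUE)
}

## ---- homology anchor table (BLAST tabular / anchor TSV) ----

#' Read a homology anchor table
#'
#' Accepts either 12-column BLAST tabular output (outfmt 6: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore),
#' in which case the mapped position is the midpoint of the subject interval
#' and the strand follows subject orientation, or the package's 5-column
#' anchor TSV (`site_id species mapped_position mapped_strand evalue`).
#' Rows with `evalue > evalue_max` are dropped; of the remaining hits, the
#' lowest-evalue hit per (site, species) pair is kept, ties broken by file
#' order.
#'
#' @param path Anchor file.
#' @param evalue_max E-value cutoff (default `1e-4`).
#' @return `data.frame` with columns `site_id`, `species`, `mapped_position`,
#'   `mapped_strand`, `evalue`.
#' @export
read_anchor_table <- function(path, evalue_max = 1e-4) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(site_id = character(), species = character(),
                      mapped_position = integer(), mapped_strand = character(),
                      evalue = numeric(), stringsAsFactors = FALSE)
  if (isTRUE(file.size(path) == 0)) return(empty)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (nrow(raw) == 0L || (nrow(raw) == 1L && all(is.na(raw[1L, ])))) {
    return(data.frame(site_id = character(), species = character(),
                      mapped_position = integer(), mapped_strand = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  if (is.character(raw[[1L]]) && raw[1L, 1L] == "site_id") {
    raw <- raw[-1L, , drop = FALSE]
  }
  if (ncol(raw) >= 12L) {
    sstart <- suppressWarnings(as.numeric(raw[[9L]]))
    send <- suppressWarnings(as.numeric(raw[[10L]]))
    evalue <- suppressWarnings(as.numeric(raw[[11L]]))
    anch <- data.frame(site_id = as.character(raw[[1L]]),
                       species = as.character(raw[[2L]]),
                       mapped_position = as.integer(round((sstart + send) / 2)),
                       mapped_strand = ifelse(send >= sstart, "+", "-"),
                       evalue = evalue, stringsAsFactors = FALSE)
  } else if (ncol(raw) == 5L) {
    anch <- suppressWarnings(data.frame(
      site_id = as.character(raw[[1L]]),
      species = as.character(raw[[2L]]),
      mapped_position = as.integer(raw[[3L]]),
      mapped_strand = as.character(raw[[4L]]),
      evalue = as.numeric(raw[[5L]]), stringsAsFactors = FALSE))
  } else {
    stop("anchor table must have 12 (BLAST outfmt 6) or 5 columns, got ",
         ncol(raw))
  }
  if (any(is.na(anch$mapped_position)) || any(is.na(anch$evalue))) {
    stop("unparseable numeric fields in anchor table")
  }
  anch <- anch[anch$evalue <= evalue_max, , drop = FALSE]
  if (nrow(anch) == 0L) { rownames(anch) <- NULL; return(anch) }
  # keep the best (lowest-evalue) hit per (site, species); ties -> file order
  key <- paste(anch$site_id, anch$species, sep = "\r")
  ord <- order(key, anch$evalue, seq_len(nrow(anch)))
  anch <- anch[ord, , drop = FALSE]
  anch <- anch[!duplicated(paste(anch$site_id, anch$species, sep = "\r")), ,
               drop = FALSE]
  anch <- anch[order(match(paste(anch$site_id, anch$species, sep = "\r"),
                           unique(key))), , drop = FALSE]
  rownames(anch) <- NULL
  anch
}

#' Write an anchor table in the 5-column TSV dialect
#'
#' @param anchors Anchor `data.frame` as returned by [read_anchor_table()].
#' @param path Output file.
#' @export
write_anchor_table <- function(anchors, path) {
  utils::write.table(anchors[, c("site_id", "species", "mapped_position",
                                 "mapped_strand", "evalue")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
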