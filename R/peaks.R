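# Peak calling on normalized coverage with Fold-Above-Threshold (FAT)
# scoring. FAT = peak maximum / high-stringency threshold, so FAT = 1 marks
# the calling threshold; low-stringency calling divides the threshold by 5
# but keeps the FAT denominator, so low-stringency peaks can have FAT < 1.

#' Normalize a coverage track to genome-wide mean 1
#'
#' When an input (control) track is supplied, the ChIP track is first
#' divided by the smoothed, floored, mean-normalized input; the ratio is
#' then normalized to mean 1. FAT scores downstream are therefore invariant
#' to multiplying the raw coverage by any positive constant.
#'
#' @param track ChIP [coverage_track()] (or numeric vector).
#' @param input Optional input/control track of the same length.
#' @param input_floor Lower floor applied to the smoothed, normalized input
#'   before division (default 0.2), preventing blow-ups in low-coverage
#'   regions.
#' @param input_smooth Width in bp of the running-mean smoother applied to
#'   the input (default 500).
#' @return A normalized [coverage_track()] with mean exactly 1.
#' @export
normalize_coverage <- function(track, input = NULL, input_floor = 0.2,
                               input_smooth = 500L) {
  x <- as.numeric(track)
  if (length(x) == 0L || sum(x) <= 0) stop("track is empty or all zero")
  if (!is.null(input)) {
    inp <- as.numeric(input)
    if (length(inp) != length(x)) stop("input track length mismatch")
    inp <- inp / mean(inp)
    inp <- running_mean_circular(inp, input_smooth)
    x <- x / pmax(inp, input_floor)
  }
  coverage_track(x / mean(x),
                 genome_id = attr(track, "genome_id") %||% "genome",
                 strand = attr(track, "strand") %||% "*")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

running_mean_circular <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  n <- length(x)
  k <- min(width, n)
  pad <- k %/% 2L
  xp <- c(x[(n - pad + 1L):n], x, x[1L:pad])
  cs <- cumsum(c(0, xp))
  (cs[(k + 1L):(k + n)] - cs[1L:n]) / k
}

#' Derive the peak-calling threshold from a normalized track
#'
#' The threshold is `mean + k_sd * SD` computed over positions at or below
#' the `trim_q` quantile of the track. Trimming makes the threshold robust
#' to the enriched positions themselves: adding a single huge outlier moves
#' it by well under 1%.
#'
#' @param normalized_track Output of [normalize_coverage()].
#' @param k_sd Number of SDs above the (trimmed) mean (default 4).
#' @param trim_q Quantile above which positions are excluded from the
#'   mean/SD (default 0.99).
#' @return Positive threshold on the normalized depth scale.
#' @export
compute_threshold <- function(normalized_track, k_sd = 4, trim_q = 0.99) {
  x <- as.numeric(normalized_track)
  q <- stats::quantile(x, trim_q, names = FALSE)
  kept <- x[x <= q]
  if (length(kept) == 0L) stop("trimming removed all positions")
  thr <- mean(kept) + k_sd * stats::sd(kept)
  if (is.na(thr)) thr <- mean(kept)   # constant track: SD undefined for n=1
  if (thr <= 0) stop("non-positive threshold")
  thr
}

#' Call peaks on a normalized coverage track
#'
#' Maximal runs of positions above the effective threshold (the supplied
#' threshold for high stringency, one fifth of it for low stringency) are
#' found; runs separated by fewer than `merge_gap` bp are merged. The peak
#' center is the position of the run maximum (leftmost on ties) and FAT is
#' the run maximum divided by the *high* threshold regardless of
#' stringency.
#'
#' @param normalized_track Output of [normalize_coverage()].
#' @param threshold High-stringency threshold from [compute_threshold()].
#' @param merge_gap Runs closer than this many bp are merged (default 200).
#' @param stringency `"high"` or `"low"` (threshold reduced 5-fold).
#' @return `data.frame` with columns `center`, `start`, `end`,
#'   `max_height`, `fat` (real; see [fat_integer()] for the reported
#'   rounding).
#' @export
call_peaks <- function(normalized_track, threshold, merge_gap = 200L,
                       stringency = c("high", "low")) {
  stringency <- match.arg(stringency)
  if (threshold <= 0) stop("threshold must be positive")
  x <- as.numeric(normalized_track)
  eff <- if (stringency == "low") threshold / 5 else threshold
  above <- x > eff
  empty <- data.frame(center = integer(), start = integer(), end = integer(),
                      max_height = numeric(), fat = numeric())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by fewer than merge_gap bp
  if (nrow(runs) > 1L) {
    gap <- runs$start[-1L] - runs$end[-nrow(runs)] - 1L
    grp <- cumsum(c(0L, as.integer(gap >= merge_gap)))
    runs <- data.frame(start = tapply(runs$start, grp, min),
                       end = tapply(runs$end, grp, max))
  }
  center <- integer(nrow(runs)); mx <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    win <- x[runs$start[i]:runs$end[i]]
    center[i] <- runs$start[i] + which.max(win) - 1L   # leftmost argmax
    mx[i] <- max(win)
  }
  data.frame(center = center, start = as.integer(runs$start),
             end = as.integer(runs$end), max_height = mx,
             fat = mx / threshold, row.names = NULL)
}

#' Integer FAT score as reported in site tables
#'
#' FAT is carried as a real number internally and rounded to the nearest
#' integer, with a minimum of 1, for table output.
#'
#' @param fat Real FAT scores.
#' @return Integer FAT scores.
#' @export
fat_integer <- function(fat) {
  pmax(1L, as.integer(round(fat)))
}

#' Evaluate peak recovery against a simulation truth table
#'
#' @param peaks Peaks from [call_peaks()].
#' @param truth Truth table from [plant_sites()].
#' @param genome_length Genome length for circular distances.
#' @param tol Positional tolerance in bp (default 50).
#' @return List with `sensitivity` (fraction of truth sites matched by a
#'   peak center within `tol`), `n_matched`, `n_truth`, `n_peaks`, and
#'   `median_abs_error` over matched sites.
#' @export
evaluate_peak_recovery <- function(peaks, truth, genome_length, tol = 50L) {
  if (nrow(truth) == 0L) stop("empty truth table")
  err <- vapply(truth$position, function(p) {
    if (nrow(peaks) == 0L) return(Inf)
    min(circ_dist(p, peaks$center, genome_length))
  }, numeric(1))
  matched <- err <= tol
  list(sensitivity = mean(matched), n_matched = sum(matched),
       n_truth = nrow(truth), n_peaks = nrow(peaks),
       median_abs_error = if (any(matched)) stats::median(err[matched]) else NA_real_)
}
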