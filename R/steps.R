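#' Remove margin events
#'
#' Margin events are saturated at (or beyond) the instrument detection
#' limits and carry no usable signal. Given per-channel boundaries in data
#' units, every event falling outside them on any bounded channel is
#' removed. Boundaries are inclusive by default: an event sitting exactly at
#' a bound is removed, because saturated events pile up exactly at the
#' detector range `$PnR`.
#'
#' @param tbl an [event_table()].
#' @param bounds named list mapping channel name to `c(low, high)`;
#'   channels absent from the list are unconstrained.
#' @param inclusive if `TRUE` (default) only events with
#'   `low < value < high` are kept; if `FALSE`, `low <= value <= high`.
#' @return the filtered [event_table()]; event identifiers preserved.
#' @export
remove_margins <- function(tbl, bounds, inclusive = TRUE) {
  stopifnot(inherits(tbl, "event_table"))
  if (length(bounds) == 0) return(tbl)
  if (is.null(names(bounds))) stop("bounds must be a named list")
  keep <- rep(TRUE, n_events(tbl))
  for (ch in names(bounds)) {
    chn <- resolve_channel(tbl, ch)
    b <- bounds[[ch]]
    if (length(b) != 2 || !(b[1] < b[2])) {
      stop("bounds for channel '", ch, "' must be c(low, high) with low < high")
    }
    v <- tbl$values[, chn]
    keep <- keep & if (inclusive) v > b[1] & v < b[2] else v >= b[1] & v <= b[2]
  }
  filter_events(tbl, keep)
}

#' Compensate fluorescence spillover
#'
#' Each dye's emission spills into neighbouring detectors; the acquisition
#' instrument stores the mixing as a spillover matrix S (rows = source dyes,
#' columns = detectors, row-normalized so the diagonal is 1). Observed
#' fluorescence is `raw = true %*% S`, so compensation right-multiplies the
#' fluorescence sub-matrix by `solve(S)`. Scatter and Time columns are
#' untouched; event identifiers are preserved.
#'
#' @param tbl an [event_table()].
#' @param spill a `spillover_matrix` (see [parse_spillover()]), or the
#'   string `"from-keywords"` to look the matrix up in the table's own FCS
#'   keywords.
#' @return the compensated [event_table()].
#' @export
compensate <- function(tbl, spill = "from-keywords") {
  stopifnot(inherits(tbl, "event_table"))
  if (identical(spill, "from-keywords")) spill <- get_spillover(tbl)
  ch <- colnames(spill)
  missing <- setdiff(ch, tbl$channels)
  if (length(missing)) {
    stop("spillover channels absent from the table: ",
         paste(missing, collapse = ", "))
  }
  s <- unclass(spill)
  s <- s / diag(s)   # ensure diagonal 1 even for hand-built matrices
  inv <- tryCatch(solve(s),
                  error = function(e) stop("spillover matrix is singular: ",
                                           conditionMessage(e)))
  tbl$values[, ch] <- tbl$values[, ch, drop = FALSE] %*% inv
  tbl
}

#' Quality control in time
#'
#' Removes acquisition-time segments with unstable signal. Events are
#' ordered by the Time channel and split into consecutive bins of
#' `bin_size` events. For every monitored channel the per-bin median is
#' computed; a bin is flagged when any channel's bin median deviates from
#' the overall median of bin medians by more than `mad_cutoff` robust
#' standard deviations (1.4826 x MAD of the bin medians). All events of
#' flagged bins are removed. This is a deliberately simple stability
#' monitor: it detects location shifts of the signal over time, which is
#' the dominant failure mode (clogs, pressure drops, fluidics drift).
#'
#' When the MAD of bin medians is zero (perfectly constant signal) nothing
#' is flagged. When fewer than `min_bins * bin_size` events are available
#' the step is skipped with a warning and the table returned unchanged.
#'
#' @param tbl an [event_table()].
#' @param channels channels to monitor.
#' @param bin_size events per time bin (>= 10).
#' @param mad_cutoff robust z-score threshold (> 0), default 6.
#' @param min_bins minimum number of bins required to run, default 5.
#' @param time_channel name of the time channel, default `"Time"`.
#' @return the filtered [event_table()].
#' @export
qc_in_time <- function(tbl, channels, bin_size = 100L, mad_cutoff = 6,
                       min_bins = 5L, time_channel = "Time") {
  stopifnot(inherits(tbl, "event_table"))
  if (bin_size < 10) stop("bin_size must be >= 10")
  if (mad_cutoff <= 0) stop("mad_cutoff must be > 0")
  tch <- resolve_channel(tbl, time_channel)
  channels <- vapply(channels, function(ch) resolve_channel(tbl, ch),
                     character(1), USE.NAMES = FALSE)
  n <- n_events(tbl)
  if (n < min_bins * bin_size) {
    warning("qc_in_time skipped: ", n, " events < ", min_bins, " bins of ",
            bin_size)
    return(tbl)
  }
  ord <- order(tbl$values[, tch])
  n_bins <- n %/% bin_size          # trailing partial bin joins the last bin
  bin_of_sorted <- pmin(ceiling(seq_len(n) / bin_size), n_bins)
  flagged <- rep(FALSE, n_bins)
  for (ch in channels) {
    med <- vapply(split(tbl$values[ord, ch], bin_of_sorted),
                  stats::median, numeric(1))
    center <- stats::median(med)
    scale <- 1.4826 * stats::median(abs(med - center))
    if (scale == 0) next            # constant signal: nothing to flag
    flagged <- flagged | (abs(med - center) / scale > mad_cutoff)
  }
  drop_rows <- ord[flagged[bin_of_sorted]]
  keep <- rep(TRUE, n)
  keep[drop_rows] <- FALSE
  filter_events(tbl, keep)
}

#' Remove doublets
#'
#' Doublets (two cells measured as one event) have a larger pulse area for
#' the same pulse height, hence an elevated FSC-A / FSC-H ratio. Per event
#' the ratio `r = area / height` is computed and events are kept when
#' `r <= median(r) + nmad * 1.4826 * MAD(r)`. With all ratios identical
#' (MAD = 0) the threshold is the median itself, so nothing is removed.
#' Events with non-positive height are excluded from the statistics and
#' removed, with a warning.
#'
#' @param tbl an [event_table()].
#' @param area_channel,height_channel pulse area / height channel names
#'   (default `"FSC-A"` / `"FSC-H"`).
#' @param nmad threshold in robust standard deviations, default 4.
#' @return the filtered [event_table()].
#' @export
remove_doublets <- function(tbl, area_channel = "FSC-A",
                            height_channel = "FSC-H", nmad = 4) {
  stopifnot(inherits(tbl, "event_table"))
  a <- tbl$values[, resolve_channel(tbl, area_channel)]
  h <- tbl$values[, resolve_channel(tbl, height_channel)]
  bad_h <- h <= 0
  if (any(bad_h)) {
    warning(sum(bad_h), " events with non-positive ", height_channel,
            " excluded from doublet statistics and removed")
  }
  r <- a / h
  r_ok <- r[!bad_h]
  med <- stats::median(r_ok)
  cutoff <- med + nmad * 1.4826 * stats::median(abs(r_ok - med))
  keep <- !bad_h & r <= cutoff
  filter_events(tbl, keep)
}

#' Remove debris
#'
#' Debris (subcellular fragments) forms a cluster near the origin of the
#' (FSC-A, SSC-A) plane. Events are clustered with a Gaussian mixture model
#' (EM, full covariances) into `n_clusters` groups on the two scatter
#' channels standardized to unit scale; the cluster whose centroid (in
#' original data units) has the smallest Euclidean norm from the origin is
#' removed. Initialization is deterministic given `seed`.
#'
#' @param tbl an [event_table()] with at least `10 * n_clusters` events.
#' @param fsc_channel,ssc_channel scatter channel names.
#' @param n_clusters number of mixture components (>= 2), typically 2:
#'   one debris cluster and one target-population cluster.
#' @param seed integer seed for the EM initialization.
#' @return the filtered [event_table()].
#' @export
remove_debris <- function(tbl, fsc_channel = "FSC-A", ssc_channel = "SSC-A",
                          n_clusters = 2L, seed = 0L) {
  stopifnot(inherits(tbl, "event_table"))
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (n_events(tbl) < 10 * n_clusters) {
    stop("too few events for debris clustering (need >= ", 10 * n_clusters, ")")
  }
  x <- tbl$values[, c(resolve_channel(tbl, fsc_channel),
                      resolve_channel(tbl, ssc_channel))]
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  z <- sweep(x, 2, sds, "/")
  local_rng(seed)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fit <- mclust::Mclust(z, G = n_clusters, modelNames = "VVV",
                        verbose = FALSE)
  if (is.null(fit)) stop("debris clustering failed: EM did not converge")
  centroids_z <- t(fit$parameters$mean)             # clusters x 2
  centroids <- sweep(centroids_z, 2, sds, "*")      # back to data units
  debris_k <- which.min(sqrt(rowSums(centroids^2)))
  filter_events(tbl, fit$classification != debris_k)
}

#' Remove dead cells
#'
#' Dead cells take up the viability (Live & Dead) dye and are bright in its
#' channel; live and dead cells form two density modes on the transformed
#' scale. A Gaussian kernel density estimate (Silverman bandwidth, 512-point
#' grid) is computed on the transformed intensities, the two highest
#' prominent local maxima are located (a peak counts as a population when it
#' reaches at least 5% of the top density and the valley between the two
#' peaks dips below half the lower one), and the threshold is placed at the
#' density minimum between them. Events above the threshold are removed. If
#' no such pair of peaks is found the distribution is treated as unimodal
#' (no dead population): the threshold falls back to the 0.99 quantile,
#' with a warning.
#'
#' Thresholding happens in display (transformed) space, where the two modes
#' are well-separated and comparably sized; `tset` supplies the channel's
#' scale transformation. Pass `tset = NULL` when the table's values are
#' already transformed.
#'
#' @param tbl an [event_table()].
#' @param ld_channel the viability channel name (or its marker label).
#' @param tset a [transform_set()] used to transform `ld_channel` before
#'   density estimation, or `NULL` if already transformed.
#' @return the filtered [event_table()].
#' @export
remove_dead_cells <- function(tbl, ld_channel, tset = NULL) {
  stopifnot(inherits(tbl, "event_table"))
  ch <- resolve_channel(tbl, ld_channel)
  x <- tbl$values[, ch]
  if (!is.null(tset)) {
    stopifnot(inherits(tset, "transform_set"))
    tr <- tset[[ch]]
    if (is.null(tr)) stop("transform set has no entry for channel '", ch, "'")
    if (!identical(tr, "identity")) x <- logicle_forward(x, tr)
  }
  if (stats::sd(x) == 0) {
    warning("remove_dead_cells skipped: constant viability channel")
    return(tbl)
  }
  threshold <- dead_cell_threshold(x)
  if (is.na(threshold)) {
    warning("remove_dead_cells: fewer than two density peaks; ",
            "using the 0.99 quantile as threshold")
    threshold <- stats::quantile(x, 0.99, names = FALSE)
  }
  filter_events(tbl, x <= threshold)
}

# Density-valley threshold between the two highest *prominent* KDE peaks.
# A candidate peak must reach at least `min_height` of the global maximum
# (a real population, not tail jitter), and the valley between the two
# chosen peaks must dip below `max_valley` of the lower peak (a genuine
# bimodal separation, not summit noise). NA when no such pair exists.
dead_cell_threshold <- function(x, n_grid = 512L, min_height = 0.05,
                                max_valley = 0.5) {
  d <- stats::density(x, bw = "nrd0", n = n_grid)
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE)
  peaks <- which(is_peak & y >= min_height * max(y))
  if (length(peaks) < 2) return(NA_real_)
  peaks <- peaks[order(y[peaks], decreasing = TRUE)]
  p1 <- peaks[1]
  for (p2 in peaks[-1]) {
    lo <- min(p1, p2); hi <- max(p1, p2)
    valley <- lo + which.min(y[lo:hi]) - 1L
    if (y[valley] < max_valley * min(y[p1], y[p2])) {
      return(d$x[valley])
    }
  }
  NA_real_
}
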