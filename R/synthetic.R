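#' Specification of a synthetic flow cytometry sample
#'
#' Describes a multi-population sample with planted, labelled artefacts: a
#' lymphocyte-like target cluster, debris near the scatter origin, dead
#' cells bright in the viability channel, doublets with an elevated
#' FSC-A/FSC-H ratio, margin events saturated at the detector limit,
#' fluorescence spillover between detectors, and a time window of unstable
#' signal. Populations are multivariate Gaussian in scatter space and
#' log-normal in fluorescence before spillover mixing — deliberately simple,
#' but sufficient to exercise every pre-processing step and to provide
#' per-event ground-truth labels.
#'
#' @param n_events total number of events.
#' @param fractions named numeric vector of population proportions for
#'   `target`, `debris`, `dead`, `doublet`, `margin`; must be non-negative
#'   and sum to 1. Population counts are `round(fraction * n_events)` for
#'   the artefact populations, with the target absorbing the remainder.
#' @param target_mean,target_cov mean and covariance of the target cluster
#'   in (FSC-A, SSC-A) space, data units.
#' @param debris_mean,debris_cov same, for the debris cluster near the
#'   origin.
#' @param dead_shift elevation of the viability-channel intensity for dead
#'   cells, in decades (multiplicative factor `10^dead_shift` in data
#'   units).
#' @param doublet_area_factor multiplier applied to FSC-A (not FSC-H) for
#'   doublets; default 2 (two cells, twice the pulse area).
#' @param spillover spillover matrix over the fluorescence channels
#'   (`FL1-A`, `FL2-A`, `LD-A`); raw fluorescence is `true %*% spillover`.
#' @param unstable_window `list(t_start, t_end, channel, shift_sd)`: events
#'   acquired in `[t_start, t_end)` seconds get `channel` shifted by
#'   `shift_sd` standard deviations; `NULL` for a stable acquisition.
#' @param acquisition_span acquisition duration in seconds.
#' @param detector_max saturation value of every detector (`$PnR`).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_events = 10000L,
                           fractions = c(target = 0.70, debris = 0.12,
                                         dead = 0.10, doublet = 0.05,
                                         margin = 0.03),
                           target_mean = c(50000, 30000),
                           target_cov = matrix(c(8000^2, 0.3 * 8000 * 6000,
                                                 0.3 * 8000 * 6000, 6000^2),
                                               2, 2),
                           debris_mean = c(8000, 5000),
                           debris_cov = diag(c(3000^2, 2500^2)),
                           dead_shift = 1.5,
                           doublet_area_factor = 2,
                           spillover = default_spillover(),
                           unstable_window = list(t_start = 100, t_end = 130,
                                                  channel = "FL1-A",
                                                  shift_sd = 6),
                           acquisition_span = 300,
                           detector_max = 262144,
                           seed = 1L) {
  pops <- c("target", "debris", "dead", "doublet", "margin")
  if (!all(pops %in% names(fractions))) {
    stop("fractions must name all of: ", paste(pops, collapse = ", "))
  }
  fractions <- fractions[pops]
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (!is.null(unstable_window)) {
    if (!(unstable_window$t_start < unstable_window$t_end &&
          unstable_window$t_end <= acquisition_span)) {
      stop("unstable_window must satisfy t_start < t_end <= acquisition_span")
    }
  }
  structure(list(n_events = as.integer(n_events), fractions = fractions,
                 target_mean = target_mean, target_cov = target_cov,
                 debris_mean = debris_mean, debris_cov = debris_cov,
                 dead_shift = dead_shift,
                 doublet_area_factor = doublet_area_factor,
                 spillover = spillover,
                 unstable_window = unstable_window,
                 acquisition_span = acquisition_span,
                 detector_max = detector_max, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_spillover <- function() {
  ch <- c("FL1-A", "FL2-A", "LD-A")
  m <- matrix(c(1, 0.10, 0.05,
                0.08, 1, 0.05,
                0.03, 0.04, 1), 3, 3, byrow = TRUE,
              dimnames = list(ch, ch))
  structure(m, class = c("spillover_matrix", "matrix", "array"))
}

synthetic_channels <- c("FSC-A", "FSC-H", "SSC-A",
                        "FL1-A", "FL2-A", "LD-A", "Time")
synthetic_markers <- c("FL1-A" = "CD8", "FL2-A" = "CD38",
                       "LD-A" = "LiveDead")

# Deterministic per-population event counts: artefacts rounded, target
# absorbs the remainder.
population_counts <- function(spec) {
  n <- spec$n_events
  f <- spec$fractions
  counts <- c(debris = round(f[["debris"]] * n),
              dead = round(f[["dead"]] * n),
              doublet = round(f[["doublet"]] * n),
              margin = round(f[["margin"]] * n))
  counts <- c(target = n - sum(counts), counts)
  if (counts[["target"]] < 0) stop("artefact fractions leave no target events")
  counts
}

rmvn <- function(n, mean, cov) {
  z <- matrix(stats::rnorm(n * 2), n, 2)
  z %*% chol(cov) + matrix(mean, n, 2, byrow = TRUE)
}

#' Generate one synthetic sample with ground-truth labels
#'
#' Returns the event table (raw detector units, fluorescence already
#' spillover-mixed, margin events clipped exactly at the detector maximum,
#' Time monotone non-decreasing) together with per-event truth labels. Good
#' events are target-population events outside the unstable time window;
#' every other event is bad. The serialized spillover matrix and per-channel
#' `$PnR = detector_max` are stored in the keywords, so the sample is fully
#' self-describing.
#'
#' @param spec a [synthetic_spec()].
#' @param sample_name sample name stored in the table.
#' @return a list with elements `table` (an [event_table()]) and `labels`
#'   (a tibble with columns `event_id`, `population`, `good`).
#' @export
generate_sample <- function(spec, sample_name = "synthetic_sample") {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_rng(spec$seed)
  counts <- population_counts(spec)
  n <- spec$n_events
  pop <- rep(names(counts), counts)

  # scatter space: debris near the origin, everything else target-like
  sc <- matrix(NA_real_, n, 2)
  is_debris <- pop == "debris"
  sc[!is_debris, ] <- rmvn(sum(!is_debris), spec$target_mean, spec$target_cov)
  if (any(is_debris)) {
    sc[is_debris, ] <- rmvn(sum(is_debris), spec$debris_mean, spec$debris_cov)
  }
  sc <- pmax(sc, 100)   # truncate at a small positive floor

  fsc_a <- sc[, 1]
  ssc_a <- sc[, 2]
  fsc_h <- fsc_a / exp(stats::rnorm(n, 0, 0.02))   # singlet pulse shape
  is_doublet <- pop == "doublet"
  fsc_a[is_doublet] <- fsc_a[is_doublet] * spec$doublet_area_factor

  # margin events: an over-dispersed saturating tail, clipped at the limit
  is_margin <- pop == "margin"
  if (any(is_margin)) {
    fsc_a[is_margin] <- spec$detector_max * (1 + abs(stats::rnorm(sum(is_margin), 0, 0.2)))
  }

  # true fluorescence, log-normal per channel
  fl1 <- stats::rlnorm(n, log(1000), 0.5)
  fl2 <- stats::rlnorm(n, log(500), 0.6)
  ld <- stats::rlnorm(n, log(150), 0.4)
  is_dead <- pop == "dead"
  ld[is_dead] <- ld[is_dead] * 10^spec$dead_shift
  true_fl <- cbind("FL1-A" = fl1, "FL2-A" = fl2, "LD-A" = ld)
  raw_fl <- true_fl %*% unclass(spec$spillover)

  # shuffle so populations are interleaved in acquisition time
  perm <- sample.int(n)
  pop <- pop[perm]
  values <- cbind(fsc_a, fsc_h, ssc_a, raw_fl)[perm, ]
  time <- sort(stats::runif(n, 0, spec$acquisition_span))
  values <- cbind(values, time)
  colnames(values) <- synthetic_channels

  # unstable acquisition window: location shift on one channel
  in_window <- rep(FALSE, n)
  if (!is.null(spec$unstable_window)) {
    uw <- spec$unstable_window
    in_window <- time >= uw$t_start & time < uw$t_end
    shift <- uw$shift_sd * stats::sd(values[, uw$channel])
    values[in_window, uw$channel] <- values[in_window, uw$channel] + shift
  }

  # saturate at the detector limit (margin events sit exactly there)
  values[, setdiff(synthetic_channels, "Time")] <-
    pmin(values[, setdiff(synthetic_channels, "Time")], spec$detector_max)

  kw <- list("$SPILLOVER" = serialize_spillover(spec$spillover),
             "$TIMESTEP" = "1")
  for (i in seq_along(synthetic_channels)) {
    top <- if (synthetic_channels[i] == "Time") {
      ceiling(spec$acquisition_span)
    } else spec$detector_max
    kw[[sprintf("$P%dR", i)]] <- format(top, scientific = FALSE)
  }

  tbl <- event_table(values, channels = synthetic_channels,
                     markers = synthetic_markers, keywords = kw,
                     sample = sample_name)
  labels <- tibble::tibble(
    event_id = event_ids(tbl),
    population = pop,
    good = pop == "target" & !in_window
  )
  list(table = tbl, labels = labels)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_samples` FCS files plus one ground-truth CSV listing, per
#' sample, the identifiers of the good events (target population outside the
#' unstable window). Per-sample population means are jittered
#' multiplicatively to create inter-sample variability.
#'
#' @param n_samples number of samples (>= 1).
#' @param out_dir writable output directory (created if absent).
#' @param spec the template [synthetic_spec()].
#' @param jitter relative standard deviation of the per-sample mean jitter
#'   (0 = all samples share the template means).
#' @param seed integer seed; sample i uses seed `seed + i`.
#' @return a list with `paths` (FCS files), `labels` (named list of label
#'   tibbles) and `truth_file` (the CSV path).
#' @export
generate_dataset <- function(n_samples, out_dir, spec = synthetic_spec(),
                             jitter = 0.05, seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n_samples)
  labels <- list()
  truth <- list()
  for (i in seq_len(n_samples)) {
    name <- sprintf("sample_%02d", i)
    spec_i <- spec
    spec_i$seed <- as.integer(seed + i)
    if (jitter > 0) {
      local_rng(seed * 1000L + i)
      spec_i$target_mean <- spec$target_mean * exp(stats::rnorm(2, 0, jitter))
      spec_i$debris_mean <- spec$debris_mean * exp(stats::rnorm(2, 0, jitter))
    }
    out <- generate_sample(spec_i, sample_name = name)
    paths[i] <- file.path(out_dir, paste0(name, ".fcs"))
    write_fcs(out$table, paths[i])
    labels[[name]] <- out$labels
    good_ids <- out$labels$event_id[out$labels$good]
    truth[[name]] <- data.frame(sample = name, event_id = good_ids)
  }
  truth_file <- file.path(out_dir, "ground_truth.csv")
  truth_df <- do.call(rbind, truth)
  utils::write.csv(truth_df, truth_file, row.names = FALSE, quote = FALSE)
  list(paths = paths, labels = labels, truth_file = truth_file)
}

#' Read a ground-truth file of retained event identifiers
#'
#' The ground truth is a CSV with columns `sample` and `event_id`, listing
#' per sample the identifiers of the events a reference (e.g. expert manual
#' gating, or the synthetic generator) considers good. Bad events are the
#' complement with respect to the raw file.
#'
#' @param path CSV file path.
#' @return named list: sample name -> integer vector of good event ids.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "event_id") %in% names(df))) {
    stop("ground truth file must have columns 'sample' and 'event_id'")
  }
  split(as.integer(df$event_id), df$sample)
}
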