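#' Benchmark event sets for one sample
#'
#' Confronts a pipeline's flagging of one sample with a ground truth. The
#' truth partitions the raw events into good events `G` (to retain) and bad
#' events `B` (to remove); the pipeline partitions the same events into
#' flagged-good `F_G` (retained) and flagged-bad `F_B` (removed). The
#' constructor enforces that both partitions are disjoint and cover the
#' same raw event universe.
#'
#' @param G,B integer vectors: ground-truth good / bad event ids.
#' @param F_G,F_B integer vectors: pipeline-retained / -removed event ids.
#' @return a `benchmark_sets` object.
#' @export
benchmark_sets <- function(G, B, F_G, F_B) {
  G <- as.integer(G); B <- as.integer(B)
  F_G <- as.integer(F_G); F_B <- as.integer(F_B)
  if (length(intersect(G, B))) stop("G and B must be disjoint")
  if (length(intersect(F_G, F_B))) stop("F_G and F_B must be disjoint")
  if (!setequal(union(G, B), union(F_G, F_B))) {
    stop("F_G and F_B must cover exactly the events of G and B ",
         "(every raw event is flagged exactly once)")
  }
  structure(list(G = G, B = B, F_G = F_G, F_B = F_B),
            class = "benchmark_sets")
}

#' Derive pipeline flags from raw and final tables
#'
#' The events a pipeline retained (its final output) are flagged good; all
#' other raw events are flagged bad.
#'
#' @param raw the sample's raw [event_table()].
#' @param final the pipeline's final [event_table()] for the same sample;
#'   its event ids must be a subset of the raw ids.
#' @return a list with integer-vector elements `F_G` and `F_B`.
#' @export
derive_flags <- function(raw, final) {
  stopifnot(inherits(raw, "event_table"), inherits(final, "event_table"))
  if (!identical(raw$sample, final$sample)) {
    stop("raw and final tables must come from the same sample")
  }
  f <- event_ids(final); r <- event_ids(raw)
  if (!all(f %in% r)) {
    stop("final event ids are not a subset of the raw ids; ",
         "a pipeline step violated id preservation")
  }
  list(F_G = f, F_B = setdiff(r, f))
}

#' Benchmark metrics from event sets
#'
#' With `F_B_correct = F_B` \eqn{\cap} `B` and `F_G_correct = F_G`
#' \eqn{\cap} `G`:
#' \deqn{sensitivity = |F_{B,correct}| / |B|}
#' \deqn{specificity = |F_{G,correct}| / |G|}
#' \deqn{precision = |F_{B,correct}| / |F_B|}
#' \deqn{recall = |F_{G,correct}| / |F_G|}
#' Sensitivity measures how much of the truly-bad material was removed,
#' specificity how much of the truly-good material was kept. A metric whose
#' denominator set is empty (e.g. precision for a pipeline that removed
#' nothing) is reported as `NA`, never as 0.
#'
#' @param sets a [benchmark_sets()] object.
#' @return a one-row tibble with columns `sensitivity`, `specificity`,
#'   `precision`, `recall`, `n_G`, `n_B`, `n_F_G`, `n_F_B`.
#' @export
compute_metrics <- function(sets) {
  stopifnot(inherits(sets, "benchmark_sets"))
  fbc <- length(intersect(sets$F_B, sets$B))
  fgc <- length(intersect(sets$F_G, sets$G))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    sensitivity = ratio(fbc, length(sets$B)),
    specificity = ratio(fgc, length(sets$G)),
    precision = ratio(fbc, length(sets$F_B)),
    recall = ratio(fgc, length(sets$F_G)),
    n_G = length(sets$G), n_B = length(sets$B),
    n_F_G = length(sets$F_G), n_F_B = length(sets$F_B)
  )
}

#' Benchmark cached experiments against a ground truth
#'
#' For every (experiment, sample) pair, compares the final per-file step
#' output with the sample's raw events (first step output) and the ground
#' truth, and computes the four metrics. Samples absent from the ground
#' truth are skipped with a warning.
#'
#' @param cache_root cache directory root.
#' @param experiments character vector of experiment names.
#' @param truth the ground-truth file path (see [read_ground_truth()]) or
#'   an already-parsed named list of good-event-id vectors.
#' @return a `benchmark_result`: a tibble with one row per (experiment,
#'   sample) carrying the four metrics and set sizes. Use [tidy()] for the
#'   table, [glance()] for per-metric quartile summaries, and
#'   [autoplot()] / [plot_benchmark_pairs()] for figures.
#' @export
benchmark_experiments <- function(cache_root, experiments, truth) {
  if (is.character(truth)) truth <- read_ground_truth(truth)
  rows <- list()
  for (exp in experiments) {
    st <- step_statuses(cache_root, exp)
    samples <- setdiff(unique(st$sample), "GLOBAL")
    for (s in samples) {
      if (is.null(truth[[s]])) {
        warning("sample '", s, "' absent from the ground truth; skipped")
        next
      }
      sub <- st[st$sample == s, ]
      done <- sub$step_index[sub$status == "completed"]
      if (length(done) < 2) {
        warning("experiment '", exp, "', sample '", s,
                "': pipeline incomplete; skipped")
        next
      }
      raw <- get_cached_output(cache_root, exp, s, min(done))
      final <- get_cached_output(cache_root, exp, s, max(done))
      flags <- derive_flags(raw, final)
      G <- intersect(truth[[s]], event_ids(raw))
      B <- setdiff(event_ids(raw), G)
      m <- compute_metrics(benchmark_sets(G, B, flags$F_G, flags$F_B))
      rows[[length(rows) + 1]] <-
        tibble::add_column(m, experiment = exp, sample = s, .before = 1)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("benchmark_result", class(out))
  out
}

#' @rdname benchmark_experiments
#' @param x,object a `benchmark_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.benchmark_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "benchmark_result")
  out
}

#' @rdname benchmark_experiments
#' @exportS3Method generics::glance
glance.benchmark_result <- function(x, ...) {
  long <- tidyr::pivot_longer(tidy(x),
                              c("sensitivity", "specificity", "precision",
                                "recall"),
                              names_to = "metric", values_to = "value")
  dplyr::group_by(long, .data$experiment, .data$metric) |>
    dplyr::summarise(
      q25 = stats::quantile(.data$value, 0.25, na.rm = TRUE),
      median = stats::median(.data$value, na.rm = TRUE),
      q75 = stats::quantile(.data$value, 0.75, na.rm = TRUE),
      mean = mean(.data$value, na.rm = TRUE),
      n_samples = dplyr::n(),
      .groups = "drop"
    )
}

#' @rdname benchmark_experiments
#' @exportS3Method ggplot2::autoplot
autoplot.benchmark_result <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              c("sensitivity", "specificity", "precision",
                                "recall"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$experiment, y = .data$value,
                                     fill = .data$experiment)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~metric, nrow = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "metric value") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 25, hjust = 1))
}

#' Per-sample scatter comparison of two experiments
#'
#' One dot per sample and metric, experiment A on x versus experiment B on
#' y, with the identity line; dots off the diagonal are samples the two
#' pipelines treat differently.
#'
#' @param result a [benchmark_experiments()] result covering both
#'   experiments.
#' @param experiment_a,experiment_b experiment names.
#' @return a ggplot object.
#' @export
plot_benchmark_pairs <- function(result, experiment_a, experiment_b) {
  long <- tidyr::pivot_longer(tidy(result),
                              c("sensitivity", "specificity", "precision",
                                "recall"),
                              names_to = "metric", values_to = "value")
  wide <- tidyr::pivot_wider(
    long[long$experiment %in% c(experiment_a, experiment_b),
         c("experiment", "sample", "metric", "value")],
    names_from = "experiment", values_from = "value")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[experiment_a]],
                                     y = .data[[experiment_b]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~metric, nrow = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = experiment_a, y = experiment_b) +
    ggplot2::theme_bw()
}
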