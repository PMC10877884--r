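#' Event-level difference between two step outputs
#'
#' Because every step preserves raw-file event identifiers, any two outputs
#' derived from the same raw sample — different steps, different parameter
#' settings, or different pipelines — can be compared by set arithmetic on
#' their identifiers. Tables from different source samples are refused:
#' event identity does not exist across samples, use distribution
#' comparison ([plot_compare()] in `"distributions"` mode) instead.
#'
#' @param left,right [event_table()] objects from the same raw sample.
#' @param left_label,right_label provenance strings used in printing and
#'   plots.
#' @return an `event_diff` object with integer-vector elements
#'   `common_ids`, `only_left_ids`, `only_right_ids`.
#' @export
diff_tables <- function(left, right,
                        left_label = "left", right_label = "right") {
  stopifnot(inherits(left, "event_table"), inherits(right, "event_table"))
  if (!identical(left$sample, right$sample)) {
    stop("cannot diff events across samples ('", left$sample, "' vs '",
         right$sample, "'); event identity only exists within one sample — ",
         "use plot_compare(mode = \"distributions\") to compare samples")
  }
  l <- event_ids(left); r <- event_ids(right)
  structure(list(common_ids = intersect(l, r),
                 only_left_ids = setdiff(l, r),
                 only_right_ids = setdiff(r, l),
                 left_label = left_label, right_label = right_label,
                 sample = left$sample),
            class = "event_diff")
}

#' @export
print.event_diff <- function(x, ...) {
  cat("<event_diff> sample '", x$sample, "': ", x$left_label, " vs ",
      x$right_label, "\n", sep = "")
  cat("  common:", length(x$common_ids),
      "| only", paste0(x$left_label, ":"), length(x$only_left_ids),
      "| only", paste0(x$right_label, ":"), length(x$only_right_ids), "\n")
  invisible(x)
}

#' @rdname diff_tables
#' @param x an `event_diff`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.event_diff <- function(x, ...) {
  tibble::tibble(
    event_id = c(x$common_ids, x$only_left_ids, x$only_right_ids),
    membership = rep(c("common", "only_left", "only_right"),
                     c(length(x$common_ids), length(x$only_left_ids),
                       length(x$only_right_ids)))
  )
}

#' Visual comparison of two step outputs
#'
#' Renders two tables side by side on one or two channels, with event
#' counts in the panel subtitles. In `"distributions"` mode the two tables
#' are shown as 1D densities (one channel) or 2D scatters (two channels).
#' In `"diff-overlay"` mode a third panel overlays the left table's events,
#' coloured by presence: blue for events present in both tables, red for
#' events present on the left only.
#'
#' @param left,right [event_table()] objects.
#' @param channels one or two channel (or marker) names.
#' @param mode `"distributions"` or `"diff-overlay"` (the latter requires
#'   both tables to come from the same sample).
#' @param tset optional [transform_set()]; when supplied, values are
#'   transformed to display units before plotting.
#' @param left_label,right_label panel titles.
#' @return a ggplot object.
#' @export
plot_compare <- function(left, right, channels,
                         mode = c("distributions", "diff-overlay"),
                         tset = NULL, left_label = "left",
                         right_label = "right") {
  mode <- match.arg(mode)
  stopifnot(length(channels) %in% 1:2)
  chl <- vapply(channels, function(ch) resolve_channel(left, ch),
                character(1), USE.NAMES = FALSE)
  vapply(channels, function(ch) resolve_channel(right, ch), character(1))
  if (!is.null(tset)) {
    left <- apply_transform_set(left, tset)
    right <- apply_transform_set(right, tset)
  }
  lab <- function(label, tbl) sprintf("%s (%d events)", label, n_events(tbl))
  tbl_df <- function(tbl, panel) {
    df <- as.data.frame(tbl$values[, chl, drop = FALSE], check.names = FALSE)
    names(df) <- paste0("ch", seq_along(chl))
    df$event_id <- event_ids(tbl)
    df$panel <- panel
    df
  }
  df <- rbind(tbl_df(left, lab(left_label, left)),
              tbl_df(right, lab(right_label, right)))
  if (mode == "diff-overlay") {
    d <- diff_tables(left, right, left_label, right_label)
    ov <- tbl_df(left, "difference")
    ov$presence <- ifelse(ov$event_id %in% d$common_ids, "both", "left only")
    df$presence <- "both"
    df <- rbind(df, ov)
    df$panel <- factor(df$panel, levels = unique(df$panel))
  } else {
    df$presence <- "both"
    df$panel <- factor(df$panel, levels = unique(df$panel))
  }
  if (length(chl) == 2) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ch1, y = .data$ch2)) +
      ggplot2::geom_point(ggplot2::aes(color = .data$presence),
                          size = 0.3, alpha = 0.5) +
      ggplot2::labs(x = channels[1], y = channels[2])
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ch1)) +
      ggplot2::geom_density(ggplot2::aes(color = .data$presence)) +
      ggplot2::labs(x = channels[1], y = "density")
  }
  p + ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::scale_color_manual(values = c(`both` = "#377eb8",
                                           `left only` = "#e41a1c")) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = if (mode == "diff-overlay") "bottom"
                   else "none")
}

#' Events retained at each pre-processing step
#'
#' For every sample of a cached experiment, reports the number of events
#' after each per-file step and the proportion of the sample's raw events
#' this represents. Across filtering steps the proportion is monotone
#' non-increasing; a sharp drop at one step is the typical signature of a
#' misbehaving method (e.g. a dead-cell threshold collapsing on the wrong
#' density mode).
#'
#' @param cache_root cache directory root.
#' @param experiment experiment name.
#' @param samples optional subset of sample names.
#' @return a tibble with columns `sample`, `step_index`, `step_name`,
#'   `n_events`, `prop_initial` (`NA` for steps without a cached output,
#'   e.g. pending ones or transform-set steps).
#' @export
retention_profile <- function(cache_root, experiment, samples = NULL) {
  st <- step_statuses(cache_root, experiment)
  st <- st[st$sample != "GLOBAL", ]
  if (!is.null(samples)) st <- st[st$sample %in% samples, ]
  dplyr::group_by(st, .data$sample) |>
    dplyr::mutate(
      n_events = ifelse(.data$status == "completed", .data$n_events,
                        NA_integer_),
      prop_initial = .data$n_events / .data$n_events[1]
    ) |>
    dplyr::ungroup() |>
    dplyr::select("sample", "step_index", "step_name", "n_events",
                  "prop_initial")
}

#' Plot retention profiles
#'
#' One line per sample over the step sequence; y is the proportion of the
#' raw events still retained after each step.
#'
#' @param profile a [retention_profile()] tibble (non-empty).
#' @return a ggplot object.
#' @export
plot_retention <- function(profile) {
  if (nrow(profile) == 0) stop("empty retention profile")
  steps <- unique(profile[, c("step_index", "step_name")])
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$step_index, y = .data$prop_initial,
                               group = .data$sample,
                               color = .data$sample)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = steps$step_index,
                                labels = steps$step_name) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion of raw events retained") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1),
                   legend.position = if (length(unique(profile$sample)) > 12)
                     "none" else "right")
}
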