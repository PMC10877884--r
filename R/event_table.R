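#' Event table: the in-memory representation of one FCS sample
#'
#' An `event_table` holds the list-mode data of one flow cytometry sample:
#' an events x channels numeric matrix, channel and (optional) marker names,
#' the FCS keyword metadata, and one stable identifier per event. Event
#' identifiers are the 0-based row indices of the events in the raw file they
#' came from; every filtering step preserves them, so they act as the join
#' key for step-to-step comparison and for benchmarking against a ground
#' truth.
#'
#' @param values numeric matrix, rows = events, columns = channels.
#' @param channels character vector of channel short names (e.g. `"FSC-A"`);
#'   defaults to `colnames(values)`.
#' @param markers named character vector mapping channel names to marker
#'   labels (e.g. `c("FL1-A" = "CD8")`); may be empty.
#' @param event_ids integer vector of per-event identifiers (0-based raw-file
#'   row indices); defaults to `0:(nrow(values) - 1)`.
#' @param keywords named list of FCS keyword values (character scalars).
#' @param sample character scalar, the source sample name.
#'
#' @return An object of class `event_table`.
#' @examples
#' tbl <- event_table(matrix(rnorm(20), 10, 2,
#'                           dimnames = list(NULL, c("FSC-A", "SSC-A"))),
#'                    sample = "s1")
#' n_events(tbl)
#' @export
event_table <- function(values,
                        channels = colnames(values),
                        markers = character(0),
                        event_ids = NULL,
                        keywords = list(),
                        sample = "sample") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(channels)) {
    stop("channel names are required (supply `channels` or matrix colnames)")
  }
  channels <- as.character(channels)
  if (length(channels) != ncol(values)) {
    stop("length(channels) must equal ncol(values)")
  }
  if (anyDuplicated(channels)) {
    stop("channel names must be unique")
  }
  if (is.null(event_ids)) {
    event_ids <- seq_len(nrow(values)) - 1L
  }
  event_ids <- as.integer(event_ids)
  if (length(event_ids) != nrow(values)) {
    stop("length(event_ids) must equal nrow(values)")
  }
  if (anyDuplicated(event_ids)) {
    stop("event_ids must be unique within a table")
  }
  markers <- markers[!is.na(markers)]
  if (length(markers) && is.null(names(markers))) {
    stop("markers must be a named character vector (channel -> marker)")
  }
  if (length(markers) && !all(names(markers) %in% channels)) {
    stop("every marker name must refer to an existing channel")
  }
  colnames(values) <- channels
  structure(
    list(values = values,
         channels = channels,
         markers = markers,
         event_ids = event_ids,
         keywords = keywords,
         sample = as.character(sample)[1]),
    class = "event_table"
  )
}

#' @rdname event_table
#' @param x,tbl an `event_table`.
#' @export
n_events <- function(tbl) nrow(tbl$values)

#' @rdname event_table
#' @export
channels <- function(tbl) tbl$channels

#' @rdname event_table
#' @export
event_ids <- function(tbl) tbl$event_ids

#' Extract one channel's values
#'
#' @param tbl an `event_table`.
#' @param channel channel short name or marker label.
#' @return numeric vector of length `n_events(tbl)`.
#' @export
channel_values <- function(tbl, channel) {
  tbl$values[, resolve_channel(tbl, channel)]
}

# Accept either a channel short name or a marker label.
resolve_channel <- function(tbl, channel) {
  if (channel %in% tbl$channels) return(channel)
  hit <- names(tbl$markers)[tbl$markers == channel]
  if (length(hit) == 1) return(hit)
  stop("unknown channel or marker: '", channel, "'")
}

#' Keep a subset of events, preserving their identifiers
#'
#' The fundamental filtering primitive every pre-processing step goes
#' through: rows are subset, event identifiers travel with their rows and
#' are never renumbered.
#'
#' @param tbl an `event_table`.
#' @param keep logical vector of length `n_events(tbl)`, or an integer vector
#'   of row positions.
#' @return the filtered `event_table`.
#' @export
filter_events <- function(tbl, keep) {
  if (is.logical(keep)) {
    stopifnot(length(keep) == n_events(tbl))
    keep <- which(keep)
  }
  tbl$values <- tbl$values[keep, , drop = FALSE]
  tbl$event_ids <- tbl$event_ids[keep]
  tbl
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> sample '", x$sample, "': ",
      n_events(x), " events x ", length(x$channels), " channels\n", sep = "")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (length(x$markers)) {
    cat("  markers: ",
        paste(names(x$markers), x$markers, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$values)

#' Tidy view of an event table
#'
#' @param x an `event_table`.
#' @param ... unused.
#' @return a tibble with one row per event: `sample`, `event_id`, and one
#'   column per channel.
#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.event_table <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$values, check.names = FALSE))
  tibble::add_column(out,
                     sample = x$sample,
                     event_id = x$event_ids,
                     .before = 1)
}
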