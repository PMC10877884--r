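#' Read an FCS 3.0 / 3.1 file
#'
#' Parses the HEADER and TEXT segments, then decodes a single list-mode DATA
#' segment of type integer (`$DATATYPE I`), float (`F`) or double (`D`).
#' Multi-dataset files (`$NEXTDATA != 0`), correlated-mode data and FCS 2.0
#' are rejected. Event identifiers are recovered from the
#' `CYTOPIPE_EVENT_IDS` keyword when present (files written by
#' [write_fcs()]), otherwise initialised to `0:(n - 1)`.
#'
#' @param path path to an FCS file.
#' @return an [event_table()].
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version '", version,
         "' (only FCS3.0/FCS3.1 are supported)")
  }
  off <- function(i) {
    v <- trimws(substr(header, 11 + (i - 1) * 8, 10 + i * 8))
    if (v == "") 0 else as.numeric(v)
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)

  seek(con, text_beg)
  text_raw <- readChar(con, text_end - text_beg + 1, useBytes = TRUE)
  kw <- parse_fcs_text(text_raw)

  need <- function(name) {
    v <- kw[[name]]
    if (is.null(v)) stop("missing required FCS keyword ", name)
    v
  }
  if (toupper(need("$MODE")) != "L") {
    stop("unsupported data mode in keyword $MODE ('", kw[["$MODE"]],
         "'); only list mode (L) is supported")
  }
  if (!is.null(kw[["$NEXTDATA"]]) && as.numeric(kw[["$NEXTDATA"]]) != 0) {
    stop("multi-dataset FCS files are not supported (keyword $NEXTDATA)")
  }
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("I", "F", "D")) {
    stop("unsupported value of keyword $DATATYPE: '", dtype, "'")
  }
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2", "1")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop("unsupported byte order in keyword $BYTEORD: '",
                      byteord, "'")
  p <- as.integer(need("$PAR"))
  n <- as.integer(need("$TOT"))
  bits <- vapply(seq_len(p),
                 function(i) as.integer(need(sprintf("$P%dB", i))),
                 integer(1))
  if (dtype == "F" && any(bits != 32)) {
    stop("$DATATYPE F requires 32-bit parameters ($PnB)")
  }
  if (dtype == "D" && any(bits != 64)) {
    stop("$DATATYPE D requires 64-bit parameters ($PnB)")
  }
  if (data_beg == 0) {
    data_beg <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  expected_bytes <- n * sum(bits / 8)
  avail_bytes <- data_end - data_beg + 1
  if (avail_bytes < expected_bytes) {
    stop("FCS data segment integrity error: $TOT = ", n, " events require ",
         expected_bytes, " bytes but the data segment holds ", avail_bytes)
  }

  seek(con, data_beg)
  values <- read_fcs_data(con, dtype, bits, n, p, endian)

  ch <- vapply(seq_len(p),
               function(i) need(sprintf("$P%dN", i)), character(1))
  colnames(values) <- ch
  mk <- vapply(seq_len(p), function(i) {
    v <- kw[[sprintf("$P%dS", i)]]
    if (is.null(v)) NA_character_ else v
  }, character(1))
  markers <- stats::setNames(mk, ch)
  markers <- markers[!is.na(markers)]

  ids <- if (!is.null(kw[["CYTOPIPE_EVENT_IDS"]])) {
    decode_id_ranges(kw[["CYTOPIPE_EVENT_IDS"]])
  } else {
    seq_len(n) - 1L
  }
  if (length(ids) != n) {
    stop("FCS integrity error: CYTOPIPE_EVENT_IDS encodes ", length(ids),
         " identifiers for ", n, " events")
  }
  sample <- kw[["CYTOPIPE_SOURCE_SAMPLE"]] %||% basename(path)

  event_table(values, channels = ch, markers = markers, event_ids = ids,
              keywords = kw, sample = sample)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a TEXT segment into a named list. The first byte is the delimiter.
parse_fcs_text <- function(text_raw) {
  delim <- substr(text_raw, 1, 1)
  body <- substr(text_raw, 2, nchar(text_raw))
  # strip one trailing delimiter if present
  if (substr(body, nchar(body), nchar(body)) == delim) {
    body <- substr(body, 1, nchar(body) - 1)
  }
  toks <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(toks) %% 2 != 0) {
    stop("malformed FCS TEXT segment: odd number of tokens")
  }
  keys <- toks[seq(1, length(toks), by = 2)]
  vals <- toks[seq(2, length(toks), by = 2)]
  stats::setNames(as.list(vals), toupper(trimws(keys)))
}

read_fcs_data <- function(con, dtype, bits, n, p, endian) {
  total <- n * p
  if (dtype == "F") {
    v <- readBin(con, "numeric", n = total, size = 4, endian = endian)
  } else if (dtype == "D") {
    v <- readBin(con, "numeric", n = total, size = 8, endian = endian)
  } else {
    if (length(unique(bits)) != 1 || !unique(bits) %in% c(8L, 16L, 32L)) {
      stop("integer data requires uniform $PnB of 8, 16 or 32 bits")
    }
    b <- unique(bits)
    if (b == 32L) {
      v <- readBin(con, "integer", n = total, size = 4, endian = endian)
      v <- as.double(v)
      v[v < 0] <- v[v < 0] + 2^32   # stored unsigned
    } else {
      v <- as.double(readBin(con, "integer", n = total, size = b / 8,
                             signed = FALSE, endian = endian))
    }
  }
  if (length(v) < total) {
    stop("FCS data segment integrity error: truncated data")
  }
  matrix(v, nrow = n, ncol = p, byrow = TRUE)
}

#' Write an event table as an FCS 3.1 file
#'
#' Always writes single-precision float data (`$DATATYPE F`, little endian).
#' Keywords of the source table are carried over ($PnR detector ranges,
#' $TIMESTEP, spillover, ...). Two custom keywords make event identity
#' survive a write/read cycle: `CYTOPIPE_EVENT_IDS` (a compact range
#' encoding of the retained 0-based raw-row indices) and
#' `CYTOPIPE_SOURCE_SAMPLE`.
#'
#' @param tbl an [event_table()]; must have at least one channel.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(tbl, path) {
  stopifnot(inherits(tbl, "event_table"))
  if (length(tbl$channels) < 1) {
    stop("cannot write an event table with zero channels")
  }
  n <- n_events(tbl)
  p <- length(tbl$channels)

  kw <- list(
    "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(p), "$TOT" = as.character(n)
  )
  for (i in seq_len(p)) {
    ch <- tbl$channels[i]
    kw[[sprintf("$P%dN", i)]] <- ch
    kw[[sprintf("$P%dB", i)]] <- "32"
    kw[[sprintf("$P%dE", i)]] <- "0,0"
    rng <- tbl$keywords[[sprintf("$P%dR", i)]]
    if (is.null(rng)) {
      top <- if (n > 0) max(1, ceiling(max(tbl$values[, i]))) else 262144
      rng <- format(top, scientific = FALSE)
    }
    kw[[sprintf("$P%dR", i)]] <- rng
    if (ch %in% names(tbl$markers)) {
      kw[[sprintf("$P%dS", i)]] <- unname(tbl$markers[ch])
    }
  }
  # carry over remaining metadata keywords (spillover, $TIMESTEP, ...)
  carry <- setdiff(names(tbl$keywords), names(kw))
  carry <- carry[!grepl("^\\$(BEGIN|END)(DATA|STEXT|ANALYSIS)$", carry)]
  for (k in carry) kw[[k]] <- as.character(tbl$keywords[[k]])
  kw[["CYTOPIPE_EVENT_IDS"]] <- encode_id_ranges(tbl$event_ids)
  kw[["CYTOPIPE_SOURCE_SAMPLE"]] <- tbl$sample

  delim <- "/"
  bad <- vapply(kw, function(v) grepl(delim, v, fixed = TRUE), logical(1))
  if (any(bad)) {
    stop("keyword value contains the TEXT delimiter '/': ",
         paste(names(kw)[bad], collapse = ", "))
  }

  data_bytes <- n * p * 4
  # Offset keywords are fixed-width so the TEXT length is known in advance.
  fmt_off <- function(x) formatC(x, width = 10, flag = "0", format = "d")
  build_text <- function(db, de) {
    head_kw <- list("$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
                    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
                    "$BEGINDATA" = fmt_off(db), "$ENDDATA" = fmt_off(de))
    all_kw <- c(head_kw, kw)
    paste0(delim,
           paste0(names(all_kw), delim, unlist(all_kw), delim,
                  collapse = ""))
  }
  text0 <- build_text(0, 0)
  text_beg <- 58
  text_end <- text_beg + nchar(text0, type = "bytes") - 1
  data_beg <- if (data_bytes > 0) text_end + 1 else 0
  data_end <- if (data_bytes > 0) data_beg + data_bytes - 1 else 0
  text <- build_text(data_beg, data_end)

  hdr_off <- function(x) {
    if (x > 99999999) "       0" else formatC(x, width = 8, format = "d")
  }
  header <- paste0("FCS3.1    ",
                   hdr_off(text_beg), hdr_off(text_end),
                   hdr_off(data_beg), hdr_off(data_end),
                   hdr_off(0), hdr_off(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (data_bytes > 0) {
    writeBin(as.vector(t(tbl$values)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Compact range encoding of event identifiers
#'
#' Sorted runs of consecutive identifiers are collapsed to `"a-b"`, joined
#' by commas: `c(0:99, 200, 205:210)` becomes `"0-99,200,205-210"`.
#'
#' @param ids integer vector of event identifiers.
#' @return character scalar.
#' @keywords internal
#' @export
encode_id_ranges <- function(ids) {
  if (length(ids) == 0) return("")
  ids <- sort(as.integer(ids))
  breaks <- c(0L, which(diff(ids) != 1L), length(ids))
  runs <- vapply(seq_len(length(breaks) - 1), function(i) {
    a <- ids[breaks[i] + 1L]; b <- ids[breaks[i + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1))
  paste(runs, collapse = ",")
}

#' @rdname encode_id_ranges
#' @param text a range encoding produced by `encode_id_ranges()`.
#' @export
decode_id_ranges <- function(text) {
  if (is.null(text) || !nzchar(text)) return(integer(0))
  runs <- strsplit(text, ",", fixed = TRUE)[[1]]
  out <- lapply(runs, function(r) {
    ab <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
    if (length(ab) == 1) ab else seq.int(ab[1], ab[2])
  })
  as.integer(unlist(out))
}

#' Spillover matrices
#'
#' `parse_spillover()` decodes the FCS serialization
#' `"n,name1,...,namen,v11,v12,...,vnn"` into a square matrix (rows = source
#' dyes, columns = detectors) and normalizes each row by its diagonal entry
#' so the diagonal equals 1. `serialize_spillover()` is its inverse.
#' `get_spillover()` looks a spillover matrix up in an event table's
#' keywords, trying `$SPILLOVER`, then `SPILL`, then `SPILLOVER`.
#'
#' @param value the FCS keyword string.
#' @return `parse_spillover()`: a `spillover_matrix` (square numeric matrix
#'   with channel dimnames); `serialize_spillover()`: a character scalar.
#' @examples
#' s <- parse_spillover("2,FL1,FL2,1,0.1,0,1")
#' s["FL1", "FL2"]
#' @export
parse_spillover <- function(value) {
  toks <- strsplit(value, ",", fixed = TRUE)[[1]]
  n <- suppressWarnings(as.integer(toks[1]))
  if (is.na(n) || n < 1) stop("spillover parse error: bad channel count")
  if (length(toks) != 1 + n + n * n) {
    stop("spillover parse error: expected ", 1 + n + n * n,
         " tokens, found ", length(toks))
  }
  ch <- toks[2:(n + 1)]
  vals <- as.numeric(toks[(n + 2):length(toks)])
  if (anyNA(vals)) stop("spillover parse error: non-numeric entry")
  m <- matrix(vals, nrow = n, ncol = n, byrow = TRUE,
              dimnames = list(ch, ch))
  d <- diag(m)
  if (any(d == 0)) stop("spillover matrix has a zero diagonal entry")
  m <- m / d   # row-normalize so the diagonal equals 1
  if (abs(det(m)) < .Machine$double.eps * n) {
    stop("spillover matrix is singular and cannot be used for compensation")
  }
  structure(m, class = c("spillover_matrix", "matrix", "array"))
}

#' @rdname parse_spillover
#' @param spill a spillover matrix with channel dimnames.
#' @export
serialize_spillover <- function(spill) {
  n <- nrow(spill)
  paste(c(n, colnames(spill),
          format(as.vector(t(unclass(spill))), scientific = FALSE,
                 trim = TRUE, digits = 15)),
        collapse = ",")
}

#' @rdname parse_spillover
#' @param tbl an [event_table()].
#' @export
get_spillover <- function(tbl) {
  for (k in c("$SPILLOVER", "SPILL", "SPILLOVER")) {
    if (!is.null(tbl$keywords[[k]])) return(parse_spillover(tbl$keywords[[k]]))
  }
  stop("no spillover keyword found ($SPILLOVER / SPILL / SPILLOVER)")
}

#' Aggregate events from a random subset of samples
#'
#' Selects `n_files` files without replacement, draws up to
#' `n_events_per_file` events uniformly without replacement from each, and
#' concatenates them. Used to build the table on which per-channel scale
#' transformations are estimated once per experiment. Event identifiers keep
#' their source sample name, so aggregated events remain traceable.
#'
#' @param paths character vector of FCS file paths.
#' @param n_files number of files to select.
#' @param n_events_per_file events drawn per selected file (capped at the
#'   file's size).
#' @param seed integer seed; the selection is deterministic given the seed.
#' @return an [event_table()] whose `sample` is `"aggregate"`; per-event
#'   provenance is kept in the `source` attribute (a character vector
#'   parallel to the rows).
#' @export
aggregate_samples <- function(paths, n_files = min(4L, length(paths)),
                              n_events_per_file = 10000L, seed = 0L) {
  if (length(paths) == 0) stop("no sample files supplied")
  if (n_files > length(paths)) {
    stop("n_files exceeds the number of supplied paths")
  }
  local_rng(seed)
  sel <- sort(sample.int(length(paths), n_files))
  parts <- lapply(paths[sel], function(p) {
    tbl <- read_fcs(p)
    n <- n_events(tbl)
    take <- min(n, n_events_per_file)
    keep <- sort(sample.int(n, take))
    filter_events(tbl, keep)
  })
  values <- do.call(rbind, lapply(parts, function(t) t$values))
  src <- unlist(lapply(parts, function(t) rep(t$sample, n_events(t))))
  ids <- unlist(lapply(parts, event_ids))
  first <- parts[[1]]
  out <- event_table(values, channels = first$channels,
                     markers = first$markers,
                     event_ids = seq_len(nrow(values)) - 1L,
                     keywords = first$keywords, sample = "aggregate")
  attr(out, "source_samples") <- src
  attr(out, "source_ids") <- ids
  out
}

# Scoped RNG: seeds deterministically, restoring the caller's .Random.seed
# when the calling function exits.
local_rng <- function(seed) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  } else NULL
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }
  caller <- parent.frame()
  assign(".fcspipe_rng_restore", restore, envir = caller)
  do.call(on.exit, list(quote(.fcspipe_rng_restore()), add = TRUE),
          envir = caller)
  invisible(NULL)
}
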