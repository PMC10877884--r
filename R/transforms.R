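#' Logicle transformation parameters
#'
#' The logicle is a biexponential display scale for flow cytometry data:
#' approximately logarithmic at high intensity, linear around zero (so
#' compensated events that fall slightly below zero remain displayable), and
#' parameterized by:
#' \describe{
#'   \item{T}{top of scale, in data units (typically the detector range).}
#'   \item{M}{total display width in decades ("positive decimals").}
#'   \item{W}{linearization width in decades around zero.}
#'   \item{A}{additional negative display decades.}
#' }
#' Display values are expressed in decades: data value `T` maps to display
#' `M`, data value 0 maps to display `W` (with `A = 0`).
#'
#' @param T,M,W,A see description; constraints `T > 0`, `M > 0`,
#'   `0 <= W <= M/2`, `-W <= A <= M - 2W`.
#' @return an object of class `logicle_params`.
#' @examples
#' p <- logicle_params(T = 262144, M = 4.5, W = 0.5)
#' logicle_forward(262144, p)   # = M
#' @export
logicle_params <- function(T = 262144, M = 4.5, W = 0.5, A = 0) {
  if (!(is.finite(T) && T > 0)) stop("invalid logicle parameter: T must be > 0")
  if (!(is.finite(M) && M > 0)) stop("invalid logicle parameter: M must be > 0")
  if (!(is.finite(W) && W >= 0 && W <= M / 2)) {
    stop("invalid logicle parameter: need 0 <= W <= M/2")
  }
  if (!(is.finite(A) && A >= -W && A <= M - 2 * W)) {
    stop("invalid logicle parameter: need -W <= A <= M - 2W")
  }
  structure(list(T = T, M = M, W = W, A = A), class = "logicle_params")
}

#' @export
print.logicle_params <- function(x, ...) {
  cat(sprintf("<logicle_params> T = %g, M = %g, W = %g, A = %g\n",
              x$T, x$M, x$W, x$A))
  invisible(x)
}

# Precompute the biexponential coefficients for a parameter set.
# Internal scale s runs over [0, 1] for display decades in [-A, M]:
#   s = (decades + A) / (M + A).
# The data value at scale s is  S(s) = a e^{b s} - c e^{-d s} - f  for
# s >= x1, extended by odd symmetry about x1 below it, with
#   w  = W / (M + A),  x2 = A / (M + A),  x1 = x2 + w,  x0 = x2 + 2 w,
#   b  = (M + A) ln 10,
#   d  the root of 2 ln(b / d) = w (b + d)    (d = b when W = 0),
#   c / a = e^{(b + d) x0},  S(x1) = 0,  S(1) = T.
logicle_coef <- function(p) {
  stopifnot(inherits(p, "logicle_params"))
  MA <- p$M + p$A
  w <- p$W / MA
  x2 <- p$A / MA
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b <- MA * log(10)
  d <- if (w == 0) b else {
    g <- function(dd) 2 * log(b / dd) - w * (b + dd)
    stats::uniroot(g, lower = b * 1e-12, upper = b * (1 - 1e-12),
                   tol = .Machine$double.eps^0.75)$root
  }
  c_a <- exp((b + d) * x0)
  mf_a <- exp(b * x1) - c_a * exp(-d * x1)
  a <- p$T / (exp(b) - c_a * exp(-d) - mf_a)
  list(a = a, b = b, c = c_a * a, d = d, f = mf_a * a,
       x1 = x1, MA = MA, A = p$A)
}

# Data value at internal scale s (vectorized), with odd reflection below x1.
biexp_at <- function(s, k) {
  neg <- s < k$x1
  s2 <- ifelse(neg, 2 * k$x1 - s, s)
  v <- k$a * exp(k$b * s2) - k$c * exp(-k$d * s2) - k$f
  ifelse(neg, -v, v)
}

#' Evaluate the logicle transformation
#'
#' `logicle_inverse()` maps display decades back to data units using the
#' closed-form biexponential. `logicle_forward()` maps data units to display
#' decades by root-finding on that closed form (bisection on a monotone
#' function, converged to well below 1e-10 relative in display units).
#'
#' @param x data value(s).
#' @param y display value(s), in decades.
#' @param p a [logicle_params()] object.
#' @return numeric vector of the same length as the input.
#' @export
logicle_forward <- function(x, p) {
  k <- logicle_coef(p)
  if (length(x) == 0) return(numeric(0))
  # bracket: data values sit within [S(lo), S(hi)] for these scale bounds
  amax <- max(abs(x), k$a)
  r <- max(2, log(amax / k$a) / k$b + 1)
  lo <- rep(k$x1 - r, length(x))
  hi <- rep(k$x1 + r, length(x))
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    v <- biexp_at(mid, k)
    below <- v < x
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  s <- (lo + hi) / 2
  s * k$MA - k$A
}

#' @rdname logicle_forward
#' @export
logicle_inverse <- function(y, p) {
  k <- logicle_coef(p)
  s <- (y + k$A) / k$MA
  biexp_at(s, k)
}

#' Estimate logicle parameters for one channel
#'
#' Follows the reference heuristic for automatic parameter estimation:
#' `T` is the channel's detector range (keyword `$PnR`, falling back to the
#' observed maximum), `A = 0`, and the linearization width is
#' `W = max(0, (M - log10(T / |r|)) / 2)` where `r` is the `q`-quantile of
#' the channel's non-positive values. When the channel has no non-positive
#' values, `W` falls back to 0.5. `W` is clamped to `[0, M/2]`.
#'
#' @param tbl an [event_table()] with at least one event.
#' @param channel channel short name.
#' @param m total display width in decades (default 4.5).
#' @param q quantile of the non-positive values used for `r` (default 0.05).
#' @return a [logicle_params()] object.
#' @export
estimate_logicle <- function(tbl, channel, m = 4.5, q = 0.05) {
  ch <- resolve_channel(tbl, channel)
  if (n_events(tbl) < 1) stop("cannot estimate a transform on an empty table")
  x <- tbl$values[, ch]
  idx <- match(ch, tbl$channels)
  rng <- tbl$keywords[[sprintf("$P%dR", idx)]]
  T <- if (!is.null(rng)) as.numeric(rng) else max(x)
  if (!is.finite(T) || T <= 0) T <- max(x[x > 0], 1)
  neg <- x[x <= 0]
  W <- if (length(neg) == 0) 0.5 else {
    r <- stats::quantile(neg, q, names = FALSE, type = 7)
    if (r == 0) 0.5 else max(0, (m - log10(T / abs(r))) / 2)
  }
  W <- min(W, m / 2)
  logicle_params(T = T, M = m, W = W, A = 0)
}

#' Transformation sets
#'
#' A `transform_set` maps every channel of an experiment to a scale
#' transformation: a logicle for fluorescence channels, the identity for
#' scatter and Time channels. Sets are estimated once per experiment on an
#' aggregated, margin-filtered, compensated table, applied to every sample,
#' and can be manually adjusted and serialized to JSON.
#'
#' @param ... named transformations; each is either the string `"identity"`
#'   or a [logicle_params()] object.
#' @return an object of class `transform_set`.
#' @export
transform_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 1 && is.list(entries[[1]]) &&
      is.null(attr(entries[[1]], "class")) && !is.null(names(entries[[1]]))) {
    entries <- entries[[1]]
  }
  if (length(entries) && is.null(names(entries))) {
    stop("transformations must be named by channel")
  }
  for (e in entries) {
    ok <- identical(e, "identity") || inherits(e, "logicle_params")
    if (!ok) stop("each transformation must be \"identity\" or logicle_params")
  }
  structure(entries, class = "transform_set")
}

#' @export
print.transform_set <- function(x, ...) {
  cat("<transform_set> with", length(x), "channels\n")
  for (ch in names(x)) {
    if (identical(x[[ch]], "identity")) {
      cat("  ", ch, ": identity\n", sep = "")
    } else {
      p <- x[[ch]]
      cat(sprintf("  %s: logicle(T = %g, M = %g, W = %g, A = %g)\n",
                  ch, p$T, p$M, p$W, p$A))
    }
  }
  invisible(x)
}

#' Estimate a transformation set for an experiment
#'
#' Runs [estimate_logicle()] independently on each fluorescence channel of
#' an aggregated event table (expected to be margin-filtered and
#' compensated), and assigns the identity to every other channel.
#'
#' @param tbl an [event_table()], typically from [aggregate_samples()].
#' @param fluoro_channels character vector of fluorescence channel names.
#' @param m,q passed to [estimate_logicle()].
#' @return a [transform_set()].
#' @export
estimate_transform_set <- function(tbl, fluoro_channels, m = 4.5, q = 0.05) {
  if (length(fluoro_channels) == 0) {
    stop("fluoro_channels must name at least one channel")
  }
  fluoro_channels <- vapply(fluoro_channels, function(ch)
    resolve_channel(tbl, ch), character(1), USE.NAMES = FALSE)
  out <- list()
  for (ch in tbl$channels) {
    out[[ch]] <- if (ch %in% fluoro_channels) {
      estimate_logicle(tbl, ch, m = m, q = q)
    } else "identity"
  }
  transform_set(out)
}

#' Apply (or invert) a transformation set on an event table
#'
#' Replaces values column-wise; the event count, identifiers and channel set
#' are untouched.
#'
#' @param tbl an [event_table()].
#' @param tset a [transform_set()]; every channel in the set must exist in
#'   the table.
#' @param inverse if `TRUE`, apply the inverse transformations (display
#'   decades back to data units).
#' @return the transformed [event_table()].
#' @export
apply_transform_set <- function(tbl, tset, inverse = FALSE) {
  stopifnot(inherits(tset, "transform_set"))
  missing <- setdiff(names(tset), tbl$channels)
  if (length(missing)) {
    stop("transform set channels absent from the table: ",
         paste(missing, collapse = ", "))
  }
  for (ch in names(tset)) {
    tr <- tset[[ch]]
    if (identical(tr, "identity")) next
    tbl$values[, ch] <- if (inverse) {
      logicle_inverse(tbl$values[, ch], tr)
    } else {
      logicle_forward(tbl$values[, ch], tr)
    }
  }
  tbl
}

#' Replace one channel's transformation parameters
#'
#' Supports the manual-adjustment workflow: when the automatic estimation is
#' unsatisfactory for one marker (e.g. spurious density oscillations in the
#' negative domain), the user replaces that channel's parameters — typically
#' the display width `M` — and re-applies the set.
#'
#' @param tset a [transform_set()].
#' @param channel channel whose transformation is replaced.
#' @param params a [logicle_params()] object or `"identity"`.
#' @return a new [transform_set()]; the input is not modified.
#' @export
adjust_transform <- function(tset, channel, params) {
  stopifnot(inherits(tset, "transform_set"))
  if (!channel %in% names(tset)) {
    stop("channel '", channel, "' is not part of the transform set")
  }
  if (!identical(params, "identity") && !inherits(params, "logicle_params")) {
    stop("params must be \"identity\" or a logicle_params object")
  }
  tset[[channel]] <- params
  tset
}

#' Serialize a transformation set to / from JSON
#'
#' @param tset a [transform_set()].
#' @param path JSON file path.
#' @return `read_transform_set()` returns a [transform_set()];
#'   `write_transform_set()` returns `path` invisibly.
#' @export
write_transform_set <- function(tset, path) {
  stopifnot(inherits(tset, "transform_set"))
  obj <- lapply(tset, function(tr) {
    if (identical(tr, "identity")) list(type = "identity")
    else list(type = "logicle", T = tr$T, M = tr$M, W = tr$W, A = tr$A)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform_set
#' @export
read_transform_set <- function(path) {
  obj <- jsonlite::read_json(path)
  entries <- lapply(obj, function(e) {
    if (identical(e$type, "identity")) "identity"
    else logicle_params(T = e$T, M = e$M, W = e$W, A = e$A)
  })
  transform_set(entries)
}
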