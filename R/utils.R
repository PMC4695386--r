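#' Interval sets
#'
#' Sorted, non-overlapping half-open intervals `[start, end)` in seconds.
#' Used for SPW-R events, SWS epochs, frames, and pause/run masks.
#'
#' @param start,end numeric vectors of interval edges (seconds).
#' @param kind character label for the set (e.g. `"spwr"`, `"frame"`,
#'   `"sws"`, `"pause"`, `"run"`).
#' @param ... extra per-interval columns (e.g. peak statistics).
#' @return a data frame of class `interval_set` with columns `start`, `end`,
#'   plus any extras, sorted by `start`.
#' @export
interval_set <- function(start, end, kind = "generic", ...) {
  stopifnot(length(start) == length(end))
  extra <- list(...)
  if (length(start) == 0L) {
    iv <- data.frame(start = numeric(0), end = numeric(0))
    for (nm in names(extra)) iv[[nm]] <- extra[[nm]]
  } else {
    if (any(end <= start)) stop("interval_set: end must exceed start")
    o <- order(start)
    iv <- data.frame(start = start[o], end = end[o])
    for (nm in names(extra)) iv[[nm]] <- extra[[nm]][o]
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
      stop("interval_set: intervals overlap")
  }
  attr(iv, "kind") <- kind
  class(iv) <- c("interval_set", "data.frame")
  iv
}

#' Merge touching or overlapping intervals
#' @param start,end interval edges.
#' @param gap merge intervals separated by less than `gap` seconds.
#' @return list with merged `start`, `end`.
#' @keywords internal
merge_interval_edges <- function(start, end, gap = 0) {
  if (length(start) == 0L) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me + gap) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Membership of time points in an interval set
#' @param t numeric times (s).
#' @param iv an `interval_set` (or data frame with start/end).
#' @return integer vector: index of the containing interval, NA outside.
#' @export
interval_index <- function(t, iv) {
  if (nrow(iv) == 0L) return(rep(NA_integer_, length(t)))
  i <- findInterval(t, iv$start)
  inside <- i >= 1L & t < iv$end[pmax(i, 1L)]
  ifelse(inside, i, NA_integer_)
}

#' @rdname interval_index
#' @export
in_intervals <- function(t, iv) !is.na(interval_index(t, iv))

#' Total duration of an interval set (s)
#' @param iv an `interval_set`.
#' @export
interval_duration <- function(iv) sum(iv$end - iv$start)

#' Complement of an interval set within a span
#' @param iv an `interval_set`.
#' @param span numeric length-2 `[t0, t1)`.
#' @export
interval_complement <- function(iv, span) {
  edges <- c(span[1], rbind(iv$start, iv$end), span[2])
  s <- edges[seq(1, length(edges) - 1, by = 2)]
  e <- edges[seq(2, length(edges), by = 2)]
  keep <- e > s
  interval_set(s[keep], e[keep], kind = "complement")
}

# --- deterministic substreams -------------------------------------------------

#' Derive a reproducible sub-seed from a master seed and a stage name
#'
#' Each generator stage and each shuffled event draws from its own named
#' substream so results do not depend on execution order.
#' @param seed master integer seed.
#' @param name character stage name (e.g. `"hippocampus"`, `"event_12"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483646 + 1)
}

#' Evaluate code under a named RNG substream
#' @param seed master seed; `name` substream name; `code` expression.
#' @keywords internal
with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, name))
  force(code)
}

# --- smoothing ----------------------------------------------------------------

#' Gaussian smoothing of a regularly sampled series
#' @param x numeric vector.
#' @param sigma_bins kernel s.d. in samples; `0` returns `x` unchanged.
#' @return smoothed vector, same length (reflected edges).
#' @export
smooth_gaussian <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(half:1, n)], x, x[pmax(n - (1:half) + 1, 1)])
  stats::filter(pad, k, sides = 2)[(half + 1):(half + n)]
}

#' Poisson event times on an interval with piecewise-constant rate
#'
#' Thinning sampler: `rate_fn(t)` must return rates bounded by `rate_max`.
#' @keywords internal
poisson_times <- function(t0, t1, rate_fn, rate_max) {
  if (rate_max <= 0 || t1 <= t0) return(numeric(0))
  n <- rpois(1L, rate_max * (t1 - t0))
  if (n == 0L) return(numeric(0))
  tt <- sort(runif(n, t0, t1))
  keep <- runif(n) < rate_fn(tt) / rate_max
  tt[keep]
}
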