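#' Autocorrelation decay time
#'
#' First lag at which the biased-normalised autocorrelation of a series
#' drops below 1/e.  Used as the unit for embedding delays, as the
#' default Theiler exclusion window, and for ACT-based trial selection.
#'
#' @param series numeric vector.
#' @param maxlag largest lag scanned (samples).
#' @return The decay time in samples, or `NA_integer_` (flagged
#'   "undefined") when the autocorrelation never falls below 1/e within
#'   `maxlag`.
#' @export
compute_act <- function(series, maxlag = 1000L) {
  maxlag <- min(as.integer(maxlag), length(series) - 1L)
  if (length(series) <= maxlag || maxlag < 1L)
    stop("series too short for maxlag = ", maxlag)
  if (sd(series) == 0) stop("degenerate input: constant series has no ACT")
  rho <- acf(series, lag.max = maxlag, plot = FALSE,
             demean = TRUE)$acf[-1]
  below <- which(rho < exp(-1))
  if (length(below) == 0L) return(NA_integer_)
  as.integer(below[1])
}

#' ACT table for a trial-based dataset
#'
#' @param data a [raw_dataset()].
#' @param maxlag lag range in samples.
#' @return An object of class `act_table`: a channels x trials integer
#'   matrix of decay times (NA = undefined within `maxlag`), with the
#'   `maxlag` used as an attribute.
#' @export
act_table <- function(data, maxlag = 1000L) {
  validate_raw_dataset(data)
  act <- matrix(NA_integer_, nrow = length(data$labels),
                ncol = n_trials(data),
                dimnames = list(data$labels, NULL))
  for (tr in seq_len(n_trials(data)))
    for (ch in seq_along(data$labels))
      act[ch, tr] <- compute_act(data$trials[[tr]][ch, ], maxlag)
  structure(act, maxlag = as.integer(maxlag), class = c("act_table", "matrix"))
}

#' Takens delay embedding
#'
#' Maps a scalar series to d-dimensional delay vectors
#' `(x(t), x(t - tau), ..., x(t - (d-1) tau))` paired with the future
#' sample `x(t + u)`.
#'
#' @param series numeric vector.
#' @param spec an [embedding_spec()] (only `d`, `tau`, `u` are used).
#' @return A list of class `embedded_series` with `points` (n_points x d
#'   matrix, column 1 = x(t)), `futures` (x(t+u) aligned to rows of
#'   `points`) and `time_indices` (the sample index t of each point).
#' @export
delay_embed <- function(series, spec) {
  d <- spec$d; tau <- spec$tau; u <- spec$u
  n <- length(series)
  need <- (d - 1L) * tau + u + 1L
  if (n < need)
    stop("series of length ", n, " too short for embedding; need >= ", need)
  t_idx <- seq.int((d - 1L) * tau + 1L, n - u)
  points <- vapply(seq_len(d) - 1L,
                   function(j) series[t_idx - j * tau],
                   numeric(length(t_idx)))
  if (!is.matrix(points)) points <- matrix(points, ncol = d)
  structure(list(points = points, futures = series[t_idx + u],
                 time_indices = t_idx),
            class = "embedded_series")
}

#' Theiler-aware neighbour counts at per-point radii
#'
#' Counts, for every point, the neighbours strictly within its query
#' radius under the maximum (Chebyshev) norm, excluding all points
#' within `theiler` samples in time (which excludes the point itself).
#'
#' @param points n x d numeric matrix.
#' @param query_radii positive radius per point.
#' @param theiler Theiler window in samples.
#' @param time_indices integer sample index per point.
#' @return Integer vector of counts.
#' @export
neighbour_counts <- function(points, query_radii, theiler, time_indices) {
  points <- as.matrix(points)
  if (length(query_radii) == 1L)
    query_radii <- rep(query_radii, nrow(points))
  if (length(query_radii) != nrow(points))
    stop("query_radii must have one radius per point")
  if (length(time_indices) != nrow(points))
    stop("time_indices must align with points")
  nn_count_cpp(points, as.numeric(query_radii), as.integer(theiler),
               as.integer(time_indices), TRUE)
}

# k-th neighbour distance per point (max-norm, Theiler-excluded).
kth_neighbour_dist <- function(points, k, theiler, time_indices) {
  nn_kdist_cpp(as.matrix(points), as.integer(k), as.integer(theiler),
               as.integer(time_indices))
}
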