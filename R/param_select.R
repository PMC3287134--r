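#' Cao criterion for the minimum embedding dimension
#'
#' For each scanned dimension d the relative growth in the distance to
#' the k-th neighbour when the embedding is extended from d to d+1
#' dimensions is averaged over all reconstruction points,
#' `E(d) = < ||v_{d+1}(t) - v_{d+1}(nn)|| / ||v_d(t) - v_d(nn)|| >_t`,
#' where the neighbour is found in d dimensions.  The saturation of
#' `E1(d) = E(d+1)/E(d)` marks the minimum embedding dimension; the
#' dimension is chosen by minimising the discrete second difference
#' `E1(d-1) + E1(d+1) - 2 E1(d)` over the interior of the scanned range.
#'
#' @param series numeric vector.
#' @param d_range dimensions to scan (at least 3, so the second
#'   difference has interior points).
#' @param tau embedding delay in samples.
#' @param k which neighbour to use for the distance ratio (fixed-mass
#'   search; default 4).
#' @param theiler Theiler exclusion window in samples (default 0:
#'   self-exclusion only).
#' @return An object of class `cao_result`: list with `E`, `E1` (named
#'   by dimension), `chosen_d`, `tau_used` and `d_range`.
#' @export
cao_scan <- function(series, d_range = 1:10, tau, k = 4L, theiler = 0L) {
  d_range <- sort(unique(as.integer(d_range)))
  if (length(d_range) < 3L)
    stop("need at least 3 scanned dimensions for the second difference")
  tau <- as.integer(tau)
  dmax <- max(d_range) + 1L
  need <- dmax * tau + 1L
  if (length(series) < need + 10L)
    stop("series too short for Cao scan up to d = ", dmax,
         " at tau = ", tau)
  d_all <- sort(unique(c(d_range, max(d_range) + 1L)))
  E <- setNames(rep(NA_real_, length(d_all)), d_all)
  for (d in d_all) {
    # embed in d+1 dimensions over the common valid range t = d*tau+1 .. N
    t_idx <- seq.int(d * tau + 1L, length(series))
    pts <- vapply(0:d, function(j) series[t_idx - j * tau],
                  numeric(length(t_idx)))
    nn <- nn_kindex_cpp(pts[, seq_len(d), drop = FALSE], as.integer(k),
                        as.integer(theiler), as.integer(t_idx))
    denom <- nn$dist
    num <- vapply(seq_along(t_idx), function(i) {
      j <- nn$index[i]
      if (is.na(j)) return(NA_real_)
      max(abs(pts[i, ] - pts[j, ]))
    }, numeric(1))
    ok <- !is.na(denom) & denom > 0
    if (!any(ok)) stop("Cao criterion degenerate at d = ", d,
                       ": all neighbour distances zero")
    E[as.character(d)] <- mean(num[ok] / denom[ok])
  }
  E1 <- setNames(rep(NA_real_, length(d_range)), d_range)
  for (d in d_range)
    E1[as.character(d)] <- E[as.character(d + 1L)] / E[as.character(d)]
  interior <- d_range[-c(1L, length(d_range))]
  crit <- vapply(interior, function(d) {
    E1[as.character(d - 1L)] + E1[as.character(d + 1L)] -
      2 * E1[as.character(d)]
  }, numeric(1))
  chosen <- interior[which.min(crit)]
  structure(list(E = E[as.character(d_range)], E1 = E1,
                 second_diff = setNames(crit, interior),
                 chosen_d = chosen, tau_used = tau, d_range = d_range),
            class = "cao_result")
}

#' @export
print.cao_result <- function(x, ...) {
  cat("<cao_result> chosen d =", x$chosen_d, " (tau =", x$tau_used,
      "samples)\n")
  cat("E1:", paste(sprintf("%d:%.3f", x$d_range, x$E1), collapse = "  "),
      "\n")
  invisible(x)
}

#' Local constant predictor
#'
#' Predicts the future of every reconstruction point as the mean of the
#' futures of its neighbourhood: either all points within a max-norm
#' radius (`mode = 'Range'`, neighbours with distance <= size) or the
#' `size` nearest neighbours (`mode = 'Mass'`), excluding the point
#' itself and its Theiler window.
#'
#' @param embedded an `embedded_series` from [delay_embed()].
#' @param mode `'Range'` or `'Mass'`.
#' @param size radius (Range) or neighbour count (Mass).
#' @param theiler Theiler exclusion window in samples.
#' @return list with `pred` (NA where the neighbourhood is empty),
#'   `n_neigh`, and `n_empty` (count of excluded points).
#' @export
local_constant_predict <- function(embedded, mode = c("Mass", "Range"),
                                   size, theiler = 0L) {
  mode <- match.arg(mode)
  if (nrow(embedded$points) == 0L) stop("empty embedding")
  res <- lcp_predict_cpp(embedded$points, embedded$futures,
                         mode == "Mass", as.numeric(size),
                         as.integer(theiler),
                         as.integer(embedded$time_indices))
  if (all(res$n_neigh == 0L)) stop("no valid prediction points")
  list(pred = res$pred, n_neigh = res$n_neigh,
       n_empty = sum(res$n_neigh == 0L))
}

#' Ragwitz criterion: joint optimisation of embedding dimension and delay
#'
#' Scans a (d, tau) grid and selects the pair minimising the mean
#' squared prediction error of the local constant predictor at horizon
#' `u`.  Delays are given as multiples of the series' autocorrelation
#' decay time and converted to samples as `round(multiple * act)` with a
#' floor of one sample.  The error is evaluated on the `repPred` latest
#' valid reconstruction points, which are common to every grid cell.
#' Ties are broken towards the smallest d, then the smallest tau.
#'
#' @param series numeric vector.
#' @param d_range dimensions to scan.
#' @param tau_range_act `c(min, max)` delay in units of ACT.
#' @param tau_steps number of equidistant steps in `tau_range_act`
#'   (minimum 5).
#' @param u prediction horizon in samples.
#' @param mode,size neighbourhood definition, see
#'   [local_constant_predict()].
#' @param repPred number of evaluation points.
#' @param act the series' autocorrelation decay time in samples.
#' @param theiler Theiler exclusion window (default 0).
#' @return An object of class `ragwitz_result`: list with `mse_grid`
#'   (d x tau), `chosen_d`, `chosen_tau` (samples), `taus` and
#'   `repPred`.
#' @export
ragwitz_scan <- function(series, d_range = 1:10, tau_range_act = c(0.5, 1.5),
                         tau_steps = 10L, u = 1L, mode = "Mass", size = 4L,
                         repPred, act, theiler = 0L) {
  d_range <- sort(unique(as.integer(d_range)))
  if (tau_steps < 5L) stop("tau_steps must be >= 5")
  mult <- seq(tau_range_act[1], tau_range_act[2], length.out = tau_steps)
  taus <- pmax(1L, as.integer(round(mult * act)))
  n <- length(series)
  mse <- matrix(NA_real_, nrow = length(d_range), ncol = length(taus),
                dimnames = list(d = d_range, tau = taus))
  cache <- new.env(parent = emptyenv())
  for (di in seq_along(d_range)) for (ti in seq_along(taus)) {
    d <- d_range[di]; tau <- taus[ti]
    key <- paste(d, tau)
    if (!is.null(cache[[key]])) { mse[di, ti] <- cache[[key]]; next }
    n_pts <- n - (d - 1L) * tau - u
    if (n_pts < repPred)
      stop("repPred = ", repPred, " infeasible at (d = ", d, ", tau = ",
           tau, "): only ", max(0L, n_pts), " valid points")
    emb <- delay_embed(series, embedding_spec(d, tau, u))
    lcp <- local_constant_predict(emb, mode, size, theiler)
    eval_idx <- seq.int(n_pts - repPred + 1L, n_pts)
    err <- emb$futures[eval_idx] - lcp$pred[eval_idx]
    err <- err[!is.na(err)]
    if (length(err) == 0L) stop("no valid prediction points at (d = ", d,
                                ", tau = ", tau, ")")
    mse[di, ti] <- mean(err^2)
    cache[[key]] <- mse[di, ti]
  }
  # tie-aware minimiser: smallest d, then smallest tau
  best <- which(mse <= min(mse) + 0, arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  structure(list(mse_grid = mse, chosen_d = d_range[best[1, 1]],
                 chosen_tau = taus[best[1, 2]], taus = taus,
                 repPred = repPred, d_range = d_range),
            class = "ragwitz_result")
}

#' @export
print.ragwitz_result <- function(x, ...) {
  cat("<ragwitz_result> chosen d =", x$chosen_d, ", tau =", x$chosen_tau,
      "samples; repPred =", x$repPred, "\n")
  invisible(x)
}
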