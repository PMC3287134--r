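#' Nearest-neighbour transfer entropy
#'
#' Estimates the transfer entropy from `source` to `target` with the
#' fixed-mass nearest-neighbour (Kraskov-Stoegbauer-Grassberger style)
#' estimator: the distance to the k-th neighbour in the joint space
#' spanned by `(y(t+u), y_t^d, x_t^d)` sets the radius for strict-count
#' neighbour searches in the three marginal spaces, and
#'
#' `TE = psi(k) + < psi(n_y + 1) - psi(n_{y+ y} + 1) - psi(n_{y x} + 1) >_t`
#'
#' in nats.  Both signals are embedded with the same dimension and
#' delay; the prediction time `u` shifts the predicted target sample.
#' Estimates can be negative for finite data (estimator bias) and are
#' returned unclipped.
#'
#' @param source,target numeric vectors of equal length.
#' @param spec an [embedding_spec()].
#' @return TE(X->Y) in nats, with attributes `n_points` (time points
#'   averaged) and `n_dropped` (points discarded because their joint
#'   k-th-neighbour distance was zero, i.e. exact duplicates).
#' @export
transfer_entropy <- function(source, target, spec) {
  if (length(source) != length(target))
    stop("source and target must have the same length")
  if (sd(source) == 0 || sd(target) == 0)
    stop("degenerate input: constant series (singular distribution)")
  emb_y <- delay_embed(target, spec)
  emb_x <- delay_embed(source, spec)
  joint <- cbind(emb_y$futures, emb_y$points, emb_x$points)
  tidx <- emb_y$time_indices
  kd <- kth_neighbour_dist(joint, spec$k, spec$theiler, tidx)
  valid <- is.finite(kd) & kd > 0
  if (!any(valid))
    stop("no valid time points: all joint k-th neighbour distances ",
         "are zero or undefined")
  radii <- ifelse(valid, kd, 0)
  n_y <- neighbour_counts(emb_y$points, radii, spec$theiler, tidx)
  n_yfut_y <- neighbour_counts(joint[, seq_len(spec$d + 1L), drop = FALSE],
                               radii, spec$theiler, tidx)
  n_y_x <- neighbour_counts(cbind(emb_y$points, emb_x$points),
                            radii, spec$theiler, tidx)
  te <- digamma(spec$k) +
    mean(digamma(n_y[valid] + 1) - digamma(n_yfut_y[valid] + 1) -
           digamma(n_y_x[valid] + 1))
  structure(te, n_points = sum(valid), n_dropped = sum(!valid))
}

#' Nearest-neighbour mutual information
#'
#' Fixed-mass (Kraskov algorithm 1 style) mutual information between the
#' simultaneous sample pairs `(a_t, b_t)`, in nats:
#' `MI = psi(k) + < psi(N_t) > - < psi(n_a + 1) + psi(n_b + 1) >_t`,
#' where the k-th-neighbour distance in the joint (a, b) plane sets the
#' strict-count radius in each marginal and `N_t` is the number of
#' admissible (Theiler-allowed) neighbours of point t plus one.
#' Symmetric in (a, b) up to estimator noise.
#'
#' @param a,b numeric vectors of equal length.
#' @param k neighbour mass (default 4).
#' @param theiler Theiler exclusion window in samples (default 0).
#' @return MI estimate in nats with attributes as [transfer_entropy()].
#' @export
mutual_information <- function(a, b, k = 4L, theiler = 0L) {
  if (length(a) != length(b)) stop("a and b must have the same length")
  if (sd(a) == 0 || sd(b) == 0)
    stop("degenerate input: constant series (singular distribution)")
  n <- length(a)
  tidx <- seq_len(n)
  joint <- cbind(a, b)
  kd <- kth_neighbour_dist(joint, k, theiler, tidx)
  valid <- is.finite(kd) & kd > 0
  if (!any(valid)) stop("no valid points for MI estimation")
  radii <- ifelse(valid, kd, 0)
  n_a <- neighbour_counts(matrix(a, ncol = 1), radii, theiler, tidx)
  n_b <- neighbour_counts(matrix(b, ncol = 1), radii, theiler, tidx)
  # admissible neighbours of point i under the Theiler rule
  n_adm <- (n - 1L) - (pmin(tidx - 1L, theiler) + pmin(n - tidx, theiler))
  mi <- digamma(k) + mean(digamma(n_adm[valid] + 1)) -
    mean(digamma(n_a[valid] + 1) + digamma(n_b[valid] + 1))
  structure(mi, n_points = sum(valid), n_dropped = sum(!valid))
}

#' Convert nats to bits
#'
#' @param x value(s) in nats.
#' @return `x / log(2)`.
#' @export
nats_to_bits <- function(x) x / log(2)

# Trial-wise TE (and MI) for one ordered channel pair of a dataset.
# Returns a data.frame with one row per trial.
pair_te_trials <- function(data, source_label, target_label, spec,
                           trials = seq_len(n_trials(data)), with_mi = TRUE) {
  source_label <- unname(source_label)
  target_label <- unname(target_label)
  trials <- unname(trials)
  te <- mi <- numeric(length(trials))
  for (j in seq_along(trials)) {
    x <- channel_series(data, source_label, trials[j])
    y <- channel_series(data, target_label, trials[j])
    te[j] <- as.numeric(transfer_entropy(x, y, spec))
    mi[j] <- if (with_mi)
      as.numeric(mutual_information(x, y, spec$k, spec$theiler)) else NA_real_
  }
  data.frame(source = source_label, target = target_label, trial = trials,
             te_nats = te, mi_nats = mi, stringsAsFactors = FALSE)
}
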