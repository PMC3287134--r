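#' Nonparametric permutation test between two groups of values
#'
#' Computes an observed statistic (difference of means, pooled-variance
#' independent-samples t, or paired t), then builds its null
#' distribution by relabelling.  When the number of distinct
#' relabellings is at most `numpermutation` the full permutation
#' distribution is enumerated and the p-value is the exact tail
#' fraction (the identity relabelling included); otherwise Monte-Carlo
#' resampling is used with the `(1 + b) / (1 + numpermutation)`
#' convention, so the smallest attainable p is
#' `1/(numpermutation + 1)`.
#'
#' @param group_a,group_b numeric vectors (equal length when `paired`).
#' @param statstype `'mean'`, `'indepsamplesT'` or `'depsamplesT'`.
#' @param tail 2 for `|t*| >= |t_obt|`, 1 for the upper tail
#'   `t* >= t_obt` (a > b).
#' @param numpermutation number of Monte-Carlo permutations.
#' @param paired permute within pairs (sign flips) instead of
#'   relabelling group membership; implied by `'depsamplesT'`.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return list with `t_obt`, `p`, `statstype`, `tail`,
#'   `numpermutation` and `exhaustive`.
#' @export
permutation_test <- function(group_a, group_b,
                             statstype = c("mean", "indepsamplesT",
                                           "depsamplesT"),
                             tail = 2L, numpermutation = 190100L,
                             paired = NULL, seed = 1L) {
  statstype <- match.arg(statstype)
  if (is.null(paired)) paired <- statstype == "depsamplesT"
  if (statstype == "depsamplesT") paired <- TRUE
  na <- length(group_a); nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("empty group")
  if (paired && na != nb) stop("paired test requires equal group sizes")
  stat <- switch(statstype,
    mean = function(a, b) mean(a) - mean(b),
    indepsamplesT = function(a, b) {
      va <- var(a); vb <- var(b)
      if (va == 0 && vb == 0)
        stop("degenerate statistic: zero variance in both groups ",
             "(indepsamplesT)")
      sp <- ((length(a) - 1) * va + (length(b) - 1) * vb) /
        (length(a) + length(b) - 2)
      (mean(a) - mean(b)) / sqrt(sp * (1 / length(a) + 1 / length(b)))
    },
    depsamplesT = function(a, b) {
      d <- a - b
      if (var(d) == 0)
        stop("degenerate statistic: zero variance of differences ",
             "(depsamplesT)")
      mean(d) / (sd(d) / sqrt(length(d)))
    })
  t_obt <- stat(group_a, group_b)
  hit <- function(t_star)
    if (tail == 2L) abs(t_star) >= abs(t_obt) else t_star >= t_obt

  if (paired) {
    n_exact <- 2^na
    if (n_exact <= numpermutation) {
      flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), na)))
      t_star <- apply(flips, 1, function(fl) {
        a <- ifelse(fl, group_b, group_a)
        b <- ifelse(fl, group_a, group_b)
        stat(a, b)
      })
      p <- mean(hit(t_star))
      return(list(t_obt = t_obt, p = p, statstype = statstype, tail = tail,
                  numpermutation = n_exact, exhaustive = TRUE))
    }
    b_hits <- with_seed(seed, {
      hits <- 0L
      for (i in seq_len(numpermutation)) {
        fl <- runif(na) < 0.5
        a <- ifelse(fl, group_b, group_a)
        b <- ifelse(fl, group_a, group_b)
        if (hit(stat(a, b))) hits <- hits + 1L
      }
      hits
    })
    p <- (1 + b_hits) / (1 + numpermutation)
    return(list(t_obt = t_obt, p = p, statstype = statstype, tail = tail,
                numpermutation = numpermutation, exhaustive = FALSE))
  }

  pool <- c(group_a, group_b)
  n <- na + nb
  n_exact <- choose(n, na)
  if (n_exact <= numpermutation) {
    idx <- combn(n, na)
    t_star <- apply(idx, 2, function(ii) stat(pool[ii], pool[-ii]))
    p <- mean(hit(t_star))
    return(list(t_obt = t_obt, p = p, statstype = statstype, tail = tail,
                numpermutation = n_exact, exhaustive = TRUE))
  }
  b_hits <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(numpermutation)) {
      ii <- sample.int(n, na)
      if (hit(stat(pool[ii], pool[-ii]))) hits <- hits + 1L
    }
    hits
  })
  p <- (1 + b_hits) / (1 + numpermutation)
  list(t_obt = t_obt, p = p, statstype = statstype, tail = tail,
       numpermutation = numpermutation, exhaustive = FALSE)
}

#' Multiple-comparison correction
#'
#' @param pvalues numeric vector of p-values.
#' @param method `'FDR'` (Benjamini-Hochberg step-up) or `'BONF'`
#'   (Bonferroni: p <= alpha/m).
#' @param alpha family-wise / FDR level.
#' @return Logical significance flags (empty input gives empty output).
#' @export
correct_multiple <- function(pvalues, method = c("FDR", "BONF"),
                             alpha = 0.05) {
  method <- match.arg(method)
  if (length(pvalues) == 0L) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  if (method == "BONF") pvalues <= alpha / length(pvalues)
  else p.adjust(pvalues, method = "BH") <= alpha
}

#' Shift test against instantaneous linear mixing
#'
#' Computes, per trial, TE from the original source and from a
#' time-advanced copy `X'(t) = X(t + s)` (s = the prediction time `u`
#' for `shifttype = 'predicttime'`, one sample for `'onesample'`) to
#' the same target, and compares the two trial-wise TE distributions
#' with a permutation test.  For a genuinely delayed coupling the
#' shifted source loses its predictive samples and TE drops;
#' instantaneously shared signal or noise instead becomes *more*
#' predictive under the shift.
#'
#' With `shifttesttype = 'TE > TEshift'` (conservative) mixing is
#' declared unless the original TE significantly exceeds the shifted TE
#' at `alpha` = 0.05; with `'TEshift > TE'` mixing is declared when the
#' shifted TE significantly exceeds the original at `alpha` = 0.1.
#'
#' @param source_trials,target_trials lists of per-trial numeric
#'   vectors.
#' @param spec an [embedding_spec()].
#' @param shifttype `'predicttime'` or `'onesample'`.
#' @param shifttesttype `'TE > TEshift'` or `'TEshift > TE'`.
#' @param statstype permutation statistic, see [permutation_test()].
#' @param numpermutation permutations for the comparison.
#' @param seed integer seed.
#' @return list with `mixing_detected`, `p`, `shifttesttype`, `alpha`,
#'   and the per-trial values `te_orig`, `te_shift`.
#' @export
shift_test <- function(source_trials, target_trials, spec,
                       shifttype = c("predicttime", "onesample"),
                       shifttesttype = c("TE > TEshift", "TEshift > TE"),
                       statstype = "indepsamplesT",
                       numpermutation = 190100L, seed = 1L) {
  shifttype <- match.arg(shifttype)
  shifttesttype <- match.arg(shifttesttype)
  s <- if (shifttype == "predicttime") spec$u else 1L
  nt <- length(source_trials)
  if (nt != length(target_trials)) stop("trial lists must align")
  te_orig <- te_shift <- numeric(nt)
  for (i in seq_len(nt)) {
    x <- source_trials[[i]]; y <- target_trials[[i]]
    if (length(x) != length(y)) stop("trial ", i, ": unequal lengths")
    m <- length(x) - s
    if (m < (spec$d - 1L) * spec$tau + spec$u + 1L)
      stop("trial ", i, " too short for shift by ", s, " samples")
    # both TE values on a common trial length for comparability
    te_orig[i] <- as.numeric(transfer_entropy(x[seq_len(m)], y[seq_len(m)],
                                              spec))
    te_shift[i] <- as.numeric(transfer_entropy(x[seq.int(s + 1L, s + m)],
                                               y[seq_len(m)], spec))
  }
  alpha <- if (shifttesttype == "TE > TEshift") 0.05 else 0.1
  if (shifttesttype == "TE > TEshift") {
    pt <- permutation_test(te_orig, te_shift, statstype, tail = 1L,
                           numpermutation = numpermutation, seed = seed)
    mixing <- pt$p > alpha  # no positive evidence against mixing
  } else {
    pt <- permutation_test(te_shift, te_orig, statstype, tail = 1L,
                           numpermutation = numpermutation, seed = seed)
    mixing <- pt$p <= alpha
  }
  list(mixing_detected = mixing, p = pt$p, t_obt = pt$t_obt,
       shifttesttype = shifttesttype, alpha = alpha,
       te_orig = te_orig, te_shift = te_shift)
}
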