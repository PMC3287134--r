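#' Group design matrix
#'
#' @param design numeric matrix with one row giving the unit of
#'   observation (subject) of each dataset and one row giving the
#'   condition (independent variable); one column per dataset.
#' @param uvar row index of the unit-of-observation row.
#' @param ivar row index of the condition row.
#' @return An object of class `group_design`.
#' @export
group_design <- function(design, uvar = 1L, ivar = 2L) {
  design <- as.matrix(design)
  if (any(c(uvar, ivar) > nrow(design)) || uvar == ivar)
    stop("uvar/ivar must index distinct rows of the design matrix")
  if (anyNA(design[c(uvar, ivar), ]))
    stop("every dataset needs a unit and a condition assignment")
  structure(list(design = design, uvar = as.integer(uvar),
                 ivar = as.integer(ivar)),
            class = "group_design")
}

# every unit present in every condition (required for paired statistics)
check_dependent_design <- function(gd) {
  units <- gd$design[gd$uvar, ]
  conds <- gd$design[gd$ivar, ]
  tab <- table(units, conds)
  if (any(tab != 1L))
    stop("dependent-samples design requires each unit exactly once ",
         "per condition")
  invisible(TRUE)
}

crop_toi <- function(data, toi) {
  if (is.null(toi)) return(data)
  out <- data
  for (i in seq_along(data$trials)) {
    keep <- which(data$times[[i]] >= toi[1] & data$times[[i]] <= toi[2])
    if (length(keep) < 2L) stop("toi leaves trial ", i, " empty")
    out$trials[[i]] <- data$trials[[i]][, keep, drop = FALSE]
    out$times[[i]] <- data$times[[i]][keep]
  }
  out
}

# per-channel embedding optimisation on up to opt_ntrials trials;
# returns list(d, tau, per_trial = <cao/ragwitz results>)
optimize_channel <- function(data, label, cfg, act, trials, u, opt_ntrials) {
  use <- head(trials, opt_ntrials)
  acts <- act[label, use]
  act_med <- max(1L, as.integer(round(stats::median(acts, na.rm = TRUE))))
  per_trial <- lapply(use, function(tr) {
    x <- channel_series(data, label, tr)
    if (cfg$optimizemethod == "cao") {
      tau_s <- max(1L, as.integer(round(cfg$tau * act_med)))
      cao_scan(x, cfg$caodim, tau = tau_s, k = cfg$caokth_neighbors)
    } else {
      repPred <- cfg$repPred
      if (is.null(repPred)) {
        worst <- length(x) - (max(cfg$ragdim) - 1L) *
          max(1L, round(max(cfg$ragtaurange) * act_med)) - u
        repPred <- max(10L, min(100L, worst))
      }
      ragwitz_scan(x, cfg$ragdim, cfg$ragtaurange, cfg$ragtausteps,
                   u = u, mode = cfg$flagNei, size = cfg$sizeNei,
                   repPred = repPred, act = act_med)
    }
  })
  ds <- vapply(per_trial, function(r) r$chosen_d, integer(1))
  taus <- vapply(per_trial, function(r)
    if (inherits(r, "cao_result")) r$tau_used else r$chosen_tau, integer(1))
  # modal dimension across trials, ties towards the larger d
  tab <- table(ds)
  d_mode <- as.integer(names(tab)[tab == max(tab)])
  d_ch <- max(d_mode)
  tau_ch <- max(1L, as.integer(round(stats::median(taus[ds == d_ch]))))
  list(d = d_ch, tau = tau_ch, act = act_med, per_trial = per_trial)
}

#' Prepare a dataset for transfer-entropy analysis
#'
#' Validates the data and configuration, crops to the time window of
#' interest, computes the autocorrelation decay times, selects trials,
#' optimises the embedding parameters per channel (Cao or Ragwitz
#' criterion) and reduces them to one [embedding_spec()] per ordered
#' channel pair: the larger of the two channels' dimensions wins
#' (under-embedding is the harmful direction) together with its
#' channel's delay.  The configured prediction time in milliseconds is
#' converted to samples.
#'
#' @param data a [raw_dataset()].
#' @param cfg an [analysis_config()] with `sgncmb` and `predicttime_u`
#'   set (when `sgncmb` is `NULL` all ordered label pairs are used).
#' @param opt_ntrials number of trials per channel on which the
#'   embedding criterion is evaluated (the per-trial choices are
#'   reduced by modal dimension, ties towards the larger d).
#' @return An object of class `prepared_dataset`.
#' @export
prepare <- function(data, cfg, opt_ntrials = 5L) {
  validate_raw_dataset(data)
  pairs <- cfg$sgncmb
  if (is.null(pairs)) {
    combos <- expand.grid(source = data$labels, target = data$labels,
                          stringsAsFactors = FALSE)
    combos <- combos[combos$source != combos$target, ]
    pairs <- as.matrix(combos[, c("source", "target")])
  }
  miss <- setdiff(unique(as.vector(pairs)), data$labels)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  data <- crop_toi(data, cfg$toi)
  u <- u_samples(cfg, data$fsample)
  act <- act_table(data, cfg$maxlag)

  select_trials <- function(chs) {
    nt <- n_trials(data)
    if (cfg$trialselect == "no") return(seq_len(nt))
    if (cfg$trialselect == "range") {
      if (is.null(cfg$trial_from) || is.null(cfg$trial_to))
        stop("trialselect='range' needs trial_from and trial_to")
      return(seq.int(cfg$trial_from, min(cfg$trial_to, nt)))
    }
    if (is.null(cfg$actthrvalue))
      stop("trialselect='ACT' needs actthrvalue")
    ok <- apply(act[chs, , drop = FALSE], 2,
                function(a) all(!is.na(a) & a <= cfg$actthrvalue))
    which(ok)
  }

  pair_trials <- vector("list", nrow(pairs))
  specs <- vector("list", nrow(pairs))
  opt <- list()
  for (p in seq_len(nrow(pairs))) {
    chs <- pairs[p, ]
    trs <- select_trials(chs)
    if (length(trs) < cfg$minnrtrials)
      stop("too few trials (", length(trs), " < minnrtrials = ",
           cfg$minnrtrials, ") for pair ", chs[1], " -> ", chs[2])
    pair_trials[[p]] <- trs
    for (ch in chs)
      if (is.null(opt[[ch]])) {
        if (!is.null(cfg$dim)) {
          tau_s <- if (!is.null(cfg$tau_samples)) as.integer(cfg$tau_samples)
          else max(1L, as.integer(round(
            cfg$tau * stats::median(act[ch, trs], na.rm = TRUE))))
          opt[[ch]] <- list(d = as.integer(cfg$dim), tau = tau_s,
                            act = max(1L, as.integer(round(
                              stats::median(act[ch, trs], na.rm = TRUE)))),
                            per_trial = NULL)
        } else {
          opt[[ch]] <- optimize_channel(data, ch, cfg, act, trs, u,
                                        opt_ntrials)
        }
      }
    # reduction: larger d wins, with its channel's tau
    o1 <- opt[[chs[1]]]; o2 <- opt[[chs[2]]]
    win <- if (o2$d >= o1$d) o2 else o1
    theiler <- if (identical(cfg$TheilerT, "ACT"))
      max(o1$act, o2$act) else as.integer(cfg$TheilerT)
    specs[[p]] <- embedding_spec(win$d, win$tau, u, cfg$kth_neighbors,
                                 theiler)
  }
  structure(list(data = data, act = act, pairs = pairs,
                 trials = pair_trials, specs = specs, opt = opt,
                 u = u, cfg = cfg,
                 fingerprint = config_fingerprint(cfg)),
            class = "prepared_dataset")
}

#' @export
print.prepared_dataset <- function(x, ...) {
  cat("<prepared_dataset> ", nrow(x$pairs), " pair(s), u = ", x$u,
      " samples, fingerprint ", x$fingerprint, "\n", sep = "")
  for (p in seq_len(nrow(x$pairs)))
    cat("  ", x$pairs[p, 1], "->", x$pairs[p, 2], ": d=", x$specs[[p]]$d,
        " tau=", x$specs[[p]]$tau, " theiler=", x$specs[[p]]$theiler,
        " (", length(x$trials[[p]]), " trials)\n", sep = "")
  invisible(x)
}

# both directions of every configured pair
directed_pairs <- function(pairs) {
  out <- unique(rbind(pairs, pairs[, 2:1, drop = FALSE]))
  colnames(out) <- c("source", "target")
  out
}

#' Surrogate-data analysis of a prepared dataset
#'
#' For every directed channel pair: trial-wise TE and MI on the
#' original data; the same on surrogate data (the source channel
#' manipulated per `cfg$surrogatetype`); a shift test against
#' instantaneous mixing (when `cfg$shifttest = 'yes'`); a permutation
#' test of original-vs-surrogate trial TE values; and multiple-
#' comparison correction across all directed pairs.  A directed pair
#' whose shift test reports mixing is returned with verdict
#' `"instantaneous mixing - no verdict"` regardless of its p-value.
#'
#' @param prepared a [prepared_dataset()].
#' @param cfg configuration; defaults to the one used in [prepare()].
#' @return list with `te` (a [te_result_set()] of original trial
#'   values), `surrogate_te` (surrogate trial values), `permtest`
#'   (data.frame per directed pair: `t_obt`, `p`, `significant`,
#'   `mixing_detected`, `verdict`) and `shift` (per-pair shift-test
#'   details).
#' @export
surrogate_analysis <- function(prepared, cfg = prepared$cfg) {
  dp <- directed_pairs(prepared$pairs)
  res_rows <- list(); surr_rows <- list(); shift_res <- list()
  stats_rows <- list()
  for (i in seq_len(nrow(dp))) {
    src <- unname(dp[i, 1]); tgt <- unname(dp[i, 2])
    p_idx <- pair_index(prepared, src, tgt)
    spec <- prepared$specs[[p_idx]]
    trs <- prepared$trials[[p_idx]]
    tag <- paste0(src, "->", tgt)
    te_orig <- pair_te_trials(prepared$data, src, tgt, spec, trs)
    sspec <- surrogate_spec(cfg$surrogatetype, src,
                            derive_seed(cfg$rng_seed, paste0("surr_", tag)))
    surr <- make_surrogate(prepared$data, sspec)
    te_surr <- pair_te_trials(surr, src, tgt, spec, trs, with_mi = FALSE)
    sh <- NULL
    if (identical(cfg$shifttest, "yes")) {
      xs <- lapply(trs, function(tr) channel_series(prepared$data, src, tr))
      ys <- lapply(trs, function(tr) channel_series(prepared$data, tgt, tr))
      sh <- shift_test(xs, ys, spec, cfg$shifttype, cfg$shifttesttype,
                       statstype = cfg$permstatstype,
                       numpermutation = cfg$numpermutation,
                       seed = derive_seed(cfg$rng_seed,
                                          paste0("shift_", tag)))
    }
    pt <- permutation_test(te_orig$te_nats, te_surr$te_nats,
                           cfg$permstatstype, tail = cfg$tail,
                           numpermutation = cfg$numpermutation,
                           seed = derive_seed(cfg$rng_seed,
                                              paste0("perm_", tag)))
    res_rows[[i]] <- te_orig
    surr_rows[[i]] <- te_surr
    shift_res[[tag]] <- sh
    stats_rows[[i]] <- data.frame(
      source = src, target = tgt, t_obt = pt$t_obt, p = pt$p,
      mixing_detected = if (is.null(sh)) NA else sh$mixing_detected,
      stringsAsFactors = FALSE)
  }
  permtest <- do.call(rbind, stats_rows)
  permtest$significant <- correct_multiple(permtest$p, cfg$correctm,
                                           cfg$alpha)
  permtest$verdict <- ifelse(
    !is.na(permtest$mixing_detected) & permtest$mixing_detected,
    "instantaneous mixing - no verdict",
    ifelse(permtest$significant, "significant interaction",
           "no significant interaction"))
  prov <- list(fingerprint = prepared$fingerprint, seed = cfg$rng_seed,
               version = as.character(utils::packageVersion("teflow")))
  list(te = te_result_set(do.call(rbind, res_rows),
                          prepared$specs, prov),
       surrogate_te = do.call(rbind, surr_rows),
       permtest = permtest, shift = shift_res)
}

pair_index <- function(prepared, src, tgt) {
  hit <- which(prepared$pairs[, 1] == src & prepared$pairs[, 2] == tgt)
  if (length(hit) == 0L)
    hit <- which(prepared$pairs[, 1] == tgt & prepared$pairs[, 2] == src)
  if (length(hit) == 0L) stop("pair ", src, "->", tgt, " not prepared")
  hit[1]
}

# one commensurable spec for two (or more) prepared datasets:
# the largest dimension wins, with its dataset's tau
common_pair_spec <- function(prepared_list, src, tgt) {
  specs <- lapply(prepared_list, function(pr)
    pr$specs[[pair_index(pr, src, tgt)]])
  ds <- vapply(specs, function(s) s$d, integer(1))
  win <- specs[[which.max(ds)]]
  win
}

#' Compare TE between two conditions of one unit of observation
#'
#' Computes trial-wise TE for both prepared datasets under one shared
#' embedding (the larger dimension of the two preparations, so values
#' are commensurable) and tests the difference per directed pair with a
#' permutation test over condition labels, corrected across pairs.
#'
#' @param prepared_a,prepared_b [prepared_dataset()]s with identical
#'   channel pairs.
#' @param cfg configuration (defaults to `prepared_a$cfg`).
#' @return data.frame per directed pair with `t_obt`, `p`,
#'   `significant`, plus per-condition mean TE.
#' @export
compare_conditions <- function(prepared_a, prepared_b,
                               cfg = prepared_a$cfg) {
  if (!identical(dim(prepared_a$pairs), dim(prepared_b$pairs)) ||
      !all(prepared_a$pairs == prepared_b$pairs))
    stop("mismatched channel pairs between conditions")
  dp <- directed_pairs(prepared_a$pairs)
  rows <- list()
  for (i in seq_len(nrow(dp))) {
    src <- unname(dp[i, 1]); tgt <- unname(dp[i, 2])
    spec <- common_pair_spec(list(prepared_a, prepared_b), src, tgt)
    te_a <- pair_te_trials(prepared_a$data, src, tgt, spec,
                           prepared_a$trials[[pair_index(prepared_a, src,
                                                         tgt)]],
                           with_mi = FALSE)
    te_b <- pair_te_trials(prepared_b$data, src, tgt, spec,
                           prepared_b$trials[[pair_index(prepared_b, src,
                                                         tgt)]],
                           with_mi = FALSE)
    pt <- permutation_test(te_a$te_nats, te_b$te_nats, cfg$permstatstype,
                           tail = cfg$tail,
                           numpermutation = cfg$numpermutation,
                           seed = derive_seed(cfg$rng_seed,
                                              paste0("cond_", src, tgt)))
    rows[[i]] <- data.frame(source = src, target = tgt, t_obt = pt$t_obt,
                            p = pt$p, mean_te_a = mean(te_a$te_nats),
                            mean_te_b = mean(te_b$te_nats),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$significant <- correct_multiple(out$p, cfg$correctm, cfg$alpha)
  out
}

#' Group-level TE comparison
#'
#' Checks that every dataset was prepared under the same configuration
#' fingerprint, derives one common [embedding_spec()] per directed pair
#' (largest dimension across datasets), recomputes each dataset's
#' trial-wise TE under the common spec (datasets are independent; the
#' merge is by dataset position, so computations may run anywhere and
#' in any order), summarises each dataset by its mean trial TE, and
#' permutes condition labels across datasets (within units for
#' `'depsamplesT'`).  P-values are corrected across directed pairs.
#'
#' @param prepared_list list of [prepared_dataset()]s, one per dataset,
#'   in the column order of the design.
#' @param design a [group_design()].
#' @param cfg configuration (defaults to the first dataset's).
#' @return data.frame per directed pair with the permutation statistic,
#'   p-value and corrected significance flag.
#' @export
group_pipeline <- function(prepared_list, design,
                           cfg = prepared_list[[1]]$cfg) {
  if (length(prepared_list) != ncol(design$design))
    stop("design has ", ncol(design$design), " columns but ",
         length(prepared_list), " datasets were given")
  fps <- vapply(prepared_list, function(p) p$fingerprint, character(1))
  if (length(unique(fps)) != 1L)
    stop("inconsistent preparation: datasets carry different ",
         "configuration fingerprints")
  if (cfg$permstatstype == "depsamplesT") check_dependent_design(design)
  conds <- design$design[design$ivar, ]
  units <- design$design[design$uvar, ]
  lv <- sort(unique(conds))
  if (length(lv) != 2L) stop("group comparison needs exactly 2 conditions")
  dp <- directed_pairs(prepared_list[[1]]$pairs)
  rows <- list()
  for (i in seq_len(nrow(dp))) {
    src <- unname(dp[i, 1]); tgt <- unname(dp[i, 2])
    spec <- common_pair_spec(prepared_list, src, tgt)
    mean_te <- vapply(prepared_list, function(pr) {
      te <- pair_te_trials(pr$data, src, tgt, spec,
                           pr$trials[[pair_index(pr, src, tgt)]],
                           with_mi = FALSE)
      mean(te$te_nats)
    }, numeric(1))
    a <- mean_te[conds == lv[1]]; b <- mean_te[conds == lv[2]]
    if (cfg$permstatstype == "depsamplesT") {
      # align by unit
      a <- a[order(units[conds == lv[1]])]
      b <- b[order(units[conds == lv[2]])]
    }
    pt <- permutation_test(a, b, cfg$permstatstype, tail = cfg$tail,
                           numpermutation = cfg$numpermutation,
                           seed = derive_seed(cfg$rng_seed,
                                              paste0("group_", src, tgt)))
    rows[[i]] <- data.frame(source = src, target = tgt, t_obt = pt$t_obt,
                            p = pt$p, mean_te_cond1 = mean(mean_te[conds == lv[1]]),
                            mean_te_cond2 = mean(mean_te[conds == lv[2]]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$significant <- correct_multiple(out$p, cfg$correctm, cfg$alpha)
  out
}
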