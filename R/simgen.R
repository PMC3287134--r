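#' Committed AR(10) coefficient vector
#'
#' The benchmark systems use a fixed, stable order-10 autoregressive
#' coefficient vector: ten standard-normal draws (seeded) rescaled so
#' the companion-matrix spectral radius is 0.9.  The vector is committed
#' as a constant so every simulation is exactly reproducible.
#'
#' @format Numeric vector of length 10.
#' @export
ar10_alpha <- c(0.1276006856802512079, -0.0525587584528856427,
                0.0337978400242992250, 0.0589030998732957764,
                0.0376268991514358900, -0.0098774408873892779,
                0.1406835077280483570, -0.0088103021885770488,
                0.1878629147513733166, -0.0058370565917319883)

companion_radius <- function(alpha) {
  p <- length(alpha)
  comp <- rbind(alpha, cbind(diag(p - 1L), 0))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Configuration of the coupled AR(10) benchmark
#'
#' Two order-10 autoregressive processes with unidirectional quadratic
#' coupling: `X(t+1) = sum_i alpha_i X(t-i) + 0.1 eta_x(t)` and
#' `Y(t+1) = sum_i alpha_i Y(t-i) + 0.1 eta_y(t) + gamma X(t+1-delta)^2`.
#' The coupling constant gamma is calibrated (once, cached) so that the
#' coupling term contributes 50% of the variance of the final signal Y;
#' the coupling delay delta defaults to 21 samples.
#'
#' @param alpha_coeffs AR coefficients (default [ar10_alpha]).
#' @param gamma coupling constant; `NULL` (default) calibrates it.
#' @param delta coupling delay in samples.
#' @param innovation_scale innovation standard deviation (0.1).
#' @param n_trials trials per dataset (40).
#' @param n_samples samples per trial after burn-in (3000).
#' @param burn_in discarded leading samples per trial (1000).
#' @param fsample nominal sampling rate in Hz (1000, so 1 sample = 1 ms).
#' @param seed master seed; trials use derived substreams.
#' @return An object of class `ar_sim_config`.
#' @export
ar_sim_config <- function(alpha_coeffs = ar10_alpha, gamma = NULL,
                          delta = 21L, innovation_scale = 0.1,
                          n_trials = 40L, n_samples = 3000L,
                          burn_in = 1000L, fsample = 1000,
                          seed = 1L) {
  if (companion_radius(alpha_coeffs) >= 1)
    stop("unstable AR coefficient vector (spectral radius >= 1)")
  structure(list(alpha_coeffs = alpha_coeffs, gamma = gamma,
                 delta = as.integer(delta),
                 innovation_scale = innovation_scale,
                 n_trials = as.integer(n_trials),
                 n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), fsample = fsample,
                 seed = as.integer(seed)),
            class = "ar_sim_config")
}

# gamma calibration cache (per alpha/delta/innovation fingerprint)
.gamma_cache <- new.env(parent = emptyenv())

#' Calibrate the quadratic coupling constant
#'
#' Y is linear in its two inputs (own innovations and the shifted
#' squared source), so the variance contribution of the coupling term
#' scales with gamma^2 and one pilot simulation per component gives the
#' gamma at which the coupling contributes exactly half of var(Y):
#' `gamma = sd(AR-filtered innovations) / sd(AR-filtered X^2 input)`.
#'
#' @param cfg an [ar_sim_config()].
#' @param pilot_n pilot length in samples.
#' @return The calibrated gamma (cached).
#' @export
calibrate_gamma <- function(cfg, pilot_n = 2e5) {
  key <- paste(c(format(cfg$alpha_coeffs, digits = 17), cfg$delta,
                 cfg$innovation_scale), collapse = "|")
  hit <- .gamma_cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- cfg$alpha_coeffs
  n <- as.integer(pilot_n)
  burn <- 2000L
  g <- with_seed(derive_seed(1L, "gamma-pilot"), {
    x <- as.numeric(filter(cfg$innovation_scale * rnorm(n + burn), a,
                           "recursive"))
    xq <- c(rep(0, cfg$delta), x[seq_len(n + burn - cfg$delta)])^2
    cpl <- as.numeric(filter(xq, a, "recursive"))[-seq_len(burn)]
    own <- as.numeric(filter(cfg$innovation_scale * rnorm(n + burn), a,
                             "recursive"))[-seq_len(burn)]
    sd(own) / sd(cpl)
  })
  .gamma_cache[[key]] <- g
  g
}

# One realization of the coupled pair, burn-in discarded.
ar_pair_trial <- function(cfg, gamma, trial_seed) {
  n <- cfg$n_samples + cfg$burn_in
  a <- cfg$alpha_coeffs
  with_seed(trial_seed, {
    ex <- rnorm(n); ey <- rnorm(n)
    x <- as.numeric(filter(cfg$innovation_scale * ex, a, "recursive"))
    xq <- c(rep(0, cfg$delta), x[seq_len(n - cfg$delta)])^2
    y <- as.numeric(filter(cfg$innovation_scale * ey + gamma * xq, a,
                           "recursive"))
    keep <- seq.int(cfg$burn_in + 1L, n)
    rbind(X = x[keep], Y = y[keep])
  })
}

#' Simulate the unidirectionally coupled AR(10) pair
#'
#' @param cfg an [ar_sim_config()].
#' @return A [raw_dataset()] with channels `X` (source) and `Y`
#'   (target); trials are independent realizations.
#' @export
simulate_ar_pair <- function(cfg = ar_sim_config()) {
  gamma <- if (is.null(cfg$gamma)) calibrate_gamma(cfg) else cfg$gamma
  trials <- lapply(seq_len(cfg$n_trials), function(j)
    ar_pair_trial(cfg, gamma, derive_seed(cfg$seed, paste0("ar_trial_", j))))
  times <- lapply(trials, function(m) seq_len(ncol(m)) / cfg$fsample)
  raw_dataset(trials, times, c("X", "Y"), cfg$fsample)
}

#' Configuration of the white-noise mixing benchmarks
#'
#' Five scenarios probing robustness against instantaneous linear
#' mixing (volume conduction, shared noise): (A) two independent unit
#' white-noise channels; (B) one white-noise source split `(eps,
#' 1 - eps)` onto two noisy sensors; (C) two independent sources
#' symmetrically mixed, `X_eps = (1-eps) X + eps Y + noise` and vice
#' versa; (D) the coupled AR(10) pair under the same symmetric mixing;
#' (E) the coupled AR(10) pair with additive shared 50 Hz line noise,
#' optionally removed with a 4th-order two-pass Butterworth band-stop
#' filter (49-51 Hz).  Sensor noise contributes 25% of the variance of
#' each final signal.
#'
#' @param case `'A'`..`'E'`.
#' @param epsilon_mix mixing coefficient (study grid
#'   0.05/0.1/0.2/0.3/0.5; other values trigger a warning but run).
#' @param sensor_noise_var_fraction fraction of final-signal variance
#'   contributed by sensor noise (0.25).
#' @param fsample_sim sampling rate for case E in Hz (500, the
#'   down-sampled LFP rate; line amplitude is 25% of the signal's
#'   standard deviation).
#' @param line_filtered case E only: apply the band-stop filter.
#' @param n_trials,n_samples,seed as in [ar_sim_config()].
#' @return An object of class `mixing_config`.
#' @export
mixing_config <- function(case = c("A", "B", "C", "D", "E"),
                          epsilon_mix = 0.1,
                          sensor_noise_var_fraction = 0.25,
                          fsample_sim = 500, line_filtered = FALSE,
                          n_trials = 40L, n_samples = 3000L, seed = 1L) {
  case <- match.arg(case)
  study_eps <- c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  if (case %in% c("B", "C", "D") &&
      !any(abs(epsilon_mix - study_eps) < 1e-12))
    warning("epsilon_mix = ", epsilon_mix,
            " is outside the benchmark grid ",
            "{0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5}")
  structure(list(case = case, epsilon_mix = epsilon_mix,
                 sensor_noise_var_fraction = sensor_noise_var_fraction,
                 fsample_sim = fsample_sim, line_filtered = line_filtered,
                 n_trials = as.integer(n_trials),
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "mixing_config")
}

# sensor-noise sd so that noise contributes `frac` of the final variance
sensor_noise_sd <- function(signal_var, frac) {
  if (signal_var <= 0) return(1)
  sqrt(signal_var * frac / (1 - frac))
}

#' Simulate a linear-mixing benchmark dataset
#'
#' @param cfg a [mixing_config()].
#' @param ar an [ar_sim_config()] for cases D and E (defaults used if
#'   `NULL`).
#' @return A [raw_dataset()] with channels `X` and `Y`.
#' @export
simulate_mixing_case <- function(cfg, ar = NULL) {
  eps <- cfg$epsilon_mix
  frac <- cfg$sensor_noise_var_fraction
  n <- cfg$n_samples
  fs <- if (cfg$case == "E") cfg$fsample_sim else 1000
  if (cfg$case %in% c("D", "E") && is.null(ar))
    ar <- ar_sim_config(n_trials = cfg$n_trials, n_samples = cfg$n_samples,
                        seed = cfg$seed)
  trials <- lapply(seq_len(cfg$n_trials), function(j) {
    sd_trial <- derive_seed(cfg$seed, paste0("mix_", cfg$case, "_trial_", j))
    if (cfg$case == "A") {
      with_seed(sd_trial, rbind(X = rnorm(n), Y = rnorm(n)))
    } else if (cfg$case == "B") {
      with_seed(sd_trial, {
        z <- rnorm(n)
        sx <- eps * z
        sy <- (1 - eps) * z
        rbind(X = sx + rnorm(n, sd = sensor_noise_sd(var(sx), frac)),
              Y = sy + rnorm(n, sd = sensor_noise_sd(var(sy), frac)))
      })
    } else if (cfg$case == "C") {
      with_seed(sd_trial, {
        x <- rnorm(n); y <- rnorm(n)
        sx <- (1 - eps) * x + eps * y
        sy <- (1 - eps) * y + eps * x
        rbind(X = sx + rnorm(n, sd = sensor_noise_sd(var(sx), frac)),
              Y = sy + rnorm(n, sd = sensor_noise_sd(var(sy), frac)))
      })
    } else if (cfg$case == "D") {
      gamma <- if (is.null(ar$gamma)) calibrate_gamma(ar) else ar$gamma
      src <- ar_pair_trial(ar, gamma, sd_trial)
      x <- src["X", ]; y <- src["Y", ]
      sx <- (1 - eps) * x + eps * y
      sy <- (1 - eps) * y + eps * x
      with_seed(derive_seed(sd_trial, "sensor"), {
        rbind(X = sx + rnorm(n, sd = sensor_noise_sd(var(sx), frac)),
              Y = sy + rnorm(n, sd = sensor_noise_sd(var(sy), frac)))
      })
    } else {  # case E: shared 50 Hz line noise on the coupled pair
      gamma <- if (is.null(ar$gamma)) calibrate_gamma(ar) else ar$gamma
      src <- ar_pair_trial(ar, gamma, sd_trial)
      x <- src["X", ]; y <- src["Y", ]
      phase <- with_seed(derive_seed(sd_trial, "line-phase"),
                         runif(1, 0, 2 * pi))
      tt <- seq_len(n) / fs
      line <- sin(2 * pi * 50 * tt + phase)
      out <- rbind(X = x + 0.25 * sd(x) * line,
                   Y = y + 0.25 * sd(y) * line)
      if (cfg$line_filtered) {
        bf <- signal::butter(4, c(49, 51) / (fs / 2), type = "stop")
        out <- rbind(X = as.numeric(signal::filtfilt(bf, out["X", ])),
                     Y = as.numeric(signal::filtfilt(bf, out["Y", ])))
      }
      out
    }
  })
  times <- lapply(trials, function(m) seq_len(ncol(m)) / fs)
  raw_dataset(trials, times, c("X", "Y"), fs)
}

#' Simulate the multi-subject group benchmark
#'
#' One dataset per subject and condition, each with four channels
#' (`F3`, `F4`, `T7`, `T8`) of independent AR(10) series; condition 1
#' adds a quadratic coupling `F3 -> T8`, condition 2 `T7 -> F4`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param conditions number of conditions (2).
#' @param seed master seed.
#' @param ar an [ar_sim_config()] template for the channel dynamics.
#' @return list with `datasets` (ordered condition 1 subjects 1..n,
#'   then condition 2), and `design` (a [group_design()] with the
#'   subject row and the condition row).
#' @export
simulate_group_study <- function(n_subjects = 15L, conditions = 2L, seed = 1L,
                                 ar = ar_sim_config()) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (conditions != 2L) stop("the group benchmark defines 2 conditions")
  gamma <- if (is.null(ar$gamma)) calibrate_gamma(ar) else ar$gamma
  labels <- c("F3", "F4", "T7", "T8")
  gen_dataset <- function(subject, condition) {
    src_lab <- if (condition == 1L) "F3" else "T7"
    tgt_lab <- if (condition == 1L) "T8" else "F4"
    trials <- lapply(seq_len(ar$n_trials), function(j) {
      sd_trial <- derive_seed(seed, paste("grp", subject, condition, j,
                                          sep = "_"))
      n <- ar$n_samples + ar$burn_in
      with_seed(sd_trial, {
        m <- matrix(0, nrow = 4, ncol = ar$n_samples,
                    dimnames = list(labels, NULL))
        src <- NULL
        for (ch in labels) {
          if (ch == src_lab) {
            src <- as.numeric(filter(ar$innovation_scale * rnorm(n),
                                     ar$alpha_coeffs, "recursive"))
            m[ch, ] <- src[-seq_len(ar$burn_in)]
          } else if (ch != tgt_lab) {
            v <- as.numeric(filter(ar$innovation_scale * rnorm(n),
                                   ar$alpha_coeffs, "recursive"))
            m[ch, ] <- v[-seq_len(ar$burn_in)]
          }
        }
        xq <- c(rep(0, ar$delta), src[seq_len(n - ar$delta)])^2
        tgt <- as.numeric(filter(ar$innovation_scale * rnorm(n) + gamma * xq,
                                 ar$alpha_coeffs, "recursive"))
        m[tgt_lab, ] <- tgt[-seq_len(ar$burn_in)]
        m
      })
    })
    times <- lapply(trials, function(m) seq_len(ncol(m)) / ar$fsample)
    raw_dataset(trials, times, labels, ar$fsample)
  }
  datasets <- c(lapply(seq_len(n_subjects), gen_dataset, condition = 1L),
                lapply(seq_len(n_subjects), gen_dataset, condition = 2L))
  design <- group_design(rbind(rep(seq_len(n_subjects), times = 2L),
                               rep(1:2, each = n_subjects)),
                         uvar = 1L, ivar = 2L)
  list(datasets = datasets, design = design)
}
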