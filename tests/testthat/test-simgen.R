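test_that("AR stability is enforced and generators are deterministic", {
  expect_error(ar_sim_config(alpha_coeffs = c(1.1, rep(0, 9))), "unstable")
  cfg <- ar_sim_config(n_trials = 3, n_samples = 400, seed = 5)
  d1 <- simulate_ar_pair(cfg)
  d2 <- simulate_ar_pair(cfg)
  expect_identical(d1$trials, d2$trials)  # bitwise
  d3 <- simulate_ar_pair(ar_sim_config(n_trials = 3, n_samples = 400,
                                       seed = 6))
  expect_false(identical(d1$trials[[1]], d3$trials[[1]]))
  # trials are distinct realizations
  expect_false(identical(d1$trials[[1]], d1$trials[[2]]))
})

test_that("uncoupled processes are uncorrelated at all lags", {
  d <- simulate_ar_pair(ar_sim_config(gamma = 0, n_trials = 1,
                                      n_samples = 5000, seed = 8))
  x <- d$trials[[1]]["X", ]; y <- d$trials[[1]]["Y", ]
  cc <- ccf(x, y, lag.max = 30, plot = FALSE)$acf
  expect_true(all(abs(cc) < 3 / sqrt(5000) + 0.02))
})

test_that("the coupling term contributes half of var(Y)", {
  cfg <- ar_sim_config()
  g <- calibrate_gamma(cfg)
  # independent decomposition oracle on a long fresh run
  set.seed(99)
  n <- 2e5; burn <- 2000
  x <- as.numeric(filter(0.1 * rnorm(n + burn), cfg$alpha_coeffs,
                         "recursive"))
  xq <- c(rep(0, cfg$delta), x[seq_len(n + burn - cfg$delta)])^2
  cpl <- as.numeric(filter(g * xq, cfg$alpha_coeffs,
                           "recursive"))[-seq_len(burn)]
  own <- as.numeric(filter(0.1 * rnorm(n + burn), cfg$alpha_coeffs,
                           "recursive"))[-seq_len(burn)]
  frac <- var(cpl) / (var(cpl) + var(own))
  expect_equal(frac, 0.5, tolerance = 0.02)
})

test_that("the lagged dependence of Y on X^2 peaks at the coupling delay", {
  d <- simulate_ar_pair(ar_sim_config(n_trials = 4, n_samples = 3000,
                                      seed = 12))
  lags <- 1:40
  score <- sapply(lags, function(l) {
    mean(sapply(1:4, function(i) {
      x <- d$trials[[i]]["X", ]; y <- d$trials[[i]]["Y", ]
      n <- length(x)
      abs(cor(y[(l + 1):n], x[1:(n - l)]^2))
    }))
  })
  expect_equal(lags[which.max(score)], 21L)
})

test_that("case B with eps = 0.5 and no sensor noise gives identical channels", {
  cfg <- mixing_config("B", epsilon_mix = 0.5,
                       sensor_noise_var_fraction = 0,
                       n_trials = 2, n_samples = 200, seed = 3)
  d <- simulate_mixing_case(cfg)
  expect_equal(d$trials[[1]]["X", ], d$trials[[1]]["Y", ],
               tolerance = 1e-12)
})

test_that("sensor noise contributes a quarter of the final variance", {
  mk <- function(frac) simulate_mixing_case(
    mixing_config("C", epsilon_mix = 0.2, sensor_noise_var_fraction = frac,
                  n_trials = 6, n_samples = 3000, seed = 14))
  noisy <- mk(0.25)
  clean <- mk(0)  # same derived seeds: identical signal component
  fracs <- unlist(lapply(1:6, function(i)
    sapply(c("X", "Y"), function(ch) {
      noise <- noisy$trials[[i]][ch, ] - clean$trials[[i]][ch, ]
      var(noise) / var(noisy$trials[[i]][ch, ])
    })))
  expect_equal(mean(fracs), 0.25, tolerance = 0.02)
})

test_that("off-grid mixing coefficients warn but run", {
  expect_warning(mixing_config("C", epsilon_mix = 0.17), "benchmark grid")
})

test_that("line-noise filtering attenuates 50 Hz by at least 20 dB", {
  base <- list(n_trials = 2, n_samples = 3000, seed = 21)
  noisy <- simulate_mixing_case(do.call(mixing_config,
                                        c(list(case = "E"), base)))
  filt <- simulate_mixing_case(do.call(mixing_config,
                                       c(list(case = "E",
                                              line_filtered = TRUE), base)))
  p50 <- function(v, fs) {
    sp <- spec.pgram(ts(v, frequency = fs), taper = 0, plot = FALSE)
    mean(sp$spec[abs(sp$freq - 50) < 0.5])
  }
  ratio <- p50(noisy$trials[[1]]["X", ], 500) /
    p50(filt$trials[[1]]["X", ], 500)
  expect_gt(10 * log10(ratio), 20)
})

test_that("group study has the documented structure and couplings", {
  ar <- ar_sim_config(n_trials = 3, n_samples = 1500)
  g <- simulate_group_study(n_subjects = 3, seed = 9, ar = ar)
  expect_length(g$datasets, 6L)
  expect_identical(g$datasets[[1]]$labels, c("F3", "F4", "T7", "T8"))
  expect_equal(dim(g$datasets[[1]]$trials[[1]]), c(4L, 1500L))
  # design matrix: subjects row then condition row
  expect_equal(g$design$design[1, ], rep(1:3, 2))
  expect_equal(g$design$design[2, ], rep(1:2, each = 3))
  # condition 1 couples F3 -> T8, condition 2 couples T7 -> F4
  lag_dep <- function(ds, src, tgt) {
    m <- ds$trials[[1]]
    n <- ncol(m)
    abs(cor(m[tgt, 22:n], m[src, 1:(n - 21)]^2))
  }
  expect_gt(lag_dep(g$datasets[[1]], "F3", "T8"), 0.2)
  expect_lt(lag_dep(g$datasets[[1]], "T7", "F4"), 0.1)
  expect_gt(lag_dep(g$datasets[[4]], "T7", "F4"), 0.2)
  expect_lt(lag_dep(g$datasets[[4]], "F3", "T8"), 0.1)
})
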