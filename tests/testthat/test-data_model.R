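make_small_dataset <- function(n_trials = 3, n_samples = 50, n_ch = 2,
                               seed = 1) {
  set.seed(seed)
  trials <- lapply(seq_len(n_trials), function(i)
    matrix(rnorm(n_ch * n_samples), nrow = n_ch))
  times <- lapply(trials, function(m) seq_len(ncol(m)) / 500)
  raw_dataset(trials, times, paste0("ch", seq_len(n_ch)), 500)
}

test_that("JSON container round-trips every numeric field exactly", {
  d <- make_small_dataset()
  path <- tempfile(fileext = ".json")
  save_dataset(d, path, "json")
  d2 <- load_dataset(path, "json")
  expect_identical(d2$labels, d$labels)
  expect_identical(d2$fsample, d$fsample)
  for (i in seq_along(d$trials)) {
    expect_identical(unname(d2$trials[[i]]), unname(d$trials[[i]]))
    expect_identical(d2$times[[i]], d$times[[i]])
  }
})

test_that("validation names the offending trial and field", {
  d <- make_small_dataset()
  bad <- d
  bad$times[[2]] <- c(bad$times[[2]], max(bad$times[[2]]) + 1 / 500)
  expect_error(validate_raw_dataset(bad), "trial 2")
  expect_error(raw_dataset(d$trials, d$times, d$labels, -1), "fsample")
  # property: deleting any single field is rejected with the field named
  for (f in c("trials", "times", "labels", "fsample")) {
    broken <- unclass(d)
    broken[[f]] <- NULL
    class(broken) <- "raw_dataset"
    expect_error(validate_raw_dataset(broken), f)
  }
})

test_that("CSV directory format is read back by an independent parser", {
  d <- make_small_dataset(n_trials = 4)
  dir <- tempfile("csvdir")
  save_dataset(d, dir, "csvdir")
  # independent check: plain read.csv, no package code
  raw <- read.csv(file.path(dir, "trial_3.csv"))
  expect_equal(unname(as.matrix(raw)), unname(t(d$trials[[3]])),
               tolerance = 1e-12)
  d2 <- load_dataset(dir, "csvdir")
  expect_equal(length(d2$trials), 4L)
  expect_equal(nrow(d2$trials[[1]]), 2L)
  expect_equal(unname(d2$trials[[2]]), unname(d$trials[[2]]),
               tolerance = 1e-12)
})

test_that("result files follow the naming contract and round-trip", {
  tab <- data.frame(source = "X", target = "Y", trial = 1:5,
                    te_nats = rnorm(5), mi_nats = rnorm(5))
  res <- te_result_set(tab, embedding_spec(2, 1, 1), list(seed = 1))
  stem <- file.path(tempdir(), "sim1")
  paths <- save_results(list(te = res, permtest = NULL), stem, "json")
  expect_true(all(file.exists(paths)))
  expect_match(paths[1], "sim1_TE_output\\.json$")
  expect_match(paths[2], "sim1_TEpermtest_output\\.json$")
  back <- load_results(paths[1])
  expect_identical(back$table$te_nats, tab$te_nats)  # bitwise
  # TSV export: one row per (pair, direction, trial)
  tsv <- save_results(list(te = res), stem, "tsv")
  expect_equal(nrow(read.delim(tsv[1])), 5L)
})

test_that("embedding_spec rejects invalid parameters", {
  expect_error(embedding_spec(0, 1, 1), "d must be")
  expect_error(embedding_spec(2, 0, 1), "tau")
  expect_error(embedding_spec(2, 1, 1, k = 0), "k must be")
  expect_error(embedding_spec(2, 1, 1, theiler = -1), "theiler")
})

test_that("config vocabulary and defaults are enforced", {
  cfg <- analysis_config()
  expect_equal(cfg$numpermutation, 190100L)
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$correctm, "FDR")
  expect_equal(cfg$surrogatetype, "trialshuffling")
  expect_equal(cfg$shifttesttype, "TE > TEshift")
  expect_equal(cfg$maxlag, 1000L)
  expect_error(analysis_config(surrogatetype = "phase"), "surrogatetype")
  expect_error(analysis_config(tail = 3), "tail")
  expect_error(analysis_config(alpha = 1.2), "alpha")
  expect_error(analysis_config(ragtausteps = 3), "ragtausteps")
  # u in milliseconds -> samples
  expect_equal(u_samples(analysis_config(predicttime_u = 21), 1000), 21L)
  expect_equal(u_samples(analysis_config(predicttime_u = 0.1), 1000), 1L)
})

test_that("config files round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  # channel names are quoted: YAML 1.1 would read bare Y as a boolean
  writeLines(c("predicttime_u: 21", "optimizemethod: cao",
               "numpermutation: 500", "sgncmb:", "- [\"X\", \"Y\"]"), path)
  cfg <- read_config(path)
  expect_equal(cfg$predicttime_u, 21)
  expect_equal(cfg$numpermutation, 500L)
  expect_equal(cfg$sgncmb[1, ], c("X", "Y"))
  writeLines("nonsense_field: 3", path)
  expect_error(read_config(path), "unknown config field")
})
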