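test_that("exhaustive permutation distributions match enumeration", {
  # {3,4} vs {1,2}, mean statistic: 2 of the 6 splits are as extreme
  res <- permutation_test(c(3, 4), c(1, 2), "mean", tail = 2,
                          numpermutation = 100)
  expect_true(res$exhaustive)
  expect_equal(res$p, 2 / 6)
  # random small groups, both statistics, against the enumeration oracle
  set.seed(41)
  for (rep in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    for (st in c("mean", "indepsamplesT")) {
      stat <- if (st == "mean") function(x, y) mean(x) - mean(y)
      else function(x, y) {
        sp <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
          (length(x) + length(y) - 2)
        (mean(x) - mean(y)) / sqrt(sp * (1 / length(x) + 1 / length(y)))
      }
      res <- permutation_test(a, b, st, tail = 2, numpermutation = 1e5)
      expect_true(res$exhaustive)
      expect_equal(res$p, enumerate_perm_p(a, b, stat, 2))
    }
  }
})

test_that("identical groups are maximally exchangeable (p = 1)", {
  a <- c(1.2, 3.4, 2.2)
  expect_equal(permutation_test(a, a, "mean", tail = 2,
                                numpermutation = 50)$p, 1)
})

test_that("p-values are invariant to common affine rescaling", {
  set.seed(42)
  a <- rnorm(5); b <- rnorm(5) + 1
  for (st in c("mean", "indepsamplesT", "depsamplesT")) {
    p1 <- permutation_test(a, b, st, tail = 2, numpermutation = 1e5)$p
    p2 <- permutation_test(10 * a + 3, 10 * b + 3, st, tail = 2,
                           numpermutation = 1e5)$p
    expect_equal(p1, p2)
  }
})

test_that("Monte-Carlo p has floor 1/(numpermutation+1) and is seeded", {
  a <- rnorm(20) + 50; b <- rnorm(20)  # total separation
  res <- permutation_test(a, b, "indepsamplesT", tail = 1,
                          numpermutation = 999, seed = 5)
  expect_false(res$exhaustive)
  expect_equal(res$p, 1 / 1000)
  res2 <- permutation_test(a, b, "indepsamplesT", tail = 1,
                           numpermutation = 999, seed = 5)
  expect_identical(res$p, res2$p)
})

test_that("null p-values are uniform at the nominal rate", {
  set.seed(43)
  ps <- replicate(400, {
    permutation_test(rnorm(20), rnorm(20), "mean", tail = 2,
                     numpermutation = 99,
                     seed = sample.int(1e6, 1))$p
  })
  frac <- mean(ps < 0.05)
  ci <- qbinom(c(0.025, 0.975), 400, 0.05) / 400
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("degenerate statistics are named in errors", {
  expect_error(permutation_test(rep(1, 5), rep(2, 5), "indepsamplesT",
                                numpermutation = 10),
               "zero variance.*indepsamplesT")
  expect_error(permutation_test(rep(1, 5), rep(0, 5), "depsamplesT",
                                numpermutation = 10),
               "depsamplesT")
})

test_that("multiple-comparison corrections match hand oracles", {
  # BH step-up: sorted p_i <= (i/4) * 0.05 holds for all i
  expect_equal(correct_multiple(c(0.01, 0.02, 0.03, 0.04), "FDR", 0.05),
               rep(TRUE, 4))
  expect_equal(correct_multiple(c(0.01, 0.2), "BONF", 0.05),
               c(TRUE, FALSE))
  expect_equal(correct_multiple(0.04, "FDR", 0.05), TRUE)
  expect_equal(correct_multiple(0.04, "BONF", 0.05), TRUE)
  expect_identical(correct_multiple(numeric(0), "FDR"), logical(0))
  expect_error(correct_multiple(c(0.5, 1.3), "FDR"), "\\[0, 1\\]")
})

test_that("shift test detects shared signal and respects delayed coupling", {
  set.seed(44)
  n <- 500; ntr <- 12
  spec <- embedding_spec(1, 1, 1, 4, 1)
  # common source on both sensors: the shifted source predicts its own
  # reappearance, so TEshift > TE and mixing is flagged
  mk_common <- function() {
    z <- rnorm(n)
    list(x = 0.5 * z + 0.3 * rnorm(n), y = 0.5 * z + 0.3 * rnorm(n))
  }
  tr <- replicate(ntr, mk_common(), simplify = FALSE)
  res <- shift_test(lapply(tr, `[[`, "x"), lapply(tr, `[[`, "y"), spec,
                    "onesample", "TEshift > TE", numpermutation = 500,
                    seed = 1)
  expect_true(res$mixing_detected)
  # genuinely lagged coupling: original TE wins, no mixing under either rule
  mk_lag <- function() {
    x <- rnorm(n + 1)
    list(x = x[-1], y = 0.9 * head(x, n) + 0.3 * rnorm(n))
  }
  tr2 <- replicate(ntr, mk_lag(), simplify = FALSE)
  res2 <- shift_test(lapply(tr2, `[[`, "x"), lapply(tr2, `[[`, "y"), spec,
                     "predicttime", "TE > TEshift", numpermutation = 500,
                     seed = 2)
  expect_false(res2$mixing_detected)
  res3 <- shift_test(lapply(tr2, `[[`, "x"), lapply(tr2, `[[`, "y"), spec,
                     "predicttime", "TEshift > TE", numpermutation = 500,
                     seed = 3)
  expect_false(res3$mixing_detected)
})
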