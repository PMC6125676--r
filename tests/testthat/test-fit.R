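afp <- published_emission_parameters("Afp")

test_that("the fitter recovers known efficiencies from simulated counts", {
  sch <- division_schedule()
  truth <- c(mu = 0.8, delta = 0.1, eta = 0.05)
  cnt <- simulate_model_counts(5000, truth, test_init(), sch, afp,
                               seed = 71)
  fit <- fit_dyad_model(cnt, sch, afp, efficiency_mode = "constant",
                        n_starts = 6, seed = 72)
  est <- unlist(fit$efficiencies[1, c("mu", "delta", "eta")])
  expect_true(all(abs(est - truth) <= 0.05))
  expect_true(is.finite(fit$log_likelihood))
  expect_equal(sum(fit$init), 1, tolerance = 1e-9)
  ## fitted distributions stay on the simplex at every time
  expect_true(all(abs(rowSums(fit$distributions) - 1) < 1e-9))
})

test_that("interval-wise fits expose one efficiency row per interval", {
  sch <- division_schedule()
  cnt <- simulate_model_counts(2000, c(0.8, 0.1, 0.05), test_init(),
                               sch, afp, seed = 81)
  fit <- fit_dyad_model(cnt, sch, afp, efficiency_mode = "interval",
                        n_starts = 4, seed = 82)
  expect_equal(nrow(fit$efficiencies), 3L)   # 4 time points, 3 intervals
  expect_identical(fit$efficiencies$interval,
                   c("t0-t1", "t1-t3", "t3-t6"))
  expect_true(all(fit$efficiencies$mu >= 0 & fit$efficiencies$mu <= 1))
})

test_that("a single observation time fits the initial distribution only", {
  sch1 <- division_schedule(0, 0)
  cnt <- simulate_model_counts(4000, c(0, 0, 0), test_init(), sch1, afp,
                               seed = 91)
  fit <- fit_dyad_model(cnt, sch1, afp, n_starts = 4, seed = 92)
  expect_null(fit$efficiencies)
  expect_equal(sum(fit$init), 1, tolerance = 1e-9)
  expect_error(fit_dyad_model(cnt, sch1, afp,
                              efficiency_mode = "constant"),
               ">= 2 times")
})

test_that("bootstrap intervals bracket the point estimate", {
  sch <- division_schedule(c(0, 1, 3), c(0, 2, 6))
  cnt <- simulate_model_counts(3000, c(0.8, 0.1, 0.05), test_init(),
                               sch, afp, seed = 95)
  fit <- fit_dyad_model(cnt, sch, afp, efficiency_mode = "constant",
                        n_starts = 4, seed = 96, n_boot = 12)
  expect_false(is.null(fit$bootstrap))
  expect_true(all(fit$bootstrap$lower <= fit$bootstrap$upper))
  est <- as.numeric(fit$efficiencies[1, c("mu", "delta", "eta")])
  ## percentile intervals of a well-behaved fit contain the MLE
  expect_true(all(fit$bootstrap$lower[1, ] <= est + 0.02))
  expect_true(all(fit$bootstrap$upper[1, ] >= est - 0.02))
})

test_that("bootstrap intervals cover the true efficiencies", {
  ## scaled-down coverage check of the 90% percentile intervals: pooled
  ## over replicates and the three efficiencies, coverage stays >= 80%
  sch <- division_schedule()
  truth <- c(mu = 0.8, delta = 0.1, eta = 0.05)
  n_rep <- 8
  covered <- 0L; total <- 0L
  for (r in seq_len(n_rep)) {
    cnt <- simulate_model_counts(5000, truth, test_init(), sch, afp,
                                 seed = 1200 + r)
    fit <- fit_dyad_model(cnt, sch, afp, efficiency_mode = "constant",
                          n_starts = 4, seed = 1300 + r, n_boot = 20)
    for (k in c("mu", "delta", "eta")) {
      total <- total + 1L
      if (fit$bootstrap$lower[1, k] <= truth[[k]] &&
            truth[[k]] <= fit$bootstrap$upper[1, k])
        covered <- covered + 1L
    }
  }
  expect_gte(covered / total, 0.8)
})

test_that("hydroxylation summaries aggregate pairing classes", {
  hh_only <- stats::setNames(c(0, 0, 0, 0, 0, 0, 0, 0, 1), dyad_states())
  s <- hydroxylation_summary(hh_only)
  expect_equal(unname(s["h_with_h"]), 1)
  expect_equal(unname(s["total_5hmC"]), 1)
  unif <- stats::setNames(rep(1 / 9, 9), dyad_states())
  s2 <- hydroxylation_summary(unif)
  expect_equal(unname(s2[c("h_with_u", "h_with_m", "h_with_h")]),
               c(2 / 9, 2 / 9, 1 / 9))
  ## class sums equal the probability of any-h states
  set.seed(33)
  for (i in 1:10) {
    d <- runif(9); d <- stats::setNames(d / sum(d), dyad_states())
    s3 <- hydroxylation_summary(d)
    any_h <- sum(d[grepl("h", names(d))])
    expect_equal(unname(s3[["h_with_u"]] + s3[["h_with_m"]] +
                          s3[["h_with_h"]]), any_h, tolerance = 1e-12)
  }
})

test_that("naive subtraction behaves as documented", {
  bs <- c(both = 0.5, hemi_top = 0.1, hemi_bottom = 0.1, unmod = 0.3)
  ox <- c(both = 0.4, hemi_top = 0.05, hemi_bottom = 0.05, unmod = 0.5)
  est <- naive_5hmC(bs, ox)
  expect_equal(unname(est["total_5hmC"]), 0.6 - 0.45)
  expect_equal(unname(est["both"]), 0.1)
  expect_equal(unname(naive_5hmC(bs, bs)), rep(0, 4))
  ## negative estimates warn, are not clipped
  expect_warning(neg <- naive_5hmC(ox, bs), "negative")
  expect_lt(neg[["total_5hmC"]], 0)
})

test_that("with ideal chemistry the model matches the naive estimate", {
  ## one time point, no conversion error: the ML initial distribution
  ## reproduces the observed class frequencies, so its 5hmC strand level
  ## equals the BS - oxBS subtraction
  sch1 <- division_schedule(0, 0)
  em <- ideal_chemistry()
  init <- c(uu = 0.15, um = 0.05, mu = 0.05, mm = 0.45, uh = 0.05,
            hu = 0.05, mh = 0.08, hm = 0.08, hh = 0.04)
  cnt <- simulate_model_counts(20000, c(0, 0, 0), init, sch1, em,
                               seed = 55)
  fit <- fit_dyad_model(cnt, sch1, em, n_starts = 6, seed = 56)
  model_total <- hydroxylation_summary(fit, 0)[["total_5hmC"]]
  freq <- function(tr) {
    r <- cnt[cnt$treatment == tr, read_classes()]
    v <- colSums(r) / sum(r)
    c(both = v[["CC"]], hemi_top = v[["CT"]], hemi_bottom = v[["TC"]],
      unmod = v[["TT"]])
  }
  naive <- suppressWarnings(naive_5hmC(freq("BS"),
                                       freq("oxBS")))[["total_5hmC"]]
  expect_equal(model_total, naive, tolerance = 5e-3)
  ## and both sit near the simulated truth
  truth <- sum(init[c("uh", "hu", "mh", "hm")]) / 2 + init[["hh"]]
  expect_equal(model_total, unname(truth), tolerance = 0.02)
})
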