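test_that("division_step reproduces hand-computable limits", {
  mm <- state_distribution(c(uu = 0, um = 0, mu = 0, mm = 1, uh = 0,
                             hu = 0, mh = 0, hm = 0, hh = 0))
  ## perfect maintenance keeps a fully methylated dyad fully methylated
  d <- division_step(mm, enzyme_efficiencies(1, 0, 0))
  expect_equal(unname(d[["mm"]]), 1)
  ## no maintenance: one division leaves one hemimethylated strand,
  ## uniformly on either side
  d <- division_step(mm, enzyme_efficiencies(0, 0, 0))
  expect_equal(unname(d[c("um", "mu")]), c(0.5, 0.5))
  expect_equal(sum(d), 1)
})

test_that("passive dilution halves methylated-strand content per division", {
  strand_m_frac <- function(dist) {
    tops <- substr(names(dist), 1, 1)
    bots <- substr(names(dist), 2, 2)
    sum(dist * ((tops == "m") + (bots == "m")) / 2)
  }
  dist <- state_distribution(c(uu = 0, um = 0, mu = 0, mm = 1, uh = 0,
                               hu = 0, mh = 0, hm = 0, hh = 0))
  for (k in 1:5) {
    dist <- division_step(dist, enzyme_efficiencies(0, 0, 0))
    expect_equal(strand_m_frac(dist), 2^-k, tolerance = 1e-12)
  }
})

test_that("division_step matches exhaustive event enumeration", {
  ## all 9 starting states, several efficiency settings, up to 3 divisions
  set.seed(41)
  settings <- rbind(c(0.8, 0.1, 0.05), c(0, 0, 0), c(1, 1, 1),
                    matrix(runif(9), ncol = 3))
  for (r in seq_len(nrow(settings))) {
    e <- settings[r, ]
    oracle <- oracle_division_matrix(e[1], e[2], e[3])
    expect_equal(max(abs(division_matrix(e[1], e[2], e[3]) - oracle)), 0,
                 tolerance = 1e-12)
    okk <- diag(9); dimnames(okk) <- dimnames(oracle)
    for (k in 1:3) {
      okk <- okk %*% oracle
      for (s in dyad_states()) {
        start <- stats::setNames(as.numeric(s == dyad_states()),
                                 dyad_states())
        dist <- start
        for (i in seq_len(k))
          dist <- division_step(dist, enzyme_efficiencies(e[1], e[2], e[3]))
        expect_equal(max(abs(dist - okk[s, ])), 0, tolerance = 1e-12)
      }
    }
  }
})

test_that("transition and emission matrices are row-stochastic", {
  set.seed(7)
  for (i in 1:20) {
    e <- runif(3)
    expect_true(all(abs(rowSums(division_matrix(e[1], e[2], e[3])) - 1)
                    < 1e-9))
    em <- emission_parameters(runif(3), runif(3))
    expect_true(all(abs(rowSums(emission_matrix(em, "BS")) - 1) < 1e-9))
    expect_true(all(abs(rowSums(emission_matrix(em, "oxBS")) - 1) < 1e-9))
    d <- runif(9); d <- d / sum(d)
    out <- division_step(stats::setNames(d, dyad_states()),
                         enzyme_efficiencies(e[1], e[2], e[3]))
    expect_true(all(out >= 0))
    expect_equal(sum(out), 1, tolerance = 1e-9)
  }
})

test_that("extreme efficiencies drive the chain to the expected corners", {
  strand_frac <- function(dist, letter) {
    sum(dist * ((substr(names(dist), 1, 1) == letter) +
                  (substr(names(dist), 2, 2) == letter)) / 2)
  }
  ## mu = 1, delta = 0, eta = 0 preserves methylated-strand content
  set.seed(9)
  for (i in 1:5) {
    d0 <- runif(9); d0 <- stats::setNames(d0 / sum(d0), dyad_states())
    ## restrict to u/m states so content is purely 5mC
    d0[c("uh", "hu", "mh", "hm", "hh")] <- 0
    d0 <- d0 / sum(d0)
    before <- strand_frac(d0, "m")
    after <- division_step(d0, enzyme_efficiencies(1, 0, 0))
    expect_equal(strand_frac(after, "m"), before, tolerance = 1e-12)
  }
  ## delta = 1 (eta = 0) saturates u/m starting states to mm in one step
  d0 <- stats::setNames(c(1, 0, 0, 0, 0, 0, 0, 0, 0), dyad_states())
  d1 <- division_step(d0, enzyme_efficiencies(0, 1, 0))
  expect_equal(unname(d1[["mm"]]), 1)
  ## with eta = 1 as well, everything is hh within two divisions
  d <- stats::setNames(rep(1 / 9, 9), dyad_states())
  for (i in 1:2) d <- division_step(d, enzyme_efficiencies(1, 1, 1))
  expect_equal(unname(d[["hh"]]), 1, tolerance = 1e-12)
})

test_that("emission matrix matches per-strand product and enumeration", {
  ## ideal chemistry corner cases
  E_bs <- emission_matrix(ideal_chemistry(), "BS")
  expect_equal(unname(E_bs["mu", "CT"]), 1)   # 5mC top reads C, u bottom T
  E_ox <- emission_matrix(ideal_chemistry(), "oxBS")
  expect_equal(unname(E_ox["hu", "TT"]), 1)   # oxidised 5hmC reads T
  ## measured chemistry vs exhaustive enumeration of conversion outcomes
  em <- published_emission_parameters("Afp")
  for (tr in c("BS", "oxBS")) {
    p <- em[[tr]]
    oracle <- oracle_emission_matrix(c(u = p[["p_T_C"]], m = p[["p_T_5mC"]],
                                       h = p[["p_T_5hmC"]]))
    expect_equal(max(abs(emission_matrix(em, tr) - oracle)), 0,
                 tolerance = 1e-12)
  }
})

test_that("log-likelihood is exact on certain data and additive", {
  sch1 <- division_schedule(0, 0)
  em <- ideal_chemistry()
  mm <- c(uu = 0, um = 0, mu = 0, mm = 1, uh = 0, hu = 0, mh = 0,
          hm = 0, hh = 0)
  counts <- data.frame(time = 0, treatment = "BS", CC = 50, CT = 0,
                       TC = 0, TT = 0)
  expect_equal(log_likelihood(c(0.5, 0.5, 0.5), mm, sch1, em, counts), 0)
  ## impossible observation under the model
  bad <- data.frame(time = 0, treatment = "BS", CC = 49, CT = 1,
                    TC = 0, TT = 0)
  expect_equal(log_likelihood(c(0.5, 0.5, 0.5), mm, sch1, em, bad), -Inf)
  ## BS + oxBS jointly = sum of the separate treatment likelihoods
  sch <- division_schedule(c(0, 1), c(0, 2))
  em2 <- published_emission_parameters("Afp")
  cnt <- simulate_model_counts(200, c(0.7, 0.1, 0.1), test_init(),
                               sch, em2, seed = 5)
  eff <- c(0.6, 0.2, 0.1)
  ll_joint <- log_likelihood(eff, test_init(), sch, em2, cnt)
  ll_bs <- log_likelihood(eff, test_init(), sch, em2,
                          cnt[cnt$treatment == "BS", ])
  ll_ox <- log_likelihood(eff, test_init(), sch, em2,
                          cnt[cnt$treatment == "oxBS", ])
  expect_equal(ll_joint, ll_bs + ll_ox, tolerance = 1e-10)
})

test_that("log-likelihood equals exhaustive hidden-path enumeration", {
  ## small instance: 2 time points, 20 molecules, Afp chemistry
  sch <- division_schedule(c(0, 1), c(0, 2))
  em <- published_emission_parameters("Afp")
  eff <- c(mu = 0.7, delta = 0.15, eta = 0.1)
  init <- test_init()
  cnt <- simulate_model_counts(20, eff, init, sch, em, seed = 8)
  ## oracle: marginal class probabilities from enumerated transitions
  M <- oracle_division_matrix(eff[["mu"]], eff[["delta"]], eff[["eta"]])
  dist_t <- list(init, drop(init %*% (M %*% M)))
  ll_oracle <- 0
  for (i in seq_len(nrow(cnt))) {
    ti <- match(cnt$time[i], sch$times)
    p <- em[[cnt$treatment[i]]]
    E <- oracle_emission_matrix(c(u = p[["p_T_C"]], m = p[["p_T_5mC"]],
                                  h = p[["p_T_5hmC"]]))
    probs <- drop(dist_t[[ti]] %*% E)
    ll_oracle <- ll_oracle +
      stats::dmultinom(unlist(cnt[i, read_classes()]), prob = probs,
                       log = TRUE)
  }
  expect_equal(log_likelihood(eff, init, sch, em, cnt), ll_oracle,
               tolerance = 1e-10)
})

test_that("division schedules are validated", {
  expect_error(division_schedule(c(0, 1), c(2, 0)), "nondecreasing")
  expect_error(division_schedule(c(0, 1), c(0, 1.5)), "integers")
  expect_error(division_schedule(c(1, 0), c(0, 2)), "nondecreasing")
  s <- division_schedule()
  expect_equal(s$times, c(0, 1, 3, 6))
  expect_equal(s$divisions, c(0L, 2L, 6L, 12L))
})
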