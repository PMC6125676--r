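## Maximum-likelihood fitting of the dyad chain to BS + oxBS read-class
## counts. The initial distribution is reparameterised through a softmax
## (8 free parameters, last state as reference) and the efficiencies
## through logits, giving an unconstrained search space.

.softmax9 <- function(z) {
  w <- exp(c(z, 0) - max(z, 0))
  stats::setNames(w / sum(w), dyad_states())
}

.theta_unpack <- function(theta, n_eff_rows) {
  eff <- matrix(stats::plogis(theta[seq_len(3 * n_eff_rows)]),
                nrow = n_eff_rows, ncol = 3,
                dimnames = list(NULL, c("mu", "delta", "eta")))
  init <- .softmax9(theta[3 * n_eff_rows + seq_len(8)])
  list(eff = eff, init = init)
}

#' Fit the dyad hidden Markov model to read-class counts
#'
#' Maximises the joint BS + oxBS [log_likelihood()] over the enzyme
#' efficiencies and the initial nine-state distribution, using seeded
#' multi-start quasi-Newton optimisation on an unconstrained
#' reparameterisation (logit efficiencies, softmax initial distribution).
#' Efficiencies are either piecewise constant per inter-observation
#' interval (`"interval"`, the default with >= 2 observation times) or
#' shared across intervals (`"constant"`).  With a single observation
#' time only the initial distribution is estimated.
#'
#' @param counts Data frame of aggregated read-class counts (columns
#'   `time`, `treatment`, `CC`, `CT`, `TC`, `TT`).
#' @param schedule A [division_schedule()].
#' @param emissions An [emission_parameters()] object (measured linker
#'   control rates plugged in as known constants).
#' @param efficiency_mode `"interval"` or `"constant"`.
#' @param n_starts Number of seeded optimisation starts (first start is a
#'   moment-based guess, the rest random).
#' @param seed Integer seed for the starts (and bootstrap).
#' @param n_boot Parametric bootstrap replicates for percentile intervals
#'   (0 = none).
#' @param boot_level Confidence level of bootstrap intervals.
#' @return List of class `dyad_fit`: `efficiencies` (data frame per
#'   interval; `NULL` for a single time), `init` (initial distribution),
#'   `distributions` (per-time fitted distributions), `log_likelihood`,
#'   `convergence` (per-start optim codes and objective values),
#'   `boundary_flags`, `bootstrap` (quantile intervals or `NULL`),
#'   `schedule`, `emissions`, `counts`, `efficiency_mode`, `seed`.
#' @export
fit_dyad_model <- function(counts, schedule, emissions,
                           efficiency_mode = c("interval", "constant"),
                           n_starts = 20, seed = 1, n_boot = 0,
                           boot_level = 0.9) {
  efficiency_mode <- match.arg(efficiency_mode)
  stopifnot(all(c("time", "treatment", read_classes()) %in% names(counts)))
  times <- sort(unique(counts$time))
  if (!all(times %in% schedule$times))
    stop("count times not covered by the schedule")
  n_t <- length(schedule$times)
  n_intervals <- max(n_t - 1L, 0L)
  if (n_t == 1L && efficiency_mode == "interval") n_eff_rows <- 0L
  else if (n_t == 1L)
    stop("a single observation time identifies only the initial ",
         "distribution; efficiencies need >= 2 times")
  else n_eff_rows <- if (efficiency_mode == "constant") 1L else n_intervals

  expand_eff <- function(eff) {
    if (n_eff_rows == 0L) matrix(0, max(n_intervals, 1L), 3,
                                 dimnames = list(NULL, c("mu", "delta", "eta")))
    else if (efficiency_mode == "constant")
      .efficiency_matrix(drop(eff), max(n_intervals, 1L))
    else eff
  }
  negll <- function(theta) {
    pars <- .theta_unpack(theta, n_eff_rows)
    ll <- log_likelihood(expand_eff(pars$eff), pars$init, schedule,
                         emissions, counts)
    if (!is.finite(ll)) 1e12 else -ll
  }

  ## moment-based first start: map time-0 BS classes onto u/m states
  moment_start <- function() {
    r0 <- counts[counts$time == times[1] & counts$treatment == "BS", ,
                 drop = FALSE]
    p <- if (nrow(r0)) unlist(r0[1, read_classes()]) + 1 else rep(1, 4)
    p <- p / sum(p)
    init <- stats::setNames(rep(0.005, 9), dyad_states())
    init["mm"] <- init["mm"] + p[["CC"]]
    init["mu"] <- init["mu"] + p[["CT"]]
    init["um"] <- init["um"] + p[["TC"]]
    init["uu"] <- init["uu"] + p[["TT"]]
    init <- init / sum(init)
    c(stats::qlogis(rep(0.5, 3 * n_eff_rows)),
      log(init[1:8]) - log(init[9]))
  }
  ## 5hmC-aware second start: per-strand u/m/h marginals from the BS
  ## minus oxBS read-C difference at the first time, combined as
  ## independent strands; low hydroxylation prior typical of real data
  naive_start <- function() {
    grab <- function(tr) {
      r <- counts[counts$time == times[1] & counts$treatment == tr, ,
                  drop = FALSE]
      if (!nrow(r)) return(NULL)
      v <- colSums(r[read_classes()]); v / sum(v)
    }
    b <- grab("BS"); o <- grab("oxBS")
    if (is.null(b) || is.null(o)) return(NULL)
    strand <- function(read_c_bs, read_c_ox) {
      h <- min(max(read_c_bs - read_c_ox, 0.01), 0.9)
      m <- min(max(read_c_ox, 0.01), 0.95 - h)
      c(u = 1 - m - h, m = m, h = h)
    }
    top <- strand(b[["CC"]] + b[["CT"]], o[["CC"]] + o[["CT"]])
    bot <- strand(b[["CC"]] + b[["TC"]], o[["CC"]] + o[["TC"]])
    init <- stats::setNames(numeric(9), dyad_states())
    for (s in dyad_states())
      init[s] <- top[[substr(s, 1, 1)]] * bot[[substr(s, 2, 2)]]
    init <- (init + 0.002) / sum(init + 0.002)
    c(stats::qlogis(rep(c(0.5, 0.2, 0.1), each = n_eff_rows)),
      log(init[1:8]) - log(init[9]))
  }
  n_par <- 3 * n_eff_rows + 8
  set.seed(seed)
  guided <- Filter(Negate(is.null), list(moment_start(), naive_start()))
  starts <- c(guided,
              lapply(seq_len(max(n_starts - length(guided), 0L)),
                     function(i)
                c(stats::qlogis(stats::runif(3 * n_eff_rows, 0.05, 0.95)),
                  stats::rnorm(8, 0, 1.5))))
  runs <- lapply(starts, function(th0) {
    tryCatch(stats::optim(th0, negll, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-8)),
             error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("no optimisation start converged; check counts")
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]
  pars <- .theta_unpack(best$par, n_eff_rows)
  eff_full <- expand_eff(pars$eff)
  dists <- propagate_distribution(pars$init, schedule,
                                  if (n_intervals > 0) eff_full else
                                    c(mu = 0, delta = 0, eta = 0))
  rownames(dists) <- paste0("t", schedule$times)
  eff_df <- if (n_eff_rows > 0) {
    data.frame(interval = paste0("t", schedule$times[-n_t], "-t",
                                 schedule$times[-1]),
               eff_full, row.names = NULL)
  }
  boundary <- if (n_eff_rows > 0) {
    v <- as.vector(eff_full)
    any(v < 1e-3 | v > 1 - 1e-3)
  } else FALSE

  boot <- NULL
  if (n_boot > 0 && n_eff_rows > 0) {
    E <- list(BS = emission_matrix(emissions, "BS"),
              oxBS = emission_matrix(emissions, "oxBS"))
    boot_eff <- array(NA_real_, dim = c(n_boot, n_eff_rows, 3))
    for (b in seq_len(n_boot)) {
      cb <- counts
      for (i in seq_len(nrow(counts))) {
        ti <- match(counts$time[i], schedule$times)
        probs <- drop(dists[ti, ] %*% E[[counts$treatment[i]]])
        n_i <- sum(unlist(counts[i, read_classes()]))
        cb[i, read_classes()] <-
          as.list(as.integer(stats::rmultinom(1, n_i, probs)))
      }
      negll_b <- function(theta) {
        p <- .theta_unpack(theta, n_eff_rows)
        ll <- log_likelihood(expand_eff(p$eff), p$init, schedule,
                             emissions, cb)
        if (!is.finite(ll)) 1e12 else -ll
      }
      rb <- tryCatch(stats::optim(best$par, negll_b, method = "BFGS",
                                  control = list(maxit = 300,
                                                 reltol = 1e-9)),
                     error = function(e) NULL)
      if (!is.null(rb))
        boot_eff[b, , ] <- .theta_unpack(rb$par, n_eff_rows)$eff
    }
    a <- (1 - boot_level) / 2
    boot <- list(
      level = boot_level,
      lower = apply(boot_eff, c(2, 3), stats::quantile, probs = a,
                    na.rm = TRUE),
      upper = apply(boot_eff, c(2, 3), stats::quantile, probs = 1 - a,
                    na.rm = TRUE))
    dimnames(boot$lower) <- dimnames(boot$upper) <-
      list(NULL, c("mu", "delta", "eta"))
  }

  structure(list(
    efficiencies = eff_df, init = pars$init, distributions = dists,
    log_likelihood = -best$value,
    convergence = data.frame(start = seq_along(runs),
                             value = -values,
                             code = vapply(runs, `[[`, integer(1),
                                           "convergence")),
    boundary_flags = boundary, bootstrap = boot,
    schedule = schedule, emissions = emissions, counts = counts,
    efficiency_mode = efficiency_mode, seed = seed),
    class = "dyad_fit")
}

#' @export
print.dyad_fit <- function(x, ...) {
  cat("Dyad model fit (", x$efficiency_mode, " efficiencies), log-likelihood ",
      format(x$log_likelihood, digits = 8), "\n", sep = "")
  if (!is.null(x$efficiencies)) print(x$efficiencies, digits = 3)
  cat("initial distribution:\n")
  print(round(x$init, 4))
  if (isTRUE(x$boundary_flags))
    cat("note: efficiency estimate(s) pinned at the [0, 1] boundary\n")
  invisible(x)
}

#' 5hmC dyad-class summary at one observation time
#'
#' Aggregates the fitted state distribution at a time point into the three
#' 5hmC pairing classes: h paired with unmodified C (`h_with_u` = uh+hu),
#' h paired with 5mC (`h_with_m` = mh+hm), and symmetric h (`h_with_h` =
#' hh), plus strand-resolved totals.  `total_5hmC` is the mean fraction of
#' strands carrying 5hmC.
#'
#' @param fit A `dyad_fit` (or a bare state distribution).
#' @param time Observation time (must be in the fit's schedule); ignored
#'   when `fit` is a distribution.
#' @return Named numeric vector with elements `h_with_u`, `h_with_m`,
#'   `h_with_h`, `top_5hmC`, `bottom_5hmC`, `total_5hmC`.
#' @export
hydroxylation_summary <- function(fit, time = NULL) {
  d <- if (inherits(fit, "dyad_fit")) {
    ti <- if (is.null(time)) 1L else match(time, fit$schedule$times)
    if (is.na(ti)) stop("time not in the fitted schedule")
    fit$distributions[ti, ]
  } else state_distribution(fit)
  top_h <- d[["hu"]] + d[["hm"]] + d[["hh"]]
  bot_h <- d[["uh"]] + d[["mh"]] + d[["hh"]]
  c(h_with_u = d[["uh"]] + d[["hu"]],
    h_with_m = d[["mh"]] + d[["hm"]],
    h_with_h = d[["hh"]],
    top_5hmC = top_h, bottom_5hmC = bot_h,
    total_5hmC = (top_h + bot_h) / 2)
}

#' Naive subtraction estimate of 5hmC
#'
#' The baseline estimator: subtract the oxBS mean modification level from
#' the BS level (total), and likewise per dyad class (`both`, `hemi_top`,
#' `hemi_bottom`).  Sampling noise and conversion errors can push
#' estimates negative; they are reported as-is with a warning, never
#' clipped silently.  Unlike the model-based estimate this ignores
#' conversion errors, which biases it (the 5mC false conversion deflates
#' both treatments, the incomplete 5hmC conversion under oxBS inflates the
#' apparent oxBS level).
#'
#' @param bs_summary,oxbs_summary `pattern_summary` objects (or named
#'   vectors of mean class frequencies `both`, `hemi_top`, `hemi_bottom`,
#'   `unmod`) of the same amplicon and time.
#' @return Named numeric vector: `total_5hmC`, `both`, `hemi_top`,
#'   `hemi_bottom`.
#' @export
naive_5hmC <- function(bs_summary, oxbs_summary) {
  grab <- function(s) {
    if (inherits(s, "pattern_summary")) {
      list(mean = s$mean, level = s$level, n = nrow(s$per_dyad))
    } else {
      lvl <- unname(s["both"] + 0.5 * (s["hemi_top"] + s["hemi_bottom"]))
      list(mean = s, level = lvl, n = NA_integer_)
    }
  }
  bs <- grab(bs_summary); ox <- grab(oxbs_summary)
  if (!is.na(bs$n) && !is.na(ox$n) && bs$n != ox$n)
    stop("BS and oxBS summaries cover different dyad sets")
  out <- c(total_5hmC = bs$level - ox$level,
           both = unname(bs$mean["both"] - ox$mean["both"]),
           hemi_top = unname(bs$mean["hemi_top"] - ox$mean["hemi_top"]),
           hemi_bottom = unname(bs$mean["hemi_bottom"] -
                                  ox$mean["hemi_bottom"]))
  if (any(out < 0))
    warning("negative naive 5hmC estimate(s) (sampling noise or ",
            "conversion error); reported unclipped")
  out
}
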