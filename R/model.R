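## Nine-state dyad chain: hidden state of one CpG dyad is a pair
## (top strand, bottom strand) over {u, m, h} = unmodified C, 5mC, 5hmC.
## State labels put the top strand first; the enumeration order below is
## fixed and used for every vector/matrix in the package.

#' Hidden dyad states and observed read classes
#'
#' `dyad_states()` returns the fixed enumeration of the nine hidden CpG dyad
#' states, each a pair of per-strand modifications over u (unmodified C),
#' m (5mC) and h (5hmC); the first letter is the top (Watson) strand.
#' `read_classes()` returns the four observable read classes after
#' conversion chemistry, first letter = top-strand read base at the dyad.
#'
#' @return Character vector of state or class labels.
#' @export
dyad_states <- function() {
  c("uu", "um", "mu", "mm", "uh", "hu", "mh", "hm", "hh")
}

#' @rdname dyad_states
#' @export
read_classes <- function() {
  c("CC", "CT", "TC", "TT")
}

## Internal constants of the state enumeration (computed once).
.STATES <- c("uu", "um", "mu", "mm", "uh", "hu", "mh", "hm", "hh")
.TOPS <- substr(.STATES, 1, 1)
.BOTS <- substr(.STATES, 2, 2)
## position of each state in an outer(top, bottom) vectorisation
## (top index fast, column-major)
.PAIR_IDX <- match(.STATES, as.vector(outer(c("u", "m", "h"), c("u", "m", "h"),
                                            paste0)))

#' Validate a distribution over the nine dyad states
#'
#' @param p Numeric vector of length 9, named or in [dyad_states()] order.
#' @param tol Tolerance for the sum-to-one check.
#' @return The distribution as a named vector in canonical state order.
#' @export
state_distribution <- function(p, tol = 1e-9) {
  states <- dyad_states()
  if (!is.null(names(p))) {
    if (!setequal(names(p), states))
      stop("state distribution must be named by the nine dyad states")
    p <- p[states]
  }
  if (length(p) != 9L) stop("state distribution must have length 9")
  if (any(p < -tol)) stop("state distribution has negative entries")
  if (abs(sum(p) - 1) > tol) stop("state distribution does not sum to 1")
  stats::setNames(pmax(as.numeric(p), 0), states)
}

#' Enzyme efficiency parameters
#'
#' Bundles the three per-division event probabilities of the dyad chain:
#' `mu`, maintenance methylation of the newly synthesised strand opposite a
#' 5mC template; `delta`, de novo methylation of any strand that is still
#' unmodified (applied independently per strand); `eta`, hydroxylation of a
#' 5mC strand to 5hmC by Tet enzymes.
#'
#' @param mu,delta,eta Probabilities in `[0, 1]`.
#' @return Named numeric vector of class `enzyme_efficiencies`.
#' @export
enzyme_efficiencies <- function(mu, delta, eta) {
  e <- c(mu = as.numeric(mu), delta = as.numeric(delta), eta = as.numeric(eta))
  if (any(e < 0 | e > 1)) stop("efficiencies must lie in [0, 1]")
  structure(e, class = "enzyme_efficiencies")
}

## Per-strand outcome distributions used to assemble the division matrix.
## The new strand starts unmodified; maintenance sees the *original* state
## of the retained template strand (only m templates are recognised), then
## de novo acts on strands still u, then hydroxylation turns m into h.
.new_strand_dist <- function(template, mu, delta, eta) {
  p_m <- if (template == "m") mu + (1 - mu) * delta else delta
  c(u = 1 - p_m, m = p_m * (1 - eta), h = p_m * eta)
}

.old_strand_dist <- function(state, delta, eta) {
  switch(state,
    u = c(u = 1 - delta, m = delta * (1 - eta), h = delta * eta),
    m = c(u = 0, m = 1 - eta, h = eta),
    h = c(u = 0, m = 0, h = 1)
  )
}

#' One-division transition matrix of the dyad chain
#'
#' Builds the 9x9 row-stochastic matrix describing one cell division acting
#' on a CpG dyad.  Events are applied in a fixed order: (1) replication —
#' one strand is retained uniformly at random and paired with an all-u new
#' strand; (2) maintenance — the new-strand cytosine opposite a 5mC template
#' becomes 5mC with probability `mu`; (3) de novo — every strand still
#' unmodified becomes 5mC with probability `delta`, independently per
#' strand; (4) hydroxylation — every 5mC strand becomes 5hmC with
#' probability `eta`.  Maintenance recognises only 5mC templates; 5hmC is
#' terminal (no further oxidation is modelled).
#'
#' @param mu,delta,eta Event probabilities, see [enzyme_efficiencies()].
#' @return A 9x9 matrix with rows and columns named by [dyad_states()];
#'   every row sums to 1.
#' @export
division_matrix <- function(mu, delta, eta) {
  mu <- unname(as.numeric(mu)); delta <- unname(as.numeric(delta))
  eta <- unname(as.numeric(eta))
  if (any(c(mu, delta, eta) < 0 | c(mu, delta, eta) > 1))
    stop("efficiencies must lie in [0, 1]")
  letters3 <- c("u", "m", "h")
  old <- lapply(stats::setNames(letters3, letters3),
                .old_strand_dist, delta = delta, eta = eta)
  new <- lapply(stats::setNames(letters3, letters3),
                .new_strand_dist, mu = mu, delta = delta, eta = eta)
  M <- matrix(0, 9, 9, dimnames = list(.STATES, .STATES))
  for (i in seq_len(9L)) {
    top <- .TOPS[i]; bot <- .BOTS[i]
    ## daughter 1: old top retained, new bottom synthesised (top index
    ## fast to mirror the outer vectorisation); daughter 2: new top
    ## synthesised, old bottom retained
    row9 <- 0.5 * (rep(old[[top]], 3L) * rep(new[[top]], each = 3L) +
                     rep(new[[bot]], 3L) * rep(old[[bot]], each = 3L))
    M[i, ] <- row9[.PAIR_IDX]
  }
  M
}

#' Propagate a dyad state distribution through one division
#'
#' @param dist A distribution over the nine dyad states
#'   (see [state_distribution()]).
#' @param efficiencies An [enzyme_efficiencies()] vector (or any numeric
#'   vector with elements `mu`, `delta`, `eta`).
#' @return The distribution after one division, named in canonical order.
#' @export
division_step <- function(dist, efficiencies) {
  dist <- state_distribution(dist)
  e <- efficiencies
  drop(dist %*% division_matrix(e[["mu"]], e[["delta"]], e[["eta"]]))
}

#' Treatment-specific emission matrix of the dyad observation channel
#'
#' Maps each hidden dyad state to probabilities of the four observable read
#' classes (CC, CT, TC, TT; first letter = top-strand read base).  The two
#' strands convert independently; the per-strand probability of reading T
#' is `p_T_C` for an unmodified cytosine, `p_T_5mC` for 5mC and `p_T_5hmC`
#' for 5hmC, each measured per treatment from the linker controls
#' (see [derive_emission_parameters()]).
#'
#' @param params An `emission_parameters` object.
#' @param treatment `"BS"` or `"oxBS"`.
#' @return A 9x4 row-stochastic matrix, rows named by [dyad_states()],
#'   columns by [read_classes()].
#' @export
emission_matrix <- function(params, treatment = c("BS", "oxBS")) {
  treatment <- match.arg(treatment)
  p <- params[[treatment]]
  pT <- c(u = p[["p_T_C"]], m = p[["p_T_5mC"]], h = p[["p_T_5hmC"]])
  t_top <- pT[.TOPS]; t_bot <- pT[.BOTS]
  E <- cbind(CC = (1 - t_top) * (1 - t_bot), CT = (1 - t_top) * t_bot,
             TC = t_top * (1 - t_bot), TT = t_top * t_bot)
  rownames(E) <- .STATES
  E
}

#' Observation schedule over cell divisions
#'
#' Pairs observation times (in days) with cumulative cell division counts.
#' The default maps the mouse embryonic stem cell time course d0, d1, d3,
#' d6 onto 0, 2, 6, 12 cumulative divisions (a 12 h cycle).
#'
#' @param times Numeric, nondecreasing observation times in days.
#' @param divisions Integer, nondecreasing cumulative divisions at `times`.
#' @return A list of class `division_schedule`.
#' @export
division_schedule <- function(times = c(0, 1, 3, 6),
                              divisions = c(0, 2, 6, 12)) {
  if (length(times) != length(divisions))
    stop("times and divisions must have equal length")
  if (is.unsorted(times) || is.unsorted(divisions))
    stop("times and divisions must be nondecreasing")
  if (any(divisions != round(divisions)))
    stop("divisions must be integers")
  structure(list(times = as.numeric(times),
                 divisions = as.integer(round(divisions))),
            class = "division_schedule")
}

## Efficiencies argument normalisation: a length-3 vector is recycled to all
## intervals ("constant" mode); otherwise a K x 3 matrix, one row per
## inter-observation interval.
.efficiency_matrix <- function(efficiencies, n_intervals) {
  if (is.null(dim(efficiencies))) {
    if (length(efficiencies) != 3L)
      stop("efficiencies must be length 3 or an interval x 3 matrix")
    efficiencies <- matrix(rep(as.numeric(efficiencies), each = n_intervals),
                           nrow = n_intervals,
                           dimnames = list(NULL, c("mu", "delta", "eta")))
  }
  efficiencies <- as.matrix(efficiencies)
  if (nrow(efficiencies) != n_intervals || ncol(efficiencies) != 3L)
    stop("efficiency matrix must be n_intervals x 3")
  colnames(efficiencies) <- c("mu", "delta", "eta")
  efficiencies
}

#' Propagate an initial dyad distribution along a division schedule
#'
#' @param init Initial distribution over the nine dyad states.
#' @param schedule A [division_schedule()].
#' @param efficiencies Either a length-3 vector (`mu`, `delta`, `eta`)
#'   applied to every interval, or a matrix with one row per
#'   inter-observation interval.
#' @return Matrix of per-time distributions, one row per observation time.
#' @export
propagate_distribution <- function(init, schedule, efficiencies) {
  init <- state_distribution(init)
  n_t <- length(schedule$times)
  eff <- .efficiency_matrix(efficiencies, max(n_t - 1L, 1L))
  out <- matrix(0, n_t, 9, dimnames = list(NULL, dyad_states()))
  out[1, ] <- init
  dist <- init
  if (n_t > 1) for (k in seq_len(n_t - 1L)) {
    steps <- schedule$divisions[k + 1L] - schedule$divisions[k]
    if (steps > 0) {
      M <- division_matrix(eff[k, "mu"], eff[k, "delta"], eff[k, "eta"])
      for (i in seq_len(steps)) dist <- drop(dist %*% M)
    }
    out[k + 1L, ] <- dist
  }
  out
}

## Multinomial log pmf with the 0*log(0) convention; a zero-probability
## class with a nonzero count yields -Inf rather than an error.
.multinom_loglik <- function(counts, probs) {
  counts <- as.numeric(counts)
  if (any(probs <= 0 & counts > 0)) return(-Inf)
  keep <- counts > 0
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)) +
    sum(counts[keep] * log(probs[keep]))
}

#' Joint BS + oxBS log-likelihood of dyad read-class counts
#'
#' Both treatments observe the same hidden dyad chain: the initial
#' distribution is propagated through the division schedule, and at every
#' observation time the BS and oxBS read-class counts are scored as
#' independent multinomial draws from the propagated distribution pushed
#' through the treatment's emission matrix.
#'
#' @param efficiencies Length-3 vector or interval x 3 matrix
#'   (`mu`, `delta`, `eta`).
#' @param init Initial distribution over the nine dyad states.
#' @param schedule A [division_schedule()]; its times must match the
#'   `time` column of `counts`.
#' @param emissions An `emission_parameters` object.
#' @param counts Data frame with columns `time`, `treatment` and the four
#'   read classes `CC`, `CT`, `TC`, `TT` (aggregated molecule counts).
#' @return Scalar log-likelihood (`-Inf` if a zero-probability class has a
#'   nonzero count).
#' @export
log_likelihood <- function(efficiencies, init, schedule, emissions, counts) {
  stopifnot(all(c("time", "treatment", read_classes()) %in% names(counts)))
  cm <- as.matrix(counts[read_classes()])
  ti <- match(counts$time, schedule$times)
  if (anyNA(ti)) stop("count row time not present in schedule: ",
                      paste(counts$time[is.na(ti)], collapse = ", "))
  dists <- propagate_distribution(init, schedule, efficiencies)
  E <- list(BS = emission_matrix(emissions, "BS"),
            oxBS = emission_matrix(emissions, "oxBS"))
  ll <- 0
  for (i in seq_len(nrow(cm))) {
    probs <- drop(dists[ti[i], ] %*% E[[counts$treatment[i]]])
    ll <- ll + .multinom_loglik(cm[i, ], probs)
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}
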