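#' Conversion rate of a cytosine control
#'
#' The conversion rate of a control base is the fraction of reads showing T
#' at its position: `n_T / n_total`.  For the unmodified-C control this is
#' the intended-conversion efficiency; for the 5mC and 5hmC controls under
#' BS it is the unwanted (false) conversion; for the 5hmC control under
#' oxBS it is again the intended conversion.
#'
#' @param n_T Number of reads showing T at the control position.
#' @param n_total Number of reads covering the position with an
#'   informative (C or T) base.
#' @return The rate in `[0, 1]`; `NA` with a warning when `n_total` is 0.
#' @export
conversion_rate <- function(n_T, n_total) {
  if (length(n_T) != length(n_total))
    stop("n_T and n_total must have equal length")
  if (any(n_T < 0 | n_total < 0 | n_T > n_total, na.rm = TRUE))
    stop("need 0 <= n_T <= n_total")
  out <- ifelse(n_total > 0, n_T / n_total, NA_real_)
  if (any(n_total == 0))
    warning("conversion rate undefined for controls with zero coverage")
  out
}

#' Measure linker control conversion rates from methylation calls
#'
#' Counts C/T observations at the linker's unmodified-C, 5mC and 5hmC
#' control positions and converts them into per-control conversion rates.
#' Calls should come from reads passing the relaxed linker identity filter
#' (0.6); bases other than C/T are ignored.
#'
#' @param calls Data frame of methylation calls (as produced by
#'   [call_methylation()] / [align_sample()]) containing at least columns
#'   `context` and `observed`; linker controls carry contexts
#'   `linker_unmodC`, `linker_5mC`, `linker_5hmC`.
#' @param treatment `"BS"` or `"oxBS"`, recorded in the result.
#' @return A data frame of class `conversion_rates` with one row per
#'   control (`C`, `5mC`, `5hmC`) and columns `n_T`, `n_total`, `rate`.
#' @export
linker_control_rates <- function(calls, treatment = c("BS", "oxBS")) {
  treatment <- match.arg(treatment)
  ctx <- c(C = "linker_unmodC", `5mC` = "linker_5mC", `5hmC` = "linker_5hmC")
  n_T <- n_tot <- integer(3)
  for (i in seq_along(ctx)) {
    obs <- calls$observed[calls$context == ctx[[i]]]
    n_T[i] <- sum(obs == "T")
    n_tot[i] <- sum(obs %in% c("C", "T"))
  }
  rate <- suppressWarnings(conversion_rate(n_T, n_tot))
  if (anyNA(rate))
    warning("control(s) with zero coverage: ",
            paste(names(ctx)[n_tot == 0], collapse = ", "),
            "; a configured default must be used downstream")
  structure(data.frame(control = names(ctx), n_T = n_T, n_total = n_tot,
                       rate = rate, stringsAsFactors = FALSE),
            treatment = treatment, class = c("conversion_rates", "data.frame"))
}

#' Pool conversion-rate measurements across amplicons
#'
#' Per-amplicon rates are preferred when each control has at least
#' `min_coverage` observations (default 200); otherwise pooled counts
#' across amplicons give a single shared estimate.
#'
#' @param rates_list List of `conversion_rates` objects of one treatment.
#' @return A pooled `conversion_rates` object.
#' @export
pool_conversion_rates <- function(rates_list) {
  stopifnot(length(rates_list) >= 1)
  treatment <- attr(rates_list[[1]], "treatment")
  n_T <- Reduce(`+`, lapply(rates_list, function(x) x$n_T))
  n_tot <- Reduce(`+`, lapply(rates_list, function(x) x$n_total))
  structure(data.frame(control = rates_list[[1]]$control, n_T = n_T,
                       n_total = n_tot,
                       rate = suppressWarnings(conversion_rate(n_T, n_tot)),
                       stringsAsFactors = FALSE),
            treatment = treatment, class = c("conversion_rates", "data.frame"))
}

#' Emission parameters of the BS/oxBS observation channels
#'
#' Per treatment, the probability that a strand's cytosine is read as T
#' given its true modification: `p_T_C` (unmodified C), `p_T_5mC`,
#' `p_T_5hmC`.  The complements are the read-C probabilities.
#'
#' @param bs,oxbs Numeric length-3 vectors `(p_T_C, p_T_5mC, p_T_5hmC)`.
#' @return List of class `emission_parameters` with elements `BS`, `oxBS`.
#' @export
emission_parameters <- function(bs, oxbs) {
  nm <- c("p_T_C", "p_T_5mC", "p_T_5hmC")
  bs <- stats::setNames(as.numeric(bs), nm)
  oxbs <- stats::setNames(as.numeric(oxbs), nm)
  if (any(c(bs, oxbs) < 0 | c(bs, oxbs) > 1))
    stop("emission probabilities must lie in [0, 1]")
  structure(list(BS = bs, oxBS = oxbs), class = "emission_parameters")
}

#' @rdname emission_parameters
#' @details `ideal_chemistry()` is the error-free limit: unmodified C
#'   always converts, 5mC never converts, 5hmC converts under oxBS only.
#' @export
ideal_chemistry <- function() {
  emission_parameters(bs = c(1, 0, 0), oxbs = c(1, 0, 1))
}

#' Turn measured conversion rates into emission parameters
#'
#' All three control rates are oriented in the read-T direction, so the
#' measured rates plug directly into the observation channel: the BS
#' channel uses the BS control rates, the oxBS channel the oxBS rates.
#'
#' @param bs_rates,oxbs_rates `conversion_rates` objects (rows `C`, `5mC`,
#'   `5hmC`) for the two treatments.
#' @return An [emission_parameters()] object.
#' @export
derive_emission_parameters <- function(bs_rates, oxbs_rates) {
  pick <- function(r) {
    stopifnot(identical(r$control, c("C", "5mC", "5hmC")))
    if (anyNA(r$rate)) stop("cannot derive emission parameters from ",
                            "controls with zero coverage")
    r$rate
  }
  emission_parameters(pick(bs_rates), pick(oxbs_rates))
}

#' Published linker control conversion rates for eight mouse loci
#'
#' Reference conversion rates of the linker's unmodified-C, 5mC and 5hmC
#' controls measured in mouse embryonic stem cells for three single-copy
#' loci (Afp, Ttc25, Zim3) and five repetitive elements (IAP, L1mdA,
#' L1mdT, mSat, MuERVL), per treatment.  Useful as realistic defaults for
#' simulation and as worked-example emission parameters.
#'
#' @return Data frame with columns `treatment`, `control`, one column per
#'   amplicon, and rows C / 5mC / 5hmC within each treatment.
#' @export
published_conversion_rates <- function() {
  amps <- c("Afp", "IAP", "L1mdA", "L1mdT", "mSat", "MuERVL", "Ttc25", "Zim3")
  bs <- rbind(
    C      = c(0.996, 0.999, 0.995, 0.993, 0.996, 0.993, 0.994, 0.995),
    `5mC`  = c(0.0674, 0.0628, 0.084, 0.088, 0.0685, 0.0819, 0.0813, 0.0763),
    `5hmC` = c(0.0765, 0.0721, 0.0736, 0.0703, 0.0642, 0.0662, 0.0785, 0.0696))
  oxbs <- rbind(
    C      = c(0.996, 0.999, 0.996, 0.994, 0.997, 0.997, 0.996, 0.996),
    `5mC`  = c(0.0636, 0.0900, 0.0795, 0.0758, 0.0685, 0.0808, 0.1078, 0.0773),
    `5hmC` = c(0.920, 0.9095, 0.909, 0.9323, 0.93693, 0.922, 0.942, 0.9315))
  colnames(bs) <- colnames(oxbs) <- amps
  out <- data.frame(treatment = rep(c("BS", "oxBS"), each = 3),
                    control = rep(c("C", "5mC", "5hmC"), 2),
                    rbind(bs, oxbs), row.names = NULL, check.names = FALSE)
  out
}

#' Emission parameters of a published amplicon
#'
#' Convenience lookup of [published_conversion_rates()] for one amplicon,
#' returned as ready-to-use emission parameters.
#'
#' @param amplicon Amplicon name, e.g. `"Afp"`.
#' @return An [emission_parameters()] object.
#' @export
published_emission_parameters <- function(amplicon = "Afp") {
  tab <- published_conversion_rates()
  if (!amplicon %in% names(tab)) stop("unknown amplicon: ", amplicon)
  emission_parameters(bs = tab[tab$treatment == "BS", amplicon],
                      oxbs = tab[tab$treatment == "oxBS", amplicon])
}
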