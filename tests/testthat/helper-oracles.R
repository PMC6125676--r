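## Independent brute-force oracles. These enumerate the per-division and
## per-conversion event trees explicitly, sharing no code with the
## package's matrix construction.

## All outcomes of one strand through one division: maintenance (new
## strand opposite an m template only), then de novo on remaining u, then
## hydroxylation of m. Returns list of (letter, prob).
oracle_strand <- function(letter, is_new, template, mu, delta, eta) {
  after_maint <- if (is_new && template == "m") {
    list(list("m", mu), list("u", 1 - mu))
  } else {
    list(list(letter, 1))
  }
  out <- list()
  for (b1 in after_maint) {
    after_denovo <- if (b1[[1]] == "u") {
      list(list("m", b1[[2]] * delta), list("u", b1[[2]] * (1 - delta)))
    } else {
      list(b1)
    }
    for (b2 in after_denovo) {
      if (b2[[1]] == "m") {
        out <- c(out, list(list("h", b2[[2]] * eta),
                           list("m", b2[[2]] * (1 - eta))))
      } else {
        out <- c(out, list(b2))
      }
    }
  }
  out
}

## 9x9 one-division transition matrix by exhaustive event enumeration.
oracle_division_matrix <- function(mu, delta, eta) {
  states <- dyad_states()
  M <- matrix(0, 9, 9, dimnames = list(states, states))
  for (s in states) {
    top <- substr(s, 1, 1)
    bot <- substr(s, 2, 2)
    for (retained in c("top", "bottom")) {
      o <- if (retained == "top") top else bot
      olds <- oracle_strand(o, is_new = FALSE, template = NA,
                            mu = mu, delta = delta, eta = eta)
      news <- oracle_strand("u", is_new = TRUE, template = o,
                            mu = mu, delta = delta, eta = eta)
      for (a in olds) for (b in news) {
        dst <- if (retained == "top") paste0(a[[1]], b[[1]])
               else paste0(b[[1]], a[[1]])
        M[s, dst] <- M[s, dst] + 0.5 * a[[2]] * b[[2]]
      }
    }
  }
  M
}

## 9x4 emission matrix by enumerating the four conversion outcomes.
oracle_emission_matrix <- function(p_T) {   # p_T named by u/m/h
  states <- dyad_states()
  E <- matrix(0, 9, 4, dimnames = list(states, read_classes()))
  for (s in states) {
    for (top_reads_T in c(FALSE, TRUE)) for (bot_reads_T in c(FALSE, TRUE)) {
      pt <- p_T[[substr(s, 1, 1)]]
      pb <- p_T[[substr(s, 2, 2)]]
      p <- (if (top_reads_T) pt else 1 - pt) *
           (if (bot_reads_T) pb else 1 - pb)
      cls <- paste0(if (top_reads_T) "T" else "C",
                    if (bot_reads_T) "T" else "C")
      E[s, cls] <- E[s, cls] + p
    }
  }
  E
}

## Model-level counts simulation (population draw + chemistry), used by
## the fitting tests; returns the counts data frame the fitter expects.
simulate_model_counts <- function(n, efficiencies, init, schedule,
                                  emissions, seed) {
  set.seed(seed)
  cfg <- simulation_config(n_molecules = n, efficiencies = efficiencies,
                           init = init, schedule = schedule,
                           emissions = emissions, seed = seed)
  pop <- simulate_population(cfg, n_dyads = 1)
  rows <- list()
  for (ti in seq_along(schedule$times)) {
    for (tr in c("BS", "oxBS")) {
      cls <- apply_chemistry(pop[[ti]][[tr]], tr, emissions)
      tab <- table(factor(cls, levels = read_classes()))
      rows[[paste(ti, tr)]] <-
        stats::setNames(data.frame(time = schedule$times[ti],
                                   treatment = tr, t(as.integer(tab))),
                        c("time", "treatment", read_classes()))
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

## Expected dyad class of a hidden state under a treatment with ideal
## chemistry (BS: m and h read C; oxBS: only m reads C).
expected_class <- function(states, treatment) {
  modified <- if (treatment == "BS") c("m", "h") else "m"
  top <- substr(states, 1, 1) %in% modified
  bot <- substr(states, 2, 2) %in% modified
  ifelse(top & bot, "both",
         ifelse(top, "hemi_top", ifelse(bot, "hemi_bottom", "unmod")))
}

## Default highly methylated starting population used across tests.
test_init <- function() {
  c(uu = 0.20, um = 0.08, mu = 0.08, mm = 0.55, uh = 0.01, hu = 0.01,
    mh = 0.03, hm = 0.03, hh = 0.01)
}
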