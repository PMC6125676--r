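## Synthetic hairpin read-set generator: forward-simulates dyad
## populations under the division chain, applies BS/oxBS conversion
## chemistry with configurable error rates, and emits paired FASTQ with
## linker controls and UMIs plus a ground-truth table.

#' Simulation configuration
#'
#' Bundles all parameters of a synthetic hairpin experiment.  Defaults
#' describe the demethylating mouse ESC time course the package models:
#' observations at days 0/1/3/6 mapping to 0/2/6/12 divisions, a highly
#' methylated starting population, enzyme efficiencies
#' `(mu, delta, eta) = (0.8, 0.1, 0.05)` per division, and conversion
#' chemistry at the published Afp linker control rates.
#'
#' @param ref A `hairpin_reference`, or `NULL` to generate one with
#'   [make_test_reference()] (parameters `n_dyads`, `arm_length`,
#'   `umi_length`).
#' @param n_dyads,arm_length,umi_length Generated-reference geometry.
#' @param efficiencies True `(mu, delta, eta)` per interval (length-3
#'   vector or interval x 3 matrix).
#' @param init Initial distribution over the nine dyad states.
#' @param schedule A [division_schedule()].
#' @param emissions An [emission_parameters()] object (true chemistry).
#' @param n_molecules Molecules per time point per treatment.
#' @param pcr_duplication Probability-like duplication rate `r`; each
#'   molecule receives `1 + rgeom(1 - r)` PCR copies (rate 0 = none,
#'   0.5 = two copies on average).
#' @param seq_error Per-base uniform substitution rate applied after
#'   conversion.
#' @param read_length Read length of each mate.
#' @param common_state If `TRUE`, all dyads of a molecule share one drawn
#'   state (pattern-map realism); default draws dyads independently.
#' @param seed Integer seed; mandatory.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(ref = NULL, n_dyads = 4, arm_length = 60,
                              umi_length = 12,
                              efficiencies = c(mu = 0.8, delta = 0.1,
                                               eta = 0.05),
                              init = c(uu = 0.20, um = 0.08, mu = 0.08,
                                       mm = 0.55, uh = 0.01, hu = 0.01,
                                       mh = 0.03, hm = 0.03, hh = 0.01),
                              schedule = division_schedule(),
                              emissions = published_emission_parameters("Afp"),
                              n_molecules = 5000, pcr_duplication = 0,
                              seq_error = 0, read_length = 120,
                              common_state = FALSE, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducible simulation")
  init <- state_distribution(init)
  stopifnot(pcr_duplication >= 0, pcr_duplication < 1,
            seq_error >= 0, seq_error < 1)
  structure(list(ref = ref, n_dyads = n_dyads, arm_length = arm_length,
                 umi_length = umi_length, efficiencies = efficiencies,
                 init = init, schedule = schedule, emissions = emissions,
                 n_molecules = n_molecules,
                 pcr_duplication = pcr_duplication, seq_error = seq_error,
                 read_length = read_length, common_state = common_state,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw hidden dyad states per time point
#'
#' Propagates the configured initial distribution along the schedule and
#' draws `n_molecules` molecules per time point per treatment, i.i.d. from
#' the population marginal (each sequenced molecule samples one cell).
#' Dyads within a molecule are independent unless `common_state` ties
#' them.  Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param config A [simulation_config()].
#' @param n_dyads Number of dyads (taken from `config$ref` if present).
#' @return Nested list `[[time index]][[treatment]]`: character matrices
#'   (`n_molecules` x `n_dyads`) of hidden states.
#' @export
simulate_population <- function(config, n_dyads = NULL) {
  if (is.null(n_dyads))
    n_dyads <- if (!is.null(config$ref))
      length(config$ref$dyad_positions) else config$n_dyads
  dists <- propagate_distribution(config$init, config$schedule,
                                  config$efficiencies)
  lapply(seq_along(config$schedule$times), function(ti) {
    out <- list()
    for (tr in c("BS", "oxBS")) {
      n <- config$n_molecules
      if (config$common_state) {
        s <- sample(dyad_states(), n, replace = TRUE, prob = dists[ti, ])
        m <- matrix(rep(s, n_dyads), nrow = n)
      } else {
        m <- matrix(sample(dyad_states(), n * n_dyads, replace = TRUE,
                           prob = dists[ti, ]), nrow = n)
      }
      out[[tr]] <- m
    }
    out
  })
}

#' Apply conversion chemistry to hidden dyad states
#'
#' Converts each strand of each dyad independently: the probability of
#' reading T is the emission parameter of the strand's true modification
#' under the given treatment.  Returns observable read classes.
#'
#' @param states Character matrix (molecules x dyads) of hidden states.
#' @param treatment `"BS"` or `"oxBS"`.
#' @param emissions An [emission_parameters()] object.
#' @return Character matrix of read classes (`CC`, `CT`, `TC`, `TT`).
#' @export
apply_chemistry <- function(states, treatment = c("BS", "oxBS"), emissions) {
  treatment <- match.arg(treatment)
  p <- emissions[[treatment]]
  pT <- c(u = p[["p_T_C"]], m = p[["p_T_5mC"]], h = p[["p_T_5hmC"]])
  top <- substr(states, 1, 1)
  bot <- substr(states, 2, 2)
  t_top <- stats::runif(length(states)) < pT[top]
  t_bot <- stats::runif(length(states)) < pT[bot]
  cls <- paste0(ifelse(t_top, "T", "C"), ifelse(t_bot, "T", "C"))
  matrix(cls, nrow = nrow(states), dimnames = dimnames(states))
}

#' Simulate linker control observations
#'
#' Draws per-read C/T observations at the linker's three control bases
#' under the configured chemistry, in the shape expected by
#' [linker_control_rates()].  Uses the current RNG state.
#'
#' @param n_reads Number of linker-covering reads.
#' @param emissions An [emission_parameters()] object.
#' @param treatment `"BS"` or `"oxBS"`.
#' @return Data frame with columns `read_id`, `context`, `observed`.
#' @export
simulate_control_calls <- function(n_reads, emissions,
                                   treatment = c("BS", "oxBS")) {
  treatment <- match.arg(treatment)
  p <- emissions[[treatment]]
  ctx <- c(linker_unmodC = p[["p_T_C"]], linker_5mC = p[["p_T_5mC"]],
           linker_5hmC = p[["p_T_5hmC"]])
  do.call(rbind, lapply(names(ctx), function(cx) {
    data.frame(read_id = paste0("read", seq_len(n_reads)), context = cx,
               observed = ifelse(stats::runif(n_reads) < ctx[[cx]],
                                 "T", "C"),
               stringsAsFactors = FALSE)
  }))
}

## Converted composite sequence of one molecule (drawn once; PCR copies
## share it and differ only by sequencing errors).
.converted_composite <- function(classes_row, umi, ref, p) {
  ch <- .chars(ref$composite)
  ch[ref$top_c_pos + 1L] <- substr(classes_row, 1, 1)
  ch[ref$bottom_c_pos + 1L] <- substr(classes_row, 2, 2)
  ## unmodified genomic nonCpG cytosines
  for (pos in c(ref$noncpg_top, ref$noncpg_bottom)) {
    if (stats::runif(1) < p[["p_T_C"]]) ch[pos + 1L] <- "T"
  }
  ## linker: controls by role, remaining linker Cs are unmodified
  ctrl_pos <- as.integer(names(ref$control_composite))
  role_p <- c(unmodC = p[["p_T_C"]], fivemC = p[["p_T_5mC"]],
              fivehmC = p[["p_T_5hmC"]])
  for (k in seq_along(ctrl_pos)) {
    if (stats::runif(1) < role_p[[ref$control_composite[[k]]]])
      ch[ctrl_pos[k] + 1L] <- "T"
  }
  lnk_range <- ref$arm_length + seq_len(ref$linker_length) - 1L
  other_c <- setdiff(lnk_range[ch[lnk_range + 1L] == "C"], ctrl_pos)
  for (pos in other_c) {
    if (stats::runif(1) < p[["p_T_C"]]) ch[pos + 1L] <- "T"
  }
  ch[ref$umi_composite + 1L] <- .chars(umi)
  paste(ch, collapse = "")
}

.seq_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- .chars(seq)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Emit paired FASTQ reads for one sample
#'
#' Builds the converted composite sequence of every molecule (dyad read
#' classes, converted nonCpG and linker cytosines, UMI slots filled
#' uniformly over A/T/G), replicates PCR clones, applies optional uniform
#' sequencing errors per copy, and writes mate 1 (composite 5' end) and
#' mate 2 (reverse complement of the 3' end) with constant quality.
#' Uses the current RNG state.
#'
#' @param classes Read-class matrix from [apply_chemistry()].
#' @param states Matching hidden-state matrix (recorded as ground truth).
#' @param ref A `hairpin_reference`.
#' @param config A [simulation_config()].
#' @param treatment,time Sample labels.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Ground-truth data frame: `molecule_id`, `umi`, `time`,
#'   `treatment`, `states` (semicolon-joined per dyad), `n_copies`.
#' @export
emit_fastq <- function(classes, states, ref, config, treatment, time,
                       r1_path, r2_path) {
  n <- nrow(classes)
  p <- config$emissions[[treatment]]
  umis <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "T", "G"), length(ref$umi_positions),
                 replace = TRUE), collapse = ""), "")
  n_copies <- 1L + stats::rgeom(n, prob = 1 - config$pcr_duplication)
  L <- nchar(ref$composite)
  rl <- min(config$read_length, L)
  seqs1 <- seqs2 <- ids <- vector("list", n)
  for (i in seq_len(n)) {
    mol <- .converted_composite(classes[i, ], umis[i], ref, p)
    copies <- vapply(seq_len(n_copies[i]), function(cp)
      .seq_errors(mol, config$seq_error), "")
    seqs1[[i]] <- substr(copies, 1L, rl)
    seqs2[[i]] <- vapply(substr(copies, L - rl + 1L, L),
                         .revcomp_chr, "", USE.NAMES = FALSE)
    ids[[i]] <- sprintf("%s:%s:t%g:mol%05d:c%d", ref$amplicon_id,
                        treatment, time, i, seq_len(n_copies[i]))
  }
  seqs1 <- unlist(seqs1); seqs2 <- unlist(seqs2); ids <- unlist(ids)
  ord <- sample(length(ids))           # shuffle clones through the file
  write_fq <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids[ord]
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  }
  write_fq(seqs1[ord], r1_path)
  write_fq(seqs2[ord], r2_path)
  data.frame(molecule_id = sprintf("%s:%s:t%g:mol%05d", ref$amplicon_id,
                                   treatment, time, seq_len(n)),
             umi = umis, time = time, treatment = treatment,
             states = apply(states, 1, paste, collapse = ";"),
             n_copies = n_copies, stringsAsFactors = FALSE)
}

#' Simulate a complete hairpin BS/oxBS dataset
#'
#' Seeded end-to-end driver: builds (or reuses) the reference, draws the
#' dyad populations along the schedule, applies chemistry, writes paired
#' FASTQ per time point and treatment plus the reference FASTA/annotation,
#' a combined ground-truth TSV and a config echo with the resolved seed.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @return Manifest list: `ref`, `samples` (data frame `name`, `time`,
#'   `treatment`, `r1`, `r2`, `n_molecules`), `ground_truth` (path),
#'   `dir`, `config`.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  ref <- config$ref
  if (is.null(ref))
    ref <- make_test_reference(config$n_dyads, config$arm_length,
                               config$umi_length,
                               seed = config$seed + 101L)
  set.seed(config$seed + 1L)
  write_reference(ref, file.path(dir, "reference.fasta"),
                  file.path(dir, "reference_annotation.tsv"))
  pop <- simulate_population(config, n_dyads = length(ref$dyad_positions))
  samples <- list(); truth <- list()
  for (ti in seq_along(config$schedule$times)) {
    tday <- config$schedule$times[ti]
    for (tr in c("BS", "oxBS")) {
      states <- pop[[ti]][[tr]]
      classes <- apply_chemistry(states, tr, config$emissions)
      nm <- sprintf("t%g_%s", tday, tr)
      r1 <- file.path(dir, paste0(nm, "_R1.fastq"))
      r2 <- file.path(dir, paste0(nm, "_R2.fastq"))
      truth[[nm]] <- emit_fastq(classes, states, ref, config, tr, tday,
                                r1, r2)
      samples[[nm]] <- data.frame(name = nm, time = tday, treatment = tr,
                                  r1 = r1, r2 = r2,
                                  n_molecules = nrow(states),
                                  stringsAsFactors = FALSE)
    }
  }
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  gt_path <- file.path(dir, "ground_truth.tsv")
  utils::write.table(truth_df, gt_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  echo <- list(seed = config$seed, n_molecules = config$n_molecules,
               pcr_duplication = config$pcr_duplication,
               seq_error = config$seq_error,
               read_length = config$read_length,
               common_state = config$common_state,
               times = config$schedule$times,
               divisions = config$schedule$divisions,
               efficiencies = as.list(as.data.frame(
                 .efficiency_matrix(config$efficiencies,
                                    max(1L, length(config$schedule$times)
                                        - 1L)))),
               init = as.list(config$init),
               emissions = lapply(config$emissions, as.list),
               amplicon_id = ref$amplicon_id)
  yaml::write_yaml(echo, file.path(dir, "config_echo.yaml"))
  list(ref = ref, samples = do.call(rbind, unname(samples)),
       ground_truth = gt_path, dir = dir, config = config)
}
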