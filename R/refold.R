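## Restoration of double-strand information: pair per-strand CpG calls
## into dyad classes, collapse PCR clones by UMI, summarise, and draw
## pattern maps.

DYAD_CLASSES <- c("both", "hemi_top", "hemi_bottom", "unmod", "unknown")

#' Refold one molecule's strand calls into dyad classes
#'
#' Combines the top- and bottom-strand methylation state at every CpG dyad
#' into one of five classes: `both` (modified/modified), `hemi_top` (only
#' the top/plus strand modified), `hemi_bottom` (only the bottom strand),
#' `unmod` (neither), `unknown` (either member not analysable).
#'
#' @param top_states,bottom_states Character vectors over
#'   `c("modified", "unmodified", "unknown")`, one entry per dyad.
#' @return Character vector of dyad classes.
#' @export
refold <- function(top_states, bottom_states) {
  if (length(top_states) != length(bottom_states))
    stop("strand call vectors must have equal length")
  ifelse(top_states == "unknown" | bottom_states == "unknown", "unknown",
  ifelse(top_states == "modified" & bottom_states == "modified", "both",
  ifelse(top_states == "modified", "hemi_top",
  ifelse(bottom_states == "modified", "hemi_bottom", "unmod"))))
}

#' Refold an aligned sample into per-molecule dyad patterns
#'
#' Applies [refold()] to every read passing the identity filter and
#' collects per-molecule metadata: UMI, nonCpG methylation rate (fraction
#' of informative nonCpG cytosines observed as C — kept separate from the
#' dyad classes) and the source read count (1 before deduplication).
#'
#' @param alignment A `hairpin_alignment` from [align_sample()].
#' @param ref The `hairpin_reference`.
#' @return List of class `dyad_patterns`: `info` (data frame `molecule_id`,
#'   `umi`, `treatment`, `nonCpG_rate`, `source_read_count`), `classes`
#'   (character matrix, molecules x dyads), `amplicon_id`.
#' @export
refold_sample <- function(alignment, ref) {
  reads <- alignment$reads[alignment$reads$pass, , drop = FALSE]
  calls <- alignment$calls
  n_dyads <- length(ref$dyad_positions)
  classes <- matrix("unknown", nrow(reads), n_dyads,
                    dimnames = list(reads$read_id, NULL))
  noncpg <- rep(NA_real_, nrow(reads))
  cpg <- calls[calls$context == "CpG", , drop = FALSE]
  ncpg <- calls[calls$context == "nonCpG", , drop = FALSE]
  for (i in seq_len(nrow(reads))) {
    id <- reads$read_id[i]
    cc <- cpg[cpg$read_id == id, , drop = FALSE]
    top <- cc$state[match(seq_len(n_dyads),
                          ifelse(cc$strand == "top", cc$dyad_index, NA))]
    bot <- cc$state[match(seq_len(n_dyads),
                          ifelse(cc$strand == "bottom", cc$dyad_index, NA))]
    top[is.na(top)] <- "unknown"; bot[is.na(bot)] <- "unknown"
    classes[i, ] <- refold(top, bot)
    nc <- ncpg[ncpg$read_id == id, , drop = FALSE]
    inf <- nc$state %in% c("modified", "unmodified")
    noncpg[i] <- if (any(inf)) mean(nc$state[inf] == "modified") else NA_real_
  }
  structure(list(
    info = data.frame(molecule_id = reads$read_id, umi = reads$umi,
                      treatment = alignment$treatment,
                      nonCpG_rate = noncpg, source_read_count = 1L,
                      stringsAsFactors = FALSE),
    classes = classes, amplicon_id = alignment$amplicon_id),
    class = "dyad_patterns")
}

#' Construct a `dyad_patterns` object directly
#'
#' Used by the simulator and by tests to build pattern sets without going
#' through alignment.
#'
#' @param classes Character matrix (molecules x dyads) over the five dyad
#'   classes.
#' @param umi Character vector of UMIs (`NA` = absent).
#' @param treatment `"BS"` or `"oxBS"`.
#' @param molecule_id Optional ids.
#' @param nonCpG_rate Optional per-molecule nonCpG methylation rates.
#' @param amplicon_id Amplicon name.
#' @return A `dyad_patterns` object.
#' @export
dyad_patterns <- function(classes, umi = rep(NA_character_, nrow(classes)),
                          treatment = "BS",
                          molecule_id = sprintf("mol%d", seq_len(nrow(classes))),
                          nonCpG_rate = rep(NA_real_, nrow(classes)),
                          amplicon_id = "amplicon") {
  stopifnot(all(classes %in% DYAD_CLASSES))
  treatment <- rep(treatment, length.out = nrow(classes))
  structure(list(
    info = data.frame(molecule_id = molecule_id, umi = umi,
                      treatment = treatment, nonCpG_rate = nonCpG_rate,
                      source_read_count = rep(1L, nrow(classes)),
                      stringsAsFactors = FALSE),
    classes = matrix(classes, nrow = nrow(classes),
                     dimnames = list(molecule_id, NULL)),
    amplicon_id = amplicon_id), class = "dyad_patterns")
}

## Majority vote over one dyad's classes; ties -> unknown.
.majority_class <- function(x) {
  tab <- table(factor(x, levels = DYAD_CLASSES))
  top <- max(tab)
  winners <- names(tab)[tab == top]
  if (length(winners) == 1L) winners else "unknown"
}

#' Collapse PCR clones by UMI
#'
#' Reads sharing a UMI (within one amplicon and treatment) derive from the
#' same original ligation event; they are collapsed to one consensus
#' molecule by per-dyad majority vote over their classes (tie gives
#' `unknown`).  Reads without a UMI pass through uncollapsed.  The
#' operation is idempotent.
#'
#' @param patterns A `dyad_patterns` object.
#' @return A deduplicated `dyad_patterns`; `source_read_count` records the
#'   group sizes.
#' @export
dedup_umis <- function(patterns) {
  info <- patterns$info
  classes <- patterns$classes
  has_umi <- !is.na(info$umi)
  groups <- split(which(has_umi), info$umi[has_umi])
  keep_rows <- which(!has_umi)
  new_rows <- lapply(groups, function(idx) {
    cls <- if (length(idx) == 1L) classes[idx, , drop = TRUE]
           else apply(classes[idx, , drop = FALSE], 2, .majority_class)
    counts <- sum(info$source_read_count[idx])
    nonc <- info$nonCpG_rate[idx]
    list(class_row = cls,
         info_row = data.frame(
           molecule_id = info$molecule_id[idx[1L]], umi = info$umi[idx[1L]],
           treatment = info$treatment[idx[1L]],
           nonCpG_rate = if (all(is.na(nonc))) NA_real_
                         else mean(nonc, na.rm = TRUE),
           source_read_count = counts, stringsAsFactors = FALSE))
  })
  info_out <- rbind(
    info[keep_rows, , drop = FALSE],
    do.call(rbind, lapply(new_rows, `[[`, "info_row")))
  classes_out <- rbind(
    classes[keep_rows, , drop = FALSE],
    do.call(rbind, lapply(new_rows, `[[`, "class_row")))
  if (is.null(dim(classes_out)))
    classes_out <- matrix(classes_out, nrow = nrow(info_out))
  rownames(classes_out) <- info_out$molecule_id
  ord <- order(info_out$molecule_id)
  structure(list(info = info_out[ord, , drop = FALSE],
                 classes = classes_out[ord, , drop = FALSE],
                 amplicon_id = patterns$amplicon_id),
            class = "dyad_patterns")
}

#' Summarise dyad patterns
#'
#' Per-dyad frequencies of the four analysable classes (among molecules
#' with a known class at that dyad), per-dyad coverage, and the amplicon
#' mean over dyads.  The mean modification level counts a `both` dyad as
#' 1 modified strand fraction and a hemimethylated dyad as 1/2.
#'
#' @param patterns A (deduplicated) `dyad_patterns` object.
#' @return List of class `pattern_summary`: `per_dyad` (data frame with
#'   `dyad`, `coverage`, `both`, `hemi_top`, `hemi_bottom`, `unmod`),
#'   `mean` (named vector of mean class frequencies), `level` (mean
#'   modified-strand fraction), `n_molecules`, `treatment`, `amplicon_id`.
#' @export
summarize_patterns <- function(patterns) {
  classes <- patterns$classes
  n_dyads <- ncol(classes)
  per <- data.frame(dyad = seq_len(n_dyads), coverage = 0L,
                    both = NA_real_, hemi_top = NA_real_,
                    hemi_bottom = NA_real_, unmod = NA_real_)
  for (d in seq_len(n_dyads)) {
    x <- classes[, d]
    known <- x != "unknown"
    per$coverage[d] <- sum(known)
    if (any(known)) {
      tab <- table(factor(x[known], levels = DYAD_CLASSES[1:4]))
      per[d, DYAD_CLASSES[1:4]] <- as.numeric(tab) / sum(known)
    }
  }
  if (any(per$coverage == 0))
    warning("dyad(s) without analysable molecules: ",
            paste(per$dyad[per$coverage == 0], collapse = ", "))
  mean_freq <- colMeans(per[per$coverage > 0, DYAD_CLASSES[1:4], drop = FALSE])
  level <- unname(mean_freq["both"] +
                    0.5 * (mean_freq["hemi_top"] + mean_freq["hemi_bottom"]))
  structure(list(per_dyad = per, mean = mean_freq, level = level,
                 n_molecules = nrow(classes),
                 treatment = patterns$info$treatment[1],
                 amplicon_id = patterns$amplicon_id),
            class = "pattern_summary")
}

## Fixed colour scheme of the pattern map (documented; bit-stable).
.pattern_colors <- function() {
  rbind(both = c(0.80, 0.00, 0.00),        # red
        hemi_top = c(0.00, 0.39, 0.00),    # dark green
        hemi_bottom = c(0.56, 0.93, 0.56), # light green
        unmod = c(0.12, 0.30, 0.80),       # blue
        unknown = c(1.00, 1.00, 1.00))     # white
}

#' Draw a methylation pattern map
#'
#' Raster image with one row per molecule and one column per dyad: red =
#' dyad modified on both strands, dark green = only the plus strand, light
#' green = only the lower strand, blue = unmodified, white = not
#' analysable.  A leading column shows each molecule's mean modification
#' level on a blue-to-red ramp.  Rows are sorted by mean level
#' (descending, ties by molecule id) so reruns are byte-identical.
#'
#' @param patterns A `dyad_patterns` object (non-empty).
#' @param path Output PNG path.
#' @param cell Pixel edge length of one cell.
#' @return Invisibly, a list with the image `rows`/`cols` (in cells).
#' @export
write_pattern_map <- function(patterns, path, cell = 6) {
  classes <- patterns$classes
  if (nrow(classes) == 0) stop("cannot draw a pattern map of zero molecules")
  lvl_of <- c(both = 1, hemi_top = 0.5, hemi_bottom = 0.5, unmod = 0,
              unknown = NA_real_)
  row_level <- apply(classes, 1, function(x) {
    v <- lvl_of[x]; if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
  })
  ord <- order(-row_level, rownames(classes))
  classes <- classes[ord, , drop = FALSE]
  row_level <- row_level[ord]
  cols <- .pattern_colors()
  blue <- cols["unmod", ]; red <- cols["both", ]
  n <- nrow(classes); d <- ncol(classes)
  img <- array(1, dim = c(n, d + 1L, 3))
  for (i in seq_len(n)) {
    img[i, 1, ] <- blue + row_level[i] * (red - blue)
    img[i, 1 + seq_len(d), ] <- cols[classes[i, ], , drop = FALSE]
  }
  big <- img[rep(seq_len(n), each = cell),
             rep(seq_len(d + 1L), each = cell), , drop = FALSE]
  png::writePNG(big, path)
  invisible(list(rows = n, cols = d + 1L))
}

#' Write per-molecule and summary tables
#'
#' For each sample a per-molecule TSV (`<prefix>_<sample>_molecules.tsv`)
#' with columns `molecule_id`, `umi`, `treatment`, `source_read_count`,
#' `nonCpG_rate` and one `dyad_<i>` column per dyad; plus one cross-sample
#' summary TSV (`<prefix>_summary.tsv`) with one row per sample per dyad
#' (`sample`, `treatment`, `n_molecules`, `dyad`, `coverage`, class
#' frequencies) and a `mean` row per sample (`dyad = NA`).
#'
#' @param patterns_list Named list of `dyad_patterns` (one per sample).
#' @param summaries_list Matching named list of `pattern_summary` objects.
#' @param path_prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_tables <- function(patterns_list, summaries_list, path_prefix) {
  stopifnot(identical(names(patterns_list), names(summaries_list)))
  paths <- character(0)
  for (nm in names(patterns_list)) {
    p <- patterns_list[[nm]]
    df <- cbind(p$info[c("molecule_id", "umi", "treatment",
                         "source_read_count", "nonCpG_rate")],
                stats::setNames(as.data.frame(p$classes),
                                paste0("dyad_", seq_len(ncol(p$classes)))))
    f <- paste0(path_prefix, "_", nm, "_molecules.tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  summary_rows <- lapply(names(summaries_list), function(nm) {
    s <- summaries_list[[nm]]
    per <- cbind(sample = nm, treatment = s$treatment,
                 n_molecules = s$n_molecules, s$per_dyad)
    mean_row <- data.frame(sample = nm, treatment = s$treatment,
                           n_molecules = s$n_molecules, dyad = NA_integer_,
                           coverage = NA_integer_, t(s$mean))
    names(mean_row) <- names(per)
    rbind(per, mean_row)
  })
  f <- paste0(path_prefix, "_summary.tsv")
  utils::write.table(do.call(rbind, summary_rows), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, f))
}

#' Aggregate dyad patterns into read-class counts for model fitting
#'
#' Maps each analysable dyad of each molecule to its observable read class
#' (`both` -> CC, `hemi_top` -> CT, `hemi_bottom` -> TC, `unmod` -> TT;
#' `unknown` dyads are dropped) and sums over dyads of the amplicon.
#'
#' @param patterns A `dyad_patterns` object.
#' @return Named integer vector over [read_classes()].
#' @export
pattern_counts <- function(patterns) {
  map <- c(both = "CC", hemi_top = "CT", hemi_bottom = "TC", unmod = "TT")
  x <- patterns$classes[patterns$classes != "unknown"]
  tab <- table(factor(unname(map[x]), levels = read_classes()))
  stats::setNames(as.integer(tab), read_classes())
}
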