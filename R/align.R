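## Bisulfite-aware alignment of hairpin amplicon read pairs against the
## composite reference. Conversion is one-directional, so the scoring is
## asymmetric: read T opposite reference C is a match (conversion
## eligible), read C opposite reference T is a mismatch. Degenerate UMI
## slots (D) match A/T/G neutrally and mismatch C.

#' Bisulfite-aware substitution matrix
#'
#' Asymmetric scoring matrix used for read-vs-composite alignment: +1 for
#' identity and for read T opposite reference C, `mismatch` otherwise;
#' reference `D` (UMI slot) scores 0 against A/T/G and `mismatch` against
#' C; `N` is neutral in either sequence.
#'
#' @param match,mismatch Match and mismatch scores.
#' @return A 6x6 numeric matrix (A, C, G, T, N, D); rows index the read
#'   base, columns the reference base.
#' @export
bisulfite_matrix <- function(match = 1, mismatch = -2) {
  letters6 <- c("A", "C", "G", "T", "N", "D")
  m <- matrix(mismatch, 6, 6, dimnames = list(letters6, letters6))
  diag(m) <- match
  m["T", "C"] <- match          # conversion-eligible
  m["N", ] <- 0; m[, "N"] <- 0
  m[c("A", "G", "T"), "D"] <- 0
  m["C", "D"] <- mismatch
  m
}

#' Identity threshold for a repeat class or analysis mode
#'
#' Single-copy amplicons are filtered at identity >= 0.9, repetitive
#' elements at >= 0.8 (their sequence variability inflates mismatches),
#' and linker conversion-rate analysis at >= 0.6 (the degenerate UMI loop
#' cannot match one reference).
#'
#' @param mode `"single_copy"`, `"repetitive"` or `"linker"`.
#' @return The threshold as a fraction.
#' @export
identity_threshold <- function(mode = c("single_copy", "repetitive", "linker")) {
  switch(match.arg(mode), single_copy = 0.9, repetitive = 0.8, linker = 0.6)
}

## Walk one gapped alignment; returns the per-reference-position base/qual
## map plus insertion count. Positions are 0-based composite offsets.
.column_walk <- function(pat, sub, sub_start, qual_int, pat_start) {
  pc <- .chars(pat); sc <- .chars(sub)
  n <- length(pc)
  pos <- integer(n); base <- character(n); qual <- integer(n)
  k <- 0L
  refpos <- sub_start - 1L            # 0-based position of next subject char
  readpos <- pat_start                # 1-based index into the read
  n_ins <- 0L
  for (j in seq_len(n)) {
    if (sc[j] == "-") {
      n_ins <- n_ins + 1L
      readpos <- readpos + 1L
    } else {
      k <- k + 1L
      pos[k] <- refpos
      base[k] <- pc[j]
      qual[k] <- if (pc[j] == "-") 0L else qual_int[readpos]
      if (pc[j] != "-") readpos <- readpos + 1L
      refpos <- refpos + 1L
    }
  }
  list(pos = pos[seq_len(k)], base = base[seq_len(k)],
       qual = qual[seq_len(k)], n_ins = n_ins)
}

## Merge the two mates' maps in reference space: overlap consensus with
## quality-weighted majority; equal quality and disagreeing bases -> N; a
## base always wins over a deletion.
.merge_mates <- function(m1, m2) {
  if (is.null(m2)) {
    return(list(pos = m1$pos, base = m1$base, n_ins = m1$n_ins))
  }
  pos <- sort(union(m1$pos, m2$pos))
  i1 <- match(pos, m1$pos); i2 <- match(pos, m2$pos)
  b1 <- ifelse(is.na(i1), NA, m1$base[i1])
  b2 <- ifelse(is.na(i2), NA, m2$base[i2])
  q1 <- ifelse(is.na(i1), -1L, m1$qual[i1])
  q2 <- ifelse(is.na(i2), -1L, m2$qual[i2])
  base <- ifelse(is.na(b1), b2, ifelse(is.na(b2), b1, b1))
  both <- !is.na(b1) & !is.na(b2)
  disagree <- both & b1 != b2
  if (any(disagree)) {
    pick <- ifelse(b1 == "-", b2,          # a base beats a deletion
            ifelse(b2 == "-", b1,
            ifelse(q1 > q2, b1, ifelse(q2 > q1, b2, "N"))))
    base[disagree] <- pick[disagree]
  }
  list(pos = pos, base = base, n_ins = m1$n_ins + m2$n_ins)
}

## Match rule of one merged column against the original composite base.
.column_matches <- function(obs, refc) {
  (obs == refc & obs != "-") |
    (refc == "C" & obs == "T") |
    (refc == "D" & obs %in% c("A", "G", "T")) |
    (refc == "N")
}

#' Sequence identity of an aligned (merged) read
#'
#' Fraction of matching alignment columns, with read T opposite reference
#' C counted as a match at conversion-eligible positions and reference D
#' matching A/T/G.  The denominator is all aligned columns including gaps
#' (insertions and deletions count as mismatching columns); soft-clipped
#' read ends are excluded.
#'
#' @param aligned An `aligned_read` (from [align_read_pair()]).
#' @param ref The `hairpin_reference` it was aligned to.
#' @return Identity in `[0, 1]`; `NA` for zero aligned columns.
#' @export
sequence_identity <- function(aligned, ref) {
  pos <- as.integer(names(aligned$aligned_bases))
  obs <- unname(aligned$aligned_bases)
  n_cols <- length(pos) + aligned$n_insertions
  if (n_cols == 0) return(NA_real_)
  refc <- .chars(ref$composite)[pos + 1L]
  sum(.column_matches(obs, refc)) / n_cols
}

#' Align one hairpin read pair to the composite reference
#'
#' Mate 2 is reverse-complemented into composite orientation; both mates
#' are aligned ends-free against the alignment variant of the composite
#' (non-control linker cytosines as T) with bisulfite-aware scoring, then
#' merged in reference space by quality-weighted overlap consensus
#' (disagreement at equal quality gives N).
#'
#' @param read1,read2 Either character sequences or lists with elements
#'   `seq` and `qual` (Phred string).  `read2` may be `NULL` for
#'   single-end input.
#' @param ref A `hairpin_reference`.
#' @param read_id Identifier stored in the result.
#' @param treatment `"BS"` or `"oxBS"`.
#' @param gap_opening,gap_extension Gap penalties (positive).
#' @return List of class `aligned_read` with elements `read_id`,
#'   `treatment`, `aligned_bases` (named by 0-based composite position),
#'   `n_insertions`, `identity` and `arms_covered`.
#' @export
align_read_pair <- function(read1, read2 = NULL, ref, read_id = "read",
                            treatment = c("BS", "oxBS"),
                            gap_opening = 6, gap_extension = 1) {
  treatment <- match.arg(treatment)
  norm <- function(r) {
    if (is.character(r)) list(seq = r, qual = strrep("I", nchar(r))) else r
  }
  r1 <- norm(read1)
  r2 <- if (!is.null(read2)) norm(read2)
  seqs1 <- Biostrings::DNAStringSet(r1$seq)
  quals1 <- r1$qual
  if (!is.null(r2)) {
    seqs2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(r2$seq))
    quals2 <- paste(rev(.chars(r2$qual)), collapse = "")
  } else {
    seqs2 <- NULL; quals2 <- NULL
  }
  batch <- .align_batch(seqs1, quals1, seqs2, quals2, ref,
                        ids = read_id, treatment = treatment,
                        gap_opening = gap_opening,
                        gap_extension = gap_extension)
  batch$aligned[[1]]
}

## Batch core: mate sets are already in composite orientation.
.align_batch <- function(seqs1, quals1, seqs2, quals2, ref, ids, treatment,
                         gap_opening = 6, gap_extension = 1) {
  subj <- Biostrings::DNAString(ref$align_seq)
  mat <- bisulfite_matrix()
  do_align <- function(seqs) {
    Biostrings::pairwiseAlignment(seqs, subj, substitutionMatrix = mat,
                                  gapOpening = gap_opening,
                                  gapExtension = gap_extension,
                                  type = "overlap")
  }
  al1 <- do_align(seqs1)
  p1 <- as.character(Biostrings::alignedPattern(al1))
  s1 <- as.character(Biostrings::alignedSubject(al1))
  st1 <- BiocGenerics::start(Biostrings::subject(al1))
  pst1 <- BiocGenerics::start(Biostrings::pattern(al1))
  if (!is.null(seqs2)) {
    al2 <- do_align(seqs2)
    p2 <- as.character(Biostrings::alignedPattern(al2))
    s2 <- as.character(Biostrings::alignedSubject(al2))
    st2 <- BiocGenerics::start(Biostrings::subject(al2))
    pst2 <- BiocGenerics::start(Biostrings::pattern(al2))
  }
  qint <- function(q) as.integer(charToRaw(q)) - 33L
  n <- length(seqs1)
  comp <- .chars(ref$composite)
  arm_ranges <- list(
    top = seq_len(ref$arm_length) - 1L,
    linker = ref$arm_length + seq_len(ref$linker_length) - 1L,
    bottom = ref$arm_length + ref$linker_length + seq_len(ref$arm_length) - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m1 <- .column_walk(p1[i], s1[i], st1[i], qint(quals1[i]), pst1[i])
    m2 <- if (!is.null(seqs2))
      .column_walk(p2[i], s2[i], st2[i], qint(quals2[i]), pst2[i])
    merged <- .merge_mates(m1, m2)
    refc <- comp[merged$pos + 1L]
    n_cols <- length(merged$pos) + merged$n_ins
    identity <- if (n_cols > 0)
      sum(.column_matches(merged$base, refc)) / n_cols else NA_real_
    covered <- vapply(arm_ranges, function(rg)
      mean(rg %in% merged$pos) >= 0.9, logical(1))
    out[[i]] <- structure(list(
      read_id = ids[i], treatment = treatment,
      aligned_bases = stats::setNames(merged$base, merged$pos),
      n_insertions = merged$n_ins, identity = identity,
      arms_covered = names(arm_ranges)[covered]
    ), class = "aligned_read")
  }
  list(aligned = out)
}

#' Per-cytosine methylation calls of one aligned read
#'
#' Produces one call per reference cytosine of the requested contexts.
#' An observed C means the modification survived conversion (`modified`),
#' an observed T means it converted (`unmodified`), anything else —
#' including uncovered positions — is `unknown`.  CpG calls are reported
#' per strand per dyad; nonCpG calls exclude dyad positions; linker
#' control positions are called with contexts `linker_unmodC`,
#' `linker_5mC`, `linker_5hmC`.
#'
#' @param aligned An `aligned_read`.
#' @param ref The `hairpin_reference`.
#' @param contexts Subset of `c("CpG", "nonCpG", "linker")`.
#' @return Data frame with columns `read_id`, `position` (0-based
#'   composite), `strand`, `context`, `dyad_index`, `observed`, `state`.
#' @export
call_methylation <- function(aligned, ref,
                             contexts = c("CpG", "nonCpG", "linker")) {
  contexts <- match.arg(contexts, several.ok = TRUE)
  bases <- aligned$aligned_bases
  obs_at <- function(pos) {
    b <- unname(bases[as.character(pos)])
    ifelse(is.na(b), NA_character_, b)
  }
  state_of <- function(obs) {
    ifelse(is.na(obs), "unknown",
           ifelse(obs == "C", "modified",
                  ifelse(obs == "T", "unmodified", "unknown")))
  }
  rows <- list()
  if ("CpG" %in% contexts && length(ref$dyad_positions)) {
    ot <- obs_at(ref$top_c_pos); ob <- obs_at(ref$bottom_c_pos)
    rows$cpg <- data.frame(
      position = c(ref$top_c_pos, ref$bottom_c_pos),
      strand = rep(c("top", "bottom"), each = length(ref$dyad_positions)),
      context = "CpG",
      dyad_index = rep(seq_along(ref$dyad_positions), 2),
      observed = c(ot, ob), state = state_of(c(ot, ob)))
  }
  if ("nonCpG" %in% contexts) {
    pos <- c(ref$noncpg_top, ref$noncpg_bottom)
    if (length(pos)) {
      o <- obs_at(pos)
      rows$noncpg <- data.frame(
        position = pos,
        strand = rep(c("top", "bottom"),
                     c(length(ref$noncpg_top), length(ref$noncpg_bottom))),
        context = "nonCpG", dyad_index = NA_integer_,
        observed = o, state = state_of(o))
    }
  }
  if ("linker" %in% contexts && length(ref$control_composite)) {
    pos <- as.integer(names(ref$control_composite))
    ctx_map <- c(unmodC = "linker_unmodC", fivemC = "linker_5mC",
                 fivehmC = "linker_5hmC")
    o <- obs_at(pos)
    rows$linker <- data.frame(
      position = pos, strand = "linker",
      context = unname(ctx_map[unname(ref$control_composite)]),
      dyad_index = NA_integer_, observed = o, state = state_of(o))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out <- cbind(read_id = aligned$read_id, out)
  rownames(out) <- NULL
  out
}

#' Extract the UMI of an aligned read
#'
#' Concatenates the observed bases at the linker's degenerate UMI slots in
#' reference order.  Any uncovered or deleted slot makes the UMI absent
#' (`NA`); the read remains usable but is exempt from deduplication.
#'
#' @param aligned An `aligned_read`.
#' @param ref The `hairpin_reference`.
#' @return The UMI string, or `NA_character_`.
#' @export
extract_umi <- function(aligned, ref) {
  b <- unname(aligned$aligned_bases[as.character(ref$umi_composite)])
  if (anyNA(b) || any(b == "-")) return(NA_character_)
  paste(b, collapse = "")
}

#' Align a FASTQ sample against a hairpin reference
#'
#' Reads paired FASTQ files (gzip tolerated), aligns every pair with
#' [align_read_pair()] semantics in one batch, applies the identity filter
#' of the reference's repeat class (overridable), and extracts methylation
#' calls and UMIs for passing reads.  Calls for all reads are kept with a
#' per-read `pass` flag so the linker conversion-rate analysis can
#' re-filter at its relaxed 0.6 threshold.
#'
#' @param r1_path,r2_path FASTQ paths (`r2_path` may be `NULL`).
#' @param ref A `hairpin_reference`.
#' @param treatment `"BS"` or `"oxBS"`.
#' @param min_identity Identity threshold; defaults to the reference's
#'   repeat class threshold (see [identity_threshold()]).
#' @param contexts Contexts passed to [call_methylation()].
#' @return List of class `hairpin_alignment` with elements `reads` (data
#'   frame: `read_id`, `identity`, `arms`, `umi`, `n_calls`, `pass`),
#'   `calls` (all reads' calls joined), `treatment`, `min_identity`,
#'   `n_unalignable`.
#' @export
align_sample <- function(r1_path, r2_path = NULL, ref,
                         treatment = c("BS", "oxBS"), min_identity = NULL,
                         contexts = c("CpG", "nonCpG", "linker")) {
  treatment <- match.arg(treatment)
  if (is.null(min_identity))
    min_identity <- identity_threshold(ref$repeat_class)
  f1 <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(r1_path))
  ids <- sub("\\s.*$", "", names(f1))
  quals1 <- as.character(Biostrings::quality(f1))
  seqs1 <- suppressWarnings(Biostrings::DNAStringSet(f1))
  names(seqs1) <- NULL
  if (!is.null(r2_path)) {
    f2 <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(r2_path))
    if (length(f2) != length(f1))
      stop("mate files have different read counts")
    seqs2 <- Biostrings::reverseComplement(
      suppressWarnings(Biostrings::DNAStringSet(f2)))
    names(seqs2) <- NULL
    quals2 <- vapply(as.character(Biostrings::quality(f2)),
                     function(q) paste(rev(.chars(q)), collapse = ""), "",
                     USE.NAMES = FALSE)
  } else {
    seqs2 <- NULL; quals2 <- NULL
  }
  batch <- .align_batch(seqs1, quals1, seqs2, quals2, ref, ids, treatment)
  aligned <- batch$aligned
  calls_list <- lapply(aligned, call_methylation, ref = ref,
                       contexts = contexts)
  umis <- vapply(aligned, extract_umi, NA_character_, ref = ref)
  identity <- vapply(aligned, function(a) a$identity, numeric(1))
  reads <- data.frame(
    read_id = ids, identity = identity,
    arms = vapply(aligned, function(a)
      paste(a$arms_covered, collapse = ","), ""),
    umi = umis,
    n_calls = vapply(calls_list, nrow, integer(1)),
    pass = !is.na(identity) & identity >= min_identity,
    stringsAsFactors = FALSE)
  calls <- do.call(rbind, calls_list)
  structure(list(reads = reads, calls = calls, treatment = treatment,
                 amplicon_id = ref$amplicon_id,
                 min_identity = min_identity,
                 n_unalignable = sum(is.na(identity))),
            class = "hairpin_alignment")
}

#' Linker control calls of reads passing the relaxed identity filter
#'
#' @param alignment A `hairpin_alignment`.
#' @param min_identity Relaxed threshold, default
#'   `identity_threshold("linker")`.
#' @return Data frame of linker-context calls.
#' @export
linker_calls <- function(alignment, min_identity = identity_threshold("linker")) {
  keep_ids <- alignment$reads$read_id[
    !is.na(alignment$reads$identity) &
      alignment$reads$identity >= min_identity]
  calls <- alignment$calls
  calls[calls$read_id %in% keep_ids &
          startsWith(calls$context, "linker"), , drop = FALSE]
}
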