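## Composite hairpin reference. All public coordinates are 0-based offsets
## into the composite sequence top + linker + reverse(bottom), where
## `bottom` stores the Crick-strand bases in Watson (top) coordinates so
## that position i of top pairs with position i of bottom. Dyads are
## indexed by the top-strand C offset.

.complement_chr <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

.revcomp_chr <- function(x) {
  paste(rev(strsplit(.complement_chr(x), "")[[1]]), collapse = "")
}

.chars <- function(x) strsplit(x, "")[[1]]

#' Hairpin linker specification
#'
#' A linker is a DNA string over `{A,C,G,T,D}` where `D` marks a degenerate
#' UMI slot (filled with A, T or G in each molecule), plus an annotation of
#' control cytosines: positions (0-based within the linker) carrying an
#' unmodified C (`unmodC`), a 5mC (`fivemC`) or a 5hmC (`fivehmC`) base.
#'
#' @param seq Linker sequence (uppercase, `D` at UMI slots).
#' @param controls Named character vector: names are 0-based linker
#'   positions, values in `c("unmodC", "fivemC", "fivehmC")`.
#' @return List of class `linker_spec`.
#' @export
linker_spec <- function(seq, controls) {
  seq <- toupper(seq)
  if (!grepl("^[ACGTD]+$", seq)) stop("linker sequence must be over ACGTD")
  pos <- as.integer(names(controls))
  if (anyNA(pos) || any(pos < 0) || any(pos >= nchar(seq)))
    stop("control positions must be 0-based offsets within the linker")
  if (!all(controls %in% c("unmodC", "fivemC", "fivehmC")))
    stop("control roles must be unmodC, fivemC or fivehmC")
  ch <- .chars(seq)
  if (any(ch[pos + 1L] != "C"))
    stop("annotated control positions must carry a C in the linker sequence")
  structure(list(seq = seq,
                 controls = stats::setNames(as.character(controls), pos),
                 umi_positions = which(ch == "D") - 1L),
            class = "linker_spec")
}

#' Default hairpin linker
#'
#' A compact linker with one unmodified-C, one 5mC and one 5hmC control in
#' the stem-adjacent segments and a degenerate loop of `umi_length` UMI
#' slots.  The default UMI length of 12 keeps the collision probability of
#' two independent molecules sharing a UMI below ~0.2% per pair at typical
#' simulated depths (3^12 = 531441 distinct UMIs).
#'
#' @param umi_length Number of degenerate `D` slots in the loop.
#' @return A [linker_spec()].
#' @export
default_linker <- function(umi_length = 12) {
  left <- "GTCATGACTGACTGACTG"        # controls at 0-based 7, 11, 15
  right <- "AGTGATG"
  linker_spec(paste0(left, strrep("D", umi_length), right),
              controls = c(`7` = "unmodC", `11` = "fivemC", `15` = "fivehmC"))
}

#' Build a composite hairpin amplicon reference
#'
#' Assembles the composite reference `top + linker + reverse(bottom)` in
#' read orientation, locates the CpG dyads, and prepares the alignment
#' variant of the composite in which non-control linker cytosines are
#' replaced by T (they are unmodified and always convert) while genomic
#' cytosines are kept (the aligner scores read-T against reference-C as a
#' conversion-eligible match).
#'
#' @param top_seq Watson-arm sequence, 5'->3'.
#' @param bottom_seq Crick-strand bases in Watson coordinates (position i
#'   pairs with `top_seq` position i).  Defaults to the complement of
#'   `top_seq`.
#' @param linker A [linker_spec()].
#' @param amplicon_id Amplicon name.
#' @param repeat_class `"single_copy"` or `"repetitive"`; selects the
#'   default identity threshold (0.9 vs 0.8).
#' @param restriction_overhang Overhang sequence of the restriction site
#'   used for ligation; a CpG inside it triggers a warning (dyads in the
#'   overhang are distorted by linker ligation).
#' @param snp_positions 0-based top offsets where the two arms may
#'   legitimately disagree.
#' @return List of class `hairpin_reference`.
#' @export
build_reference <- function(top_seq, bottom_seq = NULL, linker = default_linker(),
                            amplicon_id = "amplicon",
                            repeat_class = c("single_copy", "repetitive"),
                            restriction_overhang = "",
                            snp_positions = integer()) {
  repeat_class <- match.arg(repeat_class)
  top_seq <- toupper(top_seq)
  if (!grepl("^[ACGTN]+$", top_seq)) stop("top_seq must be over ACGTN")
  if (is.null(bottom_seq)) bottom_seq <- .complement_chr(top_seq)
  bottom_seq <- toupper(bottom_seq)
  if (nchar(bottom_seq) != nchar(top_seq))
    stop("top and bottom arms must have equal length")
  tc <- .chars(top_seq); bc <- .chars(bottom_seq)
  mism <- which(tc != .chars(.complement_chr(bottom_seq)) &
                  tc != "N" & bc != "N") - 1L
  undeclared <- setdiff(mism, as.integer(snp_positions))
  if (length(undeclared))
    stop("arms are not complementary at 0-based position(s) ",
         paste(undeclared, collapse = ", "),
         " and no SNP is declared there")
  if (nchar(restriction_overhang) > 0 &&
      grepl("CG", toupper(restriction_overhang)))
    warning("restriction overhang contains a CpG; dyads within the ",
            "restriction site cannot be analysed reliably")

  n <- nchar(top_seq)
  ## dyads: C at p, G at p+1 on top with complementary CpG on the bottom arm
  dyads <- integer(0)
  for (p in seq_len(n - 1L) - 1L) {
    if (tc[p + 1L] == "C" && tc[p + 2L] == "G" &&
        bc[p + 1L] == "G" && bc[p + 2L] == "C")
      dyads <- c(dyads, p)
  }

  lnk <- linker
  stopifnot(inherits(lnk, "linker_spec"))
  llen <- nchar(lnk$seq)
  composite <- paste0(top_seq, lnk$seq,
                      paste(rev(bc), collapse = ""))

  ## alignment variant: non-control linker C -> T
  lch <- .chars(lnk$seq)
  ctrl_pos <- as.integer(names(lnk$controls))
  conv <- lch
  conv[conv == "C" & !(seq_along(conv) - 1L) %in% ctrl_pos] <- "T"
  align_seq <- paste0(top_seq, paste(conv, collapse = ""),
                      paste(rev(bc), collapse = ""))

  ## composite coordinates
  off <- n + llen
  bottom_c_pos <- off + (n - 1L - (dyads + 1L))   # Crick C pairs the top G
  ctrl_comp <- n + ctrl_pos
  umi_comp <- n + lnk$umi_positions
  ## non-CpG cytosines: top-arm Cs outside dyad Cs; bottom-arm composite
  ## positions holding a Crick C outside dyad bottom Cs
  top_c_all <- which(tc == "C") - 1L
  noncpg_top <- setdiff(top_c_all, dyads)
  comp_ch <- .chars(composite)
  bottom_range <- off + seq_len(n) - 1L
  bottom_c_all <- bottom_range[comp_ch[bottom_range + 1L] == "C"]
  noncpg_bottom <- setdiff(bottom_c_all, bottom_c_pos)

  structure(list(
    amplicon_id = amplicon_id,
    top_seq = top_seq, bottom_seq = bottom_seq,
    linker_seq = lnk$seq,
    control_annotation = lnk$controls,
    umi_positions = lnk$umi_positions,
    dyad_positions = dyads,
    repeat_class = repeat_class,
    restriction_overhang = toupper(restriction_overhang),
    snp_positions = as.integer(snp_positions),
    arm_length = n, linker_length = llen,
    composite = composite, align_seq = align_seq,
    top_c_pos = dyads, bottom_c_pos = bottom_c_pos,
    control_composite = stats::setNames(as.character(lnk$controls), ctrl_comp),
    umi_composite = umi_comp,
    noncpg_top = noncpg_top, noncpg_bottom = noncpg_bottom
  ), class = "hairpin_reference")
}

#' @export
print.hairpin_reference <- function(x, ...) {
  cat("Hairpin reference", x$amplicon_id, sprintf("(%s)\n", x$repeat_class))
  cat("  arm:", x$arm_length, "bp; linker:", x$linker_length,
      "bp; composite:", nchar(x$composite), "bp\n")
  cat("  dyads at top offsets:", paste(x$dyad_positions, collapse = ", "), "\n")
  cat("  UMI slots:", length(x$umi_positions),
      " controls:", paste(unname(x$control_annotation), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic amplicon reference for testing and simulation
#'
#' Draws a random Watson arm with `n_dyads` CpG sites at roughly even
#' spacing and no other CpG dinucleotides, pairs it with its complement,
#' and attaches the [default_linker()].
#'
#' @param n_dyads Number of CpG dyads.
#' @param arm_length Arm length in bp.
#' @param umi_length UMI slots in the linker loop.
#' @param amplicon_id,repeat_class Passed to [build_reference()].
#' @param seed Integer seed (mandatory; the reference is deterministic
#'   given the seed).
#' @return A `hairpin_reference`.
#' @export
make_test_reference <- function(n_dyads = 4, arm_length = 60, umi_length = 12,
                                amplicon_id = "synth1",
                                repeat_class = "single_copy", seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  repeat {
    arm <- sample(c("A", "C", "G", "T"), arm_length, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
    ## scrub accidental CpGs
    for (i in seq_len(arm_length - 1L)) {
      if (arm[i] == "C" && arm[i + 1L] == "G") arm[i + 1L] <- "A"
    }
    ## place dyads at even spacing, away from the ends
    pos <- round(seq(4, arm_length - 5, length.out = n_dyads))
    ok <- TRUE
    for (p in pos) {
      arm[p + 1L] <- "C"; arm[p + 2L] <- "G"
      ## avoid creating an extra CpG with the preceding base
      if (p >= 1 && arm[p] == "C") arm[p] <- "A"
      if (p + 3L <= arm_length && arm[p + 3L] == "G") arm[p + 3L] <- "T"
    }
    top <- paste(arm, collapse = "")
    ref <- build_reference(top, linker = default_linker(umi_length),
                           amplicon_id = amplicon_id,
                           repeat_class = repeat_class)
    if (length(ref$dyad_positions) == n_dyads && ok) return(ref)
  }
}

#' Write / read a hairpin reference as FASTA plus annotation TSV
#'
#' The FASTA stores three records (`<id>|top`, `<id>|bottom`, `<id>|linker`);
#' the sidecar TSV lists one row per annotated position with columns
#' `position` (0-based composite offset; for `dyad` rows the top-strand C
#' offset), `role` in `{dyad, unmodC, 5mC, 5hmC, UMI, SNP}`.  Header
#' comment lines carry `amplicon_id`, `repeat_class` and
#' `restriction_overhang`.
#'
#' @param ref A `hairpin_reference`.
#' @param fasta_path,annot_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta_path, annot_path) {
  seqs <- Biostrings::DNAStringSet(c(ref$top_seq, ref$bottom_seq,
                                     chartr("D", "N", ref$linker_seq)))
  names(seqs) <- paste0(ref$amplicon_id, "|", c("top", "bottom", "linker"))
  Biostrings::writeXStringSet(seqs, fasta_path)
  role_map <- c(unmodC = "unmodC", fivemC = "5mC", fivehmC = "5hmC")
  ann <- rbind(
    data.frame(position = ref$dyad_positions, role = "dyad"),
    data.frame(position = as.integer(names(ref$control_composite)),
               role = unname(role_map[ref$control_annotation])),
    data.frame(position = ref$umi_composite, role = "UMI"),
    if (length(ref$snp_positions))
      data.frame(position = ref$snp_positions, role = "SNP"))
  con <- file(annot_path, "w")
  writeLines(c(paste0("# amplicon_id=", ref$amplicon_id),
               paste0("# repeat_class=", ref$repeat_class),
               paste0("# restriction_overhang=", ref$restriction_overhang),
               "position\trole"), con)
  utils::write.table(ann, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(c(fasta_path, annot_path))
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta_path, annot_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- sub("\\|.*$", "", names(seqs))
  part <- sub("^.*\\|", "", names(seqs))
  id <- unique(nm)
  if (length(id) != 1) stop("reference FASTA must describe one amplicon")
  hdr <- readLines(annot_path)
  meta <- hdr[startsWith(hdr, "#")]
  getmeta <- function(key, default = "") {
    line <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (!length(line)) return(default)
    sub(paste0("^# ", key, "="), "", line[1])
  }
  ann <- utils::read.delim(annot_path, comment.char = "#")
  lnk_seq <- as.character(seqs[[which(part == "linker")]])
  top <- as.character(seqs[[which(part == "top")]])
  umi_lnk <- sort(ann$position[ann$role == "UMI"]) - nchar(top)
  ctrl <- ann[ann$role %in% c("unmodC", "5mC", "5hmC"), ]
  role_map <- c(unmodC = "unmodC", `5mC` = "fivemC", `5hmC` = "fivehmC")
  lch <- .chars(lnk_seq)
  lch[umi_lnk + 1L] <- "D"
  lnk <- linker_spec(paste(lch, collapse = ""),
                     stats::setNames(unname(role_map[ctrl$role]),
                                     ctrl$position - nchar(top)))
  build_reference(top, as.character(seqs[[which(part == "bottom")]]),
                  linker = lnk, amplicon_id = getmeta("amplicon_id", id),
                  repeat_class = getmeta("repeat_class", "single_copy"),
                  restriction_overhang = getmeta("restriction_overhang"),
                  snp_positions = sort(ann$position[ann$role == "SNP"]))
}
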