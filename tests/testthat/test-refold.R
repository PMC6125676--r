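test_that("refold pairs strand states into dyad classes", {
  top <- c("modified", "modified", "unmodified", "unmodified", "unknown",
           "modified")
  bot <- c("modified", "unmodified", "modified", "unmodified", "modified",
           "unknown")
  expect_identical(refold(top, bot),
                   c("both", "hemi_top", "hemi_bottom", "unmod",
                     "unknown", "unknown"))
  expect_error(refold(top, bot[-1]), "equal length")
})

test_that("swapping strands maps hemi classes and fixes both/unmod", {
  states <- c("modified", "unmodified", "unknown")
  set.seed(13)
  for (i in 1:20) {
    top <- sample(states, 8, replace = TRUE)
    bot <- sample(states, 8, replace = TRUE)
    fwd <- refold(top, bot)
    swp <- refold(bot, top)
    map <- c(both = "both", hemi_top = "hemi_bottom",
             hemi_bottom = "hemi_top", unmod = "unmod",
             unknown = "unknown")
    expect_identical(swp, unname(map[fwd]))
  }
})

test_that("UMI groups collapse to a per-dyad majority consensus", {
  cls <- rbind(c("both", "both"), c("both", "unmod"), c("both", "both"),
               c("unmod", "unmod"),
               c("hemi_top", "both"))
  p <- dyad_patterns(cls, umi = c("AAA", "AAA", "AAA", "TTT", NA))
  d <- dedup_umis(p)
  ## 1 consensus molecule + 1 singleton UMI + 1 UMI-absent read
  expect_equal(nrow(d$classes), 3L)
  grp <- d$classes[d$info$umi %in% "AAA" & !is.na(d$info$umi), ,
                   drop = FALSE]
  expect_identical(unname(grp[1, ]), c("both", "both"))
  expect_equal(d$info$source_read_count[d$info$umi %in% "AAA"][1], 3L)
  ## tie between two classes gives unknown
  tie <- dyad_patterns(rbind(c("both", "both"), c("unmod", "both")),
                       umi = c("GGG", "GGG"))
  dt <- dedup_umis(tie)
  expect_identical(unname(dt$classes[1, ]), c("unknown", "both"))
})

test_that("deduplication is idempotent and preserves molecule accounting", {
  set.seed(23)
  n <- 40
  cls <- matrix(sample(c("both", "hemi_top", "hemi_bottom", "unmod",
                         "unknown"), n * 3, replace = TRUE), nrow = n)
  umis <- sample(c("AAA", "ATG", "GGT", "TTT", NA), n, replace = TRUE)
  p <- dyad_patterns(cls, umi = umis)
  d1 <- dedup_umis(p)
  expect_equal(nrow(d1$classes),
               length(unique(umis[!is.na(umis)])) + sum(is.na(umis)))
  d2 <- dedup_umis(d1)
  expect_identical(d2$classes, d1$classes)
  expect_identical(d2$info$umi, d1$info$umi)
  ## distinct UMIs never collapse
  q <- dyad_patterns(cls[1:4, ], umi = c("AAA", "AAT", "ATA", "TAA"))
  expect_equal(nrow(dedup_umis(q)$classes), 4L)
})

test_that("pattern summaries normalise over analysable molecules", {
  all_both <- dyad_patterns(matrix("both", 6, 3))
  s <- summarize_patterns(all_both)
  expect_true(all(s$per_dyad$both == 1))
  expect_equal(unname(s$mean["both"]), 1)
  expect_equal(s$level, 1)
  half <- dyad_patterns(matrix(rep(c("both", "unmod"), each = 3,
                                   times = 2), ncol = 2))
  s2 <- summarize_patterns(half)
  expect_equal(unname(s2$mean[c("both", "unmod")]), c(0.5, 0.5))
  expect_equal(s2$level, 0.5)
  ## frequencies sum to one at every covered dyad
  set.seed(5)
  rnd <- dyad_patterns(matrix(sample(c("both", "hemi_top", "hemi_bottom",
                                       "unmod", "unknown"), 60,
                                     replace = TRUE), ncol = 3))
  s3 <- summarize_patterns(rnd)
  sums <- rowSums(s3$per_dyad[c("both", "hemi_top", "hemi_bottom",
                                "unmod")])
  expect_true(all(abs(sums - 1) < 1e-12))
  ## a dyad with no analysable molecule is flagged
  blank <- dyad_patterns(cbind(rep("unknown", 4), rep("both", 4)))
  expect_warning(s4 <- summarize_patterns(blank), "without analysable")
  expect_true(is.na(s4$per_dyad$both[1]))
})

test_that("pattern maps have the documented geometry and colours", {
  p <- dyad_patterns(matrix("both", 10, 4))
  path <- tempfile(fileext = ".png")
  dims <- write_pattern_map(p, path, cell = 2)
  expect_equal(dims, list(rows = 10, cols = 5))
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], c(20L, 10L))
  ## every non-leading cell is the 'both' red
  body <- img[, 3:10, ]
  expect_true(all(abs(body[, , 1] - 0.8) < 0.01))
  expect_true(all(body[, , 2] < 0.01))
  ## unknown renders white
  p2 <- dyad_patterns(matrix("unknown", 3, 2))
  path2 <- tempfile(fileext = ".png")
  write_pattern_map(p2, path2, cell = 1)
  img2 <- png::readPNG(path2)
  expect_true(all(img2[, 2:3, ] > 0.99))
  expect_error(write_pattern_map(dyad_patterns(
    matrix(character(0), 0, 2)), tempfile()), "zero molecules")
})

test_that("molecule and summary tables are written with stable schemas", {
  p1 <- dyad_patterns(matrix("both", 5, 2), umi = rep(NA, 5))
  p2 <- dyad_patterns(matrix(c("unmod", "hemi_top"), 4, 2), treatment = "oxBS")
  pats <- list(a = p1, b = p2)
  sums <- lapply(pats, summarize_patterns)
  prefix <- file.path(tempdir(), "tabtest")
  paths <- write_tables(pats, sums, prefix)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  mol <- read.delim(paths[1])
  expect_equal(nrow(mol), 5L)
  expect_true(all(c("molecule_id", "umi", "treatment", "source_read_count",
                    "nonCpG_rate", "dyad_1", "dyad_2") %in% names(mol)))
  smry <- read.delim(paths[3])
  ## per-dyad rows plus one mean row per sample
  expect_equal(nrow(smry), 2 * (2 + 1))
  expect_setequal(unique(smry$sample), c("a", "b"))
})

test_that("pattern counts map dyad classes onto read classes", {
  p <- dyad_patterns(rbind(c("both", "hemi_top"),
                           c("hemi_bottom", "unmod"),
                           c("unknown", "both")))
  expect_equal(pattern_counts(p),
               stats::setNames(c(2L, 1L, 1L, 1L), read_classes()))
})
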