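test_that("the assay probe duplexes classify to their named element classes", {
  cl <- classify_ebox(probe_oligos())
  expect_equal(as.character(cl$class), c("TCACGTGA", "TCATGTGA", "TCATGTGB"))
})

test_that("minus-strand cores are found and classified", {
  # brute-force oracle: the reverse complement contains TCATGTGA
  s <- "GGTCACATGAGG"
  rc <- paste(rev(strsplit("GGTCACATGAGG", "")[[1]]), collapse = "")
  rc <- chartr("ACGT", "TGCA", rc)
  expect_true(grepl("TCATGTGA", rc, fixed = TRUE))
  cl <- classify_ebox(s)
  expect_equal(as.character(cl$class), "TCATGTGA")
  expect_equal(cl$strand, "-")
})

test_that("sequences without any core are class none; bad characters error", {
  expect_equal(as.character(classify_ebox("GGGGGAAAATTTTCCCC")$class), "none")
  expect_error(classify_ebox("ACGTX"), "A, C, G, T or N")
  # N never completes a core or a flank
  expect_equal(as.character(classify_ebox("TCANGTGA")$class), "none")
  expect_equal(as.character(classify_ebox("TCACGTGN")$class), "CACGTG_other")
})

test_that("edge cores lacking a flank fall to the _other class", {
  expect_equal(as.character(classify_ebox("CACGTGAGG")$class), "CACGTG_other")
  expect_equal(as.character(classify_ebox("GGACATGTG")$class), "CATGTG_other")
})

test_that("priority picks the highest class among multiple cores", {
  s <- paste0("AAAA", "ACATGTGC", "AAAA", "TCACGTGA", "AAAA")
  expect_equal(as.character(classify_ebox(s)$class), "TCACGTGA")
})

test_that("classification is strand-symmetric for arbitrary sequences", {
  seqs <- withr::with_seed(71, vapply(1:200, function(i) {
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  }, character(1)))
  rc <- vapply(strsplit(seqs, ""), function(ch)
    chartr("ACGT", "TGCA", paste(rev(ch), collapse = "")), character(1))
  expect_equal(as.character(classify_ebox(seqs)$class),
               as.character(classify_ebox(rc)$class))
})

test_that("single-class peak sets classify uniformly, on either strand", {
  ps <- simulate_peakset(50, c(TCACGTGA = 1), seed = 72)
  cl <- classify_ebox(ps$seq)
  expect_true(all(cl$class == "TCACGTGA"))
  expect_true(all(c("+", "-") %in% ps$strand))  # both strands get planted
})

test_that("planted class proportions are recovered within binomial error", {
  ps <- simulate_peakset(2000, c(TCACGTGA = 0.5, TCATGTGA = 0.5), seed = 73)
  cl <- classify_ebox(ps$seq)
  # zero confusion between planted and assigned classes
  expect_equal(as.character(cl$class), ps$class_true)
  p_hat <- mean(cl$class == "TCACGTGA")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("ratio tables sum to one per condition and ignore peak order", {
  ps <- simulate_peakset(300, c(TCACGTGA = 0.4, TCATGTGB = 0.3, none = 0.3),
                         seed = 74)
  cl <- as.character(classify_ebox(ps$seq)$class)
  tab <- motif_ratio_table(cl, condition = "wt")
  expect_equal(sum(tab$proportion), 1)
  shuf <- withr::with_seed(75, sample(seq_along(cl)))
  tab2 <- motif_ratio_table(cl[shuf], condition = "wt")
  expect_equal(tab2$proportion, tab$proportion)
})

test_that("moving-average incidence follows the windowed-mean oracle", {
  # constant incidence gives a flat line at 1
  flat <- motif_incidence_moving_avg(scores = 200:1,
                                     classes = rep("TCACGTGA", 200),
                                     target_classes = "TCACGTGA",
                                     window = 100)
  expect_true(all(flat$moving_avg == 1))
  expect_equal(nrow(flat), 200)

  # step incidence: top-100 peaks hit, bottom-100 miss
  cls <- c(rep("TCACGTGA", 100), rep("none", 100))
  step <- motif_incidence_moving_avg(scores = 200:1, classes = cls,
                                     target_classes = "TCACGTGA",
                                     window = 100)
  expect_equal(step$moving_avg[100], 0.5, tolerance = 0.011)
  expect_equal(step$moving_avg[1], 1)  # truncated edge window is all hits
  expect_error(motif_incidence_moving_avg(200:1, cls, "TCACGTGA", window = 1),
               "window")
})

test_that("peak sets round-trip through the BED6 + FASTA pair", {
  ps <- simulate_peakset(30, c(TCACGTGB = 0.6, none = 0.4), seed = 76)
  bed <- tempfile(fileext = ".bed"); fa <- tempfile(fileext = ".fa")
  write_peaks(ps, bed, fa)
  back <- read_peaks(bed, fa)
  expect_equal(back$seq, ps$seq)
  expect_equal(back$score, ps$score, tolerance = 1e-6)
  expect_equal(back$start, ps$start)
})

test_that("genome-mode reading extracts 0-based half-open intervals", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrT", "AAAATCACGTGATTTT"), fa)
  bed <- tempfile(fileext = ".bed")
  writeLines("chrT\t3\t13\tp1\t5\t.", bed)
  pk <- read_peaks(bed, fa, genome = TRUE)
  expect_equal(pk$seq, "ATCACGTGAT")
  expect_equal(as.character(classify_ebox(pk$seq)$class), "TCACGTGA")
})
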