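make_locus <- function(seed, n = 300, fix_after = integer(0)) {
  set.seed(seed)
  s <- random_seq(n)
  # guarantee junction recoverability where requested (no G after junction)
  for (j in fix_after) substr(s, j + 2, j + 2) <- "A"
  s
}

test_that("telomere seed motifs are reverse complements of each other", {
  m <- telomere_motifs()
  expect_identical(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(m$plus_seed))),
    m$minus_seed)
})

test_that("reads are assigned by longest exact match against either locus", {
  target <- make_locus(1)
  control <- make_locus(2)
  reads <- c(
    ctrl = substring(control, 50, 199),                      # 150-mer, exact
    tgt = paste0(substring(target, 101, 140), "GGGTGTGGGTGTGG"),
    ctrl_rc = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substring(control, 10, 80)))),   # minus strand
    junk = strrep("ACT", 20))
  asn <- assign_reads(reads, target, control, min_match = 30)
  expect_setequal(asn$control, c("ctrl", "ctrl_rc"))
  expect_equal(asn$target, "tgt")
  expect_equal(asn$unassigned, "junk")
  # a read matching both goes with the longer match
  both <- c(x = paste0(substring(control, 1, 35), substring(target, 101, 180)))
  asn2 <- assign_reads(both, target, control, min_match = 30)
  expect_equal(asn2$target, "x")
  # empty input
  asn0 <- assign_reads(character(0), target, control)
  expect_length(asn0$target, 0)
})

test_that("junction calling maps the last aligned base on the TG-rich strand", {
  target <- make_locus(3, fix_after = 139)
  read <- paste0(substring(target, 101, 140), "GGGTGTGGGTGTGG")
  ev <- detect_telomere_addition(read, target)
  expect_equal(ev$junction, 139L)
  expect_equal(ev$orientation, "plus")
  expect_equal(ev$tail_length, 14L)
  # strand symmetry: the reverse complement read yields the same junction
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  ev2 <- detect_telomere_addition(rc, target)
  expect_equal(ev2$junction, 139L)
  expect_equal(ev2$orientation, "minus")
  expect_equal(ev2$tail_length, 14L)
  # a pure target subsequence carries no event
  expect_null(detect_telomere_addition(substring(target, 101, 200), target))
})

test_that("seed motifs inside the target-matching segment are not events", {
  # target that itself contains the seed (a TG-rich hotspot core)
  target <- paste0(make_locus(4, 140), "GGGTGTGG", make_locus(5, 152))
  stopifnot(nchar(target) == 300)
  inside <- substring(target, 121, 200)  # covers the embedded seed, no tail
  expect_null(detect_telomere_addition(inside, target))
  # with a non-telomeric tail: strict rule still refuses, lenient accepts
  tailed <- paste0(substring(target, 121, 200), strrep("ACT", 4))
  expect_null(detect_telomere_addition(tailed, target))
  lenient <- detect_telomere_addition(tailed, target,
                                      require_tail_outside = FALSE)
  expect_equal(lenient$junction, 199L)
})

test_that("summaries normalize to control depth and profile junctions", {
  ev <- data.frame(junction = c(139, 139, 139, 200),
                   tail_length = 20, orientation = "plus")
  s <- summarize_ptseq(ev, n_target_reads = 10, n_control_reads = 1000)
  expect_equal(s$normalized_pct, 0.4)
  expect_equal(s$junction_profile$fraction, c(0.75, 0.25))
  expect_equal(sum(s$junction_profile$fraction), 1)
  s2 <- summarize_ptseq(ev[1:2, ], 1000, 100)
  expect_equal(s2$normalized_pct, 2)
  expect_error(summarize_ptseq(ev, 10, 0),
               class = "sirtascan_validation_error")
  expect_error(summarize_ptseq(ev, 2, 100),
               class = "sirtascan_validation_error")
  empty <- summarize_ptseq(NULL, 5, 100)
  expect_equal(empty$normalized_pct, 0)
})

test_that("standard curves calibrate and clamp; activity cutoff is strict", {
  vii <- standard_curve("chrVII")
  expect_equal(apply_standard_curve(10, vii), 3.961 * 10 - 2.039)
  expect_equal(apply_standard_curve(0, vii), 0)    # clamped from -2.039
  expect_equal(apply_standard_curve(1000, vii), 100)
  ix <- standard_curve("chrIX")
  expect_equal(ix$slope, 3.8022)
  expect_equal(ix$intercept, -0.5505)
  custom <- standard_curve(2, 1)
  expect_equal(apply_standard_curve(3, custom), 7)
  expect_error(standard_curve(-1, 0), class = "sirtascan_validation_error")
  expect_error(apply_standard_curve(-2, vii),
               class = "sirtascan_validation_error")
  expect_equal(classify_active(c(80.5, 2.3, 6.6)), c(TRUE, FALSE, FALSE))
  expect_true(classify_active(6.7))
})

test_that("planted junctions are recovered exactly with no spurious calls", {
  target <- make_locus(6, fix_after = c(120, 199, 250))
  control <- make_locus(7)
  sim <- simulate_ptseq_reads(target, control,
                              junctions = c(120, 199, 250),
                              counts = c(4, 2, 1), n_control = 700,
                              read_length = 100, tail_length = 30, seed = 31)
  s <- ptseq_quantify(sim$reads, target, control)
  expect_equal(s$n_control_reads, 700L)
  expect_equal(s$n_telomere_reads, 7L)
  expect_equal(s$junction_profile$junction, c(120L, 199L, 250L))
  expect_equal(s$junction_profile$n_reads, c(4L, 2L, 1L))
  expect_equal(s$normalized_pct, 100 * 7 / 700)
  # per-read truth: every event read is recovered at its planted junction
  truth <- sim$truth[!is.na(sim$truth$junction), ]
  got <- setNames(s$events$junction, s$events$read_id)
  expect_setequal(names(got), truth$read_id)
  expect_equal(unname(got[truth$read_id]), truth$junction)
})

test_that("normalized percentage is duplication-invariant and monotone", {
  target <- make_locus(8, fix_after = 150)
  control <- make_locus(9)
  sim <- simulate_ptseq_reads(target, control, junctions = 150, counts = 5,
                              n_control = 500, seed = 41)
  s1 <- ptseq_quantify(sim$reads, target, control)
  dup <- c(sim$reads, setNames(sim$reads, paste0(names(sim$reads), "_dup")))
  s2 <- ptseq_quantify(dup, target, control)
  expect_equal(s2$normalized_pct, s1$normalized_pct)
  expect_equal(s2$junction_profile$fraction, s1$junction_profile$fraction)
  # more planted events at fixed control depth -> strictly larger pct
  sim3 <- simulate_ptseq_reads(target, control, junctions = 150, counts = 9,
                               n_control = 500, seed = 41)
  s3 <- ptseq_quantify(sim3$reads, target, control)
  expect_gt(s3$normalized_pct, s1$normalized_pct)
})

test_that("minus-orientation reads give identical junctions, flipped label", {
  target <- make_locus(10, fix_after = 180)
  control <- make_locus(11)
  plus <- simulate_ptseq_reads(target, control, junctions = 180, counts = 3,
                               n_control = 100, seed = 51)
  minus <- simulate_ptseq_reads(target, control, junctions = 180, counts = 3,
                                orientations = "minus", n_control = 100,
                                seed = 51)
  sp <- ptseq_quantify(plus$reads, target, control)
  sm <- ptseq_quantify(minus$reads, target, control)
  expect_equal(sm$junction_profile, sp$junction_profile)
  expect_true(all(sp$events$orientation == "plus"))
  expect_true(all(sm$events$orientation == "minus"))
})

test_that("degenerate (seedless) tails are never called as events", {
  target <- make_locus(12, fix_after = 150)
  control <- make_locus(13)
  sim <- simulate_ptseq_reads(target, control, junctions = 150, counts = 5,
                              n_control = 200, degenerate_tail = TRUE,
                              seed = 61)
  s <- ptseq_quantify(sim$reads, target, control)
  expect_equal(s$n_telomere_reads, 0L)
  expect_equal(s$normalized_pct, 0)
})

test_that("efficiency calibration plugs into the quantifier", {
  target <- make_locus(14, fix_after = 150)
  control <- make_locus(15)
  sim <- simulate_ptseq_reads(target, control, junctions = 150, counts = 30,
                              n_control = 1000, seed = 71)
  s <- ptseq_quantify(sim$reads, target, control,
                      curve = standard_curve("chrVII"))
  expect_equal(s$efficiency_pct,
               max(0, min(100, 3.961 * s$normalized_pct - 2.039)))
  expect_identical(s$active, s$efficiency_pct > 6.6)
})

test_that("read sets can be recovered from SAM/BAM alignments", {
  target <- make_locus(16, fix_after = 139)
  control <- make_locus(17)
  tread <- paste0(substring(target, 101, 140), "GGGTGTGGGTGTGG")
  cread <- substring(control, 21, 120)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:target\tLN:300",
    "@SQ\tSN:control\tLN:300",
    paste("r1", 0, "target", 101, 60, "40M14S", "*", 0, 0, tread,
          strrep("I", nchar(tread)), sep = "\t"),
    paste("r2", 0, "control", 21, 60, "100M", "*", 0, 0, cread,
          strrep("I", nchar(cread)), sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, strrep("ACT", 20),
          strrep("I", 60), sep = "\t")), sam)
  sets <- ptseq_reads_from_bam(sam, "target", "control", min_match = 30)
  expect_equal(names(sets$target), "r1")
  expect_equal(names(sets$control), "r2")
  ev <- detect_telomere_addition(as.character(sets$target[[1]]), target)
  expect_equal(ev$junction, 139L)
})
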