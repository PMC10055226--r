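toy_layout <- function(len = 10000, cen = c(4999, 5001), chrom = "chrI", ...) {
  genome_layout(data.frame(chrom = chrom, length = len,
                           analysis_start = 0, analysis_end = len,
                           cen_start = cen[1], cen_end = cen[2]), ...)
}

test_that("layout construction validates bounds and landmark intervals", {
  expect_s3_class(toy_layout(), "genome_layout")
  expect_error(genome_layout(data.frame(chrom = "c", length = 100,
                                        analysis_start = 0, analysis_end = 200,
                                        cen_start = 10, cen_end = 20)),
               class = "sirtascan_validation_error")
  expect_error(genome_layout(data.frame(chrom = "c", length = 100,
                                        analysis_start = 50, analysis_end = 50,
                                        cen_start = 10, cen_end = 20)),
               class = "sirtascan_validation_error")
  expect_error(genome_layout(data.frame(chrom = "c", length = 100,
                                        analysis_start = 20, analysis_end = 90,
                                        cen_start = 10, cen_end = 30)),
               class = "sirtascan_validation_error")  # centromere outside
  expect_error(toy_layout(subtelomeres = data.frame(chrom = "chrX",
                                                    start = 0, end = 10)),
               class = "sirtascan_validation_error")  # unknown chromosome
})

test_that("YAML layouts round-trip, including the 1-based flag", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "chromosomes:",
    "  - chrom: chrVI",
    "    length: 270161",
    "    analysis_start: 100",
    "    analysis_end: 270000",
    "    centromere: [148510, 148627]",
    "    subtelomeres:",
    "      - [100, 5000]",
    "      - [264000, 270000]",
    "    nonessential:",
    "      - [1, 40000]"), path)
  lay <- read_genome_layout(path)
  expect_equal(lay$chromosomes$number, 6L)
  expect_equal(lay$chromosomes$analysis_start, 100)
  expect_equal(nrow(lay$subtelomeres), 2L)
  expect_equal(lay$nonessential$end, 40000)
  lay1 <- read_genome_layout(path, one_based = TRUE)
  expect_equal(lay1$chromosomes$analysis_start, 99)
  expect_equal(lay1$chromosomes$analysis_end, 270000)
  expect_equal(lay1$nonessential$start, 0)
  expect_error(read_genome_layout(tempfile()),
               class = "sirtascan_validation_error")
})

test_that("planted tracts are recovered on both strands of a toy genome", {
  sim <- simulate_planted_genome(2, 20000, plants = data.frame(
    pattern = "(TG)15", chrom = c(1, 1, 2, 2),
    position = c(3000, 9000, 4000, 12000),
    strand = c("+", "-", "+", "-")), seed = 7)
  rec <- scan_genome(sim$genome, sim$layout,
                     scoring_params(ggtgg_penalty = 1.5))
  expect_equal(nrow(rec), 4L)
  # every record overlaps its plant and carries the planted strand and score
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    hit <- rec$chrom == tr$chrom & rec$strand == tr$strand &
      rec$start < tr$end & rec$end > tr$start
    expect_equal(sum(hit), 1L)
    expect_equal(rec$score[hit], tr$score)
  }
})

test_that("a genome with no G on either strand yields no regions", {
  sim <- simulate_planted_genome(1, 20000, plants = NULL, seed = 5)
  rec <- scan_genome(sim$genome, sim$layout,
                     scoring_params(cluster_threshold = 1))
  expect_equal(nrow(rec), 0L)
})

test_that("scan errors name the offending chromosome or bounds", {
  g <- Biostrings::DNAStringSet(c(chrZ = strrep("AT", 100)))
  expect_error(scan_genome(g, toy_layout()), "chrZ",
               class = "sirtascan_validation_error")
  lay <- toy_layout(len = 10000, chrom = "chrZ")
  expect_error(scan_genome(g, lay, scoring_params()),
               class = "sirtascan_validation_error")  # bounds exceed sequence
})

test_that("orientation follows the arm/strand truth table", {
  # left arm: minus strand is TG-oriented; right arm: plus strand is
  plants <- data.frame(pattern = "(TG)15", chrom = 1,
                       position = c(1000, 2000, 7000, 8000),
                       strand = c("+", "-", "+", "-"))
  sim <- simulate_planted_genome(1, 10000, plants, seed = 3)
  lay <- toy_layout()
  rec <- scan_genome(sim$genome, lay, scoring_params(ggtgg_penalty = 1.5))
  rec <- rec[order(rec$start), ]
  expect_equal(rec$arm, c("L", "L", "R", "R"))
  expect_equal(rec$orientation, c("CA", "TG", "TG", "CA"))
})

test_that("names encode chromosome number, arm, kb distance and strand", {
  lay <- genome_layout(data.frame(
    chrom = c("chrVI", "chrIX"), length = c(270161, 439888),
    analysis_start = 0, analysis_end = c(270161, 439888),
    cen_start = c(148510, 355629), cen_end = c(148627, 355745)))
  rec <- data.frame(chrom = c("chrVI", "chrIX"),
                    start = c(210200, 44000), end = c(210400, 44200),
                    strand = c("+", "-"))
  expect_equal(name_sirta(rec, lay), c("6R210(+)", "9L44(-)"))
  # round-half-up at the kb boundary
  rec2 <- data.frame(chrom = "chrVI", start = c(499, 500),
                     end = c(599, 600), strand = "+")
  expect_equal(name_sirta(rec2, lay), c("6L0(+)", "6L1(+)"))
})

test_that("genic classification follows the strand-relation and tie rules", {
  genes <- data.frame(chrom = "chrI", start = c(50, 400), end = c(500, 450),
                      strand = c("+", "-"))
  rec <- data.frame(chrom = "chrI",
                    start = c(100, 100, 600, 390), end = c(175, 175, 700, 460),
                    strand = c("+", "-", "-", "-"))
  out <- classify_genic(rec, genes)
  expect_equal(out$genic_status, c("genic", "genic", "intergenic", "genic"))
  # same strand as gene -> coding; opposite -> template
  expect_equal(out$gene_strand_relation[1:2], c("coding", "template"))
  expect_equal(out$gene_strand_relation[3], "not_applicable")
  # row 4 overlaps both genes; the [400,450) gene covers 50 bp vs 60 bp for
  # the [50,500) gene -> largest overlap wins -> gene on +, record on -
  expect_equal(out$gene_strand_relation[4], "template")
  expect_warning(
    classify_genic(rec, rbind(genes,
                              data.frame(chrom = "chrI", start = 10, end = 5,
                                         strand = "+"))),
    "malformed")
})

test_that("BED output round-trips coordinates, names, scores and strands", {
  rec <- data.frame(chrom = c("chrI", "chrI", "chrII"),
                    start = c(0L, 150L, 42L), end = c(100L, 400L, 99L),
                    strand = c("+", "-", "+"),
                    score = c(20.5, 61, 23),
                    name = c("1L0(+)", "1L0(-)", "2L0(+)"))
  path <- tempfile(fileext = ".bed")
  write_sirta_bed(rec, path)
  back <- read_sirta_bed(path)
  expect_equal(back$chrom, rec$chrom)
  expect_equal(back$start, rec$start)
  expect_equal(back$end, rec$end)
  expect_equal(back$strand, rec$strand)
  expect_equal(back$name, rec$name)
  expect_equal(back$score, rec$score)
})

test_that("gene annotations are read from GFF3 in 0-based coordinates", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\tsgd\tgene\t101\t500\t.\t+\t.\tID=YAL001C",
    "chrI\tsgd\tgene\t700\t900\t.\t-\t.\tID=YAL002W",
    "chrI\tsgd\tCDS\t101\t500\t.\t+\t.\tID=cds1"), path)
  genes <- read_gene_annotations(path)
  expect_equal(nrow(genes), 2L)
  expect_equal(genes$start, c(100L, 699L))
  expect_equal(genes$end, c(500L, 900L))
  expect_equal(genes$strand, c("+", "-"))
})

test_that("subtelomere excision adjusts scan bounds and masks hits", {
  # a plant inside the subtelomere and one outside
  plants <- data.frame(pattern = "(TG)15", chrom = 1,
                       position = c(500, 6000), strand = "+")
  sim <- simulate_planted_genome(1, 10000, plants, seed = 13)
  lay_sub <- toy_layout(subtelomeres = data.frame(chrom = "chrI",
                                                  start = 0, end = 2000))
  p <- scoring_params(ggtgg_penalty = 1.5)
  full <- scan_genome(sim$genome, lay_sub, p)
  masked <- scan_genome(sim$genome, lay_sub, p, exclude_subtelomeres = TRUE)
  expect_equal(nrow(full), 2L)
  expect_true(any(full$in_subtelomere))
  expect_equal(nrow(masked), 1L)
  expect_false(any(masked$start < 2000))
  # the surviving region is identical to its unmasked counterpart
  keep <- full[full$start >= 2000, c("start", "end", "score")]
  rownames(keep) <- NULL
  expect_equal(masked[, c("start", "end", "score")], keep)
})
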