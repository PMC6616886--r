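tab_line <- function(q = "ctgA", s = "ctgB", qstart = 1, qend = 100,
                     sstart = 1, send = 100, evalue = 1e-20, len = 100) {
  paste(q, s, "99.0", len, 1, 0, qstart, qend, sstart, send,
        format(evalue, scientific = TRUE), 180, sep = "\t")
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("tabular coordinates convert to 0-based half-open intervals", {
  path <- write_lines_tmp(c(tab_line(qstart = 1, qend = 100,
                                     sstart = 1, send = 100),
                            tab_line(qstart = 5, qend = 40,
                                     sstart = 200, send = 101)))
  blocks <- parse_alignments(path, "tabular")
  expect_equal(blocks$start_a, c(0L, 4L))
  expect_equal(blocks$end_a, c(100L, 40L))
  # reversed subject coordinates are swapped and flagged as minus strand
  expect_equal(blocks$start_b[2], 100L)
  expect_equal(blocks$end_b[2], 200L)
  expect_equal(blocks$strand_b, c("+", "-"))
})

test_that("tabular parse failures carry line numbers", {
  path <- write_lines_tmp(c(tab_line(), "ctgA\tctgB\tonly-three"))
  expect_error(parse_alignments(path, "tabular"), "line 2",
               class = "hcr_parse_error")
  expect_error(parse_alignments(path, "nonsense"),
               class = "hcr_config_error")
  expect_error(parse_alignments(tempfile(), "tabular"),
               class = "hcr_input_error")
})

test_that("MAF blocks parse with strand normalisation", {
  maf <- c("# maf output",
           "a score=1000 EG2=0 E=1e-30",
           "s ctgA 10 40 + 1000 ACGT",
           "s ctgB 20 40 + 2000 ACGT",
           "",
           "a score=900 E=1e-15",
           "s ctgA 0 50 + 1000 ACGT",
           # reverse strand: start counted from the reverse strand of 2000 bp
           "s ctgB 100 50 - 2000 ACGT")
  path <- write_lines_tmp(maf, ".maf")
  blocks <- parse_alignments(path, "maf")
  expect_equal(nrow(blocks), 2L)
  expect_equal(blocks$start_a, c(10L, 0L))
  expect_equal(blocks$end_a, c(50L, 50L))
  expect_equal(blocks$start_b[2], 2000L - 100L - 50L)
  expect_equal(blocks$end_b[2], 2000L - 100L)
  expect_equal(blocks$strand_b, c("+", "-"))
  expect_equal(blocks$evalue, c(1e-30, 1e-15))
})

test_that("malformed MAF blocks are parse errors", {
  one_s <- write_lines_tmp(c("a score=1 E=1e-20",
                             "s ctgA 0 10 + 100 ACGT", ""), ".maf")
  expect_error(parse_alignments(one_s, "maf"), class = "hcr_parse_error")
  no_e <- write_lines_tmp(c("a score=1",
                            "s ctgA 0 10 + 100 ACGT",
                            "s ctgB 0 10 + 100 ACGT", ""), ".maf")
  expect_error(parse_alignments(no_e, "maf"), class = "hcr_parse_error")
})

test_that("E-value filtering is strictly less-than", {
  blocks <- parse_alignments(
    write_lines_tmp(c(tab_line(evalue = 1e-12),
                      tab_line(evalue = 1e-10),
                      tab_line(evalue = 1e-9))), "tabular")
  kept <- filter_by_evalue(blocks, 1e-10)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$evalue, 1e-12)
  expect_equal(nrow(filter_by_evalue(blocks[0, ], 1e-10)), 0L)
})

test_that("union_length merges overlaps and separates contigs", {
  expect_equal(union_length(c(0, 5), c(10, 15)), 15L)
  expect_equal(union_length(c(0, 20), c(10, 30)), 20L)
  expect_equal(union_length(integer(0), integer(0)), 0L)
  expect_equal(union_length(c(0, 0), c(10, 10), c("c1", "c2")), 20L)
  expect_error(union_length(5, 5), class = "hcr_input_error")
})

test_that("union_length agrees with the per-base boolean-array oracle", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(1:40, 1)
    start <- sample(0:5000, n, replace = TRUE)
    width <- sample(1:500, n, replace = TRUE)
    contig <- sample(c("c1", "c2", "c3"), n, replace = TRUE)
    expect_equal(union_length(start, start + width, contig),
                 oracle_union_length(start, start + width, contig))
  }
})

test_that("coverage ratio matches the worked overlap example", {
  ga <- genome_assembly("A", strrep("A", 100), "ctgA")
  gb <- genome_assembly("B", strrep("C", 100), "ctgB")
  blocks <- data.frame(
    contig_a = "ctgA", start_a = c(0L, 20L), end_a = c(30L, 50L),
    contig_b = "ctgB", start_b = c(0L, 100L), end_b = c(30L, 130L),
    strand_b = "+", evalue = 1e-20, stringsAsFactors = FALSE)
  gb130 <- genome_assembly("B", strrep("C", 130), "ctgB")
  res <- hcr_alignment(blocks, ga, gb130)
  expect_equal(res$H_a, 50L)
  expect_equal(res$H_b, 60L)
  expect_equal(res$hcr, (50 + 60) / (100 + 130))
  expect_equal(res$n_blocks_used, 2L)

  # full-length self alignment scores exactly 1
  self <- data.frame(contig_a = "ctgA", start_a = 0L, end_a = 100L,
                     contig_b = "ctgA", start_b = 0L, end_b = 100L,
                     strand_b = "+", evalue = 0, stringsAsFactors = FALSE)
  expect_equal(hcr_alignment(self, ga, ga)$hcr, 1)
})

test_that("coverage is symmetric, monotone, and ignores redundant blocks", {
  ga <- genome_assembly("A", strrep("A", 200), "ctgA")
  gb <- genome_assembly("B", strrep("C", 300), "ctgB")
  base <- data.frame(contig_a = "ctgA", start_a = 10L, end_a = 60L,
                     contig_b = "ctgB", start_b = 0L, end_b = 50L,
                     strand_b = "+", evalue = 1e-30,
                     stringsAsFactors = FALSE)
  r0 <- hcr_alignment(base, ga, gb)

  # blocks at/above the threshold never change the result
  weak <- rbind(base, transform(base, start_a = 100L, end_a = 150L,
                                start_b = 100L, end_b = 150L,
                                evalue = 1e-10))
  expect_equal(hcr_alignment(weak, ga, gb)$hcr, r0$hcr)

  # a block fully inside covered territory never changes the result
  nested <- rbind(base, transform(base, start_a = 20L, end_a = 40L,
                                  start_b = 10L, end_b = 30L))
  expect_equal(hcr_alignment(nested, ga, gb)$hcr, r0$hcr)

  # a block covering new bases strictly increases the ratio
  extra <- rbind(base, transform(base, start_a = 100L, end_a = 150L,
                                 start_b = 100L, end_b = 150L))
  expect_gt(hcr_alignment(extra, ga, gb)$hcr, r0$hcr)

  # exchanging genomes together with block sides leaves the ratio fixed
  swapped <- data.frame(contig_a = base$contig_b, start_a = base$start_b,
                        end_a = base$end_b, contig_b = base$contig_a,
                        start_b = base$start_a, end_b = base$end_a,
                        strand_b = base$strand_b, evalue = base$evalue,
                        stringsAsFactors = FALSE)
  expect_equal(hcr_alignment(swapped, gb, ga)$hcr, r0$hcr)
})

test_that("blocks exceeding contig bounds are rejected by name", {
  ga <- genome_assembly("A", strrep("A", 50), "ctgA")
  gb <- genome_assembly("B", strrep("C", 50), "ctgB")
  bad <- data.frame(contig_a = "ctgA", start_a = 0L, end_a = 60L,
                    contig_b = "ctgB", start_b = 0L, end_b = 10L,
                    strand_b = "+", evalue = 1e-20,
                    stringsAsFactors = FALSE)
  expect_error(hcr_alignment(bad, ga, gb), "ctgA",
               class = "hcr_input_error")
  unknown <- transform(bad, end_a = 10L, contig_b = "nope")
  expect_error(hcr_alignment(unknown, ga, gb), "nope",
               class = "hcr_input_error")
})

test_that("external aligner wrapper validates template and executable", {
  ga <- genome_assembly("A", strrep("A", 50), "ctgA")
  expect_error(run_external_aligner(ga, ga, "aligner {a} {b}"),
               class = "hcr_config_error")
  expect_error(
    run_external_aligner(ga, ga,
                         "no-such-aligner-xyz {a} {b} > {out}"),
    class = "hcr_environment_error")
})
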