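# Screening statistics on synthetic collections with planted taxonomies,
# plus the flagging criteria applied to the curated reference tables.

make_scores <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(accession_a = r[[1]], accession_b = r[[2]],
               hcr = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}

toy_taxonomy <- function(acc, genus) {
  data.frame(accession = acc, species = paste0(genus, " sp"),
             genus = genus, phylum = paste0("P_", genus),
             domain = "Bacteria", stringsAsFactors = FALSE)
}

test_that("taxon pair statistics pick inter maxima and anchored intra maxima", {
  tax <- toy_taxonomy(c("a1", "a2", "a3", "b1", "b2"),
                      c("GA", "GA", "GA", "GB", "GB"))
  scores <- make_scores(
    list("a1", "a2", 0.50), list("a1", "a3", 0.30), list("a2", "a3", 0.20),
    list("b1", "b2", 0.40),
    list("a1", "b1", 0.55), list("a2", "b1", 0.10),
    list("a3", "b2", 0.05), list("a1", "b2", 0.15), list("a2", "b2", 0.1),
    list("a3", "b1", 0.1))
  rec <- taxon_pair_stats(scores, tax, level = "genus")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$max_inter_hcr, 0.55)
  expect_equal(rec$inter_pair, "a1 & b1")
  # anchored on a1/b1: best within-taxon score involving either is a1-a2
  expect_equal(rec$max_intra_hcr, 0.50)
  expect_equal(rec$intra_pair, "a1 & a2")
  expect_equal(rec$min_intra_hcr, 0.20)
  expect_equal(rec$ratio, 0.55 / 0.20)
  # the global variant instead takes the overall within-taxon maximum
  recg <- taxon_pair_stats(scores, tax, level = "genus",
                           intra_variant = "global")
  expect_equal(recg$max_intra_hcr, 0.50)

  flagged <- flag_ambiguous(rec, "anchored_max")
  expect_true(flagged$flagged)
  expect_false(flag_ambiguous(rec, "min_intra_ratio", threshold = 3)$flagged)
})

test_that("statistics are invariant to score-row orientation", {
  tax <- toy_taxonomy(c("a1", "a2", "b1", "b2"), c("GA", "GA", "GB", "GB"))
  scores <- make_scores(
    list("a1", "a2", 0.5), list("b1", "b2", 0.4),
    list("a1", "b1", 0.6), list("a1", "b2", 0.1),
    list("a2", "b1", 0.1), list("a2", "b2", 0.1))
  swapped <- scores[, c("accession_b", "accession_a", "hcr")]
  names(swapped) <- c("accession_a", "accession_b", "hcr")
  r1 <- flag_ambiguous(taxon_pair_stats(scores, tax, "genus"),
                       "anchored_max")
  r2 <- flag_ambiguous(taxon_pair_stats(swapped, tax, "genus"),
                       "anchored_max")
  expect_equal(r1$flagged, r2$flagged)
  expect_equal(r1$max_inter_hcr, r2$max_inter_hcr)
  expect_equal(r1$max_intra_hcr, r2$max_intra_hcr)
})

test_that("taxa with a single scored genome are skipped with a note", {
  tax <- toy_taxonomy(c("a1", "a2", "b1"), c("GA", "GA", "GB"))
  scores <- make_scores(list("a1", "a2", 0.5), list("a1", "b1", 0.6),
                        list("a2", "b1", 0.2))
  expect_message(rec <- taxon_pair_stats(scores, tax, "genus"),
                 "single scored genome")
  expect_equal(nrow(rec), 0L)
})

test_that("unknown accessions and criteria are rejected", {
  tax <- toy_taxonomy(c("a1", "a2"), c("GA", "GA"))
  scores <- make_scores(list("a1", "zz", 0.5))
  expect_error(taxon_pair_stats(scores, tax, "genus"), "zz",
               class = "hcr_input_error")
  rec <- data.frame(max_inter_hcr = 1, max_intra_hcr = 0.5, ratio = 2)
  expect_error(flag_ambiguous(rec, "bogus"), class = "hcr_config_error")
})

test_that("raising the ratio threshold never flags more pairs", {
  recs <- reference_phylum_records()
  counts <- vapply(c(1, 2, 4, 8, 16), function(thr) {
    sum(flag_ambiguous(recs, "min_intra_ratio", thr)$flagged)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("reference genus table: ties are not flagged under anchored_max", {
  recs <- flag_ambiguous(reference_genus_records(), "anchored_max")
  tie <- recs[recs$taxon_a == "Pseudodesulfovibrio", ]
  expect_equal(tie$max_inter_hcr, tie$max_intra_hcr)
  expect_false(tie$flagged)
})

test_that("planted ambiguity is recovered end-to-end from k-mer scores", {
  fix <- make_taxonomy_fixture(n_genera = 3, genomes_per_genus = 3,
                               intra_fraction = 0.6, inter_fraction = 0.1,
                               ambiguous_pair = c(1, 2),
                               ambiguous_fraction = 0.7,
                               genome_length = 12000, seed = 42)
  profiles <- lapply(fix$genomes, build_kmer_profile)
  scores <- hcr_kmer_all_vs_all(unname(profiles))
  recs <- flag_ambiguous(taxon_pair_stats(scores, fix$taxonomy, "genus"),
                         "anchored_max")
  expect_equal(sum(recs$flagged), 1L)
  hit <- recs[recs$flagged, ]
  expect_setequal(c(hit$taxon_a, hit$taxon_b), fix$ambiguous)

  # the same pair tops the candidate ranking
  cand <- candidate_screen(scores, fix$taxonomy, top_n = 5)
  expect_setequal(c(cand$taxon_a[1], cand$taxon_b[1]), fix$ambiguous)
  expect_equal(nrow(candidate_screen(scores, fix$taxonomy, top_n = 0)), 0L)
})

test_that("a fixture without planted ambiguity flags nothing", {
  fix <- make_taxonomy_fixture(n_genera = 3, genomes_per_genus = 3,
                               intra_fraction = 0.6, inter_fraction = 0.1,
                               genome_length = 12000, seed = 7)
  profiles <- lapply(fix$genomes, build_kmer_profile)
  scores <- hcr_kmer_all_vs_all(unname(profiles))
  recs <- flag_ambiguous(taxon_pair_stats(scores, fix$taxonomy, "genus"),
                         "anchored_max")
  expect_equal(nrow(recs), 3L)
  expect_false(any(recs$flagged))
  expect_equal(nrow(candidate_screen(scores, fix$taxonomy, 5)), 0L)
})
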