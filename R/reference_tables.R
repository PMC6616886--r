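# Curated reference values from a published large-scale survey of 7,861
# RefSeq microbial assemblies: the fifteen genus pairs short-listed for
# ambiguous classification boundaries (with the anchored within-genus
# comparison), the per-phylum within-phylum HCR minima, and the thirteen
# phylum pairs whose cross-phylum maxima most exceed them. They serve as
# fixed inputs for the screening criteria, not as computed outputs.

ref_path <- function(file) {
  system.file("extdata", file, package = "hcr", mustWork = TRUE)
}

#' Reference genus pairs with ambiguous classification boundaries
#'
#' Fifteen genus pairs short-listed by k-mer screening of 7,861 RefSeq
#' assemblies and refined with alignment coverage. Columns: `genus_a`,
#' `genus_b`, the best cross-genus HCR (`max_inter_hcr`) with its achieving
#' accession pair, and the anchored within-genus maximum (`max_intra_hcr`,
#' the best within-genus HCR involving the cross-genus anchor genome) with
#' its pair.
#'
#' @return Data.frame of 15 rows.
#' @export
reference_genus_pairs <- function() {
  utils::read.delim(ref_path("genus_boundary_pairs.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference within-phylum HCR minima
#'
#' The ten phyla with the smallest within-phylum HCR, each with the
#' achieving accession pair.
#'
#' @return Data.frame of 10 rows.
#' @export
reference_phylum_min_intra <- function() {
  utils::read.delim(ref_path("phylum_min_intra.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference phylum pairs with high cross-phylum HCR
#'
#' The thirteen phylum pairs whose maximum cross-phylum HCR most exceeds
#' the within-phylum minimum of phylum A.
#'
#' @return Data.frame of 13 rows.
#' @export
reference_phylum_pairs <- function() {
  utils::read.delim(ref_path("phylum_boundary_pairs.tsv"),
                    stringsAsFactors = FALSE)
}

#' Ambiguity records from the reference genus table
#'
#' Recasts [reference_genus_pairs()] into the ambiguity-record layout so the
#' genus-level flagging criterion can be applied to the published values.
#'
#' @return Ambiguity-record data.frame (15 rows, `flagged` unset).
#' @export
reference_genus_records <- function() {
  tab <- reference_genus_pairs()
  data.frame(
    level = "genus", taxon_a = tab$genus_a, taxon_b = tab$genus_b,
    max_inter_hcr = tab$max_inter_hcr, inter_pair = tab$inter_pair,
    max_intra_hcr = tab$max_intra_hcr, intra_pair = tab$intra_pair,
    min_intra_hcr = NA_real_, min_intra_pair = NA_character_,
    ratio = NA_real_, flagged = NA, stringsAsFactors = FALSE
  )
}

#' Ambiguity records from the reference phylum tables
#'
#' Recasts [reference_phylum_pairs()] into the ambiguity-record layout
#' (ratio = cross-phylum maximum over phylum A's within-phylum minimum) so
#' the phylum-level ratio criterion can be applied to the published values.
#'
#' @return Ambiguity-record data.frame (13 rows, `flagged` unset).
#' @export
reference_phylum_records <- function() {
  tab <- reference_phylum_pairs()
  data.frame(
    level = "phylum", taxon_a = tab$phylum_a, taxon_b = tab$phylum_b,
    max_inter_hcr = tab$max_inter_hcr,
    inter_pair = paste(tab$accession_a, tab$accession_b, sep = " & "),
    max_intra_hcr = NA_real_, intra_pair = NA_character_,
    min_intra_hcr = tab$min_intra_hcr_a, min_intra_pair = NA_character_,
    ratio = tab$max_inter_hcr / tab$min_intra_hcr_a,
    flagged = NA, stringsAsFactors = FALSE
  )
}
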