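# Taxonomy-aware ambiguity screening: a taxon pair (two genera, or two
# phyla) is suspect when genomes across the boundary share more homologous
# sequence than genomes within it. Cross-taxon maxima are compared against
# within-taxon statistics, either anchored on the genome achieving the
# cross-taxon maximum, or as a ratio against the within-taxon minimum.

pair_label <- function(a, b) paste(a, b, sep = " & ")

#' Per-taxon-pair HCR screening statistics
#'
#' For every unordered pair of taxa (genus or phylum level) with at least one
#' cross-taxon score, computes:
#' \itemize{
#'   \item `max_inter_hcr`: the largest HCR across the boundary, with the
#'     achieving genome pair;
#'   \item `max_intra_hcr` (anchored form, the default): the largest
#'     within-taxon HCR involving either genome of the cross-taxon maximum —
#'     the direct "does this genome look more like a foreign genus than its
#'     own" comparison; the `global` variant instead takes the maximum over
#'     all within-taxon pairs of both taxa;
#'   \item `min_intra_hcr`: the smallest within-taxon HCR over both taxa,
#'     with the achieving pair; `ratio = max_inter_hcr / min_intra_hcr`.
#' }
#' `taxon_a` is oriented as the taxon owning the within-taxon minimum. Pairs
#' in which either taxon has fewer than two scored genomes have undefined
#' within-taxon statistics and are skipped with a message.
#'
#' @param scores Pair-score data.frame (`accession_a`, `accession_b`, `hcr`).
#' @param taxonomy Taxonomy data.frame from [load_taxonomy()].
#' @param level `"genus"` or `"phylum"`.
#' @param intra_variant `"anchored"` (default) or `"global"`.
#' @return Data.frame of ambiguity records (one row per taxon pair) with
#'   `flagged` unset (`NA`) until [flag_ambiguous()] is applied.
#' @export
taxon_pair_stats <- function(scores, taxonomy,
                             level = c("genus", "phylum"),
                             intra_variant = c("anchored", "global")) {
  level <- match.arg(level)
  intra_variant <- match.arg(intra_variant)
  accs <- unique(c(scores$accession_a, scores$accession_b))
  missing <- setdiff(accs, taxonomy$accession)
  if (length(missing) > 0L) {
    stop_input("accession(s) missing from taxonomy: ",
               paste(missing, collapse = ", "))
  }
  taxon_of <- stats::setNames(taxonomy[[level]], taxonomy$accession)
  if (any(!nzchar(taxon_of[accs]))) {
    stop_input("empty ", level, " label for accession(s): ",
               paste(accs[!nzchar(taxon_of[accs])], collapse = ", "))
  }
  ta <- taxon_of[scores$accession_a]
  tb <- taxon_of[scores$accession_b]
  n_genomes <- table(taxon_of[accs])

  intra <- scores[ta == tb, , drop = FALSE]
  intra$taxon <- taxon_of[intra$accession_a]
  inter <- scores[ta != tb, , drop = FALSE]
  if (nrow(inter) == 0L) return(empty_ambiguity(level))
  key <- ifelse(taxon_of[inter$accession_a] < taxon_of[inter$accession_b],
                paste(taxon_of[inter$accession_a],
                      taxon_of[inter$accession_b], sep = "\r"),
                paste(taxon_of[inter$accession_b],
                      taxon_of[inter$accession_a], sep = "\r"))

  rows <- lapply(split(inter, key), function(grp) {
    t1 <- taxon_of[grp$accession_a[1L]]
    t2 <- taxon_of[grp$accession_b[1L]]
    if (n_genomes[t1] < 2L || n_genomes[t2] < 2L) {
      message("skipping ", pair_label(t1, t2),
              ": a taxon has a single scored genome, ",
              "within-taxon statistics undefined")
      return(NULL)
    }
    intra1 <- intra[intra$taxon == t1, , drop = FALSE]
    intra2 <- intra[intra$taxon == t2, , drop = FALSE]
    if (nrow(intra1) == 0L || nrow(intra2) == 0L) {
      message("skipping ", pair_label(t1, t2),
              ": no within-taxon scores for one taxon")
      return(NULL)
    }
    imax <- which.max(grp$hcr)
    anchor_accs <- c(grp$accession_a[imax], grp$accession_b[imax])
    both_intra <- rbind(intra1, intra2)
    if (intra_variant == "anchored") {
      hit <- both_intra[both_intra$accession_a %in% anchor_accs |
                        both_intra$accession_b %in% anchor_accs, ,
                        drop = FALSE]
      if (nrow(hit) == 0L) {
        message("skipping ", pair_label(t1, t2),
                ": no within-taxon score involves the cross-taxon anchor")
        return(NULL)
      }
      amax <- which.max(hit$hcr)
      max_intra <- hit$hcr[amax]
      max_intra_pair <- pair_label(hit$accession_a[amax],
                                   hit$accession_b[amax])
    } else {
      amax <- which.max(both_intra$hcr)
      max_intra <- both_intra$hcr[amax]
      max_intra_pair <- pair_label(both_intra$accession_a[amax],
                                   both_intra$accession_b[amax])
    }
    imin <- which.min(both_intra$hcr)
    min_intra <- both_intra$hcr[imin]
    # orient taxon_a as the owner of the within-taxon minimum
    min_owner <- both_intra$taxon[imin]
    taxon_a <- min_owner
    taxon_b <- if (min_owner == t1) t2 else t1
    data.frame(
      level = level, taxon_a = taxon_a, taxon_b = taxon_b,
      max_inter_hcr = grp$hcr[imax],
      inter_pair = pair_label(grp$accession_a[imax], grp$accession_b[imax]),
      max_intra_hcr = max_intra, intra_pair = max_intra_pair,
      min_intra_hcr = min_intra,
      min_intra_pair = pair_label(both_intra$accession_a[imin],
                                  both_intra$accession_b[imin]),
      ratio = if (min_intra > 0) grp$hcr[imax] / min_intra else Inf,
      flagged = NA,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_ambiguity(level))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$taxon_a, out$taxon_b), , drop = FALSE]
}

empty_ambiguity <- function(level) {
  data.frame(level = character(0), taxon_a = character(0),
             taxon_b = character(0), max_inter_hcr = numeric(0),
             inter_pair = character(0), max_intra_hcr = numeric(0),
             intra_pair = character(0), min_intra_hcr = numeric(0),
             min_intra_pair = character(0), ratio = numeric(0),
             flagged = logical(0), stringsAsFactors = FALSE)
}

#' Flag ambiguous taxon pairs
#'
#' Two criteria are available:
#' \describe{
#'   \item{`anchored_max`}{flag when the best cross-taxon HCR strictly
#'     exceeds the (anchored) best within-taxon HCR — ties are not flagged.
#'     The genus-level criterion.}
#'   \item{`min_intra_ratio`}{flag when `max_inter_hcr / min_intra_hcr`
#'     strictly exceeds `threshold` — the phylum-level criterion, with
#'     thresholds 2 (survey) and 4 (stringent short-list) as conventional
#'     choices.}
#' }
#'
#' @param records Data.frame from [taxon_pair_stats()].
#' @param criterion `"anchored_max"` or `"min_intra_ratio"`.
#' @param threshold Ratio threshold (default 2); used only by
#'   `min_intra_ratio`.
#' @return `records` with the `flagged` column filled in.
#' @export
flag_ambiguous <- function(records,
                           criterion = c("anchored_max", "min_intra_ratio"),
                           threshold = 2) {
  if (length(criterion) != 1L ||
      !criterion %in% c("anchored_max", "min_intra_ratio")) {
    criterion <- tryCatch(match.arg(criterion),
                          error = function(e) stop_config(
                            "unknown flagging criterion: ",
                            paste(criterion, collapse = "/")))
  }
  records$flagged <- switch(
    criterion,
    anchored_max = records$max_inter_hcr > records$max_intra_hcr,
    min_intra_ratio = records$ratio > threshold
  )
  records
}

#' Rank genus pairs for alignment-stage refinement
#'
#' Screens k-mer-stage scores for genus pairs whose best cross-genus HCR
#' exceeds the anchored within-genus maximum, ranked by the excess
#' `max_inter_hcr - max_intra_hcr`; only pairs with positive excess are
#' candidates.
#'
#' @param kmer_scores Pair scores from the k-mer stage.
#' @param taxonomy Taxonomy data.frame.
#' @param top_n Maximum number of candidate pairs to return.
#' @return Data.frame of candidate genus pairs ordered by descending excess,
#'   with the achieving cross-genus accession pair.
#' @export
candidate_screen <- function(kmer_scores, taxonomy, top_n = 20L) {
  recs <- taxon_pair_stats(kmer_scores, taxonomy, level = "genus",
                           intra_variant = "anchored")
  recs$excess <- recs$max_inter_hcr - recs$max_intra_hcr
  recs <- recs[recs$excess > 0, , drop = FALSE]
  recs <- recs[order(-recs$excess, recs$taxon_a, recs$taxon_b), , drop = FALSE]
  utils::head(recs[c("taxon_a", "taxon_b", "max_inter_hcr", "max_intra_hcr",
                     "excess", "inter_pair")], max(0L, as.integer(top_n)))
}

#' Write an ambiguity report to TSV
#'
#' Rows are sorted by descending ratio.
#'
#' @param records Flagged records from [flag_ambiguous()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ambiguity_report <- function(records, path) {
  out <- records[order(-records$ratio, records$taxon_a, records$taxon_b), ,
                 drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
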