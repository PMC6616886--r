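# K-mer stage of the two-stage workflow: distinct-k-mer membership per
# genome, and the approximate coverage ratio
#   HCRkmer(A, B) = (Hit_A + Hit_B) / (HS_A + HS_B)
# where HS_X is the number of distinct k-mers of genome X and Hit_X the
# number of X's distinct k-mers found in the other genome's table.

revcomp_chr <- function(s) {
  s <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", s)
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# All length-k windows of one contig; windows containing a non-ACGT symbol
# are skipped; canonical mode replaces each window by the lexicographic
# minimum of itself and its reverse complement.
contig_kmers <- function(seq, k, canonical) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  m <- n - k + 1L
  fwd <- substring(seq, seq_len(m), seq_len(m) + k - 1L)
  ok <- !grepl("[^ACGT]", fwd)
  if (canonical) {
    # windows of the reverse complement, re-reversed, align index-for-index
    # with forward windows as their reverse complements
    rc <- revcomp_chr(seq)
    rcw <- rev(substring(rc, seq_len(m), seq_len(m) + k - 1L))
    fwd <- pmin(fwd, rcw)
  }
  fwd[ok]
}

#' Build a genome's distinct k-mer profile
#'
#' Collects the set of distinct k-mers over all contigs of an assembly
#' (windows never span contig boundaries; windows containing any non-ACGT
#' symbol are skipped). This set plays the role of the genome's hash table in
#' the approximate coverage ratio: its cardinality is the denominator
#' contribution `HS`.
#'
#' @param genome A [genome_assembly()].
#' @param k K-mer length (default 12). `4^12` distinct keys keep random
#'   collisions between unrelated bacterial genomes negligible while the
#'   table stays small.
#' @param canonical If `TRUE` (default) each k-mer is strand-collapsed to the
#'   lexicographic minimum of itself and its reverse complement, so assembly
#'   orientation does not affect the score.
#' @return An object of class `kmer_profile`: list with `accession`, `k`,
#'   `canonical`, `members` (sorted distinct k-mers) and `size`.
#' @export
build_kmer_profile <- function(genome, k = 12L, canonical = TRUE) {
  stopifnot(inherits(genome, "genome_assembly"))
  k <- as.integer(k)
  if (is.na(k) || k < 3L) stop_input("k must be an integer >= 3")
  kmers <- unlist(lapply(genome$sequence, contig_kmers, k = k,
                         canonical = isTRUE(canonical)), use.names = FALSE)
  members <- sort(unique(kmers))
  if (length(members) == 0L) {
    stop_input("no valid ", k, "-mers in assembly '", genome$accession,
               "' (contigs shorter than k or saturated with non-ACGT symbols)")
  }
  out <- list(accession = genome$accession, k = k,
              canonical = isTRUE(canonical), members = members,
              size = length(members))
  class(out) <- "kmer_profile"
  out
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("kmer_profile '%s': %d distinct %d-mers (%s)\n",
              x$accession, x$size, x$k,
              if (x$canonical) "canonical" else "stranded"))
  invisible(x)
}

#' Approximate coverage ratio between two k-mer profiles
#'
#' Computes `HCRkmer = (Hit_A + Hit_B) / (HS_A + HS_B)` where `Hit_A` is the
#' number of A's distinct k-mers present in B's set and vice versa. Under
#' this cross-containment reading the two hit counts are equal, the score is
#' symmetric and bounded by 1, and identical genomes score exactly 1.
#'
#' @param profile_a,profile_b `kmer_profile` objects built with the same `k`
#'   and `canonical` settings.
#' @return One-row data.frame with columns `accession_a`, `accession_b`,
#'   `method` (`"kmer"`) and `hcr`.
#' @export
hcr_kmer <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "kmer_profile"),
            inherits(profile_b, "kmer_profile"))
  if (profile_a$k != profile_b$k) {
    stop_config("profiles built with different k: ",
                profile_a$k, " vs ", profile_b$k)
  }
  if (profile_a$canonical != profile_b$canonical) {
    stop_config("profiles differ in canonical flag")
  }
  hit <- length(intersect(profile_a$members, profile_b$members))
  data.frame(
    accession_a = profile_a$accession,
    accession_b = profile_b$accession,
    method = "kmer",
    hcr = (hit + hit) / (profile_a$size + profile_b$size),
    stringsAsFactors = FALSE
  )
}

#' All-vs-all approximate coverage ratios
#'
#' Scores every unordered pair of profiles, `n(n-1)/2` pairs in total, in
#' lexicographic accession order.
#'
#' @param profiles List of `kmer_profile` objects with homogeneous `k` and
#'   `canonical` settings.
#' @return Data.frame of pair scores (one row per unordered pair), ordered
#'   lexicographically by `(accession_a, accession_b)`.
#' @export
hcr_kmer_all_vs_all <- function(profiles) {
  if (length(profiles) < 2L) {
    stop_input("need at least 2 profiles for pairwise comparison")
  }
  accs <- vapply(profiles, function(p) p$accession, character(1))
  if (anyDuplicated(accs)) stop_input("duplicate accessions among profiles")
  profiles <- profiles[order(accs)]
  accs <- sort(accs)
  n <- length(profiles)
  rows <- vector("list", n * (n - 1L) / 2L)
  idx <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      rows[[idx]] <- hcr_kmer(profiles[[i]], profiles[[j]])
      idx <- idx + 1L
    }
  }
  do.call(rbind, rows)
}

#' Write pair scores to TSV
#'
#' Columns `accession_a`, `accession_b`, `method`, `hcr`, with `hcr` printed
#' to 9 decimal places.
#'
#' @param scores Pair-score data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_scores <- function(scores, path) {
  out <- scores
  out$hcr <- sprintf("%.9f", out$hcr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pair scores from TSV
#'
#' @param path Path to a TSV written by [write_pair_scores()] (or any TSV
#'   with columns `accession_a`, `accession_b`, `hcr`).
#' @return Pair-score data.frame.
#' @export
read_pair_scores <- function(path) {
  if (!file.exists(path)) stop_input("scores file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("accession_a", "accession_b", "hcr")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop_format("scores file missing column(s): ",
                paste(missing, collapse = ", "))
  }
  tab$hcr <- as.numeric(tab$hcr)
  tab
}
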