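#' Construct a genome assembly object
#'
#' A genome assembly is one accession's set of nucleotide contigs. The total
#' length (the `S_A` / `S_B` of the coverage-ratio denominator) is the sum of
#' contig lengths.
#'
#' @param accession Assembly identifier, e.g. `"GCF_000620945.1"`.
#' @param sequence Character vector of contig sequences (uppercased on entry).
#' @param contig_id Character vector of contig identifiers (first header token).
#' @param description Full header descriptions; defaults to `contig_id`.
#'   Plasmid filtering matches against this field.
#' @return An object of class `genome_assembly`: a list with elements
#'   `accession`, `contig_id`, `description`, `sequence` and `total_length`.
#' @export
genome_assembly <- function(accession, sequence, contig_id = NULL,
                            description = NULL) {
  if (!is.character(accession) || length(accession) != 1L || !nzchar(accession)) {
    stop_input("accession must be a non-empty string")
  }
  if (length(sequence) == 0L) {
    stop_input("genome assembly '", accession, "' has no contigs")
  }
  if (is.null(contig_id)) contig_id <- paste0("contig", seq_along(sequence))
  if (is.null(description)) description <- contig_id
  stopifnot(length(contig_id) == length(sequence),
            length(description) == length(sequence))
  if (anyDuplicated(contig_id)) {
    stop_format("duplicate contig identifiers in assembly '", accession, "'")
  }
  sequence <- toupper(sequence)
  out <- list(
    accession = accession,
    contig_id = as.character(contig_id),
    description = as.character(description),
    sequence = sequence,
    total_length = sum(nchar(sequence))
  )
  class(out) <- "genome_assembly"
  out
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly '%s': %d contig(s), %d bp total\n",
              x$accession, length(x$sequence), x$total_length))
  invisible(x)
}

#' Read a genome assembly from a FASTA file
#'
#' Reads all records of a (plain or gzip-compressed) FASTA file into one
#' [genome_assembly()]. Sequences are uppercased; soft-masking is discarded.
#'
#' @param path Path to the FASTA file.
#' @param accession Assembly accession; defaults to the filename stem with
#'   `.fa/.fasta/.fna` (and `.gz`) extensions stripped.
#' @return A `genome_assembly`.
#' @details Records whose sequence is not dominated by nucleotide symbols
#'   (less than 90% `A/C/G/T/N`) trigger a warning but are retained.
#' @export
read_genome_fasta <- function(path, accession = NULL) {
  if (!file.exists(path)) stop_input("FASTA file not found: ", path)
  if (is.null(accession)) {
    stem <- basename(path)
    stem <- sub("\\.gz$", "", stem, ignore.case = TRUE)
    stem <- sub("\\.(fa|fasta|fna)$", "", stem, ignore.case = TRUE)
    accession <- stem
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop_input("empty FASTA file: ", path)
  headers <- names(recs)
  seqs <- toupper(as.character(recs))
  names(seqs) <- NULL
  ids <- sub("\\s.*$", "", headers)
  acgtn <- vapply(seqs, function(s) {
    n <- nchar(s)
    if (n == 0L) return(1)
    nchar(gsub("[^ACGTN]", "", s)) / n
  }, numeric(1))
  if (any(acgtn < 0.9)) {
    warning("record(s) not nucleotide-dominant in ", path, ": ",
            paste(ids[acgtn < 0.9], collapse = ", "), call. = FALSE)
  }
  genome_assembly(accession, seqs, contig_id = ids, description = headers)
}

#' Write a genome assembly to FASTA
#'
#' @param genome A `genome_assembly`.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_assembly"))
  seqs <- Biostrings::BStringSet(genome$sequence)
  names(seqs) <- genome$description
  Biostrings::writeXStringSet(
    seqs, path,
    compress = grepl("\\.gz$", path, ignore.case = TRUE)
  )
  invisible(path)
}

#' Remove plasmid contigs from an assembly
#'
#' Drops every contig whose description contains the case-insensitive token
#' "plasmid" and recomputes the total length. Whole-genome relatedness is
#' scored on chromosomal sequence only; plasmids are mobile and would inflate
#' apparent homology between unrelated taxa.
#'
#' @param genome A `genome_assembly`.
#' @return The filtered `genome_assembly`.
#' @export
filter_plasmids <- function(genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  keep <- !grepl("plasmid", genome$description, ignore.case = TRUE)
  if (!any(keep)) {
    stop_input("all contigs of '", genome$accession,
               "' are plasmids; nothing left to score")
  }
  if (all(keep)) return(genome)
  genome_assembly(genome$accession,
                  genome$sequence[keep],
                  contig_id = genome$contig_id[keep],
                  description = genome$description[keep])
}

#' Load a taxonomy table
#'
#' Reads a tab-separated taxonomy table with header columns `accession`,
#' `species`, `genus`, `phylum`, `domain` — one row per assembly.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the five character columns above.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop_input("taxonomy file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  required <- c("accession", "species", "genus", "phylum", "domain")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop_format("taxonomy table missing column(s): ",
                paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$accession)) {
    dups <- unique(tab$accession[duplicated(tab$accession)])
    stop_format("duplicated accession(s) in taxonomy table: ",
                paste(dups, collapse = ", "))
  }
  tab[required]
}

#' Write a taxonomy table
#'
#' @param taxonomy Data.frame as returned by [load_taxonomy()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
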