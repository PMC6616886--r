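# Alignment stage: the precise homologous coverage ratio
#   HCRlast(A, B) = (H_A + H_B) / (S_A + S_B)
# where H_X is the number of bases of genome X covered by the union of
# local-alignment blocks passing the E-value filter, and S_X its total
# length. Alignments are consumed from external aligner output (MAF or
# 12-column BLAST-style tabular); E-values are never computed here.

empty_blocks <- function() {
  data.frame(contig_a = character(0), start_a = integer(0), end_a = integer(0),
             contig_b = character(0), start_b = integer(0), end_b = integer(0),
             strand_b = character(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Parse pairwise alignment files into alignment blocks
#'
#' Supported dialects:
#' \describe{
#'   \item{`tabular`}{12-column BLAST-outfmt-6-like: `qseqid sseqid pident
#'     length mismatch gapopen qstart qend sstart send evalue bitscore`.
#'     1-based inclusive coordinates are converted to 0-based half-open;
#'     reversed subject coordinates (`sstart > send`) are swapped and the
#'     block's strand set to `-`.}
#'   \item{`maf`}{Each `a` block must carry an `E=` attribute and contain
#'     exactly two `s` lines (query genome first, subject second). MAF's
#'     0-based start plus length becomes a half-open interval;
#'     reverse-strand coordinates are normalised to forward-strand
#'     intervals using the source sequence length.}
#' }
#'
#' @param path Alignment file path.
#' @param dialect `"tabular"` or `"maf"`.
#' @return Data.frame of alignment blocks with columns `contig_a`,
#'   `start_a`, `end_a`, `contig_b`, `start_b`, `end_b`, `strand_b`,
#'   `evalue`; intervals are 0-based half-open on the forward strand.
#' @export
parse_alignments <- function(path, dialect = c("tabular", "maf")) {
  if (length(dialect) != 1L || !dialect %in% c("tabular", "maf")) {
    dialect <- tryCatch(match.arg(dialect),
                        error = function(e) stop_config(
                          "unknown alignment dialect: ",
                          paste(dialect, collapse = "/")))
  }
  if (!file.exists(path)) stop_input("alignment file not found: ", path)
  switch(dialect,
         tabular = parse_tabular(path),
         maf = parse_maf(path))
}

parse_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad) > 0L) {
    stop_parse("tabular alignment line ", bad[1L], " has ",
               lengths(fields)[bad[1L]], " columns (12 required) in ", path)
  }
  mat <- do.call(rbind, fields)
  qstart <- as.integer(mat[, 7L]); qend <- as.integer(mat[, 8L])
  sstart <- as.integer(mat[, 9L]); send <- as.integer(mat[, 10L])
  evalue <- as.numeric(mat[, 11L])
  if (anyNA(qstart) || anyNA(qend) || anyNA(sstart) || anyNA(send) ||
      anyNA(evalue)) {
    stop_parse("non-numeric coordinate or E-value field in ", path)
  }
  rev_s <- sstart > send
  b_start <- ifelse(rev_s, send - 1L, sstart - 1L)
  b_end <- ifelse(rev_s, sstart, send)
  data.frame(
    contig_a = mat[, 1L], start_a = qstart - 1L, end_a = qend,
    contig_b = mat[, 2L], start_b = b_start, end_b = b_end,
    strand_b = ifelse(rev_s, "-", "+"), evalue = evalue,
    stringsAsFactors = FALSE
  )
}

parse_maf_sline <- function(line, lineno, path) {
  f <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(f) < 6L) {
    stop_parse("malformed MAF s line at ", path, ":", lineno)
  }
  start <- suppressWarnings(as.integer(f[3L]))
  size <- suppressWarnings(as.integer(f[4L]))
  src <- suppressWarnings(as.integer(f[6L]))
  strand <- f[5L]
  if (anyNA(c(start, size, src)) || !strand %in% c("+", "-") || size <= 0L) {
    stop_parse("malformed MAF s line at ", path, ":", lineno)
  }
  if (strand == "-") {
    # MAF gives reverse-strand starts counted from the reverse strand
    list(name = f[2L], start = src - start - size, end = src - start,
         strand = "-")
  } else {
    list(name = f[2L], start = start, end = start + size, strand = "+")
  }
}

parse_maf <- function(path) {
  lines <- readLines(path)
  rows <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (startsWith(line, "a")) {
      ev <- regmatches(line, regexpr("E=[0-9.eE+-]+", line))
      if (length(ev) == 0L) {
        stop_parse("MAF a line without E= attribute at ", path, ":", i)
      }
      evalue <- as.numeric(sub("^E=", "", ev))
      j <- i + 1L
      slines <- integer(0)
      while (j <= n && !startsWith(lines[j], "a") &&
             (nzchar(lines[j]) || length(slines) < 2L)) {
        if (startsWith(lines[j], "s")) slines <- c(slines, j)
        if (!nzchar(lines[j])) break
        j <- j + 1L
      }
      if (length(slines) != 2L) {
        stop_parse("MAF block at ", path, ":", i, " has ", length(slines),
                   " sequence lines (2 required)")
      }
      sa <- parse_maf_sline(lines[slines[1L]], slines[1L], path)
      sb <- parse_maf_sline(lines[slines[2L]], slines[2L], path)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_a = sa$name, start_a = sa$start, end_a = sa$end,
        contig_b = sb$name, start_b = sb$start, end_b = sb$end,
        strand_b = if (sa$strand == sb$strand) "+" else "-",
        evalue = evalue, stringsAsFactors = FALSE
      )
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (length(rows) == 0L) return(empty_blocks())
  do.call(rbind, rows)
}

#' Filter alignment blocks by E-value
#'
#' Retains exactly the blocks whose E-value is strictly less than the
#' threshold; blocks at or above it are not considered homologous.
#'
#' @param blocks Alignment-block data.frame.
#' @param threshold E-value cutoff (default `1e-10`).
#' @return The retained blocks.
#' @export
filter_by_evalue <- function(blocks, threshold = 1e-10) {
  blocks[blocks$evalue < threshold, , drop = FALSE]
}

#' Total length of a union of intervals
#'
#' Number of distinct bases covered by a set of 0-based half-open intervals;
#' overlapping intervals are counted once and intervals on different contigs
#' never merge.
#'
#' @param start,end Integer vectors of interval bounds (`start < end`).
#' @param contig Optional character vector assigning each interval to a
#'   contig; a single contig is assumed when omitted.
#' @return Integer: the number of covered bases.
#' @export
union_length <- function(start, end, contig = NULL) {
  if (length(start) != length(end)) stop_input("start/end length mismatch")
  if (length(start) == 0L) return(0L)
  if (any(start >= end)) {
    stop_input("invalid interval: start >= end at index ",
               which(start >= end)[1L])
  }
  if (is.null(contig)) contig <- rep("*", length(start))
  ir <- IRanges::IRanges(start = start + 1L, end = end)
  total <- 0L
  for (ctg in unique(contig)) {
    total <- total +
      sum(IRanges::width(IRanges::reduce(ir[contig == ctg])))
  }
  as.integer(total)
}

#' Alignment-based homologous coverage ratio for one genome pair
#'
#' Applies the E-value filter, projects the surviving blocks onto both
#' genomes, measures per-genome covered length as an interval union (so one
#' locus hit by many alignments is counted once and `H_X <= S_X`), and forms
#' `HCR = (H_A + H_B) / (S_A + S_B)`.
#'
#' @param blocks Alignment blocks from [parse_alignments()].
#' @param genome_a,genome_b The two [genome_assembly()] objects, supplying
#'   total lengths and contig bounds.
#' @param threshold E-value cutoff (default `1e-10`).
#' @return One-row data.frame with columns `accession_a`, `accession_b`,
#'   `S_a`, `S_b`, `H_a`, `H_b`, `hcr`, `n_blocks_used`, `n_blocks_filtered`.
#' @export
hcr_alignment <- function(blocks, genome_a, genome_b, threshold = 1e-10) {
  stopifnot(inherits(genome_a, "genome_assembly"),
            inherits(genome_b, "genome_assembly"))
  used <- filter_by_evalue(blocks, threshold)
  check_bounds <- function(ctg, start, end, genome, side) {
    len <- stats::setNames(nchar(genome$sequence), genome$contig_id)
    unknown <- !(ctg %in% genome$contig_id)
    if (any(unknown)) {
      stop_input("block ", which(unknown)[1L], ": contig '",
                 ctg[unknown][1L], "' not in assembly '",
                 genome$accession, "' (side ", side, ")")
    }
    over <- end > len[ctg] | start < 0L
    if (any(over)) {
      stop_input("block ", which(over)[1L], " exceeds bounds of contig '",
                 ctg[over][1L], "' in assembly '", genome$accession, "'")
    }
  }
  if (nrow(used) > 0L) {
    check_bounds(used$contig_a, used$start_a, used$end_a, genome_a, "A")
    check_bounds(used$contig_b, used$start_b, used$end_b, genome_b, "B")
  }
  h_a <- union_length(used$start_a, used$end_a, used$contig_a)
  h_b <- union_length(used$start_b, used$end_b, used$contig_b)
  data.frame(
    accession_a = genome_a$accession,
    accession_b = genome_b$accession,
    S_a = genome_a$total_length, S_b = genome_b$total_length,
    H_a = h_a, H_b = h_b,
    hcr = (h_a + h_b) / (genome_a$total_length + genome_b$total_length),
    n_blocks_used = nrow(used),
    n_blocks_filtered = nrow(blocks) - nrow(used),
    stringsAsFactors = FALSE
  )
}

#' Write coverage results to TSV
#'
#' @param results Data.frame of [hcr_alignment()] rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_results <- function(results, path) {
  out <- results
  out$hcr <- sprintf("%.9f", out$hcr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run an external pairwise aligner (optional convenience)
#'
#' Writes the two assemblies to temporary FASTA files and invokes an aligner
#' through a command template containing the placeholders `{a}`, `{b}` and
#' `{out}`. The core library never requires this: alignment files may always
#' be supplied directly to [parse_alignments()].
#'
#' @param genome_a,genome_b `genome_assembly` objects.
#' @param command Template string, e.g.
#'   `"lastal -f TAB db_{a} {b} > {out}"`; every placeholder must appear.
#' @param out Output file path (substituted for `{out}`).
#' @return `out`, invisibly.
#' @export
run_external_aligner <- function(genome_a, genome_b, command,
                                 out = tempfile(fileext = ".aln")) {
  for (ph in c("{a}", "{b}", "{out}")) {
    if (!grepl(ph, command, fixed = TRUE)) {
      stop_config("aligner command template lacks placeholder ", ph)
    }
  }
  exe <- strsplit(trimws(command), "[ \t]+")[[1]][1L]
  if (Sys.which(exe) == "") {
    stop_env("aligner executable '", exe, "' not found on PATH; ",
             "run the aligner yourself and supply its output ",
             "to parse_alignments() instead")
  }
  fa <- tempfile(fileext = ".fasta")
  fb <- tempfile(fileext = ".fasta")
  write_genome_fasta(genome_a, fa)
  write_genome_fasta(genome_b, fb)
  cmd <- command
  cmd <- gsub("{a}", fa, cmd, fixed = TRUE)
  cmd <- gsub("{b}", fb, cmd, fixed = TRUE)
  cmd <- gsub("{out}", out, cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L) stop_env("aligner exited with status ", status)
  invisible(out)
}
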