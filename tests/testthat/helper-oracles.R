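# Independent brute-force oracles: deliberately naive, character-by-character
# implementations kept separate from the package's code paths.

oracle_revcomp <- function(kmer) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", kmer), "")[[1]]), collapse = "")
}

# all distinct k-mers of a sequence by explicit window loop
oracle_kmer_set <- function(seq, k, canonical = FALSE) {
  n <- nchar(seq)
  out <- character(0)
  if (n >= k) {
    for (i in seq_len(n - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      if (canonical) {
        rc <- oracle_revcomp(w)
        if (rc < w) w <- rc
      }
      out <- c(out, w)
    }
  }
  unique(out)
}

oracle_hcr_kmer <- function(seq_a, seq_b, k, canonical = FALSE) {
  a <- oracle_kmer_set(seq_a, k, canonical)
  b <- oracle_kmer_set(seq_b, k, canonical)
  hit <- sum(a %in% b)
  (hit + sum(b %in% a)) / (length(a) + length(b))
}

# covered bases by explicit per-base boolean arrays, one per contig
oracle_union_length <- function(start, end, contig = NULL) {
  if (length(start) == 0) return(0L)
  if (is.null(contig)) contig <- rep("*", length(start))
  total <- 0L
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    covered <- logical(max(end[sel]))
    for (i in which(sel)) {
      covered[(start[i] + 1):end[i]] <- TRUE
    }
    total <- total + sum(covered)
  }
  total
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(headers, seqs, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  con <- if (grepl("\\.gz$", ext)) gzfile(path, "w") else file(path, "w")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), con)
  close(con)
  path
}
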