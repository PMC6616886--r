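# Deterministic synthetic data: random genomes, genome pairs with a planted
# shared-homology fraction, and planted taxonomies with controllable intra-
# and inter-genus relatedness. Copied segments receive substitutions only
# (no indels), so planted coordinates stay exact and the expected coverage
# ratio of a planted layout is available in closed form.

BASES <- c("A", "C", "G", "T")

rand_seq_chr <- function(n) sample(BASES, n, replace = TRUE)

#' Generate a random genome
#'
#' One contig of i.i.d. uniform A/C/G/T, reproducible by seed.
#'
#' @param length Genome length in bases (> 0).
#' @param seed Integer seed.
#' @param accession Assembly identifier; defaults to `"synth<seed>"`.
#' @return A [genome_assembly()] with a single contig `chr1`.
#' @export
random_genome <- function(length, seed, accession = paste0("synth", seed)) {
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) stop_input("length must be positive")
  seq <- with_local_seed(seed, paste(rand_seq_chr(length), collapse = ""))
  genome_assembly(accession, seq, contig_id = "chr1")
}

# split total into n near-equal positive parts (first part takes remainder)
split_lengths <- function(total, n) {
  if (total <= 0L) return(integer(0))
  n <- min(n, total)
  base <- total %/% n
  lens <- rep(base, n)
  lens[1L] <- lens[1L] + total - base * n
  lens
}

# place segments of the given lengths without overlap on a sequence of
# length n: one segment per equal-width block, uniform offset inside it
place_segments <- function(lens, n) {
  k <- length(lens)
  if (k == 0L) return(integer(0))
  block <- n %/% k
  if (any(lens > block)) {
    stop_input("cannot place ", k, " non-overlapping segments of up to ",
               max(lens), " bases on a ", n,
               "-base sequence; use fewer or shorter segments")
  }
  starts <- integer(k)
  for (i in seq_len(k)) {
    slack <- block - lens[i]
    starts[i] <- (i - 1L) * block +
      if (slack > 0L) sample.int(slack + 1L, 1L) - 1L else 0L
  }
  starts  # 0-based
}

mutate_chr <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  chars
}

#' Generate a genome pair with a planted shared-homology fraction
#'
#' Genome A is random; genome B is random background into which
#' `segment_count` non-overlapping segments copied from non-overlapping
#' source regions of A (totalling `shared_fraction * length_a` bases) are
#' planted, each independently mutated at `substitution_rate`. Because
#' sources and destinations never overlap, the planted per-genome
#' homologous fractions are exact.
#'
#' @param length_a,length_b Genome lengths; requires
#'   `shared_fraction * length_a <= length_b`.
#' @param shared_fraction Fraction of genome A copied into B, in `[0, 1]`.
#' @param substitution_rate Per-base substitution probability applied to the
#'   copied segments, in `[0, 1)`.
#' @param segment_count Number of planted segments.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `genome_a`, `genome_b`, `segments` (data.frame of
#'   0-based half-open source/destination coordinates), and the exact
#'   `planted_fraction_a`, `planted_fraction_b`.
#' @export
make_pair <- function(length_a, length_b = length_a, shared_fraction = 0.5,
                      substitution_rate = 0, segment_count = 5L, seed = 1L) {
  length_a <- as.integer(length_a); length_b <- as.integer(length_b)
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop_input("shared_fraction must be in [0, 1]")
  }
  if (substitution_rate < 0 || substitution_rate >= 1) {
    stop_input("substitution_rate must be in [0, 1)")
  }
  total <- round(shared_fraction * length_a)
  if (total > length_b) {
    stop_input("shared_fraction * length_a exceeds length_b")
  }
  with_local_seed(seed, {
    a <- rand_seq_chr(length_a)
    b <- rand_seq_chr(length_b)
    lens <- split_lengths(total, segment_count)
    if (length(lens) > 0L) {
      src <- place_segments(lens, length_a)
      dst <- place_segments(lens, length_b)
      for (i in seq_along(lens)) {
        seg <- a[(src[i] + 1L):(src[i] + lens[i])]
        b[(dst[i] + 1L):(dst[i] + lens[i])] <- mutate_chr(seg,
                                                          substitution_rate)
      }
      segments <- data.frame(start_a = src, end_a = src + lens,
                             start_b = dst, end_b = dst + lens,
                             length = lens)
    } else {
      segments <- data.frame(start_a = integer(0), end_a = integer(0),
                             start_b = integer(0), end_b = integer(0),
                             length = integer(0))
    }
    list(
      genome_a = genome_assembly(paste0("synthA", seed),
                                 paste(a, collapse = ""),
                                 contig_id = "chrA"),
      genome_b = genome_assembly(paste0("synthB", seed),
                                 paste(b, collapse = ""),
                                 contig_id = "chrB"),
      segments = segments,
      planted_fraction_a = sum(lens) / length_a,
      planted_fraction_b = sum(lens) / length_b
    )
  })
}

#' Generate a planted taxonomy of related genomes
#'
#' Every genome is one contig of length `genome_length` laid out as
#' `[shared backbone | genus backbone | free tail]`: the leading
#' `inter_fraction` of every genome is a backbone common to all genera, the
#' next `intra_fraction - inter_fraction` is a genus-private backbone, and
#' the tail is genome-private random sequence. Within-genus pairs therefore
#' share a fraction `intra_fraction` of their length and cross-genus pairs
#' `inter_fraction`. When `ambiguous_pair = c(i, j)` is given, the first
#' genome of genus `j` has the region after its shared prefix overwritten
#' with the corresponding region of the first genome of genus `i`, so that
#' one cross-genus pair shares `ambiguous_fraction > intra_fraction` — a
#' planted classification ambiguity.
#'
#' @param n_genera Number of genera.
#' @param genomes_per_genus Genomes per genus.
#' @param intra_fraction Within-genus shared fraction (must exceed
#'   `inter_fraction`).
#' @param inter_fraction Cross-genus shared fraction.
#' @param ambiguous_pair Optional integer vector `c(i, j)` of genus indices
#'   to plant an ambiguity between.
#' @param ambiguous_fraction Shared fraction of the planted cross-genus pair
#'   (must exceed `intra_fraction`).
#' @param genome_length Genome length in bases.
#' @param seed Integer seed.
#' @return List with `genomes` (named list of [genome_assembly()]),
#'   `taxonomy` (data.frame), and `ambiguous` (the planted genus-name pair,
#'   or `NULL`).
#' @export
make_taxonomy_fixture <- function(n_genera = 3L, genomes_per_genus = 3L,
                                  intra_fraction = 0.6,
                                  inter_fraction = 0.1,
                                  ambiguous_pair = NULL,
                                  ambiguous_fraction = 0.7,
                                  genome_length = 20000L, seed = 1L) {
  if (intra_fraction <= inter_fraction) {
    stop_input("intra_fraction must exceed inter_fraction")
  }
  if (intra_fraction > 1 || inter_fraction < 0) {
    stop_input("fractions must lie in [0, 1]")
  }
  if (!is.null(ambiguous_pair)) {
    if (length(ambiguous_pair) != 2L ||
        any(ambiguous_pair < 1L | ambiguous_pair > n_genera) ||
        ambiguous_pair[1L] == ambiguous_pair[2L]) {
      stop_input("ambiguous_pair must name two distinct genus indices")
    }
    if (ambiguous_fraction <= intra_fraction || ambiguous_fraction > 1) {
      stop_input("ambiguous_fraction must exceed intra_fraction (and be <= 1)")
    }
  }
  L <- as.integer(genome_length)
  g_len <- as.integer(round(inter_fraction * L))
  q_len <- as.integer(round(intra_fraction * L))
  with_local_seed(seed, {
    global_bb <- rand_seq_chr(g_len)
    genomes <- list()
    tax <- list()
    seqs <- list()  # per-accession character vectors, for the planted copy
    for (gi in seq_len(n_genera)) {
      genus_bb <- c(global_bb, rand_seq_chr(q_len - g_len))
      for (si in seq_len(genomes_per_genus)) {
        acc <- sprintf("G%02dS%02d", gi, si)
        seqs[[acc]] <- c(genus_bb, rand_seq_chr(L - q_len))
        tax[[acc]] <- data.frame(
          accession = acc,
          species = sprintf("Genus%02d sp%02d", gi, si),
          genus = sprintf("Genus%02d", gi),
          phylum = sprintf("Phylum%02d", gi),
          domain = "Bacteria", stringsAsFactors = FALSE
        )
      }
    }
    ambiguous <- NULL
    if (!is.null(ambiguous_pair)) {
      p_len <- as.integer(round(ambiguous_fraction * L))
      src <- sprintf("G%02dS01", ambiguous_pair[1L])
      dst <- sprintf("G%02dS01", ambiguous_pair[2L])
      idx <- (g_len + 1L):p_len
      seqs[[dst]][idx] <- seqs[[src]][idx]
      ambiguous <- sprintf("Genus%02d", sort(ambiguous_pair))
    }
    for (acc in names(seqs)) {
      genomes[[acc]] <- genome_assembly(acc, paste(seqs[[acc]],
                                                   collapse = ""),
                                        contig_id = "chr1")
    }
    list(genomes = genomes, taxonomy = do.call(rbind, unname(tax)),
         ambiguous = ambiguous)
  })
}

#' Write a tabular alignment fixture for a planted genome pair
#'
#' Emits one 12-column BLAST-style tabular record per planted segment of a
#' [make_pair()] result, with caller-supplied E-values, so the expected
#' alignment coverage ratio is computable in closed form from the planted
#' layout.
#'
#' @param pair A [make_pair()] result.
#' @param path Output path.
#' @param evalues E-value(s) assigned to the records (recycled).
#' @return `path`, invisibly.
#' @export
emit_alignment_fixture <- function(pair, path, evalues = 1e-20) {
  seg <- pair$segments
  n <- nrow(seg)
  evalues <- rep_len(evalues, if (n > 0L) n else 0L)
  lines <- character(n)
  for (i in seq_len(n)) {
    lines[i] <- paste(
      pair$genome_a$contig_id[1L], pair$genome_b$contig_id[1L],
      "100.000", seg$length[i], 0L, 0L,
      seg$start_a[i] + 1L, seg$end_a[i],
      seg$start_b[i] + 1L, seg$end_b[i],
      format(evalues[i], scientific = TRUE), 2L * seg$length[i],
      sep = "\t"
    )
  }
  writeLines(lines, path)
  invisible(path)
}
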