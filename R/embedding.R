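# Ordination of HCR scores: distances d = 1 - HCR (identical genomes at
# distance 0), embedded in the plane by classical (Torgerson) metric MDS.

#' Distance matrix from pairwise HCR scores
#'
#' Builds the symmetric matrix `d[i, j] = 1 - hcr(i, j)` with a zero
#' diagonal. Every unordered pair of the accession set must be scored.
#'
#' @param scores Pair-score data.frame (`accession_a`, `accession_b`, `hcr`).
#' @param accessions Optional accession order; defaults to the sorted set of
#'   accessions occurring in `scores`.
#' @return Square symmetric numeric matrix with accession dimnames.
#' @export
distance_from_scores <- function(scores, accessions = NULL) {
  if (is.null(accessions)) {
    accessions <- sort(unique(c(scores$accession_a, scores$accession_b)))
  }
  n <- length(accessions)
  if (n < 2L) stop_input("need at least two accessions")
  if (any(scores$hcr < 0 | scores$hcr > 1)) {
    stop_input("hcr values outside [0, 1]")
  }
  d <- matrix(NA_real_, n, n, dimnames = list(accessions, accessions))
  diag(d) <- 0
  ia <- match(scores$accession_a, accessions)
  ib <- match(scores$accession_b, accessions)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(scores$accession_a[is.na(ia)],
                    scores$accession_b[is.na(ib)]))
    stop_input("scored accession(s) not in requested set: ",
               paste(bad, collapse = ", "))
  }
  d[cbind(ia, ib)] <- 1 - scores$hcr
  d[cbind(ib, ia)] <- 1 - scores$hcr
  if (anyNA(d)) {
    miss <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop_input("missing pair score(s): ",
               paste(paste(accessions[miss[, 1L]], accessions[miss[, 2L]],
                           sep = " & "),
                     collapse = ", "))
  }
  d
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson scaling: squared distances are double-centred and the top
#' non-negative eigenpairs give coordinates (negative eigenvalues contribute
#' nothing). A fixed sign convention — the largest-magnitude coordinate of
#' each axis is made positive — makes the ordination reproducible
#' bit-for-bit.
#'
#' @param d Square symmetric distance matrix (from
#'   [distance_from_scores()]), or a [stats::dist] object.
#' @param dims Number of output dimensions (default 2); requires
#'   `n >= dims + 1` points.
#' @return Object of class `hcr_ordination`: list with `accessions`,
#'   `coords` (`n x dims`, columns centred) and `eigenvalues` (first `dims`
#'   eigenvalues of the double-centred matrix).
#' @export
classical_mds <- function(d, dims = 2L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  dims <- as.integer(dims)
  if (n <= dims) {
    stop_input("need at least dims + 1 = ", dims + 1L, " points, got ", n)
  }
  accessions <- rownames(d)
  if (is.null(accessions)) accessions <- paste0("obj", seq_len(n))
  fit <- suppressWarnings(stats::cmdscale(d, k = dims, eig = TRUE))
  coords <- fit$points
  if (ncol(coords) < dims) {
    # rank-deficient configuration: pad truncated axes with zeros
    coords <- cbind(coords,
                    matrix(0, n, dims - ncol(coords)))
  }
  # axes with (numerically) non-positive eigenvalues contribute nothing
  null_axis <- fit$eig[seq_len(dims)] < max(fit$eig[1L], 0) * 1e-8
  coords[, null_axis] <- 0
  for (j in seq_len(dims)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(accessions, paste0("axis", seq_len(dims)))
  out <- list(accessions = accessions, coords = coords,
              eigenvalues = fit$eig[seq_len(dims)])
  class(out) <- "hcr_ordination"
  out
}

#' @export
print.hcr_ordination <- function(x, ...) {
  cat(sprintf("hcr_ordination: %d points in %d dimensions\n",
              length(x$accessions), ncol(x$coords)))
  cat("leading eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Write ordination coordinates to TSV
#'
#' Columns `accession`, `x`, `y` (first two axes) and `taxon_label`.
#'
#' @param ordination An `hcr_ordination`.
#' @param path Output path.
#' @param taxonomy Optional taxonomy data.frame supplying labels.
#' @param label_level Taxonomy column used for the label (default
#'   `"genus"`).
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(ordination, path, taxonomy = NULL,
                              label_level = "genus") {
  lab <- rep("", length(ordination$accessions))
  if (!is.null(taxonomy)) {
    m <- match(ordination$accessions, taxonomy$accession)
    lab <- ifelse(is.na(m), "", taxonomy[[label_level]][m])
  }
  out <- data.frame(accession = ordination$accessions,
                    x = ordination$coords[, 1L],
                    y = ordination$coords[, 2L],
                    taxon_label = lab, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of an ordination, coloured by taxon
#'
#' Thin base-graphics layer over the coordinates; the coordinates TSV is the
#' primary artifact.
#'
#' @param x An `hcr_ordination`.
#' @param taxonomy Optional taxonomy data.frame for colouring.
#' @param label_level Taxonomy column used for colours.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hcr_ordination <- function(x, taxonomy = NULL, label_level = "genus",
                                ...) {
  col <- "black"
  if (!is.null(taxonomy)) {
    m <- match(x$accessions, taxonomy$accession)
    grp <- factor(taxonomy[[label_level]][m])
    col <- as.integer(grp) + 1L
  }
  graphics::plot(x$coords[, 1L], x$coords[, 2L], col = col, pch = 19,
                 xlab = "MDS axis 1", ylab = "MDS axis 2", ...)
  if (!is.null(taxonomy)) {
    graphics::legend("topright", legend = levels(grp),
                     col = seq_along(levels(grp)) + 1L, pch = 19, cex = 0.7)
  }
  invisible(x)
}
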