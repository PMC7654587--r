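#' @useDynLib radialct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor prcomp quantile rpois runif rnorm sd loess predict
#'   setNames aggregate
#' @importFrom utils read.table write.table
"_PACKAGE"

#' Canonical chromosome order
#'
#' The 23 chromosomes retained by the method (22 autosomes plus chrX;
#' chrY is always excluded), in the fixed order used for all 23 x 23
#' summaries, distance-matrix columns and property vectors.
#'
#' @return Character vector `c("chr1", ..., "chr22", "chrX")`.
#' @export
ct_chromosomes <- function() paste0("chr", c(1:22, "X"))

## ---- bin table ----------------------------------------------------------

#' Construct a bin table
#'
#' A bin table annotates the rows/columns of a binned contact matrix with
#' genomic coordinates. Bins are 0-based half-open intervals; `bin_index`
#' equals the matrix row/column (0-based).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer genomic coordinates (bp), 0-based half-open.
#' @param mappable logical; bins flagged unmappable are removed by
#'   [filter_bins()]. Defaults to all `TRUE`.
#' @return A `data.frame` with columns `bin_index`, `chrom`, `start`,
#'   `end`, `mappable`.
#' @export
bin_table <- function(chrom, start, end, mappable = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  if (any(end <= start)) stop("bin table invariant violated: end <= start")
  if (is.null(mappable)) mappable <- rep(TRUE, length(chrom))
  data.frame(bin_index = seq_along(chrom) - 1L, chrom = chrom,
             start = start, end = end, mappable = as.logical(mappable),
             stringsAsFactors = FALSE)
}

#' Read a BED-like bin table
#'
#' Expects tab-separated columns chrom, start, end and an optional fourth
#' column with a 0/1 or TRUE/FALSE mappability flag.
#'
#' @param path file path.
#' @return bin table `data.frame` (see [bin_table()]).
#' @export
read_bin_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3) stop("bin table needs at least 3 columns (chrom, start, end)")
  mp <- if (ncol(tab) >= 4) tab[[4]] %in% c(1, "1", TRUE, "TRUE") else NULL
  bin_table(tab[[1]], tab[[2]], tab[[3]], mp)
}

#' Write a bin table as BED-like TSV
#'
#' @param bins bin table.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_bin_table <- function(bins, path) {
  write.table(data.frame(bins$chrom, bins$start, bins$end,
                         as.integer(bins$mappable)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- contact matrix container ------------------------------------------

#' Construct a binned Hi-C contact matrix
#'
#' Bundles a square symmetric non-negative contact matrix with its bin
#' annotation. This is the container every pipeline stage consumes.
#'
#' @param values square numeric matrix of contact counts/frequencies.
#' @param bins bin table whose number of rows equals `nrow(values)`.
#' @param normalized logical; `TRUE` after ICE balancing.
#' @param tol symmetry tolerance (relative).
#' @return Object of class `hic_matrix`: list with elements `values`,
#'   `bins`, `normalized`.
#' @export
hic_matrix <- function(values, bins, normalized = FALSE, tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (nrow(values) != nrow(bins))
    stop("dimension mismatch: matrix has ", nrow(values),
         " bins but bin table has ", nrow(bins))
  if (any(values < 0)) stop("contact matrix must be non-negative")
  asym <- max(abs(values - t(values)))
  if (asym > tol * max(1, max(abs(values))))
    stop("contact matrix is asymmetric beyond tolerance (max |h_ij - h_ji| = ",
         signif(asym, 4), ")")
  values <- (values + t(values)) / 2  # enforce exact symmetry
  dimnames(values) <- NULL
  structure(list(values = values, bins = bins,
                 normalized = isTRUE(normalized)),
            class = "hic_matrix")
}

#' @export
print.hic_matrix <- function(x, ...) {
  cat("Binned Hi-C contact matrix\n")
  cat("  bins       :", nrow(x$bins), "on",
      length(unique(x$bins$chrom)), "chromosomes\n")
  cat("  normalized :", x$normalized, "\n")
  cat("  total      :", format(sum(x$values)), "\n")
  invisible(x)
}

#' Read a binned Hi-C matrix from disk
#'
#' Two plain-text dialects are supported: `dense` (whitespace/TSV square
#' numeric matrix) and `triplet` (TSV `bin1 <TAB> bin2 <TAB> count`,
#' 0-based bin indices; each off-diagonal record populates both (i,j) and
#' (j,i)).
#'
#' @param path matrix file.
#' @param bins bin table (see [read_bin_table()]); its length fixes the
#'   matrix dimension.
#' @param dialect `"dense"` or `"triplet"`.
#' @return raw (unnormalized) [hic_matrix()].
#' @export
read_hic_matrix <- function(path, bins, dialect = c("dense", "triplet")) {
  dialect <- match.arg(dialect)
  m <- nrow(bins)
  if (dialect == "dense") {
    vals <- as.matrix(read.table(path, header = FALSE, comment.char = "#"))
    if (nrow(vals) != ncol(vals))
      stop("dense matrix file is not square: ", nrow(vals), " x ", ncol(vals))
    if (nrow(vals) != m)
      stop("dimension mismatch: matrix is ", nrow(vals), " x ", ncol(vals),
           " but bin table has ", m, " bins")
    storage.mode(vals) <- "double"
    hic_matrix(vals, bins)
  } else {
    tr <- read.table(path, header = FALSE, comment.char = "#")
    if (ncol(tr) != 3) stop("triplet file needs 3 columns (bin1, bin2, count)")
    i <- as.integer(tr[[1]]); j <- as.integer(tr[[2]]); v <- as.numeric(tr[[3]])
    if (any(i < 0L) || any(j < 0L) || any(i >= m) || any(j >= m))
      stop("dimension mismatch: triplet references bin index ",
           max(c(i, j)), " but bin table has ", m, " bins")
    vals <- matrix(0, m, m)
    vals[cbind(i + 1L, j + 1L)] <- v
    vals[cbind(j + 1L, i + 1L)] <- v  # symmetrize
    hic_matrix(vals, bins)
  }
}

#' Write a Hi-C matrix to disk
#'
#' @param H [hic_matrix()].
#' @param path destination file.
#' @param dialect `"dense"` or `"triplet"` (upper triangle incl. diagonal,
#'   zeros omitted).
#' @return `path`, invisibly.
#' @export
write_hic_matrix <- function(H, path, dialect = c("dense", "triplet")) {
  dialect <- match.arg(dialect)
  if (dialect == "dense") {
    write.table(H$values, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    m <- nrow(H$values)
    idx <- which(upper.tri(H$values, diag = TRUE) & H$values != 0,
                 arr.ind = TRUE)
    write.table(data.frame(idx[, 1] - 1L, idx[, 2] - 1L,
                           H$values[idx]),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

## ---- filtering and balancing -------------------------------------------

#' Remove chrY and unmappable bins from a contact matrix
#'
#' chrY is always dropped (it is absent from female cells, so the method
#' works on the 22 autosomes plus chrX). Bins flagged unmappable in the
#' bin table are dropped; when `auto_flag_empty = TRUE` (default) a bin
#' whose raw row sum is zero is additionally treated as unmappable, since
#' an operational unmappable-region mask is rarely available.
#'
#' @param H [hic_matrix()].
#' @param auto_flag_empty flag all-zero bins as unmappable.
#' @return filtered [hic_matrix()] with a re-indexed bin table.
#' @export
filter_bins <- function(H, auto_flag_empty = TRUE) {
  keep <- H$bins$mappable & H$bins$chrom != "chrY"
  if (auto_flag_empty) keep <- keep & rowSums(H$values) > 0
  before <- unique(H$bins$chrom[H$bins$chrom != "chrY"])
  bins <- H$bins[keep, , drop = FALSE]
  lost <- setdiff(before, unique(bins$chrom))
  if (length(lost))
    warning("all bins removed for: ", paste(lost, collapse = ", "))
  bins$bin_index <- seq_len(nrow(bins)) - 1L
  rownames(bins) <- NULL
  hic_matrix(H$values[keep, keep, drop = FALSE], bins,
             normalized = H$normalized)
}

#' ICE balancing of a contact matrix
#'
#' Iterative correction: each iteration divides the matrix by the outer
#' product of its (scaled) row-coverage vector, converging to a matrix
#' with uniform row sums. The result is rescaled so its total equals the
#' input total, and marked `normalized`.
#'
#' @param H raw, filtered [hic_matrix()]; no all-zero bins.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the coefficient of variation of
#'   the row sums.
#' @return normalized [hic_matrix()].
#' @export
ice_normalize <- function(H, max_iter = 200, tol = 1e-6) {
  vals <- H$values
  rs <- rowSums(vals)
  if (any(rs == 0))
    stop("zero-sum bin present; run filter_bins() before ice_normalize()")
  total <- sum(vals)
  cv <- Inf
  for (it in seq_len(max_iter)) {
    rs <- rowSums(vals)
    cv <- sd(rs) / mean(rs)
    if (is.na(cv)) cv <- 0  # 1x1 matrix
    if (cv < tol) break
    b <- rs / mean(rs)
    vals <- vals / outer(b, b)
  }
  if (cv >= tol)
    warning("ICE did not reach tol in ", max_iter,
            " iterations (row-sum CV = ", signif(cv, 4), ")")
  vals <- vals * (total / sum(vals))
  out <- hic_matrix(vals, H$bins, normalized = TRUE)
  out
}

## ---- chromosome properties ---------------------------------------------

#' Construct a chromosome property table
#'
#' Per-chromosome gene density (genes per sequenced Mb) and length (bp)
#' for the 23 retained chromosomes, used both to interpret the principal
#' components of the contact pattern and to tune consensus radial
#' distances.
#'
#' @param chrom chromosome names (must cover [ct_chromosomes()]).
#' @param gene_density genes per sequenced Mb, positive.
#' @param length_bp chromosome length in bp, positive.
#' @return `data.frame` with columns `chrom`, `gene_density`,
#'   `length_bp`, ordered chr1..chr22, chrX.
#' @export
chrom_properties <- function(chrom, gene_density, length_bp) {
  chrom <- as.character(chrom)
  want <- ct_chromosomes()
  if (!setequal(chrom, want))
    stop("property table must contain exactly chr1..chr22 and chrX")
  if (any(gene_density <= 0) || any(length_bp <= 0))
    stop("gene_density and length_bp must be positive")
  o <- match(want, chrom)
  data.frame(chrom = want, gene_density = as.numeric(gene_density)[o],
             length_bp = as.numeric(length_bp)[o], stringsAsFactors = FALSE)
}

#' Read a chromosome property TSV
#'
#' Expects a header line and columns `chrom`, `gene_density`, `length_bp`.
#'
#' @param path file path.
#' @return property table (see [chrom_properties()]).
#' @export
read_chrom_properties <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
  chrom_properties(tab$chrom, tab$gene_density, tab$length_bp)
}

#' hg19 chromosome properties
#'
#' Compiled reference table of hg19 chromosome lengths (UCSC) and
#' protein-coding gene densities in genes per sequenced Mb, shipped with
#' the package.
#'
#' @return property table (see [chrom_properties()]).
#' @export
hg19_chrom_properties <- function() {
  read_chrom_properties(system.file("extdata", "hg19_chrom_properties.tsv",
                                    package = "radialct", mustWork = TRUE))
}
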