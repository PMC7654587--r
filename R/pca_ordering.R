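## PCA of the pairwise trans strong-contact pattern: radial ordering and
## distribution-type inference.

#' Project chromosomes onto principal components of the trans pattern
#'
#' Treats each chromosome's row of the trans-only strong-contact count
#' matrix as its interaction profile, mean-centers the columns (no
#' standardization) and computes principal components. The projection on
#' PC1 captures the dominant axis of dissimilarity between chromosome
#' territories, which tracks their radial ordering.
#'
#' Sign conventions (PCA signs are arbitrary): PC1 is oriented so that
#' its correlation with chromosome length is non-negative when lengths
#' are supplied, otherwise so that its largest-magnitude score is
#' positive; PC2 so that its largest-magnitude loading is positive.
#'
#' @param chr_trans symmetric non-negative matrix with zero diagonal
#'   (from [summarize_by_chromosome()]), rows/columns named by
#'   chromosome.
#' @param lengths optional per-chromosome lengths used only for the PC1
#'   sign convention.
#' @return object of class `ct_ordering`: list with `pc_scores`
#'   (chromosomes x 2), `var_explained` (all PC variance fractions),
#'   `chrom_order`.
#' @export
pca_project <- function(chr_trans, lengths = NULL) {
  chr_trans <- as.matrix(chr_trans)
  if (nrow(chr_trans) != ncol(chr_trans))
    stop("chr_trans must be square")
  if (any(diag(chr_trans) != 0)) stop("chr_trans must have a zero diagonal")
  if (all(chr_trans == 0)) stop("zero matrix: no variance to decompose")
  chroms <- rownames(chr_trans)
  if (is.null(chroms)) chroms <- ct_chromosomes()[seq_len(nrow(chr_trans))]
  pc <- prcomp(chr_trans, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  ## sign conventions
  if (!is.null(lengths) && cor(scores[, 1], lengths) < 0) {
    scores[, 1] <- -scores[, 1]
  } else if (is.null(lengths) &&
             scores[which.max(abs(scores[, 1])), 1] < 0) {
    scores[, 1] <- -scores[, 1]
  }
  l2 <- pc$rotation[, 2]
  if (l2[which.max(abs(l2))] < 0) scores[, 2] <- -scores[, 2]
  rownames(scores) <- chroms
  colnames(scores) <- c("PC1", "PC2")
  structure(list(pc_scores = scores, var_explained = ve,
                 chrom_order = chroms),
            class = "ct_ordering")
}

#' Infer the territory distribution type
#'
#' Correlates the PC1 projection with gene density and with chromosome
#' length; whichever has the larger absolute Pearson correlation names
#' the inferred radial distribution type. Ties break toward `length`
#' (the pattern random data drifts to). Gene-density organization —
#' gene-rich territories internal — is typical of spherical
#' (lymphoblastoid-like) nuclei; length organization — short territories
#' internal — of ellipsoidal (fibroblast-like) nuclei.
#'
#' @param ordering `ct_ordering` from [pca_project()].
#' @param props property table (see [chrom_properties()]) covering the
#'   ordering's chromosomes.
#' @return the `ct_ordering` completed with `corr_gene_density`,
#'   `corr_length`, `inferred_type`.
#' @export
infer_distribution_type <- function(ordering, props) {
  o <- match(ordering$chrom_order, props$chrom)
  if (anyNA(o)) stop("property table does not cover the ordering's chromosomes")
  pc1 <- ordering$pc_scores[, 1]
  if (sd(pc1) == 0) stop("constant PC1: cannot infer distribution type")
  cg <- cor(pc1, props$gene_density[o])
  cl <- cor(pc1, props$length_bp[o])
  ordering$corr_gene_density <- cg
  ordering$corr_length <- cl
  ordering$inferred_type <-
    if (abs(cg) > abs(cl)) "gene_density" else "length"
  ordering
}

#' Order chromosomes along PC1
#'
#' Sorts chromosomes by their PC1 projection. The center-to-periphery
#' direction of that axis cannot be read from the contact data alone;
#' supply an `anchor` chromosome known to sit at the periphery (chrX in
#' the cell types where it is peripheral) to orient the ordering, else
#' the direction is reported as `"arbitrary"`.
#'
#' @param ordering `ct_ordering`.
#' @param anchor optional chromosome name anchoring the peripheral end.
#' @return list with `chrom` (chromosomes sorted center to periphery
#'   when anchored), `pc1`, `rank`, `direction` (`"anchored"` or
#'   `"arbitrary"`).
#' @export
radial_order <- function(ordering, anchor = NULL) {
  pc1 <- ordering$pc_scores[, 1]
  ord <- order(pc1)
  direction <- "arbitrary"
  if (!is.null(anchor)) {
    if (!anchor %in% ordering$chrom_order)
      stop("anchor chromosome not present: ", anchor)
    r <- rank(pc1)[match(anchor, ordering$chrom_order)]
    n <- length(pc1)
    if (r > n / 3 && r <= 2 * n / 3)
      warning("anchor ", anchor,
              " is not in an extreme tercile of PC1; orientation unreliable")
    if (r <= n / 2) ord <- rev(ord)  # anchor (periphery) goes last
    direction <- "anchored"
  }
  list(chrom = ordering$chrom_order[ord], pc1 = unname(pc1[ord]),
       rank = seq_along(ord), direction = direction)
}

#' @export
print.ct_ordering <- function(x, ...) {
  cat("Chromosome-territory PCA ordering\n")
  cat("  variance explained: PC1 ",
      sprintf("%.1f%%", 100 * x$var_explained[1]), ", PC2 ",
      sprintf("%.1f%%", 100 * x$var_explained[2]), "\n", sep = "")
  if (!is.null(x$inferred_type)) {
    cat(sprintf("  corr(PC1, gene density) = %+.3f\n", x$corr_gene_density))
    cat(sprintf("  corr(PC1, length)       = %+.3f\n", x$corr_length))
    cat("  inferred distribution type:", x$inferred_type, "\n")
  }
  invisible(x)
}
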