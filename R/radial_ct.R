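## The top-level estimator: from a binned contact matrix to a tuned
## radial chromosome-territory profile.

#' Infer radial chromosome-territory organization from a Hi-C matrix
#'
#' Runs the full inference pipeline on a binned genome-wide contact
#' matrix: (1) bin filtering and ICE balancing (skipped for an already
#' normalized input); (2) percentile thresholding into strong
#' interactions and per-chromosome-pair counting; (3) PCA of the trans
#' strong-contact pattern, giving the radial ordering and the inferred
#' distribution type (gene-density vs length); (4) an ensemble of
#' `n_models` 3D force-directed layouts of the strong-contact graph,
#' each fitted with a minimum-volume enclosing ellipsoid to yield
#' normalized radial territory distances; (5) deterministic K-means
#' clustering of the models and selection of the cluster matching the
#' inferred type; (6) chromosome-property tuning of the consensus
#' profile by weighted PC averaging and loess smoothing.
#'
#' All randomness is controlled by `base_seed`; identical inputs and
#' settings reproduce identical results.
#'
#' @param H [hic_matrix()], raw or normalized.
#' @param props chromosome property table (see [chrom_properties()];
#'   default [hg19_chrom_properties()]).
#' @param percentile strong-interaction percentile (default 95).
#' @param n_models layout ensemble size (analysis default 1000; use
#'   ~50 for desk-scale runs).
#' @param base_seed first layout seed.
#' @param anchor optional peripheral anchor chromosome for
#'   [radial_order()].
#' @param k_range candidate cluster counts.
#' @param iterations,gravity force-layout parameters (see
#'   [fr_layout_3d()]).
#' @param epsilon ellipsoid tolerance (see [fit_mve()]).
#' @param span,degree loess parameters (see [loess_tune()]).
#' @param min_size smallest selectable model cluster (see
#'   [select_cluster()]).
#' @param stop_after run only part of the pipeline: `"order"` stops
#'   after the PCA ordering, `"ensemble"` after the distance matrix,
#'   `"cluster"` after cluster selection, `"tune"` (default) runs all.
#' @return object of class `radialct_fit` with elements `hcut`,
#'   `summary` (chromosome-pair counts), `ordering`, `radial_order`,
#'   `distances`, `k_selection`, `cluster`, `profile`, plus the `call`
#'   and settings. Stages beyond `stop_after` are `NULL`.
#' @export
radial_ct <- function(H, props = hg19_chrom_properties(),
                      percentile = 95, n_models = 1000, base_seed = 1,
                      anchor = NULL, k_range = 2:15,
                      iterations = 500, gravity = 1, epsilon = 1e-3,
                      span = 0.75, degree = 2, min_size = 5,
                      stop_after = c("tune", "order", "ensemble",
                                     "cluster")) {
  stop_after <- match.arg(stop_after)
  if (!inherits(H, "hic_matrix")) stop("H must be a hic_matrix")
  if (stop_after != "order" && is.null(props))
    stop("a chromosome property table is required beyond the ordering stage")

  if (!H$normalized) H <- ice_normalize(filter_bins(H))
  hcut <- compute_hcut(H, percentile)
  S <- threshold_strong(H, hcut)
  summ <- summarize_by_chromosome(S)
  lens <- props$length_bp[match(summ$chrom_order, props$chrom)]
  ordering <- pca_project(summ$chr_trans, lengths = lens)
  ordering <- infer_distribution_type(ordering, props)
  rorder <- radial_order(ordering, anchor = anchor)

  fit <- structure(list(call = match.call(), hcut = hcut,
                        percentile = percentile, summary = summ,
                        ordering = ordering, radial_order = rorder,
                        distances = NULL, k_selection = NULL,
                        cluster = NULL, profile = NULL,
                        n_models = n_models, base_seed = base_seed,
                        props = props),
                   class = "radialct_fit")
  if (stop_after == "order") return(fit)

  G <- build_graph(S)
  ensemble <- generate_ensemble(G, n_models = n_models,
                                base_seed = base_seed,
                                iterations = iterations,
                                gravity = gravity)
  fit$distances <- build_distance_matrix(ensemble, epsilon = epsilon)
  if (stop_after == "ensemble") return(fit)

  ks <- choose_k(fit$distances, k_range = k_range)
  fit$k_selection <- ks[c("k", "elbow_k", "inertia_curve",
                          "silhouette_by_k")]
  labels <- ks$fits[[as.character(ks$k)]]$labels
  fit$cluster <- select_cluster(labels, fit$distances, props,
                                ordering$inferred_type,
                                min_size = min_size)
  if (stop_after == "cluster") return(fit)

  fit$profile <- tune_profile(fit$cluster, props, span = span,
                              degree = degree, min_models = min_size)
  fit
}

#' @export
print.radialct_fit <- function(x, ...) {
  cat("Radial chromosome-territory organization fit\n")
  cat("  strong-contact threshold:", signif(x$hcut, 5),
      sprintf("(%gth percentile)\n", x$percentile))
  cat("  inferred distribution type:", x$ordering$inferred_type,
      sprintf("(corr GD %+.3f, corr length %+.3f)\n",
              x$ordering$corr_gene_density, x$ordering$corr_length))
  if (!is.null(x$distances))
    cat("  ensemble:", nrow(x$distances$values), "models\n")
  if (!is.null(x$cluster))
    cat("  selected cluster:", x$cluster$selected_cluster, "of",
        x$cluster$k, "(", nrow(x$cluster$selected_models), "models, corr",
        sprintf("%+.3f", x$cluster$selection_corr), ")\n")
  if (!is.null(x$profile))
    cat("  tuned profile: W1 =", sprintf("%.3f", x$profile$W1), "\n")
  invisible(x)
}

#' @export
summary.radialct_fit <- function(object, ...) {
  print(object)
  cat("\nRadial ordering (", object$radial_order$direction,
      " direction):\n  ", sep = "")
  cat(object$radial_order$chrom, sep = " ")
  cat("\n")
  if (!is.null(object$profile)) {
    cat("\nTuned radial distances:\n")
    print(as.data.frame(object$profile), digits = 3)
  }
  invisible(object)
}

#' Tuned radial distances of a fit
#'
#' @param object `radialct_fit`.
#' @param ... unused.
#' @return named vector of tuned radial distances (or the PC1 scores if
#'   the pipeline stopped before tuning).
#' @export
coef.radialct_fit <- function(object, ...) {
  if (!is.null(object$profile)) object$profile$tuned
  else setNames(object$ordering$pc_scores[, 1],
                object$ordering$chrom_order)
}

#' @export
fitted.radialct_fit <- function(object, ...) coef(object)

#' Diagnostic plots of a radial-organization fit
#'
#' Left: chromosomes in the PC1/PC2 plane of the trans strong-contact
#' pattern. Right (when available): consensus (`M`) and tuned radial
#' distances per chromosome, ordered by tuned distance.
#'
#' @param x `radialct_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.radialct_fit <- function(x, ...) {
  has_profile <- !is.null(x$profile)
  if (has_profile) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  sc <- x$ordering$pc_scores
  graphics::plot(sc[, 1], sc[, 2], type = "n",
                 xlab = sprintf("PC1 (%.1f%%)",
                                100 * x$ordering$var_explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * x$ordering$var_explained[2]),
                 main = "Trans strong-contact PCA", ...)
  graphics::text(sc[, 1], sc[, 2],
                 sub("chr", "", rownames(sc)), cex = 0.8)
  if (has_profile) {
    p <- x$profile
    o <- order(p$tuned)
    graphics::plot(seq_along(o), p$tuned[o], type = "b", pch = 16,
                   ylim = range(c(p$tuned, p$M)),
                   xaxt = "n", xlab = "", ylab = "radial distance",
                   main = "Consensus and tuned profile")
    graphics::lines(seq_along(o), p$M[o], type = "b", pch = 1,
                    lty = 2, col = "grey40")
    graphics::axis(1, at = seq_along(o),
                   labels = sub("chr", "", x$profile$chrom_order[o]),
                   las = 2, cex.axis = 0.7)
    graphics::legend("topleft", legend = c("tuned", "consensus M"),
                     pch = c(16, 1), lty = c(1, 2),
                     col = c("black", "grey40"), bty = "n")
  }
  invisible(x)
}

#' Write the tabular outputs of a fit
#'
#' Writes `ordering.tsv` (chromosome, PC1, PC2, rank), `distances.tsv`
#' (model seed + one column per chromosome) and, when present,
#' `tuned.tsv` (chrom, M, P, C, R, tuned) into a directory. Headers
#' carry key settings as `# key: value` comment lines. Output is
#' deterministic given the fit.
#'
#' @param fit `radialct_fit`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_radialct <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- c(sprintf("# percentile: %g", fit$percentile),
           sprintf("# h_cut: %.10g", fit$hcut),
           sprintf("# inferred_type: %s", fit$ordering$inferred_type),
           sprintf("# corr_gene_density: %.10g",
                   fit$ordering$corr_gene_density),
           sprintf("# corr_length: %.10g", fit$ordering$corr_length))
  f <- file.path(dir, "ordering.tsv")
  writeLines(hdr, f)
  sc <- fit$ordering$pc_scores
  suppressWarnings(write.table(
    data.frame(chrom = rownames(sc), PC1 = sc[, 1], PC2 = sc[, 2],
               rank = rank(sc[, 1])),
    f, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  if (!is.null(fit$distances)) {
    d <- data.frame(seed = fit$distances$model_seeds,
                    fit$distances$values, check.names = FALSE)
    write.table(d, file.path(dir, "distances.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$profile)) {
    write.table(as.data.frame(fit$profile),
                file.path(dir, "tuned.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
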