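## Chromosome-property tuning of the selected cluster's consensus radial
## distances: weighted PC averaging plus loess smoothing.

#' PC1 of the chromosome correlation structure of the selected cluster
#'
#' Computes the pairwise Pearson correlation matrix between chromosome
#' columns of the selected model sub-matrix, applies PCA to it, and
#' returns the chromosome projections on PC1 — the dominant axis of
#' separation between chromosomes within the cluster — together with the
#' PC variance fractions. P is oriented so its correlation with the mean
#' distance profile `M` is non-negative and min-max scaled to `[0, 1]`
#' so it is commensurate with `M`.
#'
#' @param Dprime selected-cluster distance sub-matrix (t models x
#'   chromosomes), t >= `min_models`; a `ct_cluster` is also accepted.
#' @param min_models smallest usable cluster (default 5).
#' @return list with `P` (named, in `[0, 1]`), `var_fractions` (all PC
#'   variance fractions), `M` (mean profile used for orientation).
#' @export
cluster_pc1 <- function(Dprime, min_models = 5) {
  if (inherits(Dprime, "ct_cluster")) Dprime <- Dprime$selected_models
  Dprime <- as.matrix(Dprime)
  if (nrow(Dprime) < min_models)
    stop("need at least ", min_models, " models in the cluster")
  M <- colMeans(Dprime)
  sds <- apply(Dprime, 2, sd)
  if (any(sds == 0))
    warning("constant chromosome column(s); their correlations set to 0: ",
            paste(colnames(Dprime)[sds == 0], collapse = ", "))
  cc <- suppressWarnings(cor(Dprime))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  pc <- prcomp(cc, center = TRUE, scale. = FALSE)
  P <- pc$x[, 1]
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  if (sd(P) > 0 && cor(P, M) < 0) P <- -P
  rng <- max(P) - min(P)
  P <- if (rng == 0) rep(0.5, length(P)) else (P - min(P)) / rng
  names(P) <- colnames(Dprime)
  list(P = P, var_fractions = vf, M = M)
}

#' Combine mean profile and correlation PC1 by variance weighting
#'
#' Weighted average of the mean radial distance profile M and the
#' correlation-structure projection P, with weights from the variance
#' fractions of PC1 and PC2:
#' `W1 = v1/(v1+v2)`, `W2 = v2/(v1+v2)`, `C = W1*M + W2*P`.
#'
#' @param M mean radial distance profile (23-vector).
#' @param P oriented, scaled PC1 projection (23-vector).
#' @param var_fractions PC variance fractions; the first two are used.
#' @return list with `C`, `W1`, `W2`.
#' @export
combine_weighted <- function(M, P, var_fractions) {
  v1 <- var_fractions[1]; v2 <- var_fractions[2]
  if (v1 + v2 == 0) stop("PC1 and PC2 explain no variance")
  if (v1 < v2) stop("variance fractions must be non-increasing")
  W1 <- v1 / (v1 + v2)
  W2 <- v2 / (v1 + v2)
  list(C = W1 * M + W2 * P, W1 = W1, W2 = W2)
}

#' Property reference vector for tuning
#'
#' Combines min-max-normalized gene density (GD) and chromosome length
#' (LN) into the reference vector the consensus profile is smoothed
#' against. The exponential `exp(1 - GD)` inverts gene density so
#' gene-poor chromosomes get large (peripheral) reference values. The
#' higher weight W1 multiplies the component matching the inferred
#' distribution type:
#' `R = W1*exp(1-GD) + W2*LN` under gene-density inference,
#' `R = W2*exp(1-GD) + W1*LN` under length inference.
#'
#' @param props property table (see [chrom_properties()]).
#' @param inferred_type `"gene_density"` or `"length"`.
#' @param W1,W2 weights from [combine_weighted()].
#' @param chroms chromosome order of the output.
#' @return named reference vector R.
#' @export
property_reference <- function(props,
                               inferred_type = c("gene_density", "length"),
                               W1, W2, chroms = props$chrom) {
  inferred_type <- match.arg(inferred_type)
  o <- match(chroms, props$chrom)
  if (anyNA(o)) stop("property table does not cover requested chromosomes")
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  GD <- mm(props$gene_density[o])
  LN <- mm(props$length_bp[o])
  R <- if (inferred_type == "gene_density")
    W1 * exp(1 - GD) + W2 * LN
  else
    W2 * exp(1 - GD) + W1 * LN
  setNames(R, chroms)
}

#' Loess smoothing of the combined profile against the reference
#'
#' Locally weighted quadratic regression of the combined consensus
#' vector C on the property reference R; the tuned radial distances are
#' the fitted values at the observed R, returned in chromosome order.
#'
#' @param C combined profile (response).
#' @param R property reference (predictor).
#' @param span loess span in (0, 1]; default 0.75.
#' @param degree local polynomial degree (default 2).
#' @return named numeric vector of tuned radial distances.
#' @export
loess_tune <- function(C, R, span = 0.75, degree = 2) {
  if (length(C) != length(R)) stop("C and R must have equal length")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (span * length(C) < degree + 1)
    stop("span too small for ", length(C), " points")
  df <- data.frame(R = as.numeric(R), C = as.numeric(C))
  fit <- loess(C ~ R, data = df, span = span, degree = degree,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  tuned <- predict(fit, newdata = df)
  setNames(as.numeric(tuned), names(C))
}

#' Tune the selected cluster's consensus radial profile
#'
#' Convenience wrapper running the whole tuning stage: correlation-PCA
#' of the selected cluster, variance-weighted combination with the mean
#' profile, property reference construction and loess smoothing.
#'
#' @param selection `ct_cluster` from [select_cluster()].
#' @param props chromosome property table.
#' @param span,degree loess parameters (see [loess_tune()]).
#' @param min_models smallest usable cluster (see [cluster_pc1()]).
#' @return object of class `ct_profile`: list with `M`, `P`, `C`, `R`,
#'   `tuned`, `W1`, `W2`, `inferred_type`, `chrom_order`.
#' @export
tune_profile <- function(selection, props, span = 0.75, degree = 2,
                         min_models = 5) {
  pcs <- cluster_pc1(selection$selected_models, min_models = min_models)
  cw <- combine_weighted(pcs$M, pcs$P, pcs$var_fractions)
  R <- property_reference(props, selection$inferred_type, cw$W1, cw$W2,
                          chroms = selection$chrom_order)
  tuned <- loess_tune(cw$C, R, span = span, degree = degree)
  structure(list(M = pcs$M, P = pcs$P, C = cw$C, R = R, tuned = tuned,
                 W1 = cw$W1, W2 = cw$W2,
                 inferred_type = selection$inferred_type,
                 chrom_order = selection$chrom_order),
            class = "ct_profile")
}

#' @export
print.ct_profile <- function(x, ...) {
  cat("Tuned radial CT profile (", x$inferred_type, " type, W1 = ",
      sprintf("%.3f", x$W1), ")\n", sep = "")
  print(round(x$tuned, 3))
  invisible(x)
}

#' @export
as.data.frame.ct_profile <- function(x, ...) {
  data.frame(chrom = x$chrom_order, M = unname(x$M), P = unname(x$P),
             C = unname(x$C), R = unname(x$R), tuned = unname(x$tuned),
             stringsAsFactors = FALSE)
}
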