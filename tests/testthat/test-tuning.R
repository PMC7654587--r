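test_that("variance weights follow the stated arithmetic", {
  cw <- combine_weighted(rep(0.5, 23), rep(0.5, 23), c(0.6, 0.2))
  expect_equal(cw$W1, 0.75)
  expect_equal(cw$W2, 0.25)
  expect_equal(cw$W1 + cw$W2, 1)

  ## P identical to M leaves the combination unchanged
  set.seed(2)
  M <- runif(23)
  cw2 <- combine_weighted(M, M, c(0.5, 0.3))
  expect_equal(cw2$C, M)

  ## vanishing PC2 weight returns M itself
  cw3 <- combine_weighted(M, runif(23), c(0.7, 0))
  expect_equal(cw3$C, M)
  expect_error(combine_weighted(M, M, c(0, 0)), "no variance")
})

test_that("correlation-PCA of the cluster matches an eigen oracle", {
  set.seed(3)
  D <- matrix(runif(30 * 23), 30, 23)
  colnames(D) <- ct_chromosomes()
  out <- cluster_pc1(D)
  ## oracle: eigendecomposition of the centered correlation matrix
  cc <- cor(D)
  Xc <- scale(cc, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(cc) - 1), symmetric = TRUE)
  p_oracle <- drop(Xc %*% ev$vectors[, 1])
  ## orientation and min-max scale applied to the oracle the same way
  if (cor(p_oracle, colMeans(D)) < 0) p_oracle <- -p_oracle
  p_oracle <- (p_oracle - min(p_oracle)) / (max(p_oracle) - min(p_oracle))
  expect_equal(unname(out$P), unname(p_oracle), tolerance = 1e-8)
  expect_equal(out$var_fractions,
               ev$values / sum(ev$values), tolerance = 1e-8)
  expect_gte(cor(out$P, out$M), 0)

  ## two independent column blocks: PC1 of the correlation structure
  ## separates the blocks
  f1 <- rnorm(30); f2 <- rnorm(30)
  D2 <- cbind(outer(f1, runif(12, 0.5, 1)),
              outer(f2, runif(11, 0.5, 1))) +
    matrix(rnorm(30 * 23, sd = 0.05), 30)
  colnames(D2) <- ct_chromosomes()
  out2 <- cluster_pc1(D2)
  blockA <- out2$P[1:12]; blockB <- out2$P[13:23]
  expect_true(max(blockA) < min(blockB) || max(blockB) < min(blockA))
  expect_gt(out2$var_fractions[1], 0.8)
})

test_that("reference vector follows the weight-swap rule", {
  props <- hg19_chrom_properties()
  W1 <- 0.75; W2 <- 0.25
  R_gd <- property_reference(props, "gene_density", W1, W2)
  R_len <- property_reference(props, "length", W1, W2)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  GD <- mm(props$gene_density); LN <- mm(props$length_bp)
  expect_equal(unname(R_gd), W1 * exp(1 - GD) + W2 * LN)
  expect_equal(unname(R_len), W2 * exp(1 - GD) + W1 * LN)

  ## chromosome with max gene density and min length: R = W1 under
  ## gene-density inference, W2 under length inference
  p2 <- props
  p2$gene_density[p2$chrom == "chr19"] <- max(p2$gene_density)
  p2$length_bp[p2$chrom == "chr19"] <- min(p2$length_bp) - 1
  expect_equal(unname(property_reference(p2, "gene_density",
                                         W1, W2)[["chr19"]]), W1)
  expect_equal(unname(property_reference(p2, "length",
                                         W1, W2)[["chr19"]]), W2)

  ## gene-poor chr18 is pushed outward relative to gene-rich chr19
  expect_gt(R_gd[["chr18"]], R_gd[["chr19"]])
})

test_that("loess tuning reproduces linear and constant signals", {
  set.seed(4)
  R <- sort(runif(23, 0.5, 2))
  C_lin <- 0.2 + 0.3 * R
  expect_equal(unname(loess_tune(C_lin, R)), unname(C_lin),
               tolerance = 1e-6)
  C_const <- rep(0.4, 23)
  expect_equal(unname(loess_tune(C_const, R)), unname(C_const),
               tolerance = 1e-10)
  expect_error(loess_tune(C_lin, R, span = 0.05), "span")

  ## noisy quadratic: fitted values stay within the noise envelope of
  ## the true curve
  truth <- 1 + 0.5 * (R - 1.2)^2
  C_noisy <- truth + rnorm(23, sd = 0.02)
  tuned <- loess_tune(C_noisy, R)
  expect_lt(max(abs(tuned - truth)), 3 * 0.02)
})

test_that("tuning is invariant to the upstream sign of P", {
  set.seed(6)
  t_ <- 40
  latent <- runif(23)
  D <- outer(rnorm(t_, 1, 0.1), latent) + matrix(rnorm(t_ * 23, sd = 0.05), t_)
  D <- (D - min(D)) / (max(D) - min(D))
  colnames(D) <- ct_chromosomes()
  out <- cluster_pc1(D)
  outf <- cluster_pc1(-D + 1)  # mirror the whole cluster
  ## orientation rule re-aligns P with each cluster's own M
  expect_gte(cor(out$P, out$M), 0)
  expect_gte(cor(outf$P, outf$M), 0)
})

test_that("full tuning stage returns a coherent profile", {
  props <- hg19_chrom_properties()
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  prof <- mm(props$length_bp)
  set.seed(7)
  D <- matrix(rep(prof, 20), 20, 23, byrow = TRUE) +
    matrix(rnorm(460, sd = 0.05), 20)
  D <- pmin(pmax(D, 0), 1)
  colnames(D) <- props$chrom
  sel <- select_cluster(rep(1L, 20), D, props, "length", min_size = 5)
  tp <- tune_profile(sel, props)
  expect_s3_class(tp, "ct_profile")
  expect_equal(tp$W1 + tp$W2, 1)
  expect_gte(tp$W1, tp$W2)
  expect_true(all(is.finite(tp$tuned)))
  ## tuned profile still tracks the planted length ordering
  expect_gt(cor(tp$tuned, props$length_bp), 0.8)
  df <- as.data.frame(tp)
  expect_equal(names(df), c("chrom", "M", "P", "C", "R", "tuned"))
})
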