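## small strong matrix over three chromosomes for graph tests
toy_strong <- function() {
  chroms <- rep(c("chrA", "chrB", "chrC"), each = 4)
  m <- length(chroms)
  vals <- matrix(0, m, m)
  ## dense cis backbone
  for (c in unique(chroms)) {
    id <- which(chroms == c)
    for (i in id) for (j in id) if (i < j) vals[i, j] <- 5
  }
  ## chrA-chrB heavily linked, chrA-chrC barely
  vals[1, 5] <- vals[2, 6] <- vals[3, 7] <- vals[4, 8] <- 4
  vals[1, 9] <- 1
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  bins <- bin_table(chroms, (seq_len(m) - 1) * 100, seq_len(m) * 100)
  structure(list(values = vals, h_cut = 0, bins = bins),
            class = "strong_matrix")
}

test_that("graph construction mirrors the strong matrix", {
  S <- toy_strong()
  G <- build_graph(S)
  ut <- upper.tri(S$values)
  expect_equal(igraph::ecount(G), sum(S$values[ut] > 0))
  expect_equal(igraph::vcount(G), 12L)
  ## edge weights equal the corresponding strong values
  el <- igraph::as_edgelist(G, names = FALSE)
  bi <- igraph::V(G)$bin_index
  w_expected <- S$values[cbind(bi[el[, 1]] + 1, bi[el[, 2]] + 1)]
  expect_equal(igraph::E(G)$weight, w_expected)

  Sz <- S; Sz$values[] <- 0
  expect_error(build_graph(Sz), "empty graph")

  ## self-loops are dropped, isolated bins excluded
  Sd <- S; Sd$values[] <- 0; diag(Sd$values) <- 3
  Sd$values[1, 2] <- Sd$values[2, 1] <- 1
  Gd <- build_graph(Sd)
  expect_equal(igraph::vcount(Gd), 2L)
  expect_equal(igraph::ecount(Gd), 1L)
})

test_that("layouts are deterministic in the seed and bounded", {
  G <- build_graph(toy_strong())
  l1 <- fr_layout_3d(G, seed = 7, iterations = 100)
  l2 <- fr_layout_3d(G, seed = 7, iterations = 100)
  l3 <- fr_layout_3d(G, seed = 8, iterations = 100)
  expect_identical(l1$coords, l2$coords)
  expect_false(identical(l1$coords, l3$coords))
  expect_true(all(is.finite(l1$coords)))

  ## two nodes, one edge: they end up at a finite positive distance
  S2 <- structure(list(values = matrix(c(0, 1, 1, 0), 2), h_cut = 0,
                       bins = bin_table(c("chrA", "chrB"), c(0, 0),
                                        c(100, 100))),
                  class = "strong_matrix")
  l <- fr_layout_3d(build_graph(S2), seed = 1, iterations = 50)
  d <- sqrt(sum((l$coords[1, ] - l$coords[2, ])^2))
  expect_gt(d, 0)
  expect_lt(d, sqrt(3))  # within the initial unit-cube diagonal scale
})

test_that("strongly linked chromosomes lie closer in the ensemble", {
  G <- build_graph(toy_strong())
  dAB <- dAC <- numeric(50)
  for (s in 1:50) {
    lay <- fr_layout_3d(G, seed = s, iterations = 150)
    com <- chromosome_com(lay, chroms = c("chrA", "chrB", "chrC"))
    dAB[s] <- sqrt(sum((com["chrA", ] - com["chrB", ])^2))
    dAC[s] <- sqrt(sum((com["chrA", ] - com["chrC", ])^2))
  }
  expect_lt(mean(dAB), mean(dAC))
})

test_that("centers of mass match the direct mean", {
  set.seed(3)
  chroms <- rep(c("chrA", "chrB", "chrC"), each = 10)
  lay <- structure(list(coords = matrix(rnorm(90), 30, 3),
                        chrom = chroms, bin_index = 0:29, seed = 1),
                   class = "ct_layout")
  com <- chromosome_com(lay, chroms = c("chrA", "chrB", "chrC"))
  for (c in unique(chroms))
    expect_equal(unname(com[c, ]),
                 colMeans(lay$coords[chroms == c, , drop = FALSE]))
  ## simple forced cases
  lay2 <- structure(list(coords = rbind(c(0, 0, 0), c(2, 0, 0), c(5, 5, 5)),
                         chrom = c("chrA", "chrA", "chrB"),
                         bin_index = 0:2, seed = 1), class = "ct_layout")
  com2 <- chromosome_com(lay2, chroms = c("chrA", "chrB"))
  expect_equal(unname(com2["chrA", ]), c(1, 0, 0))
  expect_equal(unname(com2["chrB", ]), c(5, 5, 5))
  expect_error(chromosome_com(lay2, chroms = c("chrA", "chrZ")), "chrZ")
})

test_that("minimum-volume ellipsoid is tight, centered and rotation-equivariant", {
  ## octahedron vertices: exact MVE is the sphere of that radius
  r <- 2.5
  P <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
             c(0, 0, r), c(0, 0, -r))
  fit <- fit_mve(P, epsilon = 1e-6)
  expect_equal(unname(fit$center), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(fit$shape, diag(3) / r^2, tolerance = 1e-4)

  ## random clouds: containment at (1+eps) and volume within 1% of the
  ## exact Titterington fit (independent oracle)
  set.seed(5)
  for (rep in 1:3) {
    X <- matrix(rnorm(60), 20, 3) %*% diag(c(3, 1, 0.5))
    f <- fit_mve(X, epsilon = 1e-3)
    q <- rowSums((sweep(X, 2, f$center) %*% f$shape) *
                   sweep(X, 2, f$center))
    expect_true(all(q <= 1 + 1e-3 + 1e-9))
    eh <- cluster::ellipsoidhull(X)
    expect_equal(mve_volume(f), cluster::volume(eh), tolerance = 0.01)

    ## rotation equivariance: volume invariant, center rotates
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    fr <- fit_mve(X %*% R, epsilon = 1e-3)
    expect_equal(mve_volume(fr), mve_volume(f), tolerance = 5e-3)
    expect_equal(unname(fr$center), unname(drop(f$center %*% R)),
                 tolerance = 1e-2)
  }

  ## degenerate coplanar input falls back with a warning
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_warning(fit_mve(flat), "degenerate")
})

test_that("radial distances are min-max normalized per model", {
  lay <- structure(list(coords = rbind(c(2, 0, 0), c(4, 0, 0), c(6, 0, 0)),
                        chrom = c("chrA", "chrB", "chrC"),
                        bin_index = 0:2, seed = 1), class = "ct_layout")
  fit <- structure(list(center = c(0, 0, 0), shape = diag(3) / 100,
                        tolerance = 1e-3), class = "mve_fit")
  d <- radial_distances(lay, fit, chroms = c("chrA", "chrB", "chrC"))
  expect_equal(unname(d), c(0, 0.5, 1))

  ## a territory at the center maps to zero
  lay$coords[1, ] <- c(0, 0, 0)
  d2 <- radial_distances(lay, fit, chroms = c("chrA", "chrB", "chrC"))
  expect_equal(unname(d2["chrA"]), 0)

  ## equidistant degenerate case: all 0.5 with warning
  lay$coords <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_warning(d3 <- radial_distances(lay, fit,
                                        chroms = c("chrA", "chrB", "chrC")),
                 "equidistant")
  expect_equal(unname(d3), rep(0.5, 3))

  ## random layout: matches independent recomputation
  set.seed(9)
  lay4 <- structure(list(coords = matrix(rnorm(45), 15, 3),
                         chrom = rep(c("chrA", "chrB", "chrC"), each = 5),
                         bin_index = 0:14, seed = 1), class = "ct_layout")
  f4 <- fit_mve(lay4$coords)
  d4 <- radial_distances(lay4, f4, chroms = c("chrA", "chrB", "chrC"))
  com <- rowsum(lay4$coords, rep(c("chrA", "chrB", "chrC"), each = 5)) / 5
  dd <- sqrt(rowSums(sweep(com, 2, f4$center)^2))
  expect_equal(unname(d4), unname((dd - min(dd)) / (max(dd) - min(dd))))
})

test_that("distance matrix stacks models with the row-wise invariant", {
  G <- build_graph(toy_strong())
  ens <- generate_ensemble(G, n_models = 4, base_seed = 11,
                           iterations = 100)
  expect_length(ens, 4)
  expect_equal(vapply(ens, `[[`, numeric(1), "seed"), 11:14)
  D <- build_distance_matrix(ens, chroms = c("chrA", "chrB", "chrC"))
  expect_equal(dim(D$values), c(4L, 3L))
  expect_equal(unname(apply(D$values, 1, min)), rep(0, 4))
  expect_equal(unname(apply(D$values, 1, max)), rep(1, 4))

  ## determinism of the whole ensemble stage
  D2 <- build_distance_matrix(generate_ensemble(G, 4, base_seed = 11,
                                                iterations = 100),
                              chroms = c("chrA", "chrB", "chrC"))
  expect_identical(D$values, D2$values)
})

test_that("distances are invariant under rigid rotation of a layout", {
  set.seed(17)
  lay <- structure(list(coords = matrix(rnorm(120), 40, 3),
                        chrom = rep(c("chrA", "chrB", "chrC", "chrD"),
                                    each = 10),
                        bin_index = 0:39, seed = 1), class = "ct_layout")
  chroms <- c("chrA", "chrB", "chrC", "chrD")
  d0 <- radial_distances(lay, fit_mve(lay$coords, 1e-4), chroms)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  layR <- lay; layR$coords <- lay$coords %*% R
  dR <- radial_distances(layR, fit_mve(layR$coords, 1e-4), chroms)
  expect_equal(unname(dR), unname(d0), tolerance = 1e-2)
})
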