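## Ensemble of 3D force-directed layouts of the strong-contact graph,
## with minimum-volume-ellipsoid nuclear fits and normalized radial
## chromosome-territory distances.

#' Build the strong-contact graph
#'
#' Treats the thresholded strong-interaction matrix as a weighted
#' adjacency matrix: nodes are genomic bins, edges connect bin pairs with
#' a positive strong contact, weighted by the contact value. Self-loops
#' (diagonal entries) carry no layout information and are dropped, as
#' are bins left with no strong edge.
#'
#' @param S `strong_matrix` from [threshold_strong()].
#' @param bins optional bin table (defaults to `S$bins`).
#' @return an [igraph::graph] with vertex attributes `bin_index` and
#'   `chrom` and edge attribute `weight`.
#' @export
build_graph <- function(S, bins = S$bins) {
  vals <- S$values
  idx <- which(upper.tri(vals) & vals > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("no strong off-diagonal contacts: empty graph")
  keep <- sort(unique(c(idx[, 1], idx[, 2])))
  remap <- match(seq_len(nrow(vals)), keep)
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  g <- igraph::add_edges(g, rbind(remap[idx[, 1]], remap[idx[, 2]]))
  igraph::E(g)$weight <- vals[idx]
  igraph::V(g)$bin_index <- bins$bin_index[keep]
  igraph::V(g)$chrom <- bins$chrom[keep]
  g
}

#' 3D Fruchterman-Reingold layout with central gravity
#'
#' Runs a fixed number of force-directed iterations in three dimensions:
#' attraction along edges proportional to edge weight, repulsion between
#' all node pairs, and a gravitational pull toward the layout centroid
#' that keeps weakly connected chromosome components in one nucleus-like
#' body. Initial coordinates are drawn uniformly in the unit cube from a
#' seeded RNG, so the layout is fully deterministic given the seed.
#'
#' @param G graph from [build_graph()].
#' @param seed integer seed for the initial configuration.
#' @param iterations number of force iterations (default 500).
#' @param gravity gravity spring constant (default 1).
#' @param k ideal spring length; default `(1/n)^(1/3)` for n nodes
#'   (unit layout volume).
#' @param t0 initial temperature, the per-iteration displacement cap
#'   (default 0.1); decays linearly to zero.
#' @return object of class `ct_layout`: list with `coords` (n x 3),
#'   `chrom` (node chromosome labels), `bin_index`, `seed`.
#' @export
fr_layout_3d <- function(G, seed, iterations = 500, gravity = 1,
                         k = NULL, t0 = 0.1) {
  n <- igraph::vcount(G)
  if (is.null(k)) k <- (1 / n)^(1 / 3)
  el <- igraph::as_edgelist(G, names = FALSE)
  w <- igraph::E(G)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  set.seed(as.integer(seed))
  init <- matrix(runif(3 * n), n, 3)
  coords <- fr_layout_cpp(init, as.integer(el[, 1] - 1L),
                          as.integer(el[, 2] - 1L), as.numeric(w),
                          as.integer(iterations), k, gravity, t0)
  structure(list(coords = coords, chrom = igraph::V(G)$chrom,
                 bin_index = igraph::V(G)$bin_index, seed = seed),
            class = "ct_layout")
}

#' Generate an ensemble of independent 3D layouts
#'
#' Repeats [fr_layout_3d()] with seeds `base_seed`, `base_seed + 1`, ...
#' so the ensemble captures the configuration-to-configuration
#' variability of territory arrangement (the biological heterogeneity
#' arising at each cell division).
#'
#' @param G graph from [build_graph()].
#' @param n_models ensemble size; the analysis default is 1000, scaled
#'   down in examples and tests.
#' @param base_seed first seed.
#' @param ... passed to [fr_layout_3d()].
#' @return list of `ct_layout` objects.
#' @export
generate_ensemble <- function(G, n_models = 1000, base_seed = 1, ...) {
  if (n_models < 1) stop("n_models must be >= 1")
  lapply(seq_len(n_models) - 1L,
         function(i) fr_layout_3d(G, seed = base_seed + i, ...))
}

#' Minimum-volume enclosing ellipsoid (Khachiyan's algorithm)
#'
#' Fits the (1+epsilon)-approximate minimum-volume ellipsoid
#' \{x : (x-c)' A (x-c) <= 1\} enclosing a 3D point set, used as the
#' surrogate nuclear envelope of a layout; its center is the nucleus
#' center. A degenerate (coplanar) point set falls back to a regularized
#' covariance fit with a warning.
#'
#' @param points n x 3 coordinate matrix, n >= 4.
#' @param epsilon approximation tolerance (default 1e-3).
#' @param max_iter iteration cap.
#' @return object of class `mve_fit`: list with `center` (3-vector),
#'   `shape` (3 x 3 positive-definite `A`), `tolerance`.
#' @export
fit_mve <- function(points, epsilon = 1e-3, max_iter = 100000) {
  P <- as.matrix(points)
  d <- ncol(P)
  n <- nrow(P)
  if (n < d + 1) stop("need at least ", d + 1, " points")
  Q <- t(cbind(P, 1))                      # (d+1) x n
  u <- rep(1 / n, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))                  # (d+1) x (d+1)
    Mv <- tryCatch(colSums(solve(X, Q) * Q), error = function(e) NULL)
    if (is.null(Mv)) break                 # singular: degenerate set
    jmax <- which.max(Mv)
    maximum <- Mv[jmax]
    if (maximum <= (1 + epsilon) * (d + 1)) { converged <- TRUE; break }
    step <- (maximum - d - 1) / ((d + 1) * (maximum - 1))
    u <- (1 - step) * u
    u[jmax] <- u[jmax] + step
  }
  ctr <- drop(crossprod(P, u))
  S <- crossprod(P, u * P) - tcrossprod(ctr)
  A <- tryCatch(solve(S) / d, error = function(e) NULL)
  ok <- !is.null(A) && all(is.finite(A)) &&
    all(eigen(A, symmetric = TRUE, only.values = TRUE)$values > 0)
  if (!converged && ok)
    warning("Khachiyan iteration hit max_iter before tolerance ", epsilon)
  if (!ok) {
    warning("degenerate point set; using regularized covariance fit")
    ctr <- colMeans(P)
    Xc <- sweep(P, 2, ctr)
    S <- crossprod(Xc) / n + diag(1e-8 * max(1, sum(Xc^2) / n), d)
    A <- solve(S)
    r2 <- max(rowSums((Xc %*% A) * Xc))
    A <- A / r2
  } else {
    ## guard against tiny numeric overshoot: rescale so all points fit
    Xc <- sweep(P, 2, ctr)
    r2 <- max(rowSums((Xc %*% A) * Xc))
    if (r2 > 1 + epsilon) A <- A / r2 * (1 + epsilon)
  }
  structure(list(center = ctr, shape = (A + t(A)) / 2,
                 tolerance = epsilon),
            class = "mve_fit")
}

#' Ellipsoid volume of an MVE fit
#'
#' @param fit `mve_fit` from [fit_mve()].
#' @return volume of \{x : (x-c)' A (x-c) <= 1\}.
#' @export
mve_volume <- function(fit) {
  d <- nrow(fit$shape)
  unit <- pi^(d / 2) / gamma(d / 2 + 1)
  unit / sqrt(det(fit$shape))
}

#' Center of mass of each chromosome territory
#'
#' Unweighted mean of the layout coordinates of each chromosome's nodes.
#'
#' @param layout `ct_layout` from [fr_layout_3d()].
#' @param chroms chromosome order for the rows (default: canonical order
#'   restricted to chromosomes present in the layout's bin table).
#' @return matrix (chromosomes x 3) of centers of mass.
#' @export
chromosome_com <- function(layout,
                           chroms = intersect(ct_chromosomes(),
                                              unique(layout$chrom))) {
  f <- factor(layout$chrom, levels = chroms)
  cnt <- table(f)
  if (any(cnt == 0))
    stop("chromosome with no nodes in layout: ",
         paste(names(cnt)[cnt == 0], collapse = ", "))
  com <- rowsum(layout$coords, f) / as.numeric(cnt)
  rownames(com) <- chroms
  com
}

#' Normalized radial territory distances of one layout
#'
#' Euclidean distance from each territory's center of mass to the fitted
#' nucleus center, min-max normalized within the layout so the
#' innermost territory maps to 0 and the outermost to 1 (removing the
#' scale heterogeneity between different ellipsoid fits).
#'
#' @param layout `ct_layout`.
#' @param fit `mve_fit` of the same layout's coordinates.
#' @param chroms chromosome order (see [chromosome_com()]).
#' @return named numeric vector of distances in `[0, 1]`.
#' @export
radial_distances <- function(layout, fit,
                             chroms = intersect(ct_chromosomes(),
                                                unique(layout$chrom))) {
  com <- chromosome_com(layout, chroms)
  d <- sqrt(rowSums(sweep(com, 2, fit$center)^2))
  rng <- max(d) - min(d)
  if (rng == 0) {
    warning("all territory centers equidistant from nucleus center")
    return(setNames(rep(0.5, length(d)), chroms))
  }
  setNames((d - min(d)) / rng, chroms)
}

#' Radial distance matrix of a layout ensemble
#'
#' Stacks the normalized radial distances of every model: row i holds
#' model i, columns follow the fixed chromosome order. Models whose
#' ellipsoid fit fails are dropped with a message naming their seed.
#'
#' @param ensemble list of `ct_layout` (see [generate_ensemble()]).
#' @param fits optional list of matching `mve_fit`s; fitted on the fly
#'   when omitted.
#' @param chroms chromosome order.
#' @param epsilon MVE tolerance used when fitting on the fly.
#' @return object of class `ct_distances`: list with `values`
#'   (models x chromosomes, each row min 0 / max 1), `model_seeds`,
#'   `chrom_order`.
#' @export
build_distance_matrix <- function(ensemble, fits = NULL,
                                  chroms = NULL, epsilon = 1e-3) {
  if (is.null(chroms))
    chroms <- intersect(ct_chromosomes(), unique(ensemble[[1]]$chrom))
  if (!is.null(fits) && length(fits) != length(ensemble))
    stop("ensemble and fits must have equal length")
  rows <- vector("list", length(ensemble))
  seeds <- numeric(0)
  for (i in seq_along(ensemble)) {
    res <- tryCatch({
      fit <- if (is.null(fits)) fit_mve(ensemble[[i]]$coords, epsilon)
             else fits[[i]]
      radial_distances(ensemble[[i]], fit, chroms)
    }, error = function(e) {
      message("dropping model with seed ", ensemble[[i]]$seed, ": ",
              conditionMessage(e))
      NULL
    })
    rows[[i]] <- res
    if (!is.null(res)) seeds <- c(seeds, ensemble[[i]]$seed)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no model produced a valid distance row")
  values <- do.call(rbind, rows)
  colnames(values) <- chroms
  structure(list(values = values, model_seeds = seeds,
                 chrom_order = chroms),
            class = "ct_distances")
}

#' @export
print.ct_distances <- function(x, ...) {
  cat("Radial CT distance matrix:", nrow(x$values), "models x",
      ncol(x$values), "chromosomes\n")
  invisible(x)
}
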