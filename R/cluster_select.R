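## Deterministic K-means over the model ensemble, elbow + silhouette
## choice of k, and selection of the cluster matching the inferred
## distribution type.

## Deterministic initial centroids: repeatedly take the closest pair of
## unassigned points, grow that set by nearest unassigned neighbors to
## size n/k, and use its mean as a centroid.
nazeer_init <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  target <- max(2L, floor(n / k))
  remaining <- seq_len(n)
  centers <- matrix(NA_real_, k, ncol(X))
  for (c in seq_len(k)) {
    if (length(remaining) == 0) {  # ran out: reuse global farthest point
      centers[c, ] <- X[which.max(rowSums(as.matrix(stats::dist(X)))), ]
      next
    }
    if (length(remaining) == 1) {
      centers[c, ] <- X[remaining, ]
      remaining <- integer(0)
      next
    }
    sub <- D[remaining, remaining, drop = FALSE]
    pair <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    set <- remaining[pair]
    remaining <- setdiff(remaining, set)
    while (length(set) < target && length(remaining) > 0) {
      dmin <- apply(D[remaining, set, drop = FALSE], 1, min)
      nxt <- remaining[which.min(dmin)]
      set <- c(set, nxt)
      remaining <- setdiff(remaining, nxt)
    }
    centers[c, ] <- colMeans(X[set, , drop = FALSE])
  }
  centers
}

#' Deterministic K-means clustering of ensemble models
#'
#' Lloyd iterations started from deterministic initial centroids (grown
#' from closest-pair seeds, so identical input always yields identical
#' labels; no RNG involved). An empty cluster arising during iteration
#' is re-seeded at the point farthest from its nearest centroid.
#'
#' @param X numeric matrix, rows = models (samples), columns =
#'   chromosomes (features); a `ct_distances` object is also accepted.
#' @param k number of clusters.
#' @param max_iter Lloyd iteration cap.
#' @return list with `labels` (1..k per row), `centroids` (k x p),
#'   `inertia` (total within-cluster sum of squares), `k`.
#' @export
kmeans_deterministic <- function(X, k, max_iter = 100) {
  if (inherits(X, "ct_distances")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be in [1, nrow(X)]")
  centers <- if (k == 1) matrix(colMeans(X), 1) else nazeer_init(X, k)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    ## squared distances to each centroid
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    new_labels <- max.col(-d2, ties.method = "first")
    ## re-seed empty clusters at the worst-fit point
    for (c in which(tabulate(new_labels, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      new_labels[far] <- c
      d2[far, ] <- Inf; d2[far, c] <- 0
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    centers <- rowsum(X, factor(labels, levels = seq_len(k))) /
      tabulate(labels, k)
  }
  d2 <- rowSums((X - centers[labels, , drop = FALSE])^2)
  list(labels = labels, centroids = centers, inertia = sum(d2), k = k)
}

## Kneedle-style knee of a decreasing convex curve y(x): normalize both
## axes to [0,1], flip y, and take the largest positive excess of the
## flipped curve over the diagonal.
find_elbow <- function(x, y, sensitivity = 1.0) {
  if (length(x) < 3) return(NA_integer_)
  xn <- (x - min(x)) / (max(x) - min(x))
  rng <- max(y) - min(y)
  if (rng == 0) return(NA_integer_)
  yn <- (y - min(y)) / rng
  diffc <- (1 - yn) - xn
  i <- which.max(diffc)
  thresh <- sensitivity * mean(abs(diff(xn)))
  if (diffc[i] <= thresh) return(NA_integer_)
  x[i]
}

## mean silhouette width for a labelling (requires >= 2 non-empty clusters)
mean_silhouette <- function(X, labels) {
  sil <- cluster::silhouette(labels, stats::dist(X))
  mean(sil[, "sil_width"])
}

#' Choose the number of model clusters
#'
#' Computes the K-means inertia curve over `k_range`, locates its elbow
#' with a kneedle-style detector, and returns as final k the value with
#' the highest mean silhouette score in the elbow's vicinity (two points
#' either side of the elbow, clipped to `k_range`). When no knee is
#' detectable the silhouette argmax over the full range is used, with a
#' warning.
#'
#' @param X model matrix or `ct_distances`.
#' @param k_range candidate cluster counts (default 2:15).
#' @param sensitivity kneedle sensitivity.
#' @return list with `k` (final choice), `elbow_k`, `inertia_curve`
#'   and `silhouette_by_k` data frames, and `fits` (the
#'   [kmeans_deterministic()] fit per candidate k).
#' @export
choose_k <- function(X, k_range = 2:15, sensitivity = 1.0) {
  if (inherits(X, "ct_distances")) X <- X$values
  X <- as.matrix(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > nrow(X) / 2))
    stop("k_range must lie in [2, nrow(X)/2]")
  fits <- lapply(k_range, function(k) kmeans_deterministic(X, k))
  inertia <- vapply(fits, `[[`, numeric(1), "inertia")
  sil <- vapply(fits, function(f) mean_silhouette(X, f$labels), numeric(1))
  ## anchor the curve at k = 1 (total scatter) so a knee right at the
  ## start of k_range is still detectable
  inertia1 <- sum(scale(X, scale = FALSE)^2)
  elbow <- find_elbow(c(1L, k_range), c(inertia1, inertia), sensitivity)
  if (is.na(elbow)) {
    warning("no knee detected in the inertia curve; ",
            "using silhouette argmax over the full k range")
    vicinity <- k_range
    elbow_k <- NA_integer_
  } else {
    elbow_k <- as.integer(elbow)
    vicinity <- intersect((elbow_k - 2):(elbow_k + 2), k_range)
  }
  vi <- match(vicinity, k_range)
  k_final <- vicinity[which.max(sil[vi])]
  list(k = k_final, elbow_k = elbow_k,
       inertia_curve = data.frame(k = k_range, inertia = inertia),
       silhouette_by_k = data.frame(k = k_range, silhouette = sil),
       fits = setNames(fits, k_range))
}

#' Select the model cluster matching the inferred distribution type
#'
#' For each cluster, correlates the cluster's mean radial distance
#' profile (column means over its rows) with the chromosome property
#' named by the inferred distribution type, and selects the cluster with
#' the largest absolute Pearson correlation. The sign of that
#' correlation is reported as it disambiguates the inward/outward
#' orientation of the cluster (mirror-image clusters occur by layout
#' symmetry and have opposite signs). Ties break toward the larger
#' cluster, then the lower cluster id. Clusters smaller than
#' `min_size` models are excluded with a warning.
#'
#' @param labels cluster labels per model (from
#'   [kmeans_deterministic()] / [choose_k()]).
#' @param D `ct_distances` or plain matrix of model radial distances.
#' @param props chromosome property table (see [chrom_properties()]).
#' @param inferred_type `"gene_density"` or `"length"` (from
#'   [infer_distribution_type()]).
#' @param min_size smallest selectable cluster.
#' @return object of class `ct_cluster`: list with `labels`, `k`,
#'   `selected_cluster`, `selected_models` (the selected sub-matrix),
#'   `selection_corr`, `cluster_corrs`, `cluster_sizes`,
#'   `inferred_type`, `chrom_order`.
#' @export
select_cluster <- function(labels, D, props,
                           inferred_type = c("gene_density", "length"),
                           min_size = 5) {
  inferred_type <- match.arg(inferred_type)
  values <- if (inherits(D, "ct_distances")) D$values else as.matrix(D)
  chroms <- if (inherits(D, "ct_distances")) D$chrom_order
            else colnames(values)
  if (is.null(chroms)) chroms <- ct_chromosomes()[seq_len(ncol(values))]
  if (length(labels) != nrow(values))
    stop("labels and distance matrix disagree in model count")
  prop <- if (inferred_type == "gene_density")
    props$gene_density else props$length_bp
  prop <- prop[match(chroms, props$chrom)]
  if (anyNA(prop)) stop("property table does not cover all chromosomes")
  ids <- sort(unique(labels))
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  corrs <- vapply(ids, function(i) {
    mu <- colMeans(values[labels == i, , drop = FALSE])
    if (sd(mu) == 0) return(NA_real_)
    cor(mu, prop)
  }, numeric(1))
  eligible <- sizes >= min_size & !is.na(corrs)
  if (any(!eligible & sizes < min_size))
    warning("excluding cluster(s) smaller than ", min_size, " models: ",
            paste(ids[sizes < min_size], collapse = ", "))
  if (!any(eligible)) stop("no eligible cluster to select")
  cand <- which(eligible)
  ## max |r|; ties -> larger cluster -> lower id (order() below encodes it)
  o <- order(-round(abs(corrs[cand]), 12), -sizes[cand], ids[cand])
  best <- cand[o[1]]
  structure(list(labels = labels, k = length(ids),
                 selected_cluster = ids[best],
                 selected_models = values[labels == ids[best], ,
                                          drop = FALSE],
                 selection_corr = corrs[best],
                 cluster_corrs = setNames(corrs, ids),
                 cluster_sizes = setNames(sizes, ids),
                 inferred_type = inferred_type,
                 chrom_order = chroms),
            class = "ct_cluster")
}

#' @export
print.ct_cluster <- function(x, ...) {
  cat("Model cluster selection (", x$k, " clusters, inferred type: ",
      x$inferred_type, ")\n", sep = "")
  cat("  selected cluster", x$selected_cluster, "with",
      nrow(x$selected_models), "models, corr =",
      sprintf("%+.3f", x$selection_corr), "\n")
  invisible(x)
}
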