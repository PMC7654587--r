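## Synthetic binned Hi-C maps with planted radial territory organization
## and a tunable random-ligation background, so every pipeline stage has
## a self-contained test surface.

#' Specification of a synthetic Hi-C map
#'
#' Describes a 23-chromosome genome (hg19-like lengths, optionally
#' scaled down), a planted radial territory organization, and the count
#' model of the simulated contact matrix. The default "small-genome
#' mode" divides hg19 lengths by `scale = 10` and bins at
#' `2.5 Mb / scale` (2.5 Mb-equivalent), giving ~1,240 bins so the full
#' pipeline runs in minutes.
#'
#' Count model: cis counts are Poisson with a power-law genomic-distance
#' decay `intra_scale * (1 + g)^(-intra_decay)` (the dominant signal, as
#' in real Hi-C); trans counts for chromosomes i, j are Poisson with
#' mean `trans_scale * exp(-dist(center_i, center_j) / decay_length)`;
#' a uniform random-ligation background is added so it constitutes
#' `noise_fraction` of the total reads.
#'
#' @param organization planted radial pattern: gene-rich chromosomes
#'   inward (`"gene_density"`), short chromosomes inward (`"length"`),
#'   or no organization (`"none"`).
#' @param scale divisor on hg19 chromosome lengths (and on the 2.5 Mb
#'   bin size), keeping the bin count at ~1,240.
#' @param resolution bin size in bp; default `2.5e6 / scale`.
#' @param nucleus_shape `"sphere"` or a length-3 numeric of ellipsoid
#'   semi-axes.
#' @param trans_scale expected trans contacts per bin pair at zero
#'   territory distance.
#' @param decay_length spatial decay constant of trans contact
#'   probability (nucleus radius = 1).
#' @param intra_scale,intra_decay cis count model parameters.
#' @param noise_fraction fraction of total reads from the uniform
#'   random-ligation background, in `[0, 1]`.
#' @param jitter_sd s.d. of the radial jitter on planted positions.
#' @param seed integer RNG seed.
#' @return object of class `synthetic_spec` (a list of the above).
#' @export
synthetic_spec <- function(organization = c("gene_density", "length",
                                            "none"),
                           scale = 10, resolution = 2.5e6 / scale,
                           nucleus_shape = "sphere",
                           trans_scale = 10, decay_length = 0.3,
                           intra_scale = 100, intra_decay = 1.0,
                           noise_fraction = 0.3, jitter_sd = 0.04,
                           seed = 1) {
  organization <- match.arg(organization)
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("noise_fraction must be in [0, 1]")
  if (decay_length <= 0) stop("decay_length must be > 0")
  props <- hg19_chrom_properties()
  genome <- data.frame(chrom = props$chrom,
                       length_bp = round(props$length_bp / scale))
  structure(list(organization = organization, genome = genome,
                 resolution = resolution, nucleus_shape = nucleus_shape,
                 trans_scale = trans_scale, decay_length = decay_length,
                 intra_scale = intra_scale, intra_decay = intra_decay,
                 noise_fraction = noise_fraction, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Chromosome properties of a synthetic genome
#'
#' hg19 gene densities paired with the (scaled) synthetic chromosome
#' lengths, for use with the inference stages.
#'
#' @param spec `synthetic_spec`.
#' @return property table (see [chrom_properties()]).
#' @export
synthetic_properties <- function(spec) {
  props <- hg19_chrom_properties()
  chrom_properties(props$chrom, props$gene_density,
                   spec$genome$length_bp)
}

#' Plant territory centers in the nucleus
#'
#' Places the 23 territory centers so the radial coordinate is monotone
#' in the organizing property (gene-rich or short chromosomes inward)
#' plus seeded jitter, with random angular directions; or uniformly at
#' random when `organization = "none"`. The jittered radius is recorded
#' as the planted ground truth.
#'
#' @param spec `synthetic_spec`.
#' @param props property table (defaults to [synthetic_properties()]).
#' @return list with `centers` (23 x 3), `radius` (planted radial
#'   coordinate, nucleus radius = 1), `rank` (planted radial rank),
#'   `chrom_order`.
#' @export
plant_positions <- function(spec, props = synthetic_properties(spec)) {
  set.seed(spec$seed)
  chroms <- props$chrom
  n <- length(chroms)
  r <- if (spec$organization == "none") {
    runif(n, 0.05, 0.95)
  } else {
    key <- switch(spec$organization,
                  gene_density = -props$gene_density,  # gene-rich inward
                  length = props$length_bp)            # short inward
    ## radial spacing follows an equal blend of the property's value and
    ## its rank: monotone in the property, graded but not dominated by
    ## outlier property values
    mm <- function(x) (x - min(x)) / (max(x) - min(x))
    base <- 0.15 + 0.75 * (0.5 * mm(key) + 0.5 * mm(rank(key)))
    pmin(pmax(base + rnorm(n, 0, spec$jitter_sd), 0.02), 1)
  }
  ## random directions on the unit sphere
  dir <- matrix(rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  centers <- dir * r
  if (is.numeric(spec$nucleus_shape)) {
    if (length(spec$nucleus_shape) != 3)
      stop("ellipsoid nucleus_shape needs 3 semi-axes")
    centers <- sweep(centers, 2, spec$nucleus_shape, `*`)
  }
  rownames(centers) <- chroms
  list(centers = centers, radius = setNames(r, chroms),
       rank = setNames(rank(r, ties.method = "first"), chroms),
       chrom_order = chroms)
}

#' Population-averaged radial contact kernel
#'
#' Expected value of the spatial contact kernel `exp(-d / lambda)`
#' between two territories at radial coordinates `r_i`, `r_j` whose
#' angular positions are independent and uniform on the sphere — the
#' cell-population average a contact map measures. Computed by
#' quadrature over the relative angle.
#'
#' @param r vector of radial coordinates.
#' @param lambda spatial decay constant.
#' @param nq quadrature points.
#' @return symmetric matrix `K[i, j] = E[exp(-d_ij / lambda)]`.
#' @export
radial_contact_kernel <- function(r, lambda, nq = 64) {
  ## u = cos(angle between the two position vectors), uniform on [-1, 1]
  u <- (seq_len(nq) - 0.5) / nq * 2 - 1
  n <- length(r)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    d <- sqrt(pmax(r[i]^2 + r[j]^2 - 2 * r[i] * r[j] * u, 0))
    K[i, j] <- K[j, i] <- mean(exp(-d / lambda))
  }
  dimnames(K) <- list(names(r), names(r))
  K
}

#' Simulate a raw binned Hi-C matrix with planted organization
#'
#' Draws the synthetic contact matrix described by the spec (see
#' [synthetic_spec()] for the count model). The matrix is symmetric,
#' integer and raw (not balanced); pass it through [ice_normalize()]
#' like real data.
#'
#' @param spec `synthetic_spec`.
#' @param positions planted positions (defaults to
#'   [plant_positions()] under the spec's seed).
#' @return list with `H` (raw [hic_matrix()]), `bins`, `positions`
#'   (the planted ground truth), `props`.
#' @export
simulate_hic_matrix <- function(spec, positions = NULL) {
  props <- synthetic_properties(spec)
  if (is.null(positions)) positions <- plant_positions(spec, props)
  set.seed(spec$seed + 1L)
  nb <- pmax(1L, as.integer(ceiling(spec$genome$length_bp /
                                      spec$resolution)))
  chrom <- rep(spec$genome$chrom, nb)
  start <- unlist(lapply(seq_along(nb), function(i)
    (seq_len(nb[i]) - 1) * spec$resolution))
  end <- unlist(lapply(seq_along(nb), function(i)
    pmin(seq_len(nb[i]) * spec$resolution, spec$genome$length_bp[i])))
  bins <- bin_table(chrom, start, end)
  m <- nrow(bins)
  ci <- match(chrom, positions$chrom_order)

  ## expected counts; the trans mean is the population average of the
  ## spatial contact kernel exp(-d / decay_length) over the random
  ## angular arrangements of the planted radii (Hi-C averages over many
  ## cells whose angular positions randomize while radial positions
  ## persist)
  trans_mean <- spec$trans_scale *
    radial_contact_kernel(positions$radius, spec$decay_length)
  mean_mat <- trans_mean[ci, ci]
  gdist <- abs(outer(seq_len(m), seq_len(m), `-`))
  intra <- outer(ci, ci, `==`)
  mean_mat[intra] <- spec$intra_scale *
    (1 + gdist[intra])^(-spec$intra_decay)
  if (any(!is.finite(mean_mat)) || max(mean_mat) > 1e9)
    stop("overflow-scale parameters")

  ut <- upper.tri(mean_mat, diag = TRUE)
  vals <- matrix(0, m, m)
  vals[ut] <- rpois(sum(ut), mean_mat[ut])
  if (spec$noise_fraction >= 1) {
    ## pure random ligation: replace all structure with a uniform
    ## background of matched depth
    bg_mean <- sum(vals[ut]) / sum(ut)
    vals[ut] <- rpois(sum(ut), bg_mean)
  } else if (spec$noise_fraction > 0) {
    structured_total <- sum(vals[ut])
    bg_total <- spec$noise_fraction / (1 - spec$noise_fraction) *
      structured_total
    bg_mean <- bg_total / sum(ut)
    vals[ut] <- vals[ut] + rpois(sum(ut), bg_mean)
  }
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  list(H = hic_matrix(vals, bins), bins = bins,
       positions = positions, props = props)
}
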