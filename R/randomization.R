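## Random-ligation null model: matched shuffle of a raw contact matrix.

#' Simulate a random-ligation Hi-C matrix
#'
#' Builds a random-ligation control matched to a real contact map by
#' shuffling the raw matrix and re-balancing it. Shuffling destroys the
#' chromosome-territory signal while conserving the total read count and
#' the dynamic range of values, so real and control maps can be compared
#' like for like.
#'
#' Two shuffle readings are provided. `mode = "values"` (default)
#' permutes the upper-triangle entry values (diagonal included) uniformly
#' over upper-triangle positions and mirrors them to the lower triangle.
#' `mode = "labels"` permutes the bin (row/column) labels instead. Both
#' destroy territory structure; they differ in which marginals survive.
#' The shuffle is applied `n_shuffles` times (default 5).
#'
#' @param H_raw raw (not ICE-balanced), filtered [hic_matrix()].
#' @param n_shuffles number of successive shuffles.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param mode `"values"` or `"labels"`.
#' @param normalize ICE-balance the shuffled matrix before returning
#'   (default `TRUE`, matching the downstream contract); set `FALSE` to
#'   inspect the raw shuffle.
#' @return [hic_matrix()] with the same bin table as the input.
#' @export
simulate_random_ligation <- function(H_raw, n_shuffles = 5, seed,
                                     mode = c("values", "labels"),
                                     normalize = TRUE) {
  mode <- match.arg(mode)
  if (isTRUE(H_raw$normalized))
    stop("random ligation is simulated from the raw matrix; ",
         "pass the un-normalized input")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  vals <- H_raw$values
  m <- nrow(vals)
  if (mode == "values") {
    ut <- upper.tri(vals, diag = TRUE)
    v <- vals[ut]
    for (s in seq_len(n_shuffles)) v <- v[sample.int(length(v))]
    vals[ut] <- v
    vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  } else {
    for (s in seq_len(n_shuffles)) {
      p <- sample.int(m)
      vals <- vals[p, p, drop = FALSE]
    }
  }
  out <- hic_matrix(vals, H_raw$bins, normalized = FALSE)
  if (normalize) out <- ice_normalize(out)
  out
}
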