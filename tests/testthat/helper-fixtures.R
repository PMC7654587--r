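# Shared fixtures built in code.

# small symmetric contact matrix with a given bin table
random_hic <- function(m, seed = 1, chroms = NULL, lambda = 10) {
  set.seed(seed)
  vals <- matrix(0, m, m)
  ut <- upper.tri(vals, diag = TRUE)
  vals[ut] <- rpois(sum(ut), lambda)
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  if (is.null(chroms)) chroms <- rep("chr1", m)
  bins <- bin_table(chroms, (seq_len(m) - 1) * 100, seq_len(m) * 100)
  hic_matrix(vals, bins)
}

# a bin table spreading m bins over the given chromosome sizes
multi_chrom_bins <- function(sizes) {
  chrom <- rep(names(sizes), sizes)
  off <- unlist(lapply(sizes, seq_len)) - 1
  bin_table(chrom, off * 100, (off + 1) * 100)
}

# reduced-size synthetic map for pipeline-level tests (~310 bins)
small_sim <- function(org = "gene_density", seed = 1, ...) {
  spec <- synthetic_spec(org, seed = seed, resolution = 1e6, ...)
  simulate_hic_matrix(spec)
}

# brute-force chromosome-pair strong counts (independent oracle)
brute_force_summary <- function(S, bins, chroms) {
  nc <- length(chroms)
  ci <- match(bins$chrom, chroms)
  out <- matrix(0L, nc, nc, dimnames = list(chroms, chroms))
  m <- nrow(S$values)
  for (i in seq_len(m)) for (j in i:m) {
    if (S$values[i, j] > 0) {
      a <- min(ci[i], ci[j]); b <- max(ci[i], ci[j])
      out[a, b] <- out[a, b] + 1L
    }
  }
  out + t(out) - diag(diag(out), nc)
}
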