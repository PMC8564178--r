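options(neurocouple.log_level = "quiet")

# interior mask on a small grid
small_mask <- function(dims = c(8, 8, 8), margin = 1) {
  m <- array(FALSE, dims)
  idx <- lapply(dims, function(L) (1 + margin):(L - margin))
  m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  m
}

white_zmap <- function(mask, seed) {
  set.seed(seed)
  zscore_map(masked_volume(array(rnorm(length(mask)), dim(mask)), mask))
}

random_bold <- function(dims = c(5, 5, 5), nt = 40, tr = 2, seed = 1) {
  set.seed(seed)
  bold_series(array(rnorm(prod(dims) * nt), c(dims, nt)), tr_s = tr,
              motion_params = matrix(rnorm(nt * 6, sd = 0.1), nt))
}

tiny_spec <- function(...) {
  cohort_spec(group_sizes = c(mild = 4, moderate = 4, severe = 4),
              atlas_shape = c(10, 10, 10), n_regions = 8,
              n_frames = 40, n_discard = 5, ...)
}

# brute-force FCS: O(N^2) double loop over voxel pairs
fcs_bruteforce <- function(ts, r0 = 0.2, denominator = "all") {
  N <- ncol(ts)
  out <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0; cnt <- 0
    for (j in seq_len(N)) {
      if (j == i) next
      r <- cor(ts[, i], ts[, j])
      if (r >= r0) { s <- s + r; cnt <- cnt + 1 }
    }
    out[i] <- if (denominator == "all") s / (N - 1)
              else if (cnt > 0) s / cnt else 0
  }
  out
}
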