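# Reduced synthetic specs used across tests: each isolates the planted
# structure the module under test is meant to detect.

# structure-free: distance decay + trans floor only (optional per-bin bias)
spec_plain <- function(seed, chrom_sizes = c(c1 = 100e6, c2 = 80e6),
                       bin_size = 1e6, bias_sd = 0, depth = 2e6, ...) {
  synthetic_spec(chrom_sizes = chrom_sizes, bin_size = bin_size,
                 compartment_strength = 0, tad_boundaries = NULL,
                 translocations = list(), small_chrom_trans_factor = c(1, 1),
                 telomere_boost = c(1, 1), bias_sd = bias_sd, depth = depth,
                 seed = seed, ...)
}

# compartments only (no TADs / telomere / trans structure)
spec_compartments <- function(seed, chrom_sizes = c(c1 = 60e6, c2 = 45e6),
                              depth = 1e6, ...) {
  synthetic_spec(chrom_sizes = chrom_sizes, bin_size = 1e6,
                 tad_boundaries = NULL, translocations = list(),
                 small_chrom_trans_factor = c(1, 1),
                 telomere_boost = c(1, 1), bias_sd = 0.2, depth = depth,
                 seed = seed, ...)
}

# TADs only, 40-kb bins
spec_tads <- function(seed, chrom_sizes = c(c1 = 12e6), depth = 1e6, ...) {
  synthetic_spec(chrom_sizes = chrom_sizes, bin_size = 4e4,
                 compartment_strength = 0, telomere_boost = c(1, 1),
                 translocations = list(), small_chrom_trans_factor = c(1, 1),
                 tad_spacing = c(20, 34), tad_strength = 3, bias_sd = 0.2,
                 depth = depth, seed = seed, ...)
}

# telomere boost in condition 1 only
spec_telomere <- function(seed, chrom_sizes = c(c1 = 60e6), bin_size = 5e5,
                          depth = 2e6, ...) {
  synthetic_spec(chrom_sizes = chrom_sizes, bin_size = bin_size,
                 compartment_strength = 0, tad_boundaries = NULL,
                 translocations = list(), small_chrom_trans_factor = c(1, 1),
                 telomere_boost = c(3, 1), bias_sd = 0.2, depth = depth,
                 seed = seed, ...)
}

ice_z <- function(map, ...) {
  r <- ice_balance(mask_low_coverage(map), ...)
  zscore_transform(r$map, distance_expected(r$map))
}

# wrap a bare z matrix as a ZScoreMap for unit tests
make_zmap <- function(binning, z) {
  structure(list(binning = binning, z = z,
                 mask = rep(FALSE, binning$n_bins)),
            class = "ZScoreMap")
}

# per-distance mean/sd of z values, pooled over chromosomes
z_calibration <- function(z) {
  b <- z$binning
  rows <- list()
  for (c in b$chroms) {
    idx <- chrom_bins(b, c)
    nb <- length(idx)
    for (d in seq_len(nb - 1)) {
      v <- z$z[cbind(idx[seq_len(nb - d)], idx[seq_len(nb - d) + d])]
      v <- v[is.finite(v)]
      if (length(v) >= 2)
        rows[[length(rows) + 1]] <- data.frame(d = d, n = length(v),
                                               m = mean(v), s = stats::sd(v))
    }
  }
  df <- do.call(rbind, rows)
  do.call(rbind, by(df, df$d, function(x)
    data.frame(d = x$d[1], n = sum(x$n),
               m = stats::weighted.mean(x$m, x$n),
               s = stats::weighted.mean(x$s, x$n))))
}

# precision/recall of called boundaries vs planted truth at +-1 bin,
# recall restricted to truth boundaries the insulation square can see
boundary_pr <- function(bd, tb, spec, w = 25L) {
  bs <- spec$bin_size
  core <- (bd$core_start + bd$core_end) / 2
  tcore <- (tb$start + tb$end) / 2
  L <- spec$chrom_sizes[tb$chrom]
  det <- tcore >= w * bs & tcore <= L - w * bs
  hit <- vapply(core, function(x) any(abs(x - tcore) <= 1.5 * bs), TRUE)
  rec <- vapply(tcore[det], function(x) any(abs(x - core) <= 1.5 * bs), TRUE)
  c(precision = mean(hit), recall = mean(rec))
}
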