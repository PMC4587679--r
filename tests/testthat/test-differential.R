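toy_binning <- function() make_binning(c(c1 = 3e6, c2 = 3e6), 1e6)

rand_zmap <- function(b, seed) {
  set.seed(seed)
  n <- b$n_bins
  Z <- matrix(stats::rnorm(n * n), n, n)
  Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
  diag(Z) <- NA
  make_zmap(b, Z)
}

test_that("identical conditions give identically zero scores", {
  b <- toy_binning()
  z1 <- rand_zmap(b, 1); z2 <- rand_zmap(b, 2)
  dm <- suppressWarnings(differential_score(z1, z2, z1, z2, n_null = 10,
                                            seed = 1))
  s <- dm$score[upper.tri(dm$score)]
  expect_true(all(s[is.finite(s)] == 0))
  expect_equal(dm$null_mean, 0)
})

test_that("the score is the null-standardized mean cross difference", {
  b <- toy_binning()
  base <- rand_zmap(b, 3)
  zA <- base; zA$z <- base$z * 0 + 2      # constant 2 off-diagonal
  zB <- base; zB$z <- base$z * 0
  # perturb one replicate pair slightly so the null has spread
  zA2 <- zA; zB2 <- zB
  set.seed(4)
  eps <- matrix(stats::rnorm(b$n_bins^2, 0, 0.1), b$n_bins)
  eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
  zA2$z <- zA$z - eps; zB2$z <- zB$z - eps
  dm <- suppressWarnings(differential_score(zA, zA2, zB, zB2,
                                            n_null = 1000, seed = 9))
  expect_equal(dm$null_mean, 0)
  # D = mean(A-B diffs) = 2 at every cell; score = 2 / null_scale
  s <- dm$score[upper.tri(dm$score) & is.finite(dm$score)]
  expect_equal(s, rep(2 / dm$null_scale, length(s)))
  # hand value: null_scale = RMS of the sampled replicate differences
  expect_equal(s[1] * dm$null_scale, 2)
})

test_that("condition swap negates the score matrix exactly", {
  b <- toy_binning()
  zs <- lapply(1:4, function(s) rand_zmap(b, s + 10))
  d1 <- suppressWarnings(differential_score(zs[[1]], zs[[2]], zs[[3]],
                                            zs[[4]], n_null = 15, seed = 2))
  d2 <- suppressWarnings(differential_score(zs[[3]], zs[[4]], zs[[1]],
                                            zs[[2]], n_null = 15, seed = 2))
  ok <- is.finite(d1$score)
  expect_equal(d1$score[ok], -d2$score[ok], tolerance = 1e-12)
})

test_that("seeded null sampling is reproducible", {
  b <- toy_binning()
  zs <- lapply(1:4, function(s) rand_zmap(b, s + 20))
  d1 <- suppressWarnings(differential_score(zs[[1]], zs[[2]], zs[[3]],
                                            zs[[4]], n_null = 10, seed = 7))
  d2 <- suppressWarnings(differential_score(zs[[1]], zs[[2]], zs[[3]],
                                            zs[[4]], n_null = 10, seed = 7))
  expect_identical(d1$score, d2$score)
  expect_identical(d1$null_scale, d2$null_scale)
})

test_that("direct subtraction is cellwise and antisymmetric", {
  b <- toy_binning()
  zA <- rand_zmap(b, 31); zB <- rand_zmap(b, 32)
  expect_true(all(subtract_zscores(zA, zA) == 0, na.rm = TRUE))
  one <- make_zmap(b, zA$z * 0 + 1.5)
  half <- make_zmap(b, zA$z * 0 + 0.5)
  expect_equal(subtract_zscores(one, half)[1, 2], 1)
  expect_equal(subtract_zscores(zA, zB), -subtract_zscores(zB, zA))
})

test_that("chromosome-set comparison reproduces the exact rank-sum p", {
  b <- make_binning(c(a = 1e6, b = 1e6, c = 1e6, d = 1e6), 1e6)
  S <- matrix(NA_real_, 4, 4)
  S[1, 2] <- 1; S[1, 3] <- 4; S[1, 4] <- 5
  S[2, 3] <- 2; S[2, 4] <- 6; S[3, 4] <- 3
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  dm <- structure(list(binning = b, score = S), class = "DifferentialMap")
  # within {a,b,c}: cells (a,b)=1,(b,c)=2,(a,c)=4; cross to {d}: 5,6,3
  r <- interchrom_set_comparison(dm, c("a", "b", "c"), "d")
  expect_equal(sort(r$within), c(1, 2, 4))
  expect_equal(sort(r$cross), c(3, 5, 6))
  expect_equal(r$p, stats::wilcox.test(c(1, 2, 4), c(3, 5, 6))$p.value)
  # a fully separated comparison gives the exact two-sided p 0.1
  S2 <- S; S2[1, 2] <- 1; S2[2, 3] <- 2; S2[1, 3] <- 3
  S2[1, 4] <- 4; S2[2, 4] <- 5; S2[3, 4] <- 6
  S2[lower.tri(S2)] <- t(S2)[lower.tri(S2)]
  dm2 <- structure(list(binning = b, score = S2), class = "DifferentialMap")
  r2 <- interchrom_set_comparison(dm2, c("a", "b", "c"), "d")
  expect_equal(r2$p, 0.1)
  # all-equal scores: medians equal, p = 1
  S3 <- S2 * 0 + 2; diag(S3) <- NA
  dm3 <- structure(list(binning = b, score = S3), class = "DifferentialMap")
  r3 <- suppressWarnings(interchrom_set_comparison(dm3, c("a", "b", "c"), "d"))
  expect_equal(r3$median_within, r3$median_cross)
  expect_equal(r3$p, 1)
})

test_that("a planted trans-block intensity difference is detected", {
  sizes <- c(c1 = 65e6, c2 = 65e6, c3 = 52e6, c4 = 52e6, c5 = 39e6,
             c6 = 39e6)
  sp <- synthetic_spec(chrom_sizes = sizes, bin_size = 6.5e6,
                       compartment_strength = 0, tad_boundaries = NULL,
                       telomere_boost = c(1, 1),
                       small_chrom_trans_factor = c(1, 1),
                       translocations = list(list(
                         chrom1 = "c1", range1 = c(13e6, 26e6),
                         chrom2 = "c3", range2 = c(13e6, 26e6),
                         intensity = c(2, 1))),
                       bias_sd = 0.2, depth = 1e6, seed = 21)
  zs <- lapply(list(c(1, 1), c(1, 2), c(2, 1), c(2, 2)), function(cr)
    ice_z(sample_map(sp, cr[1], cr[2])))
  dm <- suppressWarnings(differential_score(zs[[1]], zs[[2]], zs[[3]],
                                            zs[[4]], n_null = 500, seed = 3))
  S <- dm$score
  ut <- upper.tri(S) & is.finite(S)
  blk <- S[chrom_bins(sp$binning, "c1")[3:4], chrom_bins(sp$binning, "c3")[3:4]]
  thr <- stats::quantile(abs(S[ut]), 0.99)
  expect_true(all(abs(blk) >= thr))
  expect_true(all(blk > 0))  # condition-A enriched
})
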