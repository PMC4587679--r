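uniform_map <- function(nb = 60, bs = 4e4, value = 5) {
  b <- make_binning(stats::setNames(nb * bs, "c1"), bs)
  M <- matrix(value, nb, nb)
  contact_map(b, M, state = "ice")
}

test_that("insulation is flat on a uniform matrix and dips at a block junction", {
  m <- uniform_map()
  tr <- insulation(m, w = 10)
  def <- is.finite(tr$normalized)
  expect_true(all(abs(tr$normalized[def]) < 1e-12))
  expect_true(all(is.na(tr$normalized[c(1:10, 51:60)])))  # within w of ends
  # normalization contract: mean of 2^normalized over defined bins = 1
  expect_equal(mean(2^tr$normalized[def]), 1)

  # two-block matrix: within 10, between 1 -> minimum exactly at the junction
  nb <- 60
  blk <- rep(1:2, each = 30)
  M <- ifelse(outer(blk, blk, "=="), 10, 1)
  m2 <- contact_map(m$binning, M, state = "ice")
  tr2 <- insulation(m2, w = 10)
  ni <- tr2$normalized
  expect_equal(sort(order(ni)[1:2]), c(30, 31))  # junction plateau
  # direct mean oracle at the junction bin
  raw30 <- mean(M[20:29, 31:40])
  expect_equal(tr2$raw[30], raw30)
})

test_that("insulation is translation-equivariant", {
  nb <- 70
  b <- make_binning(c(c1 = nb * 4e4), 4e4)
  set.seed(12)
  base <- matrix(stats::runif(nb * nb, 1, 3), nb, nb)
  base[lower.tri(base)] <- t(base)[lower.tri(base)]
  k <- 5
  shifted <- matrix(2, nb, nb)  # pad with the mean level
  shifted[(k + 1):nb, (k + 1):nb] <- base[1:(nb - k), 1:(nb - k)]
  t1 <- insulation(contact_map(b, base, state = "ice"), w = 8)
  t2 <- insulation(contact_map(b, shifted, state = "ice"), w = 8)
  i <- 20:40
  expect_equal(t2$raw[i + k], t1$raw[i])
})

test_that("boundary calling applies the strength rule", {
  # flat track -> no boundaries
  m <- uniform_map()
  tr <- insulation(m, w = 10)
  expect_equal(nrow(call_boundaries(tr)), 0L)

  # planted single valley of depth 1.0 between flat flanks -> strength 1.0
  b <- make_binning(c(c1 = 60 * 4e4), 4e4)
  mk_track <- function(depth) {
    ni <- rep(0, 60); ni[c(1:5, 56:60)] <- NA
    ni[30] <- -depth
    structure(cbind(b$bins, raw = 2^ni, normalized = ni),
              class = c("InsulationTrack", "data.frame"), w = 5L, binning = b)
  }
  bd <- call_boundaries(mk_track(1.0), smooth_bins = 0)
  expect_equal(nrow(bd), 1L)
  expect_equal(bd$core_start, 29 * 4e4)
  expect_equal(bd$strength, 1.0)
  # extended interval spans core +- 80 kb
  expect_equal(bd$end - bd$start, 4e4 + 2 * 8e4)
  # sub-threshold valley rejected
  expect_equal(nrow(call_boundaries(mk_track(0.10), smooth_bins = 0)), 0L)
  expect_equal(nrow(call_boundaries(mk_track(0.16), smooth_bins = 0)), 1L)
})

test_that("planted boundaries are recovered with high precision and recall", {
  pr <- vapply(1:3, function(seed) {
    sp <- spec_tads(seed)
    r <- ice_balance(mask_low_coverage(sample_map(sp, 1, 1)))
    bd <- call_boundaries(insulation(r$map, w = 25))
    boundary_pr(bd, truth_boundaries(sp, 1), sp)
  }, c(precision = 0, recall = 0))
  expect_true(all(pr["precision", ] >= 0.9))
  expect_true(all(pr["recall", ] >= 0.85))
})

test_that("replicate insulation tracks are strongly correlated", {
  sp <- spec_tads(17)
  t1 <- insulation(ice_balance(mask_low_coverage(sample_map(sp, 1, 1)))$map, w = 25)
  t2 <- insulation(ice_balance(mask_low_coverage(sample_map(sp, 1, 2)))$map, w = 25)
  expect_gt(stats::cor(t1$normalized, t2$normalized, use = "pairwise"), 0.8)
})

test_that("TADs are the complement of boundaries minus exclusions", {
  b <- make_binning(c(c1 = 60 * 4e4), 4e4)
  bd <- structure(
    data.frame(chrom = "c1", start = 1.12e6, end = 1.32e6,
               core_start = 1.2e6, core_end = 1.24e6, strength = 0.5),
    class = c("BoundarySet", "data.frame"), binning = b)
  tads <- derive_tads(bd)
  expect_equal(nrow(tads), 2L)
  expect_equal(tads$start, c(0, 1.32e6))
  expect_equal(tads$end, c(1.12e6, 2.4e6))
  # exclusion swallowing the first TAD removes it
  tads2 <- derive_tads(bd, exclusions = data.frame(chrom = "c1", start = 0,
                                                   end = 1.12e6))
  expect_equal(nrow(tads2), 1L)
  expect_equal(tads2$start, 1.32e6)
})

test_that("boundary sets classify by extended-interval intersection", {
  b <- make_binning(c(c1 = 60 * 4e4), 4e4)
  mk <- function(cores) structure(
    data.frame(chrom = "c1", start = cores - 8e4, end = cores + 4e4 + 8e4,
               core_start = cores, core_end = cores + 4e4,
               strength = 0.5),
    class = c("BoundarySet", "data.frame"), binning = b)
  b1 <- mk(c(4e5, 1.2e6))
  same <- classify_boundaries(b1, b1)
  expect_equal(same$n_overlap1, 2L)
  expect_equal(same$n_specific1, 0L)
  # one extra far-away boundary is set1-specific
  b1x <- mk(c(4e5, 1.2e6, 2e6))
  r <- classify_boundaries(b1x, b1)
  expect_equal(r$n_specific1, 1L)
  expect_equal(r$set1$category[3], "set1-specific")
  # a copy shifted within the 200-kb extension still overlaps
  b2 <- mk(c(4e5 + 1.6e5, 1.2e6))
  r2 <- classify_boundaries(b1, b2)
  expect_equal(r2$n_specific1, 0L)
  expect_equal(r2$n_overlap1, r2$n_overlap2)  # symmetric here
})

test_that("TAD classification uses inclusive reciprocal overlap", {
  b <- make_binning(c(c1 = 10e6), 4e4)
  mk <- function(df) structure(df, class = c("TadSet", "data.frame"),
                               binning = b)
  t1 <- mk(data.frame(chrom = "c1", start = c(0, 5e6), end = c(5e6, 10e6)))
  same <- classify_tads(t1, t1)
  expect_true(all(same$set1$category == "overlapping"))
  # 50% overlap at threshold 0.9: both specific
  t2 <- mk(data.frame(chrom = "c1", start = 2.5e6, end = 7.5e6))
  r <- classify_tads(t1, t2, 0.9)
  expect_true(all(r$set1$category != "overlapping"))
  # exactly 90.0% reciprocal overlap is inclusive
  t3 <- mk(data.frame(chrom = "c1", start = 0, end = 1e6))
  t4 <- mk(data.frame(chrom = "c1", start = 0.5e5, end = 0.95e6))
  r2 <- classify_tads(t3, t4, 0.9)
  expect_equal(r2$set1$category, "overlapping")
})

test_that("boundary-centred profiles localize features", {
  b <- make_binning(c(c1 = 20e6), 4e4)
  cores <- c(5e6, 10e6, 15e6)
  bd <- structure(
    data.frame(chrom = "c1", start = cores - 8e4, end = cores + 4e4 + 8e4,
               core_start = cores, core_end = cores + 4e4, strength = 1),
    class = c("BoundarySet", "data.frame"), binning = b)
  # all features exactly at boundary midpoints -> single spike at offset 0
  mids <- cores + 2e4
  feats <- data.frame(chrom = "c1", start = mids - 10, end = mids + 10)
  pr <- boundary_profile(bd, feats, window = 1e6, step = 2.5e4)
  expect_equal(sum(pr$mean_frequency > 0), 1L)
  expect_equal(pr$offset[pr$mean_frequency > 0], 2.5e4 / 2)
  expect_equal(max(pr$mean_frequency), 1)
  # uniform features -> approximately flat profile
  set.seed(5)
  uf <- data.frame(chrom = "c1", start = runif(2000, 0, 20e6))
  uf$end <- uf$start + 10
  pu <- boundary_profile(bd, uf, window = 1e6, step = 2.5e4)
  expect_lt(stats::sd(pu$mean_frequency) / mean(pu$mean_frequency), 0.5)
  # no boundaries -> empty profile with warning
  empty <- bd[0, ]
  expect_warning(pe <- boundary_profile(empty, feats), "no boundaries")
  expect_equal(nrow(pe), 0L)
})
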