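checkerboard_zmap <- function(nb = 20, block = 5) {
  b <- make_binning(stats::setNames(nb * 1e6, "c1"), 1e6)
  e <- ifelse((((seq_len(nb) - 1) %/% block) %% 2) == 0, 1, -1)
  set.seed(8)
  Z <- outer(e, e) + matrix(stats::rnorm(nb * nb, 0, 0.2), nb, nb)
  Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
  diag(Z) <- NA
  list(z = make_zmap(b, Z), e = e, binning = b)
}

genes_in <- function(binning, bins) {
  s <- binning$bins$start[bins] + 100
  interval_set(binning$bins$chrom[bins], s, s + 500,
               name = sprintf("g%03d", seq_along(bins)))
}

test_that("the first principal component separates plaid blocks", {
  cb <- checkerboard_zmap()
  genes <- genes_in(cb$binning, which(cb$e > 0))  # gene-dense in e>0 bins
  p <- call_compartments(cb$z, genes)
  expect_true(all(sign(p$eigen) == cb$e))
  expect_equal(p$label, ifelse(cb$e > 0, "A", "B"))
  # positive scaling of the z matrix leaves labels unchanged
  z10 <- cb$z; z10$z <- z10$z * 10
  p10 <- call_compartments(z10, genes)
  expect_equal(p10$label, p$label)
})

test_that("gene density orients the eigenvector; flipping density flips labels", {
  cb <- checkerboard_zmap()
  gA <- genes_in(cb$binning, which(cb$e > 0))
  gB <- genes_in(cb$binning, which(cb$e < 0))
  pA <- call_compartments(cb$z, gA)
  pB <- call_compartments(cb$z, gB)
  expect_equal(pB$eigen, -pA$eigen)
  expect_equal(pB$label, ifelse(pA$label == "A", "B", "A"))
})

test_that("short chromosomes are left undefined with a warning", {
  b <- make_binning(c(c1 = 5e6), 1e6)
  Z <- matrix(stats::rnorm(25), 5, 5)
  Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
  z <- make_zmap(b, Z)
  expect_warning(p <- call_compartments(z, genes_in(b, 1:3)), "fewer than")
  expect_true(all(p$label == "undefined"))
})

test_that("planted compartments are recovered from sampled maps", {
  agree <- vapply(1:3, function(seed) {
    sp <- spec_compartments(seed)
    z <- ice_z(sample_map(sp, 1, 1))
    p <- suppressWarnings(call_compartments(z, truth_genes(sp)))
    e <- truth_compartments(sp, 1)$value
    ok <- !is.na(p$eigen)
    mean(sign(p$eigen[ok]) == sign(e[ok]))
  }, 0)
  expect_true(all(agree >= 0.95))
})

test_that("switch classification is exhaustive and conservative", {
  cb <- checkerboard_zmap()
  genes <- genes_in(cb$binning, which(cb$e > 0))
  p1 <- call_compartments(cb$z, genes)
  sw_same <- classify_switches(p1, p1)
  expect_true(all(sw_same$category %in% c("A->A", "B->B")))
  # one bin flipped in condition 2
  p2 <- p1
  flip <- which(p1$label == "A")[1]
  p2$label[flip] <- "B"; p2$eigen[flip] <- -p2$eigen[flip]
  sw <- classify_switches(p1, p2)
  expect_equal(sum(sw$category == "A->B"), 1L)
  expect_equal(which(sw$category == "A->B"), flip)
  counts <- attr(sw, "counts")
  expect_equal(sum(counts), nrow(sw))  # categories partition the bins
})

test_that("Yates-corrected enrichment reproduces the hand value 11.281", {
  # 2x2 table [[30,70],[10,90]]: E = {20,80,20,80},
  # statistic = sum((|O-E|-0.5)^2/E) = 9.5^2 * (2/20 + 2/80) = 11.28125
  m <- rbind(c(30, 70), c(10, 90))
  ct <- stats::chisq.test(m, correct = TRUE)
  expect_equal(unname(ct$statistic), 11.28125, tolerance = 1e-6)

  # through the module surface: build a SwitchTable realizing the table
  b <- make_binning(c(small = 100e6, big = 100e6), 1e6)
  cat <- c(rep("A->B", 30), rep("A->A", 70),    # subset: 30 switched / 70
           rep("A->B", 10), rep("A->A", 90))    # rest: 10 switched / 90
  tab <- structure(cbind(b$bins, category = cat),
                   class = c("SwitchTable", "data.frame"), binning = b)
  enr <- suppressWarnings(switch_enrichment(tab, "small"))
  expect_equal(enr[["A->B"]]$statistic, 11.28125, tolerance = 1e-6)
  expect_lt(enr[["A->B"]]$p, 0.001)

  # independent table: statistic ~ 0, p ~ 1
  cat2 <- c(rep("B->A", 20), rep("B->B", 80), rep("B->A", 20), rep("B->B", 80))
  tab2 <- structure(cbind(b$bins, category = cat2),
                    class = c("SwitchTable", "data.frame"), binning = b)
  enr2 <- suppressWarnings(switch_enrichment(tab2, "small"))
  expect_lt(enr2[["B->A"]]$statistic, 0.05)
  expect_gt(enr2[["B->A"]]$p, 0.95)
})

test_that("expression aggregates by switch category with rank-sum tests", {
  b <- make_binning(c(c1 = 20e6), 1e6)
  cat <- c(rep("A->A", 8), rep("B->B", 4), rep("B->A", 4), rep("A->B", 4))
  tab <- structure(cbind(b$bins, category = cat),
                   class = c("SwitchTable", "data.frame"), binning = b)
  mk_expr <- function(l2fc) {
    mid <- b$bins$start + 5e5
    data.frame(chrom = "c1", start = mid - 100, end = mid + 100,
               log2fc = l2fc)
  }
  # all zero: medians 0, p = 1
  r0 <- suppressWarnings(expression_by_switch(tab, mk_expr(rep(0, 20))))
  expect_true(all(r0$medians == 0))
  expect_equal(r0$p_BA_vs_stable, 1)
  # B->A genes at +2, rest 0: median 2, significant for n = 4 per group
  fc <- ifelse(cat == "B->A", 2, 0)
  r1 <- suppressWarnings(expression_by_switch(tab, mk_expr(fc)))
  expect_equal(unname(r1$medians["B->A"]), 2)
  expect_lt(r1$p_BA_vs_stable, 0.05)
  expect_equal(r1$p_BA_vs_stable,
               suppressWarnings(stats::wilcox.test(rep(2, 4),
                                                   rep(0, 12))$p.value))
  # midpoint exactly on a bin edge goes to the right-hand bin
  e2 <- data.frame(chrom = "c1", start = 1e6 - 100, end = 1e6 + 100,
                   log2fc = 7)  # midpoint 1e6 = start of bin 2
  r2 <- suppressWarnings(expression_by_switch(tab, e2))
  expect_equal(unname(r2$values[["A->A"]]), 7)  # bin 2 is A->A
  # genes outside the binning are counted as skipped
  e3 <- data.frame(chrom = "cX", start = 1, end = 100, log2fc = 1)
  r3 <- suppressWarnings(expression_by_switch(tab, e3))
  expect_equal(r3$n_skipped, 1L)
})
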