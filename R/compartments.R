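#' A/B compartment calling by first principal component
#'
#' Per chromosome, the Pearson correlation matrix of the cis z-score columns
#' is computed and its first principal component (leading eigenvector)
#' extracted. The plaid pattern of preferential same-compartment interaction
#' makes the eigenvector sign track the two compartments; the sign is
#' oriented so that bins with above-median gene density have a positive mean
#' value, which labels the open, gene-rich compartment "A" and its opposite
#' "B". The correlation of the eigenvector with gene density is kept as
#' orientation evidence (the first component "usually" captures the plaid —
#' a low evidence value flags chromosomes where it may not).
#'
#' @param z A \code{ZScoreMap} at compartment resolution (250 kb
#'   conventionally).
#' @param genes Gene interval data frame (chrom, start, end); density is the
#'   count of gene midpoints per bin.
#' @param min_bins Chromosomes with fewer defined bins are left undefined
#'   (with a warning).
#' @return A \code{CompartmentProfile}: data frame (chrom, start, end,
#'   eigen, label) with per-chromosome orientation evidence in attribute
#'   \code{orientation}.
#' @export
call_compartments <- function(z, genes, min_bins = 10L) {
  b <- z$binning
  if (is.null(genes) || !nrow(genes)) stop("gene intervals required")
  validate_intervals(genes)
  mid <- floor((genes$start + genes$end) / 2)
  gbin <- bin_index(b, genes$chrom, mid)
  density <- tabulate(gbin[!is.na(gbin)], nbins = b$n_bins)
  ev <- rep(NA_real_, b$n_bins)
  evidence <- stats::setNames(rep(NA_real_, length(b$chroms)), b$chroms)
  for (c in b$chroms) {
    idx <- chrom_bins(b, c)
    sub <- z$z[idx, idx, drop = FALSE]
    def <- which(colSums(is.finite(sub)) >= 2 & !z$mask[idx])
    if (length(def) < min_bins) {
      warning("chromosome ", c, ": fewer than ", min_bins,
              " defined bins, compartments undefined")
      next
    }
    cc <- suppressWarnings(stats::cor(sub[def, def],
                                      use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    e1 <- eigen(cc, symmetric = TRUE)$vectors[, 1]
    dens <- density[idx][def]
    hi <- dens > stats::median(dens)
    if (any(hi) && mean(e1[hi]) < 0) e1 <- -e1
    evidence[c] <- suppressWarnings(stats::cor(e1, dens))
    ev[idx[def]] <- e1
  }
  label <- ifelse(is.na(ev), "undefined", ifelse(ev > 0, "A", "B"))
  label[!is.na(ev) & ev == 0] <- "undefined"
  out <- cbind(b$bins, eigen = ev, label = label)
  structure(out, class = c("CompartmentProfile", "data.frame"),
            orientation = evidence, binning = b)
}

#' Classify compartment switches between two conditions
#'
#' @param p1,p2 \code{CompartmentProfile}s on one binning (condition 1 and
#'   2).
#' @return A \code{SwitchTable}: per-bin category in \{A->A, B->B, A->B,
#'   B->A, undefined\} with a category count attribute. Categories read
#'   condition1 -> condition2.
#' @export
classify_switches <- function(p1, p2) {
  if (!same_binning(attr(p1, "binning"), attr(p2, "binning")))
    stop("profiles must share one binning")
  l1 <- p1$label; l2 <- p2$label
  cat <- ifelse(l1 == "undefined" | l2 == "undefined", "undefined",
                paste0(l1, "->", l2))
  out <- cbind(p1[, c("chrom", "start", "end")], category = cat)
  counts <- table(factor(cat, levels = c("A->A", "B->B", "A->B", "B->A",
                                         "undefined")))
  structure(out, class = c("SwitchTable", "data.frame"),
            counts = counts, binning = attr(p1, "binning"))
}

#' Switch enrichment on a chromosome subset (Yates chi-square)
#'
#' For each switch direction a 2x2 contingency table (subset vs rest of the
#' genome) x (switched in that direction vs stable) is tested with the
#' continuity-corrected chi-square statistic
#' sum((|O-E|-0.5)^2 / E), 1 df. Stable means A->A or B->B; the opposite
#' switch direction is excluded from the table.
#'
#' @param table A \code{SwitchTable}.
#' @param subset Chromosome names forming the subset of interest.
#' @return List with one entry per direction ("A->B", "B->A"), each holding
#'   the 2x2 \code{table}, \code{statistic} and \code{p}.
#' @export
switch_enrichment <- function(table, subset) {
  stopifnot(length(subset) > 0)
  insub <- table$chrom %in% subset
  res <- list()
  for (dir in c("A->B", "B->A")) {
    keep <- table$category %in% c(dir, "A->A", "B->B")
    sw <- table$category == dir
    m <- rbind(subset = c(sum(sw & insub & keep), sum(!sw & insub & keep)),
               rest = c(sum(sw & !insub & keep), sum(!sw & !insub & keep)))
    colnames(m) <- c("switched", "stable")
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      warning("degenerate margin in switch table for direction ", dir)
      res[[dir]] <- list(table = m, statistic = NA_real_, p = NA_real_)
      next
    }
    ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    if (any(ct$expected < 1))
      warning("expected cell count < 1 for direction ", dir)
    res[[dir]] <- list(table = m,
                       statistic = unname(ct$statistic),
                       p = ct$p.value)
  }
  res
}

#' Expression change by compartment switch category
#'
#' Assigns each gene (by interval midpoint, half-open bins) to the switch
#' category of its bin and compares the log2 fold-change distributions of
#' the switching categories against the stable genes with two-sided
#' Wilcoxon rank-sum tests.
#'
#' @param table A \code{SwitchTable}.
#' @param expr Gene table with columns chrom, start, end, log2fc (0-based
#'   half-open coordinates on the same assembly).
#' @return List with per-category value vectors (\code{values}), medians,
#'   rank-sum p values (\code{p_AB_vs_stable}, \code{p_BA_vs_stable}) and
#'   the count of genes outside the binning (\code{n_skipped}).
#' @export
expression_by_switch <- function(table, expr) {
  stopifnot(all(c("chrom", "start", "end", "log2fc") %in% names(expr)))
  b <- attr(table, "binning")
  mid <- floor((expr$start + expr$end) / 2)
  gbin <- bin_index(b, expr$chrom, mid)
  skipped <- sum(is.na(gbin))
  keep <- !is.na(gbin)
  cats <- table$category[gbin[keep]]
  vals <- split(expr$log2fc[keep], cats)
  stable <- c(vals[["A->A"]], vals[["B->B"]])
  ranksum <- function(x) {
    if (is.null(x)) return(NA_real_)
    ranksum_p(x, stable)
  }
  list(values = vals,
       medians = vapply(vals, stats::median, 0),
       p_AB_vs_stable = ranksum(vals[["A->B"]]),
       p_BA_vs_stable = ranksum(vals[["B->A"]]),
       n_skipped = skipped)
}
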