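#' Replicate-null standardized differential interaction score
#'
#' For each cell the mean between-condition z-score difference
#' D = mean(A1-B1, A1-B2, A2-B1, A2-B2) is standardized against a null
#' distribution of within-condition replicate differences: at \code{n_null}
#' cells sampled uniformly without replacement from the cells defined in all
#' four maps, the replicate differences (both orders, so the null mean is
#' exactly zero and the statistic is exactly antisymmetric under condition
#' swap) of both conditions are pooled; the score is
#' (D - null_mean) / null_sd. Positive scores are condition-A-enriched.
#'
#' @param zA1,zA2,zB1,zB2 \code{ZScoreMap}s sharing one binning (condition A
#'   replicates 1,2 and condition B replicates 1,2); the conventional
#'   resolution for this statistic is 6.5 Mb.
#' @param n_null Number of null cells to sample (default 500000); if fewer
#'   cells are defined, all are used with a warning.
#' @param seed Seed for the null sampling.
#' @return A \code{DifferentialMap}: binning, symmetric score matrix,
#'   null_mean, null_scale, n_null (cells actually sampled), seed.
#' @export
differential_score <- function(zA1, zA2, zB1, zB2, n_null = 500000L,
                               seed = 1L) {
  maps <- list(zA1, zA2, zB1, zB2)
  b <- zA1$binning
  for (m in maps[-1]) if (!same_binning(b, m$binning))
    stop("z-score maps must share one binning")
  stopifnot(n_null >= 1)
  ok <- is.finite(zA1$z) & is.finite(zA2$z) & is.finite(zB1$z) &
    is.finite(zB2$z)
  D <- ((zA1$z - zB1$z) + (zA1$z - zB2$z) +
          (zA2$z - zB1$z) + (zA2$z - zB2$z)) / 4
  D[!ok] <- NA_real_
  cells <- which(upper.tri(D) & ok)
  if (!length(cells)) stop("no cells defined in all four maps")
  if (length(cells) < n_null) {
    warning("only ", length(cells), " defined cells; sampling all")
    n_use <- length(cells)
  } else n_use <- as.integer(n_null)
  pick <- with_seed(as.integer(seed) %% 2147483000L + 1L,
                    sample(cells, n_use))
  ra <- zA1$z[pick] - zA2$z[pick]
  rb <- zB1$z[pick] - zB2$z[pick]
  null <- c(ra, -ra, rb, -rb)
  null_mean <- mean(null)      # exactly 0 by symmetrization
  null_scale <- stats::sd(null)
  if (!is.finite(null_scale) || null_scale == 0)
    stop("degenerate replicate null (zero dispersion)")
  S <- (D - null_mean) / null_scale
  structure(list(binning = b, score = S, null_mean = null_mean,
                 null_scale = null_scale, n_null = n_use,
                 seed = as.integer(seed)),
            class = "DifferentialMap")
}

#' @export
print.DifferentialMap <- function(x, ...) {
  cat(sprintf("DifferentialMap: %d bins, null sd %.3f (%d null cells)\n",
              x$binning$n_bins, x$null_scale, x$n_null))
  invisible(x)
}

#' Direct z-score subtraction
#'
#' Cellwise zA - zB with missing values propagated; the simple variant of
#' the differential map.
#'
#' @param zA,zB \code{ZScoreMap}s on one binning.
#' @return Numeric matrix of differences.
#' @export
subtract_zscores <- function(zA, zB) {
  if (!same_binning(zA$binning, zB$binning))
    stop("z-score maps must share one binning")
  zA$z - zB$z
}

#' Compare trans differential scores between chromosome sets
#'
#' Collects the differential scores of inter-chromosomal cells for
#' chromosome pairs within \code{set1} versus pairs crossing from
#' \code{set1} to \code{set2}, and tests their location shift with a
#' two-sided Wilcoxon rank-sum test. This quantifies, e.g., preferential
#' clustering of the small chromosomes relative to the rest of the genome.
#'
#' @param diff A \code{DifferentialMap}.
#' @param set1,set2 Chromosome name vectors (non-empty; \code{set2} disjoint
#'   from \code{set1} in typical use).
#' @return List with \code{within} and \code{cross} score vectors, their
#'   medians, and \code{p} (two-sided rank-sum).
#' @export
interchrom_set_comparison <- function(diff, set1, set2) {
  b <- diff$binning
  stopifnot(length(set1) > 0, length(set2) > 0)
  collect <- function(pairs) {
    v <- unlist(lapply(pairs, function(p) {
      blk <- diff$score[chrom_bins(b, p[1]), chrom_bins(b, p[2])]
      blk[is.finite(blk)]
    }))
    if (is.null(v)) numeric(0) else v
  }
  wpairs <- if (length(set1) >= 2) utils::combn(set1, 2, simplify = FALSE)
            else list()
  cpairs <- unlist(lapply(set1, function(a) lapply(set2, function(b2) c(a, b2))),
                   recursive = FALSE)
  within <- collect(wpairs)
  cross <- collect(cpairs)
  if (!length(within) || !length(cross)) stop("empty score sample")
  list(within = within, cross = cross,
       median_within = stats::median(within),
       median_cross = stats::median(cross),
       p = ranksum_p(within, cross))
}
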