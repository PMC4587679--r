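#' Contact-frequency scaling curve
#'
#' Mean unmasked cis contact value per log-spaced genomic-distance bin, for
#' the whole genome, per chromosome, or per chromosome arm (requires a
#' centromere interval table; cells crossing the centromere are excluded
#' from arm curves). The log-log slope of the curve summarizes the folding
#' of the chromatin fiber; an upturn at the largest distances reveals
#' telomere-to-telomere clustering.
#'
#' @param map An ICE-corrected \code{ContactMap}.
#' @param scope "genome", "chromosome" or "arm".
#' @param n_logbins Number of log-spaced distance bins (default 50).
#' @param centromeres Interval data frame (chrom, start, end), required for
#'   scope "arm".
#' @return A \code{ScalingCurve} data frame (group, distance, mean, n);
#'   distance is the geometric bin centre in bp.
#' @export
scaling_curve <- function(map, scope = c("genome", "chromosome", "arm"),
                          n_logbins = 50L, centromeres = NULL) {
  scope <- match.arg(scope)
  if (scope == "arm" && is.null(centromeres))
    stop("scope 'arm' requires centromere intervals")
  b <- map$binning
  M <- masked_values(map)
  gather <- function(idx, group) {
    nb <- length(idx)
    if (nb < 2) return(NULL)
    pos <- (b$bins$start[idx] + b$bins$end[idx]) / 2
    ut <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
    v <- M[cbind(idx[ut[, 1]], idx[ut[, 2]])]
    ok <- !is.na(v)
    data.frame(group = group, d = abs(pos[ut[, 2]] - pos[ut[, 1]])[ok],
               v = v[ok], stringsAsFactors = FALSE)
  }
  parts <- list()
  for (c in b$chroms) {
    idx <- chrom_bins(b, c)
    if (scope == "arm") {
      cen <- centromeres[centromeres$chrom == c, , drop = FALSE]
      if (!nrow(cen)) next
      left <- idx[b$bins$end[idx] <= min(cen$start)]
      right <- idx[b$bins$start[idx] >= max(cen$end)]
      parts[[length(parts) + 1]] <- gather(left, paste0(c, "_p"))
      parts[[length(parts) + 1]] <- gather(right, paste0(c, "_q"))
    } else {
      grp <- if (scope == "genome") "genome" else c
      parts[[length(parts) + 1]] <- gather(idx, grp)
    }
  }
  cells <- do.call(rbind, parts)
  if (is.null(cells) || !nrow(cells)) stop("no cis cells in requested scope")
  out <- do.call(rbind, lapply(split(cells, cells$group), function(s) {
    rng <- range(s$d)
    brk <- exp(seq(log(rng[1] * 0.999), log(rng[2] * 1.001),
                   length.out = n_logbins + 1))
    bin <- findInterval(s$d, brk, rightmost.closed = TRUE)
    mm <- tapply(s$v, bin, mean)
    nn <- tapply(s$v, bin, length)
    ctr <- sqrt(brk[-1] * brk[-length(brk)])
    data.frame(group = s$group[1],
               distance = ctr[as.integer(names(mm))],
               mean = as.numeric(mm), n = as.integer(nn),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("ScalingCurve", "data.frame"))
}

#' Log-log slope of a scaling curve
#'
#' Weighted least-squares fit of log(mean) against log(distance); the
#' negated slope estimates the distance-decay exponent.
#'
#' @param curve A \code{ScalingCurve} (one group, or specify \code{group}).
#' @param group Group to fit when the curve holds several.
#' @param d_range Optional distance range (bp) to restrict the fit, e.g. to
#'   exclude the telomeric upturn.
#' @return The fitted slope (numeric).
#' @export
fit_scaling_slope <- function(curve, group = NULL, d_range = NULL) {
  s <- as.data.frame(curve)
  if (!is.null(group)) s <- s[s$group == group, ]
  if (!is.null(d_range)) s <- s[s$distance >= d_range[1] &
                                  s$distance <= d_range[2], ]
  s <- s[is.finite(s$mean) & s$mean > 0, ]
  if (nrow(s) < 3) stop("too few curve points to fit a slope")
  fit <- stats::lm(log(mean) ~ log(distance), data = s, weights = s$n)
  unname(stats::coef(fit)[2])
}

#' Tail upturn of a scaling curve
#'
#' Quantifies an end-of-chromosome upturn: a log-log line is fitted to the
#' mid-range of the curve and the observed tail means are compared with its
#' extrapolation. A ratio near 1 means the power-law decay continues to the
#' end; a ratio well above 1 (telomere-to-telomere clustering) means the
#' largest-distance contacts exceed the decay trend.
#'
#' @param curve A \code{ScalingCurve}.
#' @param group Group to evaluate when the curve holds several.
#' @param fit_range Fractions of the maximum distance delimiting the fit
#'   window (default 5\%-60\%).
#' @param tail_from Fraction of the maximum distance where the tail starts
#'   (default 0.9).
#' @return Weighted mean of observed/extrapolated over the tail bins.
#' @export
scaling_upturn <- function(curve, group = NULL, fit_range = c(0.05, 0.6),
                           tail_from = 0.9) {
  s <- as.data.frame(curve)
  if (!is.null(group)) s <- s[s$group == group, ]
  s <- s[is.finite(s$mean) & s$mean > 0, ]
  dmax <- max(s$distance)
  mid <- s[s$distance >= fit_range[1] * dmax &
             s$distance <= fit_range[2] * dmax, ]
  if (nrow(mid) < 3) stop("too few curve points in the fit window")
  fit <- stats::lm(log(mean) ~ log(distance), data = mid, weights = mid$n)
  tail <- s[s$distance >= tail_from * dmax, ]
  if (!nrow(tail)) stop("no curve points in the tail window")
  pred <- exp(stats::predict(fit, newdata = tail))
  stats::weighted.mean(tail$mean / pred, tail$n)
}

#' Telomeric end-to-end interaction frequency
#'
#' Per chromosome, the mean unmasked contact value between bins in the
#' first and last \code{end_fraction} of the chromosome length — the
#' intra-chromosomal telomere/sub-telomere association level.
#'
#' @param map An ICE-corrected \code{ContactMap}.
#' @param end_fraction End size as a proportion of chromosome length
#'   (0 < f < 0.5; default 0.05).
#' @return A \code{TelomereStats} data frame (chrom, mean, n_cells);
#'   chromosomes whose end regions hold no full bin are skipped with a
#'   warning.
#' @export
telomere_interaction <- function(map, end_fraction = 0.05) {
  stopifnot(end_fraction > 0, end_fraction < 0.5)
  b <- map$binning
  M <- masked_values(map)
  rows <- lapply(b$chroms, function(c) {
    eb <- end_bins(b, c, end_fraction)
    if (!length(eb$left) || !length(eb$right) ||
        length(intersect(eb$left, eb$right))) {
      warning("chromosome ", c, ": end regions degenerate, skipped")
      return(NULL)
    }
    blk <- M[eb$left, eb$right, drop = FALSE]
    v <- blk[!is.na(blk)]
    if (!length(v)) return(NULL)
    data.frame(chrom = c, mean = mean(v), n_cells = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("TelomereStats", "data.frame"),
            end_fraction = end_fraction)
}

#' Compare telomeric interaction levels between conditions
#'
#' Two-sided Wilcoxon rank-sum test on the per-chromosome end-to-end mean
#' interaction values of two conditions, with per-chromosome ratios.
#'
#' @param statsA,statsB \code{TelomereStats} for the two conditions.
#' @return List with \code{p}, a data frame of per-chromosome
#'   \code{ratios} (A/B), and both mean vectors.
#' @export
compare_telomere <- function(statsA, statsB) {
  common <- intersect(statsA$chrom, statsB$chrom)
  if (length(common) < 3)
    warning("fewer than 3 shared chromosomes; p value unreliable")
  a <- statsA$mean[match(common, statsA$chrom)]
  b <- statsB$mean[match(common, statsB$chrom)]
  list(p = ranksum_p(a, b),
       ratios = data.frame(chrom = common, ratio = a / b,
                           stringsAsFactors = FALSE),
       meanA = stats::setNames(a, common),
       meanB = stats::setNames(b, common))
}
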