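#' Distance-expected contact profile (weighted LOWESS)
#'
#' For every genomic distance d (in bins) the unmasked cis values at
#' separation d are collected, an interquartile-range outlier filter is
#' applied, and their mean and sample SD are computed. The per-distance mean
#' and SD curves are then smoothed by weighted local regression
#' (\code{limma::weightedLowess}, weights = number of surviving
#' observations) in log-log space, where a power-law decay is exactly
#' linear; span \code{alpha} follows the 1\% convention.
#'
#' @param map An ICE-corrected \code{ContactMap} (raw maps are accepted for
#'   diagnostic use).
#' @param alpha LOWESS span as a proportion of the distance range; 0
#'   disables smoothing.
#' @param iqr_factor Values outside [Q1 - f*IQR, Q3 + f*IQR] at each
#'   distance are dropped before mean/SD; \code{Inf} disables the filter.
#' @param scope "genome" (one profile pooled over chromosomes) or
#'   "chromosome" (one profile each).
#' @return An \code{ExpectedProfile}: data frame (chrom, distance,
#'   distance_bp, mean, sd, n_used) with smoothing metadata. Distances with
#'   fewer than 2 surviving values have NA mean/SD and yield missing
#'   z-scores downstream.
#' @export
distance_expected <- function(map, alpha = 0.01, iqr_factor = 1.5,
                              scope = c("genome", "chromosome")) {
  scope <- match.arg(scope)
  b <- map$binning
  M <- masked_values(map)
  groups <- if (scope == "genome") list(genome = b$chroms) else
    stats::setNames(as.list(b$chroms), b$chroms)
  res <- lapply(names(groups), function(g) {
    chroms <- groups[[g]]
    maxd <- max(b$chrom_nbins[chroms]) - 1L
    if (maxd < 1) return(NULL)
    rows <- lapply(seq_len(maxd), function(d) {
      v <- unlist(lapply(chroms, function(c) {
        idx <- chrom_bins(b, c)
        nb <- length(idx)
        if (nb <= d) return(numeric(0))
        M[cbind(idx[seq_len(nb - d)], idx[seq_len(nb - d) + d])]
      }))
      v <- v[!is.na(v)]
      if (length(v) >= 4 && is.finite(iqr_factor)) {
        q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
        iqr <- q[2] - q[1]
        if (iqr > 0)  # a zero IQR (discrete low counts) gives a degenerate band
          v <- v[v >= q[1] - iqr_factor * iqr & v <= q[2] + iqr_factor * iqr]
      }
      data.frame(chrom = g, distance = d, distance_bp = d * b$bin_size,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                 n_used = length(v), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  prof <- do.call(rbind, res)
  if (alpha > 0) {
    for (g in unique(prof$chrom)) {
      sel <- prof$chrom == g
      prof$mean[sel] <- smooth_loglog(prof$distance[sel], prof$mean[sel],
                                      prof$n_used[sel], alpha)
      prof$sd[sel] <- smooth_loglog(prof$distance[sel], prof$sd[sel],
                                    prof$n_used[sel], alpha)
    }
  }
  structure(prof, class = c("ExpectedProfile", "data.frame"),
            alpha = alpha, iqr_factor = iqr_factor, scope = scope,
            bin_size = b$bin_size)
}

# smooth y over log(d) in log space; entries with y <= 0 or NA pass through
smooth_loglog <- function(d, y, w, alpha) {
  ok <- is.finite(y) & y > 0 & w > 0
  if (sum(ok) < 10) return(y)
  span <- max(alpha, 5 / sum(ok))
  fit <- limma::weightedLowess(log(d[ok]), log(y[ok]), weights = w[ok],
                               span = span, iterations = 2)
  y[ok] <- exp(fit$fitted)
  y
}

#' Write an expected profile as TSV
#' @param profile An \code{ExpectedProfile}.
#' @param path Output path.
#' @export
write_expected_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Distance-normalized Z-score transform
#'
#' Cis cells are standardized against the expected profile at their
#' distance: z(i,j) = (value - mean(d)) / sd(d). Trans cells are
#' standardized against the mean and SD of all unmasked trans values of
#' their chromosome pair. Cells are missing where the profile is undefined,
#' the SD is zero, or a bin is masked; the diagonal is always missing.
#'
#' @param map A \code{ContactMap} (same binning and, for per-chromosome
#'   scope, the same chromosomes as the profile).
#' @param profile An \code{ExpectedProfile} from
#'   \code{\link{distance_expected}}.
#' @return A \code{ZScoreMap}: binning, symmetric z matrix, mask.
#' @export
zscore_transform <- function(map, profile) {
  b <- map$binning
  M <- masked_values(map)
  scope <- attr(profile, "scope")
  Z <- matrix(NA_real_, nrow(M), ncol(M))
  for (c1 in b$chroms) {
    idx <- chrom_bins(b, c1)
    nb <- length(idx)
    g <- if (scope == "genome") "genome" else c1
    p <- profile[profile$chrom == g, ]
    if (nrow(p)) {
      mu <- sdv <- rep(NA_real_, nb - 1)
      mu[p$distance] <- p$mean
      sdv[p$distance] <- ifelse(p$n_used >= 2 & p$sd > 0, p$sd, NA_real_)
      for (d in seq_len(nb - 1)) {
        if (!is.finite(mu[d]) || !is.finite(sdv[d])) next
        ii <- idx[seq_len(nb - d)]; jj <- idx[seq_len(nb - d) + d]
        z <- (M[cbind(ii, jj)] - mu[d]) / sdv[d]
        Z[cbind(ii, jj)] <- z
        Z[cbind(jj, ii)] <- z
      }
    }
    for (c2 in b$chroms[seq_along(b$chroms) > match(c1, b$chroms)]) {
      jdx <- chrom_bins(b, c2)
      block <- M[idx, jdx, drop = FALSE]
      v <- block[!is.na(block)]
      if (length(v) >= 2) {
        s <- stats::sd(v)
        if (is.finite(s) && s > 0) {
          zb <- (block - mean(v)) / s
          Z[idx, jdx] <- zb
          Z[jdx, idx] <- t(zb)
        }
      }
    }
  }
  structure(list(binning = b, z = Z, mask = map$mask),
            class = "ZScoreMap")
}

#' @export
print.ZScoreMap <- function(x, ...) {
  cat(sprintf("ZScoreMap: %d bins, %.1f%% cells defined\n",
              x$binning$n_bins, 100 * mean(is.finite(x$z))))
  invisible(x)
}
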