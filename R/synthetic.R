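#' Specification of a synthetic two-condition Hi-C study
#'
#' Parameterizes a planted-truth generator for two conditions (1 = normal-like,
#' 2 = tumor-like) with two replicates each. The expected contact intensity is
#' built from: power-law distance decay in cis; a plaid A/B compartment factor
#' \code{1 + compartment_strength * e_i * e_j}; a within-TAD enrichment factor;
#' a telomeric end-to-end boost; a flat trans floor modulated by
#' small-chromosome clustering, translocation blocks, per-bin multiplicative
#' biases and per-chromosome copy-number factors. Replicates are independent
#' Poisson draws around the expectation, scaled to a target sequencing depth.
#'
#' Defaults mirror a two-cell-line breast-epithelium study design: condition 1
#' carries a 3x telomere end-to-end boost and 2x clustering of the small
#' chromosomes; condition 2 carries a translocation block and ~12% of bins
#' with flipped compartment sign; ~85% of TAD boundaries are shared.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param bin_size Bin width (bp).
#' @param decay_exponent Power-law exponent of cis contact decay (value 1
#'   means contacts fall off as 1/distance).
#' @param trans_floor Baseline inter-chromosomal level relative to the
#'   one-bin cis level.
#' @param compartment_strength Plaid amplitude (0 disables compartments;
#'   must be < 1 so intensities stay positive).
#' @param compartment_block Block length (bins) of the auto-generated
#'   alternating compartment profile.
#' @param switch_fraction Fraction of bins whose compartment sign is flipped
#'   in condition 2.
#' @param compartment_profile Optional list of two per-bin vectors in [-1,1]
#'   overriding the auto-generated profiles.
#' @param tad_spacing Integer range (bins) of spacing between auto-generated
#'   TAD boundaries; use \code{NULL} boundaries to disable TADs.
#' @param boundary_conservation Probability that a condition-1 boundary is
#'   kept in place in condition 2 (otherwise it is moved, creating a pair of
#'   condition-specific boundaries).
#' @param tad_boundaries Optional list (per condition) of per-chromosome
#'   integer vectors of local boundary bin indices; \code{NA} to auto-generate,
#'   \code{NULL} for no TADs.
#' @param tad_strength Within-TAD over between-TAD contact ratio.
#' @param translocations List of blocks, each
#'   \code{list(chrom1, range1, chrom2, range2, intensity)} where
#'   \code{intensity} is a length-2 multiplier (per condition) on the trans
#'   floor inside the block.
#' @param small_chroms Chromosome subset whose mutual trans contacts are
#'   scaled by \code{small_chrom_trans_factor}; default: chromosomes
#'   shorter than 30 Mb.
#' @param small_chrom_trans_factor Length-2 per-condition multiplier.
#' @param telomere_boost Length-2 per-condition multiplier on contacts
#'   between the two \code{end_fraction} ends of each chromosome.
#' @param end_fraction Chromosome-length proportion defining an "end"
#'   (0 < f < 0.5).
#' @param bias_sd Log-SD of the lognormal per-bin visibility bias
#'   (0 disables bias).
#' @param bias Optional explicit per-bin positive bias vector.
#' @param copy_number Optional named per-chromosome positive multiplier
#'   (default all 1).
#' @param depth Expected total read pairs per sampled map.
#' @param seed Integer seed; all auto-generated structure and all sampled
#'   replicates derive from it deterministically.
#' @return A \code{SyntheticSpec} with materialized profiles, boundaries,
#'   bias and binning.
#' @export
synthetic_spec <- function(chrom_sizes = c(chr1 = 60e6, chr2 = 45e6, chr3 = 25e6),
                           bin_size = 1e6,
                           decay_exponent = 1.0,
                           trans_floor = 0.05,
                           compartment_strength = 0.6,
                           compartment_block = 8L,
                           switch_fraction = 0.12,
                           compartment_profile = NULL,
                           tad_spacing = c(18L, 30L),
                           boundary_conservation = 0.85,
                           tad_boundaries = NA,
                           tad_strength = 3,
                           translocations = list(
                             list(chrom1 = "chr1", range1 = c(10e6, 20e6),
                                  chrom2 = "chr2", range2 = c(5e6, 15e6),
                                  intensity = c(1, 8))),
                           small_chroms = NULL,
                           small_chrom_trans_factor = c(2, 1),
                           telomere_boost = c(3, 1),
                           end_fraction = 0.05,
                           bias_sd = 0.25,
                           bias = NULL,
                           copy_number = NULL,
                           depth = 1e6,
                           seed = 1L) {
  stopifnot(end_fraction > 0, end_fraction < 0.5,
            tad_strength > 0, trans_floor > 0,
            all(telomere_boost > 0), all(small_chrom_trans_factor > 0),
            compartment_strength >= 0, compartment_strength < 1,
            depth > 0)
  binning <- make_binning(chrom_sizes, bin_size)
  n <- binning$n_bins
  translocations <- translocations[vapply(translocations, function(t)
    t$chrom1 %in% binning$chroms && t$chrom2 %in% binning$chroms, TRUE)]
  if (is.null(small_chroms))
    small_chroms <- binning$chroms[binning$lengths < 30e6]

  materialized <- with_seed(as.integer(seed) %% 2147483000L + 1L, {
    prof <- compartment_profile
    if (is.null(prof)) {
      e1 <- unlist(lapply(binning$chroms, function(c) {
        nb <- binning$chrom_nbins[[c]]
        s0 <- sample(c(-1, 1), 1)
        blk <- ((seq_len(nb) - 1) %/% compartment_block) %% 2
        s0 * ifelse(blk == 0, 1, -1)
      }))
      e2 <- e1
      if (switch_fraction > 0) {
        for (c in binning$chroms) {
          idx <- chrom_bins(binning, c)
          k <- max(1L, round(switch_fraction * length(idx)))
          st <- sample(length(idx) - k + 1L, 1)
          flip <- idx[st:(st + k - 1L)]
          e2[flip] <- -e2[flip]
        }
      }
      prof <- list(e1, e2)
    }
    bnd <- tad_boundaries
    if (!is.list(bnd) && length(bnd) == 1 && is.na(bnd)) {
      b1 <- lapply(binning$chroms, function(c) {
        nb <- binning$chrom_nbins[[c]]
        pos <- integer(0); p <- 0L
        repeat {
          p <- p + sample(seq.int(tad_spacing[1], tad_spacing[2]), 1)
          if (p >= nb - 2L) break
          pos <- c(pos, p)
        }
        pos
      })
      names(b1) <- binning$chroms
      b2 <- lapply(binning$chroms, function(c) {
        nb <- binning$chrom_nbins[[c]]
        sort(unique(vapply(b1[[c]], function(p) {
          if (stats::runif(1) < boundary_conservation) p
          else {
            q <- p + sample(c(-6:-4, 4:6), 1)
            as.integer(min(max(q, 2L), nb - 2L))
          }
        }, 1L)))
      })
      names(b2) <- binning$chroms
      bnd <- list(b1, b2)
    } else if (is.null(bnd)) {
      empty <- stats::setNames(rep(list(integer(0)), length(binning$chroms)),
                               binning$chroms)
      bnd <- list(empty, empty)
    }
    bv <- bias
    if (is.null(bv)) {
      bv <- if (bias_sd > 0) stats::rlnorm(n, 0, bias_sd) else rep(1, n)
    }
    list(profile = prof, boundaries = bnd, bias = bv)
  })

  if (is.null(copy_number))
    copy_number <- stats::setNames(rep(1, length(binning$chroms)), binning$chroms)
  stopifnot(all(copy_number > 0), all(materialized$bias > 0))
  for (k in 1:2) for (c in binning$chroms) {
    b <- materialized$boundaries[[k]][[c]]
    if (length(b) && (any(b < 1) || any(b >= binning$chrom_nbins[[c]])))
      stop("TAD boundaries must lie strictly inside the chromosome")
  }

  structure(list(
    binning = binning, chrom_sizes = binning$lengths, bin_size = bin_size,
    decay_exponent = decay_exponent, trans_floor = trans_floor,
    compartment_strength = compartment_strength,
    compartment_profile = materialized$profile,
    tad_boundaries = materialized$boundaries, tad_strength = tad_strength,
    translocations = translocations, small_chroms = small_chroms,
    small_chrom_trans_factor = small_chrom_trans_factor,
    telomere_boost = telomere_boost, end_fraction = end_fraction,
    bias = materialized$bias, copy_number = copy_number,
    depth = depth, seed = as.integer(seed)
  ), class = "SyntheticSpec")
}

#' @export
print.SyntheticSpec <- function(x, ...) {
  nb <- vapply(1:2, function(k)
    sum(lengths(x$tad_boundaries[[k]])), 0L)
  cat(sprintf(paste0(
    "SyntheticSpec: %d chromosomes, bin %s bp, %d bins, depth %s, seed %d\n",
    "  decay %.2f, trans floor %.3f, compartments s=%.2f, TADs x%.1f ",
    "(%d/%d boundaries)\n",
    "  telomere boost (%.1f, %.1f), small-chrom trans (%.1f, %.1f), ",
    "%d translocation(s)\n"),
    length(x$binning$chroms), format(x$bin_size, big.mark = ","),
    x$binning$n_bins, format(x$depth, big.mark = ","), x$seed,
    x$decay_exponent, x$trans_floor, x$compartment_strength,
    x$tad_strength, nb[1], nb[2],
    x$telomere_boost[1], x$telomere_boost[2],
    x$small_chrom_trans_factor[1], x$small_chrom_trans_factor[2],
    length(x$translocations)))
  invisible(x)
}

# run expr with a local RNG seed, restoring the global RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# bins belonging to each chromosome end under the spec's end_fraction
end_bins <- function(binning, chrom, end_fraction) {
  idx <- chrom_bins(binning, chrom)
  L <- binning$lengths[[chrom]]
  starts <- binning$bins$start[idx]
  ends <- binning$bins$end[idx]
  list(left = idx[starts < end_fraction * L],
       right = idx[ends > (1 - end_fraction) * L])
}

#' Expected (noise-free) contact intensities of a synthetic spec
#'
#' @param spec A \code{SyntheticSpec}.
#' @param condition 1 or 2.
#' @return A \code{ContactMap} with state "expected"; its upper triangle
#'   (diagonal included) sums to \code{spec$depth}.
#' @export
expected_map <- function(spec, condition = 1) {
  b <- spec$binning
  n <- b$n_bins
  E <- matrix(NA_real_, n, n)
  e <- spec$compartment_profile[[condition]]
  for (c1 in b$chroms) {
    i1 <- chrom_bins(b, c1)
    nb <- length(i1)
    # cis
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    cell <- pmax(d, 1) ^ (-spec$decay_exponent)
    if (spec$compartment_strength > 0) {
      ec <- e[i1]
      cell <- cell * pmax(1 + spec$compartment_strength * outer(ec, ec), 0.05)
    }
    bd <- spec$tad_boundaries[[condition]][[c1]]
    if (length(bd)) {
      seg <- findInterval(seq_len(nb), bd + 0.5)
      cell <- cell * ifelse(outer(seg, seg, "=="), spec$tad_strength, 1)
    }
    if (spec$telomere_boost[condition] != 1) {
      eb <- end_bins(b, c1, spec$end_fraction)
      li <- match(eb$left, i1); ri <- match(eb$right, i1)
      if (length(li) && length(ri) && !any(li %in% ri)) {
        cell[li, ri] <- cell[li, ri] * spec$telomere_boost[condition]
        cell[ri, li] <- cell[ri, li] * spec$telomere_boost[condition]
      }
    }
    E[i1, i1] <- cell
    # trans
    for (c2 in b$chroms[match(c1, b$chroms) < seq_along(b$chroms)]) {
      i2 <- chrom_bins(b, c2)
      block <- matrix(spec$trans_floor, length(i1), length(i2))
      if (c1 %in% spec$small_chroms && c2 %in% spec$small_chroms)
        block <- block * spec$small_chrom_trans_factor[condition]
      for (tr in spec$translocations) {
        hit <- NULL
        if (tr$chrom1 == c1 && tr$chrom2 == c2) hit <- list(tr$range1, tr$range2)
        if (tr$chrom1 == c2 && tr$chrom2 == c1) hit <- list(tr$range2, tr$range1)
        if (!is.null(hit)) {
          r1 <- which(b$bins$start[i1] < hit[[1]][2] & b$bins$end[i1] > hit[[1]][1])
          r2 <- which(b$bins$start[i2] < hit[[2]][2] & b$bins$end[i2] > hit[[2]][1])
          block[r1, r2] <- block[r1, r2] * tr$intensity[condition]
        }
      }
      E[i1, i2] <- block
      E[i2, i1] <- t(block)
    }
  }
  bias <- spec$bias * sqrt(spec$copy_number[b$bins$chrom])
  E <- E * outer(bias, bias)
  tot <- sum(E[upper.tri(E, diag = TRUE)])
  E <- E * (spec$depth / tot)
  contact_map(b, E, state = "expected")
}

#' Sample a noisy replicate contact map
#'
#' Independent Poisson counts around \code{\link{expected_map}}; identical
#' (spec, condition, replicate) always yields identical output.
#'
#' @param spec A \code{SyntheticSpec}.
#' @param condition 1 or 2.
#' @param replicate Replicate number (any small integer).
#' @return A raw \code{ContactMap} of integer counts.
#' @export
sample_map <- function(spec, condition = 1, replicate = 1) {
  E <- expected_map(spec, condition)
  n <- nrow(E$values)
  seed <- (spec$seed * 2053L + condition * 131L + as.integer(replicate)) %%
    2147483000L + 1L
  M <- with_seed(seed, {
    ut <- upper.tri(E$values, diag = TRUE)
    counts <- stats::rpois(sum(ut), E$values[ut])
    M <- matrix(0, n, n)
    M[ut] <- counts
    M <- M + t(M)
    diag(M) <- diag(M) / 2
    M
  })
  contact_map(spec$binning, M, state = "raw")
}

#' Planted compartment truth of a synthetic spec
#' @param spec A \code{SyntheticSpec}.
#' @param condition 1 or 2.
#' @return Data frame (chrom, start, end, value) of the planted per-bin
#'   compartment profile.
#' @export
truth_compartments <- function(spec, condition = 1) {
  cbind(spec$binning$bins, value = spec$compartment_profile[[condition]])
}

#' Planted TAD boundary truth of a synthetic spec
#' @param spec A \code{SyntheticSpec}.
#' @param condition 1 or 2.
#' @return BED-like data frame of boundary bins (one bin each) plus the
#'   global \code{bin} index.
#' @export
truth_boundaries <- function(spec, condition = 1) {
  b <- spec$binning
  out <- do.call(rbind, lapply(b$chroms, function(c) {
    loc <- spec$tad_boundaries[[condition]][[c]]
    if (!length(loc)) return(NULL)
    gb <- chrom_bins(b, c)[loc + 1L]  # boundary between bins loc and loc+1
    data.frame(chrom = c, start = b$bins$start[gb], end = b$bins$end[gb],
               bin = gb, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), bin = integer())
  out
}

#' Synthetic gene intervals consistent with the planted compartments
#'
#' Gene density is higher in planted A (positive-profile) bins, so the
#' gene-density orientation step of compartment calling can be exercised.
#' Deterministic given the spec seed.
#'
#' @param spec A \code{SyntheticSpec}.
#' @param lambda_a,lambda_b Mean genes per bin in A / B bins.
#' @return BED-like data frame of gene intervals.
#' @export
truth_genes <- function(spec, lambda_a = 4, lambda_b = 1) {
  b <- spec$binning
  e <- spec$compartment_profile[[1]]
  with_seed(spec$seed %% 2147480000L + 7777L, {
    rows <- lapply(seq_len(b$n_bins), function(i) {
      lam <- if (e[i] > 0) lambda_a else lambda_b
      k <- stats::rpois(1, lam)
      if (!k) return(NULL)
      w <- b$bins$end[i] - b$bins$start[i]
      s <- b$bins$start[i] + floor(stats::runif(k, 0, max(w - 1000, 1)))
      data.frame(chrom = b$bins$chrom[i], start = s, end = s + 1000,
                 name = sprintf("g%06d_%02d", i, seq_len(k)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write the generator's planted truth to a directory
#' @param spec A \code{SyntheticSpec}.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_truth <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in 1:2) {
    tb <- truth_boundaries(spec, k)
    write_bed(tb[, c("chrom", "start", "end")],
              file.path(dir, sprintf("boundaries_cond%d.bed", k)))
    tc <- truth_compartments(spec, k)
    names(tc)[4] <- "value"
    write_bedgraph(tc, file.path(dir, sprintf("compartments_cond%d.bedgraph", k)))
  }
  utils::write.table(
    data.frame(bin = bin_labels(spec$binning), bias = spec$bias),
    file.path(dir, "bias.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
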