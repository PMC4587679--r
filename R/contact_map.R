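#' Contact map container
#'
#' A symmetric N x N matrix of interaction values on a \code{GenomeBinning},
#' with a per-bin exclusion mask and a normalization state tag. Masked bins
#' are treated as missing throughout the package — they are excluded from all
#' means and standard deviations, never counted as zeros.
#'
#' @param binning A \code{GenomeBinning}.
#' @param values Symmetric numeric matrix (defaults to all zeros).
#' @param mask Logical per-bin vector, TRUE = excluded.
#' @param state One of "raw", "ice", "expected".
#' @return A \code{ContactMap} object.
#' @export
contact_map <- function(binning, values = NULL, mask = NULL, state = "raw") {
  n <- binning$n_bins
  if (is.null(values)) values <- matrix(0, n, n)
  if (!is.matrix(values) || nrow(values) != n || ncol(values) != n)
    stop("values must be an ", n, "x", n, " matrix")
  if (is.null(mask)) mask <- rep(FALSE, n)
  sym_dev <- max(abs(values - t(values)), na.rm = TRUE)
  if (is.finite(sym_dev) && sym_dev > 1e-8 * (1 + max(abs(values), na.rm = TRUE)))
    stop("values must be symmetric")
  structure(list(binning = binning, values = values,
                 mask = as.logical(mask), state = state),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap [%s]: %d bins (%d masked), total %s\n",
              x$state, x$binning$n_bins, sum(x$mask),
              format(sum(x$values[upper.tri(x$values, diag = TRUE)],
                         na.rm = TRUE), big.mark = ",")))
  invisible(x)
}

# matrix with NA on masked rows/columns
masked_values <- function(map) {
  M <- map$values
  if (any(map$mask)) {
    M[map$mask, ] <- NA_real_
    M[, map$mask] <- NA_real_
  }
  M
}

#' Per-bin marginal sums (masked bins NA)
#' @param map A \code{ContactMap}.
#' @return Numeric vector of row sums over unmasked cells.
#' @export
marginals <- function(map) {
  m <- rowSums(masked_values(map), na.rm = TRUE)
  m[map$mask] <- NA_real_
  m
}

#' Read a valid-pairs file
#'
#' Four tab-separated columns (chromA, posA, chromB, posB), 1-based
#' positions; '#' comment lines ignored, a single header line is detected
#' and skipped.
#'
#' @param path File path.
#' @return Data frame with columns chromA, posA, chromB, posB.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("valid-pairs file needs 4 columns")
  df <- df[, 1:4]
  if (is.character(df[[2]]) && is.na(suppressWarnings(as.numeric(df[1, 2])))) {
    df <- df[-1, , drop = FALSE]  # header line
    df[[2]] <- as.numeric(df[[2]]); df[[4]] <- as.numeric(df[[4]])
  }
  names(df) <- c("chromA", "posA", "chromB", "posB")
  df
}

#' Bin valid pairs into a raw contact map
#'
#' Each pair increments the matrix symmetrically at (bin(A), bin(B)); pairs
#' with both ends in the same bin are counted once on the diagonal. Pairs
#' with a position outside the chromosome are rejected and counted.
#'
#' @param pairs Data frame from \code{\link{read_pairs}} (1-based positions).
#' @param binning A \code{GenomeBinning}; all pair chromosomes must exist in
#'   it.
#' @return A raw \code{ContactMap}; attribute \code{n_rejected} counts
#'   dropped pairs.
#' @export
bin_pairs <- function(pairs, binning) {
  unknown <- setdiff(unique(c(pairs$chromA, pairs$chromB)), binning$chroms)
  if (length(unknown))
    stop("chromosome(s) not in binning: ", paste(unknown, collapse = ", "))
  i <- bin_index(binning, pairs$chromA, pairs$posA - 1)
  j <- bin_index(binning, pairs$chromB, pairs$posB - 1)
  ok <- !is.na(i) & !is.na(j)
  n_rej <- sum(!ok)
  if (n_rej) message(n_rej, " pair(s) outside chromosome bounds rejected")
  i <- i[ok]; j <- j[ok]
  n <- binning$n_bins
  M <- matrix(0, n, n)
  if (length(i)) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    tab <- table(factor(lo + (hi - 1) * n))  # linear upper-triangle index
    lin <- as.integer(names(tab))
    M[lin] <- as.numeric(tab)
    M <- M + t(M)
    diag(M) <- diag(M) / 2
  }
  out <- contact_map(binning, M, state = "raw")
  attr(out, "n_rejected") <- n_rej
  out
}

#' Mask uncovered and low-coverage bins
#'
#' Bins with zero marginal are always masked (unmappable regions such as
#' centromeres produce empty rows); in addition the lowest \code{fraction}
#' of the nonzero-marginal bins are masked. Values are left untouched —
#' only the mask is updated.
#'
#' @param map A \code{ContactMap}.
#' @param fraction Proportion in [0, 1) of nonzero bins to mask.
#' @return The map with an updated mask.
#' @export
mask_low_coverage <- function(map, fraction = 0.02) {
  stopifnot(fraction >= 0, fraction < 1)
  m <- rowSums(map$values, na.rm = TRUE)
  mask <- map$mask | (m == 0)
  nz <- which(!mask)
  k <- floor(fraction * length(nz))
  if (k > 0) {
    ord <- nz[order(m[nz])]
    mask[ord[seq_len(k)]] <- TRUE
  }
  map$mask <- mask
  map
}

#' Write a contact map to text
#'
#' Dense format: TSV with bin labels "chrom:start-end" as row and column
#' headers, masked cells as NA. Triplet format: upper-triangle nonzero cells
#' as (binA, binB, value) with masked bins recorded in a '# masked:' header
#' comment.
#'
#' @param map A \code{ContactMap}.
#' @param path Output path.
#' @param format "dense" or "triplet".
#' @export
write_contact_map <- function(map, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  labs <- bin_labels(map$binning)
  M <- masked_values(map)
  if (format == "dense") {
    df <- as.data.frame(M)
    names(df) <- labs
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# state: %s", map$state), con)
    utils::write.table(cbind(bin = labs, df), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    ut <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
    df <- data.frame(binA = labs[ut[, 1]], binB = labs[ut[, 2]],
                     value = M[ut], stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# state: %s", map$state), con)
    if (any(map$mask))
      writeLines(paste0("# masked: ", paste(labs[map$mask], collapse = ",")), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a contact map written by \code{\link{write_contact_map}}
#'
#' @param path File path.
#' @param format "dense" or "triplet".
#' @param binning Optional \code{GenomeBinning} to validate against; when
#'   omitted it is reconstructed from the bin labels.
#' @return A \code{ContactMap}.
#' @export
read_contact_map <- function(path, format = c("dense", "triplet"),
                             binning = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  state <- sub("^# state: ", "", grep("^# state: ", lines, value = TRUE)[1])
  if (is.na(state)) state <- "raw"
  body <- lines[!grepl("^#", lines)]
  if (format == "dense") {
    df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    labs <- df[[1]]
    M <- as.matrix(df[, -1, drop = FALSE])
    dimnames(M) <- NULL
    if (!identical(labs, names(df)[-1]))
      stop("dense matrix row/column labels disagree")
    bins <- parse_bin_labels(labs)
    b <- binning_from_bins(bins)
    check_read_binning(b, binning, labs)
    mask <- apply(M, 1, function(r) all(is.na(r)))
    M[is.na(M)] <- NA_real_
    contact_map(b, M, mask = mask, state = state)
  } else {
    masked_line <- grep("^# masked: ", lines, value = TRUE)
    df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    labs <- sort(unique(c(df$binA, df$binB)))
    if (!is.null(binning)) {
      b <- binning
    } else {
      b <- binning_from_bins(parse_bin_labels(labs))
    }
    all_labs <- bin_labels(b)
    ia <- match(df$binA, all_labs); ib <- match(df$binB, all_labs)
    if (anyNA(ia) || anyNA(ib)) {
      off <- which(is.na(ia) | is.na(ib))[1]
      stop("record ", off, ": bin label not in binning (",
           df$binA[off], " / ", df$binB[off], ")")
    }
    n <- b$n_bins
    M <- matrix(0, n, n)
    M[cbind(ia, ib)] <- df$value
    M[cbind(ib, ia)] <- df$value
    mask <- rep(FALSE, n)
    if (length(masked_line)) {
      ml <- strsplit(sub("^# masked: ", "", masked_line[1]), ",")[[1]]
      mask[match(ml, all_labs)] <- TRUE
    }
    M[mask, ] <- NA_real_; M[, mask] <- NA_real_
    contact_map(b, M, mask = mask, state = state)
  }
}

check_read_binning <- function(found, expected, labs) {
  if (!is.null(expected) && !same_binning(found, expected)) {
    stop("matrix binning does not match the expected binning (first bin: ",
         labs[1], ")")
  }
  invisible(TRUE)
}

# per-chromosome cis block of a matrix, as index vector
cis_block <- function(binning, chrom) chrom_bins(binning, chrom)
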