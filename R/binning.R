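#' Fixed-width genome binning
#'
#' Tile a set of chromosomes with non-overlapping bins of fixed width. Bins
#' start at 0 and the final bin of each chromosome may be shorter than
#' \code{bin_size} so that the tiling ends exactly at the chromosome length.
#' The binning is the shared coordinate system for every contact matrix and
#' track in the package: global bin ordinals run 1..N in chromosome order.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp), a
#'   two-column data frame (name, length), or the path of a two-column TSV.
#' @param bin_size Bin width in bp (> 0).
#' @return An object of class \code{GenomeBinning}: chromosome names and
#'   lengths, bin size, a \code{bins} data frame (chrom, start, end, 0-based
#'   half-open), and per-chromosome offsets into the global bin index.
#' @examples
#' b <- make_binning(c(chr1 = 1e5), 4e4)
#' b$bins   # 3 bins: [0,40k) [40k,80k) [80k,100k)
#' @export
make_binning <- function(chrom_sizes, bin_size) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  if (is.data.frame(chrom_sizes)) {
    sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]),
                             as.character(chrom_sizes[[1]]))
  } else {
    sizes <- chrom_sizes
  }
  if (is.null(names(sizes)) || any(names(sizes) == ""))
    stop("chromosome sizes must be named")
  if (anyDuplicated(names(sizes)))
    stop("duplicate chromosome name")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("chromosome lengths must be positive")
  if (!is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be positive")

  chroms <- names(sizes)
  nb <- as.integer(ceiling(sizes / bin_size))
  bins <- do.call(rbind, lapply(seq_along(chroms), function(k) {
    starts <- (seq_len(nb[k]) - 1) * bin_size
    data.frame(chrom = chroms[k], start = starts,
               end = pmin(starts + bin_size, sizes[k]),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  structure(list(
    chroms = chroms,
    lengths = sizes,
    bin_size = bin_size,
    bins = bins,
    n_bins = sum(nb),
    chrom_nbins = stats::setNames(nb, chroms),
    chrom_offset = stats::setNames(cumsum(c(0L, nb[-length(nb)])), chroms)
  ), class = "GenomeBinning")
}

#' @export
print.GenomeBinning <- function(x, ...) {
  cat(sprintf("GenomeBinning: %d chromosomes, bin size %s bp, %d bins\n",
              length(x$chroms), format(x$bin_size, big.mark = ","), x$n_bins))
  invisible(x)
}

read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("chromosome sizes file needs two columns")
  df[, 1:2]
}

#' Global bin index of genomic positions
#'
#' @param binning A \code{GenomeBinning}.
#' @param chrom,pos Chromosome names and 0-based positions (vectors recycled
#'   to common length). Positions outside the chromosome give \code{NA}.
#' @return Integer vector of 1-based global bin indices.
#' @export
bin_index <- function(binning, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  known <- chrom %in% binning$chroms
  idx <- rep(NA_integer_, n)
  len <- binning$lengths[chrom[known]]
  p <- pos[known]
  ok <- p >= 0 & p < len
  off <- binning$chrom_offset[chrom[known]]
  val <- as.integer(off + p %/% binning$bin_size + 1L)
  val[!ok] <- NA_integer_
  idx[known] <- val
  idx
}

#' Global bin index range of one chromosome
#' @param binning A \code{GenomeBinning}.
#' @param chrom Chromosome name.
#' @return Integer vector of global bin indices belonging to \code{chrom}.
#' @export
chrom_bins <- function(binning, chrom) {
  if (!chrom %in% binning$chroms) stop("unknown chromosome: ", chrom)
  off <- binning$chrom_offset[[chrom]]
  seq.int(off + 1L, off + binning$chrom_nbins[[chrom]])
}

#' Bin labels in "chrom:start-end" form
#' @param binning A \code{GenomeBinning}.
#' @return Character vector, one label per global bin.
#' @export
bin_labels <- function(binning) {
  with(binning$bins, sprintf("%s:%d-%d", chrom, as.integer(start),
                             as.integer(end)))
}

parse_bin_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+):([0-9]+)-([0-9]+)$", labels))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed bin label: ", labels[which(bad)[1]])
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.numeric(vapply(m, `[`, "", 3L)),
             end = as.numeric(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

binning_from_bins <- function(bins) {
  chroms <- unique(bins$chrom)
  lengths <- vapply(chroms, function(c) max(bins$end[bins$chrom == c]), 0)
  bin_size <- max(bins$end - bins$start)
  make_binning(stats::setNames(lengths, chroms), bin_size)
}

same_binning <- function(a, b) {
  identical(a$chroms, b$chroms) &&
    isTRUE(all.equal(unname(a$lengths), unname(b$lengths))) &&
    a$bin_size == b$bin_size
}

# ---- genomic interval sets (plain data frames, BED conventions) ----

#' Validate / construct a genomic interval set
#'
#' Intervals are plain data frames with columns chrom, start, end and
#' optionally name and score, 0-based half-open as in BED.
#'
#' @param chrom,start,end,name,score Interval fields.
#' @return A sorted data frame of intervals.
#' @export
interval_set <- function(chrom, start, end, name = NULL, score = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- score
  validate_intervals(df)
  df[order(df$chrom, df$start), , drop = FALSE]
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval at record ", bad[1], ": start must satisfy 0 <= start < end")
  invisible(df)
}

#' Read a BED file (3 or 5 columns)
#' @param path File path. '#' comment and 'track' lines are skipped.
#' @return Interval data frame (chrom, start, end[, name, score]).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  validate_intervals(df)
  df
}

#' Write intervals as BED
#' @param df Interval data frame (chrom, start, end[, name, score]).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
  out <- df[, cols, drop = FALSE]
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-interval value track as bedGraph
#' @param df Data frame with chrom, start, end, value.
#' @param path Output path.
#' @export
write_bedgraph <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  out <- df[is.finite(df$value), c("chrom", "start", "end", "value")]
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
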