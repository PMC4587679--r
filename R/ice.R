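#' Iterative correction (ICE) matrix balancing
#'
#' Symmetric alternating-scaling balancing: per-bin factors b are estimated
#' so that corrected values values[i,j] / (b_i * b_j) have equal unmasked
#' marginals, absorbing coverage, visibility and copy-number differences
#' into the bias vector. The corrected matrix keeps the total sum of the
#' input, so per-cell values remain on the raw count scale; divide by the
#' total to obtain the relative (sum-normalized) form.
#'
#' Bins whose marginal is zero are masked before balancing (they cannot be
#' scaled) with a warning.
#'
#' @param map A raw \code{ContactMap}.
#' @param tol Convergence tolerance on the coefficient of variation of the
#'   unmasked marginals.
#' @param max_iter Maximum iterations; non-convergence raises a warning that
#'   reports the final CV.
#' @return List with \code{map} (state "ice"), \code{bias} (per-bin factors,
#'   NA on masked bins), \code{iterations} and final \code{cv}.
#' @export
ice_balance <- function(map, tol = 1e-5, max_iter = 200L) {
  if (!map$state %in% c("raw", "expected"))
    stop("ice_balance expects a raw map")
  mask <- map$mask
  M <- masked_values(map)
  m0 <- rowSums(M, na.rm = TRUE)
  dead <- !mask & m0 == 0
  if (any(dead)) {
    warning(sum(dead), " zero-marginal bin(s) masked before balancing")
    mask <- mask | dead
    M[dead, ] <- NA_real_; M[, dead] <- NA_real_
  }
  live <- which(!mask)
  if (length(live) < 2) stop("need at least 2 unmasked bins")
  total <- sum(M[upper.tri(M, diag = TRUE)], na.rm = TRUE)
  b <- rep(1, length(mask))
  cv <- Inf
  it <- 0L
  while (it < max_iter) {
    marg <- rowSums(M, na.rm = TRUE)[live]
    mu <- mean(marg)
    cv <- stats::sd(marg) / mu
    if (is.na(cv)) cv <- 0
    if (cv <= tol) break
    it <- it + 1L
    s <- marg / mu
    b[live] <- b[live] * s
    M[live, live] <- M[live, live] / outer(s, s)
  }
  if (cv > tol)
    warning(sprintf("ICE did not reach tol %.1e in %d iterations (CV %.3e)",
                    tol, max_iter, cv))
  # restore total mass, folding the scale into the bias vector
  cur <- sum(M[upper.tri(M, diag = TRUE)], na.rm = TRUE)
  r <- sqrt(cur / total)
  M <- M / r^2
  b[live] <- b[live] * r
  b[mask] <- NA_real_
  out <- map
  out$values <- M
  out$values[is.na(out$values)] <- NA_real_
  out$mask <- mask
  out$state <- "ice"
  list(map = out, bias = b, iterations = it, cv = cv)
}
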