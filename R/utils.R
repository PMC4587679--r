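# two-sided Wilcoxon rank-sum p; degenerate all-tied samples give p = 1
# (the normal approximation is 0/0 there, but no shift is detectable)
ranksum_p <- function(x, y) {
  if (!length(x) || !length(y)) return(NA_real_)
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided",
    exact = length(x) < 50 && length(y) < 50)$p.value)
}
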