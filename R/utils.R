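# Internal helpers shared across modules.

# Half the smallest positive value of `x` -- the scale-adaptive pseudocount
# used for log2 fold changes and activity ratios. Errors if nothing positive.
half_min_positive <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  if (length(pos) == 0L) {
    abort("cannot derive a pseudocount: no positive values present")
  }
  min(pos) / 2
}

# log2((m1 + eps) / (m2 + eps))
log2_fc <- function(m1, m2, eps) {
  log2((m1 + eps) / (m2 + eps))
}

# Assert that `x` is a single number inside (lo, hi] / [lo, hi] etc.
check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = TRUE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%g, %g%s, got %s",
                  name, if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]", paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

# Deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer whatever the master seed.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}

comparison_label <- function(g1, g2) paste0(g1, "_vs_", g2)

# Average-rank ties; returns the Kruskal-Wallis style tie-correction sum
# T = sum(t^3 - t) over tie groups.
tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}
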