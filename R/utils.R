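# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# One global seed drives a named stream per artifact so that, e.g., the
# expression draw does not shift when the count draw changes length.
stream_seed <- function(seed, stream) {
  offsets <- c(counts = 101L, expression = 202L, permutation = 303L,
               rarefy = 404L, contrast = 505L, indval = 606L, cca = 707L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 1009 + offsets[[stream]]) %% 2147483647)
}

softmax_log <- function(loga) {
  w <- exp(loga - max(loga))
  w / sum(w)
}

# Centered log-ratio with a small pseudo-proportion for zeros.
clr <- function(p, pseudo = 1e-6) {
  lp <- log(p + pseudo)
  sweep(lp, 1, rowMeans(lp), "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided Wilcoxon rank-sum with a guard for all-tied inputs (the normal
# approximation degenerates to 0/0 there; such data carry no evidence)
ranksum_test <- function(x, y) {
  if (stats::sd(c(x, y)) == 0)
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
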