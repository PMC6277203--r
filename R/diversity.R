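#' Remove features observed in fewer than two samples
#'
#' Drops "doubleton-filtered" features: any feature present (count > 0) in
#' fewer than 2 samples, including all-zero features.
#'
#' @param table a [feature_table()].
#' @return filtered [feature_table()]; dropped feature ids in attribute
#'   `"dropped_features"`.
#' @export
filter_doubletons <- function(table) {
  m <- ft_mat(table)
  prev <- colSums(m > 0)
  keep <- prev >= 2
  out <- feature_table(m[, keep, drop = FALSE], kind = ft_kind(table))
  attr(out, "dropped_features") <- colnames(m)[!keep]
  out
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads; samples with fewer total reads than `depth` are dropped and
#' reported. Deterministic given `seed`.
#'
#' @param table a [feature_table()] of counts.
#' @param depth target depth (reads per sample); default 6000.
#' @param seed RNG seed.
#' @return rarefied [feature_table()]; dropped sample ids in attribute
#'   `"dropped_samples"`.
#' @export
rarefy <- function(table, depth = 6000, seed = NULL) {
  stopifnot(depth >= 1)
  m <- ft_mat(table)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth")
  dropped <- rownames(m)[!keep]
  if (length(dropped))
    message("rarefy: dropped ", length(dropped), " sample(s) below depth ",
            depth)
  m <- m[keep, , drop = FALSE]
  out <- with_seed(seed, {
    r <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    for (i in seq_len(nrow(m))) {
      r[i, ] <- .subsample_counts(m[i, ], depth)
    }
    r
  })
  res <- feature_table(out, kind = ft_kind(table))
  attr(res, "dropped_samples") <- dropped
  res
}

# draw `depth` reads without replacement from a count vector
.subsample_counts <- function(x, depth) {
  reads <- rep.int(seq_along(x), x)
  tabulate(reads[sample.int(length(reads), depth)], nbins = length(x))
}

#' Per-sample richness and Shannon diversity
#'
#' Richness is the number of features with count > 0; Shannon diversity is
#' \eqn{H' = -\sum p_i \log_b p_i} over present features, with relative
#' abundances \eqn{p_i} and logarithm base `log_base` (default 2).
#'
#' @param table a [feature_table()].
#' @param log_base logarithm base for Shannon (2 or `exp(1)`).
#' @return data.frame with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table, log_base = 2) {
  m <- ft_mat(table)
  totals <- rowSums(m)
  if (any(totals == 0)) stop("sample(s) with zero total count")
  shannon <- vapply(seq_len(nrow(m)), function(i) {
    p <- m[i, ][m[i, ] > 0] / totals[i]
    -sum(p * log(p)) / log(log_base)
  }, numeric(1))
  data.frame(sample_id = rownames(m),
             richness = as.integer(rowSums(m > 0)),
             shannon = shannon,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rarefaction curves (mean richness per subsampling depth)
#'
#' @param table a [feature_table()] of counts.
#' @param depths increasing vector of depths.
#' @param reps subsample replicates per depth.
#' @param seed RNG seed.
#' @return data.frame `sample_id`, `depth`, `mean_richness` (NA where the
#'   sample total is below the depth).
#' @export
rarefaction_curve <- function(table, depths, reps = 10, seed = NULL) {
  if (is.unsorted(depths, strictly = TRUE)) stop("depths must be increasing")
  m <- ft_mat(table)
  totals <- rowSums(m)
  with_seed(seed, {
    out <- expand.grid(sample_id = rownames(m), depth = depths,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$mean_richness <- NA_real_
    for (i in seq_len(nrow(m))) {
      reads <- rep.int(seq_len(ncol(m)), m[i, ])
      for (d in depths) {
        if (totals[i] < d) next
        rich <- vapply(seq_len(reps), function(r) {
          sum(tabulate(reads[sample.int(length(reads), d)],
                       nbins = ncol(m)) > 0)
        }, numeric(1))
        out$mean_richness[out$sample_id == rownames(m)[i] & out$depth == d] <-
          mean(rich)
      }
    }
    out
  })
}

#' Mixed-effects model for a per-sample diversity response
#'
#' Fits a random-intercept linear mixed model by REML for a diversity
#' response (richness or Shannon) on fixed experimental factors, with family
#' as the default random intercept. Marginal F-tests are reported per fixed
#' effect. With `unit = "fish"` the response is first averaged over gut
#' parts within fish (one row per fish).
#'
#' @param values numeric response, one per metadata row (or a column name of
#'   the result of [alpha_diversity()] joined to `meta`).
#' @param meta a [sample_metadata()] aligned with `values`.
#' @param fixed character vector of fixed-effect factors.
#' @param random_intercept grouping factor for the random intercept.
#' @param unit `"sample"` (default) or `"fish"` (average parts within fish).
#' @return `lmm_result` list: `fixed` (term, F, num/den df, p, estimates),
#'   `varcomp` (random-intercept and residual variances), `logLik` (REML),
#'   `AIC`, `BIC`, `unit`, and the underlying `nlme::lme` fit.
#' @export
fit_diversity_lmm <- function(values, meta,
                              fixed = c("temperature", "tolerance"),
                              random_intercept = "family",
                              unit = c("sample", "fish")) {
  unit <- match.arg(unit)
  stopifnot(length(values) == nrow(meta))
  df <- data.frame(.y = values, as.data.frame(meta))
  if (unit == "fish") {
    agg <- stats::aggregate(df$.y, by = df[c("fish")], FUN = mean)
    names(agg) <- c("fish", ".y")
    key <- df[!duplicated(df$fish),
              c("fish", "tolerance", "temperature", "family")]
    df <- merge(key, agg, by = "fish")
  }
  for (f in c(fixed, random_intercept)) {
    if (!f %in% names(df)) stop("unknown factor: ", f)
    if (length(unique(df[[f]])) < 2)
      stop("factor ", f, " needs at least 2 levels")
  }
  fml <- stats::as.formula(paste(".y ~", paste(fixed, collapse = " + ")))
  rml <- stats::as.formula(paste("~ 1 |", random_intercept))
  fit <- nlme::lme(fixed = fml, random = rml, data = df, method = "REML")
  an <- stats::anova(fit, type = "marginal")
  an <- an[rownames(an) != "(Intercept)", , drop = FALSE]
  vc <- nlme::VarCorr(fit)
  varcomp <- c(as.numeric(vc["(Intercept)", "Variance"]),
               as.numeric(vc["Residual", "Variance"]))
  names(varcomp) <- c(random_intercept, "residual")
  res <- list(
    fixed = data.frame(term = rownames(an),
                       numDF = an$numDF, denDF = an$denDF,
                       F = an[["F-value"]], p = an[["p-value"]],
                       row.names = NULL, stringsAsFactors = FALSE),
    estimates = nlme::fixef(fit),
    varcomp = varcomp,
    logLik = as.numeric(stats::logLik(fit)),
    AIC = stats::AIC(fit), BIC = stats::BIC(fit),
    unit = unit, n = nrow(df),
    fit = fit)
  class(res) <- "lmm_result"
  res
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (REML), unit = %s, n = %d\n", x$unit, x$n))
  print(x$fixed, digits = 4)
  cat("variance components:", paste(sprintf("%s = %.4g", names(x$varcomp),
                                            x$varcomp), collapse = ", "), "\n")
  invisible(x)
}
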