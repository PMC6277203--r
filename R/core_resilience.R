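#' Identify the core microbiome by prevalence across individuals
#'
#' A feature belongs to the core when its prevalence among *individuals*
#' (fish, not samples: a fish counts as positive when the feature is present
#' in either gut part) strictly exceeds `prevalence_threshold` within the
#' warm arm or within the cold arm (`mode = "either"`, the default) or
#' within both arms (`mode = "both"`).
#'
#' @param table a [feature_table()].
#' @param meta a [sample_metadata()] covering the table's samples.
#' @param prevalence_threshold prevalence cutoff in (0, 1); default 0.5.
#' @param mode `"either"` or `"both"` temperature arm requirement.
#' @return character vector of core feature ids, with per-arm prevalences in
#'   attribute `"prevalence"`.
#' @export
find_core <- function(table, meta, prevalence_threshold = 0.5,
                      mode = c("either", "both")) {
  mode <- match.arg(mode)
  if (prevalence_threshold <= 0 || prevalence_threshold >= 1)
    stop("prevalence_threshold must be in (0, 1)")
  m <- ft_mat(table)
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  prev_arm <- function(temp) {
    sel <- meta$temperature == temp
    if (!any(sel)) stop("empty temperature arm: ", temp)
    pres <- rowsum((m[sel, , drop = FALSE] > 0) * 1, meta$fish[sel]) > 0
    colMeans(pres)
  }
  pw <- prev_arm("warm24")
  pc <- prev_arm("cold12")
  in_core <- if (mode == "either")
    pw > prevalence_threshold | pc > prevalence_threshold
  else
    pw > prevalence_threshold & pc > prevalence_threshold
  core <- colnames(m)[in_core]
  attr(core, "prevalence") <- data.frame(feature = colnames(m),
                                         warm24 = pw, cold12 = pc,
                                         row.names = NULL)
  core
}

#' Renormalize abundances within the core microbiome
#'
#' Restricts the table to the core features and rescales each sample's core
#' counts to percentages summing to 100. Samples with no core reads are
#' dropped and reported.
#'
#' @param table a [feature_table()].
#' @param core character vector of core feature ids.
#' @return `core_profile` list: `core`, `percent` (samples x core features,
#'   rows summing to 100), `dropped_samples`.
#' @export
renormalize_core <- function(table, core) {
  if (!length(core)) stop("core feature set is empty")
  m <- ft_mat(table)
  missing <- setdiff(core, colnames(m))
  if (length(missing)) stop("core features not in table: ",
                            paste(missing, collapse = ", "))
  cm <- m[, core, drop = FALSE]
  tot <- rowSums(cm)
  dropped <- rownames(cm)[tot == 0]
  if (length(dropped))
    message("renormalize_core: dropped ", length(dropped),
            " sample(s) with no core reads")
  cm <- cm[tot > 0, , drop = FALSE]
  pct <- sweep(cm, 1, rowSums(cm), "/") * 100
  structure(list(core = core, percent = pct, dropped_samples = dropped),
            class = "core_profile")
}

#' Warm-to-cold fold-change resilience of the core microbiome
#'
#' For each tolerance group, each core feature's fold change is the mean
#' renormalized abundance at cold divided by that at warm (group-level
#' means: warm and cold fish are different full-sib individuals, so no
#' pairing exists). A zero warm mean is replaced by half the smallest
#' nonzero renormalized value and flagged. The two groups' |log2 FC|
#' distributions are compared by a two-sided Wilcoxon rank-sum test.
#'
#' @param profile a `core_profile` from [renormalize_core()].
#' @param meta a [sample_metadata()].
#' @return `resilience_contrast` list: `fc` (feature x group fold changes),
#'   `log2fc`, `pseudo_flagged`, `wilcoxon` (statistic, p),
#'   `median_abs_log2fc` per group.
#' @export
resilience_contrast <- function(profile, meta) {
  stopifnot(inherits(profile, "core_profile"))
  pct <- profile$percent
  meta <- meta[match(rownames(pct), meta$sample_id), , drop = FALSE]
  groups <- c("resistant", "sensitive")
  pseudo <- min(pct[pct > 0]) / 2
  fc <- matrix(NA_real_, ncol(pct), length(groups),
               dimnames = list(colnames(pct), groups))
  flagged <- matrix(FALSE, ncol(pct), length(groups),
                    dimnames = dimnames(fc))
  for (g in groups) {
    for (temp in c("warm24", "cold12")) {
      sel <- meta$tolerance == g & meta$temperature == temp
      if (!any(sel)) stop("tolerance group ", g, " lacks arm ", temp)
    }
    mw <- colMeans(pct[meta$tolerance == g & meta$temperature == "warm24", ,
                       drop = FALSE])
    mc <- colMeans(pct[meta$tolerance == g & meta$temperature == "cold12", ,
                       drop = FALSE])
    flagged[, g] <- mw == 0
    mw[mw == 0] <- pseudo
    mc[mc == 0] <- pseudo
    fc[, g] <- mc / mw
  }
  l2 <- log2(fc)
  wt <- ranksum_test(abs(l2[, "resistant"]), abs(l2[, "sensitive"]))
  structure(list(fc = fc, log2fc = l2, pseudo_flagged = flagged,
                 wilcoxon = wt,
                 median_abs_log2fc = apply(abs(l2), 2, stats::median)),
            class = "resilience_contrast")
}

#' @export
print.resilience_contrast <- function(x, ...) {
  cat("core-microbiome resilience (warm -> cold fold change)\n")
  cat(sprintf("median |log2 FC|: resistant %.3f, sensitive %.3f\n",
              x$median_abs_log2fc["resistant"],
              x$median_abs_log2fc["sensitive"]))
  cat(sprintf("Wilcoxon rank-sum: W = %.1f, p = %.4g\n",
              x$wilcoxon$statistic, x$wilcoxon$p))
  invisible(x)
}
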