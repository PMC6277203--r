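#' Ordination scores for one omic data set
#'
#' Returns the top-`k` sample scores from either a principal component
#' analysis of the (column-centered) data or a principal coordinates
#' analysis of Bray-Curtis dissimilarities.
#'
#' `"pca_log"` applies the PCA to `log(x + offset)` with half the smallest
#' positive value as offset — the usual transform for non-negative
#' normalized expression, whose raw scale is dominated by a few
#' high-abundance transcripts.
#'
#' @param data a [feature_table()] or expression matrix (samples as rows).
#' @param method `"pca"`, `"pca_log"` or `"pcoa_braycurtis"`.
#' @param k number of components.
#' @return samples x k score matrix with attribute
#'   `"proportion_explained"`.
#' @export
component_scores <- function(data,
                             method = c("pca", "pca_log", "pcoa_braycurtis"),
                             k = 4) {
  method <- match.arg(method)
  m <- ft_mat(data)
  if (method == "pca_log") {
    if (any(m < 0)) stop("pca_log requires non-negative values")
    m <- log(m + min(m[m > 0]) / 2)
    method <- "pca"
  }
  if (method == "pca") {
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    npos <- sum(pc$sdev > pc$sdev[1] * 1e-9)
    if (k > npos) stop(sprintf("k = %d exceeds %d non-null components", k,
                               npos))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  } else {
    ord <- pcoa(bray_curtis(m), k = k)
    scores <- ord$coordinates
    expl <- ord$proportion_explained[seq_len(k)]
  }
  rownames(scores) <- rownames(m)
  attr(scores, "proportion_explained") <- expl
  scores
}

#' Canonical correlations and the redundancy (variance explained) statistic
#'
#' Computes the canonical correlations between two score matrices through an
#' orthonormalized cross-product SVD, and the redundancy index of `A` given
#' `B` (Stewart-Love): the fraction of `A`'s total variance carried by each
#' of `A`'s canonical variates, weighted by the squared canonical
#' correlation, summed over variates. With `B = A` the statistic is exactly
#' 1; with a single column per side it reduces to the squared Pearson
#' correlation.
#'
#' @param A,B sample-aligned score matrices (n x p, n x q).
#' @return list: `rho` (canonical correlations, non-increasing),
#'   `variance_explained` (redundancy of A given B), `k` (variates used).
#' @export
cca_redundancy <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must have the same sample rows")
  n <- nrow(A)
  if (n <= max(ncol(A), ncol(B)))
    stop("need more samples than components per side")
  Ac <- scale(A, center = TRUE, scale = FALSE)
  Bc <- scale(B, center = TRUE, scale = FALSE)
  qa <- qr(Ac); qb <- qr(Bc)
  ra <- qa$rank; rb <- qb$rank
  k <- min(ra, rb)
  if (k < min(ncol(A), ncol(B)))
    warning(sprintf("rank deficiency: using %d canonical variate(s)", k))
  Qa <- qr.Q(qa)[, seq_len(ra), drop = FALSE]
  Qb <- qr.Q(qb)[, seq_len(rb), drop = FALSE]
  sv <- svd(crossprod(Qa, Qb))
  rho <- pmin(1, sv$d[seq_len(k)])
  # canonical variates of A, orthonormal columns
  Ua <- Qa %*% sv$u[, seq_len(k), drop = FALSE]
  # variance of A captured by each variate: projection SS over total SS
  proj <- crossprod(Ua, Ac)                 # k x p
  frac <- rowSums(proj^2) / sum(Ac^2)
  list(rho = rho, variance_explained = sum(rho^2 * frac), k = k)
}

#' Permutation test of microbiome-transcriptome linkage via CCA redundancy
#'
#' The observed statistic is the redundancy of `A` given `B` on aligned
#' rows; the null distribution shuffles the row order of `B` only
#' (destroying the sample correspondence while preserving each side's
#' internal structure). `p = (1 + #[stat* >= stat]) / (1 + n_perm)`.
#'
#' @param A,B sample-aligned score matrices.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return `cca_result` list: `rho`, `variance_explained`,
#'   `permuted_values`, `p`, `n_perm`, `k`.
#' @export
cca_permutation_test <- function(A, B, n_perm = 1000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (nrow(as.matrix(A)) < 8) stop("need at least 8 samples")
  obs <- cca_redundancy(A, B)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      suppressWarnings(
        cca_redundancy(A, B[sample.int(nrow(B)), , drop = FALSE]))$variance_explained
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs$variance_explained)) / (1 + n_perm)
  structure(list(rho = obs$rho, variance_explained = obs$variance_explained,
                 permuted_values = perm, p = p, n_perm = n_perm, k = obs$k),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf(
    "CCA redundancy test: variance explained = %.4f (permuted mean %.4f)\n",
    x$variance_explained, mean(x$permuted_values)))
  cat(sprintf("canonical correlations: %s\n",
              paste(sprintf("%.3f", x$rho), collapse = ", ")))
  cat(sprintf("p = %.4g (%d permutations)\n", x$p, x$n_perm))
  invisible(x)
}

#' Warm-to-cold expression fold-change contrast between tolerance groups
#'
#' Per gene and tolerance group, the fold change is the mean expression at
#' cold over the mean at warm (zero denominators replaced by half the
#' smallest nonzero group mean and flagged); the two groups' |log2 FC|
#' distributions are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param expr samples x genes expression matrix.
#' @param meta a [sample_metadata()] covering the expression samples.
#' @return `fold_change_contrast` list: `fc`, `log2fc` (gene x group),
#'   `wilcoxon`, `median_abs_log2fc`, `pseudo_flagged`.
#' @export
expression_fold_change <- function(expr, meta) {
  m <- ft_mat(expr)
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  groups <- c("resistant", "sensitive")
  fc <- matrix(NA_real_, ncol(m), length(groups),
               dimnames = list(colnames(m), groups))
  flagged <- matrix(FALSE, ncol(m), length(groups), dimnames = dimnames(fc))
  for (g in groups) {
    for (temp in c("warm24", "cold12"))
      if (!any(meta$tolerance == g & meta$temperature == temp))
        stop("tolerance group ", g, " lacks arm ", temp)
    mw <- colMeans(m[meta$tolerance == g & meta$temperature == "warm24", ,
                     drop = FALSE])
    mc <- colMeans(m[meta$tolerance == g & meta$temperature == "cold12", ,
                     drop = FALSE])
    pseudo <- min(c(mw[mw > 0], mc[mc > 0])) / 2
    flagged[, g] <- mw == 0 | mc == 0
    mw[mw == 0] <- pseudo
    mc[mc == 0] <- pseudo
    fc[, g] <- mc / mw
  }
  l2 <- log2(fc)
  wt <- ranksum_test(abs(l2[, "resistant"]), abs(l2[, "sensitive"]))
  structure(list(fc = fc, log2fc = l2, pseudo_flagged = flagged,
                 wilcoxon = wt,
                 median_abs_log2fc = apply(abs(l2), 2, stats::median)),
            class = "fold_change_contrast")
}
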