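#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)} on (optionally
#' rarefied) counts.
#'
#' @param table a [feature_table()] or abundance matrix (samples as rows).
#' @return labeled symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  m <- ft_mat(table)
  if (any(rowSums(m) == 0)) stop("zero-total sample(s)")
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Jaccard presence/absence dissimilarity
#'
#' Binarizes at value > `detect_threshold`, then
#' \eqn{d = 1 - |A \cap B| / |A \cup B|}; two empty presence sets get
#' distance 0.
#'
#' @param mat expression matrix or [feature_table()].
#' @param detect_threshold presence cutoff (strict `>`); default 0.
#' @return labeled symmetric dissimilarity matrix.
#' @export
jaccard_presence <- function(mat, detect_threshold = 0) {
  a <- (ft_mat(mat) > detect_threshold) * 1
  inter <- tcrossprod(a)
  rs <- rowSums(a)
  uni <- outer(rs, rs, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0  # both sets empty
  diag(d) <- 0
  dimnames(d) <- list(rownames(a), rownames(a))
  d
}

#' Principal coordinates analysis (classical MDS on a dissimilarity matrix)
#'
#' Gower-centers \eqn{-\frac12 D^2}, eigendecomposes, and returns coordinates
#' \eqn{v_j \sqrt{\lambda_j}} for the top `k` positive eigenvalues. Negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are dropped and reported.
#'
#' @param dm labeled symmetric dissimilarity matrix.
#' @param k number of axes to return.
#' @return `ordination` list: `coordinates` (samples x k), `eigenvalues`
#'   (positive, decreasing), `proportion_explained` (relative to the sum of
#'   positive eigenvalues), `negative_eigenvalues`.
#' @export
pcoa <- function(dm, k = 2) {
  stopifnot(k >= 1)
  G <- gower_center(dm)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  if (sum(pos) < k)
    stop(sprintf("only %d positive eigenvalue(s); k = %d requested",
                 sum(pos), k))
  lam <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), length(lam))
  dimnames(coords) <- list(rownames(as.matrix(dm)),
                           sprintf("Axis%d", seq_along(lam)))
  structure(list(coordinates = coords[, seq_len(k), drop = FALSE],
                 eigenvalues = lam,
                 proportion_explained = lam / sum(lam),
                 negative_eigenvalues = e$values[e$values < -tol]),
            class = "ordination")
}

#' Declare a set of pairwise distances by stratum and mode
#'
#' A pair-selector names a stratum (metadata filter as named list of
#' column = allowed values), a factor, and a mode: `"within"` keeps pairs of
#' samples sharing `level` of `factor` (or sharing any level when `level` is
#' NULL); `"between"` keeps pairs whose levels of `factor` differ.
#'
#' @param factor metadata column defining the pairing.
#' @param mode `"within"` or `"between"`.
#' @param level for `mode = "within"`: the level both pair members share.
#' @param stratum named list restricting samples before pairing.
#' @return a `pair_selector`.
#' @export
pair_selector <- function(factor, mode = c("within", "between"), level = NULL,
                          stratum = list()) {
  mode <- match.arg(mode)
  structure(list(factor = factor, mode = mode, level = level,
                 stratum = stratum), class = "pair_selector")
}

#' Extract the distances named by a pair-selector
#' @param dm labeled distance matrix.
#' @param meta a [sample_metadata()].
#' @param sel a [pair_selector()].
#' @return numeric vector of distances (one per unordered sample pair).
#' @export
select_distances <- function(dm, meta, sel) {
  stopifnot(inherits(sel, "pair_selector"))
  d <- as.matrix(dm)
  meta <- meta[match(rownames(d), meta$sample_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(meta))
  for (col in names(sel$stratum))
    keep <- keep & meta[[col]] %in% sel$stratum[[col]]
  idx <- which(keep)
  if (length(idx) < 2) stop("selector stratum keeps fewer than 2 samples")
  f <- as.character(meta[[sel$factor]][idx])
  d <- d[idx, idx, drop = FALSE]
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  same <- f[pairs[, 1]] == f[pairs[, 2]]
  sel_pairs <- if (sel$mode == "within") {
    if (is.null(sel$level)) same
    else same & f[pairs[, 1]] == sel$level
  } else !same
  out <- d[pairs[sel_pairs, , drop = FALSE]]
  if (length(out) < 2) stop("selector yields fewer than 2 distances")
  out
}

#' Monte-Carlo contrast between two groups of pairwise distances
#'
#' Two-sample t statistic on the distances selected by `selA` vs `selB`;
#' significance by pooled relabeling of the distance values
#' (`p = (1 + #[|t*| >= |t|]) / (1 + n_perm)`), with optional Bonferroni
#' correction across a declared number of comparisons. Distance pairs are
#' treated as exchangeable units, mirroring the classical Monte-Carlo
#' distance t-test of amplicon pipelines; the non-independence of pairs
#' sharing a sample is a property of that procedure, not corrected here.
#'
#' @param dm labeled distance matrix.
#' @param meta a [sample_metadata()].
#' @param selA,selB [pair_selector()]s.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param n_comparisons Bonferroni divisor (default 1).
#' @return `distance_contrast` list: the two distance sets, `t`, `p`,
#'   `p_corrected`, `n_perm`.
#' @export
distance_contrast <- function(dm, meta, selA, selB, n_perm = 1000,
                              seed = NULL, n_comparisons = 1) {
  a <- select_distances(dm, meta, selA)
  b <- select_distances(dm, meta, selB)
  tstat <- function(x, y) {
    sp <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    md <- mean(x) - mean(y)
    if (sp == 0) return(if (md == 0) 0 else sign(md) * Inf)
    md / sqrt(sp * (1 / length(x) + 1 / length(y)))
  }
  t0 <- tstat(a, b)
  pooled <- c(a, b)
  na <- length(a)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(length(pooled))
      abs(tstat(pooled[p[seq_len(na)]], pooled[p[-seq_len(na)]])) >= abs(t0)
    }, logical(1)))
  })
  p <- (1 + exceed) / (1 + n_perm)
  structure(list(distances_A = a, distances_B = b, t = t0, p = p,
                 p_corrected = min(1, p * n_comparisons), n_perm = n_perm),
            class = "distance_contrast")
}

#' @export
print.distance_contrast <- function(x, ...) {
  cat(sprintf(
    "distance contrast: nA = %d (mean %.4f), nB = %d (mean %.4f)\n",
    length(x$distances_A), mean(x$distances_A),
    length(x$distances_B), mean(x$distances_B)))
  cat(sprintf("t = %.4f, Monte-Carlo p = %.4g (corrected %.4g, %d perms)\n",
              x$t, x$p, x$p_corrected, x$n_perm))
  invisible(x)
}
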