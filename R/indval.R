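#' Dufrene-Legendre indicator-value analysis
#'
#' For feature i and group j, specificity is the share of i's mean abundance
#' found in group j (\eqn{A_{ij} = \bar{x}_{ij} / \sum_k \bar{x}_{ik}}),
#' fidelity is the within-group prevalence
#' (\eqn{B_{ij} = } fraction of group-j samples where i is present), and
#' \eqn{IndVal_{ij} = A_{ij} B_{ij} \times 100}. The test statistic per
#' feature is \eqn{\max_j IndVal_{ij}}, with a permutation p-value from
#' shuffling group labels: `p = (1 + #[stat* >= stat]) / (1 + n_perm)`.
#' Features absent from every sample get IndVal 0 and p 1.
#'
#' @param mat a [feature_table()] or expression matrix (samples as rows).
#' @param groups per-sample group labels (length `nrow(mat)`), or a metadata
#'   column name when `meta` is supplied.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param meta optional [sample_metadata()] to resolve `groups` by name.
#' @param detect_threshold presence cutoff (strict `>`), default 0.
#' @return `indval_result`: `records` data.frame (feature, best_group,
#'   indval, p) plus `specificity`, `fidelity`, `indval` matrices
#'   (features x groups).
#' @export
indval <- function(mat, groups, n_perm = 1000, seed = NULL, meta = NULL,
                   detect_threshold = 0) {
  m <- ft_mat(mat)
  if (!is.null(meta) && is.character(groups) && length(groups) == 1) {
    meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
    groups <- meta[[groups]]
  }
  g <- as.character(groups)
  if (length(g) != nrow(m)) stop("group labels do not match sample rows")
  glev <- sort(unique(g))
  if (length(glev) < 2) stop("need at least 2 groups")
  sizes <- table(factor(g, glev))
  if (any(sizes == 0)) stop("group with 0 samples")

  iv_stat <- function(labels) {
    f <- factor(labels, glev)
    mean_ab <- rowsum(m, f) / as.vector(table(f))        # groups x features
    prev <- rowsum((m > detect_threshold) * 1, f) / as.vector(table(f))
    tot <- colSums(mean_ab)
    spec <- sweep(mean_ab, 2, ifelse(tot > 0, tot, 1), "/")
    spec[, tot == 0] <- 0
    list(spec = spec, fid = prev, iv = spec * prev * 100)
  }
  obs <- iv_stat(g)
  stat <- apply(obs$iv, 2, max)
  best <- glev[apply(obs$iv, 2, which.max)]
  absent <- colSums(m > detect_threshold) == 0
  best[absent] <- NA

  exceed <- with_seed(seed, {
    ex <- numeric(ncol(m))
    for (i in seq_len(n_perm)) {
      ivp <- iv_stat(g[sample.int(length(g))])$iv
      ex <- ex + (apply(ivp, 2, max) >= stat)
    }
    ex
  })
  p <- (1 + exceed) / (1 + n_perm)
  p[absent] <- 1

  records <- data.frame(feature = colnames(m), best_group = best,
                        indval = stat, p = p,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(records = records,
                 specificity = t(obs$spec), fidelity = t(obs$fid),
                 indval = t(obs$iv), n_perm = n_perm),
            class = "indval_result")
}

#' Filter indicator records by significance and effect size
#'
#' Keeps features with raw permutation `p <= alpha` and `indval >=
#' min_indval`; a Holm-adjusted p-value over all input features is attached
#' (`p_holm`). Raw p remains the primary criterion, the adjustment is
#' reported for reference.
#'
#' @param result an `indval_result` (or its `records` data.frame).
#' @param alpha significance cutoff in (0, 1].
#' @param min_indval minimum indicator value (0-100 scale).
#' @return filtered records data.frame with `p_holm` column.
#' @export
filter_indicators <- function(result, alpha = 0.05, min_indval = 0) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  rec <- if (inherits(result, "indval_result")) result$records else result
  if (!nrow(rec)) return(cbind(rec, p_holm = numeric(0)))
  rec$p_holm <- stats::p.adjust(rec$p, method = "holm")
  rec[rec$p <= alpha & rec$indval >= min_indval, , drop = FALSE]
}

#' @export
print.indval_result <- function(x, ...) {
  cat(sprintf("IndVal analysis: %d features, %d groups, %d permutations\n",
              nrow(x$records), ncol(x$indval), x$n_perm))
  top <- x$records[order(-x$records$indval), ]
  print(utils::head(top, 10), digits = 4, row.names = FALSE)
  invisible(x)
}
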