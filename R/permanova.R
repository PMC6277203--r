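#' Gower-center a dissimilarity matrix
#'
#' Computes \eqn{G = C (-\frac12 D \circ D) C} with the centering matrix
#' \eqn{C = I - \mathbf{1}\mathbf{1}^T/n}. The trace of \eqn{G} is the total
#' sum of squares of the multivariate dispersion, the quantity a
#' permutational multivariate ANOVA partitions.
#'
#' @param dm labeled symmetric dissimilarity matrix (or `dist`).
#' @return centered matrix `G` with the same dimnames.
#' @export
gower_center <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples")
  a <- -0.5 * d * d
  rm_ <- rowMeans(a)
  G <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), colMeans(a)) + mean(a)
  dimnames(G) <- dimnames(d)
  G
}

.parse_terms <- function(formula) {
  if (inherits(formula, "formula")) {
    attr(stats::terms(formula), "term.labels")
  } else {
    f <- stats::as.formula(paste("~", paste(formula, collapse = "+")))
    attr(stats::terms(f), "term.labels")
  }
}

#' Permutational multivariate ANOVA on a dissimilarity matrix (Adonis-style)
#'
#' Sequential (Type I) decomposition of the total sum of squares of a
#' dissimilarity matrix among model terms. For cumulative treatment-coded
#' design matrices \eqn{X_0 \subset X_1 \subset \dots \subset X_m} with hat
#' matrices \eqn{H_k}, each term's sum of squares is
#' \eqn{SS_k = tr((H_k - H_{k-1}) G)} on the Gower-centered matrix \eqn{G},
#' with \eqn{SS_{res} = tr((I - H_m) G)}; pseudo-F is
#' \eqn{(SS_k/df_k)/(SS_{res}/df_{res})} and p-values come from joint
#' row/column permutation of the dissimilarity matrix
#' (`p = (1 + #[F* >= F]) / (1 + n_perm)`, ties counted as exceeding).
#'
#' @param dm labeled dissimilarity matrix.
#' @param meta a [sample_metadata()] (or data.frame) holding the factors.
#' @param formula model formula (e.g. `~ tolerance + temperature +
#'   tolerance:temperature`) or character vector of term labels; terms enter
#'   in the order given.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param family_numeric if TRUE, recode `family` as a single numeric
#'   covariate (df = 1) instead of a factor with natural df.
#' @return a `permanova_table` data.frame: per-term `Df`, `SS`, `MS`,
#'   `PseudoF`, `R2`, `p`, plus `Residuals` and `Total` rows.
#' @export
adonis_dm <- function(dm, meta, formula, n_perm = 999, seed = NULL,
                      family_numeric = FALSE) {
  d <- as.matrix(dm)
  meta <- as.data.frame(meta)
  meta <- meta[match(rownames(d), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing for some dm samples")
  term_labels <- .parse_terms(formula)
  if (anyDuplicated(term_labels)) stop("duplicate model terms")
  vars <- unique(unlist(strsplit(term_labels, ":", fixed = TRUE)))
  for (v in vars) {
    if (!v %in% names(meta)) stop("factor not in metadata: ", v)
    if (length(unique(meta[[v]])) < 2)
      stop("factor ", v, " has a single level among the dm samples")
  }
  mf <- meta[vars]
  mf[] <- lapply(mf, function(x) if (is.character(x)) factor(x) else x)
  if (family_numeric && "family" %in% names(mf))
    mf$family <- as.numeric(factor(mf$family))

  n <- nrow(d)
  G <- gower_center(d)
  SS_total <- sum(diag(G))

  # cumulative hat matrices (treatment coding; interactions are products of
  # main-effect columns via model.matrix)
  m <- length(term_labels)
  H <- vector("list", m + 1)
  H[[1]] <- matrix(1 / n, n, n)  # intercept-only
  ranks <- numeric(m + 1); ranks[1] <- 1
  for (k in seq_len(m)) {
    fk <- stats::as.formula(paste("~", paste(term_labels[seq_len(k)],
                                             collapse = "+")))
    X <- stats::model.matrix(fk, data = mf)
    qrx <- qr(X)
    ranks[k + 1] <- qrx$rank
    Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
    H[[k + 1]] <- tcrossprod(Q)
  }
  df_terms <- diff(ranks)
  if (any(df_terms == 0))
    stop("rank-deficient cumulative design at term(s): ",
         paste(term_labels[df_terms == 0], collapse = ", "))
  Dk <- lapply(seq_len(m), function(k) H[[k + 1]] - H[[k]])
  R <- diag(n) - H[[m + 1]]
  df_res <- n - ranks[m + 1]
  if (df_res <= 0) stop("no residual degrees of freedom")

  SS <- vapply(Dk, function(D) sum(D * G), numeric(1))
  SS_res <- sum(R * G)
  if (SS_res <= 0) stop("non-positive residual sum of squares")
  MS <- SS / df_terms
  MS_res <- SS_res / df_res
  Fobs <- MS / MS_res

  exceed <- numeric(m)
  if (n_perm > 0) {
    exceed <- with_seed(seed, {
      ex <- numeric(m)
      for (i in seq_len(n_perm)) {
        p <- sample.int(n)
        Gp <- G[p, p]
        ssr <- sum(R * Gp)
        Fp <- vapply(seq_len(m), function(k)
          (sum(Dk[[k]] * Gp) / df_terms[k]) / (ssr / df_res), numeric(1))
        ex <- ex + (Fp >= Fobs)
      }
      ex
    })
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  tab <- data.frame(
    term = c(term_labels, "Residuals", "Total"),
    Df = c(df_terms, df_res, n - 1),
    SS = c(SS, SS_res, SS_total),
    MS = c(MS, MS_res, NA),
    PseudoF = c(Fobs, NA, NA),
    R2 = c(SS, SS_res, SS_total) / SS_total,
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  attr(tab, "n_perm") <- n_perm
  class(tab) <- c("permanova_table", "data.frame")
  tab
}

#' Assemble the derived columns of one PERMANOVA row
#'
#' From a term's sum of squares and degrees of freedom plus the residual sum
#' of squares/df and the total sum of squares, computes the mean square,
#' pseudo-F and R-squared exactly as they appear in an Adonis table.
#'
#' @param SS_term,df_term term sum of squares and df.
#' @param SS_res,df_res residual sum of squares and df.
#' @param SS_total total sum of squares.
#' @return named list `MS`, `pseudoF`, `R2`.
#' @export
assemble_permanova_row <- function(SS_term, df_term, SS_res, df_res,
                                   SS_total) {
  if (df_term <= 0 || df_res <= 0) stop("degrees of freedom must be positive")
  if (SS_total <= 0) stop("SS_total must be positive")
  MS <- SS_term / df_term
  list(MS = MS,
       pseudoF = MS / (SS_res / df_res),
       R2 = SS_term / SS_total)
}

#' @export
print.permanova_table <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations)\n",
              attr(x, "n_perm") %||% NA))
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}
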