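test_that("doubleton filtering keeps features present in >= 2 samples", {
  m <- matrix(0, 4, 3, dimnames = list(paste0("s", 1:4), c("once", "twice",
                                                           "never")))
  m["s1", "once"] <- 5
  m[c("s1", "s3"), "twice"] <- 1
  out <- filter_doubletons(feature_table(m))
  expect_equal(colnames(out), "twice")
  expect_equal(attr(out, "dropped_features"), c("once", "never"))
})

test_that("rarefaction conserves depth, never inflates counts, drops shallow samples", {
  meta <- tiny_meta()
  tab <- tiny_table(meta, n_feat = 12, lambda = 40)
  m <- unclass(tab)[, ]
  m[1, ] <- c(rep(1, 5), rep(0, 7))  # total 5, below depth
  tab <- feature_table(m)
  expect_message(r <- rarefy(tab, depth = 100, seed = 42), "dropped 1")
  rm_ <- unclass(r)[, ]
  expect_true(all(rowSums(rm_) == 100))
  expect_true(all(rm_ <= m[rownames(rm_), ]))
  expect_equal(attr(r, "dropped_samples"), rownames(m)[1])
  r2 <- rarefy(tab, depth = 100, seed = 42)
  expect_identical(rm_, suppressMessages(unclass(r2)[, ]))
  expect_error(rarefy(feature_table(m[1, , drop = FALSE]), depth = 100),
               "below the rarefaction depth")
})

test_that("Shannon and richness match direct evaluation of the formula", {
  m <- rbind(uniform = c(5, 5, 5, 5), single = c(10, 0, 0, 0),
             skew = c(3, 1, 0, 0))
  colnames(m) <- paste0("f", 1:4)
  a <- alpha_diversity(feature_table(m), log_base = 2)
  expect_equal(a$shannon[a$sample_id == "uniform"], 2)
  expect_equal(a$shannon[a$sample_id == "single"], 0)
  expect_equal(a$richness[a$sample_id == "single"], 1L)
  expect_equal(a$shannon[a$sample_id == "skew"], 0.811278, tolerance = 1e-6)
  # natural-log base
  ae <- alpha_diversity(feature_table(m), log_base = exp(1))
  expect_equal(ae$shannon[1], log(4))
  expect_error(alpha_diversity(feature_table(
    rbind(z = c(0, 0, 0, 0), m))), "zero total")
})

test_that("Shannon is order-invariant and maximal at uniform composition", {
  set.seed(8)
  x <- rmultinom(1, 500, runif(10))[, 1]
  m1 <- matrix(x, 1, dimnames = list("s", paste0("f", 1:10)))
  perm <- sample(10)
  m2 <- m1[, perm, drop = FALSE]
  expect_equal(alpha_diversity(feature_table(m1))$shannon,
               alpha_diversity(feature_table(m2))$shannon)
  expect_lte(alpha_diversity(feature_table(m1))$shannon,
             log2(sum(x > 0)))
})

test_that("rarefaction curves hit observed richness at full depth and rise monotonically", {
  meta <- tiny_meta()
  tab <- tiny_table(meta, n_feat = 15, lambda = 10)
  m <- unclass(tab)[, ]
  tot <- rowSums(m)[1]
  rc <- rarefaction_curve(feature_table(m[1, , drop = FALSE]),
                          depths = c(1, floor(tot / 2), tot), reps = 30,
                          seed = 1)
  expect_equal(rc$mean_richness[rc$depth == 1], 1)
  expect_equal(rc$mean_richness[rc$depth == tot], sum(m[1, ] > 0))
  expect_true(!is.unsorted(rc$mean_richness))
  expect_error(rarefaction_curve(tab, depths = c(10, 5)), "increasing")
})

test_that("LMM reduces to two-way ANOVA when the family variance is zero", {
  meta <- tiny_meta(per_cell = 9)
  set.seed(21)
  y <- 2 * (meta$temperature == "cold12") + rnorm(nrow(meta))
  fit <- fit_diversity_lmm(y, meta)
  ref <- anova(lm(y ~ temperature + tolerance, data = meta))
  fF <- fit$fixed$F[fit$fixed$term == "temperature"]
  expect_equal(fF, ref["temperature", "F value"], tolerance = 0.05)
  expect_lt(fit$varcomp[["family"]], 0.2)
})

test_that("LMM recovers planted variance components and detects a strong effect", {
  rel_err <- function(est, true) abs(est - true) / true
  n_seeds <- 40
  errs <- matrix(NA_real_, n_seeds, 2)
  pvals <- numeric(n_seeds)
  meta <- tiny_meta(per_cell = 21, parts = 2)  # 6 families x 28 obs
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    # plant effects with realized variance exactly 1 so the check isolates
    # estimator error from the 6-draw sampling of the effects themselves
    fam_eff <- rnorm(nlevels(meta$family))
    fam_eff <- (fam_eff - mean(fam_eff)) / sd(fam_eff)
    y <- 2 * (meta$temperature == "cold12") +
      fam_eff[as.integer(meta$family)] + rnorm(nrow(meta), 0, 1)
    fit <- fit_diversity_lmm(y, meta)
    errs[s, ] <- c(rel_err(fit$varcomp[["family"]], 1),
                   rel_err(fit$varcomp[["residual"]], 1))
    pvals[s] <- fit$fixed$p[fit$fixed$term == "temperature"]
  }
  expect_lt(median(errs[, 1]), 0.5)
  expect_lt(median(errs[, 2]), 0.5)
  expect_gte(mean(pvals < 0.01), 0.95)
})

test_that("LMM unit = fish averages the two gut parts", {
  meta <- tiny_meta(per_cell = 6, parts = 2)
  set.seed(2)
  y <- rnorm(nrow(meta))
  fit <- fit_diversity_lmm(y, meta, unit = "fish")
  expect_equal(fit$n, length(unique(meta$fish)))
  expect_error(fit_diversity_lmm(y, meta, fixed = "nope"), "unknown factor")
})
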