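test_that("Gower centering yields the total sum of squares as its trace", {
  pts <- c(0, 1, 10, 11)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  G <- gower_center(d)
  expect_equal(sum(diag(G)), sum((pts - mean(pts))^2))  # = 101
  expect_equal(gower_center(matrix(0, 3, 3)), matrix(0, 3, 3),
               ignore_attr = TRUE)
  p <- c(3, 1, 4, 2)
  expect_equal(sum(diag(gower_center(d[p, p]))), sum(diag(G)))
  expect_error(gower_center(matrix(0, 1, 1)), "at least 2")
})

test_that("adonis on grouped 1-D points reproduces univariate ANOVA exactly", {
  d <- as.matrix(dist(c(0, 1, 10, 11)))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  meta <- data.frame(sample_id = letters[1:4], grp = c("a", "a", "b", "b"))
  tab <- adonis_dm(d, meta, ~ grp, n_perm = 0)
  expect_equal(tab$SS[tab$term == "grp"], 100)
  expect_equal(tab$SS[tab$term == "Residuals"], 1)
  expect_equal(tab$PseudoF[tab$term == "grp"], 200)
  expect_equal(tab$Df, c(1, 2, 3))
})

test_that("adonis SS on Euclidean distances equals coordinate-space sequential ANOVA", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(8:12, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n)
    mf <- data.frame(f1 = factor(sample(c("u", "v"), n, replace = TRUE)),
                     f2 = factor(sample(c("p", "q", "r"), n,
                                        replace = TRUE)))
    while (length(unique(mf$f1)) < 2 || length(unique(mf$f2)) < 2) {
      mf$f1 <- factor(sample(c("u", "v"), n, replace = TRUE))
      mf$f2 <- factor(sample(c("p", "q", "r"), n, replace = TRUE))
    }
    md <- cbind(sample_id = paste0("s", seq_len(n)), mf)
    dm <- as.matrix(dist(x))
    dimnames(dm) <- list(md$sample_id, md$sample_id)
    mine <- adonis_dm(dm, md, ~ f1 + f2, n_perm = 0)
    oracle <- coord_anova_ss(x, mf, c("f1", "f2"))
    expect_equal(mine$SS[1:2], oracle$ss, tolerance = 1e-8)
    expect_equal(mine$SS[mine$term == "Residuals"], oracle$ss_res,
                 tolerance = 1e-8)
    expect_equal(mine$SS[mine$term == "Total"], oracle$ss_total,
                 tolerance = 1e-8)
  }
})

test_that("adonis agrees with an independent reference implementation", {
  set.seed(12)
  x <- matrix(rpois(14 * 6, 15), 14)
  md <- data.frame(sample_id = paste0("s", 1:14),
                   f1 = rep(c("u", "v"), 7),
                   f2 = rep(c("p", "q"), each = 7))
  dm <- as.matrix(vegan::vegdist(x, "bray"))
  dimnames(dm) <- list(md$sample_id, md$sample_id)
  mine <- adonis_dm(dm, md, ~ f1 + f2 + f1:f2, n_perm = 0)
  ref <- vegan::adonis2(vegan::vegdist(x, "bray") ~ f1 + f2 + f1:f2,
                        data = md, permutations = 2, by = "terms")
  expect_equal(mine$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(mine$PseudoF[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(mine$Df[1:3], ref$Df[1:3])
})

test_that("partition identities hold on synthetic data for any term order", {
  sim <- generate_microbiome(small_synth(seed = 17))
  dm <- bray_curtis(sim$table)
  G <- gower_center(dm)
  for (fml in list(~ tolerance + temperature + family + part +
                     tolerance:temperature,
                   ~ part + temperature + tolerance + family +
                     tolerance:temperature)) {
    tab <- adonis_dm(dm, sim$meta, fml, n_perm = 0)
    terms <- !(tab$term %in% c("Residuals", "Total"))
    expect_equal(sum(tab$SS[terms]) + tab$SS[tab$term == "Residuals"],
                 sum(diag(G)), tolerance = 1e-8)
    expect_equal(sum(tab$R2[terms]) + tab$R2[tab$term == "Residuals"], 1,
                 tolerance = 1e-8)
    expect_equal(sum(tab$Df), 2 * (nrow(dm) - 1))
  }
  # order changes the sequential SS of correlated terms, never the partition
  set.seed(5)
  x <- matrix(rnorm(12 * 2), 12)
  md <- data.frame(sample_id = paste0("s", 1:12),
                   f1 = c(rep("u", 8), rep("v", 4)),
                   f2 = c(rep("p", 3), rep("q", 9)))
  dmu <- as.matrix(dist(x))
  dimnames(dmu) <- list(md$sample_id, md$sample_id)
  t1 <- adonis_dm(dmu, md, ~ f1 + f2, n_perm = 0)
  t2 <- adonis_dm(dmu, md, ~ f2 + f1, n_perm = 0)
  expect_false(isTRUE(all.equal(t1$SS[t1$term == "f1"],
                                t2$SS[t2$term == "f1"])))
  expect_equal(sum(t1$SS[1:2]), sum(t2$SS[1:2]), tolerance = 1e-8)
})

test_that("degenerate designs are rejected and family coding is configurable", {
  sim <- generate_microbiome(small_synth(seed = 2))
  dm <- bray_curtis(sim$table)
  md <- sim$meta
  md$constant <- "x"
  expect_error(adonis_dm(dm, md, ~ constant, n_perm = 0), "single level")
  nat <- adonis_dm(dm, md, ~ family, n_perm = 0)
  expect_equal(nat$Df[nat$term == "family"], 5)
  num <- adonis_dm(dm, md, ~ family, n_perm = 0, family_numeric = TRUE)
  expect_equal(num$Df[num$term == "family"], 1)
})

test_that("assembled PERMANOVA columns follow MS = SS/df, F = MS/MS_res, R2 = SS/SS_tot", {
  row <- assemble_permanova_row(SS_term = 0.5046, df_term = 1,
                                SS_res = 22.2176, df_res = 159,
                                SS_total = 28.2401)
  expect_equal(row$MS, 0.5046)
  expect_equal(row$pseudoF, (0.5046 / 1) / (22.2176 / 159))
  expect_equal(row$R2, 0.5046 / 28.2401)
  zero <- assemble_permanova_row(0, 1, 22.2176, 159, 28.2401)
  expect_equal(zero$pseudoF, 0)
  expect_equal(zero$R2, 0)
  expect_error(assemble_permanova_row(1, 1, 1, 0, 2), "positive")
})
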