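test_that("Bray-Curtis matches hand evaluation and stays in [0, 1]", {
  m <- rbind(u = c(6, 2), v = c(2, 2), w = c(0, 7))
  colnames(m) <- c("f1", "f2")
  d <- bray_curtis(feature_table(m))
  expect_equal(d["u", "v"], 4 / 12)
  expect_equal(d["u", "u"], 0)
  expect_equal(d, t(d))
  disj <- rbind(a = c(5, 0), b = c(0, 3))
  colnames(disj) <- c("f1", "f2")
  expect_equal(bray_curtis(feature_table(disj))["a", "b"], 1)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "zero-total")
})

test_that("Bray-Curtis on presence/absence equals Sorensen from set arithmetic", {
  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(rbinom(6 * 10, 1, 0.5), 6, 10,
                dimnames = list(paste0("s", 1:6), paste0("f", 1:10)))
    m[rowSums(m) == 0, 1] <- 1
    d <- bray_curtis(feature_table(m))
    for (i in 1:5) for (j in (i + 1):6) {
      a <- which(m[i, ] > 0); b <- which(m[j, ] > 0)
      soren <- 1 - 2 * length(intersect(a, b)) / (length(a) + length(b))
      expect_equal(d[i, j], soren)
    }
  }
})

test_that("Jaccard presence distance matches set arithmetic with edge cases", {
  m <- rbind(x = c(1, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0),
             z = c(1, 1, 1, 0, 0), e1 = c(0, 0, 0, 0, 0),
             e2 = c(0, 0, 0, 0, 0))
  colnames(m) <- paste0("f", 1:5)
  d <- jaccard_presence(m)
  expect_equal(d["x", "y"], 0.75)  # 1 - 1/4
  expect_equal(d["x", "z"], 0)
  expect_equal(d["e1", "e2"], 0)   # both empty
  expect_equal(d["x", "e1"], 1)
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(jaccard_presence(disj)[1, 2], 1)
  # threshold: values at the cutoff do not count as present
  expect_equal(jaccard_presence(rbind(a = c(0.5, 1), b = c(0.5, 1)),
                                detect_threshold = 0.5)[1, 2], 0)
})

test_that("PCoA recovers Euclidean configurations and conserves the trace", {
  pts <- c(0, 1, 3)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord <- pcoa(d, k = 1)
  expect_length(ord$eigenvalues, 1)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-10)
  G <- gower_center(d)
  expect_equal(sum(ord$eigenvalues), sum(diag(G)))
  expect_error(pcoa(d, k = 3), "positive eigenvalue")
})

test_that("PCoA coordinates approximately reconstruct Bray-Curtis distances", {
  sim <- generate_microbiome(small_synth(seed = 6))
  sub <- feature_table(unclass(sim$table)[1:20, ])
  dm <- bray_curtis(sub)
  ord <- pcoa(dm, k = length(pcoa(dm, k = 1)$eigenvalues))
  full <- ord$coordinates
  rec <- as.matrix(dist(full))
  off <- upper.tri(dm)
  expect_gt(cor(rec[off], dm[off]), 0.99)
  # error bounded by the dropped negative part of the spectrum
  neg <- sum(abs(ord$negative_eigenvalues))
  expect_lt(mean(abs(rec[off] - dm[off])), sqrt(neg))
})

test_that("distance contrasts detect separation and respect identical sets", {
  meta <- tiny_meta(per_cell = 4)
  tab <- tiny_table(meta, n_feat = 10, seed = 3)
  dm <- bray_curtis(tab)
  selA <- pair_selector("temperature", "between",
                        stratum = list(tolerance = "resistant"))
  dc <- distance_contrast(dm, meta, selA, selA, n_perm = 199, seed = 1)
  expect_equal(dc$t, 0)
  expect_gt(dc$p, 0.9)

  # maximal separation: p hits the permutation floor
  d2 <- matrix(0.5, 20, 20, dimnames = list(paste0("s", 1:20),
                                            paste0("s", 1:20)))
  g <- rep(c("resistant", "sensitive"), each = 10)
  md <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:20), tolerance = g, temperature = "warm24",
    family = "R1", part = "anterior", fish = paste0("s", 1:20)))
  d2[1:10, 1:10] <- 0.1; d2[11:20, 11:20] <- 0.9; diag(d2) <- 0
  wA <- pair_selector("tolerance", "within", level = "resistant")
  wB <- pair_selector("tolerance", "within", level = "sensitive")
  dc2 <- distance_contrast(d2, md, wA, wB, n_perm = 999, seed = 7)
  expect_equal(dc2$p, 1 / 1000)
  expect_equal(dc2$p_corrected, min(1, dc2$p * 1))

  expect_error(select_distances(dm, meta,
    pair_selector("temperature", "within", level = "warm24",
                  stratum = list(tolerance = "nope"))), "fewer than 2")
})

test_that("Monte-Carlo contrast p is valid under an exchangeable null", {
  meta <- tiny_meta(per_cell = 3)
  selA <- pair_selector("temperature", "between",
                        stratum = list(tolerance = "resistant"))
  selB <- pair_selector("temperature", "between",
                        stratum = list(tolerance = "sensitive"))
  p <- vapply(1:60, function(s) {
    tab <- tiny_table(meta, n_feat = 10, seed = 1000 + s)
    distance_contrast(bray_curtis(tab), meta, selA, selB,
                      n_perm = 99, seed = s)$p
  }, numeric(1))
  expect_gt(mean(p <= 0.05), 0)   # not degenerate at 1
  expect_lt(mean(p <= 0.10), 0.35)  # roughly calibrated
  expect_gt(mean(p), 0.3)
})
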