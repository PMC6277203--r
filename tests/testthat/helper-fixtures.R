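# Shared in-code fixtures for the suite.

# minimal balanced metadata: 2 tolerance groups x 2 temperatures x
# `per_cell` fish, single gut part unless parts = 2
tiny_meta <- function(per_cell = 2, parts = 1) {
  rows <- list()
  for (g in c("resistant", "sensitive")) for (temp in c("warm24", "cold12"))
    for (i in seq_len(per_cell))
      for (p in c("anterior", "posterior")[seq_len(parts)]) {
        fish <- sprintf("%s_%s_%d", substr(g, 1, 1), substr(temp, 1, 1), i)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = paste0(fish, "_", substr(p, 1, 1)),
          tolerance = g, temperature = temp,
          family = paste0(substr(g, 1, 1), 1 + i %% 3),
          part = p, fish = fish, stringsAsFactors = FALSE)
      }
  sample_metadata(do.call(rbind, rows))
}

# random small count table matching a metadata object
tiny_table <- function(meta, n_feat = 8, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(nrow(meta) * n_feat, lambda), nrow(meta), n_feat,
              dimnames = list(meta$sample_id,
                              sprintf("f%02d", seq_len(n_feat))))
  feature_table(m)
}

# fast small synthetic config for pipeline-level tests
small_synth <- function(seed = 1, ...) {
  synth_config(seed = seed, fish_per_family = 3, n_taxa = 60,
               n_core_taxa = 6, depth_mean = 4000, n_transcripts = 100, ...)
}

# sequential ANOVA sums of squares computed directly on coordinates via
# nested linear models -- the independent oracle for the distance-based path
coord_anova_ss <- function(x, mf, terms) {
  x <- as.matrix(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  fit0 <- lapply(seq_len(ncol(xc)), function(j) fitted(lm(xc[, j] ~ 1)))
  ss <- numeric(length(terms))
  prev <- fit0
  for (k in seq_along(terms)) {
    fk <- as.formula(paste("y ~", paste(terms[seq_len(k)], collapse = "+")))
    cur <- lapply(seq_len(ncol(xc)), function(j) {
      d <- cbind(y = xc[, j], mf)
      fitted(lm(fk, data = d))
    })
    ss[k] <- sum(vapply(seq_len(ncol(xc)), function(j)
      sum((cur[[j]] - prev[[j]])^2), numeric(1)))
    prev <- cur
  }
  res <- sum(vapply(seq_len(ncol(xc)), function(j)
    sum((xc[, j] - prev[[j]])^2), numeric(1)))
  list(ss = ss, ss_res = res, ss_total = sum(xc^2))
}
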