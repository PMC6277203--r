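#' Configuration for the synthetic study generator
#'
#' Defines a study-like design: two host tolerance groups (resistant,
#' sensitive), each with `n_families_per_group` full-sib families,
#' `fish_per_family` fish per family *per temperature arm* (warm and cold
#' fish are different full siblings), and `parts` gut compartments sampled
#' per fish. Counts are Dirichlet-multinomial around a group-by-temperature
#' composition; the cold composition is the warm one perturbed by log-normal
#' fold-changes whose scale differs between tolerance groups
#' (`shift_resistant` <= `shift_sensitive`), with a fraction of non-core taxa
#' zeroed at cold and a lower Dirichlet concentration at cold (more
#' dispersion under stress).
#'
#' @param seed integer; drives named RNG streams for counts, expression and
#'   permutations.
#' @param n_families_per_group families per tolerance group.
#' @param fish_per_family fish per family per temperature arm.
#' @param parts gut compartments per fish (1 = anterior only, 2 adds
#'   posterior).
#' @param n_taxa number of taxa.
#' @param n_core_taxa taxa given high baseline abundance so their prevalence
#'   exceeds 0.5 in each temperature arm.
#' @param depth_mean mean sequencing depth; per-sample library sizes are
#'   Poisson(`depth_mean`).
#' @param dm_concentration_warm,dm_concentration_cold Dirichlet concentration
#'   (precision) at each temperature; cold < warm yields the higher
#'   compositional dispersion seen under cold stress.
#' @param shift_resistant,shift_sensitive log-fold-change scale of the
#'   warm-to-cold compositional shift per group (delta_R <= delta_S encodes
#'   the buffered response of the resistant group).
#' @param diversity_drop_cold fraction of non-core taxa zeroed in the cold
#'   composition (drives the cold richness drop).
#' @param family_sd standard deviation of the per-family random log-scale
#'   intercept on composition.
#' @param group_sd standard deviation of the group-level baseline log
#'   perturbation (warm-condition compositional difference between groups).
#' @param n_transcripts transcripts in the companion expression matrix.
#' @param latent_dim number of latent factors shared between microbiome and
#'   expression.
#' @param latent_loading in [0, 1]; weight of the shared latent signal in the
#'   expression matrix (0 = independent).
#' @param noise_sd Gaussian noise SD on log expression.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_families_per_group = 3L,
                         fish_per_family = 7L,
                         parts = 2L,
                         n_taxa = 150L,
                         n_core_taxa = 11L,
                         depth_mean = 20000L,
                         dm_concentration_warm = 60,
                         dm_concentration_cold = 30,
                         shift_resistant = 0.3,
                         shift_sensitive = 1.0,
                         diversity_drop_cold = 0.30,
                         family_sd = 0.15,
                         group_sd = 0.3,
                         n_transcripts = 400L,
                         latent_dim = 4L,
                         latent_loading = 0.9,
                         noise_sd = 1.0) {
  cfg <- list(seed = as.integer(seed),
              n_families_per_group = as.integer(n_families_per_group),
              fish_per_family = as.integer(fish_per_family),
              parts = as.integer(parts),
              n_taxa = as.integer(n_taxa),
              n_core_taxa = as.integer(n_core_taxa),
              depth_mean = as.integer(depth_mean),
              dm_concentration_warm = dm_concentration_warm,
              dm_concentration_cold = dm_concentration_cold,
              shift_resistant = shift_resistant,
              shift_sensitive = shift_sensitive,
              diversity_drop_cold = diversity_drop_cold,
              family_sd = family_sd,
              group_sd = group_sd,
              n_transcripts = as.integer(n_transcripts),
              latent_dim = as.integer(latent_dim),
              latent_loading = latent_loading,
              noise_sd = noise_sd)
  sizes <- cfg[c("n_families_per_group", "fish_per_family", "parts", "n_taxa",
                 "n_core_taxa", "depth_mean", "n_transcripts", "latent_dim")]
  if (any(unlist(sizes) <= 0)) stop("all counts/sizes must be positive")
  if (cfg$n_core_taxa > cfg$n_taxa) stop("n_core_taxa exceeds n_taxa")
  if (cfg$dm_concentration_warm <= 0 || cfg$dm_concentration_cold <= 0)
    stop("Dirichlet concentrations must be positive")
  if (cfg$shift_resistant < 0 || cfg$shift_sensitive < 0)
    stop("shift parameters must be non-negative")
  if (cfg$shift_resistant > cfg$shift_sensitive)
    stop("shift_resistant must not exceed shift_sensitive")
  if (cfg$diversity_drop_cold < 0 || cfg$diversity_drop_cold >= 1)
    stop("diversity_drop_cold must be in [0, 1)")
  if (cfg$latent_loading < 0 || cfg$latent_loading > 1)
    stop("latent_loading must be in [0, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  class(cfg) <- "synth_config"
  cfg
}

.synth_design <- function(cfg) {
  groups <- c("resistant", "sensitive")
  prefix <- c(resistant = "R", sensitive = "S")
  rows <- list()
  for (g in groups) for (f in seq_len(cfg$n_families_per_group)) {
    fam <- sprintf("%s%d", prefix[[g]], f)
    for (temp in c("warm24", "cold12")) for (i in seq_len(cfg$fish_per_family)) {
      fish <- sprintf("%s_%s_f%02d", fam, substr(temp, 1, 4), i)
      for (p in c("anterior", "posterior")[seq_len(cfg$parts)]) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste(fish, substr(p, 1, 4), sep = "_"),
          tolerance = g, temperature = temp, family = fam, part = p,
          fish = fish, stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, rows)
  meta <- meta[order(meta$sample_id, method = "radix"), ]
  sample_metadata(meta)
}

.rdirichlet_row <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  s <- sum(g)
  if (s == 0) stop("degenerate Dirichlet draw (all-zero alpha)")
  g / s
}

#' Generate a synthetic microbiome count table with known ground truth
#'
#' Draws a study-like dataset: group baseline compositions perturbed from a
#' common log-normal abundance spectrum; cold compositions obtained by
#' applying a shared taxon log-fold-change vector scaled by the group's shift
#' parameter, zeroing a fraction of non-core taxa; per-family random
#' log-intercepts; and per-sample Dirichlet-multinomial counts with
#' Poisson library sizes. Fully reproducible from `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `table` ([feature_table()]), `meta`
#'   ([sample_metadata()]) and `truth` (group compositions, per-group
#'   warm-to-cold log-fold-changes, core taxon ids, per-sample latent factor
#'   scores).
#' @export
generate_microbiome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  meta <- .synth_design(cfg)
  taxa <- sprintf("taxon%03d", seq_len(cfg$n_taxa))

  with_seed(stream_seed(cfg$seed, "counts"), {
    base_log <- stats::rnorm(cfg$n_taxa, 0, 1.5)
    core_idx <- sample.int(cfg$n_taxa, cfg$n_core_taxa)
    # core taxa: abundant by construction so each arm keeps them prevalent
    base_log[core_idx] <- pmax(base_log[core_idx], 0) + 2.5
    lfc <- stats::rnorm(cfg$n_taxa)                 # shared direction of shift
    # core members are the resilient fraction: their response is damped so
    # they stay prevalent in both arms
    lfc[core_idx] <- 0.3 * lfc[core_idx]
    # cold filters out the rarest community members (detection-limit
    # dropout), never the abundant core
    n_drop <- floor(cfg$diversity_drop_cold * cfg$n_taxa)
    droppable <- setdiff(order(base_log), core_idx)
    drop_idx <- if (n_drop > 0) droppable[seq_len(min(n_drop,
                                                      length(droppable)))]
                else integer(0)

    shifts <- c(resistant = cfg$shift_resistant, sensitive = cfg$shift_sensitive)
    comp <- list()
    for (g in c("resistant", "sensitive")) {
      gw_log <- base_log + stats::rnorm(cfg$n_taxa, 0, cfg$group_sd)
      warm <- softmax_log(gw_log)
      cold_log <- gw_log + shifts[[g]] * lfc
      cold <- softmax_log(cold_log)
      cold[drop_idx] <- 0
      cold <- cold / sum(cold)
      comp[[g]] <- list(warm24 = warm, cold12 = cold)
    }

    fams <- levels(meta$family)
    fam_eff <- matrix(stats::rnorm(length(fams) * cfg$n_taxa, 0, cfg$family_sd),
                      nrow = length(fams), dimnames = list(fams, taxa))

    n <- nrow(meta)
    P <- matrix(0, n, cfg$n_taxa, dimnames = list(meta$sample_id, taxa))
    counts <- matrix(0L, n, cfg$n_taxa, dimnames = list(meta$sample_id, taxa))
    depths <- stats::rpois(n, cfg$depth_mean)
    conc <- c(warm24 = cfg$dm_concentration_warm,
              cold12 = cfg$dm_concentration_cold)
    for (i in seq_len(n)) {
      g <- as.character(meta$tolerance[i]); tmp <- as.character(meta$temperature[i])
      mu <- comp[[g]][[tmp]] * exp(fam_eff[as.character(meta$family[i]), ])
      mu <- mu / sum(mu)
      p <- .rdirichlet_row(mu * conc[[tmp]])
      P[i, ] <- p
      counts[i, ] <- stats::rmultinom(1, depths[i], p)[, 1]
    }

    # Latent factors: leading principal directions of the realized clr
    # compositions (half-read pseudo-proportion at nominal depth),
    # standardized; these drive the companion expression matrix.
    sc <- stats::prcomp(clr(P, pseudo = 0.5 / cfg$depth_mean),
                        center = TRUE, scale. = FALSE)$x
    k <- min(cfg$latent_dim, ncol(sc))
    scores <- scale(sc[, seq_len(k), drop = FALSE])
    colnames(scores) <- sprintf("LF%d", seq_len(k))

    truth <- list(
      composition = comp,
      log_fold_change = list(resistant = cfg$shift_resistant * lfc,
                             sensitive = cfg$shift_sensitive * lfc),
      core_taxa = taxa[sort(core_idx)],
      dropped_cold_taxa = taxa[sort(drop_idx)],
      latent_scores = scores,
      library_sizes = stats::setNames(depths, meta$sample_id)
    )
    list(table = feature_table(counts, kind = "taxa"), meta = meta,
         truth = truth)
  })
}

#' Generate an expression matrix sharing latent structure with the microbiome
#'
#' Expression is built as `latent_loading * (scores %*% loadings)` plus
#' Gaussian noise on the log scale, then exponentiated to a non-negative
#' normalized-abundance scale. With `latent_loading = 0` the matrix is
#' independent of the microbiome (a null configuration for the
#' canonical-correlation permutation test).
#'
#' @param config the [synth_config()] used for [generate_microbiome()].
#' @param truth the `truth` element returned by [generate_microbiome()].
#' @return samples x transcripts numeric matrix.
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  scores <- truth$latent_scores
  if (is.null(scores)) stop("truth lacks latent scores; run generate_microbiome")
  n <- nrow(scores)
  with_seed(stream_seed(config$seed, "expression"), {
    W <- matrix(stats::rnorm(ncol(scores) * config$n_transcripts),
                nrow = ncol(scores))
    E <- config$latent_loading * (scores %*% W) +
      matrix(stats::rnorm(n * config$n_transcripts, 0, config$noise_sd),
             nrow = n)
    expr <- exp(E)
    dimnames(expr) <- list(rownames(scores),
                           sprintf("tr%04d", seq_len(config$n_transcripts)))
    expr
  })
}

#' Write a full synthetic dataset to a directory
#'
#' Convenience wrapper producing the three TSVs (counts, metadata,
#' expression) plus a ground-truth JSON.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list from [generate_microbiome()] plus `expr`.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_microbiome(config)
  expr <- generate_expression(config, sim$truth)
  write_feature_table(sim$table, file.path(out_dir, "counts.tsv"))
  write_metadata(sim$meta, file.path(out_dir, "metadata.tsv"))
  write_expression(expr, file.path(out_dir, "expression.tsv"))
  truth <- sim$truth
  truth$latent_scores <- NULL  # matrix; keep the JSON compact
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(sim, list(expr = expr)))
}
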