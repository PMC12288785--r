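#' Simulation configuration
#'
#' Parameters of the synthetic count generator. The defaults emulate the
#' sibling-cross design the pipeline targets: 3 families x 3 Eda genotypes
#' (CC, CL, LL) x 2 sexes x 2 replicates = 36 samples, with family batch
#' effects, planted recessive-L expression effects, planted exon-usage
#' shifts, planted co-expression modules, and negative binomial noise with a
#' mean-dispersion trend.
#'
#' @param n_genes total number of genes.
#' @param n_modules,module_size planted co-expression modules (first
#'   `n_modules * module_size` genes, block-wise).
#' @param samples_per_cell replicates per family x genotype x sex cell.
#' @param families,genotypes,sexes factor levels of the design.
#' @param baseline_log2_mean_sd mean and sd of per-gene baseline abundance on
#'   the log2-CPM scale.
#' @param family_sd sd (log2 units) of the per-gene family offsets.
#' @param loading_range band for module factor loadings (log2 units per unit
#'   latent factor); each module receives one random orientation sign.
#' @param n_deg number of planted differentially expressed genes.
#' @param deg_effect_range range of |log2 fold change| for planted DEGs;
#'   signs random.
#' @param genotype_model `"recessive_L"` (LL differs, CC = CL; the default,
#'   matching the observed CC ~ CL transcriptomes), `"additive"` or
#'   `"dominant_L"`.
#' @param n_dsg number of planted differentially spliced genes.
#' @param usage_shift added usage proportion on the target exon in affected
#'   genotypes, in (0, 1).
#' @param exons_per_gene_range inclusive integer range of exons per gene.
#' @param dirichlet_alpha concentration of the symmetric Dirichlet from which
#'   each gene's baseline exon-usage proportions are drawn.
#' @param dm_overdispersion if `TRUE`, redraw usage proportions per sample
#'   from a Dirichlet centred on the gene's usage (Dirichlet-multinomial
#'   exon noise); default `FALSE` (exact multinomial).
#' @param dispersion_intercept,dispersion_slope NB dispersion trend
#'   `phi = b0 + b1 / mu` in the mean expected count.
#' @param library_size_mean,library_size_cv log-normal library sizes.
#' @param exon_length_range range of exon lengths (bp) for TPM support.
#' @param seed integer seed; fixed seed implies a bit-identical dataset.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 3000,
                       n_modules = 10,
                       module_size = 100,
                       samples_per_cell = 2,
                       families = c("A", "B", "C"),
                       genotypes = c("CC", "CL", "LL"),
                       sexes = c("F", "M"),
                       baseline_log2_mean_sd = c(4, 2),
                       family_sd = 0.2,
                       loading_range = c(0.4, 0.8),
                       n_deg = 200,
                       deg_effect_range = c(1, 2),
                       genotype_model = c("recessive_L", "additive",
                                          "dominant_L"),
                       n_dsg = 100,
                       usage_shift = 0.2,
                       exons_per_gene_range = c(2, 8),
                       dirichlet_alpha = 5,
                       dm_overdispersion = FALSE,
                       dispersion_intercept = 0.05,
                       dispersion_slope = 2,
                       library_size_mean = 5e5,
                       library_size_cv = 0.1,
                       exon_length_range = c(100, 500),
                       seed = 1234) {
  genotype_model <- match.arg(genotype_model)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    abort("module overflow: n_modules * module_size exceeds n_genes")
  }
  if (cfg$n_deg > cfg$n_genes || cfg$n_dsg > cfg$n_genes) {
    abort("more planted effects than genes")
  }
  if (cfg$usage_shift <= 0 || cfg$usage_shift >= 1) {
    abort("usage_shift must lie in (0, 1)")
  }
  if (cfg$exons_per_gene_range[1] < 1) abort("genes need at least one exon")
  if (cfg$family_sd < 0 || cfg$library_size_cv < 0) {
    abort("negative variability parameter")
  }
  invisible(cfg)
}

# Genotype design value x in [0, 1] per genotype label.
genotype_design_value <- function(genotype, model) {
  switch(model,
    recessive_L = c(CC = 0, CL = 0, LL = 1),
    additive    = c(CC = 0, CL = 0.5, LL = 1),
    dominant_L  = c(CC = 0, CL = 1, LL = 1)
  )[as.character(genotype)]
}

#' Generate a synthetic gene + exon count dataset with known truth
#'
#' Draws per-gene baselines on the log2-CPM scale, adds module latent
#' factors, family offsets and genotype effects, converts log2 means to
#' expected counts through a per-sample softmax times the library size,
#' draws gene counts from a negative binomial with a mean-dispersion trend,
#' and partitions each gene count multinomially into exon counts. Planted
#' differentially spliced genes shift their target exon's usage proportion
#' by `usage_shift` (renormalising the others) in samples whose genotype
#' design value is 1.
#'
#' @param config a [sim_config()].
#' @return A list with elements `counts` (genes x samples matrix),
#'   `exon_counts` ([exon_counts]), `samples` (tibble), `annotation`
#'   (tibble: `gene_id`, `length`, `n_exons`), and `truth` (list: `deg`
#'   tibble with planted and realized log2FC, `dsg` tibble, `modules`
#'   tibble, `family_offsets`, `library_sizes`, `dispersions`,
#'   `expected_counts`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  samples <- tidyr::expand_grid(
    family = cfg$families, genotype = cfg$genotypes, sex = cfg$sexes,
    replicate = seq_len(cfg$samples_per_cell)
  ) |>
    mutate(sample_id = sprintf("%s_%s_%s_%d", .data$family, .data$genotype,
                               .data$sex, .data$replicate),
           genotype = factor(.data$genotype, levels = cfg$genotypes),
           family = factor(.data$family, levels = cfg$families),
           sex = factor(.data$sex, levels = cfg$sexes),
           tissue = "skin") |>
    select("sample_id", "genotype", "family", "sex", "tissue", "replicate")
  n_s <- nrow(samples)
  n_g <- cfg$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n_g))

  # module membership: first n_modules*module_size genes, block-wise
  module <- rep("M0", n_g)
  in_mod <- seq_len(cfg$n_modules * cfg$module_size)
  module[in_mod] <- rep(sprintf("M%d", seq_len(cfg$n_modules)),
                        each = cfg$module_size)

  baseline <- rnorm(n_g, cfg$baseline_log2_mean_sd[1],
                    cfg$baseline_log2_mean_sd[2])
  loading <- numeric(n_g)
  orient <- sample(c(-1, 1), cfg$n_modules, replace = TRUE)
  loading[in_mod] <- runif(length(in_mod), cfg$loading_range[1],
                           cfg$loading_range[2]) *
    rep(orient, each = cfg$module_size)
  z <- matrix(rnorm(cfg$n_modules * n_s), cfg$n_modules, n_s)

  fam_idx <- as.integer(samples$family)
  gamma <- matrix(rnorm(n_g * length(cfg$families), 0, cfg$family_sd),
                  n_g, length(cfg$families),
                  dimnames = list(gene_ids, cfg$families))

  deg_ids <- sort(sample(gene_ids, cfg$n_deg))
  delta <- setNames(numeric(n_g), gene_ids)
  if (cfg$n_deg > 0) {
    delta[deg_ids] <- sample(c(-1, 1), cfg$n_deg, replace = TRUE) *
      runif(cfg$n_deg, cfg$deg_effect_range[1], cfg$deg_effect_range[2])
  }
  x <- genotype_design_value(samples$genotype, cfg$genotype_model)

  # log2 mean matrix mu_gk
  mu_log2 <- matrix(baseline, n_g, n_s) +
    outer(delta, x) + gamma[, fam_idx]
  mod_idx <- match(module, sprintf("M%d", seq_len(cfg$n_modules)))
  has_mod <- !is.na(mod_idx)
  mu_log2[has_mod, ] <- mu_log2[has_mod, ] +
    loading[has_mod] * z[mod_idx[has_mod], , drop = FALSE]

  lib <- cfg$library_size_mean *
    exp(rnorm(n_s, 0, sqrt(log(1 + cfg$library_size_cv^2)))) /
    sqrt(1 + cfg$library_size_cv^2)
  lib <- setNames(round(lib), samples$sample_id)

  # softmax over genes per sample -> expected counts
  w <- 2^mu_log2
  expected <- sweep(sweep(w, 2, colSums(w), "/"), 2, lib, "*")
  dimnames(expected) <- list(gene_ids, samples$sample_id)

  mu_bar <- rowMeans(expected)
  phi <- pmax(cfg$dispersion_intercept + cfg$dispersion_slope / mu_bar, 1e-8)
  counts <- matrix(rnbinom(n_g * n_s, mu = expected, size = 1 / phi),
                   n_g, n_s, dimnames = dimnames(expected))

  # realized log2FC: compositional softmax makes the achieved fold change
  # differ from the planted delta; record the achieved value from the
  # expected-count matrix so recovery compares like with like
  g1 <- x == 1
  g0 <- x == 0
  realized <- if (any(g1) && any(g0)) {
    rowMeans(log2(expected[, g1, drop = FALSE])) -
      rowMeans(log2(expected[, g0, drop = FALSE]))
  } else rep(NA_real_, n_g)

  # exon structure
  n_exons <- sample(seq(cfg$exons_per_gene_range[1],
                        cfg$exons_per_gene_range[2]),
                    n_g, replace = TRUE)
  multi <- which(n_exons >= 2)
  dsg_ids <- sort(sample(gene_ids[multi], min(cfg$n_dsg, length(multi))))
  target_exon <- setNames(integer(0), character(0))

  exon_gene <- rep(gene_ids, n_exons)
  exon_ord <- unlist(lapply(n_exons, seq_len))
  exon_ids <- sprintf("%s_e%d", exon_gene, exon_ord)
  exon_len <- round(runif(length(exon_ids), cfg$exon_length_range[1],
                          cfg$exon_length_range[2]))

  # baseline usage proportions per gene
  usage <- lapply(n_exons, function(m) {
    g <- rgamma(m, shape = cfg$dirichlet_alpha)
    g / sum(g)
  })
  names(usage) <- gene_ids

  if (length(dsg_ids) > 0) {
    # target exon must keep the shifted proportion inside (0,1)
    target_exon <- setNames(vapply(dsg_ids, function(g) {
      pi0 <- usage[[g]]
      feasible <- which(pi0 + cfg$usage_shift < 1)
      if (length(feasible) == 0) {
        abort(sprintf(
          "usage_shift %.2f pushes every exon proportion of %s outside (0,1)",
          cfg$usage_shift, g))
      }
      feasible[sample.int(length(feasible), 1)]
    }, integer(1)), dsg_ids)
  }

  exon_counts_m <- matrix(0, length(exon_ids), n_s,
                          dimnames = list(exon_ids, samples$sample_id))
  offset <- c(0, cumsum(n_exons))
  for (gi in seq_len(n_g)) {
    m <- n_exons[gi]
    rows <- (offset[gi] + 1):(offset[gi] + m)
    pi_base <- usage[[gi]]
    is_dsg <- gene_ids[gi] %in% dsg_ids
    for (k in seq_len(n_s)) {
      tot <- counts[gi, k]
      if (tot == 0) next
      p <- pi_base
      if (is_dsg && x[k] == 1) {
        t <- target_exon[[gene_ids[gi]]]
        p <- pi_base * (1 - pi_base[t] - cfg$usage_shift) / (1 - pi_base[t])
        p[t] <- pi_base[t] + cfg$usage_shift
      }
      if (cfg$dm_overdispersion) {
        g <- rgamma(m, shape = cfg$dirichlet_alpha * m * p)
        p <- g / sum(g)
      }
      exon_counts_m[rows, k] <- rmultinom(1, tot, p)
    }
  }

  truth <- list(
    deg = tibble(gene_id = deg_ids,
                 delta = delta[deg_ids],
                 realized_log2fc = realized[match(deg_ids, gene_ids)]),
    dsg = tibble(gene_id = dsg_ids,
                 target_exon = unname(target_exon[dsg_ids]),
                 usage_shift = cfg$usage_shift),
    modules = tibble(gene_id = gene_ids, module = module,
                     loading = loading),
    realized_log2fc = setNames(realized, gene_ids),
    family_offsets = gamma,
    library_sizes = lib,
    dispersions = setNames(phi, gene_ids),
    expected_counts = expected,
    genotype_model = cfg$genotype_model
  )

  list(
    counts = counts,
    exon_counts = exon_counts(exon_counts_m, exon_gene, exon_ord, exon_len),
    samples = samples,
    annotation = tibble(gene_id = gene_ids,
                        length = as.numeric(rowsum(exon_len, exon_gene)[gene_ids, 1]),
                        n_exons = n_exons),
    truth = truth,
    config = cfg
  )
}
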