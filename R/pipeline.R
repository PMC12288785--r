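#' Pipeline configuration
#'
#' Assembles the full-run configuration. Exactly one of `simulate` /
#' `input` must be given. All thresholds default to the analysis'
#' standard values: filter min count 10, TREAT threshold 0.585 log2
#' (1.5-fold), FDR 0.05, top-500 MDS genes, soft threshold 14,
#' maxPOutliers 0.10, B = 10,000 permutations, seed 1234.
#'
#' @param simulate a [sim_config()], or `NULL` when reading files.
#' @param input list with paths `counts`, `exons`, `samples` (TSV) and
#'   optionally `lengths`; or `NULL` when simulating.
#' @param min_count,max_low_samples low-expression filter.
#' @param tau,alpha TREAT log2 threshold and FDR cut (shared by DE and
#'   splicing).
#' @param mds_top genes per pair in the MDS distance.
#' @param beta fixed soft threshold, or `NULL` to pick from `candidates`.
#' @param candidates,r2_cut,max_p_outliers,cut_height,min_size,merge_cor
#'   network parameters (see [build_network()]).
#' @param perm_B,seed permutation count and master seed.
#' @param atomize gene ids to atomize into exons, or `NULL`.
#' @param hub_focal gene or module ids for subnetwork extraction; default
#'   picks the highest-kTotal gene and the largest module.
#' @param hub_n neighbourhood size.
#' @param gmt optional GMT path for over-representation of the DEG set.
#' @return List of class `edanet_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), input = NULL,
                            min_count = 10, max_low_samples = NULL,
                            tau = 0.585, alpha = 0.05, mds_top = 500,
                            beta = 14, candidates = c(1:10, 12, 14, 16, 18,
                                                      20),
                            r2_cut = 0.85, max_p_outliers = 0.10,
                            cut_height = 0.99, min_size = 20,
                            merge_cor = 0.75,
                            perm_B = 10000, seed = 1234,
                            atomize = NULL, hub_focal = NULL, hub_n = 10,
                            gmt = NULL) {
  if (is.null(simulate) == is.null(input)) {
    abort("exactly one of `simulate` or `input` must be given")
  }
  if (!is.null(input)) {
    need <- c("counts", "exons", "samples")
    if (!all(need %in% names(input))) {
      abort("`input` needs paths `counts`, `exons`, `samples`")
    }
    for (p in unlist(input)) {
      if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
    }
  }
  cfg <- as.list(environment())
  class(cfg) <- "edanet_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load or simulate counts; low-expression filter; TMM
#' factors; log2-CPM; leading-logFC MDS table; TREAT differential
#' expression for the three genotype contrasts (LL vs CC, CL vs CC,
#' LL vs CL); differential exon usage with the union DSG rule; family
#' adjustment; signed co-expression network with kTotal; module x DEG/DSG
#' cross-tabulation; permutation median comparisons of kTotal and TPM for
#' the DEG-only and DSG-only sets (genes in both categories are excluded
#' first); the DEG-DSG overlap permutation test; optional exon
#' atomization; hub/neighbourhood edge lists; optional over-representation
#' of the DEG set. With `outdir` set, every table is persisted as TSV plus
#' a JSON summary and a parameter log; a fixed seed makes the whole bundle
#' byte-identical across runs.
#'
#' @param config an [pipeline_config()].
#' @param outdir output directory, or `NULL` to skip writing.
#' @return Invisible list with all intermediate results and the `summary`
#'   list.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "edanet_config"))
  log_lines <- c("edanet pipeline run",
                 sprintf("seed: %d", config$seed),
                 sprintf("tau: %g  alpha: %g  min_count: %d  mds_top: %d",
                         config$tau, config$alpha, config$min_count,
                         config$mds_top),
                 sprintf("beta: %s  maxPOutliers: %g  B: %d",
                         if (is.null(config$beta)) "auto" else config$beta,
                         config$max_p_outliers, config$perm_B))
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      if (!is.null(outdir)) {
        writeLines(c(log_lines, sprintf("FAILED at stage: %s (%s)", name,
                                        conditionMessage(e))),
                   file.path(outdir, "run.log"))
      }
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  # --- load or simulate -----------------------------------------------
  data <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- simulate_dataset(config$simulate)
      note("simulated dataset: %d genes x %d samples (seed %d)",
           nrow(sim$counts), ncol(sim$counts), config$simulate$seed)
      sim
    } else {
      counts <- read_counts(config$input$counts, "gene")
      exons <- read_counts(config$input$exons, "exon")
      samples <- read_sample_table(config$input$samples)
      lengths <- NULL
      if (!is.null(config$input$lengths)) {
        lt <- utils::read.delim(config$input$lengths,
                                stringsAsFactors = FALSE)
        lengths <- setNames(lt$length, lt$gene_id)
      }
      note("loaded dataset: %d genes x %d samples", nrow(counts),
           ncol(counts))
      list(counts = counts, exon_counts = exons, samples = samples,
           annotation = if (!is.null(lengths))
             tibble(gene_id = names(lengths), length = lengths) else NULL,
           truth = NULL)
    }
  })
  samples <- data$samples

  # --- filter / normalise ---------------------------------------------
  filtered <- stage("filter", filter_low_expression(
    data$counts, config$min_count, config$max_low_samples))
  note("filter: %d of %d genes kept", nrow(filtered), nrow(data$counts))
  ec <- stage("filter", filter_exons_by_gene(data$exon_counts,
                                             rownames(filtered)))
  factors <- stage("tmm", tmm_factors(filtered))
  logcpm <- stage("normalise", to_units(filtered, factors, "log2CPM"))

  # --- MDS -------------------------------------------------------------
  mds <- stage("mds", {
    d <- leading_logfc_distance(logcpm, config$mds_top)
    classical_mds(d, k = 2, samples = samples)
  })

  # --- differential expression ----------------------------------------
  de <- stage("de", de_analysis(filtered, samples, tau = config$tau,
                                alpha = config$alpha))
  for (ct in names(de$results)) {
    note("DE %s: %d genes at FDR < %g", ct,
         sum(!is.na(de$results[[ct]]$fdr) &
               de$results[[ct]]$fdr < config$alpha), config$alpha)
  }

  # --- differential exon usage ----------------------------------------
  splice <- stage("splice", splice_analysis(ec, samples,
                                            alpha = config$alpha))
  for (ct in names(splice$dsg_sets)) {
    note("DSG %s: %d genes (union rule)", ct,
         length(splice$dsg_sets[[ct]]))
  }

  # --- network ---------------------------------------------------------
  adjusted <- stage("adjust", adjust_family(logcpm, samples))
  net <- stage("network", build_network(
    adjusted, beta = config$beta, candidates = config$candidates,
    r2_cut = config$r2_cut, max_p_outliers = config$max_p_outliers,
    cut_height = config$cut_height, min_size = config$min_size,
    merge_cor = config$merge_cor))
  note("network: beta %d, %d modules, %d unassigned", net$beta,
       ncol(net$eigengenes), sum(net$labels == "M0"))

  # --- gene-set statistics (primary contrast LL vs CC) -----------------
  deg_set <- de$degs$sets[["LLvsCC"]]
  dsg_set <- splice$dsg_sets[["LLvsCC"]]
  both <- intersect(deg_set, dsg_set)
  deg_only <- setdiff(deg_set, both)
  dsg_only <- setdiff(dsg_set, both)
  note("LLvsCC: %d DEGs, %d DSGs, %d in both (excluded from medians)",
       length(deg_set), length(dsg_set), length(both))

  crosstab <- stage("crosstab",
                    crosstab_modules(deg_set, dsg_set, net$labels))

  k_total <- net$k_total
  tpm_values <- NULL
  if (!is.null(data$annotation)) {
    lengths <- setNames(data$annotation$length, data$annotation$gene_id)
    tpm <- to_units(filtered, factors, "TPM", lengths = lengths)
    tpm_values <- rowMeans(tpm)
  }
  perm <- stage("permtest", {
    res <- list()
    seeds <- config$seed + seq_len(8)
    vv <- list(k_total = k_total[names(k_total) %in% rownames(filtered)],
               tpm = tpm_values)
    i <- 0
    for (vn in names(vv)) {
      v <- vv[[vn]]
      if (is.null(v)) next
      ok <- function(s) length(s) > 0 && all(s %in% names(v))
      if (ok(deg_only) && ok(dsg_only)) {
        i <- i + 1
        res[[paste0(vn, "_deg_vs_dsg")]] <- perm_median_diff(
          v, deg_only, dsg_only, B = config$perm_B, seed = seeds[i])
      }
      if (ok(deg_only)) {
        i <- i + 1
        res[[paste0(vn, "_deg_vs_all")]] <- perm_median_diff(
          v, deg_only, NULL, B = config$perm_B, seed = seeds[i])
      }
      if (ok(dsg_only)) {
        i <- i + 1
        res[[paste0(vn, "_dsg_vs_all")]] <- perm_median_diff(
          v, dsg_only, NULL, B = config$perm_B, seed = seeds[i])
      }
    }
    res
  })
  overlap <- stage("overlap", {
    if (length(deg_set) > 0 && length(dsg_set) > 0) {
      perm_overlap(nrow(filtered), length(deg_set), length(dsg_set),
                   length(both), B = config$perm_B,
                   seed = config$seed + 99)
    } else NULL
  })

  # --- atomization / subnetworks / ORA --------------------------------
  atom <- stage("atomize", {
    if (is.null(config$atomize)) NULL else
      lapply(setNames(config$atomize, config$atomize), function(g)
        atomize_gene(g, ec, net, samples, factors,
                     colSums(ec$counts)))
  })
  hubs <- stage("subnetwork", {
    focal <- config$hub_focal
    if (is.null(focal)) {
      focal <- names(which.max(net$k_total))
      if ("M1" %in% net$labels) focal <- c(focal, "M1")
    }
    lapply(setNames(focal, focal), function(f)
      extract_subnetwork(net, f, config$hub_n))
  })
  ora_res <- stage("ora", {
    if (is.null(config$gmt) || length(deg_set) == 0) NULL else
      ora(read_gmt(config$gmt), deg_set, rownames(filtered))
  })

  summary <- list(
    n_genes_input = nrow(data$counts),
    n_genes_filtered = nrow(filtered),
    n_samples = ncol(filtered),
    deg_counts = lapply(de$degs$sets, length),
    dsg_counts = lapply(splice$dsg_sets, length),
    n_both = length(both),
    beta = net$beta,
    n_modules = ncol(net$eigengenes),
    n_unassigned = sum(net$labels == "M0"),
    median_k_total = unname(median(k_total)),
    perm = lapply(perm, function(x)
      list(observed = x$observed, exceed = x$exceed, B = x$B, p = x$p,
           p_display = x$p_display, seed = x$seed)),
    overlap = if (!is.null(overlap))
      list(observed = overlap$observed, p = overlap$p,
           p_display = overlap$p_display, p_exact = overlap$p_exact)
      else NULL,
    seed = config$seed
  )

  result <- list(data = data, filtered = filtered, factors = factors,
                 logcpm = logcpm, mds = mds, de = de, splice = splice,
                 adjusted = adjusted, network = net, crosstab = crosstab,
                 perm = perm, overlap = overlap, atomize = atom,
                 hubs = hubs, ora = ora_res, tpm_values = tpm_values,
                 summary = summary, log = log_lines)

  if (!is.null(outdir)) write_bundle(result, config, outdir)
  invisible(result)
}

# persist every pipeline table plus summary.json and run.log
write_bundle <- function(result, config, outdir) {
  wtsv <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(outdir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wtsv(result$mds, "mds.tsv")
  for (ct in names(result$de$results)) {
    wtsv(tidy(result$de$results[[ct]]), sprintf("de_%s.tsv", ct))
  }
  for (ct in names(result$splice$results)) {
    wtsv(result$splice$results[[ct]], sprintf("splice_%s.tsv", ct))
    wtsv(result$splice$exon_stats[[ct]], sprintf("exon_usage_%s.tsv", ct))
  }
  wtsv(result$network$module_table, "module_table.tsv")
  if (!is.null(result$network$sft)) {
    wtsv(result$network$sft$table, "soft_threshold.tsv")
  }
  wtsv(result$crosstab, "crosstab_modules.tsv")
  if (length(result$perm) > 0) {
    wtsv(purrr::imap_dfr(result$perm, function(x, nm)
      dplyr::mutate(tidy(x), comparison = nm, .before = 1)),
      "perm_tests.tsv")
  }
  if (!is.null(result$overlap)) wtsv(tidy(result$overlap), "overlap.tsv")
  for (g in names(result$atomize %||% list())) {
    wtsv(result$atomize[[g]], sprintf("atomize_%s.tsv", g))
  }
  for (f in names(result$hubs)) {
    wtsv(result$hubs[[f]]$edges, sprintf("edges_%s.tsv", f))
    wtsv(result$hubs[[f]]$nodes, sprintf("nodes_%s.tsv", f))
  }
  if (!is.null(result$ora)) wtsv(result$ora, "ora.tsv")
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$log, file.path(outdir, "run.log"))
  invisible(outdir)
}
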