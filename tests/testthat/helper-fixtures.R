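# Shared fixtures, computed once per session and memoised. The heavy
# simulations back both the unit tests and the acceptance checks.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# full-scale recovery dataset at the generator's default study conditions
recovery_sim <- function() {
  fixture("recovery_sim", function() {
    simulate_dataset(sim_config(seed = 20260901))
  })
}

recovery_filtered <- function() {
  fixture("recovery_filtered", function() {
    filter_low_expression(recovery_sim()$counts)
  })
}

recovery_de <- function() {
  fixture("recovery_de", function() {
    de_analysis(recovery_filtered(), recovery_sim()$samples)
  })
}

recovery_splice <- function() {
  fixture("recovery_splice", function() {
    sim <- recovery_sim()
    ec <- filter_exons_by_gene(sim$exon_counts,
                               rownames(recovery_filtered()))
    splice_analysis(ec, sim$samples, contrasts = list(c("LL", "CC")))
  })
}

recovery_network <- function() {
  fixture("recovery_network", function() {
    sim <- recovery_sim()
    f <- recovery_filtered()
    lc <- to_units(f, tmm_factors(f), "log2CPM")
    build_network(adjust_family(lc, sim$samples), beta = 14)
  })
}

# zero planted effects: no DEGs, no DSGs, no family offsets, no modules
null_sim <- function() {
  fixture("null_sim", function() {
    simulate_dataset(sim_config(n_deg = 0, n_dsg = 0, family_sd = 0,
                                n_modules = 0, module_size = 0,
                                seed = 20260902))
  })
}

null_de <- function() {
  fixture("null_de", function() {
    de_analysis(filter_low_expression(null_sim()$counts),
                null_sim()$samples)
  })
}

null_splice <- function() {
  fixture("null_splice", function() {
    sim <- null_sim()
    f <- filter_low_expression(sim$counts)
    ec <- filter_exons_by_gene(sim$exon_counts, rownames(f))
    splice_analysis(ec, sim$samples, contrasts = list(c("LL", "CC")))
  })
}

# small dataset for pipeline / io round trips
small_sim <- function(seed = 42, ...) {
  simulate_dataset(sim_config(n_genes = 200, n_modules = 2,
                              module_size = 40, n_deg = 30, n_dsg = 15,
                              seed = seed, ...))
}
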