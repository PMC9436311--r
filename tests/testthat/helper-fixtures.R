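# Shared fixtures: all tiny, generated in code.

tiny_panel <- function(n_genes = 4, seed = 1, ...) {
  build_gene_panel(n_genes = n_genes, seed = seed, ...)
}

# Mutation supply cranked far above the somatic rate so that desk-scale
# lattices yield enough clones for distributional tests.
hot_panel <- function(n_genes = 12, seed = 3, factor = 300) {
  p <- build_gene_panel(n_genes = n_genes, seed = seed)
  p$genes$mu_g <- p$genes$mu_g * factor
  p
}

tiny_config <- function(area = 0.01, ...) {
  sim_config(biopsy_area_mm2 = area, ...)
}

# A founder tissue where every cell already carries a driver genotype.
grafted_state <- function(config, panel, driver = c("notch1", "tp53"),
                          sites = NULL) {
  driver <- match.arg(driver)
  st <- init_tissue(config, panel)
  st$genotypes <- list(parent = c(0L, 1L),
                       has_notch1 = c(0L, as.integer(driver == "notch1")),
                       has_tp53 = c(0L, as.integer(driver == "tp53")))
  gene <- if (driver == "notch1") 1L else 2L
  st$mutations <- data.frame(gene = gene,
                             pos = st$panel$genes$start[gene] + 5L,
                             ref = 1L, alt = 3L, genotype = 2L,
                             birth_day = 0)
  if (is.null(sites)) st$occ[st$occ == 1L] <- 2L
  else st$occ[, , 1][sites] <- 2L
  st
}

# End-to-end clone-size sample from a small neutral run.
neutral_clone_sample <- function(seed, panel, config, days = 300,
                                 depth = depth_model(5, 100),
                                 cutoff = 0.005) {
  set.seed(seed)
  st <- init_tissue(config, panel)
  st <- run_epidermis(st, config, days)
  calls <- filter_calls(sequence_variants(mutation_table(st), depth), cutoff)
  list(state = st, calls = calls,
       sizes = if (nrow(calls)) clone_size_distribution(
         calls, config$biopsy_area_mm2, config$cell_size_um) else NULL)
}
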