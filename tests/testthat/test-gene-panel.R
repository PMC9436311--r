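test_that("default panel has 72 genes with consistent lengths and counts", {
  p <- build_gene_panel(seed = 1)
  g <- p$genes
  expect_equal(nrow(g), 72)
  expect_equal(g$end - g$start, g$nA + g$nC + g$nG + g$nT)
  expect_equal(sum(g$driver_class == "NOTCH1-like"), 1)
  expect_equal(sum(g$driver_class == "TP53-like"), 1)
  expect_true(all(g$mu_g > 0))
  expect_equal(panel_mean_rate(p), 3.2e-9, tolerance = 1e-12)
})

test_that("degenerate composition: GC = 0 leaves no C or G", {
  p <- build_gene_panel(n_genes = 1, lengths = 100, gc = 0, seed = 2)
  expect_equal(p$genes$nC, 0)
  expect_equal(p$genes$nG, 0)
  expect_equal(p$genes$nA + p$genes$nT, 100)
})

test_that("panel TSV round-trips and parser reports malformed rows", {
  p <- build_gene_panel(n_genes = 3, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_gene_panel(p, f)
  q <- read_gene_panel(f)
  expect_equal(q$genes$gene, p$genes$gene)
  expect_equal(q$genes$end - q$genes$start, p$genes$end - p$genes$start)
  expect_equal(q$genes$mu_g, p$genes$mu_g, tolerance = 1e-10)

  lines <- readLines(f)
  bad <- c(lines, "ONLY\tTHREE\tFIELDS")
  writeLines(bad, f)
  expect_error(read_gene_panel(f), "line 5")

  bad2 <- lines
  row <- strsplit(bad2[2], "\t")[[1]]
  row[3] <- row[4] # start == end
  bad2[2] <- paste(row, collapse = "\t")
  writeLines(bad2, f)
  expect_error(read_gene_panel(f), "end must exceed start")
})

test_that("rate normalization scales globally, hits the target exactly, and is idempotent", {
  p <- build_gene_panel(n_genes = 2, lengths = c(100, 300), seed = 1)
  p$genes$mu_g <- c(1e-9, 5e-9)
  target <- 3.2e-9
  q <- normalize_rates(p, target)
  # one global factor, solving sum(mu L)/sum(L) = target
  L <- c(100, 300)
  expected_factor <- target * sum(L) / sum(c(1e-9, 5e-9) * L)
  expect_equal(q$genes$mu_g / p$genes$mu_g, rep(expected_factor, 2))
  expect_equal(panel_mean_rate(q), target, tolerance = 1e-12)
  q2 <- normalize_rates(q, target)
  expect_equal(q2$genes$mu_g, q$genes$mu_g, tolerance = 1e-12)

  # uniform input rates end up equal to the target itself
  u <- p
  u$genes$mu_g <- c(7e-9, 7e-9)
  expect_equal(normalize_rates(u, target)$genes$mu_g, rep(target, 2))
  expect_error(normalize_rates(p, 0), "positive")
})

test_that("per-gene mutation counts are Poisson with mean mu_g * L_g", {
  p <- build_gene_panel(n_genes = 3, lengths = c(10000, 5000, 2000), seed = 1)
  p$genes$mu_g <- rep(3.2e-9, 3)
  lam <- 3.2e-9 * 10000
  set.seed(1)
  x <- draw_mutation_count(p, 1, n = 1e6)
  expect_lt(abs(mean(x) - lam), 3 * sqrt(lam / 1e6))
  set.seed(9)
  a <- draw_mutation_count(p, 2, n = 50)
  set.seed(9)
  b <- draw_mutation_count(p, 2, n = 50)
  expect_identical(a, b)
})

test_that("Poisson dispersion index is 1 at large draw counts", {
  p <- build_gene_panel(n_genes = 1, lengths = 50000, seed = 2)
  p$genes$mu_g <- 2e-5 # lambda = 1: dispersion measurable
  set.seed(3)
  x <- draw_mutation_count(p, 1, n = 1e5)
  expect_gt(var(x) / mean(x), 0.98)
  expect_lt(var(x) / mean(x), 1.02)
})

test_that("mutation events carry the cytosine-enriched signature", {
  p <- build_gene_panel(seed = 7)
  set.seed(11)
  ev <- draw_mutations(p, 1e5)
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(mean(ev$ref == "C") - 0.5), 3 * se)
  # C>T enrichment at the configured weight
  ct <- mean(ev$alt[ev$ref == "C"] == "T")
  expect_lt(abs(ct - 0.9), 3 * sqrt(0.09 / sum(ev$ref == "C")))
  expect_true(all(ev$ref != ev$alt))
  # positions lie within their gene
  gi <- match(ev$gene, p$genes$gene)
  expect_true(all(ev$pos >= p$genes$start[gi] & ev$pos < p$genes$end[gi]))
})

test_that("an all-cytosine gene always yields cytosine reference draws", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tchrom\tstart\tend\tnA\tnC\tnG\tnT\tmu_g\tdriver_class",
    "CGENE\tchrS\t0\t100\t0\t100\t0\t0\t3.2e-9\tpassenger"), f)
  p <- read_gene_panel(f)
  set.seed(1)
  ev <- draw_mutations(p, 500)
  expect_true(all(ev$ref == "C"))
})

test_that("a gene with two cytosines splits position draws evenly", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tchrom\tstart\tend\tnA\tnC\tnG\tnT\tmu_g\tdriver_class",
    "G2C\tchrS\t0\t100\t98\t2\t0\t0\t3.2e-9\tpassenger"), f)
  p <- read_gene_panel(f)
  set.seed(5)
  ev <- draw_mutations(p, 4e4)
  cpos <- ev$pos[ev$ref == "C"]
  expect_equal(sort(unique(cpos)), c(98L, 99L)) # block layout: C last
  frac <- mean(cpos == 98L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / length(cpos)))
})

test_that("genotype inheritance is nested with nondecreasing birth times", {
  p <- hot_panel(n_genes = 3, factor = 3e5) # several events per division
  store <- new_genotype_store()
  set.seed(2)
  chain <- 1L
  for (d in 1:6) chain <- c(chain, inherit_and_mutate(store, tail(chain, 1), p,
                                                      time = d))
  sets <- lapply(chain, genotype_mutations, store = store)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
  bt <- store$mutations$birth_day[order(store$mutations$id)]
  expect_true(!is.unsorted(bt))
})

test_that("inheritance flags drivers and preserves the parent set when quiet", {
  # near-zero rate: no de novo events, parent genotype id returned
  p <- tiny_panel(n_genes = 3)
  p$genes$mu_g[] <- 1e-15
  store <- new_genotype_store()
  set.seed(1)
  expect_identical(inherit_and_mutate(store, 1L, p), 1L)

  # all mutation mass on the NOTCH1-like gene: daughter gains the flag
  p2 <- tiny_panel(n_genes = 3)
  p2$genes$mu_g <- c(1e-2 / (p2$genes$end[1] - p2$genes$start[1]), 1e-18, 1e-18)
  store2 <- new_genotype_store()
  set.seed(4)
  gid <- 1L
  while (gid == 1L) gid <- inherit_and_mutate(store2, 1L, p2)
  expect_equal(store2$has_notch1[gid], 1L)
  expect_equal(store2$has_tp53[gid], 0L)
})

test_that("de novo totals follow the Poisson superposition over many divisions", {
  p <- tiny_panel(n_genes = 3)
  L <- p$genes$end - p$genes$start
  p$genes$mu_g <- 0.01 / L # lambda_tot = 0.03 per division
  lam_tot <- sum(p$genes$mu_g * L)
  store <- new_genotype_store()
  n_div <- 2e4
  set.seed(6)
  for (i in seq_len(n_div)) inherit_and_mutate(store, 1L, p, time = i)
  expect_lt(abs(nrow(store$mutations) - n_div * lam_tot),
            3 * sqrt(n_div * lam_tot))
})
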