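#' Build a gene panel for base-pair-resolution mutation tracking
#'
#' Constructs the per-gene mutation model: each gene has a genomic interval
#' (0-based, half-open, so length \code{L = end - start}), a synthetic base
#' sequence with a configurable GC fraction, and a gene-specific mutation
#' rate \code{mu_g} (substitutions per base pair per division). Rates are
#' drawn heterogeneously across genes and then normalised so that the
#' length-weighted mean equals \code{target_mu} (default
#' \eqn{3.2\times 10^{-9}}). One gene is labelled NOTCH1-like and one
#' TP53-like; these driver classes feed the selection mechanisms of the
#' tissue engine.
#'
#' @param n_genes number of genes (default 72).
#' @param lengths optional integer vector of gene lengths in bp; by default
#'   lengths are drawn log-uniformly between \code{min_length} and
#'   \code{max_length}.
#' @param gc GC fraction of the synthetic sequences (default 0.41).
#' @param target_mu target length-weighted mean mutation rate, per bp per
#'   division.
#' @param mu_sdlog log-scale standard deviation of the per-gene rate
#'   heterogeneity (lognormal; 0 gives uniform rates).
#' @param min_length,max_length bounds of the default length distribution.
#' @param base_weights multinomial weights for the reference base of a new
#'   mutation, in A, C, G, T order. The default puts probability 1/2 on
#'   cytosine and 1/6 on each remaining base, realising the UV-type
#'   C-enriched signature. Weights are renormalised per gene over the bases
#'   actually present.
#' @param alt_ct probability that a cytosine mutation is a C>T transition;
#'   the remainder is split evenly between C>A and C>G. Non-cytosine
#'   reference bases mutate uniformly to the three alternatives.
#' @param seed optional seed for reproducible panel construction.
#' @return an object of class \code{gene_panel}: a list with a \code{genes}
#'   data frame (gene, chrom, start, end, nA, nC, nG, nT, mu_g,
#'   driver_class) and the per-gene integer-coded sequences.
#' @examples
#' panel <- build_gene_panel(n_genes = 5, seed = 1)
#' panel$genes[, c("gene", "start", "end", "mu_g", "driver_class")]
#' @export
build_gene_panel <- function(n_genes = 72, lengths = NULL, gc = 0.41,
                             target_mu = 3.2e-9, mu_sdlog = 0.5,
                             min_length = 2000L, max_length = 120000L,
                             base_weights = c(A = 1 / 6, C = 1 / 2,
                                              G = 1 / 6, T = 1 / 6),
                             alt_ct = 0.9, seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  if (target_mu <= 0) stop("target_mu must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lengths)) {
    lengths <- as.integer(round(exp(runif(n_genes, log(min_length),
                                          log(max_length)))))
  }
  lengths <- as.integer(lengths)
  if (length(lengths) != n_genes) stop("lengths must have n_genes entries")
  if (any(lengths < 100L)) stop("gene lengths must be >= 100 bp")

  # synthetic sequences: iid bases with the requested GC fraction
  pbase <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2) # A C G T
  sequences <- lapply(lengths, function(L) {
    sample.int(4L, L, replace = TRUE, prob = pbase) - 1L
  })

  # lay genes head-to-tail on one synthetic chromosome with 10 kb gaps
  starts <- cumsum(c(0L, head(lengths, -1L) + 10000L))
  ends <- starts + lengths

  driver <- rep("passenger", n_genes)
  names_g <- sprintf("GENE%03d", seq_len(n_genes))
  if (n_genes >= 2) {
    driver[1] <- "NOTCH1-like"; names_g[1] <- "NOTCH1L"
    driver[2] <- "TP53-like"; names_g[2] <- "TP53L"
  }

  mu <- target_mu * exp(stats::rnorm(n_genes, 0, mu_sdlog))
  counts <- t(vapply(sequences, function(s) tabulate(s + 1L, 4L), integer(4)))

  genes <- data.frame(
    gene = names_g, chrom = "chrS",
    start = starts, end = ends,
    nA = counts[, 1], nC = counts[, 2], nG = counts[, 3], nT = counts[, 4],
    mu_g = mu, driver_class = driver,
    stringsAsFactors = FALSE)
  panel <- new_gene_panel(genes, sequences, base_weights, alt_ct)
  normalize_rates(panel, target_mu)
}

new_gene_panel <- function(genes, sequences, base_weights, alt_ct) {
  stopifnot(nrow(genes) == length(sequences))
  L <- genes$end - genes$start
  if (any(L != genes$nA + genes$nC + genes$nG + genes$nT))
    stop("base counts must sum to the gene length end - start")
  if (any(genes$mu_g <= 0)) stop("all mutation rates must be positive")
  bw <- base_weights / sum(base_weights)
  structure(list(genes = genes, sequences = sequences,
                 base_weights = bw, alt_ct = alt_ct),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  g <- x$genes
  cat(sprintf("<gene_panel> %d genes, %.3g Mb, mean rate %.3g /bp/division\n",
              nrow(g), sum(g$end - g$start) / 1e6, panel_mean_rate(x)))
  cat(sprintf("  drivers: %s\n",
              paste(g$gene[g$driver_class != "passenger"], collapse = ", ")))
  invisible(x)
}

#' Length-weighted mean mutation rate of a panel
#'
#' @param panel a \code{gene_panel}.
#' @return \eqn{\sum_g \mu_g L_g / \sum_g L_g}.
#' @export
panel_mean_rate <- function(panel) {
  L <- panel$genes$end - panel$genes$start
  sum(panel$genes$mu_g * L) / sum(L)
}

#' Normalise per-gene mutation rates to a target length-weighted mean
#'
#' All rates are scaled by a single global factor so that
#' \eqn{\sum_g \mu_g L_g / \sum_g L_g} equals \code{target_mean}. The
#' operation is idempotent.
#'
#' @param panel a \code{gene_panel}.
#' @param target_mean desired mean rate, per bp per division.
#' @return the panel with rescaled \code{mu_g}.
#' @export
normalize_rates <- function(panel, target_mean = 3.2e-9) {
  if (!inherits(panel, "gene_panel")) stop("panel must be a gene_panel")
  if (target_mean <= 0) stop("target_mean must be positive")
  panel$genes$mu_g <- panel$genes$mu_g * (target_mean / panel_mean_rate(panel))
  panel
}

#' Read a gene panel from a tab-separated table
#'
#' Expects a header row and columns gene, chrom, start, end, nA, nC, nG, nT,
#' mu_g, driver_class (0-based half-open coordinates). Since only base
#' counts are stored, a deterministic synthetic sequence consistent with the
#' counts is laid out per gene (contiguous blocks of A, C, G, T): the model
#' only requires a uniform draw among positions of the reference base, so
#' the layout is immaterial to the statistics but keeps reloads reproducible.
#'
#' @param file path to the TSV.
#' @param base_weights,alt_ct signature parameters, as in
#'   \code{\link{build_gene_panel}}.
#' @return a \code{gene_panel}.
#' @export
read_gene_panel <- function(file, base_weights = c(A = 1 / 6, C = 1 / 2,
                                                   G = 1 / 6, T = 1 / 6),
                            alt_ct = 0.9) {
  lines <- readLines(file)
  if (length(lines) < 2) stop("panel file has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("gene", "chrom", "start", "end", "nA", "nC", "nG", "nT",
            "mu_g", "driver_class")
  if (!identical(header, need))
    stop("panel header must be: ", paste(need, collapse = ", "))
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(need))
      stop(sprintf("malformed panel row at line %d: expected %d columns, got %d",
                   i, length(need), length(f)))
    st <- as.numeric(f[3]); en <- as.numeric(f[4])
    if (is.na(st) || is.na(en) || en <= st)
      stop(sprintf("malformed panel row at line %d: end must exceed start", i))
    f
  })
  m <- do.call(rbind, rows)
  genes <- data.frame(
    gene = m[, 1], chrom = m[, 2],
    start = as.integer(m[, 3]), end = as.integer(m[, 4]),
    nA = as.integer(m[, 5]), nC = as.integer(m[, 6]),
    nG = as.integer(m[, 7]), nT = as.integer(m[, 8]),
    mu_g = as.numeric(m[, 9]), driver_class = m[, 10],
    stringsAsFactors = FALSE)
  L <- genes$end - genes$start
  if (any(L != genes$nA + genes$nC + genes$nG + genes$nT))
    stop("base counts must sum to end - start for every gene")
  sequences <- lapply(seq_len(nrow(genes)), function(i) {
    rep(0:3, times = c(genes$nA[i], genes$nC[i], genes$nG[i], genes$nT[i]))
  })
  new_gene_panel(genes, sequences, base_weights, alt_ct)
}

#' Write a gene panel to a tab-separated table
#'
#' @param panel a \code{gene_panel}.
#' @param file output path.
#' @export
write_gene_panel <- function(panel, file) {
  write.table(panel$genes, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

# Internal: per-gene list of genomic coordinates holding each base, and the
# per-gene cumulative reference-base probabilities (weights renormalised over
# bases present in the gene). Cached on the panel by the engine wrappers.
panel_positions <- function(panel) {
  lapply(seq_along(panel$sequences), function(i) {
    s <- panel$sequences[[i]]
    coords <- panel$genes$start[i] + seq_along(s) - 1L
    lapply(0:3, function(b) coords[s == b])
  })
}

panel_base_cum <- function(panel) {
  counts <- as.matrix(panel$genes[, c("nA", "nC", "nG", "nT")])
  w <- matrix(panel$base_weights, nrow(counts), 4, byrow = TRUE)
  w[counts == 0] <- 0
  if (any(rowSums(w) == 0)) stop("gene with no usable bases in the panel")
  w <- w / rowSums(w)
  t(apply(w, 1, cumsum))
}

# Internal: the flat list handed to the C++ engine.
panel_for_engine <- function(panel) {
  L <- panel$genes$end - panel$genes$start
  drv <- match(panel$genes$driver_class,
               c("passenger", "NOTCH1-like", "TP53-like")) - 1L
  if (anyNA(drv))
    stop("driver_class must be one of passenger, NOTCH1-like, TP53-like")
  list(lambda = panel$genes$mu_g * L,
       base_cum = panel_base_cum(panel),
       pos_by_base = panel_positions(panel),
       driver = drv,
       alt_ct = panel$alt_ct)
}

#' Draw per-division mutation counts for one gene
#'
#' The number of new mutations a daughter cell acquires in gene \eqn{g} at a
#' division is Poisson with mean \eqn{\mu_g L_g}.
#'
#' @param panel a \code{gene_panel}.
#' @param gene gene name or row index.
#' @param n number of draws.
#' @return integer vector of counts.
#' @export
draw_mutation_count <- function(panel, gene, n = 1) {
  i <- if (is.character(gene)) match(gene, panel$genes$gene) else as.integer(gene)
  if (is.na(i) || i < 1 || i > nrow(panel$genes)) stop("unknown gene")
  L <- panel$genes$end[i] - panel$genes$start[i]
  rpois(n, panel$genes$mu_g[i] * L)
}

#' Draw de novo mutation events from a panel
#'
#' Vectorised sampler for substitution events: the gene is chosen with
#' probability proportional to its mutation mass \eqn{\mu_g L_g}, the
#' reference base by the cytosine-enriched multinomial (renormalised over
#' bases present in the gene), the position uniformly among positions
#' carrying that base, and the alternate base by the substitution model
#' (C>T with probability \code{alt_ct} for cytosine, uniform otherwise).
#'
#' @param panel a \code{gene_panel}.
#' @param n number of events.
#' @param time birth time (simulated days) stamped on the events.
#' @return data frame with id, gene, chrom, pos, ref, alt, birth_day.
#' @export
draw_mutations <- function(panel, n, time = 0) {
  stopifnot(n >= 1)
  lam <- panel$genes$mu_g * (panel$genes$end - panel$genes$start)
  gi <- sample.int(nrow(panel$genes), n, replace = TRUE, prob = lam)
  cum <- panel_base_cum(panel)
  u <- runif(n)
  ref <- 4L - (u <= cum[cbind(gi, 1)]) - (u <= cum[cbind(gi, 2)]) -
    (u <= cum[cbind(gi, 3)])
  pos <- integer(n)
  posidx <- panel_positions(panel)
  key <- paste(gi, ref)
  for (k in unique(key)) {
    sel <- which(key == k)
    g1 <- gi[sel[1]]; b1 <- ref[sel[1]]
    v <- posidx[[g1]][[b1]]
    pos[sel] <- v[sample.int(length(v), length(sel), replace = TRUE)]
  }
  bases <- c("A", "C", "G", "T")
  alt <- integer(n)
  isC <- ref == 2L
  if (any(isC)) {
    toT <- runif(sum(isC)) < panel$alt_ct
    altC <- ifelse(toT, 4L, ifelse(runif(sum(isC)) < 0.5, 1L, 3L))
    alt[isC] <- altC
  }
  if (any(!isC)) {
    r <- ref[!isC]
    a <- sample.int(3L, sum(!isC), replace = TRUE)
    alt[!isC] <- ifelse(a >= r, a + 1L, a)
  }
  data.frame(id = seq_len(n),
             gene = panel$genes$gene[gi],
             chrom = panel$genes$chrom[gi],
             pos = pos,
             ref = bases[ref], alt = bases[alt],
             birth_day = time,
             stringsAsFactors = FALSE)
}

#' Create an empty genotype store
#'
#' A genotype is an immutable set of mutations shared through parent
#' pointers: a child genotype holds its parent's mutations plus its own de
#' novo events. The store starts with genotype 1, the mutation-free founder.
#'
#' @return an environment-backed store of class \code{genotype_store}.
#' @export
new_genotype_store <- function() {
  e <- new.env(parent = emptyenv())
  e$parent <- 0L
  e$has_notch1 <- 0L
  e$has_tp53 <- 0L
  e$mutations <- data.frame(id = integer(), gene = character(),
                            pos = integer(), ref = character(),
                            alt = character(), birth_day = numeric(),
                            genotype = integer(), stringsAsFactors = FALSE)
  class(e) <- "genotype_store"
  e
}

#' Inherit a parent genotype and add de novo mutations
#'
#' Called once per daughter cell per division: the daughter receives every
#' ancestral mutation (by reference, through the parent pointer) plus
#' \eqn{\sum_g X_g} new events with \eqn{X_g \sim Poisson(\mu_g L_g)}.
#' When no new event occurs the parent genotype id is returned unchanged.
#'
#' @param store a \code{genotype_store}.
#' @param parent parent genotype id (1 is the founder).
#' @param panel a \code{gene_panel}.
#' @param time birth time in simulated days.
#' @return the daughter's genotype id.
#' @export
inherit_and_mutate <- function(store, parent, panel, time = 0) {
  stopifnot(inherits(store, "genotype_store"))
  if (parent < 1 || parent > length(store$parent)) stop("unknown parent genotype")
  n <- sum(rpois(nrow(panel$genes),
                 panel$genes$mu_g * (panel$genes$end - panel$genes$start)))
  if (n == 0) return(parent)
  ev <- draw_mutations(panel, n, time = time)
  gid <- length(store$parent) + 1L
  ev$id <- nrow(store$mutations) + seq_len(n)
  ev$genotype <- gid
  ev$chrom <- NULL
  store$parent <- c(store$parent, as.integer(parent))
  drv <- panel$genes$driver_class[match(ev$gene, panel$genes$gene)]
  store$has_notch1 <- c(store$has_notch1,
                        max(store$has_notch1[parent],
                            as.integer(any(drv == "NOTCH1-like"))))
  store$has_tp53 <- c(store$has_tp53,
                      max(store$has_tp53[parent],
                          as.integer(any(drv == "TP53-like"))))
  store$mutations <- rbind(store$mutations, ev)
  gid
}

#' Mutations carried by a genotype
#'
#' @param store a \code{genotype_store}.
#' @param id genotype id.
#' @return integer vector of mutation ids, ancestral first.
#' @export
genotype_mutations <- function(store, id) {
  ids <- integer()
  while (id >= 1) {
    ids <- c(store$mutations$id[store$mutations$genotype == id], ids)
    id <- store$parent[id]
  }
  sort(ids)
}
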