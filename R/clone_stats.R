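#' Per-mutation summary of a tissue state
#'
#' Every recorded substitution is an intrinsic cell-fate marker: a cell
#' carries a mutation if the mutation arose in the cell's genotype or in
#' any ancestral genotype. Cell counts are obtained by accumulating the
#' per-genotype occupancy up the genotype tree, and true variant allele
#' frequencies follow as \code{n_cells / (2 N)}.
#'
#' @param state an \code{epidermis_state}.
#' @param drop_extinct drop mutations no longer carried by any cell.
#' @return data frame with id, gene, chrom, pos, ref, alt, birth_day,
#'   driver_class, n_cells, vaf_true.
#' @export
mutation_table <- function(state, drop_extinct = TRUE) {
  m <- state$mutations
  panel <- state$panel
  n_geno <- length(state$genotypes$parent)
  counts <- tabulate(state$occ[state$occ > 0], nbins = n_geno)
  parent <- state$genotypes$parent
  if (n_geno >= 2)
    for (g in n_geno:2) {
      p <- parent[g]
      if (p >= 1) counts[p] <- counts[p] + counts[g]
    }
  n_total <- sum(state$occ > 0)
  bases <- c("A", "C", "G", "T")
  out <- data.frame(
    id = seq_len(nrow(m)),
    gene = panel$genes$gene[m$gene],
    chrom = panel$genes$chrom[m$gene],
    pos = m$pos,
    ref = bases[m$ref + 1L], alt = bases[m$alt + 1L],
    birth_day = m$birth_day,
    driver_class = panel$genes$driver_class[m$gene],
    n_cells = if (nrow(m)) counts[m$genotype] else integer(0),
    stringsAsFactors = FALSE)
  out$vaf_true <- if (n_total > 0) true_vaf(out$n_cells, n_total) else 0
  if (drop_extinct) out <- out[out$n_cells > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Physical clone area from a variant allele frequency
#'
#' A clone occupying a fraction \code{2 * VAF} of a biopsy of area \code{B}
#' square millimetres has area \code{2 * VAF * B}, clamped at \code{B}
#' (sequencing noise can push a VAF above 0.5).
#'
#' @param vaf variant allele frequency in [0, 1].
#' @param B biopsy area in square millimetres.
#' @return clone area in square millimetres.
#' @examples
#' clone_area(0.005, 3.14) # smallest observable clone in the largest biopsy
#' @export
clone_area <- function(vaf, B) {
  if (any(vaf < 0) || any(vaf > 1)) stop("vaf must lie in [0, 1]")
  if (any(B <= 0)) stop("B must be positive")
  pmin(2 * vaf * B, B)
}

#' Clone-size distribution of a filtered variant table
#'
#' Converts simulated VAFs into clone areas and discrete clone sizes in
#' units of one cell footprint (\code{cell_size_um^2}), the discrete size
#' variable of the neutral-drift theory.
#'
#' @param calls a variant-call table (normally after
#'   \code{\link{filter_calls}}) with a \code{vaf_sim} column, or a numeric
#'   vector of VAFs.
#' @param B biopsy area in square millimetres.
#' @param cell_size_um cell edge length in micrometres.
#' @return an object of class \code{clone_sizes}: list with areas_mm2,
#'   cells (integer sizes, floored at 1), B and the mean clone size.
#' @export
clone_size_distribution <- function(calls, B, cell_size_um = 15) {
  vaf <- if (is.numeric(calls)) calls else calls$vaf_sim
  if (length(vaf) == 0) stop("no clones in the table")
  areas <- clone_area(vaf, B)
  footprint <- (cell_size_um / 1000)^2
  cells <- pmax(1L, as.integer(round(areas / footprint)))
  structure(list(areas_mm2 = areas, cells = cells, B = B,
                 mean_size = mean(cells)),
            class = "clone_sizes")
}

#' Neutral-drift clone-size probability
#'
#' For a neutrally drifting progenitor population with loss/replacement
#' rate \code{r_lambda} (per week), the probability that a surviving clone
#' has discrete size \code{n} at age \code{t} weeks is
#' \deqn{P_n(t) = \frac{1}{\ln(r_\lambda t)} \frac{e^{-n/(r_\lambda t)}}{n}.}
#' Defined for \code{r_lambda * t > 1}.
#'
#' @param n clone sizes (positive integers); vectorised.
#' @param r_lambda basal progenitor loss/replacement rate per week.
#' @param t_weeks age in weeks.
#' @return probabilities.
#' @export
neutral_clone_pmf <- function(n, r_lambda = 0.51, t_weeks) {
  rt <- r_lambda * t_weeks
  if (rt <= 1) stop("r_lambda * t must exceed 1")
  if (any(n < 1)) stop("clone sizes must be >= 1")
  exp(-n / rt) / n / log(rt)
}

#' First incomplete moment of a clone-size sample
#'
#' The normalised upper partial expectation
#' \deqn{\mu_1(n) = \frac{1}{\langle n \rangle} \sum_{m \ge n} m \hat P(m)}
#' computed from the empirical size distribution: the fraction of total
#' clone mass held by clones of size at least \code{n}. It equals 1 at the
#' minimum size, is nonincreasing, and is log-linear in \code{n} with
#' slope \eqn{-\beta} (for large \eqn{\beta n}) when sizes are exponential
#' with rate \eqn{\beta} — the neutral-drift expectation.
#'
#' @param sizes a numeric vector of clone sizes, or a \code{clone_sizes}
#'   object (its discrete cell counts are used).
#' @param n_grid evaluation grid; defaults to the sorted unique sizes.
#' @return data frame with columns n and mu1.
#' @export
first_incomplete_moment <- function(sizes, n_grid = NULL) {
  x <- if (inherits(sizes, "clone_sizes")) sizes$cells else sizes
  if (length(x) < 1) stop("empty clone-size distribution")
  if (any(x <= 0)) stop("clone sizes must be positive")
  if (is.null(n_grid)) n_grid <- sort(unique(x))
  tot <- sum(x)
  mu1 <- vapply(n_grid, function(n) sum(x[x >= n]) / tot, numeric(1))
  data.frame(n = n_grid, mu1 = mu1)
}

# Asymptotic two-sample Kolmogorov-Smirnov critical coefficient
# c(alpha) = sqrt(-log(alpha/2)/2); c(0.05) = 1.358.
ks_coefficient <- function(alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  sqrt(-log(alpha / 2) / 2)
}

#' Two-sample Kolmogorov-Smirnov comparison with critical-value decision
#'
#' Computes the two-sample statistic
#' \eqn{D_{m,n} = \sup_x |F_a(x) - F_b(x)|} over the pooled sample and the
#' asymptotic critical value
#' \eqn{D_\alpha = c(\alpha)\sqrt{(m+n)/(mn)}} with
#' \eqn{c(0.05) = 1.358}; the null (one common distribution) is rejected
#' iff \eqn{D_{m,n} > D_\alpha}. The signed excess \eqn{D_{m,n} - D_\alpha}
#' is also returned.
#'
#' @param a,b numeric samples (e.g. clone sizes), or \code{clone_sizes}
#'   objects.
#' @param alpha significance level.
#' @return list with d_stat, d_crit, excess and reject.
#' @export
ks_compare <- function(a, b, alpha = 0.05) {
  xa <- if (inherits(a, "clone_sizes")) a$cells else a
  xb <- if (inherits(b, "clone_sizes")) b$cells else b
  m <- length(xa); n <- length(xb)
  if (m == 0 || n == 0) stop("both samples must be nonempty")
  pooled <- sort(unique(c(xa, xb)))
  fa <- vapply(pooled, function(t) sum(xa <= t), numeric(1)) / m
  fb <- vapply(pooled, function(t) sum(xb <= t), numeric(1)) / n
  d <- max(abs(fa - fb))
  dcrit <- ks_coefficient(alpha) * sqrt((m + n) / (m * n))
  list(d_stat = d, d_crit = dcrit, excess = d - dcrit, reject = d > dcrit)
}

#' Clone size and age summary by driver class
#'
#' Bins mutations by age (simulation end minus birth time) and reports,
#' per age bin and driver class, the clone count and the median and upper
#' quantile of clone area.
#'
#' @param mutations a table with columns birth_day, driver_class and
#'   area_mm2 (e.g. a \code{\link{mutation_table}} joined with
#'   \code{\link{clone_area}}).
#' @param end_day simulation end time in days.
#' @param age_breaks_years age bin edges in years.
#' @param upper upper quantile to report (default 0.9).
#' @return data frame with age_bin, driver_class, n, median_area_mm2,
#'   upper_area_mm2. Driver classes absent from the table yield no rows.
#' @export
age_size_summary <- function(mutations, end_day,
                             age_breaks_years = c(0, 1, 5, 10, 20, 60),
                             upper = 0.9) {
  if (nrow(mutations) == 0)
    return(data.frame(age_bin = character(), driver_class = character(),
                      n = integer(), median_area_mm2 = numeric(),
                      upper_area_mm2 = numeric()))
  age <- (end_day - mutations$birth_day) / 365
  bin <- cut(age, breaks = age_breaks_years, include.lowest = TRUE)
  key <- data.frame(bin = bin, class = mutations$driver_class,
                    stringsAsFactors = FALSE)
  uk <- unique(key)
  uk <- uk[order(uk$bin, uk$class), , drop = FALSE]
  rows <- lapply(seq_len(nrow(uk)), function(j) {
    i <- which(key$bin == uk$bin[j] & key$class == uk$class[j])
    data.frame(age_bin = as.character(uk$bin[j]),
               driver_class = uk$class[j],
               n = length(i),
               median_area_mm2 = median(mutations$area_mm2[i]),
               upper_area_mm2 = unname(quantile(mutations$area_mm2[i], upper)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
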