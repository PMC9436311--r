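#' True variant allele frequency of a clone
#'
#' For a diploid genome with copy number untracked, a heterozygous somatic
#' mutation carried by \code{n_cells} of \code{n_total} cells has true
#' variant allele frequency \eqn{n / (2N)}.
#'
#' @param n_cells cells carrying the mutation.
#' @param n_total total population size.
#' @return the true VAF in [0, 0.5].
#' @examples
#' true_vaf(30000, 120000) # 0.125
#' @export
true_vaf <- function(n_cells, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_cells < 0) || any(n_cells > n_total))
    stop("n_cells must lie in [0, n_total]")
  n_cells / (2 * n_total)
}

#' Gamma read-depth model
#'
#' Per-variant sequencing depths are modelled as gamma draws with shape
#' \code{kp} and scale \code{theta_p}; the mean depth is
#' \code{kp * theta_p}.
#'
#' @param shape,scale gamma parameters, both positive.
#' @return an object of class \code{depth_model}.
#' @export
depth_model <- function(shape, scale) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  structure(list(shape = shape, scale = scale), class = "depth_model")
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf("<depth_model> Gamma(shape = %.4g, scale = %.4g), mean depth %.1f\n",
              x$shape, x$scale, x$shape * x$scale))
  invisible(x)
}

#' Fit the gamma depth model by maximum likelihood
#'
#' Fits shape and scale to observed per-variant read depths by gamma
#' maximum likelihood (via \code{MASS::fitdistr}, which starts from the
#' moment estimates).
#'
#' @param depth_samples positive read depths, at least 30 of them.
#' @return a \code{\link{depth_model}}.
#' @export
fit_depth_model <- function(depth_samples) {
  if (length(depth_samples) < 30) stop("need at least 30 depth samples")
  if (any(depth_samples <= 0)) stop("depths must be positive")
  if (stats::sd(depth_samples) == 0)
    stop("degenerate (constant) depth samples: use a moment fit instead")
  # optimiser probes of invalid (negative) parameters raise NaN warnings
  fit <- suppressWarnings(MASS::fitdistr(as.numeric(depth_samples), "gamma"))
  depth_model(shape = unname(fit$estimate["shape"]),
              scale = 1 / unname(fit$estimate["rate"]))
}

#' Simulate sequencing of a variant table
#'
#' For each variant with true frequency \code{vaf_true}: the read depth is
#' a gamma draw rounded to the nearest integer with floor 1, the variant
#' read count is binomial(depth, vaf_true), and the simulated frequency is
#' their ratio.
#'
#' @param variants a data frame with a \code{vaf_true} column (and
#'   optionally an \code{id}); or the output of
#'   \code{\link{mutation_table}}.
#' @param model a \code{\link{depth_model}}.
#' @return the input with added columns depth, alt_reads, vaf_sim.
#' @export
sequence_variants <- function(variants, model) {
  stopifnot(inherits(model, "depth_model"))
  if (!"vaf_true" %in% names(variants)) stop("variants need a vaf_true column")
  v <- variants$vaf_true
  if (any(v < 0 | v > 1)) stop("vaf_true must lie in [0, 1]")
  n <- length(v)
  depth <- pmax(1L, as.integer(round(rgamma(n, shape = model$shape,
                                            scale = model$scale))))
  alt <- rbinom(n, depth, v)
  variants$depth <- depth
  variants$alt_reads <- alt
  variants$vaf_sim <- alt / depth
  variants
}

#' Filter a variant-call table on simulated VAF
#'
#' Rows with \code{vaf_sim} below the cutoff are removed; the boundary
#' value itself is kept (the cutoff is the lowest observable frequency).
#'
#' @param calls a table from \code{\link{sequence_variants}}.
#' @param cutoff minimum simulated VAF (default 0.005).
#' @return the filtered table.
#' @export
filter_calls <- function(calls, cutoff = 0.005) {
  if (!"vaf_sim" %in% names(calls)) stop("calls need a vaf_sim column")
  calls[calls$vaf_sim >= cutoff, , drop = FALSE]
}

#' Write / read a variant-call table
#'
#' Plain tab-separated dialect with a header row; patient VAF tables in
#' the same dialect can be read back for comparisons.
#'
#' @param calls a variant-call data frame.
#' @param file path.
#' @export
write_variant_calls <- function(calls, file) {
  write.table(calls, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_variant_calls
#' @export
read_variant_calls <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}
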