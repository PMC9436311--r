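#' Run a seeded simulation experiment
#'
#' Orchestrates complete runs of the tissue engine over a parameter grid:
#' for every (f0, theta_s) pair and every replicate seed, the tissue is
#' initialised, burnt in under neutral dynamics, run for the requested
#' duration with selection active, and summarised (population series,
#' mutation table, sequenced variant calls, clone sizes, and the departure
#' from homeostasis against a matched neutral reference). When
#' \code{out_dir} is given, per-replicate TSV bundles and a manifest are
#' written.
#'
#' @param mode one of "neutral", "notch1", "tp53", "combined", "scan".
#'   "scan" delegates to \code{\link{scan_uv_parameters}}.
#' @param seeds integer vector of replicate seeds.
#' @param f0_grid,theta_grid parameter grids (scalars for single-driver
#'   modes; ignored where the mode fixes them to 0).
#' @param config a \code{\link{sim_config}}.
#' @param panel a gene panel.
#' @param schedule a \code{\link{sun_schedule}} (used when theta_s > 0).
#' @param years simulated duration after burn-in.
#' @param burnin_years neutral burn-in before selection starts.
#' @param depth a \code{\link{depth_model}} for virtual sequencing.
#' @param vaf_cutoff VAF filter applied before clone statistics.
#' @param out_dir optional output directory for TSV bundles.
#' @param ... passed to \code{\link{scan_uv_parameters}} in scan mode.
#' @return a list of per-run results (invisible in scan mode: the scan
#'   table).
#' @export
run_experiment <- function(mode = c("neutral", "notch1", "tp53", "combined",
                                    "scan"),
                           seeds = 1L, f0_grid = 0, theta_grid = 0,
                           config = sim_config(), panel = NULL,
                           schedule = sun_schedule(n = 12), years = 2,
                           burnin_years = 1, depth = depth_model(5, 100),
                           vaf_cutoff = 0.005, out_dir = NULL, ...) {
  mode <- match.arg(mode)
  if (anyDuplicated(seeds)) stop("replicate seeds must be unique")
  if (mode == "scan") return(scan_uv_parameters(...))
  if (is.null(panel)) panel <- build_gene_panel(seed = 1)
  grid <- switch(mode,
    neutral = data.frame(f0 = 0, theta_s = 0),
    notch1 = data.frame(f0 = f0_grid, theta_s = 0),
    tp53 = data.frame(f0 = 0, theta_s = theta_grid),
    combined = expand.grid(f0 = f0_grid, theta_s = theta_grid))
  if (nrow(grid) == 0) stop("empty parameter grid for mode ", mode)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  runs <- list()
  for (si in seq_along(seeds)) {
    for (gi in seq_len(nrow(grid))) {
      sel <- selection_params(f0 = grid$f0[gi], theta_s = grid$theta_s[gi])
      tag <- sprintf("seed%d_f0_%g_th_%g", seeds[si], sel$f0, sel$theta_s)
      res <- simulate_biopsy(config, panel, seed = seeds[si],
                             years = years, burnin_years = burnin_years,
                             selection = sel, schedule = schedule,
                             depth = depth, vaf_cutoff = vaf_cutoff)
      if (!is.null(out_dir)) {
        write.table(res$state$series,
                    file.path(out_dir, paste0(tag, "_series.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write_variant_calls(res$calls,
                            file.path(out_dir, paste0(tag, "_calls.tsv")))
      }
      runs[[tag]] <- res
    }
  }
  # departure from homeostasis against the first neutral-equivalent run
  ref <- NULL
  for (r in runs) if (r$selection$f0 == 0 && r$selection$theta_s == 0) {
    ref <- r; break
  }
  if (is.null(ref)) ref <- runs[[1]]
  for (tag in names(runs)) {
    n <- min(nrow(ref$state$series), nrow(runs[[tag]]$state$series))
    runs[[tag]]$dH <- departure_from_homeostasis(
      head(ref$state$series$total, n), head(runs[[tag]]$state$series$total, n))
  }
  if (!is.null(out_dir)) {
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- data.frame(file = basename(files),
                           md5 = vapply(files, function(f)
                             unname(tools::md5sum(f)), character(1)))
    write.table(manifest, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(runs)
}

#' Simulate one biopsy end to end
#'
#' Initialise, burn in neutrally, run with selection, then sequence and
#' filter the resulting mutations.
#'
#' @inheritParams run_experiment
#' @param seed master seed of the replicate.
#' @param selection a \code{\link{selection_params}}.
#' @return list with state, selection, the mutation table, the sequenced
#'   calls (filtered) and the clone-size distribution (NULL when no clone
#'   survives the filter).
#' @export
simulate_biopsy <- function(config, panel, seed, years = 2, burnin_years = 1,
                            selection = selection_params(),
                            schedule = sun_schedule(),
                            depth = depth_model(5, 100),
                            vaf_cutoff = 0.005) {
  set.seed(seed)
  state <- init_tissue(config, panel)
  if (burnin_years > 0)
    state <- run_epidermis(state, config, round(365 * burnin_years))
  state <- run_epidermis(state, config, round(365 * years), selection,
                         schedule)
  muts <- mutation_table(state)
  calls <- filter_calls(sequence_variants(muts, depth), vaf_cutoff)
  sizes <- if (nrow(calls) > 0)
    clone_size_distribution(calls, config$biopsy_area_mm2,
                            config$cell_size_um) else NULL
  list(state = state, selection = selection, mutations = muts,
       calls = calls, clone_sizes = sizes)
}

#' Calibrate the neutral engine against tissue targets
#'
#' Grid search over the division/death response amplitudes: short pilot
#' runs score each candidate by the squared relative error to the target
#' density (cells per square millimetre) and basal loss/replacement rate
#' (per basal cell per week), and the best configuration is returned with
#' its achieved values attached.
#'
#' @param targets named vector with \code{density} (cells/mm^2) and
#'   \code{loss_rate} (/week).
#' @param config starting \code{\link{sim_config}}.
#' @param panel a gene panel.
#' @param p_max_grid,d_max_grid candidate response amplitudes.
#' @param pilot_days duration of each pilot run.
#' @param seed pilot seed.
#' @param tol_frac acceptable relative error on each target; exceeding it
#'   raises a calibration failure reporting the best candidate found.
#' @return the calibrated \code{sim_config} with attribute
#'   \code{"achieved"}.
#' @export
calibrate <- function(targets = c(density = 120000, loss_rate = 0.51),
                      config = sim_config(biopsy_area_mm2 = 0.04),
                      panel = NULL,
                      p_max_grid = config$p_max * c(0.8, 1, 1.25),
                      d_max_grid = config$d_max * c(0.8, 1, 1.25),
                      pilot_days = 540, seed = 1, tol_frac = 0.2) {
  if (any(targets <= 0)) stop("targets must be positive")
  if (is.null(panel)) panel <- build_gene_panel(n_genes = 3, seed = 1)
  best <- NULL
  for (pm in p_max_grid) for (dm in d_max_grid) {
    cand <- config
    cand$p_max <- pm
    cand$d_max <- dm
    set.seed(seed)
    st <- init_tissue(cand, panel)
    st <- run_epidermis(st, cand, pilot_days)
    window <- min(180, pilot_days %/% 2)
    dens <- measure_density(st, cand, last_days = window)
    loss <- measure_basal_loss_rate(st, cand, last_days = window)
    err <- ((dens - targets["density"]) / targets["density"])^2 +
      ((loss - targets["loss_rate"]) / targets["loss_rate"])^2
    if (is.null(best) || err < best$err)
      best <- list(config = cand, err = err,
                   achieved = c(density = dens, loss_rate = loss))
  }
  rel <- abs(best$achieved - targets) / targets
  if (any(rel > tol_frac))
    stop(sprintf(paste0("calibration failed: best candidate achieved ",
                        "density %.0f /mm^2 and loss rate %.3f /week ",
                        "(targets %.0f, %.3f)"),
                 best$achieved["density"], best$achieved["loss_rate"],
                 targets["density"], targets["loss_rate"]))
  out <- best$config
  attr(out, "achieved") <- best$achieved
  out
}

#' Generate the package's reference fixtures
#'
#' Writes a small deterministic bundle used by examples and tests: the
#' default 72-gene synthetic panel, a depth-sample file drawn from a known
#' gamma distribution, and a 10-variant VAF table whose clone areas are
#' hand-checkable as \code{2 * VAF * B}.
#'
#' @param dir output directory.
#' @param seed fixture seed.
#' @return (invisibly) the paths written.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  paths <- character(0)
  panel <- build_gene_panel(seed = seed)
  paths <- c(paths, write_gene_panel(panel, file.path(dir, "panel72.tsv")))
  depths <- rgamma(2000, shape = 5, scale = 100)
  f <- file.path(dir, "depth_samples.tsv")
  write.table(data.frame(depth = depths), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, f)
  vafs <- c(0.005, 0.008, 0.01, 0.02, 0.05, 0.1, 0.15, 0.25, 0.4, 0.5)
  tab <- data.frame(id = seq_along(vafs),
                    gene = sprintf("GENE%03d", seq_along(vafs)),
                    vaf_sim = vafs,
                    area_mm2 = clone_area(vafs, B = 1))
  f <- file.path(dir, "vaf_fixture.tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)
  invisible(paths)
}

#' Read a flat key/value simulation config file
#'
#' Accepts a YAML (or plain "key: value") file whose keys match
#' \code{\link{sim_config}} arguments, plus optional keys \code{f0},
#' \code{theta_s} and \code{sun_days} (a list of day-of-year integers or a
#' string "evenly:N").
#'
#' @param file path.
#' @return list with \code{config}, \code{selection}, \code{schedule}.
#' @export
read_sim_config <- function(file) {
  vals <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(file)
  } else {
    lines <- grep("^\\s*(#|$)", readLines(file), value = TRUE, invert = TRUE)
    kv <- strsplit(lines, ":", fixed = TRUE)
    setNames(lapply(kv, function(x) {
      v <- trimws(paste(x[-1], collapse = ":"))
      n <- suppressWarnings(as.numeric(v))
      if (is.na(n)) v else n
    }), vapply(kv, function(x) trimws(x[1]), character(1)))
  }
  sched <- sun_schedule()
  if (!is.null(vals$sun_days)) {
    sched <- if (is.character(vals$sun_days) &&
                 grepl("^evenly:", vals$sun_days))
      sun_schedule(n = as.integer(sub("^evenly:", "", vals$sun_days)))
    else sun_schedule(days = unlist(vals$sun_days))
    vals$sun_days <- NULL
  }
  sel <- selection_params(f0 = vals$f0 %||% 0, theta_s = vals$theta_s %||% 0)
  vals$f0 <- NULL; vals$theta_s <- NULL
  keep <- intersect(names(vals), names(formals(sim_config)))
  cfg <- do.call(sim_config, vals[keep])
  list(config = cfg, selection = sel, schedule = sched)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
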