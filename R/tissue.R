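#' Simulation configuration
#'
#' Collects the geometric, growth-factor and cell-response parameters of the
#' tissue engine. The lateral lattice size is derived from the biopsy area
#' and the cell size (one voxel per cell); lateral boundaries are periodic,
#' the growth factor is sourced at the basal plane (Dirichlet, concentration
#' \code{s0}) and absorbed above the top layer, and the time step is one
#' day. Growth-factor decay and per-cell consumption are expressed relative
#' to the diffusion coefficient (voxel units), so only the ratios enter the
#' quasi-steady field.
#'
#' The default division/death response parameters are the package's
#' calibration product: they reproduce a basal progenitor loss/replacement
#' rate of about 0.51 per week and an equilibrium density of about 120,000
#' cells per square millimetre (see the methods vignette).
#'
#' @param biopsy_area_mm2 simulated area in square millimetres.
#' @param cell_size_um cell (voxel) edge length in micrometres.
#' @param Lz number of cell layers, including the basal layer.
#' @param s0 basal growth-factor source concentration (arbitrary units).
#' @param gf_lambda first-order growth-factor decay rate relative to
#'   diffusion (per voxel^2).
#' @param gf_consumption per-occupied-voxel consumption rate relative to
#'   diffusion.
#' @param gf_tol convergence tolerance of the quasi-steady solver (maximum
#'   per-sweep update, scaled by \code{s0}).
#' @param gf_max_sweeps sweep cap for the solver.
#' @param p_max,K_div,h_div division response: a cell divides in a day with
#'   probability \code{p_max * u^h / (u^h + K_div^h)} at local growth
#'   factor \code{u}.
#' @param d_max,K_die,h_die death response: a cell dies in a day with
#'   probability \code{d_max * K_die^h / (u^h + K_die^h)}.
#' @param place_w daughter placement weights over the five candidate sites
#'   (+x, -x, +y, -y, above), renormalised internally.
#' @return an object of class \code{sim_config}.
#' @examples
#' cfg <- sim_config(biopsy_area_mm2 = 0.25)
#' c(cfg$Lx, cfg$Ly, cfg$Lz)
#' @export
sim_config <- function(biopsy_area_mm2 = 0.25, cell_size_um = 15, Lz = 30L,
                       s0 = 1, gf_lambda = 5e-4, gf_consumption = 0.024,
                       gf_tol = 1e-5, gf_max_sweeps = 20000L,
                       p_max = 0.13, K_div = 0.4, h_div = 1,
                       d_max = 0.5, K_die = 0.010, h_die = 4,
                       place_w = rep(1 / 5, 5)) {
  if (biopsy_area_mm2 <= 0) stop("biopsy_area_mm2 must be positive")
  if (cell_size_um <= 0) stop("cell_size_um must be positive")
  side_um <- sqrt(biopsy_area_mm2) * 1000
  Lx <- max(1L, as.integer(floor(side_um / cell_size_um)))
  if (Lz < 2) stop("Lz must be at least 2")
  stopifnot(length(place_w) == 5, all(place_w >= 0), sum(place_w) > 0)
  rates <- c(gf_lambda, gf_consumption, p_max, d_max)
  if (any(rates < 0)) stop("rates must be nonnegative")
  structure(list(
    biopsy_area_mm2 = biopsy_area_mm2, cell_size_um = cell_size_um,
    Lx = Lx, Ly = Lx, Lz = as.integer(Lz),
    s0 = s0, gf_lambda = gf_lambda, gf_consumption = gf_consumption,
    gf_tol = gf_tol, gf_max_sweeps = as.integer(gf_max_sweeps),
    p_max = p_max, K_div = K_div, h_div = h_div,
    d_max = d_max, K_die = K_die, h_die = h_die,
    place_w = place_w / sum(place_w), dt_days = 1),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %g mm^2 (%d x %d x %d voxels of %g um)\n",
              x$biopsy_area_mm2, x$Lx, x$Ly, x$Lz, x$cell_size_um))
  invisible(x)
}

engine_params <- function(config, selection) {
  c(config[c("Lx", "Ly", "Lz", "s0", "gf_lambda", "gf_consumption",
             "gf_tol", "gf_max_sweeps", "p_max", "K_div", "h_div",
             "d_max", "K_die", "h_die", "place_w")],
    list(f0 = selection$f0, theta_s = selection$theta_s,
         uv_basal_only = selection$uv_basal_only))
}

#' Initialise a tissue state
#'
#' The basal layer (z = 1 in R indexing) is fully occupied by mutation-free
#' founder cells; all other voxels are empty. The growth-factor field is
#' solved to quasi-steady state before the first cell step.
#'
#' @param config a \code{\link{sim_config}}.
#' @param panel a \code{\link{build_gene_panel}} gene panel.
#' @param seed optional seed for the simulation RNG.
#' @return an object of class \code{epidermis_state}.
#' @export
init_tissue <- function(config, panel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c(config$Lx, config$Ly, config$Lz)
  occ <- array(0L, dims)
  occ[, , 1] <- 1L # founder genotype
  gfres <- solve_gf_cpp(as.integer(occ), config$Lx, config$Ly, config$Lz,
                        config$s0, config$gf_lambda, config$gf_consumption,
                        config$gf_tol, config$gf_max_sweeps)
  state <- structure(list(
    occ = occ,
    gf = array(gfres$gf, dims),
    lineage = array(0L, dims),
    birth = array(0, dims),
    genotypes = list(parent = 0L, has_notch1 = 0L, has_tp53 = 0L),
    mutations = data.frame(gene = integer(), pos = integer(),
                           ref = integer(), alt = integer(),
                           genotype = integer(), birth_day = numeric()),
    panel = panel,
    clock_days = 0,
    n_lineage_labels = 0L,
    series = NULL,
    lineage_weekly = NULL),
    class = "epidermis_state")
  state
}

#' @export
print.epidermis_state <- function(x, ...) {
  cat(sprintf("<epidermis_state> day %g: %d cells (%d basal), %d mutations\n",
              x$clock_days, sum(x$occ > 0), sum(x$occ[, , 1] > 0),
              nrow(x$mutations)))
  invisible(x)
}

state_mut_list <- function(state) {
  m <- state$mutations
  list(gene = as.integer(m$gene), pos = as.integer(m$pos),
       ref = as.integer(m$ref), alt = as.integer(m$alt),
       genotype = as.integer(m$genotype), birth_day = as.numeric(m$birth_day))
}

state_geno_list <- function(state) {
  list(parent = as.integer(state$genotypes$parent),
       has_notch1 = as.integer(state$genotypes$has_notch1),
       has_tp53 = as.integer(state$genotypes$has_tp53))
}

absorb_engine_result <- function(state, res, dims) {
  state$occ <- array(res$occ, dims)
  state$gf <- array(res$gf, dims)
  state$lineage <- array(res$lineage, dims)
  state$birth <- array(res$birth, dims)
  state$genotypes <- list(parent = res$geno_parent,
                          has_notch1 = res$geno_notch1,
                          has_tp53 = res$geno_tp53)
  state$mutations <- data.frame(gene = res$mut_gene, pos = res$mut_pos,
                                ref = res$mut_ref, alt = res$mut_alt,
                                genotype = res$mut_genotype,
                                birth_day = res$mut_birth_day)
  state
}

#' Advance the tissue by whole days
#'
#' Runs the hybrid automaton: each day the ultraviolet kill is applied if
#' the day is a scheduled sun day, the growth-factor field is re-solved to
#' quasi-steady state, and every cell (in a fresh random permutation) first
#' faces death with probability \code{p_die(u)} and otherwise attempts
#' division with probability \code{p_div(u)}. Daughters displace occupants
#' with the knock-on rule; cells pushed past the top layer are shed.
#'
#' @param state an \code{epidermis_state}.
#' @param config the \code{\link{sim_config}} used to create it.
#' @param days number of one-day steps.
#' @param selection a \code{\link{selection_params}} object.
#' @param schedule a \code{\link{sun_schedule}}; kills apply on days whose
#'   day-of-year (1-based, modulo 365) is in the schedule.
#' @return the updated state; \code{state$series} accumulates the daily
#'   population ledger (day, total, basal, n_notch1, n_tp53, births,
#'   deaths, sheds, uv_deaths, basal_losses, gf_sweeps, divisions) and
#'   \code{state$lineage_weekly} the weekly count of surviving labelled
#'   basal lineages.
#' @export
run_epidermis <- function(state, config, days, selection = selection_params(),
                          schedule = sun_schedule()) {
  stopifnot(inherits(state, "epidermis_state"), days >= 1)
  dims <- c(config$Lx, config$Ly, config$Lz)
  doy <- ((state$clock_days + seq_len(days) - 1) %% 365) + 1
  sun <- doy %in% schedule$days
  res <- run_epidermis_cpp(as.integer(state$occ), as.numeric(state$gf),
                           as.integer(state$lineage), as.numeric(state$birth),
                           state_geno_list(state), state_mut_list(state),
                           panel_for_engine(state$panel),
                           engine_params(config, selection),
                           state$clock_days, as.integer(days), sun,
                           state$n_lineage_labels)
  state <- absorb_engine_result(state, res, dims)
  state$clock_days <- state$clock_days + days
  state$series <- rbind(state$series, as.data.frame(res$series))
  if (nrow(res$lineage_weekly) > 0)
    state$lineage_weekly <- rbind(state$lineage_weekly,
                                  as.data.frame(res$lineage_weekly))
  state
}

#' One time step of the automaton
#'
#' @inheritParams run_epidermis
#' @return the state advanced by one day.
#' @export
tissue_step <- function(state, config, selection = selection_params(),
                        schedule = sun_schedule()) {
  run_epidermis(state, config, 1, selection, schedule)
}

#' Re-solve the growth-factor field to quasi-steady state
#'
#' @inheritParams run_epidermis
#' @return the state with an updated \code{gf} field.
#' @export
solve_gf <- function(state, config) {
  res <- solve_gf_cpp(as.integer(state$occ), config$Lx, config$Ly, config$Lz,
                      config$s0, config$gf_lambda, config$gf_consumption,
                      config$gf_tol, config$gf_max_sweeps)
  state$gf <- array(res$gf, c(config$Lx, config$Ly, config$Lz))
  state
}

#' Single daughter-placement attempt
#'
#' Exposes the placement machinery of the engine for one division by the
#' cell at lattice coordinates (x, y, z) (1-based): target choice among the
#' four lateral neighbours and the site above, the NOTCH1 displacement veto
#' (which aborts the division), knock-on column displacement and shedding,
#' and de novo mutation of both daughters.
#'
#' @inheritParams run_epidermis
#' @param x,y,z 1-based coordinates of the dividing cell.
#' @return a list with the updated \code{state} and the placement
#'   \code{outcome} ("placed", "shed" or "aborted").
#' @export
place_daughter <- function(state, config, x, y, z,
                           selection = selection_params()) {
  dims <- c(config$Lx, config$Ly, config$Lz)
  res <- place_daughter_cpp(as.integer(state$occ), as.numeric(state$gf),
                            as.integer(state$lineage), as.numeric(state$birth),
                            state_geno_list(state), state_mut_list(state),
                            panel_for_engine(state$panel),
                            engine_params(config, selection),
                            x, y, z, state$clock_days)
  state <- absorb_engine_result(state, res, dims)
  list(state = state, outcome = res$outcome, births = res$births,
       sheds = res$sheds, basal_losses = res$basal_losses)
}

#' Remove all cells in a box of the lattice
#'
#' Wounding: the affected voxels are emptied; in subsequent steps the local
#' growth factor rises (no consumption by the lost cells) and the tissue
#' regrows into the void.
#'
#' @param state an \code{epidermis_state}.
#' @param x_range,y_range,z_range integer ranges of 1-based lattice
#'   coordinates; \code{z_range = NULL} wounds the full column height.
#' @return the state with the region cleared.
#' @export
wound <- function(state, x_range, y_range, z_range = NULL) {
  if (is.null(z_range)) z_range <- seq_len(dim(state$occ)[3])
  state$occ[x_range, y_range, z_range] <- 0L
  state$lineage[x_range, y_range, z_range] <- 0L
  state
}

#' Label every basal cell as the founder of a lineage
#'
#' Assigns a distinct lineage label to each currently occupied basal voxel;
#' labels are inherited by all daughters. Weekly counts of labels still
#' present in the basal layer are recorded by \code{\link{run_epidermis}}.
#'
#' @param state an \code{epidermis_state}.
#' @return the state with labels installed.
#' @export
label_basal_lineages <- function(state) {
  state$lineage[] <- 0L
  basal <- which(state$occ[, , 1] > 0)
  lab <- array(0L, dim(state$occ)[1:2])
  lab[basal] <- seq_along(basal)
  state$lineage[, , 1] <- lab
  state$n_lineage_labels <- length(basal)
  state$lineage_weekly <- NULL
  state
}

#' Surviving-lineage fraction over time
#'
#' @param state a state whose lineages were labelled with
#'   \code{\link{label_basal_lineages}} and then run.
#' @return data frame with day, week, n_surviving and the surviving
#'   fraction of the initially labelled basal lineages.
#' @export
lineage_survival <- function(state) {
  if (is.null(state$lineage_weekly) || state$n_lineage_labels == 0)
    stop("no labelled lineage records; run label_basal_lineages() first")
  lw <- state$lineage_weekly
  data.frame(day = lw$day,
             week = seq_len(nrow(lw)),
             n_surviving = lw$n_surviving,
             frac = lw$n_surviving / state$n_lineage_labels)
}

#' Exponential half-life of basal lineage survival
#'
#' Fits the decay model \eqn{S(t) = e^{-kt}} to the weekly
#' surviving-lineage fraction by least squares on the survival scale. The
#' curve is anchored at \eqn{S(0) = 1}, which is an exact datum (every
#' labelled lineage is present at labelling time), so no free amplitude is
#' estimated; this weights the fit towards the informative early decay
#' rather than the long tail of rare persistent lineages (holoclone-like
#' survivors).
#'
#' @param survival a data frame from \code{\link{lineage_survival}} (or
#'   with columns \code{week} and \code{frac}).
#' @return list with \code{half_life_weeks}, \code{rate_per_week} and
#'   \code{ci} (weeks, 95 percent, from the curvature of the fit).
#' @export
fit_lineage_halflife <- function(survival) {
  s <- survival[complete.cases(survival[, c("week", "frac")]), ]
  if (nrow(s) < 3) stop("need at least 3 survival points")
  if (all(s$frac >= 1)) stop("survival does not decay; half-life undefined")
  k0 <- max(1e-3, -coef(lm(log(pmax(s$frac, 1e-6)) ~ s$week))[[2]])
  fit <- stats::nls(frac ~ exp(-k * week), data = s, start = list(k = k0))
  k <- coef(fit)[["k"]]
  se <- summary(fit)$coefficients["k", "Std. Error"]
  ci <- log(2) / (k + c(1.96, -1.96) * se)
  ci[ci < 0] <- Inf
  list(half_life_weeks = log(2) / k,
       rate_per_week = k,
       ci = sort(ci))
}

#' Label basal cells, run, and summarise lineage survival
#'
#' Convenience wrapper for the labelled-lineage experiment: labels all
#' basal cells at the current clock, advances the tissue by \code{weeks}
#' weeks under neutral dynamics, and returns the weekly survival curve with
#' an exponential half-life fit.
#'
#' @inheritParams run_epidermis
#' @param weeks number of weeks to track.
#' @return list with \code{state}, \code{survival} and \code{fit}.
#' @export
track_lineages <- function(state, config, weeks = 26,
                           selection = selection_params(),
                           schedule = sun_schedule()) {
  state <- label_basal_lineages(state)
  state <- run_epidermis(state, config, weeks * 7, selection, schedule)
  surv <- lineage_survival(state)
  list(state = state, survival = surv, fit = fit_lineage_halflife(surv))
}

#' Time-averaged cell density per square millimetre
#'
#' @param state an \code{epidermis_state} with a recorded series.
#' @param config its \code{\link{sim_config}}.
#' @param last_days average over the trailing this-many days of the series.
#' @return cells per square millimetre.
#' @export
measure_density <- function(state, config, last_days = 365) {
  s <- tail(state$series, last_days)
  mean(s$total) / config$biopsy_area_mm2
}

#' Measured basal loss/replacement rate
#'
#' Basal loss events (deaths at the basal layer, upward displacement out of
#' the basal layer, and ultraviolet kills at the basal layer) per basal
#' cell per week, averaged over the trailing days of the series.
#'
#' @inheritParams measure_density
#' @return rate per basal cell per week.
#' @export
measure_basal_loss_rate <- function(state, config, last_days = 365) {
  s <- tail(state$series, last_days)
  sum(s$basal_losses) / mean(s$basal) / nrow(s) * 7
}
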