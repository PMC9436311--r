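#' Logistic-growth surrogate with pulsed ultraviolet kill
#'
#' Fast approximation of the keratinocyte population for scanning sun-day
#' schedules before committing to full lattice runs. Between sun days the
#' population follows logistic growth
#' \deqn{dN/dt = r N (1 - N/K),}
#' advanced exactly by the closed-form solution; at the start of each
#' scheduled sun day the population is multiplied instantaneously by
#' \code{(1 - theta_s)}. Two pulses on the same day would compose
#' multiplicatively.
#'
#' @param r intrinsic growth rate per day.
#' @param K carrying capacity (cells).
#' @param N0 initial population (defaults to K, i.e. homeostasis).
#' @param theta_s kill fraction per sun day.
#' @param schedule a \code{\link{sun_schedule}}.
#' @param t_end duration in days.
#' @return data frame with columns day (0..t_end) and N.
#' @examples
#' tr <- simulate_logistic_uv(r = 0.1, K = 1e5, theta_s = 0.2,
#'                            schedule = sun_schedule(n = 4), t_end = 365)
#' range(tr$N) / 1e5
#' @export
simulate_logistic_uv <- function(r, K, N0 = K, theta_s = 0,
                                 schedule = sun_schedule(), t_end = 365) {
  if (r <= 0 || K <= 0) stop("r and K must be positive")
  if (N0 <= 0 || N0 > K) stop("N0 must lie in (0, K]")
  if (theta_s < 0 || theta_s > 1) stop("theta_s must lie in [0, 1]")
  t_end <- as.integer(t_end)
  N <- numeric(t_end + 1)
  N[1] <- N0
  n <- N0
  for (d in seq_len(t_end)) {
    doy <- ((d - 1) %% 365) + 1
    if (doy %in% schedule$days) n <- n * (1 - theta_s)
    if (n > 0) n <- K / (1 + (K / n - 1) * exp(-r))
    N[d + 1] <- n
  }
  data.frame(day = 0:t_end, N = N)
}

#' Scan ultraviolet exposure schedules with the logistic surrogate
#'
#' Evaluates every combination of sun-day count, spacing mode and kill
#' fraction and summarises the population trajectory: the minimum and mean
#' density as fractions of carrying capacity, the recovery time from the
#' deepest trough back to 99 percent of K, and whether the minimum stays
#' above a homeostasis floor.
#'
#' @param n_days_set integer vector of sun-day counts per year.
#' @param theta_set numeric vector of kill fractions.
#' @param spacing_modes character vector, subset of c("even", "cluster").
#' @param r,K logistic parameters (see
#'   \code{\link{simulate_logistic_uv}}).
#' @param years duration of each trajectory in years.
#' @param floor_frac homeostasis floor as a fraction of K.
#' @return data frame with one row per combination: n_sun_days, spacing,
#'   theta_s, min_density_frac, mean_density_frac, recovery_days,
#'   homeostatic.
#' @export
scan_uv_parameters <- function(n_days_set, theta_set,
                               spacing_modes = "even",
                               r = 0.12, K = 120000, years = 3,
                               floor_frac = 0.8) {
  grid <- expand.grid(n_sun_days = n_days_set, spacing = spacing_modes,
                      theta_s = theta_set, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sch <- sun_schedule(n = grid$n_sun_days[i], mode = grid$spacing[i])
    tr <- simulate_logistic_uv(r, K, theta_s = grid$theta_s[i],
                               schedule = sch, t_end = round(365 * years))
    imin <- which.min(tr$N)
    rec <- which(tr$N[imin:nrow(tr)] >= 0.99 * K)
    data.frame(min_density_frac = tr$N[imin] / K,
               mean_density_frac = mean(tr$N) / K,
               recovery_days = if (tr$N[imin] >= 0.99 * K) 0
                               else if (length(rec)) rec[1] - 1 else NA_real_,
               homeostatic = tr$N[imin] / K >= floor_frac)
  })
  cbind(grid, do.call(rbind, out))
}
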