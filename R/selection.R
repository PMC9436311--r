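#' Selection parameters for driver mutations
#'
#' \code{f0} is the blocking probability by which a NOTCH1-class mutant
#' occupant vetoes being displaced by a neighbour's division (a persistence
#' advantage: division rates are untouched). \code{theta_s} is the fraction
#' of non-TP53-mutant cells killed on each scheduled sun day; TP53-class
#' mutants are spared, which is their entire advantage.
#'
#' @param f0 blocking probability in [0, 1].
#' @param theta_s sun-day kill fraction in [0, 1].
#' @param uv_basal_only if TRUE, ultraviolet kills are restricted to the
#'   basal layer (default FALSE: all layers are exposed).
#' @return an object of class \code{selection_params}.
#' @export
selection_params <- function(f0 = 0, theta_s = 0, uv_basal_only = FALSE) {
  if (f0 < 0 || f0 > 1) stop("f0 must lie in [0, 1]")
  if (theta_s < 0 || theta_s > 1) stop("theta_s must lie in [0, 1]")
  structure(list(f0 = f0, theta_s = theta_s,
                 uv_basal_only = isTRUE(uv_basal_only)),
            class = "selection_params")
}

#' Yearly schedule of sun-damage days
#'
#' The sun-day set S is a set of day-of-year integers in 1..365, repeated
#' every simulated year. \code{mode = "even"} spaces \code{n} days evenly
#' through the year; \code{mode = "cluster"} packs them consecutively (a
#' "vacation") starting at \code{start}.
#'
#' @param days explicit day-of-year integers (overrides \code{n}).
#' @param n number of sun days to generate.
#' @param mode "even" or "cluster".
#' @param start first day of a clustered schedule.
#' @return an object of class \code{sun_schedule}.
#' @examples
#' sun_schedule(n = 12)$days
#' @export
sun_schedule <- function(days = NULL, n = 0, mode = c("even", "cluster"),
                         start = 150) {
  mode <- match.arg(mode)
  if (is.null(days)) {
    if (n < 0 || n > 365) stop("n must lie in 0..365")
    days <- if (n == 0) integer(0)
    else if (mode == "even") as.integer(floor(seq(1, 365, by = 365 / n)))
    else ((start - 1 + seq_len(n) - 1) %% 365) + 1
  }
  days <- sort(unique(as.integer(days)))
  if (length(days) && (min(days) < 1 || max(days) > 365))
    stop("sun days must lie in 1..365")
  structure(list(days = days), class = "sun_schedule")
}

#' Does a NOTCH1-mutant occupant veto a displacement?
#'
#' Bernoulli draw with probability \code{f0} when the occupant carries a
#' NOTCH1-class mutation; non-mutant occupants never veto.
#'
#' @param occupant_has_notch1 logical.
#' @param f0 blocking probability.
#' @param n number of independent trials.
#' @return logical vector: TRUE where the displacement is vetoed.
#' @export
notch_block <- function(occupant_has_notch1, f0, n = 1) {
  if (f0 < 0 || f0 > 1) stop("f0 must lie in [0, 1]")
  if (!occupant_has_notch1 || f0 == 0) return(rep(FALSE, n))
  if (f0 == 1) return(rep(TRUE, n))
  runif(n) < f0
}

#' Apply one ultraviolet sun day to a tissue state
#'
#' Every cell whose genotype lacks a TP53-class mutation is independently
#' removed with probability \code{theta_s}; TP53 mutants are untouched.
#' Removals count as deaths in the population ledger.
#'
#' @param state an \code{epidermis_state}.
#' @param selection a \code{\link{selection_params}}.
#' @return the state after the kill; the number of cells removed is
#'   attached as attribute \code{"uv_deaths"}.
#' @export
apply_uv_day <- function(state, selection) {
  dims <- dim(state$occ)
  res <- uv_kill_cpp(as.integer(state$occ), as.integer(state$lineage),
                     state_geno_list(state), selection$theta_s,
                     selection$uv_basal_only, dims[1], dims[2], dims[3])
  state$occ <- array(res$occ, dims)
  state$lineage <- array(res$lineage, dims)
  attr(state, "uv_deaths") <- res$deaths
  state
}

#' Departure from homeostasis
#'
#' Log mean squared deviation between a test population trajectory and a
#' homeostatic reference sampled at the same timepoints:
#' \deqn{d_H = \log\left(\frac{1}{n}\sum_i (N_k(t_i) - N_s(t_i))^2\right).}
#' The mean squared deviation is floored at 1 cell^2 inside the logarithm
#' so that identical trajectories give \eqn{d_H = 0} rather than minus
#' infinity.
#'
#' @param reference,test numeric vectors of population sizes, or data
#'   frames with a \code{total} column (e.g. \code{state$series}).
#' @return the scalar \eqn{d_H} (natural log).
#' @export
departure_from_homeostasis <- function(reference, test) {
  nk <- if (is.data.frame(reference)) reference$total else reference
  ns <- if (is.data.frame(test)) test$total else test
  if (length(nk) != length(ns))
    stop("reference and test series must have the same length")
  if (length(nk) == 0) stop("empty series")
  log(max(mean((nk - ns)^2), 1))
}
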