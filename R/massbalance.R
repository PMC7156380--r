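# Coupled Mo-U seawater concentration + isotope mass balance.
#
# Each metal is tracked as a dissolved inventory N (mol) and an
# isotope-weighted inventory N*delta (mol permil), mirroring the model's
# governing equations directly so no chain-rule rearrangement is needed;
# seawater delta is the derived ratio. One riverine source feeds three
# redox-sensitive sinks (oxic, broadly reducing, euxinic) whose fluxes are
# first-order in seawater concentration:
#   F_i = b_i * A_i * alpha_i * [Me]_sw / [Me]_M.sw
# so the system is linear and has a unique closed-form steady state, which the
# numerical (ODE) path is validated against.

#' Fixed modern oceanographic constants
#'
#' Total seafloor area, seawater mass, modern seawater Mo and U concentrations
#' and isotope values. The modern concentrations are 150 and 14 nmol/kg
#' (expressed in mol/kg); with the default riverine fluxes these give modern
#' residence times of roughly 0.7-0.9 Myr, consistent with both metals being
#' well-mixed in seawater.
#'
#' @param ... name = value overrides of any constant.
#' @return named list: \code{area_m2}, \code{seawater_kg}, \code{mo_modern_conc},
#'   \code{u_modern_conc} (mol/kg), \code{d98mo_modern_sw}, \code{d238u_modern_sw}
#'   (permil).
#' @export
mb_constants <- function(...) {
  const <- list(
    area_m2 = 3.6e14,
    seawater_kg = 1.41e21,
    mo_modern_conc = 150e-9,
    u_modern_conc = 14e-9,
    d98mo_modern_sw = 2.34,
    d238u_modern_sw = -0.39
  )
  modifyList(const, list(...))
}

#' Monte Carlo parameter ranges
#'
#' Uniform prior [min, max] for every varied mass-balance parameter:
#' global and local sink fractionation factors (permil), riverine fluxes
#' (mol/yr), per-area burial rates (mol m^-2 yr^-1), riverine isotope
#' compositions (permil), the oxic-deposition limit f_ox.lim (fraction) and
#' the reducing-sink fraction f_red (whose upper bound is 1 - f_eux and is
#' applied at draw time).
#'
#' @param riverine_multiplier multiplier applied to both riverine flux ranges
#'   (the elevated-weathering sensitivity variant).
#' @param overrides named list of \code{c(min, max)} range replacements.
#' @return named list of length-2 numeric ranges.
#' @export
mb_param_ranges <- function(riverine_multiplier = 1, overrides = list()) {
  rng <- list(
    d238u_eux      = c(0.4, 0.8),
    d238u_eux_loc  = c(0.4, 0.8),
    d98mo_eux      = c(-0.8, 0),
    d98mo_eux_loc  = c(-0.8, 0),
    f_riv_u        = c(2.75e7, 5.65e7) * riverine_multiplier,
    f_riv_mo       = c(1.88e8, 3.0e8) * riverine_multiplier,
    b_u_eux        = c(5.4e-6, 4.62e-5),
    b_mo_eux       = c(5.0e-5, 1.25e-4),
    b_u_red        = c(9.2e-7, 4.37e-6),
    b_mo_red       = c(2.61e-5, 2.81e-5),
    b_u_ox         = c(2.72e-8, 6.75e-8),
    b_mo_ox        = c(2.08e-7, 2.87e-7),
    b_u_eux_loc    = c(5.4e-6, 4.62e-5),
    b_mo_eux_loc   = c(5.0e-5, 1.25e-4),
    d238u_riv      = c(-0.40, -0.10),
    d98mo_riv      = c(0.5, 0.9),
    d238u_red      = c(-0.23, 0.23),
    d98mo_red      = c(-2.8, -0.8),
    d238u_oxic     = c(-0.043, 0.029),
    d98mo_oxic     = c(-3.0, -2.8),
    d238u_carb_loc = c(0.2, 0.4),
    f_ox_lim       = c(0.8389, 1)
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(rng)) stop("unknown parameter range: ", nm)
    if (overrides[[nm]][1] > overrides[[nm]][2]) stop("range min > max for ", nm)
    rng[[nm]] <- overrides[[nm]]
  }
  rng
}

#' Burial flux of one redox-sensitive sink
#'
#' \code{F_i = b_i * A_i * alpha_i * conc / modern_conc}: per-area burial rate
#' times sink area times pseudospatial scaling, linear in seawater
#' concentration normalized to the modern value.
#'
#' @param b per-area burial rate, mol m^-2 yr^-1.
#' @param area sink area, m^2.
#' @param alpha pseudospatial scaling coefficient.
#' @param conc seawater concentration, mol/kg.
#' @param modern_conc modern seawater concentration, mol/kg.
#' @return flux in mol/yr.
#' @export
sink_flux <- function(b, area, alpha, conc, modern_conc) {
  stopifnot(all(b >= 0), all(area >= 0), all(alpha >= 0), all(conc >= 0),
            all(modern_conc > 0))
  b * area * alpha * conc / modern_conc
}

# First-order rate constants k_i (1/yr) acting on the inventory N (mol):
# F_i = k_i * N, with k_i = b_i A_i alpha_i / ([Me]_M.sw * M).
metal_rate_constants <- function(draw, partition, const, metal) {
  if (metal == "Mo") {
    b <- c(draw$b_mo_ox, draw$b_mo_red, draw$b_mo_eux)
    modern <- const$mo_modern_conc
  } else {
    b <- c(draw$b_u_ox, draw$b_u_red, draw$b_u_eux)
    modern <- const$u_modern_conc
  }
  areas <- c(partition$a_oxic, partition$a_red, partition$a_eux)
  alphas <- c(partition$alpha_oxic, partition$alpha_red, partition$alpha_eux)
  setNames(b * areas * alphas / (modern * const$seawater_kg),
           c("oxic", "red", "eux"))
}

metal_deltas <- function(draw, metal) {
  if (metal == "Mo") {
    list(riv_flux = draw$f_riv_mo, riv_delta = draw$d98mo_riv,
         sink_delta = c(oxic = draw$d98mo_oxic, red = draw$d98mo_red,
                        eux = draw$d98mo_eux))
  } else {
    list(riv_flux = draw$f_riv_u, riv_delta = draw$d238u_riv,
         sink_delta = c(oxic = draw$d238u_oxic, red = draw$d238u_red,
                        eux = draw$d238u_eux))
  }
}

#' Time derivatives of the coupled Mo-U state
#'
#' The four state components are the Mo inventory, the isotope-weighted Mo
#' inventory, and their U counterparts (mol and mol permil). The mass
#' derivative is riverine input minus the three sink fluxes; the
#' isotope-weighted derivative removes each sink at its own composition
#' \code{delta_sw + Delta_i}.
#'
#' @param state named numeric vector \code{c(n_mo, nd_mo, n_u, nd_u)}.
#' @param draw one-row list/data.frame of drawn parameters
#'   (see \code{\link{mb_param_ranges}} for names).
#' @param partition a \code{\link{partition_seafloor}} result.
#' @param const \code{\link{mb_constants}}.
#' @return named numeric vector of derivatives (mol/yr, mol permil/yr).
#' @export
mb_rhs <- function(state, draw, partition, const = mb_constants()) {
  if (any(!is.finite(state))) stop("non-finite state")
  out <- numeric(4)
  names(out) <- c("n_mo", "nd_mo", "n_u", "nd_u")
  idx <- list(Mo = c(1, 2), U = c(3, 4))
  floor_n <- c(Mo = 1e-6 * const$mo_modern_conc * const$seawater_kg,
               U = 1e-6 * const$u_modern_conc * const$seawater_kg)
  for (metal in c("Mo", "U")) {
    n <- state[idx[[metal]][1]]
    nd <- state[idx[[metal]][2]]
    delta_sw <- if (n > floor_n[[metal]]) nd / n else 0
    k <- metal_rate_constants(draw, partition, const, metal)
    md <- metal_deltas(draw, metal)
    fluxes <- k * n
    out[idx[[metal]][1]] <- md$riv_flux - sum(fluxes)
    out[idx[[metal]][2]] <- md$riv_flux * md$riv_delta -
      sum(fluxes * (delta_sw + md$sink_delta))
  }
  out
}

#' Closed-form steady state of the coupled mass balance
#'
#' The sink fluxes are linear in the inventory, so the steady inventory is
#' \code{N_ss = F_riv / sum(k_i)} and the steady seawater isotope value is
#' \code{delta_riv - sum(k_i Delta_i) / sum(k_i)} (riverine composition minus
#' the rate-weighted mean sink fractionation).
#'
#' @inheritParams mb_rhs
#' @return a \code{steady_state} list: per metal the inventory (mol),
#'   concentration (mol/kg), seawater delta (permil) and sink + riverine
#'   fluxes (mol/yr); \code{converged = TRUE}; \code{method = "analytic"}.
#' @export
analytic_steady_state <- function(draw, partition, const = mb_constants()) {
  out <- list(converged = TRUE, method = "analytic")
  for (metal in c("Mo", "U")) {
    k <- metal_rate_constants(draw, partition, const, metal)
    if (sum(k) <= 0) stop("all sink rate constants zero: no steady state")
    md <- metal_deltas(draw, metal)
    n_ss <- md$riv_flux / sum(k)
    delta_ss <- md$riv_delta - sum(k * md$sink_delta) / sum(k)
    key <- tolower(metal)
    out[[paste0("n_", key)]] <- n_ss
    out[[paste0("conc_", key)]] <- n_ss / const$seawater_kg
    out[[paste0("delta_", key)]] <- delta_ss
    out[[paste0("flux_", key)]] <- c(k * n_ss, riv = md$riv_flux)
  }
  class(out) <- "steady_state"
  out
}

#' Integrate the coupled system to steady state
#'
#' Integrates the four-component system with a variable-coefficient stiff-
#' capable ODE solver (VODE) in 1 Myr windows until the largest relative
#' change of any component over a window falls below \code{tol}, or until
#' \code{t_max} with a convergence-failure flag.
#'
#' @inheritParams mb_rhs
#' @param init initial state; defaults to modern inventories and isotope values.
#' @param tol relative-change convergence tolerance per 1 Myr window.
#' @param t_max maximum integration time (yr).
#' @return a \code{steady_state} list as \code{\link{analytic_steady_state}},
#'   with \code{method = "ode"}, \code{converged} flag and \code{t_converged}.
#' @export
integrate_to_steady_state <- function(draw, partition, const = mb_constants(),
                                      init = NULL, tol = 1e-8, t_max = 5e7) {
  if (is.null(init)) {
    init <- c(n_mo = const$mo_modern_conc * const$seawater_kg,
              nd_mo = const$mo_modern_conc * const$seawater_kg * const$d98mo_modern_sw,
              n_u = const$u_modern_conc * const$seawater_kg,
              nd_u = const$u_modern_conc * const$seawater_kg * const$d238u_modern_sw)
  }
  times <- seq(0, t_max, by = 1e6)
  sol <- deSolve::vode(
    y = init, times = times,
    func = function(t, y, parms) list(mb_rhs(y, draw, partition, const)),
    parms = NULL, rtol = 1e-10, atol = 1e-4)
  y <- sol[, -1, drop = FALSE]
  rel <- abs(y[-1, , drop = FALSE] - y[-nrow(y), , drop = FALSE]) /
    pmax(abs(y[-nrow(y), , drop = FALSE]), 1e-300)
  hit <- which(apply(rel, 1, max) < tol)
  converged <- length(hit) > 0
  row <- if (converged) hit[1] + 1 else nrow(y)
  state <- y[row, ]
  out <- list(converged = converged, method = "ode",
              t_converged = if (converged) times[row] else NA_real_)
  for (metal in c("Mo", "U")) {
    key <- tolower(metal)
    n <- state[[paste0("n_", key)]]
    nd <- state[[paste0("nd_", key)]]
    floor_n <- 1e-6 * const[[paste0(key, "_modern_conc")]] * const$seawater_kg
    k <- metal_rate_constants(draw, partition, const, metal)
    md <- metal_deltas(draw, metal)
    out[[paste0("n_", key)]] <- n
    out[[paste0("conc_", key)]] <- n / const$seawater_kg
    out[[paste0("delta_", key)]] <- if (n > floor_n) nd / n else NA_real_
    out[[paste0("flux_", key)]] <- c(k * n, riv = md$riv_flux)
  }
  class(out) <- "steady_state"
  out
}

#' Project steady-state seawater onto sediment archives
#'
#' Sediment compositions follow seawater plus an independently drawn local
#' fractionation: \code{d98Mo_eux = d98Mo_sw + D98Mo_eux.loc},
#' \code{d238U_eux = d238U_sw + D238U_eux.loc},
#' \code{d238U_carb = d238U_sw + D238U_carb.loc}.
#'
#' @param ss a \code{steady_state}.
#' @param draw the parameter draw supplying the local fractionations.
#' @return named numeric vector \code{c(d98mo_eux_sed, d238u_eux_sed,
#'   d238u_carb_sed)} (permil).
#' @export
project_sediment_values <- function(ss, draw) {
  c(d98mo_eux_sed = ss$delta_mo + draw$d98mo_eux_loc,
    d238u_eux_sed = ss$delta_u + draw$d238u_eux_loc,
    d238u_carb_sed = ss$delta_u + draw$d238u_carb_loc)
}
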