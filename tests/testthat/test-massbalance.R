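# Coupled Mo-U mass balance: fluxes, ODE right-hand side, steady states.

test_that("sink fluxes are linear in concentration with the right identities", {
  expect_equal(sink_flux(1e-5, 2e13, 1, 150e-9, 150e-9), 1e-5 * 2e13)
  expect_equal(sink_flux(1e-5, 2e13, 0.7, 0, 150e-9), 0)
  f1 <- sink_flux(3e-5, 1e13, 0.8, 100e-9, 150e-9)
  f2 <- sink_flux(3e-5, 1e13, 0.8, 50e-9, 150e-9)
  expect_equal(f1, 2 * f2)
  expect_error(sink_flux(-1, 1, 1, 1, 1))
})

test_that("the right-hand side reduces to source-only and fixed-point limits", {
  const <- mb_constants()
  draw <- px_mid_draw()
  part0 <- list(a_eux = 0, a_red = 0, a_oxic = 0,
                alpha_eux = 1, alpha_red = 1, alpha_oxic = 1)
  st <- c(n_mo = 2e14, nd_mo = 4e14, n_u = 2e13, nd_u = -8e12)
  d <- mb_rhs(st, draw, part0, const)
  expect_equal(d[["n_mo"]], draw$f_riv_mo)
  expect_equal(d[["nd_mo"]], draw$f_riv_mo * draw$d98mo_riv)
  expect_equal(d[["n_u"]], draw$f_riv_u)
  expect_equal(d[["nd_u"]], draw$f_riv_u * draw$d238u_riv)
  # the analytic steady state is a fixed point of the rhs
  curve <- px_curve()
  part <- partition_seafloor(0.1, draw$f_red, draw$f_ox_lim, curve)
  ss <- analytic_steady_state(draw, part, const)
  st_ss <- c(n_mo = ss$n_mo, nd_mo = ss$n_mo * ss$delta_mo,
             n_u = ss$n_u, nd_u = ss$n_u * ss$delta_u)
  d_ss <- mb_rhs(st_ss, draw, part, const)
  scale <- c(draw$f_riv_mo, draw$f_riv_mo, draw$f_riv_u, draw$f_riv_u)
  expect_true(all(abs(d_ss) / scale < 1e-10))
  expect_error(mb_rhs(c(NaN, 1, 1, 1), draw, part, const), "non-finite")
})

test_that("the rhs agrees with an independent term-by-term evaluation", {
  const <- mb_constants()
  curve <- px_curve()
  set.seed(71)
  for (i in 1:5) {
    draw <- draw_parameters(1, 0.2, seed = 300 + i)
    part <- partition_seafloor(0.2, draw$f_red,
                               max(draw$f_ox_lim, 0.2 + draw$f_red), curve)
    st <- c(n_mo = runif(1, 1e13, 4e14), nd_mo = 0,
            n_u = runif(1, 1e12, 4e13), nd_u = 0)
    st["nd_mo"] <- st["n_mo"] * runif(1, 0.5, 2.5)
    st["nd_u"] <- st["n_u"] * runif(1, -0.8, 0)
    got <- mb_rhs(st, draw, part, const)
    # spreadsheet-style evaluation, written out flux by flux
    conc_mo <- st[["n_mo"]] / const$seawater_kg
    dmo <- st[["nd_mo"]] / st[["n_mo"]]
    f_ox <- draw$b_mo_ox * part$a_oxic * 1 * conc_mo / const$mo_modern_conc
    f_rd <- draw$b_mo_red * part$a_red * part$alpha_red * conc_mo / const$mo_modern_conc
    f_ex <- draw$b_mo_eux * part$a_eux * part$alpha_eux * conc_mo / const$mo_modern_conc
    expect_equal(got[["n_mo"]], draw$f_riv_mo - f_ox - f_rd - f_ex)
    expect_equal(got[["nd_mo"]],
                 draw$f_riv_mo * draw$d98mo_riv -
                   f_ox * (dmo + draw$d98mo_oxic) -
                   f_rd * (dmo + draw$d98mo_red) -
                   f_ex * (dmo + draw$d98mo_eux))
  }
})

test_that("closed-form steady state has the expected isotope structure", {
  const <- mb_constants()
  curve <- px_curve()
  draw <- px_mid_draw()
  part <- partition_seafloor(0.1, draw$f_red, draw$f_ox_lim, curve)
  # equal fractionations across sinks: delta_sw = delta_riv - Delta
  dd <- draw
  dd$d98mo_oxic <- dd$d98mo_red <- dd$d98mo_eux <- -1.3
  ss <- analytic_steady_state(dd, part, const)
  expect_equal(ss$delta_mo, dd$d98mo_riv + 1.3)
  dd$d98mo_oxic <- dd$d98mo_red <- dd$d98mo_eux <- 0
  expect_equal(analytic_steady_state(dd, part, const)$delta_mo, dd$d98mo_riv)
  # doubling the riverine flux doubles concentration, leaves delta unchanged
  d2 <- draw; d2$f_riv_mo <- 2 * draw$f_riv_mo
  ss1 <- analytic_steady_state(draw, part, const)
  ss2 <- analytic_steady_state(d2, part, const)
  expect_equal(ss2$conc_mo, 2 * ss1$conc_mo)
  expect_equal(ss2$delta_mo, ss1$delta_mo)
  part_dead <- list(a_eux = 0, a_red = 0, a_oxic = 0,
                    alpha_eux = 1, alpha_red = 1, alpha_oxic = 1)
  expect_error(analytic_steady_state(draw, part_dead, const), "no steady state")
})

test_that("ODE integration reaches the analytic steady state", {
  const <- mb_constants()
  curve <- px_curve()
  set.seed(81)
  for (i in 1:5) {
    f_eux <- sample(scenario_grid(), 1)
    draw <- draw_parameters(1, f_eux, seed = 400 + i)
    part <- partition_seafloor(f_eux, draw$f_red, draw$f_ox_lim, curve)
    ssA <- analytic_steady_state(draw, part, const)
    ssO <- integrate_to_steady_state(draw, part, const)
    expect_true(ssO$converged)
    expect_equal(ssO$conc_mo, ssA$conc_mo, tolerance = 1e-6)
    expect_equal(ssO$conc_u, ssA$conc_u, tolerance = 1e-6)
    expect_lt(abs(ssO$delta_mo - ssA$delta_mo), 1e-5)
    expect_lt(abs(ssO$delta_u - ssA$delta_u), 1e-5)
  }
})

test_that("a single euxinic sink and far-field initial conditions behave", {
  const <- mb_constants()
  draw <- px_mid_draw(f_red = 0)
  part <- list(a_eux = const$area_m2, a_red = 0, a_oxic = 0,
               alpha_eux = 1, alpha_red = 1, alpha_oxic = 1)
  ss <- integrate_to_steady_state(draw, part, const)
  expect_equal(ss$delta_mo, draw$d98mo_riv - draw$d98mo_eux, tolerance = 1e-7)
  expect_equal(ss$delta_u, draw$d238u_riv - draw$d238u_eux, tolerance = 1e-7)
  # 10x modern inventories converge to the same fixed point
  init_far <- c(n_mo = 10 * const$mo_modern_conc * const$seawater_kg,
                nd_mo = 10 * const$mo_modern_conc * const$seawater_kg * 2.34,
                n_u = 10 * const$u_modern_conc * const$seawater_kg,
                nd_u = 10 * const$u_modern_conc * const$seawater_kg * -0.39)
  ss_far <- integrate_to_steady_state(draw, part, const, init = init_far)
  expect_equal(ss_far$conc_mo, ss$conc_mo, tolerance = 1e-6)
  expect_equal(ss_far$delta_u, ss$delta_u, tolerance = 1e-5)
})

test_that("steady-state mass and isotope budgets close", {
  const <- mb_constants()
  curve <- px_curve()
  for (i in 1:10) {
    f_eux <- scenario_grid()[3 * i]
    draw <- draw_parameters(1, f_eux, seed = 500 + i)
    part <- partition_seafloor(f_eux, draw$f_red, draw$f_ox_lim, curve)
    ss <- analytic_steady_state(draw, part, const)
    for (m in c("mo", "u")) {
      fl <- ss[[paste0("flux_", m)]]
      sinks <- fl[c("oxic", "red", "eux")]
      expect_lt(abs(sum(sinks) - fl[["riv"]]) / fl[["riv"]], 1e-6)
      pre <- if (m == "mo") "d98mo" else "d238u"
      dsw <- ss[[paste0("delta_", m)]]
      deltas <- c(draw[[paste0(pre, "_oxic")]], draw[[paste0(pre, "_red")]],
                  draw[[paste0(pre, "_eux")]])
      lhs <- fl[["riv"]] * draw[[paste0(pre, "_riv")]]
      rhs <- sum(sinks * (dsw + deltas))
      expect_lt(abs(lhs - rhs) / fl[["riv"]], 1e-9)
    }
  }
})

test_that("seawater isotopes fall and concentrations draw down as euxinia expands", {
  const <- mb_constants()
  curve <- px_curve()
  grid <- scenario_grid()
  draw <- px_mid_draw(f_red = 0.1)
  res <- t(sapply(grid, function(f) {
    part <- partition_seafloor(f, min(draw$f_red, 1 - f), draw$f_ox_lim, curve)
    ss <- analytic_steady_state(draw, part, const)
    ktot <- draw$b_mo_ox * part$a_oxic + draw$b_mo_red * part$a_red * part$alpha_red +
      draw$b_mo_eux * part$a_eux * part$alpha_eux
    c(dmo = ss$delta_mo, du = ss$delta_u, cmo = ss$conc_mo, ktot = ktot)
  }))
  expect_true(all(diff(res[, "dmo"]) <= 1e-12))
  expect_true(all(diff(res[, "du"]) <= 1e-12))
  # concentration is inversely proportional to the total sink rate constant,
  # so expanded anoxia (larger total burial constant) draws seawater down
  expect_equal(res[, "cmo"], res[1, "cmo"] * res[1, "ktot"] / res[, "ktot"],
               tolerance = 1e-9)
  expect_lt(res[31, "cmo"], res[1, "cmo"])
})

test_that("sediment projections add the local fractionations", {
  ss <- list(delta_mo = 1.2, delta_u = -0.4)
  draw <- list(d98mo_eux_loc = 0, d238u_eux_loc = 0.5, d238u_carb_loc = 0.3)
  sed <- project_sediment_values(ss, draw)
  expect_equal(sed[["d98mo_eux_sed"]], 1.2)
  expect_equal(sed[["d238u_eux_sed"]], 0.1)
  expect_equal(sed[["d238u_carb_sed"]], -0.1)
})
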