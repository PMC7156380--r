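# Detrital corrections, uncertainty propagation and redox screening.

make_sample_row <- function(mo = 30, u = 10, al = 8, th = 10,
                            d98mo = 0.7, d238u = 0, toc = 5,
                            fe = c(0.3, 0.2, 0.1, 2.0), fe_total = 3.5) {
  data.frame(sample_id = "S1", depth_m = 100, biozone = "ascensus",
             toc_wt = toc, fe_carb = fe[1], fe_ox = fe[2], fe_mag = fe[3],
             fe_py = fe[4], fe_total = fe_total,
             mo_ppm = mo, u_ppm = u, al_wt = al, th_ppm = th,
             d98mo = d98mo, d98mo_2se = 0.08, d238u = d238u, d238u_2se = 0.06)
}

test_that("detrital concentrations are the crustal ratio times the normalizer", {
  ref <- make_crustal_reference(mo_over_al = 0.135, u_over_th = 0.26)
  s <- make_sample_row(al = 8.0)
  expect_equal(detrital_concentration(s, ref, "Mo"), 0.135 * 8.0)  # = 1.08 ppm
  expect_equal(detrital_concentration(make_sample_row(al = 0), ref, "Mo"), 0)
  # definition holds for random ratio/normalizer pairs
  set.seed(11)
  for (i in 1:20) {
    r <- runif(1, 0.05, 0.5); t <- runif(1, 1, 20)
    refi <- make_crustal_reference(mo_over_al = 0.1, u_over_th = r)
    expect_equal(detrital_concentration(make_sample_row(th = t), refi, "U"), r * t)
  }
})

test_that("authigenic correction unmixes a known two-component mixture", {
  ref <- make_crustal_reference(mo_over_al = 0.125, u_over_th = 0.26,
                                d98mo_detr = -0.3, d238u_detr = -0.3)
  # bulk built from authigenic (10 ppm, +0.5) and detrital (1 ppm, -0.3)
  al <- 8; mo_detr <- 0.125 * al
  mo_auth <- 10; d_auth <- 0.5
  mo_bulk <- mo_auth + mo_detr
  d_bulk <- (d_auth * mo_auth + (-0.3) * mo_detr) / mo_bulk
  s <- make_sample_row(mo = mo_bulk, al = al, d98mo = d_bulk)
  res <- authigenic_correction(s, ref, "Mo")
  expect_equal(res$me_auth, mo_auth)
  expect_equal(res$delta_auth, d_auth)
  expect_true(res$valid)
})

test_that("degenerate corrections behave: no detrital component, over-correction", {
  ref0 <- make_crustal_reference(mo_over_al = 1e-12, u_over_th = 0.26,
                                 d98mo_detr = -0.3)
  s <- make_sample_row(al = 0, mo = 25, d98mo = 1.1)
  res <- authigenic_correction(s, ref0, "Mo")
  expect_equal(res$me_auth, s$mo_ppm)
  expect_equal(res$delta_auth, s$d98mo)
  # me_bulk == me_detr -> invalid, flagged not thrown
  refx <- make_crustal_reference(mo_over_al = 25 / 8, u_over_th = 0.26)
  resx <- authigenic_correction(make_sample_row(mo = 25, al = 8), refx, "Mo")
  expect_false(resx$valid)
  expect_true(is.na(resx$delta_auth))
})

test_that("mass and isotope closure hold to machine precision on random samples", {
  set.seed(21)
  ref <- crustal_reference()
  for (i in 1:30) {
    s <- make_sample_row(mo = runif(1, 2, 80), u = runif(1, 3, 40),
                         al = runif(1, 2, 10), th = runif(1, 4, 15),
                         d98mo = runif(1, -0.5, 1.5), d238u = runif(1, -0.6, 0.4))
    for (m in c("Mo", "U")) {
      res <- authigenic_correction(s, ref, m)
      bulk <- if (m == "Mo") s$mo_ppm else s$u_ppm
      dbulk <- if (m == "Mo") s$d98mo else s$d238u
      ddetr <- if (m == "Mo") ref$d98mo_detr else ref$d238u_detr
      expect_equal(res$me_auth + res$me_detr, bulk)
      if (res$valid) {
        expect_equal(res$delta_auth * res$me_auth + ddetr * res$me_detr,
                     dbulk * bulk)
      }
    }
  }
})

test_that("resampled uncertainty collapses correctly in degenerate cases", {
  s <- make_sample_row()
  ref0 <- make_crustal_reference(mo_over_al = 0.135, u_over_th = 0.26)
  s0 <- s; s0$d98mo_2se <- 0
  r0 <- propagate_uncertainty(s0, ref0, "Mo", n_draws = 5000, seed = 3)
  expect_equal(r0$me_auth_2sd, 0)
  expect_equal(r0$delta_auth_2sd, 0)
  # single error source: crustal 2SD = 0, no detrital Mo -> isotope 2sigma = 2SE
  refz <- make_crustal_reference(mo_over_al = 1e-15, u_over_th = 0.26)
  sz <- make_sample_row(al = 0); sz$d98mo_2se <- 0.12
  rz <- propagate_uncertainty(sz, refz, "Mo", n_draws = 2e4, seed = 4)
  expect_equal(rz$delta_auth_2sd, 0.12, tolerance = 0.03)
})

test_that("resampled uncertainty matches a brute-force Monte Carlo oracle", {
  set.seed(31)
  ref <- make_crustal_reference(mo_over_al = 0.135, u_over_th = 0.26,
                                mo_over_al_2sd = 0.037, u_over_th_2sd = 0.06,
                                d98mo_detr = 0.15, d238u_detr = -0.3)
  for (i in 1:20) {
    s <- make_sample_row(mo = runif(1, 10, 60), al = runif(1, 3, 10),
                         d98mo = runif(1, 0, 1.2))
    s$d98mo_2se <- runif(1, 0.02, 0.15)
    res <- propagate_uncertainty(s, ref, "Mo", n_draws = 1e4, seed = 100 + i)
    # independent brute-force resampling of the same generative assumptions
    n <- 1e6
    r <- rnorm(n, ref$mo_over_al, ref$mo_over_al_2sd / 2)
    d <- rnorm(n, s$d98mo, s$d98mo_2se / 2)
    detr <- r * s$al_wt
    auth <- s$mo_ppm - detr
    ok <- auth > 0
    dauth <- (d[ok] * s$mo_ppm - ref$d98mo_detr * detr[ok]) / auth[ok]
    expect_equal(res$me_auth_2sd, 2 * sd(auth), tolerance = 0.05)
    expect_equal(res$delta_auth_2sd, 2 * sd(dauth), tolerance = 0.05)
  }
})

test_that("iron speciation thresholds classify the water column", {
  mk <- function(fehr_fet, fepy_fehr, fet = 4) {
    fe_hr <- fehr_fet * fet
    fe_py <- fepy_fehr * fe_hr
    rest <- fe_hr - fe_py
    make_sample_row(fe = c(rest / 2, rest / 4, rest / 4, fe_py), fe_total = fet)
  }
  expect_equal(as.character(classify_redox(mk(0.9, 0.95))$water_column), "euxinic")
  expect_equal(as.character(classify_redox(mk(0.2, 0.95))$water_column), "oxic")
  expect_equal(as.character(classify_redox(mk(0.5, 0.75))$water_column),
               "possibly_euxinic")
  expect_equal(as.character(classify_redox(mk(0.5, 0.5))$water_column),
               "anoxic_ferruginous")
  expect_false(classify_redox(mk(0.9, 0.9, fet = 0))$redox_valid)
  # monotone: raising Fe_Py/Fe_HR never demotes toward less-reducing classes
  lv <- levels(classify_redox(mk(0.5, 0.5))$water_column)
  set.seed(41)
  for (i in 1:25) {
    fh <- runif(1, 0.39, 1)
    fp <- sort(runif(2, 0, 1))
    c1 <- as.integer(classify_redox(mk(fh, fp[1]))$water_column)
    c2 <- as.integer(classify_redox(mk(fh, fp[2]))$water_column)
    expect_gte(c2, c1)
  }
})

test_that("enrichment factors and TOC ratios follow their definitions", {
  ref <- make_crustal_reference(mo_over_al = 0.135, u_over_th = 0.26)
  crustal <- make_sample_row(mo = 0.135 * 8, u = (2.7 / 8.15) * 8, al = 8)
  ef <- enrichment_factors(crustal, ref)
  expect_equal(ef$ef_mo, 1)
  expect_equal(ef$ef_u, 1)
  doubled <- make_sample_row(mo = 2 * 0.135 * 8, al = 8)
  expect_equal(enrichment_factors(doubled, ref)$ef_mo, 2)
  expect_true(is.na(enrichment_factors(make_sample_row(al = 0), ref)$ef_mo))
  # linear in the metal concentration
  set.seed(51)
  for (i in 1:10) {
    m <- runif(1, 1, 50); k <- runif(1, 1.5, 4)
    e1 <- enrichment_factors(make_sample_row(mo = m), ref)$ef_mo
    e2 <- enrichment_factors(make_sample_row(mo = k * m), ref)$ef_mo
    expect_equal(e2, k * e1)
  }
  tn <- toc_normalize(make_sample_row(mo = 100, toc = 5))
  expect_equal(tn$mo_toc, 20)
  expect_true(is.na(toc_normalize(make_sample_row(toc = 0))$mo_toc))
  t1 <- toc_normalize(make_sample_row(mo = 30, toc = 3))
  t2 <- toc_normalize(make_sample_row(mo = 60, toc = 6))
  expect_equal(t1$mo_toc, t2$mo_toc)
})

test_that("sample tables round-trip through CSV and validation catches bad rows", {
  s <- synth_shale_record(synth_config(n_samples = 10, seed = 5))
  f <- tempfile(fileext = ".csv")
  write.csv(s, f, row.names = FALSE)
  back <- read_samples(f)
  expect_equal(back$mo_ppm, s$mo_ppm)
  expect_equal(back$d98mo, s$d98mo)
  # a negative concentration is rejected with the field named
  bad <- s; bad$u_ppm[3] <- -1
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_samples(f), "u_ppm")
  # empty optional fields parse as missing
  s2 <- s; s2$d238u[1] <- NA
  write.csv(s2, f, row.names = FALSE, na = "")
  expect_true(is.na(read_samples(f)$d238u[1]))
  # missing mandatory column is named
  s3 <- s[, setdiff(names(s), "th_ppm")]
  write.csv(s3, f, row.names = FALSE)
  expect_error(read_samples(f), "th_ppm")
})
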