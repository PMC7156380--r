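# Seafloor hypsometry and pseudospatial burial scaling.
#
# As reducing conditions expand across the seafloor they necessarily encroach
# on deeper water; metal complexes then sink through a longer water column and
# are increasingly remineralized before burial. The pseudospatial scaling
# coefficient alpha down-weights per-area burial accordingly, using an
# empirical organic-carbon remineralization depth law (1.58 - 0.16 ln z)
# averaged over the depth window the sink occupies on the global depth-area
# curve, normalized to its value at the shallowest euxinic depth.

#' Fit a monotone depth-area curve from a hypsometric table
#'
#' Fits a local-regression (LOESS) smoother of depth against cumulative
#' seafloor area fraction, with the span chosen by leave-one-out
#' cross-validation over a span grid, followed by a monotonization step
#' (running maximum on a fine grid). The returned curve evaluates in both
#' directions (depth from area fraction and area fraction from depth).
#'
#' @param table data.frame with columns \code{depth_m} and
#'   \code{cum_area_fraction}; at least 5 rows, fractions in [0, 1], covering
#'   the full [0, 1] domain.
#' @param spans candidate LOESS spans for leave-one-out cross-validation.
#' @param degree local polynomial degree.
#' @param n_grid size of the evaluation grid used for monotonization.
#' @return A \code{depth_area_curve} object with functions \code{depth_at(f)}
#'   and \code{fraction_at(z)}, the chosen \code{span}, and the per-span
#'   \code{cv_error} table.
#' @export
fit_depth_area <- function(table,
                           spans = seq(0.4, 1, by = 0.1),
                           degree = 2, n_grid = 1000) {
  if (!all(c("depth_m", "cum_area_fraction") %in% names(table))) {
    stop("hypsometric table needs columns depth_m and cum_area_fraction")
  }
  f <- table$cum_area_fraction
  z <- table$depth_m
  if (nrow(table) < 5) stop("hypsometric table needs at least 5 rows")
  if (any(f < 0 | f > 1)) stop("cumulative area fractions must lie in [0, 1]")
  if (is.unsorted(f) || is.unsorted(z)) {
    stop("hypsometric table must be sorted with depth and area fraction non-decreasing")
  }
  cv <- vapply(spans, function(s) loo_cv_error(f, z, span = s, degree = degree),
               numeric(1))
  if (all(!is.finite(cv))) stop("no candidate span produced a valid LOESS fit")
  span <- spans[which.min(cv)]
  fit <- loess(z ~ f, span = span, degree = degree,
               control = loess.control(surface = "direct"))
  fg <- seq(0, 1, length.out = n_grid)
  zg <- predict(fit, data.frame(f = fg))
  zg <- pmax(cummax(zg), 0)  # monotone non-decreasing, physical depths
  depth_at <- approxfun(fg, zg, rule = 2)
  fraction_at <- approxfun(zg, fg, rule = 2, ties = "ordered")
  structure(list(depth_at = depth_at, fraction_at = fraction_at,
                 span = span, cv_error = data.frame(span = spans, loo_mse = cv),
                 grid = data.frame(f = fg, z = zg)),
            class = "depth_area_curve")
}

# Leave-one-out cross-validation MSE of loess(y ~ x) at a given span.
loo_cv_error <- function(x, y, span, degree = 2) {
  n <- length(x)
  err <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dat <- data.frame(x = x[-i], y = y[-i])
    fit <- tryCatch(
      suppressWarnings(loess(y ~ x, data = dat, span = span, degree = degree,
                             control = loess.control(surface = "direct"))),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pred <- tryCatch(suppressWarnings(predict(fit, data.frame(x = x[i]))),
                     error = function(e) NA_real_)
    err[i] <- (pred - y[i])^2
  }
  mean(err, na.rm = TRUE)
}

#' Euxinic depth window on the depth-area curve
#'
#' The shallowest ~5\% of the seafloor is treated as authigenically neutral
#' unless total euxinia exceeds 95\%: for \code{f_eux <= 0.95} the euxinic
#' window spans cumulative area fractions [0.05, 0.05 + f_eux]; beyond that it
#' spans [1 - f_eux, 1]. The window is discretized into \code{n_disc}
#' equal-area increments evaluated at increment midpoints.
#'
#' @param f_eux euxinic seafloor fraction in (0, 1].
#' @param curve a \code{\link{fit_depth_area}} curve.
#' @param n_disc number of equal-area increments (default 100). Each increment
#'   is represented by the depth at its area midpoint; \code{min_z} and
#'   \code{max_z} are the window's edge depths.
#' @return list with \code{f_lo}, \code{f_hi}, \code{min_z}, \code{max_z} and
#'   \code{depths} (length \code{n_disc}); an empty window for \code{f_eux = 0}.
#' @export
euxinic_depth_window <- function(f_eux, curve, n_disc = 100) {
  stopifnot(f_eux >= 0, f_eux <= 1)
  if (f_eux == 0) {
    return(list(f_lo = 0.05, f_hi = 0.05, min_z = curve$depth_at(0.05),
                max_z = curve$depth_at(0.05), depths = numeric(0)))
  }
  f_lo <- if (f_eux <= 0.95) 0.05 else 1 - f_eux
  f_hi <- f_lo + f_eux
  mids <- f_lo + (seq_len(n_disc) - 0.5) / n_disc * (f_hi - f_lo)
  list(f_lo = f_lo, f_hi = f_hi,
       min_z = curve$depth_at(f_lo), max_z = curve$depth_at(f_hi),
       depths = curve$depth_at(mids))
}

# Remineralization depth law underlying the scaling coefficients.
remin_term <- function(z) 1.58 - 0.16 * log(z)

#' Euxinic pseudospatial burial scaling coefficient
#'
#' Mean of (1.58 - 0.16 ln z) over the discretized euxinic depth window,
#' normalized by its value at the shallowest euxinic depth min(z_eux) (the
#' window's shallow edge), so that \code{alpha_eux} is 1 for a window
#' collapsed to a single depth and decreases as euxinia expands into deeper
#' water. The midpoint discretization makes the area-weighted mean converge
#' quadratically in \code{n_disc}.
#'
#' @inheritParams euxinic_depth_window
#' @param depths optional explicit depth list overriding the window
#'   discretization (used for hand-worked checks); the normalization then
#'   uses the shallowest listed depth.
#' @return scalar coefficient in (0, 1].
#' @export
alpha_eux <- function(f_eux, curve, n_disc = 100, depths = NULL) {
  if (is.null(depths)) {
    if (f_eux <= 0) stop("alpha_eux undefined for f_eux = 0")
    w <- euxinic_depth_window(f_eux, curve, n_disc)
    depths <- w$depths
    min_z <- max(w$min_z, 1)
  } else {
    min_z <- max(min(depths), 1)
  }
  depths <- pmax(depths, 1)  # guard against z < 1 m at the curve's shallow end
  terms <- remin_term(depths)
  if (any(terms <= 0)) stop("remineralization term non-positive: window too deep")
  mean(terms) / remin_term(min_z)
}

#' Reducing-sink pseudospatial burial scaling coefficient
#'
#' The broadly reducing (ferruginous + suboxic) sink occupies the depth window
#' directly below the euxinic one (cumulative area fractions
#' [0.05 + f_eux, 0.05 + f_eux + f_red], with the same >95\% encroachment
#' rule). Depths below the euxinic window are absolute water depths from the
#' depth-area curve (incremental depth beyond max z_eux plus max z_eux), and
#' the mean remineralization term is normalized by the same alpha_eux.min
#' denominator (the term at the shallowest euxinic depth; for f_eux = 0 the
#' neutral-zone base depth at area fraction 0.05).
#'
#' @param f_eux,f_red seafloor fractions with \code{f_eux + f_red <= 1}.
#' @inheritParams euxinic_depth_window
#' @return scalar coefficient in (0, 1]; 1 when \code{f_red = 0} (the sink has
#'   zero area, so the coefficient is never used).
#' @export
alpha_red <- function(f_eux, f_red, curve, n_disc = 100) {
  stopifnot(f_eux >= 0, f_red >= 0, f_eux + f_red <= 1 + 1e-12)
  if (f_red == 0) return(1)
  ew <- euxinic_depth_window(f_eux, curve, n_disc)
  f_lo <- ew$f_hi
  f_hi <- f_lo + f_red
  if (f_hi > 1) { f_hi <- 1; f_lo <- 1 - f_red }
  mids <- f_lo + (seq_len(n_disc) - 0.5) / n_disc * (f_hi - f_lo)
  depths <- pmax(curve$depth_at(mids), 1)
  terms <- remin_term(depths)
  if (any(terms <= 0)) stop("remineralization term non-positive: window too deep")
  denom_z <- if (f_eux > 0) max(ew$min_z, 1) else max(curve$depth_at(0.05), 1)
  mean(terms) / remin_term(denom_z)
}

#' Partition the seafloor into euxinic, reducing and oxic sinks
#'
#' \code{f_oxic = max(f_ox_lim - f_eux - f_red, 0)} (clamped at zero with a
#' flag when the oxic limit is exceeded); sink areas are \code{A * f_i}; the
#' pseudospatial scaling coefficients are attached (\code{alpha_oxic = 1}).
#'
#' @param f_eux,f_red seafloor fractions.
#' @param f_ox_lim maximum extent of oxic deposition (fraction, 0.8389-1).
#' @param curve a \code{\link{fit_depth_area}} curve.
#' @param total_area total seafloor area in m^2.
#' @param n_disc discretization of the alpha windows.
#' @return list with fractions, areas (m^2), alphas and \code{oxic_clamped}.
#' @export
partition_seafloor <- function(f_eux, f_red, f_ox_lim, curve,
                               total_area = 3.6e14, n_disc = 100) {
  stopifnot(f_eux >= 0, f_eux <= 1, f_red >= 0, f_red <= 1 - f_eux + 1e-12)
  f_oxic_raw <- f_ox_lim - f_eux - f_red
  f_oxic <- max(f_oxic_raw, 0)
  list(f_eux = f_eux, f_red = f_red, f_oxic = f_oxic,
       a_eux = total_area * f_eux, a_red = total_area * f_red,
       a_oxic = total_area * f_oxic,
       alpha_eux = if (f_eux > 0) alpha_eux(f_eux, curve, n_disc) else 1,
       alpha_red = alpha_red(f_eux, f_red, curve, n_disc),
       alpha_oxic = 1,
       oxic_clamped = f_oxic_raw < 0)
}

#' Vectorized reducing-sink alphas for an ensemble
#'
#' Computes \code{alpha_red} for many (f_eux, f_red) pairs at once, sharing the
#' window discretization; used by \code{\link{run_ensemble}} where per-run
#' looping would dominate the runtime.
#'
#' @param f_eux,f_red equal-length vectors of seafloor fractions.
#' @inheritParams euxinic_depth_window
#' @return numeric vector of coefficients.
#' @export
alpha_red_vec <- function(f_eux, f_red, curve, n_disc = 100) {
  n <- length(f_eux)
  stopifnot(length(f_red) == n)
  f_lo_e <- ifelse(f_eux <= 0.95, 0.05, 1 - f_eux)
  f_lo <- ifelse(f_eux > 0, f_lo_e + f_eux, 0.05)
  f_hi <- f_lo + f_red
  shift <- f_hi > 1
  f_lo[shift] <- 1 - f_red[shift]
  f_hi[shift] <- 1
  steps <- (seq_len(n_disc) - 0.5) / n_disc
  mids <- rep(f_lo, each = n_disc) + rep(f_hi - f_lo, each = n_disc) * steps
  terms <- remin_term(pmax(curve$depth_at(mids), 1))
  num <- colMeans(matrix(terms, nrow = n_disc))
  # same alpha_eux.min convention as alpha_eux(): the euxinic window's
  # shallow edge
  denom_z <- pmax(ifelse(f_eux > 0, curve$depth_at(f_lo_e), curve$depth_at(0.05)), 1)
  out <- num / remin_term(denom_z)
  out[f_red == 0] <- 1
  out
}
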