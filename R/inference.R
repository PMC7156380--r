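# Inference: compatibility filtering of the Monte Carlo ensemble against
# measured isotope records.
#
# Each ensemble run projects one steady seawater state onto three sediment
# archives (euxinic shale d98Mo and d238U, carbonate d238U). A run is
# compatible with a set of measured records when its projection for EVERY
# supplied proxy lies within that record's measured range (or, in bin mode,
# in a bin occupied by measurements); the retained f_eux values form the
# filtered distribution summarized by nearest-rank percentiles.

.proxy_columns <- c(d98mo_eux = "d98mo_eux_sed",
                    d238u_eux = "d238u_eux_sed",
                    d238u_carb = "d238u_carb_sed")

#' Build a measured record
#'
#' @param proxy one of "d98mo_eux", "d238u_eux", "d238u_carb".
#' @param values measured values (permil); at least 2 (5 for LOESS use).
#' @param sigma2 optional per-observation 2-sigma uncertainties.
#' @param depth_m,age_ma optional per-observation depths or ages.
#' @param archive free-text archive label.
#' @return a \code{measured_record} list.
#' @export
measured_record <- function(proxy, values, sigma2 = NULL,
                            depth_m = NULL, age_ma = NULL, archive = "") {
  proxy <- match.arg(proxy, names(.proxy_columns))
  if (length(values) < 2) stop("a record needs at least 2 observations")
  structure(list(proxy = proxy, values = values, sigma2 = sigma2,
                 depth_m = depth_m, age_ma = age_ma, archive = archive),
            class = "measured_record")
}

#' Nearest-rank percentile
#'
#' The smallest sample value whose cumulative rank reaches the requested
#' fraction: sorted x at index ceiling(p * n). On grid-valued samples this
#' returns an actual grid value.
#'
#' @param x numeric sample.
#' @param p probability in (0, 1].
#' @return the percentile value.
#' @export
quantile_nearest_rank <- function(x, p) {
  n <- length(x)
  if (n == 0) stop("empty sample")
  sort(x)[pmax(ceiling(p * n), 1)]
}

#' Summarize a filtered f_eux sample
#'
#' Mean, median and 5th/95th percentiles (nearest-rank convention, so
#' percentiles land on actual scenario-grid values).
#'
#' @param feux numeric vector of retained f_eux fractions.
#' @return list \code{mean, median, p5, p95, n_retained}.
#' @export
summarize_feux <- function(feux) {
  if (length(feux) == 0) stop("empty f_eux sample")
  list(mean = mean(feux),
       median = quantile_nearest_rank(feux, 0.5),
       p5 = quantile_nearest_rank(feux, 0.05),
       p95 = quantile_nearest_rank(feux, 0.95),
       n_retained = length(feux))
}

# Per-proxy compatibility mask over ensemble rows.
proxy_mask <- function(ensemble, record, mode, n_bins, widen_sigma) {
  col <- .proxy_columns[[record$proxy]]
  vals <- record$values
  proj <- ensemble[[col]]
  if (mode == "range") {
    lo <- min(vals); hi <- max(vals)
    if (widen_sigma && !is.null(record$sigma2)) {
      lo <- min(vals - record$sigma2); hi <- max(vals + record$sigma2)
    }
    proj >= lo & proj <= hi
  } else {
    breaks <- .proxy_breaks(vals, n_bins)
    occupied <- unique(.bin_index(vals, breaks))
    bin <- .bin_index(proj, breaks)
    !is.na(bin) & bin %in% occupied
  }
}

# Uniform bins over the measured range; a constant record degenerates to one
# narrow bin around its value so filtering on it remains defined.
.proxy_breaks <- function(vals, n_bins) {
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) {
    eps <- max(abs(lo) * 1e-9, 1e-9)
    lo <- lo - eps; hi <- hi + eps
  }
  seq(lo, hi, length.out = n_bins + 1)
}

# Half-open bins [b_k, b_{k+1}) with the top bin closed; NA outside the range.
.bin_index <- function(x, breaks) {
  n_bins <- length(breaks) - 1
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  idx[idx < 1 | idx > n_bins] <- NA_integer_
  idx
}

#' Filter the ensemble against measured records
#'
#' Retains runs whose projected sediment value for every supplied proxy is
#' compatible with that proxy's record: within the record's inclusive
#' min-max range ("range" mode, optionally widened by the per-observation
#' 2-sigma) or falling in one of the record-occupied uniform bins
#' ("bin" mode, \code{n_bins} between the measured min and max). Joint,
#' per-run filtering: one run must satisfy all proxies simultaneously.
#'
#' @param ensemble a \code{\link{run_ensemble}} table.
#' @param records list of \code{\link{measured_record}}s.
#' @param mode "range" (default) or "bin".
#' @param n_bins bins per proxy in bin mode.
#' @param widen_sigma widen range bounds by the per-observation 2-sigma.
#' @return list with the \code{\link{summarize_feux}} summary, the retained
#'   \code{feux} values, \code{proxies} used and \code{empty} flag.
#' @export
range_filter <- function(ensemble, records, mode = c("range", "bin"),
                         n_bins = 10, widen_sigma = FALSE) {
  mode <- match.arg(mode)
  if (inherits(records, "measured_record")) records <- list(records)
  keep <- rep(TRUE, nrow(ensemble))
  for (rec in records) {
    keep <- keep & proxy_mask(ensemble, rec, mode, n_bins, widen_sigma)
  }
  feux <- ensemble$f_eux[keep]
  if (length(feux) == 0) {
    return(list(summary = NULL, feux = numeric(0),
                proxies = vapply(records, `[[`, "", "proxy"), empty = TRUE))
  }
  list(summary = summarize_feux(feux), feux = feux,
       proxies = vapply(records, `[[`, "", "proxy"), empty = FALSE)
}

#' Linear stratigraphic age model
#'
#' Linear interpolation between (depth, age) anchor pairs; ages must decrease
#' upsection (increase with depth). Depths outside the anchored span are
#' linearly extrapolated from the nearest segment and flagged.
#'
#' @param anchors data.frame with columns \code{depth_m}, \code{age_ma}
#'   (>= 2 rows).
#' @return an \code{age_model} function-carrying list.
#' @export
age_model <- function(anchors) {
  stopifnot(nrow(anchors) >= 2)
  o <- order(anchors$depth_m)
  d <- anchors$depth_m[o]; a <- anchors$age_ma[o]
  if (any(diff(a) <= 0)) stop("ages must increase with depth (decrease upsection)")
  structure(list(anchors = data.frame(depth_m = d, age_ma = a)),
            class = "age_model")
}

#' Convert depth to age under an age model
#'
#' @param depth_m numeric depths.
#' @param model an \code{\link{age_model}}.
#' @return data.frame \code{age_ma}, \code{extrapolated}.
#' @export
depth_to_age <- function(depth_m, model) {
  d <- model$anchors$depth_m; a <- model$anchors$age_ma
  inside <- depth_m >= min(d) & depth_m <= max(d)
  age <- approx(d, a, xout = depth_m, rule = 2)$y
  # linear extrapolation beyond the anchored span, flagged
  lo <- depth_m < min(d); hi <- depth_m > max(d)
  if (any(lo)) {
    s <- (a[2] - a[1]) / (d[2] - d[1])
    age[lo] <- a[1] + s * (depth_m[lo] - d[1])
  }
  if (any(hi)) {
    n <- length(d)
    s <- (a[n] - a[n - 1]) / (d[n] - d[n - 1])
    age[hi] <- a[n] + s * (depth_m[hi] - d[n])
  }
  data.frame(age_ma = age, extrapolated = !inside)
}

#' Cross-validated LOESS smoother
#'
#' Local regression of y on x with the span selected by leave-one-out
#' cross-validation over a span grid; returns a function evaluable at
#' arbitrary x within (and clamped to) the data span.
#'
#' @param x,y numeric vectors (>= 5 points).
#' @param spans candidate spans.
#' @param degree local polynomial degree (default 1; degree-1 LOESS
#'   reproduces exactly linear data to machine precision).
#' @return list with \code{predict(newx)}, chosen \code{span},
#'   \code{cv_error} table and the data \code{range}.
#' @export
loess_cv_fit <- function(x, y, spans = seq(0.3, 1, by = 0.05), degree = 1) {
  if (length(x) < 5) stop("LOESS smoothing needs at least 5 points")
  cv <- vapply(spans, function(s) loo_cv_error(x, y, span = s, degree = degree),
               numeric(1))
  if (all(!is.finite(cv))) stop("no candidate span produced a valid LOESS fit")
  span <- spans[which.min(cv)]
  fit <- suppressWarnings(loess(y ~ x, span = span, degree = degree,
                                control = loess.control(surface = "direct")))
  rng <- range(x)
  structure(list(
    predict = function(newx) {
      newx <- pmin(pmax(newx, rng[1]), rng[2])
      as.numeric(suppressWarnings(predict(fit, data.frame(x = newx))))
    },
    span = span, cv_error = data.frame(span = spans, loo_mse = cv),
    range = rng), class = "loess_cv_fit")
}

#' Time-dependent f_eux reconstruction
#'
#' At fixed timesteps, each proxy record that temporally covers the timestep
#' contributes a "measured" value from its cross-validated LOESS smoother;
#' the value is assigned to one of the proxy's uniform bins (spanning the
#' measured min-max), and ensemble runs whose projection falls in the same
#' bin are retained. The joint retained set across covering proxies yields a
#' per-timestep f_eux summary, and cross-validated LOESS curves through the
#' median / 5th / 95th percentile series form the envelope.
#'
#' @param ensemble a \code{\link{run_ensemble}} table.
#' @param records list of \code{\link{measured_record}}s carrying
#'   \code{age_ma} (directly or via \code{models}).
#' @param models optional named list of \code{\link{age_model}}s keyed by
#'   proxy, applied to records that carry \code{depth_m} but no ages.
#' @param t_start,t_end reconstruction window (Ma; start older).
#' @param dt timestep (Myr, default 0.02 = 20 kyr).
#' @param n_bins proxy-specific bins between measured min and max.
#' @return list: \code{timesteps} data.frame (age_ma, n_retained, mean,
#'   median, p5, p95, n_proxies), and \code{envelope} with LOESS-smoothed
#'   median/p5/p95 curves at the same ages (NA in record gaps).
#' @export
reconstruct_timeseries <- function(ensemble, records, models = NULL,
                                   t_start = 444.7, t_end = 440.8, dt = 0.02,
                                   n_bins = 10) {
  ages <- seq(t_start, t_end, by = -dt)
  prox <- list()
  for (rec in records) {
    rec_age <- rec$age_ma
    if (is.null(rec_age)) {
      if (is.null(models[[rec$proxy]])) {
        stop("record for ", rec$proxy, " has no ages and no age model")
      }
      rec_age <- depth_to_age(rec$depth_m, models[[rec$proxy]])$age_ma
    }
    if (length(rec$values) < 5) stop("timeseries records need >= 5 observations")
    sm <- loess_cv_fit(rec_age, rec$values)
    breaks <- .proxy_breaks(rec$values, n_bins)
    col <- .proxy_columns[[rec$proxy]]
    prox[[length(prox) + 1]] <- list(
      span = range(rec_age), smoother = sm, breaks = breaks,
      ens_bin = .bin_index(ensemble[[col]], breaks))
  }
  n_t <- length(ages)
  res <- data.frame(age_ma = ages, n_retained = NA_integer_,
                    mean = NA_real_, median = NA_real_,
                    p5 = NA_real_, p95 = NA_real_, n_proxies = 0L)
  for (ti in seq_len(n_t)) {
    t <- ages[ti]
    keep <- rep(TRUE, nrow(ensemble))
    covering <- 0L
    for (p in prox) {
      if (t < p$span[1] || t > p$span[2]) next
      covering <- covering + 1L
      # clamp into the measured range so boundary predictions stay binnable
      v <- p$smoother$predict(t)
      v <- min(max(v, p$breaks[1]), p$breaks[length(p$breaks)])
      bin <- .bin_index(v, p$breaks)
      keep <- keep & !is.na(p$ens_bin) & p$ens_bin == bin
    }
    res$n_proxies[ti] <- covering
    if (covering == 0L) next  # gap: no proxy covers this timestep
    feux <- ensemble$f_eux[keep]
    res$n_retained[ti] <- length(feux)
    if (length(feux) > 0) {
      s <- summarize_feux(feux)
      res$mean[ti] <- s$mean; res$median[ti] <- s$median
      res$p5[ti] <- s$p5; res$p95[ti] <- s$p95
    }
  }
  ok <- !is.na(res$median)
  envelope <- data.frame(age_ma = ages, median = NA_real_,
                         p5 = NA_real_, p95 = NA_real_)
  if (sum(ok) >= 5) {
    for (colname in c("median", "p5", "p95")) {
      sm <- loess_cv_fit(res$age_ma[ok], res[[colname]][ok])
      v <- sm$predict(ages)
      v[ages < min(res$age_ma[ok]) | ages > max(res$age_ma[ok])] <- NA_real_
      envelope[[colname]] <- pmin(pmax(v, 0), 1)
    }
  }
  list(timesteps = res, envelope = envelope)
}
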