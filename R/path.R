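#' Z-standardise a series
#'
#' Centre to mean 0 and scale to sample standard deviation 1.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return standardised vector (NAs preserved).
#' @export
zscale <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot z-scale a constant series")
  (x - mean(x, na.rm = TRUE)) / s
}

path_rate_names <- function(split_immigration = FALSE) {
  base <- c("phi_a_male", "phi_a_female", "phi_j_male", "phi_j_female",
            "fecundity")
  if (split_immigration) c(base, "immigration_male", "immigration_female")
  else c(base, "immigration")
}

path_weather_names <- function() c("wetbulb_mean", "n_storms", "espi_lag2")

#' Fit the seven path regressions for one posterior draw
#'
#' Given one draw's annual vital-rate and growth series and the (already
#' z-scaled) weather covariates, fits by least squares: one multiple linear
#' regression of each z-scaled vital rate on the three weather metrics
#' (rows with a missing lagged ESPI are dropped listwise), and one of
#' z-scaled `lambda_t` on all z-scaled vital rates. Vital-rate series are
#' z-scaled within the draw.
#'
#' @param rates data.frame with one row per annual transition and one
#'   column per rate in `rate_names`, plus a `lambda` column.
#' @param weather_z data.frame with the same rows and columns
#'   `wetbulb_mean`, `n_storms`, `espi_lag2` (z-scaled; `espi_lag2` may be
#'   `NA` in early rows).
#' @param rate_names character vector of vital-rate column names.
#' @return list with `a` (rates x weather direct-effect matrix) and `b`
#'   (named vector of rate -> lambda effects).
#' @export
fit_path_draw <- function(rates, weather_z,
                          rate_names = path_rate_names()) {
  wn <- path_weather_names()
  W <- as.matrix(weather_z[, wn])
  keep <- stats::complete.cases(W)
  if (sum(keep) < length(wn) + 2) {
    stop("too few complete years for the weather regressions")
  }
  Zrate <- vapply(rate_names, function(rn) zscale(rates[[rn]]),
                  numeric(nrow(rates)))
  a <- matrix(NA_real_, nrow = length(rate_names), ncol = length(wn),
              dimnames = list(rate_names, wn))
  Xw <- cbind(1, W[keep, , drop = FALSE])
  qrXw <- qr(Xw)
  if (qrXw$rank < ncol(Xw)) {
    stop("weather design is rank deficient; collinear column(s): ",
         paste(colnames(Xw)[-seq_len(qrXw$rank)], collapse = ", "))
  }
  for (rn in rate_names) {
    a[rn, ] <- qr.coef(qrXw, Zrate[keep, rn])[-1]
  }
  Xr <- cbind(1, Zrate)
  qrXr <- qr(Xr)
  if (qrXr$rank < ncol(Xr)) {
    stop("vital-rate design is rank deficient within this draw")
  }
  b <- qr.coef(qrXr, zscale(rates$lambda))[-1]
  names(b) <- rate_names
  list(a = a, b = b)
}

#' Posterior-propagating path analysis
#'
#' Refits the seven-regression path system once for every retained IPM
#' posterior draw, so that the uncertainty of the IPM is carried into the
#' weather-effect estimates.
#'
#' Every series is labelled by its end year `t`: the weather metrics of
#' year `t` (including the 2-year-lagged ESPI, the documented driver of
#' return rates in this system) predict the apparent survival over
#' `t-1 -> t`, the immigrant arrivals at `t`, the fecundity of season `t`,
#' and the growth `lambda_t = N_t / N_{t-1}`. One row per transition; rows
#' whose lagged ESPI is undefined are dropped from the weather -> rate
#' regressions only.
#'
#' @param post an `ipm_posterior`.
#' @param weather data.frame from [weather_series()] covering the study
#'   years (raw scale; weather is z-scaled once, across study years).
#' @param split_immigration model male and female immigration as separate
#'   predictors instead of their sum.
#' @param max_draws optionally subsample the posterior to at most this many
#'   draws (evenly spaced), for speed.
#' @return object of class `path_effects`: list with `a` (draw x rate x
#'   weather array of direct weather effects), `b` (draw x rate matrix of
#'   rate -> lambda effects), `net` (draw x weather matrix of net effects,
#'   computed draw-by-draw as `sum_rate a * b`), `rate_names`,
#'   `weather_names`.
#' @export
run_path_analysis <- function(post, weather, split_immigration = FALSE,
                              max_draws = NULL) {
  dr <- extract_vital_draws(post)
  years <- post$years
  T <- length(years)
  wy <- weather[match(years, weather$year), , drop = FALSE]
  if (anyNA(wy$year)) stop("weather table must cover every study year")

  wz <- data.frame(
    wetbulb_mean = zscale(wy$wetbulb_mean),
    n_storms = zscale(wy$n_storms),
    espi_lag2 = zscale(wy$espi_lag2)
  )[2:T, , drop = FALSE]  # predictor = weather of the transition-end year

  rn <- path_rate_names(split_immigration)
  nd <- nrow(dr$F)
  use <- seq_len(nd)
  if (!is.null(max_draws) && nd > max_draws) {
    use <- unique(round(seq(1, nd, length.out = max_draws)))
  }
  wn <- path_weather_names()
  a <- array(NA_real_, dim = c(length(use), length(rn), length(wn)),
             dimnames = list(NULL, rn, wn))
  b <- matrix(NA_real_, nrow = length(use), ncol = length(rn),
              dimnames = list(NULL, rn))
  for (i in seq_along(use)) {
    d <- use[i]
    rates <- data.frame(
      phi_a_male = dr$phi_a[d, 1, ],
      phi_a_female = dr$phi_a[d, 2, ],
      phi_j_male = dr$phi_j[d, 1, ],
      phi_j_female = dr$phi_j[d, 2, ],
      fecundity = dr$F[d, 2:T],
      lambda = dr$lambda[d, ]
    )
    if (split_immigration) {
      rates$immigration_male <- dr$I[d, 1, ]
      rates$immigration_female <- dr$I[d, 2, ]
    } else {
      rates$immigration <- dr$I[d, 1, ] + dr$I[d, 2, ]
    }
    fit <- fit_path_draw(rates, wz, rate_names = rn)
    a[i, , ] <- fit$a
    b[i, ] <- fit$b
  }
  net <- net_effects(a, b)
  structure(list(a = a, b = b, net = net, rate_names = rn,
                 weather_names = wn, n_draws = length(use)),
            class = "path_effects")
}

#' Net weather effects on population growth
#'
#' For each posterior draw and weather metric, the net effect is the sum
#' over vital rates of (direct weather -> rate effect) x (direct rate ->
#' lambda effect). Computed draw-by-draw, never from averaged coefficients.
#'
#' @param a draw x rate x weather array of direct weather effects.
#' @param b draw x rate matrix of rate -> lambda effects.
#' @return draw x weather matrix of net effects.
#' @export
net_effects <- function(a, b) {
  if (dim(a)[1] != nrow(b) || dim(a)[2] != ncol(b)) {
    stop("mismatched draw or rate dimensions between a and b")
  }
  wn <- dimnames(a)[[3]]
  net <- matrix(NA_real_, nrow = nrow(b), ncol = length(wn),
                dimnames = list(NULL, wn))
  for (w in seq_along(wn)) {
    aw <- matrix(a[, , w], nrow = dim(a)[1])
    net[, w] <- rowSums(aw * b)
  }
  net
}

#' Summarise a path analysis
#'
#' Posterior mean and central 95% interval for every direct weather -> rate
#' effect, every rate -> lambda effect, and every net weather -> lambda
#' effect.
#'
#' @param effects a `path_effects` object.
#' @param level interval probability (default 0.95).
#' @return data.frame `effect_type` (`direct_weather`, `direct_rate`,
#'   `net`), `weather`, `rate`, `mean`, `lower`, `upper`.
#' @export
summarize_effects <- function(effects, level = 0.95) {
  if (effects$n_draws < 2) stop("need at least 2 draws")
  alpha <- (1 - level) / 2
  summ <- function(x) c(mean = mean(x),
                        lower = unname(stats::quantile(x, alpha)),
                        upper = unname(stats::quantile(x, 1 - alpha)))
  rows <- list()
  for (w in effects$weather_names) {
    for (r in effects$rate_names) {
      s <- summ(effects$a[, r, w])
      rows[[length(rows) + 1]] <- data.frame(
        effect_type = "direct_weather", weather = w, rate = r,
        mean = s["mean"], lower = s["lower"], upper = s["upper"])
    }
  }
  for (r in effects$rate_names) {
    s <- summ(effects$b[, r])
    rows[[length(rows) + 1]] <- data.frame(
      effect_type = "direct_rate", weather = NA_character_, rate = r,
      mean = s["mean"], lower = s["lower"], upper = s["upper"])
  }
  for (w in effects$weather_names) {
    s <- summ(effects$net[, w])
    rows[[length(rows) + 1]] <- data.frame(
      effect_type = "net", weather = w, rate = NA_character_,
      mean = s["mean"], lower = s["lower"], upper = s["upper"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
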