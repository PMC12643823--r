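test_that("z-scaling centres and scales to unit sample SD", {
  expect_equal(zscale(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(20, 5, 3)
  z <- zscale(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(zscale(z), z, tolerance = 1e-12)
  expect_error(zscale(rep(2, 5)), "constant")
})

toy_path_data <- function(seed = 1, n = 8, b = NULL) {
  set.seed(seed)
  w <- data.frame(wetbulb_mean = rnorm(n), n_storms = rnorm(n),
                  espi_lag2 = rnorm(n))
  rates <- data.frame(
    phi_a_male = runif(n, 0.4, 0.7), phi_a_female = runif(n, 0.3, 0.6),
    phi_j_male = runif(n, 0.1, 0.3), phi_j_female = runif(n, 0.1, 0.3),
    fecundity = runif(n, 1, 4), immigration = rpois(n, 50))
  rates$lambda <- runif(n, 0.8, 1.3)
  list(rates = rates, w = w)
}

test_that("path coefficients equal the normal-equations solution", {
  td <- toy_path_data(3)
  fit <- fit_path_draw(td$rates, td$w)
  # independent oracle: solve the normal equations directly
  X <- cbind(1, as.matrix(td$w))
  for (rn in rownames(fit$a)) {
    beta <- solve(t(X) %*% X, t(X) %*% zscale(td$rates[[rn]]))
    expect_equal(unname(fit$a[rn, ]), unname(beta[-1, 1]),
                 tolerance = 1e-10)
  }
  Z <- cbind(1, vapply(setdiff(names(td$rates), "lambda"),
                       function(v) zscale(td$rates[[v]]), numeric(8)))
  bz <- solve(t(Z) %*% Z, t(Z) %*% zscale(td$rates$lambda))
  expect_equal(unname(fit$b), unname(bz[-1, 1]), tolerance = 1e-10)
})

test_that("a known weather slope is recovered", {
  # the response carries a standardized-slope-0.8 signal plus unit-filling
  # variation orthogonal to the design (so re-standardizing the response
  # leaves the slope at 0.8) and a small independent perturbation
  set.seed(14)
  slopes <- replicate(200, {
    w <- data.frame(wetbulb_mean = zscale(rnorm(8)),
                    n_storms = zscale(rnorm(8)),
                    espi_lag2 = zscale(rnorm(8)))
    e <- residuals(lm(rnorm(8) ~ ., data = w))
    e <- e / sd(e)
    rates <- toy_path_data(sample.int(1e6, 1))$rates
    rates$phi_a_male <- 0.8 * w$wetbulb_mean + 0.6 * e +
      rnorm(8, 0, 0.01)
    fit_path_draw(rates, w)$a["phi_a_male", "wetbulb_mean"]
  })
  expect_lt(max(abs(slopes - 0.8)), 0.05)
  expect_lt(abs(mean(slopes) - 0.8), 0.01)
  # and a null response gives slopes centred on zero
  set.seed(15)
  null_slopes <- replicate(300, {
    w <- data.frame(wetbulb_mean = rnorm(8), n_storms = rnorm(8),
                    espi_lag2 = rnorm(8))
    rates <- toy_path_data(sample.int(1e6, 1))$rates
    fit_path_draw(rates, w)$a["phi_a_male", "wetbulb_mean"]
  })
  expect_lt(abs(mean(null_slopes)), 3 * sd(null_slopes) / sqrt(300))
})

test_that("rank-deficient designs are refused with a diagnosis", {
  td <- toy_path_data(4)
  td$w$n_storms <- td$w$wetbulb_mean
  expect_error(fit_path_draw(td$rates, td$w), "rank deficient")
})

test_that("net effects are the draw-wise sum of effect products", {
  a <- array(NA_real_, dim = c(1, 2, 1),
             dimnames = list(NULL, c("r1", "r2"), "espi_lag2"))
  a[1, , 1] <- c(0.5, 0.2)
  b <- matrix(c(0.4, -0.5), 1, dimnames = list(NULL, c("r1", "r2")))
  expect_equal(unname(net_effects(a, b)[1, 1]), 0.5 * 0.4 + 0.2 * (-0.5))
  expect_equal(unname(net_effects(a, 0 * b)[1, 1]), 0)
  expect_error(net_effects(a, rbind(b, b)), "mismatch")
})

test_that("effect summaries are empirical means and quantiles", {
  nd <- 4000
  a <- array(0.3, dim = c(nd, 1, 3),
             dimnames = list(NULL, "r1", path_weather_names()))
  b <- matrix(1, nd, 1, dimnames = list(NULL, "r1"))
  eff <- structure(list(a = a, b = b, net = net_effects(a, b),
                        rate_names = "r1",
                        weather_names = path_weather_names(),
                        n_draws = nd), class = "path_effects")
  s <- summarize_effects(eff)
  expect_true(all(s$lower == s$upper))   # constant draws: zero width
  set.seed(6)
  a[, 1, ] <- rnorm(nd * 3)
  eff$a <- a; eff$net <- net_effects(a, b)
  s2 <- summarize_effects(eff)
  dir <- s2[s2$effect_type == "direct_weather", ]
  expect_equal(dir$lower, rep(-1.96, 3), tolerance = 0.08)
  expect_equal(dir$upper, rep(1.96, 3), tolerance = 0.08)
})

test_that("the posterior path analysis propagates IPM uncertainty", {
  fx <- shared_fixture()
  post <- shared_fit()
  ws <- weather_series(fx$weather$daily, fx$weather$espi_monthly,
                       years = sort(unique(fx$weather$espi_monthly$year)))
  pe <- run_path_analysis(post, ws, max_draws = 400)
  expect_equal(pe$n_draws, 400)
  expect_setequal(pe$rate_names, path_rate_names())
  # net identity holds draw by draw
  w1 <- pe$weather_names[1]
  expect_equal(pe$net[, w1], rowSums(pe$a[, , w1] * pe$b),
               tolerance = 1e-12)
  # widening the posterior of the vital rates widens the effect intervals
  post2 <- post
  jit <- post$draws
  set.seed(9)
  phi_cols <- grep("^phi_", colnames(jit))
  jit[, phi_cols] <- 0.3 + 0.6 * matrix(runif(length(phi_cols) *
                                                nrow(jit)),
                                        nrow(jit))
  post2$draws <- jit
  pe2 <- run_path_analysis(post2, ws, max_draws = 400)
  width <- function(p) {
    s <- summarize_effects(p)
    mean(s$upper[s$effect_type == "net"] - s$lower[s$effect_type == "net"])
  }
  expect_gt(width(pe2), width(pe))
  # split immigration option exposes both sexes
  pe3 <- run_path_analysis(post, ws, split_immigration = TRUE,
                           max_draws = 50)
  expect_true(all(c("immigration_male", "immigration_female") %in%
                    pe3$rate_names))
})

test_that("a configured weather effect is recovered with the right sign", {
  # strong negative lagged-ESPI effect on adult survival, recovered from
  # the generator's true rate series (regression stage in isolation)
  set.seed(30)
  hits <- replicate(40, {
    truth <- simulation_truth("paper-like", effects = list(
      phi_a = c(wetbulb_mean = 0, n_storms = 0, espi_lag2 = -0.8),
      phi_j = c(wetbulb_mean = 0, n_storms = 0, espi_lag2 = 0),
      fecundity = c(wetbulb_mean = 0, n_storms = 0, espi_lag2 = 0),
      immigration = c(wetbulb_mean = 0, n_storms = 0, espi_lag2 = 0)))
    sd_seed <- sample.int(1e6, 1)
    w <- simulate_weather(2011:2021, truth$weather, seed = sd_seed)
    ws <- weather_series(w$daily, w$espi_monthly, years = 2011:2021)
    pop <- simulate_population(truth, w, seed = sd_seed + 1)
    led <- pop$ledger$rates
    rates <- data.frame(
      phi_a_male = led$phi_a[1, -1], phi_a_female = led$phi_a[2, -1],
      phi_j_male = led$phi_j[1, -1] + rnorm(8, 0, 1e-6),
      phi_j_female = led$phi_j[2, -1] + rnorm(8, 0, 1e-6),
      fecundity = led$fecundity[-1] + rnorm(8, 0, 1e-6),
      immigration = colSums(led$immigration)[-1] + rnorm(8, 0, 1e-6),
      lambda = pop$ledger$lambda)
    wz <- ws[match(truth$years, ws$year), ]
    wzd <- data.frame(wetbulb_mean = zscale(wz$wetbulb_mean),
                      n_storms = zscale(wz$n_storms),
                      espi_lag2 = zscale(wz$espi_lag2))[-1, ]
    fit <- fit_path_draw(rates, wzd)
    fit$a["phi_a_male", "espi_lag2"] < 0
  })
  expect_gte(mean(hits), 0.95)
})
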