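test_that("single-history likelihoods match hand-computed fates", {
  # released at 1, detected at the final occasion 2: phi * p
  ch <- matrix(c(1L, 1L), 1, 2)
  ll <- cjs_log_likelihood(ch, phi = matrix(0.5, 1, 1),
                           p = matrix(0.4, 1, 2))
  expect_equal(exp(ll), 0.5 * 0.4, tolerance = 1e-12)
  # released at 1, never seen over one remaining occasion:
  # dead (1 - phi) or alive-but-missed phi * (1 - p)
  ch0 <- matrix(c(1L, 0L), 1, 2)
  ll0 <- cjs_log_likelihood(ch0, phi = matrix(0.5, 1, 1),
                            p = matrix(0.4, 1, 2))
  expect_equal(exp(ll0), 0.5 + 0.5 * 0.6, tolerance = 1e-12)
  # certain survival and detection, fully detected history
  ch1 <- matrix(1L, 1, 4)
  expect_equal(cjs_log_likelihood(ch1, phi = matrix(1, 1, 3),
                                  p = matrix(1, 1, 4)), 0)
})

test_that("parameters outside [0, 1] are rejected", {
  ch <- matrix(c(1L, 1L), 1, 2)
  expect_error(cjs_log_likelihood(ch, phi = matrix(1.2, 1, 1),
                                  p = matrix(0.4, 1, 2)), "0, 1")
})

test_that("likelihood equals exhaustive fate enumeration (5 occasions)", {
  set.seed(31)
  T <- 5
  for (rep in 1:20) {
    phi <- runif(T - 1, 0.05, 0.95)
    p <- runif(T, 0.05, 0.95)
    f <- sample.int(T - 1, 1)
    h <- integer(T); h[f] <- 1L
    later <- seq.int(f + 1, T)
    h[later] <- rbinom(length(later), 1, 0.5)
    ll <- cjs_log_likelihood(matrix(h, 1), phi = matrix(phi, 1),
                             p = matrix(p, 1))
    expect_equal(exp(ll), enumerate_cjs(h, phi, p), tolerance = 1e-12)
  }
})

test_that("history probabilities for a release cohort sum to one", {
  phi <- c(0.6, 0.45, 0.7)
  p <- c(0.9, 0.3, 0.5, 0.25)
  pats <- expand.grid(rep(list(0:1), 3))
  tot <- sum(apply(pats, 1, function(tail) {
    h <- c(1L, as.integer(tail))
    exp(cjs_log_likelihood(matrix(h, 1), matrix(phi, 1), matrix(p, 1)))
  }))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("group rates expand with the juvenile one-year transition", {
  H <- rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L))
  ch <- tiny_caphist(H, c("juvenile_female", "adult_male"))
  phi_a <- rbind(c(0.6, 0.61, 0.62), c(0.5, 0.51, 0.52))
  phi_j <- rbind(c(0.2, 0.21, 0.22), c(0.1, 0.11, 0.12))
  ex <- expand_cjs_rates(ch, phi_a, phi_j, p_a = c(0.7, 0.3),
                         p_j = c(0.4, 0.15))
  # juvenile female released at 1: first interval at the juvenile rate,
  # first occasion after marking at the juvenile detection rate
  expect_equal(ex$phi[1, ], c(0.1, 0.51, 0.52))
  expect_equal(ex$p[1, ], c(0.3, 0.15, 0.3, 0.3))
  # adult male: adult rates throughout
  expect_equal(ex$phi[2, ], c(0.6, 0.61, 0.62))
  expect_equal(ex$p[2, ], c(0.7, 0.7, 0.7, 0.7))
})

test_that("m-arrays count first recaptures and re-releases by age class", {
  H <- rbind(c(1L, 1L, 0L, 1L),   # juvenile male: recaptured at 2, then 4
             c(1L, 0L, 0L, 0L),   # juvenile male: never seen again
             c(0L, 1L, 0L, 0L),   # adult female released at 2, never again
             c(1L, 0L, 1L, 0L))   # adult male: first recapture at 3
  ch <- tiny_caphist(H, c("juvenile_male", "juvenile_male",
                          "adult_female", "adult_male"))
  m <- build_marray(ch)
  jm <- matrix(0L, 3, 4); jm[1, 1] <- 1L; jm[1, 4] <- 1L
  expect_equal(m$juv_male, jm)
  # the recaptured juvenile male re-enters as an adult release at 2
  am <- matrix(0L, 3, 4); am[2, 3] <- 1L; am[1, 2] <- 1L; am[3, 4] <- 1L
  expect_equal(m$ad_male, am)
  af <- matrix(0L, 3, 4); af[2, 4] <- 1L
  expect_equal(m$ad_female, af)
  # every detection before the last occasion is a release
  n_rel <- sum(vapply(m, sum, numeric(1)))
  expect_equal(n_rel, sum(H[, 1:3] == 1L))
})

test_that("m-array cell probabilities agree with the history likelihood", {
  T <- 5
  phi_a <- c(0.6, 0.55, 0.65, 0.5)
  phi_j <- c(0.25, 0.2, 0.3, 0.22)
  p_a <- 0.45; p_j <- 0.18
  for (juv in c(TRUE, FALSE)) {
    pr <- marray_cell_probs(phi_a, phi_j, p_a, p_j, T, juvenile = juv)
    expect_equal(unname(rowSums(pr)), rep(1, T - 1), tolerance = 1e-12)
    grp <- if (juv) "juvenile_male" else "adult_male"
    for (r in 1:(T - 1)) {
      # the never-recaptured probability is the chi of a single-detection
      # history released at r
      h <- integer(T); h[r] <- 1L
      ch <- tiny_caphist(matrix(h, 1), grp)
      ex <- expand_cjs_rates(ch, rbind(phi_a, phi_a), rbind(phi_j, phi_j),
                             p_a = c(p_a, p_a), p_j = c(p_j, p_j))
      expect_equal(pr[r, T], exp(cjs_log_likelihood(ch, ex$phi, ex$p)),
                   tolerance = 1e-12)
      # a first-recapture cell is survive x miss x detect, which equals
      # the likelihood of the two-detection history divided by the chi
      # of the re-release
      for (j in r:(T - 1)) {
        h2 <- integer(T); h2[r] <- 1L; h2[j + 1] <- 1L
        ch2 <- tiny_caphist(matrix(h2, 1), grp)
        ex2 <- expand_cjs_rates(ch2, rbind(phi_a, phi_a),
                                rbind(phi_j, phi_j),
                                p_a = c(p_a, p_a), p_j = c(p_j, p_j))
        lik2 <- exp(cjs_log_likelihood(ch2, ex2$phi, ex2$p))
        h3 <- integer(T); h3[j + 1] <- 1L
        ch3 <- tiny_caphist(matrix(h3, 1),
                            if (juv) "adult_male" else grp)
        ex3 <- expand_cjs_rates(ch3, rbind(phi_a, phi_a),
                                rbind(phi_j, phi_j),
                                p_a = c(p_a, p_a), p_j = c(p_j, p_j))
        chi3 <- exp(cjs_log_likelihood(ch3, ex3$phi, ex3$p))
        expect_equal(pr[r, j], lik2 / chi3, tolerance = 1e-12)
      }
    }
  }
})

test_that("a cohort with zero survival is never recaptured", {
  truth <- simulation_truth("paper-like",
                            phi_a = c(male = 0, female = 0),
                            phi_j = c(male = 0, female = 0),
                            immigration_mean = c(male = 30, female = 30),
                            initial_N = c(male = 50, female = 50))
  weather <- simulate_weather(2011:2021, truth$weather, seed = 3)
  pop <- simulate_population(truth, weather, seed = 4)
  d <- ingest_simulated(pop, truth, seed = 5)
  H <- d$histories$histories
  after_first <- mapply(function(i, f) any(H[i, -seq_len(f)] == 1L),
                        seq_len(nrow(H)), d$histories$first_occasion)
  expect_false(any(after_first))
})
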