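# Independent CJS oracle: sums the probability of a history over every
# compatible latent fate (alive through occasion a, then dead/emigrated),
# conditional on first capture. Deliberately brute force; no code shared
# with cjs_log_likelihood().
enumerate_cjs <- function(h, phi, p) {
  T <- length(h)
  f <- which(h == 1L)[1]
  last <- max(which(h == 1L))
  total <- 0
  for (a in f:T) {           # alive through occasion a
    if (a < last) next       # must be alive at every detection
    pr <- 1
    if (a > f) for (t in f:(a - 1)) pr <- pr * phi[t]
    if (a < T) pr <- pr * (1 - phi[a])
    if (a > f) {
      for (t in (f + 1):a) {
        pr <- pr * if (h[t] == 1L) p[t] else (1 - p[t])
      }
    }
    total <- total + pr
  }
  total
}

# Build a capture_histories object directly from a 0/1 matrix.
tiny_caphist <- function(mat, group, years = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("id%03d", seq_len(nrow(mat)))
  }
  if (is.null(years)) years <- 2000 + seq_len(ncol(mat)) - 1
  colnames(mat) <- years
  structure(list(
    histories = mat,
    first_occasion = apply(mat, 1, function(r) which(r == 1L)[1]),
    group = factor(group, levels = c("juvenile_male", "juvenile_female",
                                     "adult_male", "adult_female")),
    years = as.integer(years)),
    class = "capture_histories")
}

# Ingest a simulated population through the real CSV path.
ingest_simulated <- function(pop, truth, seed = 1) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(pop$encounters, f, row.names = FALSE)
  rec <- assign_unknown_sex(read_encounters(f), seed = seed)
  unlink(f)
  list(
    records = rec,
    histories = build_capture_histories(rec, years = truth$years),
    counts = build_counts(rec, years = truth$years),
    productivity = build_productivity(nest_table = stats::setNames(
      pop$productivity, c("year", "females", "juveniles")))
  )
}

# Reduced MCMC settings used for desk-scale fits in the tests.
test_mcmc <- function(seed) {
  mcmc_config(n_chains = 2, n_iterations = 6000, burn_in = 3000, thin = 5,
              seed = seed)
}

# One shared paper-like fixture and IPM fit, computed lazily and cached for
# the whole test session.
.shared <- new.env(parent = emptyenv())

shared_fixture <- function() {
  if (is.null(.shared$fx)) {
    truth <- simulation_truth("paper-like")
    wyears <- (min(truth$years) - 2):max(truth$years)
    weather <- simulate_weather(wyears, truth$weather, seed = 42)
    pop <- simulate_population(truth, weather, seed = 43)
    .shared$fx <- list(truth = truth, weather = weather, pop = pop,
                       data = ingest_simulated(pop, truth, seed = 7))
  }
  .shared$fx
}

shared_fit <- function() {
  if (is.null(.shared$post)) {
    fx <- shared_fixture()
    .shared$post <- suppressWarnings(
      fit_ipm(fx$data$counts, fx$data$histories, fx$data$productivity,
              config = test_mcmc(5)))
  }
  .shared$post
}
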