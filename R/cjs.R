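#' Cormack-Jolly-Seber log-likelihood of annual capture histories
#'
#' Computes the CJS likelihood conditional on first capture, with fully
#' general per-individual, per-occasion parameters: `phi[i, t]` is the
#' probability that individual `i` survives (and stays in the study area)
#' over the interval from occasion `t` to `t + 1`, and `p[i, t]` the
#' probability it is detected at occasion `t` given alive and present.
#' Group- and age-structured models (sex x age classes, the juvenile ->
#' adult transition one year after first capture) are expressed by building
#' the per-individual matrices with [expand_cjs_rates()].
#'
#' The likelihood of one history is the product of the observed segment
#' (survive and be detected/missed between first and last detection) and the
#' probability `chi` of never being seen after the last detection, where
#' `chi_t = (1 - phi_t) + phi_t (1 - p_{t+1}) chi_{t+1}` sums the bird's two
#' latent fates (dead/emigrated vs alive but missed).
#'
#' @param histories individuals x occasions 0/1 matrix (or a
#'   `capture_histories` object).
#' @param phi individuals x (occasions - 1) survival matrix.
#' @param p individuals x occasions detection matrix (column 1 is unused:
#'   the model conditions on first capture).
#' @param first optional integer vector of first-capture occasions; derived
#'   from the histories when omitted.
#' @param by_individual return the per-individual log-likelihood vector
#'   instead of the total.
#' @return Total log-likelihood (scalar) or a vector per individual.
#' @export
cjs_log_likelihood <- function(histories, phi, p, first = NULL,
                               by_individual = FALSE) {
  if (inherits(histories, "capture_histories")) {
    if (is.null(first)) first <- histories$first_occasion
    histories <- histories$histories
  }
  H <- as.matrix(histories)
  n <- nrow(H); T <- ncol(H)
  phi <- as.matrix(phi); p <- as.matrix(p)
  if (!all(dim(phi) == c(n, T - 1))) stop("phi must be n x (T-1)")
  if (!all(dim(p) == c(n, T))) stop("p must be n x T")
  if (any(phi < 0 | phi > 1) || any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("survival and detection probabilities must lie in [0, 1]")
  }
  if (is.null(first)) first <- apply(H, 1, function(r) which(r == 1L)[1])
  if (anyNA(first)) stop("every history must contain at least one detection")

  ll <- numeric(n)
  for (i in seq_len(n)) {
    f <- first[i]
    last <- max(which(H[i, ] == 1L))
    li <- 0
    if (last > f) {
      for (t in (f + 1):last) {
        li <- li + log(phi[i, t - 1]) +
          ifelse(H[i, t] == 1L, log(p[i, t]), log1p(-p[i, t]))
      }
    }
    # chi: never seen again after `last`
    chi <- 1
    if (last < T) {
      for (t in (T - 1):last) {
        chi <- (1 - phi[i, t]) + phi[i, t] * (1 - p[i, t + 1]) * chi
      }
    }
    ll[i] <- li + log(chi)
  }
  if (by_individual) ll else sum(ll)
}

#' Expand group-level CJS rates to per-individual matrices
#'
#' Builds the per-individual survival and detection matrices used by
#' [cjs_log_likelihood()] from group-level parameters. A bird first captured
#' as an adult uses its sex's adult rates throughout. A bird first captured
#' as a juvenile survives its first interval with the juvenile rate and is
#' detected at the first occasion after marking with the juvenile recapture
#' probability; from then on it uses the adult rates of its sex.
#'
#' @param caphist a `capture_histories` object.
#' @param phi_a adult survival: matrix 2 x (T-1), rows `male`, `female`
#'   (recycled from a length-2 vector for time-constant rates).
#' @param phi_j juvenile first-interval survival, same shape.
#' @param p_a adult detection probability per sex (length-2 vector `male`,
#'   `female`, or 2 x T matrix).
#' @param p_j juvenile detection probability per sex, same shape.
#' @return list with `phi` (n x (T-1)) and `p` (n x T).
#' @export
expand_cjs_rates <- function(caphist, phi_a, phi_j, p_a, p_j) {
  H <- caphist$histories
  n <- nrow(H); T <- ncol(H)
  as_mat <- function(x, nc) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == 2, ncol(x) == nc)
      x
    } else {
      stopifnot(length(x) == 2)
      matrix(rep(x, nc), nrow = 2)
    }
  }
  phi_a <- as_mat(phi_a, T - 1); phi_j <- as_mat(phi_j, T - 1)
  p_a <- as_mat(p_a, T); p_j <- as_mat(p_j, T)

  grp <- as.character(caphist$group)
  sex_idx <- ifelse(grepl("female", grp), 2L, 1L)
  juv <- grepl("juvenile", grp)
  first <- caphist$first_occasion

  phi <- phi_a[sex_idx, , drop = FALSE]
  p <- p_a[sex_idx, , drop = FALSE]
  for (i in which(juv)) {
    f <- first[i]
    if (f <= T - 1) phi[i, f] <- phi_j[sex_idx[i], f]
    if (f + 1 <= T) p[i, f + 1] <- p_j[sex_idx[i], f + 1]
  }
  list(phi = phi, p = p)
}

#' Summarise capture histories as m-arrays
#'
#' Condenses the individual histories into the sufficient statistics of the
#' CJS likelihood: for each release cohort, the number first recaptured at
#' each later occasion (or never). Four arrays are produced, one per sex for
#' juvenile first-releases and one per sex for adult releases; a
#' juvenile-marked bird moves to its sex's adult array at every re-release
#' after its first recapture.
#'
#' @param caphist a `capture_histories` object.
#' @return list of four (T-1) x T integer matrices named `juv_male`,
#'   `juv_female`, `ad_male`, `ad_female`; column `j < T` counts birds first
#'   recaptured at occasion `j + 1`, column `T` those never seen again.
#' @export
build_marray <- function(caphist) {
  H <- caphist$histories
  n <- nrow(H); T <- ncol(H)
  empty <- matrix(0L, nrow = T - 1, ncol = T)
  marr <- list(juv_male = empty, juv_female = empty,
               ad_male = empty, ad_female = empty)
  grp <- as.character(caphist$group)
  sex <- ifelse(grepl("female", grp), "female", "male")
  juv <- grepl("juvenile", grp)

  for (i in seq_len(n)) {
    occ <- which(H[i, ] == 1L)
    for (k in seq_along(occ)) {
      r <- occ[k]
      if (r == T) break
      as_juv <- juv[i] && k == 1L
      key <- paste0(if (as_juv) "juv_" else "ad_", sex[i])
      j <- if (k < length(occ)) occ[k + 1L] else T  # T = never recaptured
      col <- if (j == T && k == length(occ)) T else j - 1L
      marr[[key]][r, col] <- marr[[key]][r, col] + 1L
    }
  }
  marr
}

#' Expected m-array cell probabilities
#'
#' Computes, for a release cohort of the given age class and sex-specific
#' rates, the multinomial cell probabilities matching [build_marray()].
#' Used both for tests and to mirror the JAGS model in R.
#'
#' @param phi_a,phi_j length T-1 survival per interval for this sex.
#' @param p_a,p_j scalar detection probabilities for this sex.
#' @param T number of occasions.
#' @param juvenile whether the cohort was released as juveniles.
#' @return (T-1) x T matrix of probabilities; rows sum to 1.
#' @export
marray_cell_probs <- function(phi_a, phi_j, p_a, p_j, T, juvenile) {
  pr <- matrix(0, T - 1, T)
  for (r in seq_len(T - 1)) {
    for (j in r:(T - 1)) {
      # released at r, first recaptured at occasion j + 1
      surv <- if (juvenile) phi_j[r] else phi_a[r]
      miss <- 1
      if (j > r) {
        for (t in (r + 1):j) {
          miss <- miss * (1 - if (juvenile && t == r + 1) p_j else p_a)
          surv <- surv * phi_a[t]
        }
      }
      pdet <- if (juvenile && j == r) p_j else p_a
      pr[r, j] <- surv * miss * pdet
    }
    pr[r, T] <- 1 - sum(pr[r, seq_len(T - 1)])
  }
  pr
}
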