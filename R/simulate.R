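#' Piecewise logistic map with a mid-series change in the dynamical rule
#'
#' Iterates the logistic map x_{t+1} = r x_t (1 - x_t) with parameter
#' `r_before` up to `change_index` and `r_after` afterwards, after a burn-in
#' on the first regime. A change in r changes the rule generating the
#' series while leaving its range similar — the minimal planted regime shift
#' for testing mutual prediction.
#'
#' @param n Series length.
#' @param change_index Last index governed by the first regime
#'   (0 < change_index < n).
#' @param r_before,r_after Map parameters, each in (0, 4].
#' @param seed Seed drawing the initial condition (ignored when `x0` given).
#' @param x0 Optional initial condition in (0, 1).
#' @param burn Burn-in iterations under the first regime.
#' @return Numeric series of length `n`.
#' @export
piecewise_map <- function(n, change_index, r_before, r_after = r_before,
                          seed = 1L, x0 = NULL, burn = 100L) {
  for (r in c(r_before, r_after)) {
    if (!is.finite(r) || r <= 0 || r > 4) stop("map parameter outside (0, 4]")
  }
  if (change_index <= 0 || change_index >= n) {
    stop("change_index must satisfy 0 < change_index < n")
  }
  if (is.null(x0)) {
    set.seed(seed)
    x0 <- stats::runif(1, 0.05, 0.95)
  }
  x <- x0
  for (i in seq_len(burn)) x <- r_before * x * (1 - x)
  out <- numeric(n)
  out[1] <- x
  for (t in 2:n) {
    r <- if (t <= change_index) r_before else r_after
    out[t] <- r * out[t - 1] * (1 - out[t - 1])
  }
  out
}

#' Configuration for the community simulator
#'
#' Defaults emulate the monitored coastal fish community: 95 species observed
#' over 88 monthly surveys, strong seasonality with a 12-month period,
#' species turnover through seasonal immigration of warm-affinity
#' (low-latitude) species, and a warming regime shift (+2 degrees C in the
#' forcing mean) midway through the series, analogous to the restart of a
#' thermal discharge.
#'
#' @param n_species Number of species in the pool.
#' @param n_time Number of surveys.
#' @param change_index Survey after which the forcing mean shifts (NULL for a
#'   stationary control).
#' @param warming Shift of the temperature mean after `change_index` (deg C).
#' @param season_amp Seasonal temperature amplitude (deg C).
#' @param season_period Seasonal period in surveys (12 = monthly data).
#' @param interaction_scale Scale of off-diagonal Ricker interactions.
#' @param immigration Mean immigration pulse (individuals/survey) for
#'   warm-affinity species.
#' @param env_noise SD of temperature noise (deg C).
#' @param proc_noise SD of lognormal process noise on growth.
#' @param seed RNG seed, recorded in the output metadata.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 95, n_time = 88, change_index = 44,
                              warming = 2, season_amp = 4, season_period = 12,
                              interaction_scale = 0.1, immigration = 0.5,
                              env_noise = 0.5, proc_noise = 0.15, seed = 1L) {
  cfg <- list(n_species = n_species, n_time = n_time,
              change_index = change_index, warming = warming,
              season_amp = season_amp, season_period = season_period,
              interaction_scale = interaction_scale,
              immigration = immigration, env_noise = env_noise,
              proc_noise = proc_noise, seed = seed)
  rates <- c("warming", "season_amp", "interaction_scale", "immigration",
             "env_noise", "proc_noise")
  if (any(unlist(cfg[rates]) < 0)) stop("rates must be >= 0")
  if (!is.null(change_index) &&
      (change_index <= 0 || change_index >= n_time)) {
    stop("change_index must lie inside the series")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a seasonally forced multispecies community
#'
#' Multispecies Ricker dynamics with temperature-dependent growth:
#' each species has a Gaussian thermal performance curve whose optimum is
#' tied to its latitudinal centre of distribution (low-COD species prefer
#' warm water), so the seasonal temperature cycle drives immigration-like
#' booms of warm-affinity species in summer and their local disappearance in
#' winter (species turnover). The optional regime shift raises the mean of
#' the forcing temperature — a warming analogue that changes the dynamical
#' rule, not just the state. Observations are Poisson counts around the
#' latent abundances, as in visual-census data.
#'
#' @param cfg A [simulation_config()].
#' @return List: `community` (a `community_ts`), `species` (metadata table
#'   with taxonomy and COD), `temperature`, `latent`, `config`.
#' @export
community_sim <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_species; nt <- cfg$n_time
  sp <- species_pool(ns)
  warm <- (max(sp$cod_latitude) - sp$cod_latitude) /
    diff(range(sp$cod_latitude))                      # 1 = lowest latitude
  t_opt <- 14 + 12 * warm                             # deg C optimum
  t_breadth <- stats::runif(ns, 4, 7)
  r <- stats::runif(ns, 0.6, 1.4)
  K <- exp(stats::rnorm(ns, mean = log(25) - 1.5 * warm, sd = 0.8))
  A <- matrix(stats::rnorm(ns^2, 0, cfg$interaction_scale), ns, ns) *
    (matrix(stats::runif(ns^2), ns, ns) < 0.1)   # sparse off-diagonal
  diag(A) <- 1

  tt <- seq_len(nt)
  shift <- if (is.null(cfg$change_index)) 0 else
    cfg$warming * (tt > cfg$change_index)
  temp <- 16 + shift + cfg$season_amp *
    sin(2 * pi * tt / cfg$season_period) +
    stats::rnorm(nt, 0, cfg$env_noise)

  latent <- matrix(0, nt, ns)
  latent[1, ] <- pmax(K * stats::runif(ns, 0.2, 1), 0.01)
  for (t in 2:nt) {
    N <- latent[t - 1, ]
    therm <- -((temp[t] - t_opt)^2 - (16 - t_opt)^2) / (2 * t_breadth^2)
    growth <- r * (1 - as.numeric(A %*% N) / K) + therm +
      stats::rnorm(ns, 0, cfg$proc_noise)
    imm <- cfg$immigration * warm *
      pmax(sin(2 * pi * t / cfg$season_period), 0)
    latent[t, ] <- pmax(N * exp(pmin(growth, 3)), 0) + imm
  }
  if (any(rowSums(latent) < 1e-6)) {
    stop("entire community went extinct; increase K or immigration")
  }
  counts <- matrix(stats::rpois(nt * ns, latent), nt, ns)
  colnames(counts) <- sp$species
  dates <- seq(as.Date("2012-01-15"), by = "month", length.out = nt)
  list(community = community_ts(counts, dates),
       species = sp,
       temperature = temp, latent = latent, config = cfg)
}

# nested taxonomy (order > family > genus) plus COD latitudes for a pool of
# `n` species; warm-affinity species sit at low latitudes
species_pool <- function(n) {
  n_ord <- max(3L, round(n / 15))
  n_fam <- max(n_ord + 1L, round(n / 6))
  n_gen <- max(n_fam + 1L, round(n / 2.5))
  fam_of_gen <- sort(sample.int(n_fam, n_gen, replace = TRUE))
  ord_of_fam <- sort(sample.int(n_ord, n_fam, replace = TRUE))
  gen <- sort(sample.int(n_gen, n, replace = TRUE))
  data.frame(
    species = sprintf("sp%03d", seq_len(n)),
    genus = sprintf("gen%02d", gen),
    family = sprintf("fam%02d", fam_of_gen[gen]),
    order = sprintf("ord%02d", ord_of_fam[fam_of_gen[gen]]),
    cod_latitude = round(stats::runif(n, 12, 42), 1),
    stringsAsFactors = FALSE)
}

#' Archetype mutual-prediction matrices
#'
#' Planted responsiveness archetypes: `uniform` — low sRMSE everywhere
#' (dynamics stable across the whole series); `block` — low within each half,
#' high across the midpoint (a mid-series regime shift); `noisy` — entries
#' scattered over \[0.3, 2\] (erratic, condition-dependent predictability).
#' Gaussian jitter of sd `noise` is added and entries are clamped at 0.
#'
#' @param kind One of "uniform", "block", "noisy".
#' @param n_w Matrix dimension (windows; default 41).
#' @param noise Jitter sd.
#' @param seed RNG seed.
#' @return `n_w` x `n_w` numeric matrix.
#' @export
archetype_matrices <- function(kind = c("uniform", "block", "noisy"),
                               n_w = 41L, noise = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  half <- seq_len(n_w) <= n_w / 2
  base <- switch(kind,
    uniform = matrix(0.5, n_w, n_w),
    block = ifelse(outer(half, half, "=="), 0.5, 1.5),
    noisy = matrix(stats::runif(n_w^2, 0.3, 2.0), n_w, n_w))
  pmax(base + matrix(stats::rnorm(n_w^2, 0, noise), n_w, n_w), 0)
}
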