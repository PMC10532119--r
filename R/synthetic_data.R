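# In-silico study designs: hierarchical species/strain growth parameters,
# two-population generalized Lotka-Volterra dynamics for every well (a
# monoculture is the same strain twice with neutral coupling), plate-reader
# noise, and multinomial cytometry counts — all with planted ground truth.
#
# The "no interaction" null is FULL niche overlap (alpha = 1 on a common
# carrying capacity), not independent growth (alpha = 0): with a total-OD
# readout, two independently growing populations would stack two carrying
# capacities and masquerade as overyielding. Facilitation is planted as
# alpha < 1 (partial niche release), antagonism as alpha > 1 and/or a
# toxicity term tau > 0; tau is what generates true underyielding below
# both monocultures.

#' Species-level default growth parameters
#'
#' Defaults for the five wine-yeast species of the reference design
#' (Hanseniaspora uvarum, Lachancea thermotolerans, Starmerella bacillaris,
#' Saccharomyces cerevisiae, Torulaspora delbrueckii): carrying capacity `K`
#' (OD units), intrinsic growth rate `r` (h^-1) and lag (hours). `K` and `r`
#' are set to the species' monoculture means reported for this design;
#' lags are chosen to give latencies on the few-hours scale typical of
#' these fermentations.
#'
#' @return Tibble `species`, `K`, `r`, `lag`.
#' @export
species_defaults <- function() {
  tibble(
    species = c("Hu", "Lt", "Sb", "Sc", "Td"),
    K = c(1.62, 2.15, 1.42, 2.11, 2.11),
    r = c(0.30, 0.43, 0.17, 0.43, 0.33),
    lag = c(1.5, 1.0, 2.0, 1.0, 1.5)
  )
}

#' Sample a strain registry around species-level defaults
#'
#' Draws `n_strains` strains per species with multiplicative Gaussian
#' strain-level deviations of coefficient of variation `strain_cv` on `K`,
#' `r` and `lag`. Deterministic given `seed`.
#'
#' @param defaults Tibble as from [species_defaults()].
#' @param strain_cv Coefficient of variation of strain deviations (>= 0).
#' @param seed Integer seed.
#' @param n_strains Strains per species (default 3).
#' @param n0_total Total inoculum in OD-equivalents per well (default 0.1,
#'   the OD600 of a 10^6 cells/mL yeast suspension at ~10^7 cells/mL per OD
#'   unit); each of the two well members starts at half of it.
#' @return Tibble `strain`, `species`, `K`, `r`, `lag`, `N0` (per member).
#' @export
sample_strain_params <- function(defaults = species_defaults(),
                                 strain_cv = 0.05, seed = 1L,
                                 n_strains = 3L, n0_total = 0.1) {
  stopifnot(strain_cv >= 0, n_strains >= 1, n0_total > 0)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(defaults)), function(i) {
    f <- matrix(pmax(rnorm(3 * n_strains, 1, strain_cv), 0.2),
                nrow = n_strains)
    tibble(
      strain = paste0(defaults$species[i], seq_len(n_strains)),
      species = defaults$species[i],
      K = defaults$K[i] * f[, 1],
      r = defaults$r[i] * f[, 2],
      lag = defaults$lag[i] * f[, 3],
      N0 = n0_total / 2
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulation scenario
#'
#' Bundles everything needed to generate a full in-silico design: species
#' defaults, strain-level variability, the species-pair interaction
#' structure (niche-overlap coefficients `alpha` and toxicity `tau`),
#' replicate counts, the sampling grid, the noise model and the master
#' seed.
#'
#' @param label Scenario name.
#' @param defaults Species defaults tibble.
#' @param alpha `n_species x n_species` matrix of niche-overlap
#'   coefficients (row species affected BY column species); diagonal and
#'   within-species couplings are 1. Default: all 1 (shared-niche null).
#' @param tau Symmetric matrix of toxicity coefficients (per OD per hour);
#'   default all 0.
#' @param strain_cv Strain-level CV.
#' @param pair_jitter_sd SD of the lognormal multiplicative jitter applied
#'   per strain pair to `alpha` and `tau` (strain-level modulation of the
#'   species-level interaction).
#' @param sigma_od Additive Gaussian OD noise SD per reading.
#' @param lag_sd SD of per-replicate lag jitter (hours).
#' @param n_mono_rep,n_co_rep Biological replicates (3 monoculture, 4
#'   coculture).
#' @param grid Sampling times in hours (default 0 to 24 by 0.5).
#' @param dt Integration step of the fixed-step RK4 scheme (hours).
#' @param n_events Cytometry events per sample (default 10000).
#' @param n0_total Total inoculum OD-equivalents (default 0.1, a 10^6
#'   cells/mL yeast suspension).
#' @param seed Master seed; all per-well randomness derives from it.
#' @return List of class `"sim_scenario"`.
#' @export
sim_scenario <- function(label = "custom", defaults = species_defaults(),
                         alpha = NULL, tau = NULL, strain_cv = 0.05,
                         pair_jitter_sd = 0, sigma_od = 0.02, lag_sd = 0.3,
                         n_mono_rep = 3L, n_co_rep = 4L,
                         grid = seq(0, 24, by = 0.5), dt = 0.01,
                         n_events = 10000L, n0_total = 0.1, seed = 1L) {
  sp <- defaults$species
  ns <- length(sp)
  if (is.null(alpha)) {
    alpha <- matrix(1, ns, ns, dimnames = list(sp, sp))
  }
  if (is.null(tau)) {
    tau <- matrix(0, ns, ns, dimnames = list(sp, sp))
  }
  stopifnot(all(dim(alpha) == ns), all(dim(tau) == ns),
            all(alpha >= 0), all(tau >= 0), all(tau == t(tau)),
            strain_cv >= 0, sigma_od >= 0, lag_sd >= 0,
            n_mono_rep >= 2, n_co_rep >= 2, dt > 0,
            all(diff(grid) > 0), n_events >= 1)
  dimnames(alpha) <- dimnames(tau) <- list(sp, sp)
  structure(
    list(label = label, defaults = defaults, alpha = alpha, tau = tau,
         strain_cv = strain_cv, pair_jitter_sd = pair_jitter_sd,
         sigma_od = sigma_od, lag_sd = lag_sd,
         n_mono_rep = as.integer(n_mono_rep),
         n_co_rep = as.integer(n_co_rep), grid = grid, dt = dt,
         n_events = as.integer(n_events), n0_total = n0_total,
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Neutral (null) scenario
#'
#' The no-interaction reference condition: all species share one carrying
#' capacity, growth rate and lag (full niche overlap, `alpha = 1`, `tau =
#' 0`), with mild strain-level jitter and plate-reader noise. Under this
#' scenario the coculture total-OD curve coincides with the monoculture
#' average up to noise, so the outcome classifier should call case A at
#' roughly its nominal rate.
#'
#' @param seed Master seed.
#' @param strain_cv Strain CV (default 0.03).
#' @param sigma_od OD noise SD (default 0.02).
#' @param ... Passed on to [sim_scenario()].
#' @return A `"sim_scenario"`.
#' @export
scenario_neutral <- function(seed = 1L, strain_cv = 0.03, sigma_od = 0.02,
                             ...) {
  defaults <- species_defaults()
  defaults$K <- 2.0
  defaults$r <- 0.40
  defaults$lag <- 1.5
  sim_scenario(label = "neutral", defaults = defaults,
               strain_cv = strain_cv, sigma_od = sigma_od, seed = seed, ...)
}

#' Species-block scenario with planted interaction structure
#'
#' Uses the species-level growth defaults and plants a species-driven
#' interaction pattern mirroring the reference design's conclusions:
#' antagonism among the three fast fermenters (Sc-Lt, Sc-Td strongly, Lt-Td
#' mildly, via increased niche overlap plus toxicity) and facilitation of
#' total growth in all pairs involving the weak grower Sb (partial niche
#' release, `alpha < 1`). Strain-level lognormal jitter modulates the
#' species-level coefficients.
#'
#' @inheritParams scenario_neutral
#' @param strain_cv Strain CV (default 0.05).
#' @param pair_jitter_sd Strain-pair jitter SD (default 0.1).
#' @return A `"sim_scenario"`.
#' @export
scenario_species_block <- function(seed = 1L, strain_cv = 0.05,
                                   sigma_od = 0.02, pair_jitter_sd = 0.1,
                                   ...) {
  sp <- species_defaults()$species
  ns <- length(sp)
  alpha <- matrix(1, ns, ns, dimnames = list(sp, sp))
  tau <- matrix(0, ns, ns, dimnames = list(sp, sp))
  plant <- function(a, b, alpha_val, tau_val) {
    alpha[a, b] <<- alpha_val
    alpha[b, a] <<- alpha_val
    tau[a, b] <<- tau_val
    tau[b, a] <<- tau_val
  }
  plant("Sc", "Lt", 1.4, 0.04)
  plant("Sc", "Td", 1.4, 0.04)
  plant("Lt", "Td", 1.25, 0.02)
  for (other in c("Sc", "Lt", "Td", "Hu")) {
    plant("Sb", other, 0.55, 0)
  }
  sim_scenario(label = "species_block", alpha = alpha, tau = tau,
               strain_cv = strain_cv, sigma_od = sigma_od,
               pair_jitter_sd = pair_jitter_sd, seed = seed, ...)
}

# Vectorized fixed-step RK4 integration of the two-population gLV system
#   dN_A/dt = r_A N_A (1 - (N_A + a_AB N_B)/K_A) - tau N_A N_B   (after lag)
# across many wells at once. `P` is a data frame with columns K1, r1, N01,
# lag1, K2, r2, N02, lag2, a12, a21, tau. Returns populations at the grid.
simulate_pairs_batch <- function(P, grid = seq(0, 24, by = 0.5), dt = 0.01) {
  stopifnot(all(c("K1", "r1", "N01", "lag1", "K2", "r2", "N02", "lag2",
                  "a12", "a21", "tau") %in% names(P)))
  if (any(P$K1 <= 0 | P$K2 <= 0 | P$r1 <= 0 | P$r2 <= 0 |
          P$N01 <= 0 | P$N02 <= 0 | P$lag1 < 0 | P$lag2 < 0 |
          P$a12 < 0 | P$a21 < 0 | P$tau < 0)) {
    stop("parameter out of admissible range")
  }
  n <- nrow(P)
  K1 <- P$K1; r1 <- P$r1; lag1 <- P$lag1
  K2 <- P$K2; r2 <- P$r2; lag2 <- P$lag2
  a12 <- P$a12; a21 <- P$a21; tau <- P$tau
  N1 <- P$N01
  N2 <- P$N02

  ng <- length(grid)
  out1 <- matrix(NA_real_, n, ng)
  out2 <- matrix(NA_real_, n, ng)

  deriv <- function(t, N1, N2) {
    g1 <- as.numeric(t >= lag1)
    g2 <- as.numeric(t >= lag2)
    list(
      g1 * (r1 * N1 * (1 - (N1 + a12 * N2) / K1) - tau * N1 * N2),
      g2 * (r2 * N2 * (1 - (N2 + a21 * N1) / K2) - tau * N1 * N2)
    )
  }

  t <- grid[1]
  gi <- 1L
  if (abs(t - grid[1]) < 1e-12) {
    out1[, 1] <- N1
    out2[, 1] <- N2
    gi <- 2L
  }
  while (gi <= ng) {
    t_target <- grid[gi]
    nsub <- max(1L, round((t_target - t) / dt))
    h <- (t_target - t) / nsub
    for (s in seq_len(nsub)) {
      k1 <- deriv(t, N1, N2)
      k2 <- deriv(t + h / 2, N1 + h / 2 * k1[[1]], N2 + h / 2 * k1[[2]])
      k3 <- deriv(t + h / 2, N1 + h / 2 * k2[[1]], N2 + h / 2 * k2[[2]])
      k4 <- deriv(t + h, N1 + h * k3[[1]], N2 + h * k3[[2]])
      N1 <- pmax(N1 + h / 6 * (k1[[1]] + 2 * k2[[1]] + 2 * k3[[1]] + k4[[1]]), 0)
      N2 <- pmax(N2 + h / 6 * (k1[[2]] + 2 * k2[[2]] + 2 * k3[[2]] + k4[[2]]), 0)
      t <- t + h
    }
    out1[, gi] <- N1
    out2[, gi] <- N2
    gi <- gi + 1L
  }
  list(n1 = out1, n2 = out2, od = out1 + out2, times = grid)
}

#' Simulate one two-population coculture
#'
#' Integrates the coupled logistic (generalized Lotka-Volterra) system
#' \deqn{dN_A/dt = r_A N_A (1 - (N_A + \alpha_{AB} N_B)/K_A) - \tau N_A N_B}
#' (and symmetrically for B), each population held at its inoculum until its
#' lag elapses, with a fixed-step 4th-order Runge-Kutta scheme. Total OD is
#' `N_A + N_B`. Deterministic.
#'
#' @param params_a,params_b Lists/rows with `K`, `r`, `N0`, `lag`.
#' @param alpha_ab Effect of B's density on A's niche (dimensionless).
#' @param alpha_ba Effect of A on B.
#' @param tau Mutual toxicity coefficient (per OD per hour).
#' @param times Output time grid (hours).
#' @param dt RK4 step (hours, default 0.01).
#' @return List `times`, `n_a`, `n_b`, `od`.
#' @export
#' @examples
#' a <- list(K = 2, r = 0.4, N0 = 0.005, lag = 0)
#' simulate_pair(a, a, 1, 1, 0)$od[49]
simulate_pair <- function(params_a, params_b, alpha_ab = 1, alpha_ba = 1,
                          tau = 0, times = seq(0, 24, by = 0.5), dt = 0.01) {
  P <- data.frame(
    K1 = params_a$K, r1 = params_a$r, N01 = params_a$N0,
    lag1 = params_a$lag %||% 0,
    K2 = params_b$K, r2 = params_b$r, N02 = params_b$N0,
    lag2 = params_b$lag %||% 0,
    a12 = alpha_ab, a21 = alpha_ba, tau = tau
  )
  res <- simulate_pairs_batch(P, grid = times, dt = dt)
  list(times = times, n_a = res$n1[1, ], n_b = res$n2[1, ], od = res$od[1, ])
}

# Species-level interaction coefficients for a strain pair, with the
# deterministic per-pair lognormal jitter already applied.
pair_coefficients <- function(scenario, registry) {
  strains <- registry$strain
  pairs <- as.data.frame(t(combn(strains, 2)), stringsAsFactors = FALSE)
  names(pairs) <- c("strain_1", "strain_2")
  sp <- setNames(registry$species, registry$strain)
  pairs$species_1 <- sp[pairs$strain_1]
  pairs$species_2 <- sp[pairs$strain_2]
  n <- nrow(pairs)
  a12 <- a21 <- tv <- numeric(n)
  for (i in seq_len(n)) {
    s1 <- pairs$species_1[i]
    s2 <- pairs$species_2[i]
    base_a12 <- scenario$alpha[s1, s2]  # effect of strain 2 on strain 1
    base_a21 <- scenario$alpha[s2, s1]
    base_tau <- scenario$tau[s1, s2]
    if (scenario$pair_jitter_sd > 0) {
      set.seed(derive_seed(scenario$seed, i, 4L))
      jit <- exp(rnorm(2, 0, scenario$pair_jitter_sd))
      a12[i] <- base_a12 * jit[1]
      a21[i] <- base_a21 * jit[1]
      tv[i] <- base_tau * jit[2]
    } else {
      a12[i] <- base_a12
      a21[i] <- base_a21
      tv[i] <- base_tau
    }
  }
  pairs$alpha_12 <- a12
  pairs$alpha_21 <- a21
  pairs$tau <- tv
  as_tibble(pairs)
}

#' Simulate a complete study design in memory
#'
#' Generates the full design of the target study: `n_strains_per_species x
#' n_species` strains, every monoculture in `n_mono_rep` replicates and
#' every unordered strain pair in `n_co_rep` replicates, OD600 sampled on
#' the scenario grid with additive Gaussian noise and per-replicate lag
#' jitter, and multinomial cytometry counts (gates = strain ids) at T0 and
#' T24 for the cocultures. A monoculture well is the strain paired with
#' itself (wild type + tagged clone) under neutral coupling. Every source
#' of randomness derives from the scenario's master seed through a per-well
#' counter scheme, so any single well is reproducible in isolation.
#'
#' @param scenario A [sim_scenario()].
#' @param include_mono_cytometry Also emit cytometry for monoculture wells
#'   (gates `tagged`/`wt`); default `FALSE`.
#' @return List: `curves` (long tibble `well`, `time_h`, `od600`), `layout`,
#'   `cytometry`, and `truth` (planted parameters: strain registry, pair
#'   coefficients, per-well lags, and the noiseless per-pair AUC interaction
#'   index and its sign).
#' @export
simulate_dataset <- function(scenario, include_mono_cytometry = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  registry <- sample_strain_params(scenario$defaults, scenario$strain_cv,
                                   seed = derive_seed(scenario$seed, 0L, 0L),
                                   n0_total = scenario$n0_total)
  pairs <- pair_coefficients(scenario, registry)
  reg <- registry
  rownames_reg <- setNames(seq_len(nrow(reg)), reg$strain)

  # --- design table -------------------------------------------------------
  mono <- tibble(
    kind = "monoculture",
    strain_a = rep(reg$strain, each = scenario$n_mono_rep),
    strain_b = rep(reg$strain, each = scenario$n_mono_rep),
    replicate = rep(seq_len(scenario$n_mono_rep), nrow(reg))
  )
  co <- tibble(
    kind = "coculture",
    strain_a = rep(pairs$strain_1, each = scenario$n_co_rep),
    strain_b = rep(pairs$strain_2, each = scenario$n_co_rep),
    replicate = rep(seq_len(scenario$n_co_rep), nrow(pairs))
  )
  design <- dplyr::bind_rows(mono, co)
  design$well <- sprintf("W%03d", seq_len(nrow(design)))
  sp <- setNames(reg$species, reg$strain)
  design$species_a <- unname(sp[design$strain_a])
  design$species_b <- unname(sp[design$strain_b])
  design$run <- ifelse(design$replicate %% 2 == 1, "run1", "run2")
  layout <- design[, c("well", "kind", "strain_a", "strain_b", "species_a",
                       "species_b", "replicate", "run")]

  # --- per-well integration parameters ------------------------------------
  pair_key <- paste(pmin(design$strain_a, design$strain_b),
                    pmax(design$strain_a, design$strain_b), sep = "|")
  pkey <- paste(pairs$strain_1, pairs$strain_2, sep = "|")
  pidx <- match(pair_key, pkey)

  n_wells <- nrow(design)
  ia <- rownames_reg[design$strain_a]
  ib <- rownames_reg[design$strain_b]
  P <- data.frame(
    K1 = reg$K[ia], r1 = reg$r[ia], N01 = reg$N0[ia], lag1 = reg$lag[ia],
    K2 = reg$K[ib], r2 = reg$r[ib], N02 = reg$N0[ib], lag2 = reg$lag[ib],
    a12 = ifelse(design$kind == "monoculture", 1, pairs$alpha_12[pidx]),
    a21 = ifelse(design$kind == "monoculture", 1, pairs$alpha_21[pidx]),
    tau = ifelse(design$kind == "monoculture", 0, pairs$tau[pidx])
  )
  # per-replicate lag jitter, one sub-seed per well (stage 1)
  if (scenario$lag_sd > 0) {
    for (i in seq_len(n_wells)) {
      set.seed(derive_seed(scenario$seed, i, 1L))
      jit <- rnorm(2, 0, scenario$lag_sd)
      P$lag1[i] <- max(0, P$lag1[i] + jit[1])
      P$lag2[i] <- max(0, P$lag2[i] + jit[2])
    }
  }

  sim <- simulate_pairs_batch(P, grid = scenario$grid, dt = scenario$dt)

  # --- plate-reader noise (stage 2) ---------------------------------------
  ng <- length(scenario$grid)
  od_noisy <- sim$od
  if (scenario$sigma_od > 0) {
    for (i in seq_len(n_wells)) {
      set.seed(derive_seed(scenario$seed, i, 2L))
      od_noisy[i, ] <- pmax(sim$od[i, ] + rnorm(ng, 0, scenario$sigma_od), 0)
    }
  }
  curves <- tibble(
    well = rep(design$well, each = ng),
    time_h = rep(scenario$grid, n_wells),
    od600 = as.vector(t(od_noisy))
  )

  # --- cytometry (stage 3) ------------------------------------------------
  cyto <- list()
  t24_i <- ng
  for (i in seq_len(n_wells)) {
    is_mono <- design$kind[i] == "monoculture"
    if (is_mono && !include_mono_cytometry) {
      next
    }
    gates <- if (is_mono) c("tagged", "wt") else
      c(design$strain_a[i], design$strain_b[i])
    sh0 <- c(P$N01[i], P$N02[i])
    sh0 <- sh0 / sum(sh0)
    tot24 <- sim$n1[i, t24_i] + sim$n2[i, t24_i]
    sh24 <- if (tot24 > 0) c(sim$n1[i, t24_i], sim$n2[i, t24_i]) / tot24 else sh0
    set.seed(derive_seed(scenario$seed, i, 3L))
    c0 <- as.vector(rmultinom(1, scenario$n_events, sh0))
    c24 <- as.vector(rmultinom(1, scenario$n_events, sh24))
    cyto[[length(cyto) + 1L]] <- tibble(
      culture_id = design$well[i],
      timepoint = rep(c("T0", "T24"), each = 2),
      gate = rep(gates, 2),
      events = c(c0, c24)
    )
  }
  cytometry <- if (length(cyto)) {
    d <- dplyr::bind_rows(cyto)
    d <- dplyr::group_by(d, .data$culture_id, .data$timepoint)
    d <- dplyr::mutate(d, total_events = sum(.data$events))
    dplyr::ungroup(d)
  } else {
    NULL
  }

  truth <- planted_truth(scenario, registry, pairs)
  truth$well_lags <- tibble(well = design$well, lag_a = P$lag1,
                            lag_b = P$lag2)

  list(curves = curves, layout = layout, cytometry = cytometry,
       truth = truth, scenario = scenario)
}

# Noiseless deterministic reference run: per-pair AUC interaction index and
# its sign (the planted truth for downstream sign-recovery checks).
planted_truth <- function(scenario, registry, pairs, sign_threshold = 0.02) {
  grid <- scenario$grid
  idx <- setNames(seq_len(nrow(registry)), registry$strain)
  mono_P <- data.frame(
    K1 = registry$K, r1 = registry$r, N01 = registry$N0, lag1 = registry$lag,
    K2 = registry$K, r2 = registry$r, N02 = registry$N0, lag2 = registry$lag,
    a12 = 1, a21 = 1, tau = 0
  )
  mono_sim <- simulate_pairs_batch(mono_P, grid, scenario$dt)
  mono_auc <- apply(mono_sim$od, 1, function(y) trapz(grid, y))

  ia <- idx[pairs$strain_1]
  ib <- idx[pairs$strain_2]
  co_P <- data.frame(
    K1 = registry$K[ia], r1 = registry$r[ia], N01 = registry$N0[ia],
    lag1 = registry$lag[ia],
    K2 = registry$K[ib], r2 = registry$r[ib], N02 = registry$N0[ib],
    lag2 = registry$lag[ib],
    a12 = pairs$alpha_12, a21 = pairs$alpha_21, tau = pairs$tau
  )
  co_sim <- simulate_pairs_batch(co_P, grid, scenario$dt)
  co_auc <- apply(co_sim$od, 1, function(y) trapz(grid, y))
  share_24 <- co_sim$n1[, length(grid)] /
    (co_sim$n1[, length(grid)] + co_sim$n2[, length(grid)])

  id_true <- interaction_index(co_auc, mono_auc[ia], mono_auc[ib])
  pairs$auc_index_true <- id_true
  pairs$auc_sign_true <- ifelse(abs(id_true) < sign_threshold, "neutral",
                                ifelse(id_true > 0, "positive", "negative"))
  pairs$share_1_t24_true <- share_24

  list(label = scenario$label, seed = scenario$seed,
       sigma_od = scenario$sigma_od, lag_sd = scenario$lag_sd,
       strain_cv = scenario$strain_cv, registry = registry,
       pairs = pairs, mono_auc_true = setNames(mono_auc, registry$strain))
}

#' Write a simulated dataset to disk
#'
#' Emits the three CSV inputs plus a YAML truth manifest capturing every
#' planted parameter (strain registry, per-pair coefficients, noise model,
#' noiseless interaction indices and their signs).
#'
#' @param scenario A [sim_scenario()].
#' @param dir Output directory.
#' @param include_mono_cytometry Passed to [simulate_dataset()].
#' @return Named character vector of written paths, invisibly; the
#'   simulated dataset is attached as attribute `"dataset"`.
#' @export
emit_dataset <- function(scenario, dir, include_mono_cytometry = FALSE) {
  ds <- simulate_dataset(scenario, include_mono_cytometry)
  paths <- write_dataset(ds$curves, ds$layout, ds$cytometry, dir)
  manifest <- list(
    label = ds$truth$label, seed = ds$truth$seed,
    sigma_od = ds$truth$sigma_od, lag_sd = ds$truth$lag_sd,
    strain_cv = ds$truth$strain_cv,
    n_wells = nrow(ds$layout),
    registry = lapply(seq_len(nrow(ds$truth$registry)), function(i) {
      as.list(ds$truth$registry[i, ])
    }),
    pairs = lapply(seq_len(nrow(ds$truth$pairs)), function(i) {
      as.list(ds$truth$pairs[i, ])
    })
  )
  truth_path <- file.path(dir, "truth_manifest.yml")
  yaml::write_yaml(manifest, truth_path)
  paths <- c(paths, truth_manifest = truth_path)
  attr(paths, "dataset") <- ds
  invisible(paths)
}
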