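# Small programmatic fixtures shared across test files.

# A tiny 2-species (x 3 strains = 6 strains, 78 wells) scenario for fast
# end-to-end checks.
mini_scenario <- function(seed = 11L, strain_cv = 0.04, sigma_od = 0.01,
                          lag_sd = 0.1, ...) {
  defaults <- tibble::tibble(
    species = c("Aa", "Bb"),
    K = c(2.0, 1.5),
    r = c(0.40, 0.25),
    lag = c(1.0, 1.5)
  )
  sim_scenario(label = "mini", defaults = defaults, strain_cv = strain_cv,
               sigma_od = sigma_od, lag_sd = lag_sd, seed = seed, ...)
}

mini_dataset <- function(seed = 11L, ...) {
  simulate_dataset(mini_scenario(seed, ...))
}

# Independent Welch t-test p-value, written from the textbook formulas
# (oracle for the classifier's testing path).
welch_oracle <- function(x, y, alternative = "two.sided") {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  switch(alternative,
         two.sided = 2 * pt(-abs(tstat), df),
         greater = pt(tstat, df, lower.tail = FALSE),
         less = pt(tstat, df))
}

# Planted species-block symmetric interaction matrix: cross-species block
# means are pairwise distinct, separated by `sep` (>= 5 x the within-block
# noise SD `sigma_w`); within-species block means are 0, consistent with the
# zero diagonal (a strain's self-pair is the monoculture reference).
planted_block_matrix <- function(seed = 5L, sigma_w = 0.02, sep = 0.15,
                                 n_species = 5, n_strains = 3) {
  set.seed(seed)
  sp <- LETTERS[seq_len(n_species)]
  strains <- paste0(rep(sp, each = n_strains), rep(seq_len(n_strains), n_species))
  # distinct cross-species block means on a grid spaced `sep` apart
  nblk <- n_species * (n_species - 1) / 2
  means <- sample(seq(-sep * floor(nblk / 2), by = sep, length.out = nblk))
  blk <- matrix(0, n_species, n_species, dimnames = list(sp, sp))
  idx <- 1
  for (i in seq_len(n_species - 1)) {
    for (j in (i + 1):n_species) {
      blk[i, j] <- blk[j, i] <- means[idx]
      idx <- idx + 1
    }
  }
  n <- length(strains)
  m <- matrix(0, n, n, dimnames = list(strains, strains))
  spec_of <- rep(sp, each = n_strains)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- blk[spec_of[i], spec_of[j]] + rnorm(1, 0, sigma_w)
      m[i, j] <- m[j, i] <- v
    }
  }
  attr(m, "species") <- setNames(spec_of, strains)
  m
}

# Logistic curve whose closed-form 24 h AUC equals `target_auc`, obtained by
# solving for K at fixed r and N0/K ratio (oracle input builder for the
# planted-effect classifier checks).
curve_with_auc <- function(target_auc, r = 0.4, n0_frac = 0.005,
                           times = seq(0, 24, 0.5)) {
  f <- function(K) {
    logistic_auc(list(K = K, r = r, N0 = n0_frac * K), 24) - target_auc
  }
  K <- uniroot(f, c(1e-3, 100))$root
  logistic_od(times, K, r, n0_frac * K)
}
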