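# Balanced nested design used throughout: s species x t strains x n reps.
make_nested <- function(species_means, strain_sd, resid_sd, t = 3, n = 3,
                        seed = 1) {
  set.seed(seed)
  s <- length(species_means)
  species <- rep(names(species_means), each = t * n)
  strain <- rep(paste0(rep(names(species_means), each = t),
                       rep(seq_len(t), s)), each = n)
  strain_eff <- rnorm(s * t, 0, strain_sd)
  value <- rep(species_means, each = t * n) +
    rep(strain_eff, each = n) + rnorm(s * t * n, 0, resid_sd)
  list(value = value, species = species, strain = strain)
}

test_that("species F uses the strain-within-species denominator", {
  d <- make_nested(c(A = 10, B = 12, C = 9), strain_sd = 0.5, resid_sd = 0.3)
  res <- nested_anova(d$value, d$species, d$strain)
  tab <- res$table
  # EMS structure: F_species = MS_species / MS_strain, df (s-1, s(t-1))
  expect_equal(tab$df, c(2, 6, 18))
  expect_equal(res$species_F, tab$mean_sq[1] / tab$mean_sq[2])
  expect_equal(res$species_p,
               pf(res$species_F, 2, 6, lower.tail = FALSE))
  expect_equal(res$strain_F, tab$mean_sq[2] / tab$mean_sq[3])

  # permuting strain labels within a species changes nothing
  perm <- d$strain
  swap <- d$species == "A" & d$strain %in% c("A1", "A2")
  perm[swap] <- ifelse(d$strain[swap] == "A1", "A2", "A1")
  res2 <- nested_anova(d$value, d$species, perm)
  expect_equal(res2$species_F, res$species_F, tolerance = 1e-12)
  expect_equal(res2$strain_F, res$strain_F, tolerance = 1e-12)
})

test_that("one strain per species reduces to classical one-way ANOVA", {
  set.seed(7)
  value <- rnorm(15, rep(c(5, 6, 7), each = 5), 1)
  species <- rep(c("A", "B", "C"), each = 5)
  strain <- paste0(species, "1")
  expect_warning(res <- nested_anova(value, species, strain), "residual")
  oneway <- summary(aov(value ~ factor(species)))[[1]]
  expect_equal(res$species_F, oneway$`F value`[1], tolerance = 1e-10)
  expect_equal(res$species_p, oneway$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("balanced nested ANOVA agrees with the mixed-model fit", {
  skip_if_not_installed("lmerTest")
  d <- make_nested(c(A = 10, B = 11, C = 9.5, D = 10.5), strain_sd = 0.4,
                   resid_sd = 0.3, seed = 42)
  res <- nested_anova(d$value, d$species, d$strain)
  fit <- lmerTest::lmer(value ~ species + (1 | species:strain),
                        data = data.frame(d))
  an <- anova(fit)
  expect_equal(res$species_F, an$`F value`[1], tolerance = 1e-6)
  expect_equal(res$species_p, an$`Pr(>F)`[1], tolerance = 1e-6)
})

test_that("null and planted-effect calibration behave as expected", {
  # all-null: species p-values are uniform (type-I ~ alpha)
  set.seed(11)
  pvals <- replicate(200, {
    d <- make_nested(c(A = 10, B = 10, C = 10), strain_sd = 0.3,
                     resid_sd = 0.3, seed = sample.int(1e6, 1))
    nested_anova(d$value, d$species, d$strain)$species_p
  })
  rate <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-9)
  # and not grossly non-uniform elsewhere
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)

  # planted species separation of 10 x residual SD: overwhelming power
  hits <- replicate(50, {
    d <- make_nested(c(A = 10, B = 13, C = 10), strain_sd = 0.3,
                     resid_sd = 0.3, seed = sample.int(1e6, 1))
    nested_anova(d$value, d$species, d$strain)$species_p < 0.01
  })
  expect_gte(mean(hits), 0.9)
})

test_that("letter groups separate species the way the tests do", {
  # identical species -> single letter for all
  d <- make_nested(c(A = 10, B = 10, C = 10), strain_sd = 0.05,
                   resid_sd = 0.05, seed = 3)
  g <- species_letter_groups(nested_anova(d$value, d$species, d$strain))
  expect_true(all(g$letters == "a"))

  # two well-separated blocks (means and noise on the scale of the
  # reference design's AUC summary): two letter groups
  d2 <- make_nested(c(Lt = 26.8, Sc = 28.2, Td = 26.1, Hu = 18.7, Sb = 15.5),
                    strain_sd = 1.0, resid_sd = 0.6, seed = 9)
  g2 <- species_letter_groups(nested_anova(d2$value, d2$species, d2$strain))
  hi <- g2$letters[g2$species %in% c("Lt", "Sc", "Td")]
  lo <- g2$letters[g2$species %in% c("Hu", "Sb")]
  expect_equal(length(unique(hi)), 1)
  expect_false(any(hi %in% lo))

  # three fully separated species -> three distinct letters
  d3 <- make_nested(c(A = 10, B = 20, C = 30), strain_sd = 0.2,
                    resid_sd = 0.2, seed = 5)
  g3 <- species_letter_groups(nested_anova(d3$value, d3$species, d3$strain))
  expect_equal(sort(g3$letters), c("a", "b", "c"))
})
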