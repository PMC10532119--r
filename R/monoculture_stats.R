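# Species and strain-within-species effects on monoculture growth
# parameters. Species and strain are hierarchical: strain is nested in
# species, so in the (near-)balanced design the species effect is tested
# against the strain-within-species mean square (the expected-mean-squares
# denominator that coincides with the mixed model for balanced data), and
# the strain effect against the residual.

#' Nested (hierarchical) ANOVA for species and strain-within-species effects
#'
#' Decomposes a growth parameter measured on replicate monocultures into a
#' species effect and a strain-within-species effect. The species F uses the
#' strain-within-species mean square as its denominator; the strain F uses
#' the residual mean square. When every species has a single strain the
#' strain stratum is empty and the species test falls back to the residual
#' denominator (with a warning), in which case it equals the classical
#' one-way ANOVA.
#'
#' @param value Numeric replicate measurements.
#' @param species Species label per measurement.
#' @param strain Strain label per measurement (nested within species).
#' @return A list of class `"nested_anova"`: `table` (stratum Df/SS/MS/F/p),
#'   `species_summary` (per-species mean, sd, n), plus the denominator mean
#'   square and df used for species-level comparisons.
#' @export
nested_anova <- function(value, species, strain) {
  stopifnot(length(value) == length(species), length(value) == length(strain))
  keep <- is.finite(value)
  value <- value[keep]
  species <- factor(species[keep])
  strain <- factor(paste(species, strain[keep], sep = ":"))
  if (nlevels(species) < 2) {
    stop("need at least two species")
  }
  n_strain <- tapply(strain, species, function(s) length(unique(s)))
  single <- names(n_strain)[n_strain < 2]

  fit <- aov(value ~ species + species:strain)
  tab <- as.data.frame(summary(fit)[[1]])
  rn <- trimws(rownames(tab))
  ms <- setNames(tab[["Mean Sq"]], rn)
  df <- setNames(tab[["Df"]], rn)
  ss <- setNames(tab[["Sum Sq"]], rn)

  has_strain <- "species:strain" %in% rn && df[["species:strain"]] > 0
  if (!has_strain) {
    warning("no strain-within-species stratum; species tested against residual")
    denom_ms <- ms[["Residuals"]]
    denom_df <- df[["Residuals"]]
  } else {
    if (length(single)) {
      warning("species with a single strain: ", paste(single, collapse = ", "),
              "; species test still uses the strain-within-species mean square")
    }
    denom_ms <- ms[["species:strain"]]
    denom_df <- df[["species:strain"]]
  }

  species_F <- ms[["species"]] / denom_ms
  species_p <- pf(species_F, df[["species"]], denom_df, lower.tail = FALSE)
  if (has_strain) {
    strain_F <- ms[["species:strain"]] / ms[["Residuals"]]
    strain_p <- pf(strain_F, df[["species:strain"]], df[["Residuals"]],
                   lower.tail = FALSE)
  } else {
    strain_F <- NA_real_
    strain_p <- NA_real_
  }

  out_tab <- tibble(
    stratum = c("species", "strain_within_species", "residual"),
    df = c(df[["species"]],
           if (has_strain) df[["species:strain"]] else 0L,
           df[["Residuals"]]),
    sum_sq = c(ss[["species"]],
               if (has_strain) ss[["species:strain"]] else 0,
               ss[["Residuals"]]),
    mean_sq = c(ms[["species"]],
                if (has_strain) ms[["species:strain"]] else NA_real_,
                ms[["Residuals"]]),
    F_value = c(species_F, strain_F, NA_real_),
    p_value = c(species_p, strain_p, NA_real_)
  )

  summ <- tibble(species = species, value = value)
  summ <- dplyr::summarise(dplyr::group_by(summ, species),
                           mean = mean(.data$value), sd = sd(.data$value),
                           n = dplyr::n(), .groups = "drop")

  structure(
    list(table = out_tab, species_summary = summ,
         species_F = unname(species_F), species_p = unname(species_p),
         strain_F = unname(strain_F), strain_p = unname(strain_p),
         denom_ms = unname(denom_ms), denom_df = unname(denom_df)),
    class = "nested_anova"
  )
}

#' @export
print.nested_anova <- function(x, ...) {
  cat("Nested ANOVA (species tested against strain-within-species MS)\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Compact letter display for species means
#'
#' Tukey-style all-pairs comparison of species means using the same error
#' term as the species test of [nested_anova()] (strain-within-species mean
#' square and df), followed by an insert-and-absorb compact letter display.
#' Species sharing a letter are not significantly different at `alpha`.
#'
#' @param result A `"nested_anova"` object.
#' @param alpha Familywise significance level (default 0.05).
#' @return Tibble `species`, `mean`, `letters`, ordered by decreasing mean.
#' @export
species_letter_groups <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "nested_anova"), alpha > 0, alpha < 1)
  s <- result$species_summary
  k <- nrow(s)
  # studentized-range p-values on the species means; near-balanced designs
  # use the harmonic mean replicate count
  n_h <- k / sum(1 / s$n)
  se <- sqrt(result$denom_ms / n_h)
  p <- matrix(1, k, k, dimnames = list(s$species, s$species))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      q <- abs(s$mean[i] - s$mean[j]) / se
      p[i, j] <- p[j, i] <- ptukey(q, k, result$denom_df, lower.tail = FALSE)
    }
  }
  sig <- p < alpha
  letters_vec <- cld_insert_absorb(s$mean, sig)
  out <- tibble(species = s$species, mean = s$mean, letters = letters_vec)
  dplyr::arrange(out, dplyr::desc(.data$mean))
}

# Insert-and-absorb compact letter display. `sig` is a symmetric logical
# matrix: TRUE where two treatments differ significantly.
cld_insert_absorb <- function(means, sig) {
  k <- length(means)
  sets <- list(seq_len(k))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  if (nrow(pairs)) {
    for (idx in seq_len(nrow(pairs))) {
      i <- pairs[idx, 1]
      j <- pairs[idx, 2]
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- unique(new_sets[keep])
    }
  }
  # letter sets ordered by their best (largest) member mean
  ord <- order(vapply(sets, function(s) -max(means[s]), numeric(1)))
  sets <- sets[ord]
  out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  out
}

#' Monoculture growth-parameter statistics for a whole dataset
#'
#' Runs [nested_anova()] and [species_letter_groups()] for each of the four
#' kinetic parameters over the monoculture wells.
#'
#' @param params Growth-parameter tibble from [fit_growth()] joined to the
#'   layout (needs columns `kind`, `species_a`, `strain_a` and the four
#'   parameter columns).
#' @param alpha Significance level for letter groups.
#' @return List with `tests` (one row per parameter: F and p for both
#'   strata), `groups` (letter display rows), and the fitted
#'   `"nested_anova"` objects.
#' @export
monoculture_stats <- function(params, alpha = 0.05) {
  mono <- params[params$kind == "monoculture", ]
  if (!nrow(mono)) {
    stop("no monoculture rows in `params`")
  }
  pars <- c(auc = "auc_odh", r = "r_per_h", max_od = "max_od",
            latency = "latency_h")
  fits <- list()
  tests <- list()
  groups <- list()
  for (p in names(pars)) {
    v <- mono[[pars[[p]]]]
    res <- nested_anova(v, mono$species_a, mono$strain_a)
    fits[[p]] <- res
    tests[[p]] <- tibble(
      parameter = p, species_F = res$species_F, species_p = res$species_p,
      strain_F = res$strain_F, strain_p = res$strain_p
    )
    g <- species_letter_groups(res, alpha)
    g$parameter <- p
    groups[[p]] <- g
  }
  list(tests = dplyr::bind_rows(tests), groups = dplyr::bind_rows(groups),
       fits = fits)
}
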