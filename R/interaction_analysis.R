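# Monoculture-referenced interaction index and the four-class coculture
# outcome classifier (A: no perceived interaction; B: overyielding beyond
# the better monoculture; C: underyielding below the worse monoculture;
# D: significantly different from the monoculture average but within the
# monoculture range).

#' Interaction index
#'
#' Signed relative deviation of a coculture parameter from the average of
#' its two monocultures:
#' \deqn{Id = \frac{P_{co} - (P_{m1} + P_{m2})/2}{(P_{m1} + P_{m2})/2}}
#' `Id = 0` means the coculture sits exactly on the monoculture average (no
#' perceived interaction); the index is symmetric in the two monocultures.
#'
#' @param co_mean Coculture parameter value (typically a replicate mean).
#' @param m1_mean,m2_mean Monoculture parameter values of the two member
#'   strains.
#' @return Dimensionless index; `NA` when the monoculture average is zero.
#' @export
#' @examples
#' interaction_index(12, 10, 10) # 0.2
interaction_index <- function(co_mean, m1_mean, m2_mean) {
  ref <- (m1_mean + m2_mean) / 2
  out <- (co_mean - ref) / ref
  out[!is.finite(ref) | abs(ref) < 1e-12] <- NA_real_
  out
}

#' Classify one coculture outcome from replicate parameter values
#'
#' Decision ladder on Welch t-tests at level `alpha`:
#' 1. coculture replicates vs the per-replicate monoculture averages
#'    (`(m1_i + m2_i)/2`, pairing replicates up to the smaller count),
#'    two-sided; not significant = case **A** (no perceived interaction);
#' 2. otherwise, coculture vs the better monoculture's replicates, one-sided
#'    greater; significant = case **B** (overyielding);
#' 3. otherwise, coculture vs the worse monoculture's replicates, one-sided
#'    less; significant = case **C** (underyielding);
#' 4. otherwise case **D** (differs from the average but within range).
#' All three p-values are reported regardless of the branch taken. "Better"
#' and "worse" are by replicate mean on the raw parameter scale; for latency
#' the biological reading of the sign is handled by [effect_direction()].
#'
#' @param co_reps Coculture replicate values (>= 2 finite).
#' @param m1_reps,m2_reps Monoculture replicate values (>= 2 finite each).
#' @param alpha Test level (default 0.05).
#' @return List: `outcome` ("A"/"B"/"C"/"D"), `index`, `p_avg`, `p_max`,
#'   `p_min`, `n_co`, `n_m1`, `n_m2`.
#' @export
classify_coculture <- function(co_reps, m1_reps, m2_reps, alpha = 0.05) {
  co <- co_reps[is.finite(co_reps)]
  m1 <- m1_reps[is.finite(m1_reps)]
  m2 <- m2_reps[is.finite(m2_reps)]
  if (length(co) < 2 || length(m1) < 2 || length(m2) < 2) {
    stop("classify_coculture needs >= 2 finite replicates per group")
  }
  npair <- min(length(m1), length(m2))
  avg <- (m1[seq_len(npair)] + m2[seq_len(npair)]) / 2
  hi <- if (mean(m1) >= mean(m2)) m1 else m2
  lo <- if (mean(m1) >= mean(m2)) m2 else m1

  p_avg <- welch_p(co, avg, "two.sided")
  p_max <- welch_p(co, hi, "greater")
  p_min <- welch_p(co, lo, "less")

  outcome <- if (p_avg >= alpha) {
    "A"
  } else if (p_max < alpha) {
    "B"
  } else if (p_min < alpha) {
    "C"
  } else {
    "D"
  }
  list(outcome = outcome,
       index = interaction_index(mean(co), mean(m1), mean(m2)),
       p_avg = p_avg, p_max = p_max, p_min = p_min,
       n_co = length(co), n_m1 = length(m1), n_m2 = length(m2))
}

#' Biological direction of a classified interaction
#'
#' Case A is neutral by definition. Otherwise the direction follows the sign
#' of the interaction index, inverted for latency: a positive latency index
#' means a longer lag, i.e. delayed growth, hence a negative interaction.
#'
#' @param parameter One of `"auc"`, `"r"`, `"max_od"`, `"latency"`.
#' @param index Interaction index.
#' @param outcome Outcome class from [classify_coculture()].
#' @return `"positive"`, `"negative"` or `"neutral"`.
#' @export
effect_direction <- function(parameter, index, outcome) {
  parameter <- match.arg(parameter, c("auc", "r", "max_od", "latency"))
  if (outcome == "A" || !is.finite(index) || index == 0) {
    return("neutral")
  }
  s <- sign(index)
  if (parameter == "latency") {
    s <- -s
  }
  if (s > 0) "positive" else "negative"
}

#' Classify every coculture of a dataset for all four growth parameters
#'
#' For each unordered strain pair and each kinetic parameter, gathers the
#' coculture replicate values and the two strains' monoculture replicate
#' values, computes the interaction index and the outcome class, and the
#' effect direction. Pairs with fewer than two usable replicates in any
#' group for a parameter are skipped with a message.
#'
#' @param params Growth-parameter tibble from [fit_growth()] joined to the
#'   layout (columns `kind`, `strain_a`, `strain_b`, `species_a`,
#'   `species_b`, `replicate` plus the parameter columns).
#' @param alpha Test level.
#' @return Tibble of interaction records: one row per coculture x parameter.
#' @export
analyze_interactions <- function(params, alpha = 0.05) {
  pars <- c(auc = "auc_odh", r = "r_per_h", max_od = "max_od",
            latency = "latency_h")
  mono <- params[params$kind == "monoculture", ]
  co <- params[params$kind == "coculture", ]
  if (!nrow(co)) {
    stop("no coculture rows in `params`")
  }
  mono_vals <- split(mono, mono$strain_a)
  species_of <- setNames(mono$species_a, mono$strain_a)

  pairs <- unique(co[, c("strain_a", "strain_b", "species_a", "species_b")])
  records <- vector("list", nrow(pairs) * length(pars))
  skipped <- 0L
  idx <- 0L
  for (i in seq_len(nrow(pairs))) {
    s1 <- pairs$strain_a[i]
    s2 <- pairs$strain_b[i]
    co_i <- co[co$strain_a == s1 & co$strain_b == s2, ]
    m1 <- mono_vals[[s1]]
    m2 <- mono_vals[[s2]]
    if (is.null(m1) || is.null(m2)) {
      stop("missing monoculture for strain(s): ",
           paste(setdiff(c(s1, s2), names(mono_vals)), collapse = ", "))
    }
    for (p in names(pars)) {
      idx <- idx + 1L
      v_co <- co_i[[pars[[p]]]]
      v_m1 <- m1[[pars[[p]]]]
      v_m2 <- m2[[pars[[p]]]]
      if (sum(is.finite(v_co)) < 2 || sum(is.finite(v_m1)) < 2 ||
          sum(is.finite(v_m2)) < 2) {
        skipped <- skipped + 1L
        next
      }
      cl <- classify_coculture(v_co, v_m1, v_m2, alpha)
      records[[idx]] <- tibble(
        parameter = p, strain_1 = s1, strain_2 = s2,
        species_1 = pairs$species_a[i], species_2 = pairs$species_b[i],
        index = cl$index, outcome = cl$outcome,
        direction = effect_direction(p, cl$index, cl$outcome),
        p_avg = cl$p_avg, p_max = cl$p_max, p_min = cl$p_min,
        n_co = cl$n_co, n_m1 = cl$n_m1, n_m2 = cl$n_m2
      )
    }
  }
  if (skipped > 0) {
    message(skipped, " coculture x parameter record(s) skipped ",
            "(insufficient usable replicates)")
  }
  dplyr::bind_rows(records)
}

#' Outcome-class summary table
#'
#' Counts and percentages of the outcome classes per growth parameter over
#' all analyzed cocultures (monoculture self-pairs are never part of the
#' records).
#'
#' @param records Tibble from [analyze_interactions()].
#' @return Tibble `parameter`, `outcome`, `n`, `percent`, `n_total`.
#' @export
outcome_summary <- function(records) {
  out <- dplyr::count(records, .data$parameter, .data$outcome)
  out <- dplyr::group_by(out, .data$parameter)
  out <- dplyr::mutate(out, n_total = sum(.data$n),
                       percent = 100 * .data$n / .data$n_total)
  dplyr::ungroup(out)
}
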