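# Cytometry gate counts -> relative abundances -> per-strain fold changes
# between inoculation (T0) and 24 h (T24), with a one-sample test against
# no change (fold change = 1).

#' Relative abundance of each gate in a cytometry sample
#'
#' @param counts Named non-negative integer vector of gate event counts.
#' @return Named fractions summing to 1.
#' @export
#' @examples
#' relative_abundance(c(gfp = 5000, wt = 5000))
relative_abundance <- function(counts) {
  if (any(counts < 0)) {
    stop("negative event count")
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("zero total events")
  }
  counts / total
}

#' Fold change of one strain's relative abundance
#'
#' Final abundance divided by initial abundance for the given gate/strain.
#'
#' @param t0,t24 Named fraction vectors (from [relative_abundance()]) at the
#'   two timepoints.
#' @param strain Gate/strain name present in both.
#' @return Positive fold change; `NA` (with a warning) if the T0 fraction is
#'   zero.
#' @export
fold_change <- function(t0, t24, strain) {
  if (!strain %in% names(t0) || !strain %in% names(t24)) {
    stop("strain ", strain, " absent from a timepoint")
  }
  if (t0[[strain]] <= 0) {
    warning("zero T0 fraction for ", strain, "; fold change undefined")
    return(NA_real_)
  }
  t24[[strain]] / t0[[strain]]
}

#' Test replicate fold changes against 1
#'
#' Two-sided one-sample t-test of the replicate fold changes against 1 (no
#' change in relative abundance), on the raw fold-change scale by default.
#'
#' @param fcs Replicate fold changes (> 0).
#' @param alpha Significance level.
#' @param scale `"raw"` (test fc against 1) or `"log"` (test log(fc)
#'   against 0).
#' @return List: `mean`, `sd`, `n`, `p_value` (`NA` with < 2 replicates),
#'   `significant`.
#' @export
test_fold_changes <- function(fcs, alpha = 0.05, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  fcs <- fcs[is.finite(fcs)]
  m <- mean(fcs)
  s <- if (length(fcs) > 1) sd(fcs) else NA_real_
  if (length(fcs) < 2) {
    return(list(mean = m, sd = s, n = length(fcs), p_value = NA_real_,
                significant = NA))
  }
  x <- if (scale == "log") log(fcs) else fcs
  mu <- if (scale == "log") 0 else 1
  p <- if (sd(x) < 1e-12 * max(1, abs(mean(x)))) {
    if (abs(mean(x) - mu) > 1e-12) 0 else 1
  } else {
    t.test(x, mu = mu)$p.value
  }
  list(mean = m, sd = s, n = length(fcs), p_value = p,
       significant = p < alpha)
}

#' Fold-change table for all cocultures of a dataset
#'
#' Joins the cytometry samples to the layout, computes each strain's
#' relative-abundance fold change per replicate (gates are strain ids), and
#' tests the replicate fold changes of each strain-in-pair against 1. Both
#' orientations of every pair are reported (focal strain with its partner).
#'
#' @param cytometry Tibble from [read_cytometry()].
#' @param layout Tibble from [read_layout()].
#' @param alpha Significance level.
#' @param scale Passed to [test_fold_changes()].
#' @return List with `replicates` (per-replicate fold changes) and `summary`
#'   (per focal strain x partner: `mean_fc`, `sd_fc`, `n`, `p_value`,
#'   `significant`).
#' @export
fold_change_table <- function(cytometry, layout, alpha = 0.05,
                              scale = c("raw", "log")) {
  scale <- match.arg(scale)
  lay <- layout[layout$well %in% unique(cytometry$culture_id), ]
  reps <- list()
  for (i in seq_len(nrow(lay))) {
    w <- lay$well[i]
    samp <- cytometry[cytometry$culture_id == w, ]
    t0 <- samp[samp$timepoint == "T0", ]
    t24 <- samp[samp$timepoint == "T24", ]
    if (!nrow(t0) || !nrow(t24)) {
      next
    }
    f0 <- relative_abundance(setNames(t0$events, t0$gate))
    f24 <- relative_abundance(setNames(t24$events, t24$gate))
    for (g in names(f0)) {
      fc <- if (f0[[g]] > 0) f24[[g]] / f0[[g]] else NA_real_
      partner <- setdiff(names(f0), g)
      reps[[length(reps) + 1L]] <- tibble(
        well = w, kind = lay$kind[i], focal = g,
        partner = if (length(partner)) partner[1] else g,
        replicate = lay$replicate[i], fc = fc
      )
    }
  }
  reps <- dplyr::bind_rows(reps)
  if (!nrow(reps)) {
    stop("no cytometry samples joined to layout wells")
  }
  summ <- dplyr::group_by(reps, .data$kind, .data$focal, .data$partner)
  summ <- dplyr::summarise(summ, res = list(test_fold_changes(
    .data$fc, alpha = alpha, scale = scale)), .groups = "drop")
  summ <- dplyr::mutate(
    summ,
    mean_fc = vapply(.data$res, function(x) x$mean, numeric(1)),
    sd_fc = vapply(.data$res, function(x) x$sd, numeric(1)),
    n = vapply(.data$res, function(x) x$n, numeric(1)),
    p_value = vapply(.data$res, function(x) x$p_value, numeric(1)),
    significant = vapply(.data$res, function(x) isTRUE(x$significant),
                         logical(1))
  )
  summ$res <- NULL
  list(replicates = reps, summary = summ)
}
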