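# End-to-end orchestration: simulate (or read), fit, monoculture stats,
# interaction classification, matrix clustering with stability, fold
# changes, and a plain-text report. Deterministic given config + seeds.

#' Pipeline configuration
#'
#' All tunable constants of the end-to-end analysis, echoed verbatim into
#' the run log (silent defaults are forbidden by design).
#'
#' @param latency_threshold OD600 threshold for latency (default 0.25).
#' @param window_h Analysis window in hours (default 24).
#' @param alpha Test level for the classifier, letter groups and
#'   fold-change tests (default 0.05).
#' @param k_clusters Number of clusters cut from each interaction-matrix
#'   dendrogram (default 5, the number of species in the reference design).
#' @param bootstrap_B Stability resampling iterations (default 1000).
#' @param bootstrap_method `"subset"` or `"bootstrap"`.
#' @param subset_frac Subset fraction for the subset method (default 0.5).
#' @param foldchange_scale `"raw"` or `"log"`.
#' @param seed Master seed (simulation and stability resampling).
#' @param scenario Optional [sim_scenario()] to simulate inputs from; when
#'   `NULL` and no `input_dir` is given, [scenario_species_block()] with
#'   `seed` is used.
#' @param input_dir Optional directory holding `timeseries.csv`,
#'   `layout.csv`, `cytometry.csv` to analyse instead of simulating.
#' @param output_dir Directory for all stage outputs.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(latency_threshold = 0.25, window_h = 24,
                            alpha = 0.05, k_clusters = 5,
                            bootstrap_B = 1000,
                            bootstrap_method = c("subset", "bootstrap"),
                            subset_frac = 0.5,
                            foldchange_scale = c("raw", "log"),
                            seed = 1L, scenario = NULL, input_dir = NULL,
                            output_dir = tempfile("cocult_run_")) {
  bootstrap_method <- match.arg(bootstrap_method)
  foldchange_scale <- match.arg(foldchange_scale)
  stopifnot(latency_threshold > 0, window_h > 0, alpha > 0, alpha < 1,
            k_clusters >= 2, bootstrap_B >= 1, subset_frac > 0,
            subset_frac <= 1)
  structure(
    list(latency_threshold = latency_threshold, window_h = window_h,
         alpha = alpha, k_clusters = as.integer(k_clusters),
         bootstrap_B = as.integer(bootstrap_B),
         bootstrap_method = bootstrap_method, subset_frac = subset_frac,
         foldchange_scale = foldchange_scale, seed = as.integer(seed),
         scenario = scenario, input_dir = input_dir,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

config_echo_lines <- function(config) {
  flat <- config[!vapply(config, is.list, logical(1))]
  flat <- flat[!vapply(flat, is.null, logical(1))]
  c(paste0("config_hash = ", pipeline_hash(config)),
    vapply(names(flat), function(nm) {
      paste0(nm, " = ", paste(format(flat[[nm]]), collapse = ", "))
    }, character(1)))
}

pipeline_hash <- function(config) {
  flat <- config[!vapply(names(config), identical, logical(1), "output_dir")]
  flat$scenario <- if (is.null(config$scenario)) NULL else
    unclass(config$scenario)
  object_hash(flat)
}

#' Run the whole coculture analysis end-to-end
#'
#' Stages: input (simulate from the scenario, or read CSVs from
#' `input_dir`), growth-parameter extraction, monoculture nested ANOVA with
#' letter groups, interaction classification and summary, per-parameter
#' interaction matrix + clustering + bootstrap stability, and cytometry
#' fold changes. Every stage's table is written under
#' `config$output_dir`; any stage error aborts with a stage-tagged message.
#' Reruns with an identical config and seed produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Result bundle (list of all stage outputs, config echo and file
#'   paths), invisibly.
#' @export
run_all <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  echo <- config_echo_lines(config)
  say(paste(echo, collapse = "\n"))
  writeLines(echo, file.path(config$output_dir, "run_config.txt"))

  # -- input ---------------------------------------------------------------
  ds <- stage("input", {
    if (!is.null(config$input_dir)) {
      list(
        curves = read_timeseries(file.path(config$input_dir, "timeseries.csv")),
        layout = read_layout(file.path(config$input_dir, "layout.csv")),
        cytometry = {
          p <- file.path(config$input_dir, "cytometry.csv")
          if (file.exists(p)) read_cytometry(p) else NULL
        }
      )
    } else {
      scen <- config$scenario %||% scenario_species_block(seed = config$seed)
      simulate_dataset(scen)
    }
  })
  say("input: ", length(unique(ds$curves$well)), " wells")

  # -- growth fitting ------------------------------------------------------
  fc <- fit_config(window_h = config$window_h,
                   latency_threshold = config$latency_threshold)
  params <- stage("growth_fitting", {
    p <- fit_growth(ds$curves, fc)
    dplyr::inner_join(ds$layout, p, by = "well")
  })
  readr::write_csv(params, file.path(config$output_dir,
                                     "growth_parameters.csv"))
  say("growth_fitting: ", sum(params$converged), "/", nrow(params),
      " fits converged")

  # -- monoculture stats ---------------------------------------------------
  mono <- stage("monoculture_stats", monoculture_stats(params, config$alpha))
  readr::write_csv(mono$tests, file.path(config$output_dir,
                                         "monoculture_stats.csv"))
  readr::write_csv(mono$groups, file.path(config$output_dir,
                                          "species_groups.csv"))

  # -- interactions --------------------------------------------------------
  records <- stage("interaction_analysis",
                   analyze_interactions(params, config$alpha))
  summary_tbl <- outcome_summary(records)
  readr::write_csv(records, file.path(config$output_dir, "interactions.csv"))
  readr::write_csv(summary_tbl, file.path(config$output_dir,
                                          "outcome_summary.csv"))
  say("interactions: ", nrow(records), " records")

  # -- matrices + clustering + stability -----------------------------------
  matrices <- list()
  clusterings <- list()
  stabilities <- list()
  for (p in unique(records$parameter)) {
    res <- stage(paste0("matrix_clustering/", p), {
      m <- build_interaction_matrix(records, p)
      k <- min(config$k_clusters, nrow(m) - 1L)
      cl <- cluster_matrix(m, k)
      st <- bootstrap_stability(m, k, B = config$bootstrap_B,
                                method = config$bootstrap_method,
                                seed = derive_seed(config$seed, match(
                                  p, c("auc", "r", "max_od", "latency")), 5L),
                                subset_frac = config$subset_frac)
      list(m = m, cl = cl, st = st)
    })
    matrices[[p]] <- res$m
    clusterings[[p]] <- res$cl
    stabilities[[p]] <- res$st
    mt <- as.data.frame(res$m)
    mt <- cbind(strain = rownames(res$m), mt)
    readr::write_csv(mt, file.path(config$output_dir,
                                   paste0("matrix_", p, ".csv")))
    readr::write_csv(
      tibble(strain = names(res$cl$assignments),
             cluster = unname(res$cl$assignments)),
      file.path(config$output_dir, paste0("clusters_", p, ".csv")))
    readr::write_csv(
      tibble(cluster = seq_len(res$st$k), jaccard = res$st$jaccard,
             dissolved = res$st$dissolved, n_assessed = res$st$n_assessed),
      file.path(config$output_dir, paste0("stability_", p, ".csv")))
    writeLines(tree_newick(res$cl),
               file.path(config$output_dir, paste0("tree_", p, ".nwk")))
  }

  # -- fold changes --------------------------------------------------------
  fold <- if (!is.null(ds$cytometry)) {
    f <- stage("abundance_foldchange",
               fold_change_table(ds$cytometry, ds$layout, config$alpha,
                                 config$foldchange_scale))
    readr::write_csv(f$summary, file.path(config$output_dir,
                                          "fold_changes.csv"))
    f
  } else {
    say("abundance_foldchange: no cytometry input, stage skipped")
    NULL
  }

  bundle <- list(
    config = config, config_echo = echo, dataset = ds, params = params,
    monoculture = mono, records = records, outcome_summary = summary_tbl,
    matrices = matrices, clusterings = clusterings,
    stabilities = stabilities, fold_changes = fold,
    output_dir = config$output_dir
  )
  rep_lines <- report(bundle)
  writeLines(rep_lines, file.path(config$output_dir, "report.txt"))
  say("run complete: outputs in ", config$output_dir)
  invisible(bundle)
}

#' Human-readable run report
#'
#' Per-parameter outcome-class table, interaction-matrix snapshots, cluster
#' stability and the significant fold changes, as plain text. Missing
#' stages are reported as explicit gaps.
#'
#' @param bundle Result bundle from [run_all()].
#' @return Character vector of report lines.
#' @export
report <- function(bundle) {
  ln <- c("cocult run report",
          paste0("config_hash: ", pipeline_hash(bundle$config)), "")
  ln <- c(ln, "Outcome classes per growth parameter:")
  s <- bundle$outcome_summary
  for (p in unique(s$parameter)) {
    si <- s[s$parameter == p, ]
    ln <- c(ln, sprintf("  %-8s %s (n=%d)", p,
                        paste(sprintf("%s:%d (%.0f%%)", si$outcome, si$n,
                                      si$percent), collapse = "  "),
                        si$n_total[1]))
  }
  ln <- c(ln, "", "Monoculture species tests (F, p):")
  mt <- bundle$monoculture$tests
  for (i in seq_len(nrow(mt))) {
    ln <- c(ln, sprintf(
      "  %-8s species F=%.2f p=%.3g | strain F=%.2f p=%.3g",
      mt$parameter[i], mt$species_F[i], mt$species_p[i], mt$strain_F[i],
      mt$strain_p[i]))
  }
  ln <- c(ln, "", "Cluster stability (mean Jaccard per cluster):")
  if (length(bundle$stabilities)) {
    for (p in names(bundle$stabilities)) {
      st <- bundle$stabilities[[p]]
      ln <- c(ln, sprintf("  %-8s k=%d  %s", p, st$k,
                          paste(sprintf("%.2f", st$jaccard), collapse = " ")))
    }
  } else {
    ln <- c(ln, "  [missing stage]")
  }
  ln <- c(ln, "", "Fold changes:")
  if (!is.null(bundle$fold_changes)) {
    fs <- bundle$fold_changes$summary
    nsig <- sum(fs$significant & fs$kind == "coculture", na.rm = TRUE)
    ln <- c(ln, sprintf(
      "  %d strain-in-pair records, %d significantly different from 1",
      sum(fs$kind == "coculture"), nsig))
  } else {
    ln <- c(ln, "  [no cytometry input]")
  }
  ln
}
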