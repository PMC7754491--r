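#' Study configuration
#'
#' Assembles and validates the configuration for a full reproducible run: the
#' experimental design and salinity-process block, the synthetic-data
#' generator block, the gating block and the analysis block. Every stochastic
#' stage is seeded from the single root `seed` through a fixed counter scheme,
#' so an identical config yields byte-identical numeric outputs.
#'
#' @param n_fluct,n_const Lines per regime (defaults 32 and 4).
#' @param n_transfers Salinity transfers per line (default 139).
#' @param mu,sigma Stationary mean and SD of the AR1 salinity process.
#' @param treatments Target autocorrelations.
#' @param params A [generator_params()] list.
#' @param days,salinities Assay days and salinities.
#' @param n_events Fixed events per condition, or `NULL` for the
#'   density-limited rule.
#' @param min_red,min_diff,fsc_w_max Gating thresholds.
#' @param cap Subsampling cap per condition (default 150).
#' @param n_perm RDA permutations (default 999).
#' @param B Bootstrap replicates (default 1000).
#' @param analysis_day Day at which the headline regression is run (default 10).
#' @param profile_days Days for the slope profile (default 1:10).
#' @param seed Root seed.
#' @param out_dir Optional output directory for TSVs and the manifest.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_fluct = 32, n_const = 4, n_transfers = 139,
                         mu = 2.4, sigma = 1,
                         treatments = c(-0.5, 0, 0.5, 0.9),
                         params = generator_params(),
                         days = 0:10, salinities = c(0.8, 2.4, 4.0),
                         n_events = NULL,
                         min_red = 3.2, min_diff = 0.5, fsc_w_max = 2.75,
                         cap = 150, n_perm = 999, B = 1000,
                         analysis_day = 10, profile_days = 1:10,
                         seed = 1, out_dir = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (n_fluct %% length(treatments) != 0) {
    stop("`n_fluct` must be divisible by the number of treatments", call. = FALSE)
  }
  assert_scalar_number(seed, "seed")
  if (!analysis_day %in% days) stop("`analysis_day` must be among `days`", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes all stages in order -- design & environment simulation, synthetic
#' study generation, gating (live gate, doublet exclusion, bead correction,
#' balanced subsampling), growth rates & phases, RDA variation partitioning
#' (fluctuating and constant regimes separately, day 0 excluded), and the
#' plasticity analysis (per-line distances, regression on rho^2, hierarchical
#' bootstrap at the analysis day, per-day slope profile, and the two standard
#' group comparisons). Any stage failure aborts with the stage name. When
#' `out_dir` is set, stage tables are written as TSV and a manifest with the
#' config hash and file checksums is saved.
#'
#' @param config A [study_config()] list.
#' @return A result bundle (list of class `study_result`) with elements
#'   `design`, `series`, `densities`, `cells` (gated, corrected, subsampled),
#'   `growth`, `rda_fluctuating`, `rda_constant`, `distances`, `regression`,
#'   `bootstrap`, `profile`, `comparisons`, `manifest` and `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  stages <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  design <- run_stage("design", generate_design(
    n_fluct = config$n_fluct, n_const = config$n_const,
    n_transfers = config$n_transfers, treatments = config$treatments,
    mu = config$mu, sigma = config$sigma, seed = derive_seed(config$seed, 1)))

  study <- run_stage("simulate", generate_study(
    design, params = config$params, days = config$days,
    salinities = config$salinities, n_events = config$n_events,
    seed = derive_seed(config$seed, 2)))

  cells <- run_stage("gate", {
    study$events |>
      gate_alive(min_red = config$min_red, min_diff = config$min_diff) |>
      remove_doublets(fsc_w_max = config$fsc_w_max) |>
      bead_correct(study$beads) |>
      subsample_events(cap = config$cap, seed = derive_seed(config$seed, 3))
  })

  growth <- run_stage("growth", growth_phases(study$densities))

  rda_input <- run_stage("rda", {
    md <- cells |>
      dplyr::filter(.data$day > 0) |>
      dplyr::inner_join(design, by = "line_id") |>
      dplyr::inner_join(dplyr::select(growth, "line_id", "salinity_M", "day",
                                      growth_rate = "r"),
                        by = c("line_id", "salinity_M", "day"))
    fl <- md[md$regime == "fluctuating", ]
    co <- md[md$regime == "constant", ]
    Yf <- as.matrix(fl[corrected_channels()])
    part_f <- rda_partition(Yf, build_design(fl, regime = "fluctuating"),
                            n_perm = config$n_perm,
                            seed = derive_seed(config$seed, 4))
    part_c <- if (nrow(co) > 0) {
      rda_partition(as.matrix(co[corrected_channels()]),
                    build_design(co, regime = "constant"),
                    n_perm = config$n_perm,
                    seed = derive_seed(config$seed, 5))
    } else NULL
    list(fluct = part_f, const = part_c)
  })

  distances <- run_stage("distances", plasticity_distances(cells))

  regression <- run_stage("regression", regress_on_predictability(
    dplyr::filter(distances, .data$day == config$analysis_day), design))

  boot <- run_stage("bootstrap", hierarchical_bootstrap(
    cells, design, day = config$analysis_day, B = config$B, n_cells = config$cap,
    seed = derive_seed(config$seed, 6)))

  profile <- run_stage("profile", slope_profile_by_day(
    cells, design, days = config$profile_days, B = config$B,
    n_cells = config$cap, seed = derive_seed(config$seed, 7)))

  comparisons <- run_stage("comparisons", {
    out <- list()
    const_lines <- design$line_id[design$regime == "constant"]
    high_pred <- design$line_id[design$regime == "fluctuating" &
                                  !is.na(design$predictability) &
                                  design$predictability >= 0.6 &
                                  design$predictability <= 0.85]
    if (length(const_lines) && length(high_pred)) {
      out$constant_vs_high_pred <- compare_groups(
        cells, design, const_lines, high_pred, day = config$analysis_day,
        B = config$B, n_cells = config$cap, seed = derive_seed(config$seed, 8))
    }
    neg <- design$line_id[!is.na(design$rho_bar) & design$rho_bar == -0.5]
    pos <- design$line_id[!is.na(design$rho_bar) & design$rho_bar == 0.5]
    if (length(neg) && length(pos)) {
      out$m05_vs_p05 <- compare_groups(
        cells, design, neg, pos, day = config$analysis_day,
        B = config$B, n_cells = config$cap, seed = derive_seed(config$seed, 9))
    }
    out
  })

  bundle <- structure(list(
    design = design, series = attr(design, "series"),
    densities = study$densities, cells = cells, growth = growth,
    rda_fluctuating = rda_input$fluct, rda_constant = rda_input$const,
    distances = distances, regression = regression, bootstrap = boot,
    profile = profile, comparisons = comparisons,
    config = config,
    manifest = tibble::tibble(stage = stages, status = "completed")
  ), class = "study_result")

  if (!is.null(config$out_dir)) {
    bundle$files <- write_bundle(bundle, config$out_dir)
  }
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_tsv(x, p)
    p
  }
  paths <- c(
    tsv(bundle$design, "design.tsv"),
    tsv(bundle$densities, "densities.tsv"),
    tsv(bundle$growth, "growth.tsv"),
    tsv(tibble::as_tibble(bundle$rda_fluctuating), "rda_fluctuating.tsv"),
    if (!is.null(bundle$rda_constant))
      tsv(tibble::as_tibble(bundle$rda_constant), "rda_constant.tsv"),
    tsv(bundle$distances, "plasticity_distances.tsv"),
    tsv(tidy(bundle$bootstrap), "bootstrap_distances.tsv"),
    tsv(tibble::as_tibble(bundle$profile), "slope_profile.tsv")
  )
  manifest <- tibble::tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    config_hash = rlang::hash(bundle$config),
    seed = bundle$config$seed,
    package_version = as.character(utils::packageVersion("plastevol"))
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  c(paths, file.path(dir, "manifest.tsv"))
}

#' Human-readable study report
#'
#' Renders a completed (or partial) result bundle as a markdown report: the
#' variation-partitioning tables, the headline plasticity regression at the
#' analysis day, the per-day slope profile and the group comparisons. Missing
#' stages are reported as warnings in the text rather than errors.
#'
#' @param bundle A [run_study()] result (a partial list is tolerated).
#' @return A single character string of markdown.
#' @export
report <- function(bundle) {
  if (is.null(bundle) || length(bundle) == 0 ||
      all(vapply(bundle, is.null, TRUE))) {
    return("# Study report\n\nno stages completed\n")
  }
  fmt_part <- function(part, title) {
    if (is.null(part)) return(sprintf("_%s: not available_\n", title))
    df <- tibble::as_tibble(part)
    hdr <- sprintf("### %s\n\n| Term | df | Variance | F | R2 | p |\n|---|---|---|---|---|---|\n", title)
    rows <- apply(df, 1, function(r) {
      sprintf("| %s | %s | %.4g | %s | %.4g | %s |", r[["term"]], r[["df"]],
              as.numeric(r[["variance"]]),
              ifelse(is.na(r[["F"]]), "", sprintf("%.4g", as.numeric(r[["F"]]))),
              as.numeric(r[["r2"]]),
              ifelse(is.na(r[["p"]]), "", sprintf("%.4g", as.numeric(r[["p"]]))))
    })
    paste0(hdr, paste(rows, collapse = "\n"), "\n")
  }
  parts <- c("# Study report\n",
             sprintf("Stages completed: %s\n",
                     if (!is.null(bundle$manifest)) paste(bundle$manifest$stage, collapse = ", ")
                     else "unknown"),
             "## Variation partitioning\n",
             fmt_part(bundle$rda_fluctuating, "Evolution in fluctuating salinity"),
             fmt_part(bundle$rda_constant, "Evolution in constant salinity"),
             "## Degree of plasticity vs predictability\n")
  if (!is.null(bundle$regression)) {
    parts <- c(parts, sprintf(
      "Day %s regression: slope %.4f, intercept %.4f, R2 = %.3f\n",
      bundle$config$analysis_day %||% "?", bundle$regression$slope,
      bundle$regression$intercept, bundle$regression$r2))
  } else parts <- c(parts, "_regression: not available_\n")
  if (!is.null(bundle$bootstrap)) {
    parts <- c(parts, sprintf(
      "Hierarchical bootstrap (%d replicates): P(slope <= 0) = %.4g, P(slope > 0) = %.4g\n",
      bundle$bootstrap$B, bundle$bootstrap$p_one_sided,
      1 - bundle$bootstrap$p_one_sided))
  }
  if (!is.null(bundle$profile)) {
    pr <- tibble::as_tibble(bundle$profile)
    parts <- c(parts, "## Per-day slope profile\n",
               "| Day | Slope | 2.5% | 97.5% | P(slope <= 0) |\n|---|---|---|---|---|",
               apply(pr, 1, function(r) sprintf(
                 "| %s | %.4f | %.4f | %.4f | %.4g |",
                 r[["day"]], as.numeric(r[["slope_mean"]]),
                 as.numeric(r[["slope_lo"]]), as.numeric(r[["slope_hi"]]),
                 as.numeric(r[["p_one_sided"]]))),
               "")
  }
  if (!is.null(bundle$comparisons) && length(bundle$comparisons)) {
    parts <- c(parts, "## Group comparisons\n",
               vapply(names(bundle$comparisons), function(nm) {
                 cmp <- bundle$comparisons[[nm]]
                 sprintf("- %s: difference %.4f, two-sided p = %.3g",
                         nm, cmp$diff_obs, cmp$p_two_sided)
               }, ""), "")
  }
  missing <- setdiff(c("rda_fluctuating", "regression", "bootstrap", "profile"),
                     names(bundle)[!vapply(bundle, is.null, TRUE)])
  if (length(missing)) {
    parts <- c(parts, sprintf("\n_Warning: missing stage output(s): %s_\n",
                              paste(missing, collapse = ", ")))
  }
  paste(parts, collapse = "\n")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study result bundle:", paste(x$manifest$stage, collapse = " -> "), "\n")
  cat(sprintf("  %d lines, %d gated cells\n", nrow(x$design), nrow(x$cells)))
  invisible(x)
}
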