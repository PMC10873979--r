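#' Bonferroni-corrected significance threshold
#'
#' @param alpha_family Family-wise level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha_family / n_tests`.
#' @export
bonferroni_threshold <- function(alpha_family, n_tests) {
  check_prob(alpha_family, "alpha_family", lo_open = TRUE, hi_open = TRUE)
  check_count(n_tests, "n_tests")
  alpha_family / n_tests
}

#' Classify a p-value against the corrected and suggestive thresholds
#'
#' `p < threshold` is `"significant"`; `threshold <= p < suggestive_upper`
#' is `"suggestive"`; anything else (including `p == suggestive_upper`,
#' strict upper bound) is `"null"`.
#'
#' @param p P-value(s).
#' @param threshold Corrected significance threshold.
#' @param suggestive_upper Upper bound of the suggestive band.
#' @return Character vector in `{"significant", "suggestive", "null"}`.
#' @export
classify_significance <- function(p, threshold, suggestive_upper = 0.05) {
  if (threshold <= 0 || threshold > suggestive_upper) {
    abort("need 0 < threshold <= suggestive_upper",
          class = "tidymr_invalid_argument")
  }
  dplyr::case_when(
    p < threshold ~ "significant",
    p < suggestive_upper ~ "suggestive",
    .default = "null"
  )
}

#' Analysis thresholds for a full MR study
#'
#' Defaults follow the conventional two-sample MR settings: genome-wide
#' instrument significance 5e-8, clumping at r^2 0.001 within 10,000 kb,
#' proxies at r^2 > 0.8, confounder/outcome screens at 5e-8, palindromic
#' EAF band 0.08, MR-PRESSO with 1000 simulations at level 0.05, and a
#' family-wise alpha of 0.05 Bonferroni-split across the exposures with a
#' suggestive band up to 0.05.
#'
#' @param p_instrument,clump_r2,clump_window_kb,proxy_r2,confounder_p,outcome_assoc_p
#'   Instrument-selection thresholds.
#' @param palindromic_band Harmonization EAF ambiguity half-width.
#' @param presso_n_sim,presso_significance MR-PRESSO settings.
#' @param alpha_family,suggestive_upper Multiple-testing settings.
#' @param n_boot Bootstrap replicates for median-type estimators.
#' @return A named list.
#' @export
study_thresholds <- function(p_instrument = 5e-8, clump_r2 = 0.001,
                             clump_window_kb = 10000, proxy_r2 = 0.8,
                             confounder_p = 5e-8, outcome_assoc_p = 5e-8,
                             palindromic_band = 0.08,
                             presso_n_sim = 1000,
                             presso_significance = 0.05,
                             alpha_family = 0.05, suggestive_upper = 0.05,
                             n_boot = 1000) {
  list(p_instrument = p_instrument, clump_r2 = clump_r2,
       clump_window_kb = clump_window_kb, proxy_r2 = proxy_r2,
       confounder_p = confounder_p, outcome_assoc_p = outcome_assoc_p,
       palindromic_band = palindromic_band, presso_n_sim = presso_n_sim,
       presso_significance = presso_significance,
       alpha_family = alpha_family, suggestive_upper = suggestive_upper,
       n_boot = n_boot)
}

#' Assemble a study configuration
#'
#' @param exposures Named list of exposure summary-stat tibbles.
#' @param outcome Outcome summary-stat tibble.
#' @param ld An `ld_reference`.
#' @param annotation Annotation tibble (may be empty).
#' @param confounder_traits Trait names screened as confounders.
#' @param thresholds A [study_thresholds()] list.
#' @param seed Integer seed driving every stochastic component.
#' @return A list of class `study_config`.
#' @export
study_config <- function(exposures, outcome, ld, annotation = NULL,
                         confounder_traits = character(0),
                         thresholds = study_thresholds(), seed = 1L) {
  if (inherits(exposures, "data.frame")) exposures <- list(exposures)
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- purrr::map_chr(seq_along(exposures), function(i) {
      tb <- exposures[[i]]
      if ("trait_id" %in% names(tb)) tb$trait_id[1] else paste0("exposure_", i)
    })
  }
  annotation <- annotation %||%
    tibble::tibble(rsid = character(), trait = character(), pvalue = double())
  structure(list(exposures = exposures, outcome = outcome, ld = ld,
                 annotation = annotation,
                 confounder_traits = confounder_traits,
                 thresholds = utils::modifyList(study_thresholds(),
                                                thresholds),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Expected structure: `exposures` (list of `trait_id`/`path`/`trait_type`
#' entries), `outcome` (same shape), `ld` (`pairs`/`positions` paths),
#' optional `annotation` path, `confounder_traits`, `thresholds` (any
#' subset of [study_thresholds()] names) and `seed`. Relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  exposures <- purrr::map(cfg$exposures, function(e) {
    read_summary_stats(resolve(e$path), trait_id = e$trait_id,
                       trait_type = e$trait_type %||% "continuous")
  })
  names(exposures) <- purrr::map_chr(cfg$exposures, "trait_id")
  outcome <- read_summary_stats(resolve(cfg$outcome$path),
                                trait_id = cfg$outcome$trait_id,
                                trait_type = cfg$outcome$trait_type %||%
                                  "binary")
  ld <- read_ld_reference(resolve(cfg$ld$pairs), resolve(cfg$ld$positions))
  annotation <- if (!is.null(cfg$annotation)) {
    read_annotation(resolve(cfg$annotation))
  } else NULL
  study_config(exposures, outcome, ld, annotation,
               confounder_traits = unlist(cfg$confounder_traits) %||%
                 character(0),
               thresholds = cfg$thresholds %||% list(),
               seed = cfg$seed %||% 1L)
}

estimate_rows <- function(frame, th, seed, pass, exposure_id) {
  n <- nrow(frame)
  ests <- list(mr_ivw(frame))
  if (n >= 3) {
    ests <- c(ests, list(mr_egger(frame),
                         mr_weighted_median(frame, n_boot = th$n_boot,
                                            seed = seed)))
  }
  purrr::map_dfr(ests, function(e) tidy(to_odds_ratio(e))) |>
    dplyr::mutate(exposure = exposure_id, pass = pass, .before = 1) |>
    dplyr::select(-"term")
}

#' Univariable arm of an MR study
#'
#' For each exposure: instrument selection, harmonization against the
#' outcome, IVW / MR-Egger / weighted-median estimation, the sensitivity
#' battery, and — when MR-PRESSO flags outliers — removal and a complete
#' re-analysis, with both passes reported. Deterministic given the
#' config's seed. Exposures with fewer than two surviving instruments are
#' skipped with an explicit report entry.
#'
#' @param cfg A [study_config()].
#' @return List with `results` (tidy estimate rows, column `pass` in
#'   `{"pre", "post_outlier_removal"}`), `sensitivity` (one Table-2-shaped
#'   row per exposure), `attrition`, `calls` (IVW significance calls at
#'   the Bonferroni and suggestive thresholds), `skipped`, and
#'   `per_exposure` (frames, estimates and sensitivity objects).
#' @export
run_univariable <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  th <- cfg$thresholds
  results <- list(); sens_rows <- list(); attrition <- list()
  per_exposure <- list(); skipped <- character(0)

  for (i in seq_along(cfg$exposures)) {
    id <- names(cfg$exposures)[i]
    seed_i <- cfg$seed + i
    sel <- select_instruments(
      cfg$exposures[[i]], cfg$outcome, cfg$ld, cfg$annotation,
      confounder_traits = cfg$confounder_traits,
      p_threshold = th$p_instrument, clump_r2 = th$clump_r2,
      clump_window_kb = th$clump_window_kb, confounder_p = th$confounder_p,
      outcome_assoc_p = th$outcome_assoc_p, proxy_r2 = th$proxy_r2)
    frame <- harmonize(sel$instruments, cfg$outcome,
                       palindromic_eaf_band = th$palindromic_band)
    att <- dplyr::bind_rows(
      sel$attrition,
      tibble::tibble(stage = "harmonization",
                     n_in = nrow(sel$instruments), n_out = nrow(frame),
                     n_removed = nrow(sel$instruments) - nrow(frame)))
    attrition[[id]] <- dplyr::mutate(att, exposure = id, .before = 1)

    if (nrow(frame) < 2) {
      skipped <- c(skipped, id)
      per_exposure[[id]] <- list(frame = frame, skipped = TRUE,
                                 selection = sel)
      next
    }

    res_pre <- estimate_rows(frame, th, seed_i, "pre", id)
    sens <- mr_sensitivity(frame, n_sim = th$presso_n_sim, seed = seed_i,
                           outlier_significance = th$presso_significance)
    out_rsids <- if (!is.null(sens$presso)) {
      sens$presso$outliers$rsid[sens$presso$outliers$is_outlier]
    } else character(0)

    res <- res_pre
    frame_post <- NULL
    q_post <- NULL
    if (length(out_rsids) > 0) {
      frame_post <- frame[!frame$rsid %in% out_rsids, , drop = FALSE]
      if (nrow(frame_post) >= 2) {
        res <- dplyr::bind_rows(
          res_pre,
          estimate_rows(frame_post, th, seed_i, "post_outlier_removal", id))
        if (nrow(frame_post) >= 2) q_post <- mr_cochran_q(frame_post)
      }
    }
    results[[id]] <- res
    sens_rows[[id]] <- tibble::tibble(
      exposure = id,
      n_snp = nrow(frame),
      q_value = sens$q$q_value, i2 = sens$q$i2, q_p = sens$q$q_p,
      egger_intercept = sens$egger_intercept$intercept %||% NA_real_,
      intercept_p = sens$egger_intercept$pvalue %||% NA_real_,
      presso_global_p = if (!is.null(sens$presso)) sens$presso$global_p
                        else NA_real_,
      presso_n_outliers = length(out_rsids),
      presso_distortion_p = if (!is.null(sens$presso))
        sens$presso$distortion_p else NA_real_
    )
    per_exposure[[id]] <- list(frame = frame, frame_post = frame_post,
                               selection = sel, sensitivity = sens,
                               q_post = q_post, skipped = FALSE)
  }

  results <- dplyr::bind_rows(results)
  thr <- bonferroni_threshold(th$alpha_family, length(cfg$exposures))
  calls <- results |>
    dplyr::filter(.data$method == "ivw") |>
    dplyr::group_by(.data$exposure) |>
    dplyr::slice_tail(n = 1) |>   # final pass (post-correction if rerun)
    dplyr::ungroup() |>
    dplyr::mutate(
      threshold = thr,
      call = classify_significance(.data$p.value, thr,
                                   th$suggestive_upper)) |>
    dplyr::select("exposure", "pass", "p.value", "threshold", "call")

  list(results = results,
       sensitivity = dplyr::bind_rows(sens_rows),
       attrition = dplyr::bind_rows(attrition),
       calls = calls, skipped = skipped, per_exposure = per_exposure)
}

#' Multivariable arm of an MR study
#'
#' Instruments are selected per exposure (significance filter + clumping),
#' pooled across exposures, and the union jointly re-clumped (keeping the
#' smallest p-value across exposures per SNP); all exposures and the
#' outcome are then harmonized complete-case to the first exposure's
#' effect alleles and the multivariable IVW, Egger and median estimators
#' fitted. When univariable totals are supplied, each exposure's indirect
#' effect is reported descriptively as total minus direct.
#'
#' @param cfg A [study_config()] with at least two exposures.
#' @param univariable Optional result of [run_univariable()], used for the
#'   total effects in the indirect-effect decomposition.
#' @return List with `results` (tidy rows per method and exposure),
#'   `egger_intercept`, `indirect` (tibble `exposure`, `total`, `direct`,
#'   `indirect`; `NULL` without `univariable`), `n_snp`, and `frame`.
#' @export
run_multivariable <- function(cfg, univariable = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  th <- cfg$thresholds
  if (length(cfg$exposures) < 2) {
    abort("multivariable MR needs at least two exposures",
          class = "tidymr_invalid_argument")
  }
  per_exp <- purrr::map(cfg$exposures, function(ex) {
    clump(filter_genome_wide(ex, th$p_instrument), cfg$ld,
          th$clump_r2, th$clump_window_kb)
  })
  union_rsids <- unique(unlist(purrr::map(per_exp, "rsid")))
  # joint clump on the union, ranking each SNP by its best p across
  # exposures
  pooled <- dplyr::bind_rows(per_exp) |>
    dplyr::filter(.data$rsid %in% union_rsids) |>
    dplyr::group_by(.data$rsid) |>
    dplyr::slice_min(.data$pvalue, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  pooled <- clump(pooled, cfg$ld, th$clump_r2, th$clump_window_kb)

  exposures_sub <- purrr::map(cfg$exposures,
                              ~ dplyr::filter(.x, .data$rsid %in% pooled$rsid))
  frame <- harmonize(exposures_sub, cfg$outcome,
                     palindromic_eaf_band = th$palindromic_band)
  k <- length(cfg$exposures)
  if (nrow(frame) < k + 2) {
    abort(sprintf("only %d SNPs survive joint selection; need >= %d",
                  nrow(frame), k + 2),
          class = "tidymr_insufficient_instruments")
  }
  seed_mv <- cfg$seed + 1000L
  ivw <- mvmr_ivw(frame)
  egger <- mvmr_egger(frame)
  med <- mvmr_median(frame, n_boot = th$n_boot, seed = seed_mv)
  results <- purrr::map_dfr(list(ivw, egger, med),
                            function(e) tidy(to_odds_ratio(e))) |>
    dplyr::rename(exposure = "term")

  indirect <- NULL
  if (!is.null(univariable)) {
    totals <- univariable$results |>
      dplyr::filter(.data$method == "ivw", .data$pass == "pre") |>
      dplyr::select("exposure", total = "estimate")
    directs <- tidy(ivw) |>
      dplyr::select(exposure = "term", direct = "estimate")
    indirect <- dplyr::inner_join(totals, directs, by = "exposure") |>
      dplyr::mutate(indirect = .data$total - .data$direct)
  }

  list(results = results,
       egger_intercept = tibble::tibble(
         intercept = egger$extras$intercept,
         se = egger$extras$intercept_se,
         pvalue = egger$extras$intercept_p),
       indirect = indirect, n_snp = nrow(frame), frame = frame)
}

#' Run the complete univariable + multivariable MR study
#'
#' @param cfg A [study_config()].
#' @return List of class `mr_study_report` with elements `univariable`,
#'   `multivariable` (`NULL` for a single exposure), `thresholds`, `seed`.
#' @export
mr_study <- function(cfg) {
  uni <- run_univariable(cfg)
  multi <- if (length(cfg$exposures) >= 2) {
    run_multivariable(cfg, univariable = uni)
  } else NULL
  structure(list(univariable = uni, multivariable = multi,
                 thresholds = cfg$thresholds, seed = cfg$seed),
            class = "mr_study_report")
}

#' @export
print.mr_study_report <- function(x, ...) {
  cat("<mr_study_report>\n\n== Univariable MR (final-pass IVW calls) ==\n")
  print(x$univariable$calls)
  cat("\n== Sensitivity ==\n")
  print(x$univariable$sensitivity)
  if (!is.null(x$multivariable)) {
    cat("\n== Multivariable MR (direct effects) ==\n")
    print(x$multivariable$results)
  }
  invisible(x)
}

#' Run a study from a YAML configuration file
#'
#' Thin wrapper: [read_study_config()] then [mr_study()], optionally
#' writing the report tables (forest-style results, sensitivity table,
#' attrition, multivariable results) as TSVs into `out_dir`.
#'
#' @param config_path YAML study configuration.
#' @param out_dir Optional output directory for the report TSVs.
#' @return The `mr_study_report`, invisibly when writing.
#' @export
run_study <- function(config_path, out_dir = NULL) {
  report <- mr_study(read_study_config(config_path))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(report$univariable$results,
                     file.path(out_dir, "univariable_results.tsv"))
    readr::write_tsv(report$univariable$sensitivity,
                     file.path(out_dir, "sensitivity.tsv"))
    readr::write_tsv(report$univariable$attrition,
                     file.path(out_dir, "attrition.tsv"))
    readr::write_tsv(report$univariable$calls,
                     file.path(out_dir, "significance_calls.tsv"))
    if (!is.null(report$multivariable)) {
      readr::write_tsv(report$multivariable$results,
                       file.path(out_dir, "multivariable_results.tsv"))
    }
    return(invisible(report))
  }
  report
}
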