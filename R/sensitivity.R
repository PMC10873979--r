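ratio_stats <- function(frame) {
  d <- frame_univariable(frame)
  list(ratio = d$by / d$bx, se_ratio = abs(d$sy / d$bx),
       w = (d$bx / d$sy)^2, d = d)
}

#' Cochran's Q heterogeneity test with I-squared
#'
#' `Q = sum_j w_j (ratio_j - pooled)^2` over the per-SNP Wald ratios with
#' inverse-variance weights `w_j = 1/se_ratio_j^2`; `df = n_snp - 1`;
#' p-value from the upper chi-square tail;
#' `I^2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param frame Harmonized frame (single exposure).
#' @param pooled_beta Pooled causal estimate; defaults to the IVW
#'   estimate of the frame.
#' @return One-row tibble `q_value`, `q_df`, `q_p`, `i2`.
#' @export
mr_cochran_q <- function(frame, pooled_beta = NULL) {
  rs <- ratio_stats(frame)
  n <- length(rs$ratio)
  if (n < 2) {
    abort("Cochran's Q needs at least 2 instruments",
          class = "tidymr_insufficient_instruments")
  }
  pooled_beta <- pooled_beta %||% mr_ivw(frame)$estimates$beta
  q <- sum(rs$w * (rs$ratio - pooled_beta)^2)
  df <- n - 1L
  tibble::tibble(
    q_value = q, q_df = df,
    q_p = stats::pchisq(q, df, lower.tail = FALSE),
    i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0
  )
}

# IVW slope and the n leave-one-out slopes, from sufficient statistics.
ivw_loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  list(full = sxy / sxx,
       loo = (sxy - w * bx * by) / (sxx - w * bx^2))
}

#' MR-PRESSO: global, outlier, and distortion tests
#'
#' Detects pleiotropic outlier SNPs by comparing observed
#' leave-one-out-residual sums of squares with those of data simulated
#' under the no-pleiotropy model.
#'
#' 1. *Global test.* `RSS_obs = sum_j w_j (beta_y_j - b_(-j) beta_x_j)^2`
#'    with leave-one-out IVW slopes `b_(-j)` and `w_j = 1/se_y_j^2`. For
#'    each of `n_sim` replicates, `beta_x_j*` and `beta_y_j*` are drawn
#'    from normal distributions centred on the observed `beta_x_j` and the
#'    fitted `b_(-j) beta_x_j` with the observed SEs, and the RSS
#'    recomputed; the Monte-Carlo p-value is
#'    `(1 + #{RSS* >= RSS_obs}) / (n_sim + 1)`.
#' 2. *Outlier test* (run when the global p is below
#'    `outlier_significance`): each SNP's observed weighted squared
#'    residual is compared with its simulated distribution; per-SNP
#'    p-values are Bonferroni-corrected across SNPs.
#' 3. *Distortion test.* The relative displacement between the IVW
#'    estimate with and without the outliers is compared against a
#'    simulated displacement distribution obtained by removing random
#'    inlier subsets of the same size.
#'
#' @param frame Harmonized frame (single exposure), at least 4 SNPs.
#' @param n_sim Simulation replicates (default 1000; the p-value
#'   resolution is `1/(n_sim+1)`).
#' @param seed Optional integer seed; identical (frame, n_sim, seed) give
#'   identical reports.
#' @param outlier_significance Level for the global test gate and the
#'   Bonferroni-corrected per-SNP outlier calls (default 0.05).
#' @return List of class `mr_presso` with `global_rss`, `global_p`,
#'   `outliers` (tibble `rsid`, `obs_residual`, `pvalue`, `is_outlier`),
#'   `distortion_p` (`NA` when no outliers), `raw_estimate`,
#'   `corrected_estimate` (IVW without the outliers; `NULL` when none).
#' @export
mr_presso <- function(frame, n_sim = 1000, seed = NULL,
                      outlier_significance = 0.05) {
  d <- frame_univariable(frame)
  n <- length(d$bx)
  if (n < 4) {
    abort("MR-PRESSO needs at least 4 instruments",
          class = "tidymr_insufficient_instruments")
  }
  with_seed_if(seed, mr_presso_impl(frame, d, n, n_sim,
                                    outlier_significance))
}

mr_presso_impl <- function(frame, d, n, n_sim, outlier_significance) {
  w <- 1 / d$sy^2
  sl <- ivw_loo_slopes(d$bx, d$by, w)
  obs_resid2 <- w * (d$by - sl$loo * d$bx)^2
  rss_obs <- sum(obs_resid2)

  # simulate under the fitted no-pleiotropy model (n_sim x n matrices)
  bx_star <- matrix(rnorm(n_sim * n, rep(d$bx, each = n_sim),
                          rep(d$sx, each = n_sim)), n_sim, n)
  by_star <- matrix(rnorm(n_sim * n, rep(sl$loo * d$bx, each = n_sim),
                          rep(d$sy, each = n_sim)), n_sim, n)
  wm <- matrix(w, n_sim, n, byrow = TRUE)
  sxy <- rowSums(wm * bx_star * by_star)
  sxx <- rowSums(wm * bx_star^2)
  loo_star <- (sxy - wm * bx_star * by_star) / (sxx - wm * bx_star^2)
  resid2_star <- wm * (by_star - loo_star * bx_star)^2
  rss_star <- rowSums(resid2_star)
  global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)

  outliers <- tibble::tibble(
    rsid = frame$rsid, obs_residual = obs_resid2,
    pvalue = NA_real_, is_outlier = FALSE
  )
  distortion_p <- NA_real_
  corrected <- NULL
  raw <- mr_ivw(frame)

  if (global_p < outlier_significance) {
    exceed <- colSums(resid2_star >=
                        matrix(obs_resid2, n_sim, n, byrow = TRUE))
    p_snp <- (1 + exceed) / (n_sim + 1)
    outliers$pvalue <- p_snp
    outliers$is_outlier <- p_snp < outlier_significance / n
  }

  if (any(outliers$is_outlier)) {
    out_idx <- which(outliers$is_outlier)
    keep <- frame[-out_idx, , drop = FALSE]
    corrected <- mr_ivw(keep)
    b_all <- raw$estimates$beta
    b_no <- corrected$estimates$beta
    d_obs <- (b_all - b_no) / abs(b_no)
    inlier <- setdiff(seq_len(n), out_idx)
    m <- length(out_idx)
    if (length(inlier) > m + 1) {
      d_sim <- vapply(seq_len(n_sim), function(i) {
        drop_i <- sample(inlier, m)
        sub <- frame[-drop_i, , drop = FALSE]
        b_sub <- mr_ivw(sub)$estimates$beta
        (b_all - b_sub) / abs(b_sub)
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
    }
  }

  structure(list(
    global_rss = rss_obs, global_p = global_p, n_sim = n_sim,
    outliers = outliers, distortion_p = distortion_p,
    raw_estimate = raw, corrected_estimate = corrected
  ), class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS %.4g, p = %.4g (%d sims)\n",
              x$global_rss, x$global_p, x$n_sim))
  n_out <- sum(x$outliers$is_outlier)
  cat(sprintf("outliers detected: %d", n_out))
  if (n_out > 0) {
    cat(" (", paste(x$outliers$rsid[x$outliers$is_outlier], collapse = ", "),
        ")", sep = "")
    cat(sprintf("; distortion p = %.4g", x$distortion_p))
  }
  cat("\n")
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each SNP excluded in turn. A SNP is
#' flagged as influential (a heuristic operationalization of "strongly
#' deviating") when its exclusion changes the sign of the estimate or
#' moves it outside the full-frame 95% confidence interval.
#'
#' @param frame Harmonized frame (single exposure), at least 3 SNPs.
#' @return Tibble with one row per left-out SNP (`rsid_left_out`, `n_snp`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `influential`) plus the
#'   full-frame estimate in attribute `"full"`.
#' @export
mr_leave_one_out <- function(frame) {
  d <- frame_univariable(frame)
  n <- length(d$bx)
  if (n < 3) {
    abort("leave-one-out needs at least 3 instruments",
          class = "tidymr_insufficient_instruments")
  }
  full <- mr_ivw(frame)
  rows <- purrr::map_dfr(seq_len(n), function(j) {
    est <- mr_ivw(frame[-j, , drop = FALSE])
    tibble::tibble(rsid_left_out = frame$rsid[j], n_snp = est$n_snp,
                   beta = est$estimates$beta, se = est$estimates$se,
                   ci_low = est$estimates$ci_low,
                   ci_high = est$estimates$ci_high,
                   pvalue = est$estimates$pvalue)
  })
  fb <- full$estimates
  rows$influential <- sign(rows$beta) != sign(fb$beta) |
    rows$beta < fb$ci_low | rows$beta > fb$ci_high
  attr(rows, "full") <- full
  rows
}

#' Per-SNP funnel data (Wald ratio vs precision)
#'
#' Emits each SNP's ratio estimate and its precision `1/se_ratio` for
#' funnel plotting, together with the pooled IVW line and an asymmetry
#' check (the weighted regression slope of ratio on precision, which is
#' approximately 0 for a symmetric funnel).
#'
#' @param frame Harmonized frame (single exposure), at least 1 SNP.
#' @return Tibble `rsid`, `ratio`, `precision`; attributes `"pooled"`
#'   (IVW estimate) and `"asymmetry_slope"`.
#' @export
mr_funnel_data <- function(frame) {
  rs <- ratio_stats(frame)
  out <- tibble::tibble(rsid = frame$rsid, ratio = rs$ratio,
                        precision = 1 / rs$se_ratio)
  attr(out, "pooled") <- if (nrow(frame) >= 2) mr_ivw(frame)$estimates$beta
                         else rs$ratio[1]
  attr(out, "asymmetry_slope") <- if (nrow(out) >= 3) {
    unname(coef(lm(ratio ~ precision, data = out, weights = rs$w))[2])
  } else NA_real_
  out
}

#' One-exposure sensitivity battery
#'
#' Convenience wrapper assembling Cochran's Q, the MR-Egger intercept
#' test, MR-PRESSO, leave-one-out and funnel data into one report.
#'
#' @param frame Harmonized frame (single exposure).
#' @param n_sim,seed,outlier_significance Passed to [mr_presso()].
#' @return List of class `mr_sensitivity`: `q` (tibble), `egger_intercept`
#'   (tibble `intercept`, `se`, `pvalue`), `presso`, `loo`, `funnel`.
#' @export
mr_sensitivity <- function(frame, n_sim = 1000, seed = NULL,
                           outlier_significance = 0.05) {
  n <- nrow(frame)
  q <- if (n >= 2) mr_cochran_q(frame) else NULL
  egger <- if (n >= 3) {
    e <- mr_egger(frame)
    tibble::tibble(intercept = e$extras$intercept,
                   se = e$extras$intercept_se,
                   pvalue = e$extras$intercept_p)
  } else NULL
  presso <- if (n >= 4) mr_presso(frame, n_sim = n_sim, seed = seed,
                                  outlier_significance = outlier_significance)
            else NULL
  loo <- if (n >= 3) mr_leave_one_out(frame) else NULL
  structure(list(q = q, egger_intercept = egger, presso = presso,
                 loo = loo, funnel = mr_funnel_data(frame)),
            class = "mr_sensitivity")
}
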