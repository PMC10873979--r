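# Constructor for a fitted MR estimate. `estimates` is a one-row tibble
# (univariable) or K-row tibble (multivariable) with columns term, beta,
# se, ci_low, ci_high, pvalue.
new_mr_result <- function(method, n_snp, estimates, extras = list()) {
  stopifnot(all(c("term", "beta", "se", "ci_low", "ci_high", "pvalue") %in%
                  names(estimates)))
  structure(list(method = method, n_snp = n_snp,
                 estimates = tibble::as_tibble(estimates),
                 extras = extras),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result: %s> %d SNPs\n", x$method, x$n_snp))
  print(x$estimates, ...)
  if (!is.null(x$extras$intercept)) {
    cat(sprintf("intercept: %.4g (se %.4g, p = %.3g)\n",
                x$extras$intercept, x$extras$intercept_se,
                x$extras$intercept_p))
  }
  invisible(x)
}

#' Tidy an MR estimate into a one-row-per-term tibble
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return Tibble with `method`, `term`, `n_snp`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`, and — after
#'   [to_odds_ratio()] — `or`, `or.conf.low`, `or.conf.high`.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  est <- x$estimates
  out <- tibble::tibble(
    method = x$method, term = est$term, n_snp = x$n_snp,
    estimate = est$beta, std.error = est$se,
    statistic = est$beta / est$se, p.value = est$pvalue,
    conf.low = est$ci_low, conf.high = est$ci_high
  )
  if ("or" %in% names(est)) {
    out$or <- est$or
    out$or.conf.low <- est$or_low
    out$or.conf.high <- est$or_high
  }
  out
}

#' One-line model-level summary of an MR estimate
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return One-row tibble with the method, instrument count, effects model
#'   and residual scale (where applicable).
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_snp = x$n_snp,
    effects_model = x$extras$effects_model %||% NA_character_,
    residual_scale = x$extras$residual_scale %||% NA_real_,
    intercept = x$extras$intercept %||% NA_real_,
    intercept_p = x$extras$intercept_p %||% NA_real_
  )
}

#' Wald ratio estimate for a single SNP
#'
#' The per-SNP causal estimate `beta_y / beta_x` with, by default, the
#' first-order delta-method standard error `|se_y / beta_x|`; the
#' second-order option adds the SNP-exposure uncertainty term
#' `beta_y^2 se_x^2 / beta_x^4`.
#'
#' @param beta_x,se_x,beta_y,se_y Per-allele effects and SEs.
#' @param order `1` (default) or `2`.
#' @return An `mr_result`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, order = 1) {
  if (beta_x == 0) {
    abort("Wald ratio undefined: beta_x is zero",
          class = "tidymr_undefined_ratio")
  }
  beta <- beta_y / beta_x
  se <- abs(se_y / beta_x)
  if (order == 2) {
    se <- sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  }
  new_mr_result("wald_ratio", 1L, tibble::tibble(
    term = "exposure", beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pvalue = two_sided_p(beta / se)
  ))
}

frame_univariable <- function(frame) {
  check_frame(frame)
  bx_col <- exposure_beta_cols(frame)
  if (length(bx_col) > 1) {
    abort("frame has multiple exposures; use the mvmr_* estimators",
          class = "tidymr_bad_frame")
  }
  list(bx = frame[[bx_col]], sx = frame[[sub("^beta_x", "se_x", bx_col)]],
       by = frame$beta_y, sy = frame$se_y,
       term = exposure_names(frame))
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools the per-SNP Wald ratios as a weighted regression of `beta_y` on
#' `beta_x` through the origin with weights `1/se_y^2` (the two
#' formulations are algebraically identical). Under the default
#' multiplicative random-effects model the standard error is scaled by
#' `max(1, residual SD)`; the fixed-effect model keeps unit residual
#' scale. The p-value is the two-sided normal test of `beta/se`.
#'
#' @param frame Harmonized frame (single exposure).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_result` (extras: `effects_model`, `residual_scale`).
#' @export
mr_ivw <- function(frame, effects_model = c("multiplicative_random",
                                            "fixed")) {
  effects_model <- match.arg(effects_model)
  d <- frame_univariable(frame)
  n <- length(d$bx)
  if (n < 1) abort("empty frame", class = "tidymr_insufficient_instruments")
  if (n < 2) {
    inform("single instrument: falling back to the Wald ratio")
    return(wald_ratio(d$bx, d$sx, d$by, d$sy))
  }
  w <- 1 / d$sy^2
  sxx <- sum(w * d$bx^2)
  beta <- sum(w * d$bx * d$by) / sxx
  se_fixed <- sqrt(1 / sxx)
  sigma <- sqrt(sum(w * (d$by - beta * d$bx)^2) / (n - 1))
  scale <- if (effects_model == "multiplicative_random") max(1, sigma) else 1
  se <- se_fixed * scale
  new_mr_result("ivw", n, tibble::tibble(
    term = d$term, beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pvalue = two_sided_p(beta / se)
  ), extras = list(effects_model = effects_model, residual_scale = sigma))
}

#' MR-Egger regression
#'
#' Orients every SNP so `beta_x >= 0`, then fits the weighted regression
#' of `beta_y` on `beta_x` *with* an intercept (weights `1/se_y^2`). The
#' slope is the causal estimate; a nonzero intercept indicates directional
#' horizontal pleiotropy. Both slope and intercept are tested against the
#' t distribution with `n_snp - 2` degrees of freedom, with multiplicative
#' random-effects scaling of the standard errors as in [mr_ivw()].
#'
#' @inheritParams mr_ivw
#' @return An `mr_result`; extras carry `intercept`, `intercept_se`,
#'   `intercept_p`, `residual_scale`.
#' @export
mr_egger <- function(frame, effects_model = c("multiplicative_random",
                                              "fixed")) {
  effects_model <- match.arg(effects_model)
  d <- frame_univariable(frame)
  n <- length(d$bx)
  if (n < 3) {
    abort("MR-Egger needs at least 3 instruments",
          class = "tidymr_insufficient_instruments")
  }
  s <- ifelse(d$bx < 0, -1, 1)
  bx <- d$bx * s
  by <- d$by * s
  w <- 1 / d$sy^2
  x <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(x, w * x)
  coefs <- solve(xtwx, crossprod(x, w * by))
  resid <- by - x %*% coefs
  sigma <- sqrt(sum(w * resid^2) / (n - 2))
  scale <- if (effects_model == "multiplicative_random") max(1, sigma) else 1
  ses <- sqrt(diag(solve(xtwx))) * scale
  slope <- unname(coefs["slope", 1])
  slope_se <- unname(ses["slope"])
  int <- unname(coefs["intercept", 1])
  int_se <- unname(ses["intercept"])
  tq <- stats::qt(0.975, df = n - 2)
  new_mr_result("mr_egger", n, tibble::tibble(
    term = d$term, beta = slope, se = slope_se,
    ci_low = slope - Z95 * slope_se, ci_high = slope + Z95 * slope_se,
    pvalue = two_sided_p_t(slope / slope_se, n - 2)
  ), extras = list(
    effects_model = effects_model, residual_scale = sigma,
    intercept = int, intercept_se = int_se,
    intercept_ci = c(int - tq * int_se, int + tq * int_se),
    intercept_p = two_sided_p_t(int / int_se, n - 2)
  ))
}

#' Weighted median causal estimate
#'
#' The 50% point of the inverse-variance-weight-ordered per-SNP Wald
#' ratios: ratios are sorted ascending, weights `1/se_ratio^2` normalized
#' to sum one, and the estimate is the linear interpolation of the ordered
#' ratios at cumulative weight 0.5 (each ratio placed at its cumulative
#' weight minus half its own). Consistent when at least half of the weight
#' comes from valid instruments. The standard error is a parametric
#' bootstrap: `beta_x` and `beta_y` are resampled from their sampling
#' distributions and the estimator recomputed.
#'
#' @param frame Harmonized frame (single exposure).
#' @param n_boot Bootstrap replicates (default 1000; 0 skips the SE, and
#'   the p-value, for fast point estimation).
#' @param seed Optional integer seed for the bootstrap.
#' @return An `mr_result` (extras: `n_boot`).
#' @export
mr_weighted_median <- function(frame, n_boot = 1000, seed = NULL) {
  d <- frame_univariable(frame)
  n <- length(d$bx)
  if (n < 3) {
    abort("weighted median needs at least 3 instruments",
          class = "tidymr_insufficient_instruments")
  }
  ratio <- d$by / d$bx
  w <- (d$bx / d$sy)^2  # 1 / se_ratio^2, first-order
  beta <- weighted_median_value(ratio, w)
  se <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed_if(seed, {
      bx_star <- matrix(rnorm(n_boot * n, rep(d$bx, each = n_boot),
                              rep(d$sx, each = n_boot)), n_boot, n)
      by_star <- matrix(rnorm(n_boot * n, rep(d$by, each = n_boot),
                              rep(d$sy, each = n_boot)), n_boot, n)
      vapply(seq_len(n_boot), function(b) {
        r <- by_star[b, ] / bx_star[b, ]
        weighted_median_value(r, (bx_star[b, ] / d$sy)^2)
      }, numeric(1))
    })
    se <- stats::sd(boots)
  }
  new_mr_result("weighted_median", n, tibble::tibble(
    term = d$term, beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pvalue = if (is.na(se)) NA_real_ else two_sided_p(beta / se)
  ), extras = list(n_boot = n_boot))
}

#' Express an MR estimate on the odds-ratio scale
#'
#' Adds `or = exp(beta)` with the normal-theory interval
#' `exp(beta -/+ 1.96 se)`. Meaningful when the outcome betas are
#' log-odds (binary outcome).
#'
#' @param est An `mr_result`.
#' @return The `mr_result` with `or`, `or_low`, `or_high` columns added to
#'   its estimates.
#' @export
to_odds_ratio <- function(est) {
  stopifnot(inherits(est, "mr_result"))
  e <- est$estimates
  e$or <- exp(e$beta)
  e$or_low <- exp(e$beta - Z95 * e$se)
  e$or_high <- exp(e$beta + Z95 * e$se)
  est$estimates <- e
  est
}
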