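frame_multivariable <- function(frame) {
  check_frame(frame)
  bx_cols <- exposure_beta_cols(frame)
  x <- as.matrix(frame[, bx_cols])
  colnames(x) <- exposure_names(frame)
  sx <- as.matrix(frame[, exposure_se_cols(frame)])
  list(x = x, sx = sx, by = frame$beta_y, sy = frame$se_y,
       terms = exposure_names(frame))
}

check_rank <- function(x, w) {
  qrx <- qr(sqrt(w) * x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    abort(paste0("collinear exposure effects; offending exposure(s): ",
                 paste(bad, collapse = ", ")),
          class = "tidymr_collinearity")
  }
}

mvmr_wls <- function(x, by, w, intercept = FALSE, extra_df = 0) {
  if (intercept) x <- cbind(`(intercept)` = 1, x)
  xtwx <- crossprod(x, w * x)
  coefs <- drop(solve(xtwx, crossprod(x, w * by)))
  resid <- by - drop(x %*% coefs)
  df <- length(by) - ncol(x) - extra_df
  sigma <- sqrt(sum(w * resid^2) / df)
  ses <- sqrt(diag(solve(xtwx)))
  list(coefs = coefs, ses = ses, sigma = sigma, df = df)
}

#' Multivariable IVW: direct effects conditional on co-exposures
#'
#' Weighted multiple regression of the SNP-outcome effects on the K
#' columns of SNP-exposure effects through the origin, weights `1/se_y^2`.
#' Each coefficient is that exposure's direct effect on the outcome
#' conditional on the other exposures. Standard errors use multiplicative
#' random-effects scaling (`max(1, residual SD)`) by default; p-values
#' from the normal test. With a single exposure this reduces exactly to
#' [mr_ivw()].
#'
#' @param frame Harmonized frame with one `beta_x_<trait>`/`se_x_<trait>`
#'   column pair per exposure.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_result` with one estimate row per exposure.
#' @export
mvmr_ivw <- function(frame, effects_model = c("multiplicative_random",
                                              "fixed")) {
  effects_model <- match.arg(effects_model)
  d <- frame_multivariable(frame)
  n <- length(d$by)
  k <- ncol(d$x)
  if (n < k + 1) {
    abort(sprintf("multivariable IVW needs at least K+1 = %d SNPs", k + 1),
          class = "tidymr_insufficient_instruments")
  }
  w <- 1 / d$sy^2
  check_rank(d$x, w)
  fit <- mvmr_wls(d$x, d$by, w, intercept = FALSE)
  # df n - k, except k = 1 where the univariable convention (n - 1) applies
  scale <- if (effects_model == "multiplicative_random") max(1, fit$sigma)
           else 1
  ses <- fit$ses * scale
  new_mr_result("mvmr_ivw", n, tibble::tibble(
    term = d$terms, beta = unname(fit$coefs), se = unname(ses),
    ci_low = unname(fit$coefs - Z95 * ses),
    ci_high = unname(fit$coefs + Z95 * ses),
    pvalue = two_sided_p(fit$coefs / ses)
  ), extras = list(effects_model = effects_model,
                   residual_scale = fit$sigma))
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] plus an intercept column, with all SNPs oriented so the
#' first exposure's effects are nonnegative. The intercept is tested
#' against the t distribution with `n_snp - K - 1` degrees of freedom.
#'
#' @inheritParams mvmr_ivw
#' @return An `mr_result`; extras carry the intercept report.
#' @export
mvmr_egger <- function(frame, effects_model = c("multiplicative_random",
                                                "fixed")) {
  effects_model <- match.arg(effects_model)
  d <- frame_multivariable(frame)
  n <- length(d$by)
  k <- ncol(d$x)
  if (n < k + 2) {
    abort(sprintf("multivariable MR-Egger needs at least K+2 = %d SNPs",
                  k + 2),
          class = "tidymr_insufficient_instruments")
  }
  s <- ifelse(d$x[, 1] < 0, -1, 1)
  x <- d$x * s
  by <- d$by * s
  w <- 1 / d$sy^2
  check_rank(x, w)
  fit <- mvmr_wls(x, by, w, intercept = TRUE)
  scale <- if (effects_model == "multiplicative_random") max(1, fit$sigma)
           else 1
  ses <- fit$ses * scale
  df <- n - k - 1
  slopes <- fit$coefs[-1]
  slope_ses <- ses[-1]
  new_mr_result("mvmr_egger", n, tibble::tibble(
    term = d$terms, beta = unname(slopes), se = unname(slope_ses),
    ci_low = unname(slopes - Z95 * slope_ses),
    ci_high = unname(slopes + Z95 * slope_ses),
    pvalue = two_sided_p_t(slopes / slope_ses, df)
  ), extras = list(
    effects_model = effects_model, residual_scale = fit$sigma,
    intercept = unname(fit$coefs[1]), intercept_se = unname(ses[1]),
    intercept_p = unname(two_sided_p_t(fit$coefs[1] / ses[1], df))
  ))
}

# Weighted L1 (median, 0.5-quantile) regression through the origin by
# iteratively reweighted least squares: minimizes sum_j w_j |by_j - x_j b|.
l1_regression <- function(x, by, w, tol = 1e-10, max_iter = 200) {
  fit <- mvmr_wls(x, by, w, intercept = FALSE)
  b <- fit$coefs
  eps <- 1e-8 * stats::median(abs(by) + 1e-300)
  for (i in seq_len(max_iter)) {
    r <- by - drop(x %*% b)
    wi <- w / pmax(abs(r), eps)
    xtwx <- crossprod(x, wi * x)
    b_new <- drop(solve(xtwx, crossprod(x, wi * by)))
    if (max(abs(b_new - b)) < tol * (1 + max(abs(b)))) {
      b <- b_new
      break
    }
    b <- b_new
  }
  b
}

#' Multivariable weighted median (0.5-quantile) regression
#'
#' Median regression of the SNP-outcome effects on the exposure-effect
#' columns through the origin with observation weights `1/se_y^2`
#' (minimizing the weighted absolute residuals), robust to a minority of
#' outlying pleiotropic SNPs. The standard error is a parametric
#' bootstrap with the given seed.
#'
#' @inheritParams mvmr_ivw
#' @param n_boot Bootstrap replicates (0 skips SEs).
#' @param seed Optional integer seed.
#' @return An `mr_result` with one estimate row per exposure.
#' @export
mvmr_median <- function(frame, n_boot = 1000, seed = NULL) {
  d <- frame_multivariable(frame)
  n <- length(d$by)
  k <- ncol(d$x)
  if (n < k + 1) {
    abort(sprintf("multivariable median needs at least K+1 = %d SNPs", k + 1),
          class = "tidymr_insufficient_instruments")
  }
  w <- 1 / d$sy^2
  check_rank(d$x, w)
  b <- l1_regression(d$x, d$by, w)
  ses <- rep(NA_real_, k)
  if (n_boot > 0) {
    boots <- with_seed_if(seed, {
      vapply(seq_len(n_boot), function(i) {
        x_star <- d$x + matrix(rnorm(n * k), n, k) * d$sx
        by_star <- rnorm(n, d$by, d$sy)
        l1_regression(x_star, by_star, w)
      }, numeric(k))
    })
    ses <- apply(matrix(boots, nrow = k), 1, stats::sd)
  }
  new_mr_result("mvmr_median", n, tibble::tibble(
    term = d$terms, beta = unname(b), se = ses,
    ci_low = unname(b - Z95 * ses), ci_high = unname(b + Z95 * ses),
    pvalue = ifelse(is.na(ses), NA_real_, two_sided_p(b / ses))
  ), extras = list(n_boot = n_boot))
}
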