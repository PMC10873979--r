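# Quick-look ggplot helpers for the standard MR displays. These render
# the underlying data tables produced elsewhere in the package; they are
# conveniences, not publication figures.

#' Forest plot of MR estimates
#'
#' @param results Tidy estimate rows (e.g. `run_univariable()$results` or
#'   `tidy()` output); expects `estimate`, `conf.low`, `conf.high`,
#'   `method`, and optionally `exposure`/`term` and `pass`.
#' @param or_scale Plot exponentiated estimates (odds ratios).
#' @return A ggplot.
#' @export
plot_forest <- function(results, or_scale = FALSE) {
  df <- results
  if (!"exposure" %in% names(df)) {
    df$exposure <- df$term %||% "exposure"
  }
  df$label <- paste(df$exposure, df$method)
  if ("pass" %in% names(df)) {
    df$label <- ifelse(df$pass == "pre", df$label,
                       paste0(df$label, "*"))
  }
  trans <- if (or_scale) exp else identity
  null_line <- if (or_scale) 1 else 0
  ggplot2::ggplot(df, ggplot2::aes(x = trans(.data$estimate),
                                   y = .data$label)) +
    ggplot2::geom_vline(xintercept = null_line, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = trans(.data$conf.low),
                                         xmax = trans(.data$conf.high)),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$method), size = 2) +
    ggplot2::labs(x = if (or_scale) "odds ratio (95% CI)"
                  else "causal estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of SNP-outcome vs SNP-exposure effects with fitted lines
#'
#' @param frame Harmonized frame (single exposure).
#' @param estimates Optional list of `mr_result`s drawn as fitted lines.
#' @return A ggplot.
#' @export
plot_scatter <- function(frame, estimates = list()) {
  d <- frame_univariable(frame)
  df <- tibble::tibble(bx = d$bx, by = d$by, sx = d$sx, sy = d$sy)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$sy,
                                        ymax = .data$by + .data$sy),
                           colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$sx,
                                         xmax = .data$bx + .data$sx),
                            colour = "grey70", height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome") +
    ggplot2::theme_minimal()
  if (length(estimates) > 0) {
    lines <- purrr::map_dfr(estimates, function(e) {
      tibble::tibble(method = e$method,
                     slope = e$estimates$beta[1],
                     intercept = e$extras$intercept %||% 0)
    })
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method))
  }
  p
}

#' Funnel plot of per-SNP ratios against precision
#'
#' @param funnel Output of [mr_funnel_data()].
#' @return A ggplot with the pooled IVW estimate as a vertical line.
#' @export
plot_funnel <- function(funnel) {
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$ratio,
                                       y = .data$precision)) +
    ggplot2::geom_vline(xintercept = attr(funnel, "pooled"),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "per-SNP Wald ratio", y = "precision (1/se)") +
    ggplot2::theme_minimal()
}

#' Leave-one-out forest plot
#'
#' @param loo Output of [mr_leave_one_out()].
#' @return A ggplot; the full-frame estimate and CI are shown as lines.
#' @export
plot_loo <- function(loo) {
  full <- attr(loo, "full")$estimates
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$beta,
                                    y = .data$rsid_left_out)) +
    ggplot2::geom_vline(xintercept = full$beta, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = c(full$ci_low, full$ci_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$influential)) +
    ggplot2::labs(x = "IVW estimate excluding SNP", y = NULL) +
    ggplot2::theme_minimal()
}
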