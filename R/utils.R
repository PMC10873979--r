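# Internal helpers shared across modules.

# Two-sided p from a z statistic, clamped into (0, 1] so downstream
# invariants (p-values strictly positive) hold even for |z| ~ 40.
two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

# Two-sided p from a t statistic.
two_sided_p_t <- function(t, df) {
  p <- 2 * stats::pt(-abs(t), df = df)
  pmax(p, .Machine$double.xmin)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) {
  unname(DNA_COMPLEMENT[x])
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

# Columns that make up a harmonized frame's exposure block. Exposure effect
# columns are named beta_x (univariable) or beta_x_<trait> (multivariable);
# matching se_x columns mirror them.
exposure_beta_cols <- function(frame) {
  nm <- names(frame)
  cols <- nm[grepl("^beta_x", nm)]
  if (length(cols) == 0) {
    abort("no exposure effect columns (beta_x*) found in frame",
          class = "tidymr_bad_frame")
  }
  cols
}

exposure_se_cols <- function(frame) {
  sub("^beta_x", "se_x", exposure_beta_cols(frame))
}

exposure_names <- function(frame) {
  cols <- exposure_beta_cols(frame)
  ifelse(cols == "beta_x", "exposure", sub("^beta_x_", "", cols))
}

check_frame <- function(frame) {
  needed <- c("rsid", "beta_y", "se_y")
  missing <- setdiff(needed, names(frame))
  if (length(missing) > 0) {
    abort(paste0("harmonized frame is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tidymr_bad_frame")
  }
  if (any(frame$se_y <= 0) ) {
    abort("se_y must be strictly positive", class = "tidymr_bad_frame")
  }
  invisible(frame)
}

# Interpolated weighted median of `x` with nonnegative weights `w`
# (normalized internally): order x ascending, cumulative weight minus half
# the element's own weight, linear interpolation at 0.5.
weighted_median_value <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

# Run `expr` under `seed` when supplied (restoring RNG state afterwards),
# else in the ambient RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "tidymr_invalid_argument")
  }
  invisible(as.integer(x))
}

check_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1 && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must lie in %s%g, %g%s", name,
                  if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]"),
          class = "tidymr_invalid_argument")
  }
  invisible(x)
}
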