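# Shared fixture builders and independent oracles used across test files.

# Minimal harmonized frame from raw effect vectors.
make_frame <- function(bx, sx, by, sy, rsid = sprintf("rs%03d", seq_along(bx))) {
  tibble::tibble(rsid = rsid, beta_x = bx, se_x = sx, beta_y = by, se_y = sy)
}

# Random harmonized frame for oracle comparisons.
random_frame <- function(n, seed) {
  withr::with_seed(seed, {
    bx <- rnorm(n, 0.08, 0.04)
    bx[abs(bx) < 1e-3] <- 0.05
    make_frame(bx = bx,
               sx = runif(n, 0.002, 0.01),
               by = 0.2 * bx + rnorm(n, 0, 0.02),
               sy = runif(n, 0.01, 0.05))
  })
}

# One-line summary-stat row for harmonization truth-table cases.
snp_row <- function(rsid, ea, oa, beta, eaf, se = 0.01, chrom = "1",
                    pos = 1000, n = 1e5, trait_id = "t",
                    trait_type = "continuous") {
  tibble::tibble(rsid = rsid, chrom = chrom, pos = pos,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = se,
                 pvalue = 2 * pnorm(-abs(beta / se)), n = n,
                 trait_id = trait_id, trait_type = trait_type)
}

# Independent IVW / Egger oracle via stats::lm (never used in R/).
lm_ivw_oracle <- function(frame) {
  fit <- lm(beta_y ~ 0 + beta_x, data = frame, weights = 1 / frame$se_y^2)
  unname(coef(fit)[1])
}

lm_egger_oracle <- function(frame) {
  s <- ifelse(frame$beta_x < 0, -1, 1)
  df <- data.frame(bx = frame$beta_x * s, by = frame$beta_y * s)
  fit <- lm(by ~ bx, data = df, weights = 1 / frame$se_y^2)
  c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

# Brute-force interpolated weighted median: explicit scan for the pair of
# ordered ratios bracketing cumulative weight 0.5, then manual linear
# interpolation (independent of stats::approx and of the implementation).
brute_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  p <- w[ord] / sum(w)
  s <- numeric(length(p))
  run <- 0
  for (i in seq_along(p)) {
    s[i] <- run + p[i] / 2
    run <- run + p[i]
  }
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  i <- max(which(s < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# Independent greedy clumping oracle on an explicit r2 matrix.
greedy_clump_oracle <- function(p, r2mat, pos, window_bp, r2_threshold) {
  remaining <- seq_along(p)
  kept <- integer(0)
  while (length(remaining) > 0) {
    idx <- remaining[which.min(p[remaining])]
    kept <- c(kept, idx)
    linked <- remaining[
      abs(pos[remaining] - pos[idx]) <= window_bp &
        r2mat[idx, remaining] > r2_threshold]
    remaining <- setdiff(remaining, union(idx, linked))
  }
  sort(kept)
}

# Small default study generator for pipeline tests.
quick_sim <- function(seed, ...) {
  simulate_study(sim_config(seed = seed, ...))
}
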