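#' Configuration for the synthetic GWAS summary-statistics generator
#'
#' Bundles every knob of the generative model behind [simulate_study()] into
#' a validated list. The defaults emulate the structure of a two-sample MR
#' study of thyroid function on a binary musculoskeletal outcome: a large
#' continuous-trait exposure GWAS, a biobank case-control outcome GWAS with a
#' small case fraction, block-structured LD, palindromic variants, and
#' outcome records whose allele labels are flipped relative to the exposure.
#'
#' The generative model, per SNP `j` and exposure `k`:
#' * minor-allele frequency `MAF_j ~ Uniform(maf_range)`;
#' * true SNP-exposure effect `gamma_jk` drawn with spread
#'   `exposure_effect_sd` for instrument SNPs, 0 otherwise; under the default
#'   `exposure_effect_dist = "halfnormal"` effects are oriented to the
#'   trait-increasing allele (standard in MR simulation, and required for
#'   directional pleiotropy to bias IVW in a fixed direction);
#' * pleiotropic effect `alpha_j` by `pleiotropy_mode`: `none` (0),
#'   `balanced` (`N(0, pleiotropy_sd^2)`), `directional`
#'   (`N(pleiotropy_mean, pleiotropy_sd^2)`), or `inside_violating`
#'   (`inside_kappa * gamma_j1 + N(0, pleiotropy_sd^2)`), applied to a
#'   random `invalid_fraction` of the instruments, plus `outlier_offset`
#'   added at `outlier_indices`;
#' * true SNP-outcome effect `Gamma_j = sum_k theta_k gamma_jk + alpha_j`
#'   on the log-odds scale;
#' * observed effects are normal draws around truth with analytic standard
#'   errors `se_X = 1/sqrt(2 N_x MAF (1-MAF))` and
#'   `se_Y = 1/sqrt(2 N_y cf (1-cf) * 2 MAF (1-MAF))` where `cf` is the
#'   outcome case fraction.
#'
#' @param n_snps Total SNPs simulated.
#' @param n_instruments Number of SNPs with nonzero exposure effects. Each
#'   instrument occupies its own LD block (so instruments are mutually
#'   independent and survive clumping).
#' @param theta True causal effect(s) of the exposure(s) on the outcome
#'   (log-odds per exposure unit). A vector of length K simulates K
#'   exposures sharing the instrument set.
#' @param exposure_effect_sd Scale of true SNP-exposure effects.
#' @param exposure_effect_dist `"halfnormal"` (default) or `"normal"`.
#' @param exposure_corr Optional K x K correlation matrix coupling the
#'   exposures' true SNP effects (e.g. to make one exposure act on the
#'   outcome only through another).
#' @param instrument_assignment `"shared"` (default: every exposure has
#'   effects at the same `n_instruments` SNPs, as multivariable MR
#'   requires) or `"disjoint"` (each exposure gets its own
#'   `n_instruments` SNPs, emulating traits instrumented by distinct
#'   loci; requires `n_instruments * K` LD blocks).
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of `alpha_j`.
#' @param inside_kappa Coupling of `alpha_j` to `gamma_j1` under
#'   `inside_violating`.
#' @param invalid_fraction Fraction of instruments receiving pleiotropy
#'   under a non-`none` mode.
#' @param n_exposure,n_outcome GWAS sample sizes (`n_exposure` may be a
#'   vector of length K).
#' @param outcome_case_fraction Case proportion of the binary outcome,
#'   strictly inside (0, 1).
#' @param maf_range Interval within (0, 0.5] for minor-allele frequencies.
#' @param palindromic_fraction Fraction of SNPs given A/T or G/C alleles.
#' @param allele_flip_fraction Fraction of outcome records whose allele
#'   labels are swapped (beta negated, EAF complemented) — label changes
#'   only, which harmonization must undo.
#' @param strand_flip_fraction Fraction of non-palindromic outcome records
#'   reported on the opposite strand (alleles complemented).
#' @param outlier_indices SNP (row) indices receiving `outlier_offset`.
#' @param outlier_offset Fixed pleiotropic offset for planted outliers.
#' @param ld_block_size,ld_rho LD block size and within-block correlation
#'   (pairwise r^2 is `ld_rho^2` inside a block, 0 across blocks).
#' @param confounder_indices SNP indices annotated to confounder traits.
#' @param confounder_traits Trait names cycled over `confounder_indices`.
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_study()], [simulate_ld_reference()]
#' @export
sim_config <- function(n_snps = 400L,
                       n_instruments = 50L,
                       theta = 0.11,
                       exposure_effect_sd = 0.05,
                       exposure_effect_dist = c("halfnormal", "normal"),
                       exposure_corr = NULL,
                       instrument_assignment = c("shared", "disjoint"),
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violating"),
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       inside_kappa = 0,
                       invalid_fraction = 1,
                       n_exposure = 119715L,
                       n_outcome = 211023L,
                       outcome_case_fraction = 5668 / 211023,
                       maf_range = c(0.05, 0.5),
                       palindromic_fraction = 0.15,
                       allele_flip_fraction = 0.15,
                       strand_flip_fraction = 0.10,
                       outlier_indices = integer(0),
                       outlier_offset = 0,
                       ld_block_size = 4L,
                       ld_rho = 0.95,
                       confounder_indices = integer(0),
                       confounder_traits = c("smoking", "chronic pain",
                                             "depression"),
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  exposure_effect_dist <- match.arg(exposure_effect_dist)
  instrument_assignment <- match.arg(instrument_assignment)

  n_snps <- check_count(n_snps, "n_snps")
  n_instruments <- check_count(n_instruments, "n_instruments")
  ld_block_size <- check_count(ld_block_size, "ld_block_size")
  seed <- check_count(seed, "seed", min = 0L)
  check_prob(outcome_case_fraction, "outcome_case_fraction",
             lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  for (f in c("invalid_fraction", "palindromic_fraction",
              "allele_flip_fraction", "strand_flip_fraction")) {
    check_prob(get(f), f)
  }
  check_prob(ld_rho, "ld_rho", lo = 0, hi = 1, hi_open = TRUE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5]",
          class = "tidymr_invalid_argument")
  }
  k <- length(theta)
  n_inst_total <- if (instrument_assignment == "disjoint") n_instruments * k
                  else n_instruments
  if (n_inst_total > n_snps) {
    abort("`n_instruments` (per exposure) must not exceed `n_snps`",
          class = "tidymr_invalid_argument")
  }
  n_blocks <- ceiling(n_snps / ld_block_size)
  if (n_inst_total > n_blocks) {
    abort(sprintf(paste0("need one LD block per instrument: %d instruments ",
                         "but only %d blocks (n_snps / ld_block_size)"),
                  n_inst_total, n_blocks),
          class = "tidymr_invalid_argument")
  }
  if (!is.null(exposure_corr)) {
    exposure_corr <- as.matrix(exposure_corr)
    if (!all(dim(exposure_corr) == k)) {
      abort("`exposure_corr` must be a K x K matrix matching length(theta)",
            class = "tidymr_invalid_argument")
    }
  }
  if (!length(n_exposure) %in% c(1L, k)) {
    abort("`n_exposure` must have length 1 or length(theta)",
          class = "tidymr_invalid_argument")
  }
  if (any(outlier_indices < 1 | outlier_indices > n_snps)) {
    abort("`outlier_indices` out of range", class = "tidymr_invalid_argument")
  }

  structure(list(
    n_snps = n_snps, n_instruments = n_instruments, theta = theta,
    exposure_effect_sd = exposure_effect_sd,
    exposure_effect_dist = exposure_effect_dist,
    exposure_corr = exposure_corr,
    instrument_assignment = instrument_assignment,
    pleiotropy_mode = pleiotropy_mode,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    inside_kappa = inside_kappa, invalid_fraction = invalid_fraction,
    n_exposure = n_exposure, n_outcome = n_outcome,
    outcome_case_fraction = outcome_case_fraction,
    maf_range = maf_range,
    palindromic_fraction = palindromic_fraction,
    allele_flip_fraction = allele_flip_fraction,
    strand_flip_fraction = strand_flip_fraction,
    outlier_indices = as.integer(outlier_indices),
    outlier_offset = outlier_offset,
    ld_block_size = ld_block_size, ld_rho = ld_rho,
    confounder_indices = as.integer(confounder_indices),
    confounder_traits = confounder_traits,
    seed = seed
  ), class = "sim_config")
}

block_positions <- function(n_snps, block_size, gap_kb) {
  block <- (seq_len(n_snps) - 1L) %/% block_size
  within <- (seq_len(n_snps) - 1L) %% block_size
  block * (block_size * 1000L + gap_kb * 1000L) + within * 1000L + 1L
}

block_pairs <- function(rsid, block, r2) {
  per_block <- split(rsid, block)
  pairs <- purrr::map(per_block, function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    tibble::tibble(rsid_a = cmb[1, ], rsid_b = cmb[2, ], r2 = r2)
  })
  empty <- tibble::tibble(rsid_a = character(), rsid_b = character(),
                          r2 = double())
  dplyr::bind_rows(c(list(empty), unname(pairs)))
}

#' Simulate a block-structured pairwise LD reference
#'
#' Builds an LD lookup in which distinct SNPs within a block have pairwise
#' `r^2 = rho^2` and SNPs in different blocks are uncorrelated. Positions
#' are strictly increasing along a single chromosome, with `block_size`
#' SNPs spaced 1 kb apart inside a block and `inter_block_gap_kb` between
#' blocks.
#'
#' @param n_blocks,block_size Number of blocks and SNPs per block.
#' @param rho Within-block correlation, in `[0, 1)`.
#' @param inter_block_gap_kb Gap between consecutive blocks (kb).
#' @param seed Integer seed (kept for interface symmetry; the construction
#'   is deterministic).
#' @return An object of class `ld_reference`: a list with `pairs`
#'   (tibble: `rsid_a`, `rsid_b`, `r2`) and `positions` (tibble: `rsid`,
#'   `chrom`, `pos`).
#' @export
simulate_ld_reference <- function(n_blocks, block_size, rho,
                                  inter_block_gap_kb = 500, seed = 1L) {
  n_blocks <- check_count(n_blocks, "n_blocks")
  block_size <- check_count(block_size, "block_size")
  check_prob(rho, "rho", lo = 0, hi = 1, hi_open = TRUE)
  n <- n_blocks * block_size
  rsid <- sprintf("rs%06d", seq_len(n))
  block <- (seq_len(n) - 1L) %/% block_size
  positions <- tibble::tibble(
    rsid = rsid, chrom = "1",
    pos = block_positions(n, block_size, inter_block_gap_kb)
  )
  pairs <- block_pairs(rsid, block, rho^2)
  if (is.null(pairs) || nrow(pairs) == 0) {
    pairs <- tibble::tibble(rsid_a = character(), rsid_b = character(),
                            r2 = double())
  }
  new_ld_reference(pairs, positions)
}

draw_alleles <- function(n, palindromic_fraction) {
  bases <- c("A", "C", "G", "T")
  pal <- runif(n) < palindromic_fraction
  a1 <- sample(bases, n, replace = TRUE)
  a2 <- character(n)
  a2[pal] <- complement_allele(a1[pal])
  for (i in which(!pal)) {
    a2[i] <- sample(setdiff(bases, c(a1[i], complement_allele(a1[i]))), 1)
  }
  list(effect = a1, other = a2, palindromic = pal)
}

#' Simulate a complete two-sample MR study with known ground truth
#'
#' Generates exposure and outcome GWAS summary statistics, a matching LD
#' reference, a trait-annotation table (a local stand-in for a
#' PhenoScanner-style lookup), and the generator's ground truth, under the
#' model described in [sim_config()].
#'
#' @param cfg A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{exposures}{named list of exposure summary-stat tibbles
#'       (columns `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'       `eaf`, `beta`, `se`, `pvalue`, `n`, `trait_id`, `trait_type`).}
#'     \item{outcome}{outcome summary-stat tibble (binary trait, log-odds
#'       betas), with constructed allele-label and strand flips.}
#'     \item{annotation}{tibble `rsid`, `trait`, `pvalue`.}
#'     \item{ld}{`ld_reference` covering all simulated SNPs.}
#'     \item{truth}{list of class `mr_truth`: `theta`, `gamma` (SNP x K
#'       matrix), `alpha`, instrument/invalid/outlier indices and rsids.}
#'   }
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_study_impl(cfg))
}

simulate_study_impl <- function(cfg) {
  n <- cfg$n_snps
  k <- length(cfg$theta)
  rsid <- sprintf("rs%06d", seq_len(n))
  block <- (seq_len(n) - 1L) %/% cfg$ld_block_size
  pos <- block_positions(n, cfg$ld_block_size, 500)
  chrom <- rep("1", n)

  # one instrument per block, at the block head, so instruments are
  # mutually unlinked and clumping retains them
  n_inst_total <- if (cfg$instrument_assignment == "disjoint") {
    cfg$n_instruments * k
  } else {
    cfg$n_instruments
  }
  instrument_idx <- which(!duplicated(block))[seq_len(n_inst_total)]

  maf <- runif(n, cfg$maf_range[1], cfg$maf_range[2])
  al <- draw_alleles(n, cfg$palindromic_fraction)

  # true SNP-exposure effects
  gamma <- matrix(0, n, k)
  z <- matrix(rnorm(n_inst_total * k), n_inst_total, k)
  if (!is.null(cfg$exposure_corr)) z <- z %*% chol(cfg$exposure_corr)
  g <- z * cfg$exposure_effect_sd
  if (cfg$exposure_effect_dist == "halfnormal") g <- abs(g)
  if (cfg$instrument_assignment == "disjoint") {
    # round-robin: exposure j instruments are idx positions j, j+K, ...
    for (j in seq_len(k)) {
      mine <- seq(j, n_inst_total, by = k)
      gamma[instrument_idx[mine], j] <- g[mine, j]
    }
  } else {
    gamma[instrument_idx, ] <- g
  }

  # pleiotropic effects
  alpha <- numeric(n)
  if (cfg$pleiotropy_mode != "none") {
    n_invalid <- ceiling(cfg$invalid_fraction * cfg$n_instruments)
    invalid_idx <- sort(sample(instrument_idx, n_invalid))
    alpha[invalid_idx] <- switch(
      cfg$pleiotropy_mode,
      balanced = rnorm(n_invalid, 0, cfg$pleiotropy_sd),
      directional = rnorm(n_invalid, cfg$pleiotropy_mean, cfg$pleiotropy_sd),
      inside_violating = cfg$inside_kappa * gamma[invalid_idx, 1] +
        rnorm(n_invalid, 0, cfg$pleiotropy_sd)
    )
  }
  alpha[cfg$outlier_indices] <- alpha[cfg$outlier_indices] + cfg$outlier_offset

  gamma_out <- as.vector(gamma %*% cfg$theta) + alpha

  n_exp <- rep(cfg$n_exposure, length.out = k)
  exposures <- purrr::map(seq_len(k), function(j) {
    se_x <- 1 / sqrt(2 * n_exp[j] * maf * (1 - maf))
    beta_hat <- rnorm(n, gamma[, j], se_x)
    tibble::tibble(
      rsid = rsid, chrom = chrom, pos = pos,
      effect_allele = al$effect, other_allele = al$other,
      eaf = maf, beta = beta_hat, se = se_x,
      pvalue = two_sided_p(beta_hat / se_x),
      n = n_exp[j],
      trait_id = if (k == 1) "exposure" else paste0("exposure_", j),
      trait_type = "continuous"
    )
  })
  names(exposures) <- purrr::map_chr(exposures, ~ .x$trait_id[1])

  cf <- cfg$outcome_case_fraction
  se_y <- 1 / sqrt(2 * cfg$n_outcome * cf * (1 - cf) * 2 * maf * (1 - maf))
  beta_y_hat <- rnorm(n, gamma_out, se_y)
  outcome <- tibble::tibble(
    rsid = rsid, chrom = chrom, pos = pos,
    effect_allele = al$effect, other_allele = al$other,
    eaf = maf, beta = beta_y_hat, se = se_y,
    pvalue = two_sided_p(beta_y_hat / se_y),
    n = cfg$n_outcome,
    trait_id = "outcome", trait_type = "binary"
  )

  # strand flips: report some non-palindromic outcome rows on the other
  # strand (pure relabelling; complements both alleles)
  flippable <- which(!al$palindromic)
  n_strand <- round(cfg$strand_flip_fraction * length(flippable))
  if (n_strand > 0) {
    i <- sample(flippable, n_strand)
    outcome$effect_allele[i] <- complement_allele(outcome$effect_allele[i])
    outcome$other_allele[i] <- complement_allele(outcome$other_allele[i])
  }
  # allele-label flips: swap effect/other, negate beta, complement EAF
  n_flip <- round(cfg$allele_flip_fraction * n)
  if (n_flip > 0) {
    i <- sample(n, n_flip)
    tmp <- outcome$effect_allele[i]
    outcome$effect_allele[i] <- outcome$other_allele[i]
    outcome$other_allele[i] <- tmp
    outcome$beta[i] <- -outcome$beta[i]
    outcome$eaf[i] <- 1 - outcome$eaf[i]
  }

  ld <- new_ld_reference(
    block_pairs(rsid, block, cfg$ld_rho^2),
    tibble::tibble(rsid = rsid, chrom = chrom, pos = pos)
  )

  annotation <- tibble::tibble(rsid = character(), trait = character(),
                               pvalue = double())
  if (length(cfg$confounder_indices) > 0) {
    annotation <- tibble::tibble(
      rsid = rsid[cfg$confounder_indices],
      trait = rep_len(cfg$confounder_traits, length(cfg$confounder_indices)),
      pvalue = 1e-12
    )
  }
  # benign annotations on instruments not planted as confounded
  benign <- setdiff(instrument_idx, cfg$confounder_indices)
  if (length(benign) >= 2) {
    annotation <- dplyr::bind_rows(
      annotation,
      tibble::tibble(rsid = rsid[benign[1:2]], trait = "standing height",
                     pvalue = 1e-9)
    )
  }

  invalid_idx <- which(alpha != 0)
  truth <- structure(list(
    theta = cfg$theta,
    gamma = gamma,
    alpha = alpha,
    instrument_snps = instrument_idx,
    instrument_rsids = rsid[instrument_idx],
    invalid_snps = invalid_idx,
    invalid_rsids = rsid[invalid_idx],
    outlier_snps = cfg$outlier_indices,
    outlier_rsids = rsid[cfg$outlier_indices]
  ), class = "mr_truth")

  list(exposures = exposures, outcome = outcome, annotation = annotation,
       ld = ld, truth = truth)
}
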