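# Align one trait's records (b1/b2, beta, eaf) to reference alleles
# (a1/a2, eaf_ref). Returns beta', eaf', action per row.
align_alleles <- function(a1, a2, eaf_ref, b1, b2, beta, eaf,
                          band, palindromic_policy) {
  n <- length(a1)
  action <- character(n)
  beta_out <- beta
  eaf_out <- eaf

  pal <- is_palindromic(a1, a2)

  # --- palindromic reference SNPs: allele labels cannot resolve strand;
  # orient purely by allele-frequency agreement
  if (palindromic_policy == "drop") {
    action[pal] <- "dropped_palindromic_ambiguous"
  } else {
    ref_inform <- !is.na(eaf_ref) & abs(eaf_ref - 0.5) > band
    trt_inform <- !is.na(eaf) & abs(eaf - 0.5) > band
    ok <- pal & ref_inform & trt_inform
    same_side <- (eaf_ref > 0.5) == (eaf > 0.5)
    action[ok & same_side] <- "palindromic_inferred"
    flip <- ok & !same_side
    action[flip] <- "palindromic_inferred"
    beta_out[flip] <- -beta[flip]
    eaf_out[flip] <- 1 - eaf[flip]
    action[pal & !ok] <- "dropped_palindromic_ambiguous"
  }

  # --- non-palindromic: direct match, swap, or strand-complement thereof
  np <- !pal
  c1 <- complement_allele(b1)
  c2 <- complement_allele(b2)
  same <- np & ((b1 == a1 & b2 == a2) | (c1 == a1 & c2 == a2))
  swap <- np & !same & ((b1 == a2 & b2 == a1) | (c1 == a2 & c2 == a1))
  action[same] <- "kept_as_is"
  action[swap] <- "flipped"
  beta_out[swap] <- -beta[swap]
  eaf_out[swap] <- 1 - eaf[swap]
  action[np & !same & !swap] <- "dropped_incompatible"

  list(beta = beta_out, eaf = eaf_out, action = action)
}

#' Harmonize exposure and outcome effect alleles
#'
#' Aligns every trait's per-allele effects to the (first) exposure's effect
#' allele so that all betas refer to the same allele. Per SNP: identical
#' alleles are kept; swapped alleles flip the sign of beta and complement
#' the EAF; complementary (strand-flipped) non-palindromic alleles are
#' complemented and then matched; palindromic SNPs (A/T, G/C) are oriented
#' by allele-frequency agreement when both EAFs lie outside
#' `0.5 +/- palindromic_eaf_band` (opposite sides of 0.5 means flip) and
#' dropped as ambiguous otherwise; irreconcilable allele sets are dropped
#' as incompatible.
#'
#' @param exposure A summary-stat tibble, or a list of them for
#'   multivariable harmonization (all aligned to the first exposure's
#'   effect allele; SNPs missing in any trait are dropped, complete-case).
#' @param outcome Outcome summary-stat tibble.
#' @param palindromic_eaf_band Half-width of the EAF ambiguity band around
#'   0.5 (default 0.08).
#' @param palindromic_policy `"infer"` (default, frequency-based
#'   orientation) or `"drop"` (discard all palindromic SNPs).
#' @return A harmonized-frame tibble with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, exposure effects `beta_x`/
#'   `se_x` (suffixed `_<trait_id>` per exposure in the multivariable
#'   case), `beta_y`, `se_y`, and `action`. Dropped SNPs are recorded in
#'   the `"audit"` attribute (tibble `rsid`, `action`) and excluded from
#'   the frame.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_band = 0.08,
                      palindromic_policy = c("infer", "drop")) {
  palindromic_policy <- match.arg(palindromic_policy)
  exposures <- if (inherits(exposure, "data.frame")) list(exposure)
               else exposure
  for (tb in c(exposures, list(outcome))) {
    if (anyDuplicated(tb$rsid)) {
      abort("duplicate rsids in input summary statistics",
            class = "tidymr_format_error")
    }
  }
  multi <- length(exposures) > 1
  ref <- exposures[[1]]
  shared <- Reduce(intersect, c(purrr::map(exposures, "rsid"),
                                list(outcome$rsid)))
  if (length(shared) == 0) {
    abort("no shared rsids between exposure(s) and outcome",
          class = "tidymr_format_error")
  }
  ref <- ref[match(shared, ref$rsid), , drop = FALSE]

  frame <- tibble::tibble(
    rsid = ref$rsid, chrom = ref$chrom, pos = ref$pos,
    effect_allele = ref$effect_allele, other_allele = ref$other_allele,
    eaf = ref$eaf
  )
  trait_ids <- purrr::map_chr(exposures, function(tb) {
    if ("trait_id" %in% names(tb)) tb$trait_id[1] else "exposure"
  })
  actions <- matrix("", nrow(frame), length(exposures) + 1)

  for (j in seq_along(exposures)) {
    tb <- exposures[[j]][match(shared, exposures[[j]]$rsid), , drop = FALSE]
    if (j == 1) {
      aligned <- list(beta = tb$beta, eaf = tb$eaf,
                      action = rep("kept_as_is", nrow(tb)))
    } else {
      aligned <- align_alleles(ref$effect_allele, ref$other_allele, ref$eaf,
                               tb$effect_allele, tb$other_allele,
                               tb$beta, tb$eaf,
                               palindromic_eaf_band, palindromic_policy)
    }
    suffix <- if (multi) paste0("_", trait_ids[j]) else ""
    frame[[paste0("beta_x", suffix)]] <- aligned$beta
    frame[[paste0("se_x", suffix)]] <- tb$se
    actions[, j] <- aligned$action
  }

  out <- outcome[match(shared, outcome$rsid), , drop = FALSE]
  aligned_y <- align_alleles(ref$effect_allele, ref$other_allele, ref$eaf,
                             out$effect_allele, out$other_allele,
                             out$beta, out$eaf,
                             palindromic_eaf_band, palindromic_policy)
  frame$beta_y <- aligned_y$beta
  frame$se_y <- out$se
  actions[, ncol(actions)] <- aligned_y$action

  dropped_any <- apply(actions, 1, function(a) any(startsWith(a, "dropped")))
  # the audited action is the outcome alignment's unless a co-trait forced
  # the drop
  action <- aligned_y$action
  forced <- dropped_any & !startsWith(action, "dropped")
  if (any(forced)) {
    action[forced] <- apply(actions[forced, , drop = FALSE], 1, function(a) {
      a[startsWith(a, "dropped")][1]
    })
  }
  frame$action <- action

  audit <- tibble::tibble(rsid = frame$rsid, action = action)
  kept <- frame[!dropped_any, , drop = FALSE]
  if (any(dropped_any)) {
    inform(sprintf("harmonization dropped %d SNP(s) (%s)",
                   sum(dropped_any),
                   paste(names(table(action[dropped_any])), collapse = ", ")))
  }
  attr(kept, "audit") <- audit
  kept
}

#' Write a harmonized frame (with its action audit column) as TSV
#'
#' @param frame Harmonized frame from [harmonize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(frame, path) {
  readr::write_tsv(frame, path, progress = FALSE)
  invisible(path)
}
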