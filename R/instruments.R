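#' Keep SNPs genome-wide significantly associated with the exposure
#'
#' Retains records with `pvalue` strictly below `p_threshold` (the
#' conventional genome-wide level, 5e-8, by default).
#'
#' @param stats Summary-stat tibble.
#' @param p_threshold Significance level, in (0, 1).
#' @return The filtered tibble.
#' @export
filter_genome_wide <- function(stats, p_threshold = 5e-8) {
  check_prob(p_threshold, "p_threshold", lo_open = TRUE, hi_open = TRUE)
  dplyr::filter(stats, .data$pvalue < p_threshold)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unprocessed SNP with the lowest p-value as an index
#' SNP and removes every other SNP within `window_kb` of it (same
#' chromosome) whose pairwise `r^2` with it exceeds `r2_threshold`. The
#' retained set therefore contains no within-window pair with
#' `r^2 > r2_threshold`. SNPs absent from the LD reference positions are
#' treated as unlinked, with a warning.
#'
#' @param stats Summary-stat tibble.
#' @param ld An `ld_reference`.
#' @param r2_threshold Linkage cutoff; pairs at or below it are independent.
#' @param window_kb Clumping window in kilobases.
#' @return The clumped tibble (index SNPs only), in the input row order.
#' @export
clump <- function(stats, ld, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(stats) == 0) return(stats)
  pos <- ld$positions
  known <- stats$rsid %in% pos$rsid
  if (any(!known)) {
    warn(sprintf("%d SNP(s) absent from the LD reference; treated as unlinked",
                 sum(!known)))
  }
  posmap <- dplyr::left_join(
    stats[, "rsid"], pos, by = "rsid"
  )
  ordp <- order(stats$pvalue, stats$rsid)
  state <- rep("pending", nrow(stats)) # pending / index / removed
  for (i in ordp) {
    if (state[i] != "pending") next
    state[i] <- "index"
    if (!known[i]) next
    cand <- which(state == "pending" & known &
                    posmap$chrom == posmap$chrom[i] &
                    abs(posmap$pos - posmap$pos[i]) <= window_kb * 1000)
    if (length(cand) == 0) next
    r2 <- ld_lookup(ld, stats$rsid[i], stats$rsid[cand])
    state[cand[r2 > r2_threshold]] <- "removed"
  }
  stats[state == "index", , drop = FALSE]
}

#' Exclude instruments annotated to confounder traits
#'
#' Removes SNPs that the annotation table associates with any of the listed
#' confounder traits at `p < p_threshold`; each removal is reported with
#' the trait that triggered it.
#'
#' @param instr Instrument summary-stat tibble.
#' @param annotation Annotation tibble (`rsid`, `trait`, `pvalue`).
#' @param confounder_traits Character vector of trait names to screen.
#' @param p_threshold Association threshold for the annotation lookup.
#' @return The filtered tibble, with removals attached as attribute
#'   `"removed"` (tibble `rsid`, `trait`).
#' @export
exclude_confounder_snps <- function(instr, annotation, confounder_traits,
                                    p_threshold = 5e-8) {
  hits <- annotation |>
    dplyr::filter(.data$trait %in% confounder_traits,
                  .data$pvalue < p_threshold,
                  .data$rsid %in% instr$rsid) |>
    dplyr::distinct(.data$rsid, .data$trait)
  if (nrow(hits) > 0) {
    inform(sprintf("excluded %d instrument(s) annotated to confounders: %s",
                   dplyr::n_distinct(hits$rsid),
                   paste(unique(hits$trait), collapse = ", ")))
  }
  out <- dplyr::filter(instr, !.data$rsid %in% hits$rsid)
  attr(out, "removed") <- hits
  out
}

#' Exclude instruments significantly associated with the outcome
#'
#' Instruments whose outcome p-value is strictly below `p_threshold` are
#' removed. Instruments absent from the outcome dataset are retained here
#' and flagged (proxy search handles them).
#'
#' @param instr Instrument summary-stat tibble.
#' @param outcome Outcome summary-stat tibble.
#' @param p_threshold Significance level.
#' @return Filtered tibble with a logical column `missing_in_outcome`.
#' @export
exclude_outcome_associated <- function(instr, outcome, p_threshold = 5e-8) {
  p_out <- outcome$pvalue[match(instr$rsid, outcome$rsid)]
  drop <- !is.na(p_out) & p_out < p_threshold
  if (any(drop)) {
    inform(sprintf("excluded %d instrument(s) associated with the outcome",
                   sum(drop)))
  }
  out <- instr[!drop, , drop = FALSE]
  out$missing_in_outcome <- is.na(p_out[!drop])
  out
}

#' Find LD proxies for instruments missing from the outcome dataset
#'
#' For each missing SNP, searches the LD reference for the
#' outcome-present SNP with the largest `r^2` strictly above `r2_min`
#' (ties broken by smaller genomic distance, then lexicographic rsid).
#'
#' @param missing_snps Character vector of rsids absent from the outcome.
#' @param ld An `ld_reference`.
#' @param outcome Outcome summary-stat tibble.
#' @param r2_min Minimum qualifying `r^2` (strict inequality).
#' @return Tibble `rsid`, `proxy`, `r2` — one row per missing SNP; `proxy`
#'   is `NA` when no qualifying proxy exists.
#' @export
find_proxies <- function(missing_snps, ld, outcome, r2_min = 0.8) {
  pos <- ld$positions
  purrr::map_dfr(missing_snps, function(snp) {
    cand <- union(ld$pairs$rsid_b[ld$pairs$rsid_a == snp],
                  ld$pairs$rsid_a[ld$pairs$rsid_b == snp])
    cand <- intersect(cand, outcome$rsid)
    if (length(cand) > 0) {
      r2 <- ld_lookup(ld, snp, cand)
      keep <- r2 > r2_min
      cand <- cand[keep]
      r2 <- r2[keep]
    } else {
      r2 <- numeric(0)
    }
    if (length(cand) == 0) {
      return(tibble::tibble(rsid = snp, proxy = NA_character_, r2 = NA_real_))
    }
    dist <- abs(pos$pos[match(cand, pos$rsid)] - pos$pos[match(snp, pos$rsid)])
    dist[is.na(dist)] <- Inf
    ord <- order(-r2, dist, cand)
    tibble::tibble(rsid = snp, proxy = cand[ord[1]], r2 = r2[ord[1]])
  })
}

#' Per-SNP variance explained and F statistics
#'
#' Uses the standardized-trait approximation
#' `r2_j = 2 MAF_j (1 - MAF_j) beta_j^2` and
#' `F_j = r2_j (n - 2) / (1 - r2_j)`; instruments with `F <= 10` are
#' flagged as weak by the usual convention. When `eaf` is missing for a
#' SNP, the `use_se_fallback` option derives `F_j = (beta_j/se_j)^2` and
#' `r2_j = F_j / (F_j + n - 2)` instead; otherwise such SNPs are flagged
#' and excluded from the summary.
#'
#' @param instr Instrument summary-stat tibble (needs `eaf`, `beta`, or
#'   `se` under the fallback).
#' @param n GWAS sample size (scalar or per-SNP); defaults to the `n`
#'   column.
#' @param use_se_fallback Use the beta/se approximation where EAF is
#'   missing.
#' @return Tibble `rsid`, `r2`, `F`, `weak`, with a `summary` attribute
#'   (list: `min_F`, `mean_F`, `max_F`, `n_weak`, `n_missing_eaf`).
#' @export
instrument_strength <- function(instr, n = NULL, use_se_fallback = FALSE) {
  n <- n %||% instr$n
  if (any(n < 3)) {
    abort("sample size must be at least 3", class = "tidymr_invalid_argument")
  }
  n <- rep(n, length.out = nrow(instr))
  maf <- pmin(instr$eaf, 1 - instr$eaf)
  r2 <- 2 * maf * (1 - maf) * instr$beta^2
  if (use_se_fallback) {
    fb <- is.na(r2)
    f_fb <- (instr$beta[fb] / instr$se[fb])^2
    r2[fb] <- f_fb / (f_fb + n[fb] - 2)
  }
  f <- r2 * (n - 2) / (1 - r2)
  missing_eaf <- is.na(r2)
  if (any(missing_eaf)) {
    inform(sprintf("%d SNP(s) lack eaf; excluded from strength summary",
                   sum(missing_eaf)))
  }
  out <- tibble::tibble(rsid = instr$rsid, r2 = r2, F = f,
                        weak = !is.na(f) & f <= 10)
  attr(out, "summary") <- list(
    min_F = if (all(missing_eaf)) NA_real_ else min(f, na.rm = TRUE),
    mean_F = if (all(missing_eaf)) NA_real_ else mean(f, na.rm = TRUE),
    max_F = if (all(missing_eaf)) NA_real_ else max(f, na.rm = TRUE),
    n_weak = sum(out$weak),
    n_missing_eaf = sum(missing_eaf)
  )
  out
}

#' Run the full instrument-selection pipeline for one exposure
#'
#' Canonical order: genome-wide significance filter, LD clumping,
#' confounder exclusion via the annotation table, outcome-association
#' exclusion, then proxy substitution for instruments missing from the
#' outcome (a missing SNP is replaced by its best proxy's own exposure and
#' outcome records; SNPs without a qualifying proxy are dropped). Counts
#' in/out of every stage are recorded.
#'
#' @param exposure,outcome Summary-stat tibbles.
#' @param ld An `ld_reference`.
#' @param annotation Annotation tibble.
#' @param confounder_traits Trait names screened as confounders.
#' @param p_threshold,clump_r2,clump_window_kb,confounder_p,outcome_assoc_p,proxy_r2
#'   Stage thresholds (defaults: 5e-8, 0.001, 10000, 5e-8, 5e-8, 0.8).
#' @return List with `instruments` (exposure records of the selected SNPs,
#'   plus `proxy_for` column), `attrition` (tibble `stage`, `n_in`,
#'   `n_out`, `n_removed`) and `strength` (from [instrument_strength()]).
#' @export
select_instruments <- function(exposure, outcome, ld, annotation,
                               confounder_traits = character(0),
                               p_threshold = 5e-8,
                               clump_r2 = 0.001, clump_window_kb = 10000,
                               confounder_p = 5e-8,
                               outcome_assoc_p = 5e-8,
                               proxy_r2 = 0.8) {
  stage <- function(name, n_in, n_out) {
    tibble::tibble(stage = name, n_in = n_in, n_out = n_out,
                   n_removed = n_in - n_out)
  }
  att <- list()

  s0 <- exposure
  s1 <- filter_genome_wide(s0, p_threshold)
  att[[1]] <- stage("genome_wide_filter", nrow(s0), nrow(s1))

  s2 <- clump(s1, ld, clump_r2, clump_window_kb)
  att[[2]] <- stage("ld_clumping", nrow(s1), nrow(s2))

  s3 <- exclude_confounder_snps(s2, annotation, confounder_traits,
                                confounder_p)
  att[[3]] <- stage("confounder_exclusion", nrow(s2), nrow(s3))

  s4 <- exclude_outcome_associated(s3, outcome, outcome_assoc_p)
  att[[4]] <- stage("outcome_association_exclusion", nrow(s3), nrow(s4))

  missing <- s4$rsid[s4$missing_in_outcome]
  s5 <- s4
  s5$proxy_for <- NA_character_
  if (length(missing) > 0) {
    prox <- find_proxies(missing, ld, outcome, proxy_r2)
    found <- prox[!is.na(prox$proxy), , drop = FALSE]
    # full substitution: the proxy's own exposure record replaces the
    # missing SNP's (requires the proxy in the exposure panel too)
    sub <- exposure[match(found$proxy, exposure$rsid), , drop = FALSE]
    usable <- !is.na(sub$rsid) & !sub$rsid %in% s5$rsid
    sub <- sub[usable, , drop = FALSE]
    sub$missing_in_outcome <- FALSE
    sub$proxy_for <- found$rsid[usable]
    s5 <- dplyr::bind_rows(
      s5[!s5$rsid %in% missing, , drop = FALSE],
      sub
    )
    inform(sprintf(
      "proxy search: %d missing instrument(s), %d substituted, %d dropped",
      length(missing), nrow(sub), length(missing) - nrow(sub)))
  }
  att[[5]] <- stage("proxy_substitution", nrow(s4), nrow(s5))
  s5$missing_in_outcome <- NULL

  strength <- instrument_strength(s5)
  list(instruments = s5,
       attrition = dplyr::bind_rows(att),
       strength = strength)
}
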