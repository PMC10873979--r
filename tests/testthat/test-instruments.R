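test_that("genome-wide filter uses a strict inequality at 5e-8", {
  stats <- dplyr::bind_rows(
    snp_row("rs1", "A", "G", 0.1, 0.3),
    snp_row("rs2", "A", "G", 0.1, 0.3),
    snp_row("rs3", "A", "G", 0.1, 0.3))
  stats$pvalue <- c(4e-8, 5e-8, 6e-8)
  kept <- filter_genome_wide(stats)
  expect_equal(kept$rsid, "rs1")
  expect_equal(nrow(filter_genome_wide(stats[0, ])), 0)
  stats$pvalue <- rep(1e-10, 3)
  expect_equal(nrow(filter_genome_wide(stats)), 3)
})

two_snp_ld <- function(r2, pos = c(1000, 2000), chrom = c("1", "1")) {
  new_ld_reference(
    tibble::tibble(rsid_a = "rs1", rsid_b = "rs2", r2 = r2),
    tibble::tibble(rsid = c("rs1", "rs2"), chrom = chrom, pos = pos))
}

test_that("clumping keeps the lowest-p SNP of a linked pair", {
  stats <- dplyr::bind_rows(
    snp_row("rs1", "A", "G", 0.1, 0.3, pos = 1000),
    snp_row("rs2", "A", "G", 0.1, 0.3, pos = 2000))
  stats$pvalue <- c(1e-20, 1e-9)
  kept <- clump(stats, two_snp_ld(0.9))
  expect_equal(kept$rsid, "rs1")
  # reversed p order keeps the other SNP
  stats$pvalue <- c(1e-9, 1e-20)
  expect_equal(clump(stats, two_snp_ld(0.9))$rsid, "rs2")
  # r2 exactly at the threshold is independent (strict >)
  stats$pvalue <- c(1e-20, 1e-9)
  expect_equal(nrow(clump(stats, two_snp_ld(0.001))), 2)
  # different chromosomes: both retained even at high r2
  ld_x <- new_ld_reference(
    tibble::tibble(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.9),
    tibble::tibble(rsid = c("rs1", "rs2"), chrom = c("1", "2"),
                   pos = c(1000, 2000)))
  expect_equal(nrow(clump(stats, ld_x)), 2)
  # SNP missing from the reference is treated as unlinked, with a warning
  ld_missing <- new_ld_reference(
    tibble::tibble(rsid_a = character(), rsid_b = character(), r2 = double()),
    tibble::tibble(rsid = "rs1", chrom = "1", pos = 1000L))
  expect_warning(out <- clump(stats, ld_missing), "unlinked")
  expect_equal(nrow(out), 2)
})

test_that("greedy clumping matches the brute-force oracle on small panels", {
  for (seed in 1:12) {
    n <- 6
    sim <- withr::with_seed(seed, {
      r2mat <- matrix(runif(n * n), n)
      r2mat <- (r2mat + t(r2mat)) / 2
      diag(r2mat) <- 1
      r2mat[r2mat < 0.3] <- 0  # sparsify
      pos <- sort(sample.int(5e6, n))
      list(r2mat = r2mat, pos = pos, p = runif(n, 1e-30, 1e-8))
    })
    rsid <- sprintf("rs%d", 1:n)
    stats <- dplyr::bind_rows(purrr::map(1:n, function(i)
      snp_row(rsid[i], "A", "G", 0.1, 0.3, pos = sim$pos[i])))
    stats$pvalue <- sim$p
    pairs <- do.call(rbind, purrr::map(1:(n - 1), function(i) {
      do.call(rbind, purrr::map((i + 1):n, function(j) {
        if (sim$r2mat[i, j] > 0)
          data.frame(rsid_a = rsid[i], rsid_b = rsid[j],
                     r2 = sim$r2mat[i, j])
      }))
    }))
    ld <- new_ld_reference(pairs,
      tibble::tibble(rsid = rsid, chrom = "1", pos = sim$pos))
    kept <- clump(stats, ld, r2_threshold = 0.3, window_kb = 2000)
    oracle <- greedy_clump_oracle(sim$p, sim$r2mat, sim$pos,
                                  2000 * 1000, 0.3)
    expect_setequal(kept$rsid, rsid[oracle])
  }
})

test_that("clumped output never contains a linked within-window pair", {
  sim <- quick_sim(21, n_snps = 120, n_instruments = 20)
  ex <- sim$exposures[[1]]
  kept <- clump(ex, sim$ld)
  if (nrow(kept) >= 2) {
    cmb <- utils::combn(seq_len(nrow(kept)), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      if (abs(kept$pos[i] - kept$pos[j]) <= 1e7) {
        expect_lte(ld_lookup(sim$ld, kept$rsid[i], kept$rsid[j]), 0.001)
      }
    }
  }
})

test_that("confounder exclusion removes exactly the annotated SNPs", {
  instr <- dplyr::bind_rows(
    snp_row("rs1", "A", "G", 0.1, 0.3),
    snp_row("rs2", "A", "G", 0.1, 0.3),
    snp_row("rs3", "A", "G", 0.1, 0.3))
  ann <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    trait = c("smoking", "height", "smoking"),
    pvalue = c(1e-12, 1e-12, 1e-5))
  expect_message(
    out <- exclude_confounder_snps(instr, ann, "smoking"),
    "smoking")
  # rs2 annotated to an unlisted trait; rs3 below-threshold association
  expect_setequal(out$rsid, c("rs2", "rs3"))
  # empty annotation table: identity
  empty <- ann[0, ]
  expect_equal(exclude_confounder_snps(instr, empty, "smoking")$rsid,
               instr$rsid)
})

test_that("planted confounder annotations are excluded exactly", {
  sim <- quick_sim(31, n_snps = 80, n_instruments = 20,
                   confounder_indices = c(1L, 9L, 17L))
  instr <- sim$exposures[[1]][sim$truth$instrument_snps, ]
  out <- exclude_confounder_snps(
    instr, sim$annotation, c("smoking", "chronic pain", "depression"))
  planted <- sprintf("rs%06d", c(1L, 9L, 17L))
  expect_setequal(setdiff(instr$rsid, out$rsid), planted)
})

test_that("outcome-associated instruments are removed; missing ones flagged", {
  instr <- dplyr::bind_rows(
    snp_row("rs1", "A", "G", 0.1, 0.3),
    snp_row("rs2", "A", "G", 0.1, 0.3),
    snp_row("rs3", "A", "G", 0.1, 0.3))
  outcome <- dplyr::bind_rows(
    snp_row("rs1", "A", "G", 0.2, 0.3),
    snp_row("rs2", "A", "G", 0.01, 0.3))
  outcome$pvalue <- c(1e-9, 0.3)
  out <- exclude_outcome_associated(instr, outcome)
  expect_setequal(out$rsid, c("rs2", "rs3"))
  expect_equal(out$missing_in_outcome[out$rsid == "rs3"], TRUE)
  expect_equal(out$missing_in_outcome[out$rsid == "rs2"], FALSE)
})

test_that("proxy search takes the best-r2 candidate above the strict cutoff", {
  ld <- new_ld_reference(
    tibble::tibble(rsid_a = c("rsM", "rsM", "rsM"),
                   rsid_b = c("rsA", "rsB", "rsC"),
                   r2 = c(0.95, 0.85, 0.99)),
    tibble::tibble(rsid = c("rsM", "rsA", "rsB", "rsC"),
                   chrom = "1", pos = c(1000L, 2000L, 3000L, 4000L)))
  outcome <- dplyr::bind_rows(
    snp_row("rsA", "A", "G", 0.1, 0.3),
    snp_row("rsB", "A", "G", 0.1, 0.3))
  # rsC not in the outcome; best available is rsA at 0.95
  got <- find_proxies("rsM", ld, outcome)
  expect_equal(got$proxy, "rsA")
  expect_equal(got$r2, 0.95)
  # boundary: r2 exactly 0.8 does not qualify
  ld2 <- new_ld_reference(
    tibble::tibble(rsid_a = "rsM", rsid_b = "rsA", r2 = 0.8),
    ld$positions)
  expect_true(is.na(find_proxies("rsM", ld2, outcome)$proxy))
  # no candidates at all
  expect_true(is.na(find_proxies("rsZ", ld, outcome)$proxy))
})

test_that("proxy ties break by genomic distance then rsid", {
  pos <- tibble::tibble(rsid = c("rsM", "rsFar", "rsNear"),
                        chrom = "1", pos = c(1000L, 90000L, 2000L))
  ld <- new_ld_reference(
    tibble::tibble(rsid_a = c("rsM", "rsM"), rsid_b = c("rsFar", "rsNear"),
                   r2 = c(0.9, 0.9)),
    pos)
  outcome <- dplyr::bind_rows(
    snp_row("rsFar", "A", "G", 0.1, 0.3),
    snp_row("rsNear", "A", "G", 0.1, 0.3))
  expect_equal(find_proxies("rsM", ld, outcome)$proxy, "rsNear")
  # equal distance: lexicographic
  pos2 <- tibble::tibble(rsid = c("rsM", "rsB", "rsA"),
                         chrom = "1", pos = c(1000L, 2000L, 2000L))
  ld2 <- new_ld_reference(
    tibble::tibble(rsid_a = c("rsM", "rsM"), rsid_b = c("rsB", "rsA"),
                   r2 = c(0.9, 0.9)), pos2)
  outcome2 <- dplyr::bind_rows(
    snp_row("rsA", "A", "G", 0.1, 0.3),
    snp_row("rsB", "A", "G", 0.1, 0.3))
  expect_equal(find_proxies("rsM", ld2, outcome2)$proxy, "rsA")
})

test_that("instrument strength follows the standardized-trait formulas", {
  instr <- snp_row("rs1", "A", "G", beta = 0.1, eaf = 0.3)
  got <- instrument_strength(instr, n = 100000)
  expect_equal(got$r2, 2 * 0.3 * 0.7 * 0.01)
  expect_equal(got$F, 0.0042 * 99998 / (1 - 0.0042), tolerance = 1e-10)
  expect_equal(round(got$F, 2), 421.76)
  expect_false(got$weak)

  # beta = 0 gives zero explained variance and F
  zero <- instrument_strength(snp_row("rs1", "A", "G", 0, 0.3), n = 1000)
  expect_equal(zero$r2, 0)
  expect_equal(zero$F, 0)

  # weak-instrument flag at F <= 10
  weak <- instrument_strength(snp_row("rs1", "A", "G", 0.1, 0.5), n = 1000)
  expect_equal(weak$r2, 0.005)
  expect_equal(weak$F, 0.005 * 998 / 0.995, tolerance = 1e-10)
  expect_true(weak$weak)

  # missing eaf: flagged and excluded from the summary; se fallback option
  two <- dplyr::bind_rows(snp_row("rs1", "A", "G", 0.1, 0.3),
                          snp_row("rs2", "A", "G", 0.1, NA_real_))
  expect_message(got2 <- instrument_strength(two, n = 100000), "lack eaf")
  expect_true(is.na(got2$F[2]))
  expect_equal(attr(got2, "summary")$n_missing_eaf, 1)
  got3 <- instrument_strength(two, n = 100000, use_se_fallback = TRUE)
  f_expected <- (0.1 / 0.01)^2
  expect_equal(got3$F[2], f_expected, tolerance = 1e-10)
  expect_error(instrument_strength(two, n = 2),
               class = "tidymr_invalid_argument")
})

test_that("the full selection pipeline records attrition at every stage", {
  sim <- quick_sim(41, n_snps = 200, n_instruments = 30,
                   confounder_indices = c(1L, 5L))
  sel <- select_instruments(sim$exposures[[1]], sim$outcome, sim$ld,
                            sim$annotation,
                            confounder_traits = c("smoking", "chronic pain",
                                                  "depression"))
  att <- sel$attrition
  expect_equal(att$stage,
               c("genome_wide_filter", "ld_clumping", "confounder_exclusion",
                 "outcome_association_exclusion", "proxy_substitution"))
  # conservation: each stage's input equals the previous stage's output
  expect_equal(att$n_in[-1], att$n_out[-length(att$n_out)])
  expect_equal(att$n_removed, att$n_in - att$n_out)
  expect_equal(nrow(sel$instruments), att$n_out[length(att$n_out)])
  expect_true(all(sel$instruments$pvalue < 5e-8))
})
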