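#' Construct a pairwise LD reference
#'
#' @param pairs Tibble with columns `rsid_a`, `rsid_b`, `r2` (each unordered
#'   pair stored once; lookups are symmetric; `r2(x, x)` is implicitly 1).
#' @param positions Tibble with columns `rsid`, `chrom`, `pos`.
#' @return An object of class `ld_reference`.
#' @export
new_ld_reference <- function(pairs, positions) {
  pairs <- tibble::as_tibble(pairs)
  positions <- tibble::as_tibble(positions)
  stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(pairs)),
            all(c("rsid", "chrom", "pos") %in% names(positions)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) {
    abort("r2 values must lie in [0, 1]", class = "tidymr_invalid_argument")
  }
  structure(list(pairs = pairs, positions = positions),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d SNPs, %d stored pairs\n",
              nrow(x$positions), nrow(x$pairs)))
  invisible(x)
}

# Symmetric r^2 lookup for one rsid against a vector of rsids.
# Unstored pairs are 0; identity is 1.
ld_lookup <- function(ld, rsid, others) {
  r2 <- numeric(length(others))
  hits_a <- ld$pairs[ld$pairs$rsid_a == rsid, ]
  hits_b <- ld$pairs[ld$pairs$rsid_b == rsid, ]
  lut <- c(stats::setNames(hits_a$r2, hits_a$rsid_b),
           stats::setNames(hits_b$r2, hits_b$rsid_a))
  found <- others %in% names(lut)
  r2[found] <- lut[others[found]]
  r2[others == rsid] <- 1
  r2
}

summary_stat_cols <- c("rsid", "chrom", "pos", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pvalue", "n")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-separated table with a header into the canonical summary-stat
#' tibble (columns `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pvalue`, `n`). Foreign headers (e.g. FinnGen-style
#' names) are supported through `column_map`. Rows failing validation
#' (non-positive SE, identical or non-ACGT alleles, i.e. indels and
#' multi-allelic records) are dropped with an informative message.
#'
#' @param path File to read.
#' @param column_map Named character vector mapping canonical column names
#'   to the file's column names, e.g. `c(rsid = "SNP", beta = "Effect")`.
#'   Unmapped canonical names are looked up verbatim.
#' @param trait_id,trait_type Trait label and type (`"continuous"` or
#'   `"binary"`) attached as columns.
#' @param p_consistency_tol Warn when `pvalue` disagrees with the two-sided
#'   normal test of `beta/se` by more than this on the log10 scale.
#' @return A summary-stat tibble.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_id = "trait",
                               trait_type = c("continuous", "binary"),
                               p_consistency_tol = 0.5) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tidymr_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    abort(paste0("empty file: ", path), class = "tidymr_format_error")
  }
  mandatory <- setdiff(summary_stat_cols, "eaf")
  resolved <- purrr::map_chr(summary_stat_cols, function(cn) {
    if (!is.null(column_map) && cn %in% names(column_map)) column_map[[cn]]
    else cn
  })
  names(resolved) <- summary_stat_cols
  missing <- resolved[mandatory][!resolved[mandatory] %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tidymr_format_error")
  }
  out <- tibble::tibble(
    rsid = as.character(raw[[resolved["rsid"]]]),
    chrom = as.character(raw[[resolved["chrom"]]]),
    pos = as.integer(raw[[resolved["pos"]]]),
    effect_allele = toupper(as.character(raw[[resolved["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[resolved["other_allele"]]])),
    eaf = if (resolved["eaf"] %in% names(raw))
      suppressWarnings(as.numeric(raw[[resolved["eaf"]]])) else NA_real_,
    beta = as.numeric(raw[[resolved["beta"]]]),
    se = as.numeric(raw[[resolved["se"]]]),
    pvalue = as.numeric(raw[[resolved["pvalue"]]]),
    n = as.numeric(raw[[resolved["n"]]]),
    trait_id = trait_id,
    trait_type = trait_type
  )
  validate_summary_stats(out, p_consistency_tol = p_consistency_tol)
}

#' Validate a summary-stat tibble, dropping malformed rows
#'
#' Enforces: unique rsids, strictly positive SEs, single-base A/C/G/T
#' alleles with `effect_allele != other_allele`, `pvalue` in (0, 1]. Rows
#' violating these are dropped and counted in a message. When `pvalue` and
#' `beta/se` are both present but disagree with the two-sided normal test,
#' a warning (not a rejection) is raised.
#'
#' @param stats Summary-stat tibble.
#' @param p_consistency_tol Tolerance on the log10 p-value scale.
#' @return The validated tibble.
#' @export
validate_summary_stats <- function(stats, p_consistency_tol = 0.5) {
  bases <- c("A", "C", "G", "T")
  ok <- !is.na(stats$rsid) & !is.na(stats$beta) & !is.na(stats$se) &
    stats$se > 0 &
    stats$effect_allele %in% bases & stats$other_allele %in% bases &
    stats$effect_allele != stats$other_allele &
    !is.na(stats$pvalue) & stats$pvalue > 0 & stats$pvalue <= 1
  ok[is.na(ok)] <- FALSE
  dropped <- sum(!ok)
  if (dropped > 0) {
    inform(sprintf("dropped %d invalid row(s) during validation", dropped))
  }
  out <- stats[ok, , drop = FALSE]
  dup <- duplicated(out$rsid)
  if (any(dup)) {
    inform(sprintf("dropped %d duplicate rsid row(s)", sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  both <- !is.na(out$pvalue) & !is.na(out$beta) & !is.na(out$se)
  if (any(both)) {
    expected <- two_sided_p(out$beta[both] / out$se[both])
    off <- abs(log10(out$pvalue[both]) - log10(expected)) > p_consistency_tol
    if (any(off)) {
      warn(sprintf(
        "%d row(s) have p-values inconsistent with beta/se (normal test)",
        sum(off)))
    }
  }
  out
}

#' Write GWAS summary statistics as tab-separated text
#'
#' Round-trip contract: `read_summary_stats(write_summary_stats(x))` equals
#' `x` field for field. Missing EAF is serialized as `NA`.
#'
#' @param stats Summary-stat tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  readr::write_tsv(stats[, intersect(summary_stat_cols, names(stats))], path,
                   progress = FALSE)
  invisible(path)
}

#' Read or write an LD reference as two TSV tables
#'
#' @param pairs_path TSV with columns `rsid_a`, `rsid_b`, `r2`.
#' @param positions_path TSV with columns `rsid`, `chrom`, `pos`.
#' @return `read_ld_reference()` returns an `ld_reference`;
#'   `write_ld_reference()` returns the paths invisibly.
#' @export
read_ld_reference <- function(pairs_path, positions_path) {
  pairs <- readr::read_tsv(pairs_path, col_types = "ccd", progress = FALSE)
  positions <- readr::read_tsv(positions_path, col_types = "cci",
                               progress = FALSE)
  new_ld_reference(pairs, positions)
}

#' @rdname read_ld_reference
#' @param ld An `ld_reference`.
#' @export
write_ld_reference <- function(ld, pairs_path, positions_path) {
  readr::write_tsv(ld$pairs, pairs_path, progress = FALSE)
  readr::write_tsv(ld$positions, positions_path, progress = FALSE)
  invisible(c(pairs_path, positions_path))
}

#' Read or write a SNP-trait annotation table
#'
#' A local stand-in for a PhenoScanner-style lookup: one row per
#' (SNP, trait) association with its p-value.
#'
#' @param path TSV with columns `rsid`, `trait`, `pvalue`.
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  if (any(out$pvalue <= 0 | out$pvalue > 1)) {
    abort("annotation p-values must lie in (0, 1]",
          class = "tidymr_format_error")
  }
  out
}

#' @rdname read_annotation
#' @param annotation Annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path, progress = FALSE)
  invisible(path)
}

#' Write or read generator ground truth as a JSON sidecar
#'
#' @param truth An `mr_truth` object from [simulate_study()].
#' @param path JSON path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   restored `mr_truth`.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$gamma <- as.data.frame(x$gamma)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$gamma <- as.matrix(x$gamma)
  dimnames(x$gamma) <- NULL
  x$instrument_snps <- as.integer(x$instrument_snps)
  x$invalid_snps <- as.integer(x$invalid_snps)
  x$outlier_snps <- as.integer(x$outlier_snps)
  structure(x, class = "mr_truth")
}
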