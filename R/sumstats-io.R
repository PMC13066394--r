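# Reading, validating and writing GWAS summary statistics.

#' Default column map for common summary-statistics headers
#'
#' Maps the semantic fields used throughout the package to the column names
#' most frequently seen in distributed GWAS summary statistics
#' (SNP/CHR/BP/A1/A2/FRQ/BETA/SE/P/N).
#'
#' @return Named character vector, semantic field -> column name.
#' @export
default_column_map <- function() {
  c(
    variant_id    = "SNP",
    chrom         = "CHR",
    pos           = "BP",
    effect_allele = "A1",
    other_allele  = "A2",
    eaf           = "FRQ",
    beta          = "BETA",
    se            = "SE",
    pvalue        = "P",
    n             = "N"
  )
}

# Fields that must be present in every usable table.
.mandatory_fields <- c("variant_id", "effect_allele", "other_allele",
                       "beta", "se", "pvalue")

#' Effective sample size of a case-control GWAS
#'
#' The standard binary-trait convention `Neff = 4 / (1/Ncases + 1/Ncontrols)`,
#' which reduces to the total sample size when cases and controls are
#' balanced. Used by the sample-size reporting filter
#' (`Neff >= 100000` or `Ncases >= 10000`).
#'
#' @param n_cases,n_controls Positive case and control counts.
#' @return Effective sample size (numeric scalar).
#' @examples
#' effective_sample_size(50000, 50000) # 100000
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  if (!is.numeric(n_cases) || !is.numeric(n_controls) ||
      any(n_cases <= 0) || any(n_controls <= 0)) {
    stop("effective_sample_size: n_cases and n_controls must be positive",
         call. = FALSE)
  }
  4 / (1 / n_cases + 1 / n_controls)
}

#' Construct a GWAS summary object
#'
#' Bundles a per-variant summary-statistics table with trait metadata. The
#' variant table is validated row-wise; rows violating the per-variant
#' invariants (positive SE, distinct alleles, p-value in (0, 1], position
#' >= 1) are dropped with a message. A p-value inconsistent with
#' `2 * pnorm(-|beta/se|)` only triggers a warning, since many published
#' tables carry truncated or re-computed p-values.
#'
#' @param variants `data.frame` with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`, and optionally `chrom`, `pos`,
#'   `eaf`, `n`.
#' @param trait_name Trait label.
#' @param is_binary Is the trait binary (case/control)?
#' @param n_cases,n_controls Case/control counts (binary traits).
#' @param n_total Total sample size; defaults to `n_cases + n_controls` for
#'   binary traits.
#' @param phecode Optional phecode label.
#' @param unit Optional free-text unit string (carried, never harmonized).
#' @param dedup One of `"keep_first"` (default; duplicated variant ids keep
#'   the first row with a warning) or `"error"`.
#' @return An object of class `gwas_summary`.
#' @export
gwas_summary <- function(variants, trait_name, is_binary = TRUE,
                         n_cases = NA_integer_, n_controls = NA_integer_,
                         n_total = NA_integer_, phecode = NA_character_,
                         unit = NA_character_, dedup = c("keep_first", "error")) {
  dedup <- match.arg(dedup)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)

  missing_cols <- setdiff(.mandatory_fields, names(variants))
  if (length(missing_cols) > 0) {
    stop("gwas_summary: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (opt in c("chrom", "pos", "eaf", "n")) {
    if (!opt %in% names(variants)) variants[[opt]] <- NA
  }

  variants$effect_allele <- toupper(as.character(variants$effect_allele))
  variants$other_allele  <- toupper(as.character(variants$other_allele))
  variants$variant_id    <- as.character(variants$variant_id)
  variants$chrom         <- as.character(variants$chrom)
  for (num in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    variants[[num]] <- suppressWarnings(as.numeric(variants[[num]]))
  }

  ok <- is.finite(variants$beta) &
    is.finite(variants$se) & variants$se > 0 &
    is.finite(variants$pvalue) & variants$pvalue > 0 & variants$pvalue <= 1 &
    nzchar(variants$effect_allele) & nzchar(variants$other_allele) &
    variants$effect_allele != variants$other_allele &
    (is.na(variants$pos) | variants$pos >= 1) &
    (is.na(variants$eaf) | (variants$eaf > 0 & variants$eaf < 1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message("gwas_summary: dropped ", n_dropped,
            " row(s) failing per-variant invariants")
    variants <- variants[ok, , drop = FALSE]
  }
  if (nrow(variants) == 0) {
    stop("gwas_summary: zero valid variant rows", call. = FALSE)
  }

  dup <- duplicated(variants$variant_id)
  if (any(dup)) {
    if (dedup == "error") {
      stop("gwas_summary: duplicated variant_id(s): ",
           paste(unique(variants$variant_id[dup]), collapse = ", "),
           call. = FALSE)
    }
    warning("gwas_summary: ", sum(dup),
            " duplicated variant_id row(s) dropped (keep-first)",
            call. = FALSE)
    variants <- variants[!dup, , drop = FALSE]
  }

  # Warn (never error) on p-values that disagree with the normal approximation.
  z <- abs(variants$beta / variants$se)
  p_expect <- 2 * stats::pnorm(-z)
  incons <- abs(log10(pmax(variants$pvalue, 1e-300)) -
                  log10(pmax(p_expect, 1e-300))) > 1
  if (any(incons, na.rm = TRUE)) {
    warning("gwas_summary: ", sum(incons, na.rm = TRUE),
            " p-value(s) inconsistent with |beta/se| under the normal ",
            "approximation", call. = FALSE)
  }

  rownames(variants) <- NULL
  is_binary <- isTRUE(is_binary)
  if (is_binary && is.na(n_total) && !is.na(n_cases) && !is.na(n_controls)) {
    n_total <- n_cases + n_controls
  }
  if (is_binary && !is.na(n_cases) && !is.na(n_controls) && !is.na(n_total) &&
      n_cases + n_controls != n_total) {
    stop("gwas_summary: n_cases + n_controls must equal n_total", call. = FALSE)
  }
  effective_n <- if (is_binary && !is.na(n_cases) && !is.na(n_controls)) {
    effective_sample_size(n_cases, n_controls)
  } else {
    as.numeric(n_total)
  }

  structure(
    list(
      trait_name  = as.character(trait_name),
      phecode     = phecode,
      unit        = unit,
      is_binary   = is_binary,
      n_cases     = as.integer(n_cases),
      n_controls  = as.integer(n_controls),
      n_total     = as.integer(n_total),
      effective_n = effective_n,
      variants    = variants,
      n_dropped   = n_dropped
    ),
    class = "gwas_summary"
  )
}

#' @export
print.gwas_summary <- function(x, ...) {
  cat("GWAS summary: ", x$trait_name,
      if (!is.na(x$phecode)) paste0(" (phecode ", x$phecode, ")"), "\n",
      sep = "")
  cat("  ", if (x$is_binary) "binary" else "continuous",
      " trait; n_total = ", x$n_total,
      if (x$is_binary) paste0(" (", x$n_cases, " cases / ",
                              x$n_controls, " controls)"),
      "; effective n = ", format(round(x$effective_n, 1)), "\n", sep = "")
  cat("  ", nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text table (tab or comma, autodetected by
#' [data.table::fread]), renames columns through `column_map`, and validates
#' it into a [gwas_summary]. Invalid rows are dropped with a logged count;
#' row order is preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping semantic fields
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to column names in the file. Defaults to
#'   [default_column_map()].
#' @param trait_meta Named list of trait metadata forwarded to
#'   [gwas_summary()] (`trait_name`, `is_binary`, `n_cases`, `n_controls`,
#'   `n_total`, `phecode`, `unit`). `trait_name` defaults to the file name.
#' @param dedup Duplicate-id policy, see [gwas_summary()].
#' @return A `gwas_summary`.
#' @export
read_gwas_table <- function(path, column_map = default_column_map(),
                            trait_meta = list(),
                            dedup = c("keep_first", "error")) {
  dedup <- match.arg(dedup)
  if (!file.exists(path)) {
    stop("read_gwas_table: file not found: ", path, call. = FALSE)
  }
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)

  need <- column_map[.mandatory_fields]
  absent <- .mandatory_fields[is.na(need) | !(need %in% names(tab))]
  if (length(absent) > 0) {
    stop("read_gwas_table: column_map does not resolve mandatory field(s) ",
         paste(absent, collapse = ", "), " in ", path, call. = FALSE)
  }
  present <- column_map[column_map %in% names(tab)]
  variants <- tab[, unname(present), drop = FALSE]
  names(variants) <- names(present)

  meta <- utils::modifyList(
    list(trait_name = basename(path), is_binary = TRUE),
    trait_meta
  )
  do.call(gwas_summary, c(list(variants = variants, dedup = dedup), meta))
}

#' Write a GWAS summary table
#'
#' Inverse of [read_gwas_table] using the same column map; full numeric
#' precision is preserved.
#'
#' @param gwas A `gwas_summary`.
#' @param path Output file path (tab-separated).
#' @param column_map Semantic field -> column name map.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(gwas, path, column_map = default_column_map()) {
  stopifnot(inherits(gwas, "gwas_summary"))
  out <- gwas$variants
  keep <- names(column_map)[names(column_map) %in% names(out)]
  out <- out[, keep, drop = FALSE]
  names(out) <- unname(column_map[keep])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

# Flatten one test evaluation into a single-row data.frame for the TSV report.
.flatten_evaluation <- function(ev) {
  num <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)
  est_cols <- function(est, prefix) {
    fields <- c("beta", "se", "ci_low", "ci_high", "pvalue",
                "or_", "or_low", "or_high")
    vals <- if (is.null(est)) {
      rep(NA_real_, length(fields))
    } else {
      vapply(fields, function(f) num(est[[f]]), numeric(1))
    }
    stats::setNames(as.list(vals), paste0(prefix, "_", sub("_$", "", fields)))
  }
  row <- c(
    list(
      exposure_name = ev$exposure_name,
      outcome_name  = ev$outcome_name,
      n_variable    = as.integer(ev$n_variable),
      mean_f        = num(ev$mean_f)
    ),
    est_cols(ev$ivw, "ivw"),
    list(fdr_q = num(ev$fdr_q)),
    est_cols(ev$egger_slope, "egger"),
    list(egger_intercept = num(ev$egger_intercept$beta),
         egger_intercept_p = num(ev$egger_intercept_p)),
    est_cols(ev$wm, "wm"),
    list(
      het_q        = num(ev$heterogeneity$q_stat),
      het_df       = num(ev$heterogeneity$df),
      het_p        = num(ev$heterogeneity$pvalue),
      loo_p_max    = num(ev$loo$p_max),
      presso_global_p   = num(ev$presso$global_pvalue),
      presso_n_outliers = if (is.null(ev$presso)) NA_integer_ else
        length(ev$presso$outlier_ids),
      presso_corrected_beta = num(ev$presso$corrected_estimate$beta),
      presso_corrected_p    = num(ev$presso$corrected_estimate$pvalue),
      steiger_n_removed = if (is.null(ev$steiger)) NA_integer_ else
        sum(!ev$steiger$per_variant$direction_ok),
      steiger_filtered_beta = num(ev$steiger$filtered_estimate$beta),
      steiger_filtered_p    = num(ev$steiger$filtered_estimate$pvalue),
      horse_theta_mean = num(ev$horse$theta_posterior_mean),
      horse_ci_low     = num(ev$horse$theta_ci_low),
      horse_ci_high    = num(ev$horse$theta_ci_high),
      horse_rhat       = num(ev$horse$rhat),
      tier   = ev$tier,
      robust = isTRUE(ev$robust)
    )
  )
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Write test-evaluation results as TSV plus JSON mirror
#'
#' One TSV row per directed exposure-outcome test carrying every estimate and
#' diagnostic plus the tier label; estimator columns not computed for a test
#' (for instance under the "Insufficient instrumental variables" tier) are
#' written as explicit `NA` markers, never zeros. A JSON mirror of the full
#' nested evaluations is written alongside at full numeric precision, so
#' `read_results()` round-trips every numeric field exactly.
#'
#' @param evaluations Non-empty list of `test_evaluation` objects (see
#'   [run_direction]).
#' @param path Output TSV path; the JSON mirror replaces the extension with
#'   `.json`.
#' @return Invisibly, a list with the `tsv` and `json` paths.
#' @export
write_results <- function(evaluations, path) {
  if (length(evaluations) == 0) {
    stop("write_results: evaluations must be non-empty", call. = FALSE)
  }
  if (inherits(evaluations, "test_evaluation")) evaluations <- list(evaluations)
  rows <- do.call(rbind, lapply(evaluations, .flatten_evaluation))
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE, na = "NA")
  json_path <- sub("\\.[^.]+$", "", path)
  json_path <- paste0(json_path, ".json")
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  stripped <- lapply(evaluations, function(ev) {
    ev$instruments <- NULL
    strip(ev)
  })
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(stripped, json_path, auto_unbox = TRUE,
                       digits = I(17), na = "null", null = "null")
  invisible(list(tsv = path, json = json_path))
}

#' Read back a results JSON mirror
#'
#' @param json_path Path written by [write_results].
#' @return List of evaluation records (plain lists).
#' @export
read_results <- function(json_path) {
  jsonlite::read_json(json_path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}
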