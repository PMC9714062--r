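#' Map an examination date to a study season
#'
#' The study enrolled over four consecutive three-month seasons:
#' Jul-Sep 2020 (season 1), Oct-Dec 2020 (2), Jan-Mar 2021 (3),
#' Apr-Jun 2021 (4). Dates inside that span map accordingly; dates
#' outside it fall back to the calendar quarter (Jan-Mar = 1, ...) with
#' a warning, so the stratification generalises to other cohorts.
#'
#' @param date A `Date` vector or character parseable by [as.Date()].
#' @return Integer vector of season labels 1..4.
#' @export
#' @examples
#' season_of(c("2020-07-01", "2021-06-30"))
season_of <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (any(is.na(d)))
    stop("unparseable date(s): ",
         paste(utils::head(date[is.na(d)], 5L), collapse = ", "))
  span_start <- as.Date("2020-07-01")
  span_end <- as.Date("2021-06-30")
  in_span <- d >= span_start & d <= span_end
  out <- integer(length(d))
  if (any(in_span)) {
    months_since <- (as.integer(format(d[in_span], "%Y")) - 2020L) * 12L +
      as.integer(format(d[in_span], "%m")) - 7L
    out[in_span] <- months_since %/% 3L + 1L
  }
  if (any(!in_span)) {
    warning("date(s) outside the Jul 2020 - Jun 2021 study span; ",
            "using calendar quarters")
    out[!in_span] <- (as.integer(format(d[!in_span], "%m")) - 1L) %/% 3L + 1L
  }
  out
}

#' Run the full sizing and validation pipeline
#'
#' Per eye: predict the vault (at the implanted size if an `icl_size_mm`
#' column is present, otherwise at the size chosen by
#' [select_icl_size()]), and — when achieved vaults are available —
#' classify the vault, compute the prediction error and assign the error
#' group. Then assembles the four report tables: per-stratum vault
#' summaries, the vault-category distribution, Bland-Altman agreement per
#' stratum and overall, and the UBM feature comparison between the
#' large-error groups. Deterministic given the input and configuration.
#'
#' Without an `actual_vault_um` column the run degrades gracefully to a
#' sizing-only report: the agreement, distribution and feature tables are
#' `NULL` and the metadata flags the mode.
#'
#' @param input A cohort data.frame, a path to a cohort CSV, or a
#'   [cohort_spec()] (which is simulated first).
#' @param window [target_window()].
#' @param coeffs [model_coefficients()].
#' @param stratum_key Column to stratify by (default `"season"`); use
#'   `NULL` for pooled-only reporting. A missing stratum column degrades
#'   to pooled-only with a message in the metadata.
#' @param apply_feature_adjustment Passed to [select_icl_size()].
#' @return An object of class `validation_report`: a list with `eyes`
#'   (the augmented per-eye table), `summary`, `distribution`,
#'   `agreement`, `features`, and `metadata`.
#' @export
#' @examples
#' rep <- run_validation(cohort_spec(n_eyes = 200, seed = 11))
#' rep$agreement
run_validation <- function(input, window = target_window(),
                           coeffs = model_coefficients(),
                           stratum_key = "season",
                           apply_feature_adjustment = FALSE) {
  if (inherits(input, "cohort_spec")) {
    eyes <- generate_cohort(input)
  } else if (is.character(input) && length(input) == 1L) {
    eyes <- read_cohort(input)
  } else if (is.data.frame(input)) {
    eyes <- input
    validate_biometry(eyes)
  } else stop("input must be a data.frame, a file path, or a cohort_spec")

  sizing <- select_icl_size(eyes, window, coeffs, apply_feature_adjustment)
  eyes <- cbind(eyes[setdiff(names(eyes), names(sizing))], sizing)
  if ("icl_size_mm" %in% names(eyes)) {
    eyes$predicted_vault <- predict_vault(eyes, eyes$icl_size_mm, coeffs)
  } else {
    eyes$icl_size_mm <- eyes$selected_size_mm
    eyes$predicted_vault <- eyes$selected_pred_um
  }

  if (!is.null(stratum_key) && !stratum_key %in% names(eyes))
    stratum_key <- NULL

  has_actual <- "actual_vault_um" %in% names(eyes)
  if (has_actual) {
    eyes$actual_vault <- eyes$actual_vault_um
    eyes$category <- classify_vault(eyes$actual_vault)
    eyes$error <- eyes$actual_vault - eyes$predicted_vault
    eyes$error_group <- assign_error_group(eyes$error)
    summary_tab <- summarize_vaults(eyes, stratum_key)
    dist_tab <- distribution_table(eyes, stratum_key)
    agree_tab <- agreement_table(eyes, stratum_key)
    feat_tab <- tryCatch(compare_features(eyes), error = function(e) NULL)
  } else {
    summary_tab <- dist_tab <- agree_tab <- feat_tab <- NULL
  }

  structure(list(
    eyes = eyes,
    summary = summary_tab,
    distribution = dist_tab,
    agreement = agree_tab,
    features = feat_tab,
    metadata = list(
      n_eyes = nrow(eyes),
      mode = if (has_actual) "validation" else "sizing-only",
      stratum_key = stratum_key,
      window = unclass(window),
      coefficients = unclass(coeffs),
      n_not_in_window = sum(!eyes$in_window),
      package_version = as.character(utils::packageVersion("iclvault")),
      note = paste("eyes within subject treated as independent;",
                   "no clustering adjustment"))
  ), class = "validation_report")
}

# flatten bland_altman per stratum plus overall into one data.frame
agreement_table <- function(eyes, stratum_key = "season") {
  groups <- if (is.null(stratum_key)) list() else
    split(eyes, eyes[[stratum_key]])
  groups <- c(groups, list(overall = eyes))
  rows <- lapply(names(groups), function(g) {
    if (nrow(groups[[g]]) < 2L) {
      # a singleton stratum has no spread to summarize
      return(data.frame(stratum = g, n = nrow(groups[[g]]), mean_diff = NA_real_,
                        sd_diff = NA_real_, min_diff = NA_real_,
                        max_diff = NA_real_, q25 = NA_real_, q75 = NA_real_,
                        ci95_low = NA_real_, ci95_high = NA_real_,
                        loa95_low = NA_real_, loa95_high = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ba <- bland_altman(groups[[g]]$actual_vault, groups[[g]]$predicted_vault)
    data.frame(stratum = g, n = ba$n, mean_diff = ba$mean_diff,
               sd_diff = ba$sd_diff,
               min_diff = ba$diff_range[1], max_diff = ba$diff_range[2],
               q25 = ba$quartiles[1], q75 = ba$quartiles[2],
               ci95_low = ba$ci95[1], ci95_high = ba$ci95[2],
               loa95_low = ba$loa95[1], loa95_high = ba$loa95[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("ICL vault validation report:", x$metadata$n_eyes, "eyes,",
      x$metadata$mode, "mode\n")
  if (!is.null(x$distribution)) {
    ov <- x$distribution[x$distribution$stratum == "overall", ]
    cat(sprintf("  vault categories: low %d (%.2f%%), normal %d (%.2f%%), high %d (%.2f%%)\n",
                ov$count[1], ov$percent[1], ov$count[2], ov$percent[2],
                ov$count[3], ov$percent[3]))
  }
  if (!is.null(x$agreement)) {
    ov <- x$agreement[x$agreement$stratum == "overall", ]
    cat(sprintf("  overall difference %.2f +/- %.2f um, 95%% LoA %.0f to %.0f um\n",
                ov$mean_diff, ov$sd_diff, ov$loa95_low, ov$loa95_high))
  }
  cat(" ", x$metadata$n_not_in_window, "eyes had no size inside the target window\n")
  invisible(x)
}

#' Write a validation report as delimited tables
#'
#' Emits `summary.csv`, `distribution.csv`, `agreement.csv`,
#' `features.csv` (whichever are present), the augmented per-eye table
#' `eyes.csv`, and `metadata.json` under `dir`.
#'
#' @param report A `validation_report` from [run_validation()].
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("summary", "distribution", "agreement", "features")) {
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  utils::write.csv(report$eyes, file.path(dir, "eyes.csv"), row.names = FALSE)
  jsonlite::write_json(report$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
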