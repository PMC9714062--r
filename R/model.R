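#' Manufactured ICL lengths
#'
#' The EVO implantable collamer lens is manufactured in four overall
#' lengths. Every sizing decision in this package is a choice among these.
#'
#' @return Numeric vector of the four ICL sizes in mm, increasing.
#' @export
#' @examples
#' icl_sizes()
icl_sizes <- function() c(12.1, 12.6, 13.2, 13.7)

#' Coefficients of the central-vault prediction formula
#'
#' The central postoperative vault (in micrometres) is modelled as a linear
#' function of the implanted ICL size, the horizontal and vertical
#' sulcus-to-sulcus (STS) diameters, and crystalline lens thickness (LT),
#' all in millimetres:
#'
#' vault = intercept + coef_size * size + coef_sts_h * STSh +
#'         coef_lt * LT + coef_sts_v * STSv
#'
#' Defaults are the published regression coefficients. They can be
#' overridden, e.g. to inject refitted values in sensitivity studies.
#'
#' @param intercept Intercept, um.
#' @param coef_size Coefficient on ICL size, um per mm.
#' @param coef_sts_h Coefficient on horizontal STS, um per mm.
#' @param coef_lt Coefficient on lens thickness, um per mm.
#' @param coef_sts_v Coefficient on vertical STS, um per mm.
#' @return A named list of class `model_coefficients`.
#' @export
#' @examples
#' model_coefficients()
model_coefficients <- function(intercept = -1369.05,
                               coef_size = 657.121,
                               coef_sts_h = -287.408,
                               coef_lt = -432.497,
                               coef_sts_v = -137.33) {
  co <- list(intercept = intercept, coef_size = coef_size,
             coef_sts_h = coef_sts_h, coef_lt = coef_lt,
             coef_sts_v = coef_sts_v)
  for (nm in names(co)) {
    if (!is.numeric(co[[nm]]) || length(co[[nm]]) != 1L || !is.finite(co[[nm]]))
      stop("coefficient '", nm, "' must be a single finite number")
  }
  structure(co, class = "model_coefficients")
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat("Central-vault prediction coefficients (um):\n")
  cat(sprintf("  vault = %.2f %+.3f*size %+.3f*STSh %+.3f*LT %+.3f*STSv\n",
              x$intercept, x$coef_size, x$coef_sts_h, x$coef_lt, x$coef_sts_v))
  invisible(x)
}

#' Target vault window for size selection
#'
#' The sizing rule aims for a predicted vault inside `[low, high]`;
#' among feasible sizes the one whose prediction is nearest `center`
#' is preferred.
#'
#' @param low Lower acceptable predicted vault, um.
#' @param high Upper acceptable predicted vault, um.
#' @param center Preferred vault, um; must lie strictly between `low`
#'   and `high`. Defaults to the window midpoint.
#' @return A named list of class `target_window`.
#' @export
target_window <- function(low = 300, high = 700, center = (low + high) / 2) {
  if (!is.numeric(low) || !is.numeric(high) || !is.numeric(center))
    stop("window bounds must be numeric")
  if (!(low < center && center < high))
    stop("target window requires low < center < high (got ",
         low, ", ", center, ", ", high, ")")
  structure(list(low = low, high = high, center = center),
            class = "target_window")
}

.ubm_features <- c("wide_ica", "iris_concavity",
                   "anterior_ciliary_body", "ciliary_body_cyst")

#' UBM feature names recognised by the pipeline
#'
#' Four anatomic features of the ciliary sulcus region, assessed on
#' ultrasound biomicroscopy and carried as 0/1 flags: wide iris-ciliary
#' angle (> 90 degrees), iris concavity (posterior iris bowing),
#' anteriorly positioned ciliary body (sulcus absent in at least two
#' quadrants), and ciliary body cyst.
#'
#' @return Character vector of the four column names.
#' @export
ubm_features <- function() .ubm_features

#' Validate a table of per-eye biometry
#'
#' Checks that the measurements feeding the prediction formula are present
#' and physiologically plausible. Sulcus-to-sulcus diameters must lie in
#' (8, 16) mm and lens thickness in (2.5, 6) mm; violations are an error
#' naming the offending column and rows, never a silent clamp.
#'
#' @param biometry A data.frame with numeric columns `sts_horizontal_mm`,
#'   `sts_vertical_mm`, `lens_thickness_mm`; optional `acd_mm`, `wtw_mm`,
#'   `season`, `actual_vault_um`, and 0/1 columns named after
#'   [ubm_features()].
#' @return The input, invisibly, after validation.
#' @export
validate_biometry <- function(biometry) {
  if (!is.data.frame(biometry)) stop("biometry must be a data.frame")
  if (nrow(biometry) == 0L) stop("biometry has no rows")
  needed <- c("sts_horizontal_mm", "sts_vertical_mm", "lens_thickness_mm")
  missing <- setdiff(needed, names(biometry))
  if (length(missing))
    stop("biometry is missing required column(s): ",
         paste(missing, collapse = ", "))
  ranges <- list(sts_horizontal_mm = c(8, 16),
                 sts_vertical_mm = c(8, 16),
                 lens_thickness_mm = c(2.5, 6))
  for (col in needed) {
    x <- biometry[[col]]
    if (!is.numeric(x)) stop("column '", col, "' must be numeric")
    r <- ranges[[col]]
    bad <- which(!is.finite(x) | x <= r[1] | x >= r[2])
    if (length(bad))
      stop("column '", col, "' out of range (", r[1], ", ", r[2],
           ") mm at row(s) ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  for (col in intersect(.ubm_features, names(biometry))) {
    x <- biometry[[col]]
    if (!all(x %in% c(0, 1, NA)))
      stop("UBM feature column '", col, "' must be 0/1")
  }
  invisible(biometry)
}

#' Predict central vault for a given ICL size
#'
#' Evaluates the linear vault formula at one or more biometry records.
#' The result is a real number in micrometres; it is not rounded and not
#' clamped (a strongly negative prediction simply means the size is far
#' too small for the eye).
#'
#' @param biometry Data.frame of biometry (see [validate_biometry()]), or a
#'   single-row data.frame.
#' @param size ICL size in mm; scalar or vector recycled against rows.
#'   Must be one of [icl_sizes()].
#' @param coeffs A [model_coefficients()] object.
#' @return Numeric vector of predicted vaults, um.
#' @export
#' @examples
#' eye <- data.frame(sts_horizontal_mm = 11.54, sts_vertical_mm = 11.96,
#'                   lens_thickness_mm = 3.67)
#' predict_vault(eye, 12.6)
predict_vault <- function(biometry, size, coeffs = model_coefficients()) {
  validate_biometry(biometry)
  stopifnot(inherits(coeffs, "model_coefficients"))
  if (!all(size %in% icl_sizes()))
    stop("size must be one of ", paste(icl_sizes(), collapse = ", "), " mm")
  coeffs$intercept +
    coeffs$coef_size * size +
    coeffs$coef_sts_h * biometry$sts_horizontal_mm +
    coeffs$coef_lt * biometry$lens_thickness_mm +
    coeffs$coef_sts_v * biometry$sts_vertical_mm
}

#' Change in predicted vault between two ICL sizes
#'
#' Because the formula is linear, switching size while holding biometry
#' fixed changes the predicted vault by the size coefficient times the
#' size difference, independent of the eye. With the default coefficients
#' this is 329 um per 0.5 mm step (12.1 to 12.6, or 13.2 to 13.7) and
#' 394 um for the 0.6 mm step (12.6 to 13.2).
#'
#' @param size_from,size_to ICL sizes in mm, each one of [icl_sizes()].
#' @param coeffs A [model_coefficients()] object.
#' @return Vault change in um, rounded half away from zero to an integer.
#' @export
#' @examples
#' vault_step(12.1, 12.6)
#' vault_step(12.6, 13.2)
vault_step <- function(size_from, size_to, coeffs = model_coefficients()) {
  if (!all(c(size_from, size_to) %in% icl_sizes()))
    stop("sizes must be among ", paste(icl_sizes(), collapse = ", "), " mm")
  round_half_away(coeffs$coef_size * (size_to - size_from))
}

# round half away from zero (reporting convention of the printed values;
# base round() is half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Select the ICL size for each eye
#'
#' Evaluates the vault formula at all four manufactured sizes and picks a
#' size per the target-window rule: among sizes whose prediction falls in
#' `[window$low, window$high]`, the one nearest `window$center` (ties to
#' the smaller size, since excess vault carries the severest
#' complications). If no size is feasible the boundary-nearest size is
#' returned with `in_window = FALSE` so callers can count exclusions
#' rather than fail. Optionally, eyes with an anteriorly positioned
#' ciliary body are shifted down to the smallest feasible size
#' (clinical practice: such eyes tend to vault higher than predicted).
#'
#' @param biometry Data.frame of biometry; may include UBM feature columns.
#' @param window A [target_window()].
#' @param coeffs A [model_coefficients()] object.
#' @param apply_feature_adjustment Logical; apply the anteriorly-positioned
#'   ciliary body downsizing rule.
#' @return A data.frame with one row per input row: predicted vaults at all
#'   sizes (`pred_vault_12_1` .. `pred_vault_13_7`, unrounded um),
#'   `selected_size_mm`, `selected_pred_um`, `in_window`,
#'   `adjusted_for_feature`.
#' @export
#' @examples
#' eye <- data.frame(sts_horizontal_mm = 11.5, sts_vertical_mm = 11.9,
#'                   lens_thickness_mm = 3.6)
#' select_icl_size(eye)
select_icl_size <- function(biometry, window = target_window(),
                            coeffs = model_coefficients(),
                            apply_feature_adjustment = FALSE) {
  validate_biometry(biometry)
  stopifnot(inherits(window, "target_window"))
  sizes <- icl_sizes()
  preds <- vapply(sizes, function(s) predict_vault(biometry, s, coeffs),
                  numeric(nrow(biometry)))
  preds <- matrix(preds, nrow = nrow(biometry))

  acb <- if ("anterior_ciliary_body" %in% names(biometry))
    biometry$anterior_ciliary_body %in% 1 else rep(FALSE, nrow(biometry))

  sel_idx <- integer(nrow(biometry))
  in_window <- logical(nrow(biometry))
  adjusted <- logical(nrow(biometry))
  for (i in seq_len(nrow(biometry))) {
    p <- preds[i, ]
    feasible <- which(p >= window$low & p <= window$high)
    if (length(feasible)) {
      in_window[i] <- TRUE
      d <- abs(p[feasible] - window$center)
      # which.min takes the first minimum; feasible is size-ordered, so
      # ties already break toward the smaller size
      j <- feasible[which.min(d)]
      if (apply_feature_adjustment && acb[i] && min(feasible) < j) {
        j <- min(feasible)
        adjusted[i] <- TRUE
      }
      sel_idx[i] <- j
    } else {
      # distance from each prediction to the window interval
      d <- pmax(window$low - p, p - window$high, 0)
      sel_idx[i] <- which.min(d)
      in_window[i] <- FALSE
    }
  }

  out <- as.data.frame(preds)
  names(out) <- paste0("pred_vault_", sub("\\.", "_", format(sizes)))
  out$selected_size_mm <- sizes[sel_idx]
  out$selected_pred_um <- preds[cbind(seq_len(nrow(preds)), sel_idx)]
  out$in_window <- in_window
  out$adjusted_for_feature <- adjusted
  out
}

#' Classify a postoperative vault
#'
#' Low vault is below 200 um, normal vault 200 to 800 um inclusive, high
#' vault above 800 um (the real-valued generalisation of the integer
#' bands 0-199 / 200-800 / 801+).
#'
#' @param actual_vault Numeric vector of measured vaults, um; must be
#'   non-negative.
#' @return Factor with levels `low`, `normal`, `high`.
#' @export
#' @examples
#' classify_vault(c(0, 150, 200, 800, 1150))
classify_vault <- function(actual_vault) {
  if (!is.numeric(actual_vault)) stop("actual_vault must be numeric")
  bad <- which(!is.finite(actual_vault) | actual_vault < 0)
  if (length(bad))
    stop("actual_vault must be finite and >= 0 um (row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), ")")
  out <- ifelse(actual_vault < 200, "low",
                ifelse(actual_vault <= 800, "normal", "high"))
  factor(out, levels = c("low", "normal", "high"))
}

#' Assign a prediction-error group
#'
#' Eyes whose achieved vault is more than 300 um below the prediction are
#' "overestimated", more than 300 um above are "underestimated"; the
#' thresholds are strict, so an error of exactly +/-300 um is "within".
#'
#' @param error Numeric vector, achieved minus predicted vault, um.
#' @return Factor with levels `overestimated`, `within`, `underestimated`.
#' @export
#' @examples
#' assign_error_group(c(-350, -300, 0, 300, 301))
assign_error_group <- function(error) {
  if (!is.numeric(error) || any(!is.finite(error)))
    stop("error must be finite numeric")
  out <- ifelse(error < -300, "overestimated",
                ifelse(error > 300, "underestimated", "within"))
  factor(out, levels = c("overestimated", "within", "underestimated"))
}
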