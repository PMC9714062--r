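#' Specification of a synthetic ICL cohort
#'
#' Describes a simulated population of myopic eyes with the statistical
#' structure of a large single-centre ICL series: normal biometry
#' marginals (truncated to physiologic ranges), correlated horizontal and
#' vertical sulcus-to-sulcus diameters, rare anatomic UBM features that
#' shift the achieved vault, seasonal enrolment strata, and an additive
#' Gaussian prediction-error model.
#'
#' Defaults reproduce the published overall biometry means/SDs (STSh
#' 11.54 +/- 0.41 mm, STSv 11.96 +/- 0.43 mm, LT 3.67 +/- 0.23 mm, ACD
#' 3.24 +/- 0.23 mm, WTW 11.61 +/- 0.38 mm), an overall prediction-error
#' distribution of mean 6 um and SD 176 um, and season weights
#' proportional to the study's per-season eye counts. Feature effects are
#' synthetic calibrations with the clinically observed directions (wide
#' iris-ciliary angle and iris concavity lower the achieved vault;
#' anteriorly positioned ciliary body and ciliary body cyst raise it);
#' their magnitudes are not estimates.
#'
#' @param n_eyes Number of eyes to simulate.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param means,sds Named numeric vectors over `sts_h`, `sts_v`, `lt`,
#'   `acd`, `wtw` (mm).
#' @param rho Correlation between horizontal and vertical STS.
#' @param noise_mean,noise_sd Mean and SD of the additive vault error, um.
#' @param feature_prevalence Named probabilities per UBM feature.
#' @param feature_effect Named vault offsets per UBM feature, um.
#' @param season_weights Four enrolment probabilities, summing to 1.
#' @param size_policy `"select"` sizes each eye by the target-window rule
#'   (the study procedure); `"random"` assigns sizes uniformly over the
#'   four manufactured lengths (used for model-calibration experiments,
#'   where size must vary independently of biometry).
#' @param window [target_window()] used when `size_policy = "select"`.
#' @param coeffs [model_coefficients()] generating the true vault.
#' @param apply_feature_adjustment Passed to [select_icl_size()].
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_eyes = 925,
                        seed = NULL,
                        means = c(sts_h = 11.54, sts_v = 11.96, lt = 3.67,
                                  acd = 3.24, wtw = 11.61),
                        sds = c(sts_h = 0.41, sts_v = 0.43, lt = 0.23,
                                acd = 0.23, wtw = 0.38),
                        rho = 0.7,
                        noise_mean = 6,
                        noise_sd = 176,
                        feature_prevalence = c(wide_ica = 0.05,
                                               iris_concavity = 0.02,
                                               anterior_ciliary_body = 0.05,
                                               ciliary_body_cyst = 0.03),
                        feature_effect = c(wide_ica = -250,
                                           iris_concavity = -250,
                                           anterior_ciliary_body = 250,
                                           ciliary_body_cyst = 150),
                        season_weights = c(221, 200, 302, 202) / 925,
                        size_policy = c("select", "random"),
                        window = target_window(),
                        coeffs = model_coefficients(),
                        apply_feature_adjustment = FALSE) {
  size_policy <- match.arg(size_policy)
  vars <- c("sts_h", "sts_v", "lt", "acd", "wtw")
  if (!all(vars %in% names(means)) || !all(vars %in% names(sds)))
    stop("means and sds must name ", paste(vars, collapse = ", "))
  if (any(sds[vars] <= 0)) stop("all SDs must be positive")
  if (!is.numeric(rho) || abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  feats <- ubm_features()
  if (!all(feats %in% names(feature_prevalence)) ||
      any(feature_prevalence[feats] < 0) || any(feature_prevalence[feats] > 1))
    stop("feature_prevalence must give a probability in [0,1] per feature")
  if (!all(feats %in% names(feature_effect)))
    stop("feature_effect must name every feature")
  if (length(season_weights) != 4L || any(season_weights < 0) ||
      abs(sum(season_weights) - 1) > 1e-8)
    stop("season_weights must be 4 probabilities summing to 1")
  if (n_eyes < 1) stop("n_eyes must be positive")
  structure(list(n_eyes = as.integer(n_eyes), seed = seed,
                 means = means[vars], sds = sds[vars], rho = rho,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 feature_prevalence = feature_prevalence[feats],
                 feature_effect = feature_effect[feats],
                 season_weights = season_weights,
                 size_policy = size_policy, window = window,
                 coeffs = coeffs,
                 apply_feature_adjustment = apply_feature_adjustment),
            class = "cohort_spec")
}

# rejection-sample the correlated (sts_h, sts_v) pair and the remaining
# independent truncated normals; returns biometry plus the proposal count
# so callers can audit the truncation rate
sample_biometry <- function(spec) {
  n <- spec$n_eyes
  mu <- spec$means; sd <- spec$sds; rho <- spec$rho
  draw_pair <- function(m) {
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    cbind(mu["sts_h"] + sd["sts_h"] * z1,
          mu["sts_v"] + sd["sts_v"] * (rho * z1 + sqrt(1 - rho^2) * z2))
  }
  sts <- matrix(numeric(0), ncol = 2)
  proposed <- 0L
  while (nrow(sts) < n) {
    m <- max(n - nrow(sts), 16L)
    cand <- draw_pair(m)
    proposed <- proposed + m
    ok <- cand[, 1] > 8 & cand[, 1] < 16 & cand[, 2] > 8 & cand[, 2] < 16
    sts <- rbind(sts, cand[ok, , drop = FALSE])
  }
  sts <- sts[seq_len(n), , drop = FALSE]
  draw_trunc <- function(m0, s0, lo, hi) {
    x <- numeric(0)
    while (length(x) < n) {
      m <- max(n - length(x), 16L)
      cand <- stats::rnorm(m, m0, s0)
      proposed <<- proposed + m
      x <- c(x, cand[cand > lo & cand < hi])
    }
    x[seq_len(n)]
  }
  out <- data.frame(sts_horizontal_mm = sts[, 1],
                    sts_vertical_mm = sts[, 2],
                    lens_thickness_mm = draw_trunc(mu["lt"], sd["lt"], 2.5, 6),
                    acd_mm = stats::rnorm(n, mu["acd"], sd["acd"]),
                    wtw_mm = stats::rnorm(n, mu["wtw"], sd["wtw"]))
  attr(out, "n_proposed") <- proposed
  out
}

#' Generate a synthetic cohort of eyes
#'
#' Draws per-eye biometry from (correlated) truncated normals, assigns
#' UBM features independently by prevalence and a season label by the
#' enrolment weights, sizes each eye (by the target-window rule or at
#' random, per `spec$size_policy`), and realises the achieved vault as
#'
#' actual = predicted(at implanted size) + noise_mean +
#'          sum(effects of present features) + N(0, noise_sd),
#'
#' floored at 0 um (vault cannot be negative; complete vault loss is the
#' clinical analogue). Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame in the pipeline's biometry input format (one eye
#'   per row) with additional columns `icl_size_mm`, `in_window`,
#'   `predicted_vault_um` (the prediction at the implanted size) and
#'   `actual_vault_um`. The proposal count of the truncated-normal
#'   rejection sampler is attached as attribute `"n_proposed"`.
#' @export
#' @examples
#' eyes <- generate_cohort(cohort_spec(n_eyes = 50, seed = 7))
#' head(eyes)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_eyes
  eyes <- sample_biometry(spec)
  n_proposed <- attr(eyes, "n_proposed", exact = TRUE)
  for (f in ubm_features())
    eyes[[f]] <- stats::rbinom(n, 1L, spec$feature_prevalence[[f]])
  eyes$season <- sample.int(4L, n, replace = TRUE, prob = spec$season_weights)

  sizing <- select_icl_size(eyes, spec$window, spec$coeffs,
                            spec$apply_feature_adjustment)
  if (spec$size_policy == "random") {
    size <- sample(icl_sizes(), n, replace = TRUE)
    pred <- predict_vault(eyes, size, spec$coeffs)
    eyes$icl_size_mm <- size
    eyes$in_window <- pred >= spec$window$low & pred <= spec$window$high
    eyes$predicted_vault_um <- pred
  } else {
    eyes$icl_size_mm <- sizing$selected_size_mm
    eyes$in_window <- sizing$in_window
    eyes$predicted_vault_um <- sizing$selected_pred_um
  }

  effect <- as.matrix(eyes[ubm_features()]) %*% spec$feature_effect
  vault <- eyes$predicted_vault_um + spec$noise_mean + as.vector(effect) +
    stats::rnorm(n, 0, spec$noise_sd)
  eyes$actual_vault_um <- pmax(vault, 0)
  attr(eyes, "n_proposed") <- n_proposed
  eyes
}

#' Refit the vault formula on a cohort by ordinary least squares
#'
#' Regresses the achieved vault on implanted size, horizontal STS, lens
#' thickness and vertical STS. Serves as a calibration check: on noise-free
#' cohorts with randomly assigned sizes it recovers the generating
#' coefficients exactly, and on noisy cohorts it recovers them to within
#' sampling error. Fitting is by QR decomposition.
#'
#' @param eyes Data.frame with columns `actual_vault_um`, `icl_size_mm`,
#'   `sts_horizontal_mm`, `lens_thickness_mm`, `sts_vertical_mm`.
#' @return A [model_coefficients()] object with the estimates; standard
#'   errors are attached as attribute `"se"`.
#' @export
refit_linear_model <- function(eyes) {
  needed <- c("actual_vault_um", "icl_size_mm", "sts_horizontal_mm",
              "lens_thickness_mm", "sts_vertical_mm")
  missing <- setdiff(needed, names(eyes))
  if (length(missing))
    stop("eyes is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(eyes) < 10L)
    stop("at least 10 eyes are required to refit (got ", nrow(eyes), ")")
  X <- cbind(1, eyes$icl_size_mm, eyes$sts_horizontal_mm,
             eyes$lens_thickness_mm, eyes$sts_vertical_mm)
  fit <- stats::lm.fit(X, eyes$actual_vault_um)
  if (fit$rank < ncol(X))
    stop("singular design: size and biometry do not vary independently ",
         "(rank ", fit$rank, " of ", ncol(X), ")")
  b <- unname(fit$coefficients)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (nrow(X) - ncol(X))
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * diag(XtXinv))
  out <- model_coefficients(intercept = b[1], coef_size = b[2],
                            coef_sts_h = b[3], coef_lt = b[4],
                            coef_sts_v = b[5])
  attr(out, "se") <- stats::setNames(
    se, c("intercept", "coef_size", "coef_sts_h", "coef_lt", "coef_sts_v"))
  out
}

#' Write / read a cohort in the pipeline's delimited format
#'
#' Plain comma-separated files with a header row; units are fixed by the
#' column names (`*_mm`, `*_um`), no autodetection.
#'
#' @param eyes Cohort data.frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the validated data.frame.
#' @export
write_cohort <- function(eyes, path) {
  utils::write.csv(eyes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  eyes <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_biometry(eyes)
  eyes
}
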