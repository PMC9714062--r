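# Independent oracles and fixture builders used across the suite.

# one-row biometry with sensible defaults
make_eye <- function(sts_h = 11.54, sts_v = 11.96, lt = 3.67, ...) {
  data.frame(sts_horizontal_mm = sts_h, sts_vertical_mm = sts_v,
             lens_thickness_mm = lt, ...)
}

# random in-range biometry, n rows
random_biometry <- function(n) {
  data.frame(sts_horizontal_mm = runif(n, 10.5, 12.8),
             sts_vertical_mm = runif(n, 10.8, 13.2),
             lens_thickness_mm = runif(n, 3.0, 4.4))
}

# solve the lens thickness that yields a target prediction at a given
# size, holding the STS values fixed (inverts the formula analytically)
lt_for_prediction <- function(target, size, sts_h = 11.54, sts_v = 11.96,
                              co = model_coefficients()) {
  (co$intercept + co$coef_size * size + co$coef_sts_h * sts_h +
     co$coef_sts_v * sts_v - target) / -co$coef_lt
}

# brute-force mean / sample SD / type-7 quartile, written from the
# textbook definitions, no calls into the summary functions under test
brute_mean <- function(x) sum(x) / length(x)
brute_sd <- function(x) {
  m <- brute_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
brute_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# direct-factorial hypergeometric point probabilities for every table
# sharing the observed margins; returns support values and probabilities
hypergeom_support_probs <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  list(support = support, probs = probs)
}

# exhaustive-enumeration two-sided Fisher p, probability-mass rule
fisher_enum_p <- function(a, b, c, d) {
  hp <- hypergeom_support_probs(a, b, c, d)
  p_obs <- hp$probs[hp$support == a]
  sum(hp$probs[hp$probs <= p_obs * (1 + 1e-7)])
}

# two-point series with an exact mean and sample SD
series_with <- function(mean, sd) mean + c(-1, 1) * sd / sqrt(2)
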