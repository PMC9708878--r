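# Brute-force oracles: direct evaluation of the defining formulas,
# independent of the package implementation.

oracle_woolf <- function(a, b, c, d, z = qnorm(0.975)) {
  lor <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(lor), se = se,
       lo = exp(lor - z * se), hi = exp(lor + z * se))
}

oracle_mh_or <- function(tabs) {
  # tabs: list of c(a, b, c, d)
  num <- den <- 0
  for (t in tabs) {
    n <- sum(t)
    num <- num + t[1] * t[4] / n
    den <- den + t[2] * t[3] / n
  }
  num / den
}

oracle_q_tau <- function(y, v) {
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  df <- length(y) - 1
  cc <- sum(w) - sum(w^2) / sum(w)
  list(q = q, tau2 = max(0, (q - df) / cc))
}

oracle_kendall_tau <- function(x, y) {
  # exhaustive pair enumeration, no tie handling (use on tie-free input)
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# tiny corpus builder for hand-constructed studies
make_corpus <- function(case, ctrl, disease = NULL, id = NULL) {
  # case/ctrl: matrices with columns aa, ab, bb (one row per study)
  if (!is.matrix(case)) case <- matrix(case, ncol = 3, byrow = TRUE)
  if (!is.matrix(ctrl)) ctrl <- matrix(ctrl, ncol = 3, byrow = TRUE)
  k <- nrow(case)
  as_study_corpus(data.frame(
    study_id = id %||% sprintf("study_%02d", seq_len(k)),
    polymorphism = "toy",
    disease = disease %||% rep("SIM", k),
    case_aa = case[, 1], case_ab = case[, 2], case_bb = case[, 3],
    ctrl_aa = ctrl[, 1], ctrl_ab = ctrl[, 2], ctrl_bb = ctrl[, 3],
    allele_common = "A", allele_variant = "B",
    stringsAsFactors = FALSE
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# absolute-tolerance comparison against a printed reference value
expect_near <- function(actual, expected, tol, info = "value") {
  testthat::expect_true(
    abs(actual - expected) <= tol,
    label = sprintf("%s: |%.6g - %.6g| <= %g", info, actual, expected, tol))
}

# Published overall pooled rows (three corpora x five contrasts):
# OR, 95% CI bounds and the selected analysis model.
published_overall <- list(
  tgfb1_509 = list(
    allele       = list(or = 1.25, lo = 1.06, hi = 1.48, model = "RE"),
    homozygote   = list(or = 1.51, lo = 1.08, hi = 2.11, model = "RE"),
    heterozygote = list(or = 1.31, lo = 1.09, hi = 1.58, model = "RE"),
    dominant     = list(or = 1.38, lo = 1.10, hi = 1.73, model = "RE"),
    recessive    = list(or = 1.25, lo = 1.00, hi = 1.57, model = "RE")),
  tgfb1_codon10 = list(
    allele       = list(or = 1.12, lo = 1.02, hi = 1.23, model = "FE"),
    homozygote   = list(or = 1.28, lo = 1.06, hi = 1.54, model = "FE"),
    heterozygote = list(or = 1.05, lo = 0.90, hi = 1.23, model = "FE"),
    dominant     = list(or = 1.11, lo = 0.96, hi = 1.29, model = "FE"),
    recessive    = list(or = 1.23, lo = 1.05, hi = 1.44, model = "FE")),
  tgfb1_codon25 = list(
    allele       = list(or = 1.09, lo = 0.78, hi = 1.52, model = "RE"),
    homozygote   = list(or = 0.97, lo = 0.38, hi = 2.51, model = "RE"),
    heterozygote = list(or = 1.01, lo = 0.73, hi = 1.39, model = "RE"),
    dominant     = list(or = 1.07, lo = 0.76, hi = 1.52, model = "RE"),
    recessive    = list(or = 1.00, lo = 0.42, hi = 2.41, model = "RE"))
)
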