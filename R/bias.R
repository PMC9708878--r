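#' Egger regression test for funnel-plot asymmetry
#'
#' Regression-based test of small-study effects. Two formulations are
#' provided:
#'
#' * `method = "classic"` (default): the original unweighted form. The
#'   standardized effect `log_or / se` is regressed by ordinary least squares
#'   on the precision `1 / se`; under no small-study bias the intercept is
#'   zero, and the statistic is `t = intercept / se(intercept)` on `k - 2`
#'   degrees of freedom, two-sided.
#' * `method = "weighted"`: the meta-regression form used by much
#'   meta-analysis software. The log odds ratio is regressed on its standard
#'   error by weighted least squares with meta-analytic weights
#'   `1/(se^2 + tau2)`; with `model = "re"` (default) `tau2` is the
#'   DerSimonian-Laird moment estimate from the residual heterogeneity of
#'   the regression, with `model = "fe"` it is zero. The coefficient on `se`
#'   is the asymmetry parameter (algebraically the classic intercept) and is
#'   tested as a normal deviate.
#'
#' Both forms agree on direction; their p-values can differ appreciably in
#' heterogeneous corpora, so report which one you used.
#'
#' @param effects An [effect table][or_estimate] with at least 3 studies.
#' @param method `"classic"` or `"weighted"` (see above).
#' @param model For `method = "weighted"`: `"re"` (default) or `"fe"`.
#' @return An object of class `"bias_test"`: `method`, `intercept` (the
#'   asymmetry coefficient), `intercept_se`, `statistic` (t for classic, z
#'   for weighted), `p`, `k`.
#' @export
egger_test <- function(effects, method = c("classic", "weighted"),
                       model = c("re", "fe")) {
  method <- match.arg(method)
  model <- match.arg(model)
  k <- nrow(effects)
  if (k < 3L) stop("Egger's test needs at least 3 studies", call. = FALSE)
  stopifnot(all(effects$se > 0))
  if (method == "classic") {
    std_eff <- effects$log_or / effects$se
    prec <- 1 / effects$se
    fit <- stats::lm(std_eff ~ prec)
    sm <- summary(fit)$coefficients
    intercept <- sm["(Intercept)", "Estimate"]
    intercept_se <- sm["(Intercept)", "Std. Error"]
    t_val <- intercept / intercept_se
    res <- list(method = "egger", form = "classic", statistic = t_val,
                p = 2 * stats::pt(abs(t_val), df = k - 2, lower.tail = FALSE),
                intercept = intercept, intercept_se = intercept_se, k = k)
  } else {
    y <- effects$log_or
    v <- effects$se^2
    x <- cbind(1, sqrt(v))
    w <- 1 / v
    xtwx <- crossprod(x, w * x)
    b_fe <- solve(xtwx, crossprod(x, w * y))
    qe <- sum(w * (y - x %*% b_fe)^2)
    tau2 <- 0
    if (model == "re") {
      # DL moment estimate from the residual Q of the FE meta-regression
      pmat <- diag(w) - (w * x) %*% solve(xtwx, t(w * x))
      tau2 <- max(0, (qe - (k - 2)) / sum(diag(pmat)))
    }
    ws <- 1 / (v + tau2)
    xtwsx <- crossprod(x, ws * x)
    b <- solve(xtwsx, crossprod(x, ws * y))
    vb <- solve(xtwsx)
    intercept <- b[2]
    intercept_se <- sqrt(vb[2, 2])
    z <- intercept / intercept_se
    res <- list(method = "egger", form = paste0("weighted-", model),
                statistic = z,
                p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                intercept = intercept, intercept_se = intercept_se, k = k)
  }
  class(res) <- "bias_test"
  res
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Kendall rank correlation between standardized study effects and their
#' variances. Each effect is standardized as
#' `v_i = (y_i - y_fe) / sqrt(var_i - var_fe)` where `y_fe` is the
#' fixed-effects inverse-variance pooled estimate and `var_fe` its variance;
#' the Kendall score between `v_i` and `var_i` is tested with the
#' continuity-corrected normal approximation. Ties are handled with the
#' tau-b tie correction in the score variance, so rounded or duplicated
#' effects are legal input.
#'
#' @param effects An [effect table][or_estimate] with at least 3 studies.
#' @return A `"bias_test"` object: `method = "begg"`, `statistic` (the
#'   continuity-corrected normal deviate), `p` (two-sided, capped at 1),
#'   `tau_kendall`, `k`.
#' @export
begg_test <- function(effects) {
  k <- nrow(effects)
  if (k < 3L) stop("Begg's test needs at least 3 studies", call. = FALSE)
  y <- effects$log_or
  v <- effects$se^2
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  v_fe <- 1 / sum(w)
  dev <- (y - y_fe) / sqrt(pmax(v - v_fe, .Machine$double.eps))
  kt <- .kendall_score(dev, v)
  z_cc <- if (kt$var_s > 0) max(0, abs(kt$s) - 1) / sqrt(kt$var_s) else 0
  res <- list(method = "begg", statistic = z_cc,
              p = min(1, 2 * stats::pnorm(z_cc, lower.tail = FALSE)),
              tau_kendall = kt$tau, k = k)
  class(res) <- "bias_test"
  res
}

# Kendall score S, its tie-corrected variance, and tau-b
.kendall_score <- function(x, y) {
  n <- length(x)
  s <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  tie_term <- function(v) {
    t <- table(v)
    t <- t[t > 1]
    list(v0 = sum(t * (t - 1) * (2 * t + 5)),
         n1 = sum(t * (t - 1)) / 2)
  }
  tx <- tie_term(x); ty <- tie_term(y)
  var_s <- (n * (n - 1) * (2 * n + 5) - tx$v0 - ty$v0) / 18
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - tx$n1) * (n0 - ty$n1))
  tau <- if (denom > 0) s / denom else 0
  list(s = s, var_s = var_s, tau = tau)
}

#' @export
print.bias_test <- function(x, ...) {
  if (x$method == "egger") {
    cat(sprintf("Egger regression test (%s): intercept = %.4f (SE %.4f), %s = %.4f, p = %.4g\n",
                x$form, x$intercept, x$intercept_se,
                if (x$form == "classic") sprintf("t[%d]", x$k - 2) else "z",
                x$statistic, x$p))
  } else {
    cat(sprintf("Begg rank-correlation test: tau = %.4f, z = %.4f (continuity-corrected), p = %.4g\n",
                x$tau_kendall, x$statistic, x$p))
  }
  invisible(x)
}

#' Funnel-plot data
#'
#' Per-study points (odds ratio on a log-scaled axis, standard error on an
#' inverted axis) plus the pseudo 95% confidence funnel around the pooled
#' estimate.
#'
#' @param effects An [effect table][or_estimate].
#' @param pooled A `meta_or` fit giving the funnel apex.
#' @return A list of two data frames: `points` (`study_id`, `or`, `log_or`,
#'   `se`) and `funnel` (`se`, `or_low`, `or_high` along an se grid from 0
#'   to the largest study se).
#' @export
funnel_data <- function(effects, pooled) {
  stopifnot(nrow(effects) >= 1L, inherits(pooled, "meta_or"))
  zq <- stats::qnorm(1 - (1 - pooled$conf_level) / 2)
  se_grid <- seq(0, max(effects$se), length.out = 50L)
  list(
    points = data.frame(study_id = effects$study_id, or = effects$or,
                        log_or = effects$log_or, se = effects$se,
                        stringsAsFactors = FALSE),
    funnel = data.frame(se = se_grid,
                        or_low = exp(pooled$log_or - zq * se_grid),
                        or_high = exp(pooled$log_or + zq * se_grid))
  )
}
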