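#' Cochran Q, I-squared and DerSimonian-Laird tau-squared
#'
#' Heterogeneity statistics on a set of per-study log odds ratios. `Q` is the
#' weighted sum of squared deviations of the study effects about the
#' fixed-effect inverse-variance pooled mean, with weights `1/se^2`; its
#' upper-tail chi-square probability on `k - 1` degrees of freedom is
#' `p_het`. `I2 = max(0, (Q - df)/Q) * 100` is the percentage of total
#' variability attributable to between-study variance, and `tau2` is the
#' DerSimonian-Laird moment estimate `max(0, (Q - df)/C)` with
#' `C = sum(w) - sum(w^2)/sum(w)`.
#'
#' A single study (`k = 1`) has no testable heterogeneity: `Q = 0`, `i2 = 0`,
#' `tau2 = 0` and `p_het = 1` by convention.
#'
#' @param effects An [effect table][or_estimate] (needs `log_or` and `se`).
#' @return An object of class `"heterogeneity"`: list with `q`, `df`,
#'   `p_het`, `i2`, `tau2`, `k`.
#' @export
heterogeneity <- function(effects) {
  y <- effects$log_or
  se <- effects$se
  k <- length(y)
  stopifnot(k >= 1L, all(se > 0))
  if (k == 1L) {
    res <- list(q = 0, df = 0L, p_het = 1, i2 = 0, tau2 = 0, k = 1L)
    class(res) <- "heterogeneity"
    return(res)
  }
  w <- 1 / se^2
  yhat <- sum(w * y) / sum(w)
  q <- sum(w * (y - yhat)^2)
  df <- k - 1L
  p_het <- stats::pchisq(q, df = df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / cc)
  res <- list(q = q, df = df, p_het = p_het, i2 = i2, tau2 = tau2, k = k)
  class(res) <- "heterogeneity"
  res
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Q = %.4f (df = %d), p_het = %.4g, I2 = %.1f%%, tau2 = %.4f\n",
              x$q, x$df, x$p_het, x$i2, x$tau2))
  invisible(x)
}

# shared constructor for pooled results
.pooled <- function(log_or, se_log, model, k, het, conf_level,
                    n_case = NA_integer_, n_control = NA_integer_,
                    contrast = NA_character_, polymorphism = NA_character_,
                    effects = NULL, weights = NULL, dropped = character(0)) {
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- log_or / se_log
  res <- list(
    polymorphism = polymorphism, contrast = contrast, model = model,
    k = k, n_case = n_case, n_control = n_control,
    log_or = log_or, se = se_log,
    or = exp(log_or),
    ci_low = exp(log_or - zq * se_log), ci_high = exp(log_or + zq * se_log),
    z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    het = het, conf_level = conf_level,
    effects = effects, weights = weights, dropped = dropped
  )
  class(res) <- "meta_or"
  res
}

#' Mantel-Haenszel fixed-effects pooled odds ratio
#'
#' Pools 2x2 tables with the Mantel-Haenszel estimator
#' `OR = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`, with the
#' Robins-Breslow-Greenland variance for the log pooled OR. Studies with a
#' zero cell have the continuity constant added to all four of their cells
#' before pooling, the same convention the per-study Woolf effects use (and
#' the one standard meta-analysis software applies); studies without zero
#' cells enter with raw counts. Heterogeneity is computed on the Woolf
#' per-study effects about the inverse-variance mean.
#'
#' @param tables A `"contrast_tables"` data frame from [build_contrast()].
#' @param continuity Continuity constant added to every cell of a zero-cell
#'   study.
#' @param conf_level Confidence level.
#' @return A `meta_or` object (see [meta_analyze()]).
#' @export
pool_fixed_mh <- function(tables, continuity = 0.5, conf_level = 0.95) {
  eff <- or_estimate(tables, continuity = continuity, conf_level = conf_level)
  zcell <- eff$corrected
  a <- eff$a + continuity * zcell
  b <- eff$b + continuity * zcell
  c <- eff$c + continuity * zcell
  d <- eff$d + continuity * zcell
  n <- a + b + c + d
  r_i <- a * d / n
  s_i <- b * c / n
  r_sum <- sum(r_i); s_sum <- sum(s_i)
  if (r_sum == 0 || s_sum == 0) {
    stop("Mantel-Haenszel pooled odds ratio undefined (zero numerator or denominator)",
         call. = FALSE)
  }
  log_or <- log(r_sum / s_sum)
  # Robins-Breslow-Greenland variance
  p_i <- (a + d) / n
  q_i <- (b + c) / n
  var_log <- sum(p_i * r_i) / (2 * r_sum^2) +
    sum(p_i * s_i + q_i * r_i) / (2 * r_sum * s_sum) +
    sum(q_i * s_i) / (2 * s_sum^2)
  het <- heterogeneity(eff)
  w_pct <- 100 * s_i / s_sum   # MH weights are proportional to b*c/n
  .pooled(log_or, sqrt(var_log), model = "FE-MH", k = nrow(eff), het = het,
          conf_level = conf_level, contrast = attr(tables, "contrast"),
          effects = eff, weights = w_pct,
          dropped = attr(eff, "dropped"))
}

#' Inverse-variance fixed-effects pooled odds ratio
#'
#' Weighted mean of per-study log odds ratios with weights `1/se^2`.
#' Provided as a cross-check estimator; the Mantel-Haenszel form
#' ([pool_fixed_mh()]) is the default fixed-effects method.
#'
#' @param effects An [effect table][or_estimate].
#' @param conf_level Confidence level.
#' @return A `meta_or` object.
#' @export
pool_fixed_iv <- function(effects, conf_level = 0.95) {
  stopifnot(nrow(effects) >= 1L)
  w <- 1 / effects$se^2
  log_or <- sum(w * effects$log_or) / sum(w)
  het <- heterogeneity(effects)
  .pooled(log_or, sqrt(1 / sum(w)), model = "FE-IV", k = nrow(effects),
          het = het, conf_level = conf_level,
          contrast = attr(effects, "contrast"), effects = effects,
          weights = 100 * w / sum(w),
          dropped = attr(effects, "dropped") %||% character(0))
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Random-effects pooling with the DerSimonian-Laird moment estimate of the
#' between-study variance: weights `1/(se^2 + tau2)`. Reduces exactly to the
#' inverse-variance fixed-effects estimate when `tau2 = 0`.
#'
#' @inheritParams pool_fixed_iv
#' @return A `meta_or` object.
#' @export
pool_random_dl <- function(effects, conf_level = 0.95) {
  stopifnot(nrow(effects) >= 1L)
  het <- heterogeneity(effects)
  w <- 1 / (effects$se^2 + het$tau2)
  log_or <- sum(w * effects$log_or) / sum(w)
  .pooled(log_or, sqrt(1 / sum(w)), model = "RE-DL", k = nrow(effects),
          het = het, conf_level = conf_level,
          contrast = attr(effects, "contrast"), effects = effects,
          weights = 100 * w / sum(w),
          dropped = attr(effects, "dropped") %||% character(0))
}

#' Fixed- vs random-effects selection rule
#'
#' The conventional heterogeneity-driven rule: fixed effects when
#' `p_het > 0.1` **and** `I2 < 50%`; random effects otherwise (boundary
#' values go to random effects).
#'
#' @param het A `"heterogeneity"` object.
#' @return `"FE"` or `"RE"`.
#' @export
select_model <- function(het) {
  stopifnot(inherits(het, "heterogeneity"))
  if (het$p_het > 0.1 && het$i2 < 50) "FE" else "RE"
}

#' Meta-analysis of a genotype-count study corpus
#'
#' The main fitting function. Runs the full pipeline on a corpus of
#' case-control genotype counts:
#'
#' 1. Hardy-Weinberg filtering of studies on the designated arm
#'    ([apply_hwe_filter()], default control arm at `alpha = 0.05`);
#' 2. construction of 2x2 exposure tables under the requested
#'    [genetic-model contrast][genetic_contrasts], dropping studies whose
#'    table is uninformative (a class empty in both arms);
#' 3. per-study Woolf log odds ratios with 0.5 continuity correction for
#'    zero-cell studies ([or_estimate()]);
#' 4. heterogeneity assessment (Cochran Q, I-squared, DerSimonian-Laird
#'    tau-squared) and model selection (`p_het > 0.1` and `I2 < 50%` gives
#'    fixed effects, otherwise random effects);
#' 5. pooling: Mantel-Haenszel on raw counts for fixed effects,
#'    DerSimonian-Laird on the corrected effects for random effects.
#'
#' @param corpus A [study corpus][as_study_corpus].
#' @param contrast `"allele"`, `"homozygote"`, `"heterozygote"`,
#'   `"dominant"` or `"recessive"`.
#' @param hwe_alpha HWE exclusion threshold (set to `0` to skip filtering).
#' @param hwe_arm Arm tested for HWE: `"control"` (default), `"case"`,
#'   `"both"`.
#' @param model `"auto"` (heterogeneity-driven selection, default), `"fe"`
#'   (force Mantel-Haenszel fixed effects) or `"re"` (force
#'   DerSimonian-Laird random effects).
#' @param continuity Continuity constant for zero-cell studies.
#' @param conf_level Confidence level of the pooled interval.
#' @return An object of class `"meta_or"`: pooled `or`, `ci_low`, `ci_high`,
#'   `z`, `p`, the heterogeneity block `het` (`q`, `p_het`, `i2`, `tau2`),
#'   the `model` label (`"FE-MH"` or `"RE-DL"`), study count `k`, summed arm
#'   sizes `n_case` / `n_control`, the per-study `effects` and percentage
#'   `weights`, the HWE `filter` report, and `dropped` (studies excluded as
#'   uninformative for this contrast). Methods: `print`, `summary`, `coef`,
#'   `confint`, `residuals`, `plot`.
#' @export
#' @examples
#' fit <- meta_analyze(load_fixture("tgfb1_509"), "allele")
#' fit
#' coef(fit)
meta_analyze <- function(corpus, contrast = .contrasts, hwe_alpha = 0.05,
                         hwe_arm = c("control", "case", "both"),
                         model = c("auto", "fe", "re"),
                         continuity = 0.5, conf_level = 0.95) {
  contrast <- match.arg(contrast)
  hwe_arm <- match.arg(hwe_arm)
  model <- match.arg(model)
  cl <- match.call()

  if (hwe_alpha > 0) {
    flt <- apply_hwe_filter(corpus, alpha = hwe_alpha, arm = hwe_arm)
    retained <- flt$retained
  } else {
    flt <- NULL
    retained <- corpus
  }
  if (nrow(retained) == 0L) {
    stop("no studies left after HWE filtering (stage: hwe_filter)",
         call. = FALSE)
  }
  tables <- build_contrast(retained, contrast)
  if (!any(tables$informative)) {
    stop("no informative studies for this contrast (stage: contrast construction)",
         call. = FALSE)
  }
  eff <- or_estimate(tables, continuity = continuity,
                     conf_level = conf_level)
  het <- heterogeneity(eff)
  chosen <- switch(model,
                   auto = select_model(het),
                   fe = "FE", re = "RE")
  fit <- if (chosen == "FE") {
    pool_fixed_mh(tables[tables$informative, , drop = FALSE],
                  continuity = continuity, conf_level = conf_level)
  } else {
    pool_random_dl(eff, conf_level = conf_level)
  }
  used <- retained[retained$study_id %in% eff$study_id, , drop = FALSE]
  fit$call <- cl
  fit$polymorphism <- paste(unique(retained$polymorphism), collapse = ", ")
  fit$contrast <- contrast
  fit$n_case <- sum(used$case_aa + used$case_ab + used$case_bb)
  fit$n_control <- sum(used$ctrl_aa + used$ctrl_ab + used$ctrl_bb)
  fit$filter <- flt
  fit$dropped <- attr(eff, "dropped")
  fit$model_rule <- model
  fit
}

# ---- methods -------------------------------------------------------------

.fmt_p <- function(p) if (p < 1e-5) "<0.00001" else sprintf("%.5g", p)

#' @export
print.meta_or <- function(x, ...) {
  cat(sprintf("Pooled odds ratio (%s model)\n",
              switch(x$model, `FE-MH` = "Mantel-Haenszel fixed-effects",
                     `FE-IV` = "inverse-variance fixed-effects",
                     `RE-DL` = "DerSimonian-Laird random-effects", x$model)))
  if (!is.na(x$contrast)) {
    cat(sprintf("Contrast: %s%s\n", x$contrast,
                if (!is.na(x$polymorphism))
                  paste0("  (", x$polymorphism, ")") else ""))
  }
  cat(sprintf("Studies: k = %d", x$k))
  if (!is.na(x$n_case)) {
    cat(sprintf("  (%d cases / %d controls)", x$n_case, x$n_control))
  }
  cat("\n")
  cat(sprintf("OR = %.2f, %d%% CI (%.2f, %.2f), Z = %.2f, p = %s\n",
              x$or, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$z, .fmt_p(x$p)))
  cat(sprintf("Heterogeneity: I2 = %d%%, p_het = %s, tau2 = %.4f\n",
              round(x$het$i2), .fmt_p(x$het$p_het), x$het$tau2))
  if (length(x$dropped) > 0L) {
    cat("Uninformative for this contrast (dropped):",
        paste(x$dropped, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.meta_or <- function(object, ...) {
  print(object)
  cat("\nPer-study effects:\n")
  eff <- object$effects
  eff$weight_pct <- object$weights
  print(data.frame(study = eff$study_id,
                   OR = round(eff$or, 2),
                   ci_low = round(eff$ci_low, 2),
                   ci_high = round(eff$ci_high, 2),
                   weight_pct = round(eff$weight_pct, 1)),
        row.names = FALSE)
  if (!is.null(object$filter) && nrow(object$filter$excluded) > 0L) {
    cat("\nHWE-excluded studies:\n")
    print(object$filter$excluded, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.meta_or <- function(object, ...) {
  c(log_or = object$log_or)
}

#' @export
confint.meta_or <- function(object, parm, level = NULL, ...) {
  lv <- level %||% object$conf_level
  zq <- stats::qnorm(1 - (1 - lv) / 2)
  out <- matrix(c(object$log_or - zq * object$se,
                  object$log_or + zq * object$se), nrow = 1)
  dimnames(out) <- list("log_or",
                        sprintf("%g %%", c((1 - lv) / 2, 1 - (1 - lv) / 2) * 100))
  out
}

#' @export
residuals.meta_or <- function(object, type = c("raw", "standardized"), ...) {
  type <- match.arg(type)
  r <- object$effects$log_or - object$log_or
  if (type == "standardized") r <- r / object$effects$se
  stats::setNames(r, object$effects$study_id)
}

#' Forest-plot data
#'
#' Per-study odds ratios, confidence bounds and pooling weights in the layout
#' a forest plot needs, followed by the pooled summary row.
#'
#' @param fit A `meta_or` object.
#' @return Data frame with `study_id`, `or`, `ci_low`, `ci_high`,
#'   `weight_pct` (the pooled row has weight 100).
#' @export
forest_data <- function(fit) {
  stopifnot(inherits(fit, "meta_or"))
  eff <- fit$effects
  rbind(
    data.frame(study_id = eff$study_id, or = eff$or,
               ci_low = eff$ci_low, ci_high = eff$ci_high,
               weight_pct = fit$weights, stringsAsFactors = FALSE),
    data.frame(study_id = sprintf("Pooled (%s)", fit$model), or = fit$or,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               weight_pct = 100, stringsAsFactors = FALSE)
  )
}

#' @export
plot.meta_or <- function(x, ...) {
  fd <- forest_data(x)
  k <- nrow(fd)
  ylim <- c(0.5, k + 0.5)
  xlim <- range(c(fd$ci_low, fd$ci_high, 1))
  graphics::plot(NA, xlim = xlim, ylim = ylim, log = "x",
                 xlab = "Odds ratio (log scale)", ylab = "",
                 yaxt = "n", ...)
  graphics::axis(2, at = rev(seq_len(k)), labels = fd$study_id, las = 1,
                 cex.axis = 0.7)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  ys <- rev(seq_len(k))
  graphics::segments(fd$ci_low, ys, fd$ci_high, ys)
  graphics::points(fd$or, ys, pch = c(rep(15, k - 1), 18),
                   cex = c(0.5 + fd$weight_pct[-k] / 40, 1.5))
  invisible(x)
}
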