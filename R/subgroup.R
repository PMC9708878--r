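#' Etiology subgroup meta-analysis
#'
#' Partitions the HWE-retained corpus by disease label and pools each
#' partition independently: every subgroup gets its own heterogeneity
#' assessment, its own fixed/random model selection and its own
#' between-study variance. Single-study subgroups carry the study's own
#' Woolf estimate (heterogeneity statistics at their k = 1 conventions and
#' printed as "-").
#'
#' @inheritParams meta_analyze
#' @return An object of class `"subgroup_report"`: list with `overall` (a
#'   `meta_or`), `groups` (named list of `meta_or`, one per etiology, in
#'   order of first appearance), `contrast`, `by = "disease"`.
#' @export
#' @examples
#' sg <- subgroup_analysis(load_fixture("tgfb1_509"), "allele")
#' sapply(sg$groups, function(g) g$k)
subgroup_analysis <- function(corpus, contrast = .contrasts,
                              hwe_alpha = 0.05,
                              hwe_arm = c("control", "case", "both"),
                              model = c("auto", "fe", "re"),
                              continuity = 0.5, conf_level = 0.95) {
  contrast <- match.arg(contrast)
  hwe_arm <- match.arg(hwe_arm)
  model <- match.arg(model)
  overall <- meta_analyze(corpus, contrast, hwe_alpha = hwe_alpha,
                          hwe_arm = hwe_arm, model = model,
                          continuity = continuity, conf_level = conf_level)
  retained <- if (hwe_alpha > 0) {
    apply_hwe_filter(corpus, alpha = hwe_alpha, arm = hwe_arm)$retained
  } else corpus
  labels <- unique(retained$disease)
  groups <- list()
  for (lb in labels) {
    sub <- retained[retained$disease == lb, , drop = FALSE]
    class(sub) <- class(retained)
    groups[[lb]] <- meta_analyze(sub, contrast, hwe_alpha = 0,
                                 model = model, continuity = continuity,
                                 conf_level = conf_level)
  }
  res <- list(overall = overall, groups = groups, contrast = contrast,
              by = "disease")
  class(res) <- "subgroup_report"
  res
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat(sprintf("Subgroup analysis by %s, contrast: %s\n\n", x$by, x$contrast))
  fmt_row <- function(label, fit) {
    single <- fit$k == 1L
    cat(sprintf("  %-12s k=%2d  OR %.2f (%.2f, %.2f)  p=%s  I2=%s  p_het=%s  %s\n",
                label, fit$k, fit$or, fit$ci_low, fit$ci_high, .fmt_p(fit$p),
                if (single) "-" else sprintf("%d%%", round(fit$het$i2)),
                if (single) "-" else .fmt_p(fit$het$p_het),
                if (single) "-" else fit$model))
  }
  fmt_row("Overall", x$overall)
  for (lb in names(x$groups)) fmt_row(lb, x$groups[[lb]])
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the corpus k times, omitting one study at a time, by default
#' under the random-effects model regardless of the heterogeneity rule (the
#' conventional sensitivity procedure); `model = "auto"` re-selects the
#' model for every omission. `all_significant` is `TRUE` when every omission
#' keeps the pooled confidence interval excluding 1 on the same side as the
#' full analysis.
#'
#' @inheritParams meta_analyze
#' @param model `"re"` (default) or `"auto"`.
#' @return An object of class `"loo_report"`: `omissions` (data frame with
#'   `omitted`, `k`, `or`, `ci_low`, `ci_high`, `p`, `model`), `full` (the
#'   full-corpus `meta_or`), `all_significant`.
#' @export
leave_one_out <- function(corpus, contrast = .contrasts,
                          model = c("re", "auto"), hwe_alpha = 0.05,
                          hwe_arm = c("control", "case", "both"),
                          continuity = 0.5, conf_level = 0.95) {
  contrast <- match.arg(contrast)
  model <- match.arg(model)
  hwe_arm <- match.arg(hwe_arm)
  retained <- if (hwe_alpha > 0) {
    apply_hwe_filter(corpus, alpha = hwe_alpha, arm = hwe_arm)$retained
  } else corpus
  k <- nrow(retained)
  if (k < 2L) stop("leave-one-out needs at least 2 studies after filtering",
                   call. = FALSE)
  full <- meta_analyze(retained, contrast, hwe_alpha = 0, model = model,
                       continuity = continuity, conf_level = conf_level)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    sub <- retained[-i, , drop = FALSE]
    class(sub) <- class(retained)
    fit <- meta_analyze(sub, contrast, hwe_alpha = 0, model = model,
                        continuity = continuity, conf_level = conf_level)
    rows[[i]] <- data.frame(omitted = retained$study_id[i], k = fit$k,
                            or = fit$or, ci_low = fit$ci_low,
                            ci_high = fit$ci_high, p = fit$p,
                            model = fit$model, stringsAsFactors = FALSE)
  }
  om <- do.call(rbind, rows)
  direction <- if (full$ci_low > 1) "above" else if (full$ci_high < 1) "below" else "none"
  all_sig <- switch(direction,
                    above = all(om$ci_low > 1),
                    below = all(om$ci_high < 1),
                    none = FALSE)
  res <- list(omissions = om, full = full, all_significant = all_sig,
              direction = direction, contrast = contrast)
  class(res) <- "loo_report"
  res
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("Leave-one-out sensitivity analysis (%s contrast, %d omissions)\n",
              x$contrast, nrow(x$omissions)))
  cat(sprintf("Full fit: OR %.2f (%.2f, %.2f); every omission significant on the same side: %s\n\n",
              x$full$or, x$full$ci_low, x$full$ci_high, x$all_significant))
  om <- x$omissions
  om[c("or", "ci_low", "ci_high")] <- round(om[c("or", "ci_low", "ci_high")], 2)
  om$p <- vapply(om$p, .fmt_p, character(1))
  print(om, row.names = FALSE)
  invisible(x)
}
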