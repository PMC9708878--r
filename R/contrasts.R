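#' Genetic-model contrasts
#'
#' The five standard ways of collapsing three genotype classes (common
#' homozygote `aa`, heterozygote `ab`, variant homozygote `bb`) into a 2x2
#' exposure table:
#'
#' * `allele`: variant vs common allele counts (each individual contributes
#'   two alleles, so arm sizes double);
#' * `homozygote`: `bb` vs `aa` individuals (heterozygotes dropped);
#' * `heterozygote`: `ab` vs `aa` individuals (`bb` dropped);
#' * `dominant`: `ab + bb` vs `aa`;
#' * `recessive`: `bb` vs `aa + ab`.
#'
#' @name genetic_contrasts
#' @keywords internal
NULL

.contrasts <- c("allele", "homozygote", "heterozygote", "dominant", "recessive")

#' Build 2x2 exposure tables for a contrast
#'
#' Converts each study of a corpus into a 2x2 table `(a, b, c, d)` = (exposed
#' cases, unexposed cases, exposed controls, unexposed controls) under one
#' [genetic-model contrast][genetic_contrasts]. A study is flagged
#' non-`informative` when one column of its table is empty in both arms (for
#' instance no variant homozygote in either arm under the homozygote or
#' recessive contrast): such a table carries no information about the odds
#' ratio and is dropped by the estimators downstream.
#'
#' @param corpus A `study_corpus` (or single-row subset).
#' @param contrast One of `"allele"`, `"homozygote"`, `"heterozygote"`,
#'   `"dominant"`, `"recessive"`.
#' @return A data frame of class `"contrast_tables"` with columns `study_id`,
#'   `disease`, `a`, `b`, `c`, `d`, `unit` (`"alleles"` for the allele
#'   contrast, else `"individuals"`), `informative`.
#' @export
#' @examples
#' corp <- load_fixture("tgfb1_509")
#' head(build_contrast(corp, "allele"))
build_contrast <- function(corpus, contrast = .contrasts) {
  contrast <- match.arg(contrast)
  ca <- corpus$case_aa; cb <- corpus$case_ab; cc_ <- corpus$case_bb
  ta <- corpus$ctrl_aa; tb <- corpus$ctrl_ab; tc <- corpus$ctrl_bb
  tab <- switch(contrast,
    allele = data.frame(
      a = 2 * cc_ + cb, b = 2 * ca + cb,
      c = 2 * tc + tb,  d = 2 * ta + tb),
    homozygote = data.frame(a = cc_, b = ca, c = tc, d = ta),
    heterozygote = data.frame(a = cb, b = ca, c = tb, d = ta),
    dominant = data.frame(a = cb + cc_, b = ca, c = tb + tc, d = ta),
    recessive = data.frame(a = cc_, b = ca + cb, c = tc, d = ta + tb)
  )
  tab <- cbind(data.frame(study_id = corpus$study_id,
                          disease = corpus$disease,
                          stringsAsFactors = FALSE),
               tab)
  tab$unit <- if (contrast == "allele") "alleles" else "individuals"
  # a 2x2 with an all-zero column (exposure class or reference class empty in
  # BOTH arms) cannot inform an odds ratio
  tab$informative <- !((tab$a == 0 & tab$c == 0) | (tab$b == 0 & tab$d == 0))
  attr(tab, "contrast") <- contrast
  class(tab) <- c("contrast_tables", "data.frame")
  tab
}

#' Per-study odds ratios with Woolf confidence intervals
#'
#' Computes, for each informative 2x2 table, the log odds ratio
#' `log(ad/bc)`, its Woolf standard error `sqrt(1/a + 1/b + 1/c + 1/d)` and
#' the log-normal 95% confidence interval. If any cell of a table is zero,
#' the continuity constant (default 0.5) is added to **all four** cells of
#' that study before estimation and the study is flagged `corrected`
#' (the usual meta-analytic convention). Non-informative tables (a class
#' empty in both arms) are excluded and listed in the `"dropped"` attribute.
#'
#' @param tables A `"contrast_tables"` data frame from [build_contrast()].
#' @param continuity Continuity constant added to zero-cell studies.
#' @param conf_level Confidence level for the interval.
#' @return A data frame of class `"effect_table"`: `study_id`, `disease`,
#'   `a`..`d` (uncorrected counts), `corrected`, `log_or`, `se`, `or`,
#'   `ci_low`, `ci_high`. Attribute `"dropped"` lists excluded study ids.
#' @export
#' @examples
#' tab <- build_contrast(load_fixture("tgfb1_509"), "allele")
#' head(or_estimate(tab))
or_estimate <- function(tables, continuity = 0.5, conf_level = 0.95) {
  stopifnot(is.data.frame(tables),
            all(c("a", "b", "c", "d") %in% names(tables)))
  dropped <- tables$study_id[!tables$informative]
  eff <- tables[tables$informative, , drop = FALSE]
  if (nrow(eff) == 0L) {
    stop("no informative 2x2 tables: odds ratio undefined for every study",
         call. = FALSE)
  }
  zcell <- with(eff, pmin(a, b, c, d) == 0)
  a <- eff$a + continuity * zcell
  b <- eff$b + continuity * zcell
  c <- eff$c + continuity * zcell
  d <- eff$d + continuity * zcell
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    study_id = eff$study_id, disease = eff$disease,
    a = eff$a, b = eff$b, c = eff$c, d = eff$d,
    corrected = zcell,
    log_or = log_or, se = se, or = exp(log_or),
    ci_low = exp(log_or - zq * se), ci_high = exp(log_or + zq * se),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "contrast") <- attr(tables, "contrast")
  attr(out, "continuity") <- continuity
  attr(out, "dropped") <- as.character(dropped)
  class(out) <- c("effect_table", "data.frame")
  out
}
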