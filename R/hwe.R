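#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit test of a biallelic genotype distribution against
#' Hardy-Weinberg proportions. Expected counts are `n*p^2`, `2n*p*q`, `n*q^2`
#' from the observed allele frequencies; the statistic is the uncorrected
#' Pearson chi-square over the three genotype classes on 1 degree of freedom
#' (no Yates correction, no exact test).
#'
#' A monomorphic arm (one allele absent) has no testable departure: the
#' degenerate result `chi2 = 0, p = 1` is returned with `monomorphic = TRUE`.
#'
#' @param n_aa,n_ab,n_bb Genotype counts: common homozygotes, heterozygotes,
#'   variant homozygotes.
#' @return An object of class `"hwe_test"`: list with `chi2`, `df`, `p`,
#'   `maf` (minor-allele frequency) and `monomorphic`.
#' @export
#' @examples
#' hwe_test(212, 432, 237)  # p ~ 0.58
#' hwe_test(25, 50, 25)     # exact HWE proportions, p = 1
hwe_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(length(n_aa) == 1L, length(n_ab) == 1L, length(n_bb) == 1L,
            n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("empty arm: no individuals to test", call. = FALSE)
  b <- 2 * n_bb + n_ab     # variant-allele count
  a <- 2 * n_aa + n_ab     # common-allele count
  q <- b / (2 * n)
  maf <- min(q, 1 - q)
  if (a == 0 || b == 0) {
    res <- list(chi2 = 0, df = 1L, p = 1, maf = maf, monomorphic = TRUE)
    class(res) <- "hwe_test"
    return(res)
  }
  expected <- c(n * (1 - q)^2, 2 * n * q * (1 - q), n * q^2)
  observed <- c(n_aa, n_ab, n_bb)
  chi2 <- sum((observed - expected)^2 / expected)
  res <- list(chi2 = chi2, df = 1L,
              p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
              maf = maf, monomorphic = FALSE)
  class(res) <- "hwe_test"
  res
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE Pearson chi-square: chi2 = %.4f (df = %d), p = %.4g, MAF = %.4f%s\n",
              x$chi2, x$df, x$p, x$maf,
              if (x$monomorphic) " [monomorphic arm]" else ""))
  invisible(x)
}

#' Hardy-Weinberg study filter
#'
#' Applies the standard meta-analytic exclusion rule: a study is dropped when
#' the genotype distribution of its designated arm departs from
#' Hardy-Weinberg equilibrium at `p < alpha`. The default (control arm only,
#' `alpha = 0.05`) is the usual quality filter for case-control genetic
#' association meta-analysis; case arms may legitimately depart from HWE under
#' a true association, so they do not drive exclusion unless requested.
#' Monomorphic arms count as passing (degenerate `p = 1`).
#'
#' @param corpus A [study corpus][as_study_corpus].
#' @param alpha Exclusion threshold in (0, 1).
#' @param arm Which arm(s) must pass: `"control"` (default), `"case"`, or
#'   `"both"`.
#' @return An object of class `"hwe_filter"`: list with `retained` (a
#'   `study_corpus`), `excluded` (data frame of `study_id`, `arm`, `p`),
#'   `alpha`, `arm`, and `hwe` (per-study chi-square and p for both arms).
#' @export
#' @examples
#' flt <- apply_hwe_filter(load_fixture("tgfb1_509"))
#' nrow(flt$retained)  # 17
apply_hwe_filter <- function(corpus, alpha = 0.05,
                             arm = c("control", "case", "both")) {
  arm <- match.arg(arm)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  k <- nrow(corpus)
  hwe <- data.frame(study_id = corpus$study_id,
                    chi2_case = NA_real_, p_case = NA_real_,
                    chi2_control = NA_real_, p_control = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    hc <- hwe_test(corpus$case_aa[i], corpus$case_ab[i], corpus$case_bb[i])
    ht <- hwe_test(corpus$ctrl_aa[i], corpus$ctrl_ab[i], corpus$ctrl_bb[i])
    hwe$chi2_case[i] <- hc$chi2; hwe$p_case[i] <- hc$p
    hwe$chi2_control[i] <- ht$chi2; hwe$p_control[i] <- ht$p
  }
  fails_control <- hwe$p_control < alpha
  fails_case <- hwe$p_case < alpha
  drop <- switch(arm,
                 control = fails_control,
                 case = fails_case,
                 both = fails_control | fails_case)
  excl_arm <- character(sum(drop))
  excl_p <- numeric(sum(drop))
  idx <- which(drop)
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (arm != "case" && fails_control[i]) {
      excl_arm[j] <- "control"; excl_p[j] <- hwe$p_control[i]
    } else {
      excl_arm[j] <- "case"; excl_p[j] <- hwe$p_case[i]
    }
  }
  retained <- corpus[!drop, , drop = FALSE]
  attr(retained, "provenance") <- attr(corpus, "provenance")
  class(retained) <- class(corpus)
  res <- list(
    retained = retained,
    excluded = data.frame(study_id = corpus$study_id[drop],
                          arm = excl_arm, p = excl_p,
                          stringsAsFactors = FALSE),
    alpha = alpha, arm = arm, hwe = hwe
  )
  class(res) <- "hwe_filter"
  res
}

#' @export
print.hwe_filter <- function(x, ...) {
  cat(sprintf("HWE filter (arm = %s, alpha = %g): %d retained, %d excluded\n",
              x$arm, x$alpha, nrow(x$retained), nrow(x$excluded)))
  if (nrow(x$excluded) > 0L) {
    cat("Excluded:\n")
    print(x$excluded, row.names = FALSE)
  }
  invisible(x)
}
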