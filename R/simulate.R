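#' Configuration for simulated study corpora
#'
#' Bundles the generative parameters of [simulate_corpus()]. The generator
#' works on the genotype scale: controls follow a (possibly HWE-departing)
#' genotype distribution given by the variant-allele frequency `q` and the
#' inbreeding coefficient `f`; cases reweight the control distribution by
#' genotype-level odds ratios `or_het` / `or_hom` (heterozygote and variant
#' homozygote vs common homozygote). Between-study heterogeneity is a shared
#' normal shift on the log odds of both variant genotypes, so the study-level
#' log odds ratios are Normal with variance `tau2` — exactly the model
#' random-effects pooling assumes.
#'
#' @param k Number of studies.
#' @param q Control variant-allele frequency, in (0, 1).
#' @param f Inbreeding coefficient (0 = exact HWE in controls).
#' @param or_het,or_hom Genotype-level odds ratios (> 0).
#' @param tau2 Between-study variance of the log-OR shift (>= 0).
#' @param n_case_range,n_control_range Inclusive integer ranges for arm sizes.
#' @param disease_labels Optional vector of etiology labels recycled over
#'   studies (for subgroup simulations).
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(k = 15L, q = 0.3, f = 0,
                             or_het = 1, or_hom = 1, tau2 = 0,
                             n_case_range = c(100L, 400L),
                             n_control_range = c(100L, 400L),
                             disease_labels = NULL, seed = 1L) {
  stopifnot(k >= 1L, q > 0, q < 1, or_het > 0, or_hom > 0, tau2 >= 0,
            length(n_case_range) == 2L, length(n_control_range) == 2L,
            n_case_range[1] >= 1, n_case_range[2] >= n_case_range[1],
            n_control_range[1] >= 1, n_control_range[2] >= n_control_range[1])
  # f must keep all three genotype probabilities non-negative
  pr <- control_genotype_probs(q, f)
  cfg <- list(k = as.integer(k), q = q, f = f, or_het = or_het,
              or_hom = or_hom, tau2 = tau2,
              n_case_range = as.integer(n_case_range),
              n_control_range = as.integer(n_control_range),
              disease_labels = disease_labels, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Control-arm genotype probabilities
#'
#' Genotype distribution for a biallelic locus with variant-allele frequency
#' `q` under the inbreeding parameterization of HWE departure:
#' `P(aa) = (1-q)^2 + f q (1-q)`, `P(ab) = 2 q (1-q) (1-f)`,
#' `P(bb) = q^2 + f q (1-q)`. `f = 0` is exact HWE; `f > 0` depletes
#' heterozygotes.
#'
#' @param q Variant-allele frequency in (0, 1).
#' @param f Inbreeding coefficient.
#' @return Numeric vector `c(aa, ab, bb)` summing to 1.
#' @export
#' @examples
#' control_genotype_probs(0.5, 0)  # 0.25 0.50 0.25
control_genotype_probs <- function(q, f = 0) {
  stopifnot(q > 0, q < 1)
  p <- 1 - q
  probs <- c(aa = p^2 + f * p * q,
             ab = 2 * p * q * (1 - f),
             bb = q^2 + f * p * q)
  if (any(probs < 0) || any(probs > 1)) {
    stop("inbreeding coefficient f = ", f,
         " gives genotype probabilities outside [0, 1] at q = ", q,
         call. = FALSE)
  }
  probs
}

#' Case-arm genotype probabilities
#'
#' Reweights a control genotype distribution by genotype-level odds ratios:
#' the unnormalized case weights are `P(aa)`, `P(ab) * or_het * exp(shift)`,
#' `P(bb) * or_hom * exp(shift)`, renormalized to sum to 1. With unit odds
#' ratios and zero shift the case distribution equals the control
#' distribution.
#'
#' @param control_probs Vector `c(aa, ab, bb)` of control probabilities.
#' @param or_het,or_hom Genotype-level odds ratios.
#' @param shift Study-level log-OR shift (between-study heterogeneity).
#' @return Numeric vector `c(aa, ab, bb)` summing to 1.
#' @export
case_genotype_probs <- function(control_probs, or_het = 1, or_hom = 1,
                                shift = 0) {
  stopifnot(length(control_probs) == 3L, all(control_probs >= 0),
            abs(sum(control_probs) - 1) < 1e-8)
  w <- control_probs * c(1, or_het * exp(shift), or_hom * exp(shift))
  w / sum(w)
}

#' Expected log odds ratio of a contrast under a generator configuration
#'
#' The ground-truth effect implied by a [synthetic_config()] at a given study
#' shift: the expected 2x2 cell probabilities are built from the control and
#' case genotype distributions and collapsed under the requested contrast,
#' and `log(ad/bc)` of those expectations is returned. Used as the truth in
#' parameter-recovery checks.
#'
#' @param config A `synthetic_config`.
#' @param contrast A [genetic-model contrast][genetic_contrasts] label.
#' @param shift Study-level log-OR shift (default 0, the ensemble mean).
#' @return The expected log odds ratio (scalar).
#' @export
expected_contrast_log_or <- function(config, contrast = .contrasts,
                                     shift = 0) {
  contrast <- match.arg(contrast)
  ctrl <- control_genotype_probs(config$q, config$f)
  case <- case_genotype_probs(ctrl, config$or_het, config$or_hom, shift)
  cells <- switch(contrast,
    allele = c(a = case[3] + case[2] / 2, b = case[1] + case[2] / 2,
               c = ctrl[3] + ctrl[2] / 2, d = ctrl[1] + ctrl[2] / 2),
    homozygote = c(a = case[3], b = case[1], c = ctrl[3], d = ctrl[1]),
    heterozygote = c(a = case[2], b = case[1], c = ctrl[2], d = ctrl[1]),
    dominant = c(a = case[2] + case[3], b = case[1],
                 c = ctrl[2] + ctrl[3], d = ctrl[1]),
    recessive = c(a = case[3], b = case[1] + case[2],
                  c = ctrl[3], d = ctrl[1] + ctrl[2])
  )
  unname(log(cells[1] * cells[4] / (cells[2] * cells[3])))
}

#' Simulate a case-control genotype-count corpus
#'
#' Draws `k` studies: arm sizes uniform over the configured ranges, a
#' study-level shift from `Normal(0, tau2)`, and genotype counts from the
#' three-class multinomial in each arm. The random stream is split
#' deterministically per study (a sub-seed sequence drawn up front), so the
#' same seed always reproduces the same corpus and appending studies does not
#' perturb earlier ones.
#'
#' @param config A [synthetic_config()].
#' @return A [study corpus][as_study_corpus] with `polymorphism =
#'   "synthetic"` and study ids `sim_001`, `sim_002`, ...
#' @export
#' @examples
#' corp <- simulate_corpus(synthetic_config(k = 5, seed = 42))
#' aggregate_counts(corp)
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ctrl_probs <- control_genotype_probs(config$q, config$f)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)
  study_seeds <- sample.int(.Machine$integer.max - 1L, config$k)
  rows <- vector("list", config$k)
  for (i in seq_len(config$k)) {
    set.seed(study_seeds[i])
    n_case <- sample(config$n_case_range[1]:config$n_case_range[2], 1L)
    n_ctrl <- sample(config$n_control_range[1]:config$n_control_range[2], 1L)
    shift <- if (config$tau2 > 0) stats::rnorm(1, 0, sqrt(config$tau2)) else 0
    case_probs <- case_genotype_probs(ctrl_probs, config$or_het,
                                      config$or_hom, shift)
    g_case <- as.integer(stats::rmultinom(1, n_case, case_probs))
    g_ctrl <- as.integer(stats::rmultinom(1, n_ctrl, ctrl_probs))
    rows[[i]] <- data.frame(
      study_id = sprintf("sim_%03d", i),
      polymorphism = "synthetic",
      disease = if (is.null(config$disease_labels)) "SIM" else
        config$disease_labels[((i - 1L) %% length(config$disease_labels)) + 1L],
      n_case = n_case, n_control = n_ctrl,
      case_aa = g_case[1], case_ab = g_case[2], case_bb = g_case[3],
      ctrl_aa = g_ctrl[1], ctrl_ab = g_ctrl[2], ctrl_bb = g_ctrl[3],
      allele_common = "A", allele_variant = "B",
      stringsAsFactors = FALSE
    )
  }
  as_study_corpus(do.call(rbind, rows),
                  provenance = sprintf("simulated (seed %d)", config$seed))
}
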