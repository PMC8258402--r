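#' Default per-outcome marginal parameters for simulated cohorts
#'
#' Mean and SD of the Gaussian marginals used for per-subject morphometry
#' summaries, anchored to the cohort the generator emulates (median LSA
#' count 8, median vessel length 17.8 mm with IQR 16.0-20.5). The SD
#' column doubles as `noise_sd`: injected standardized effects are
#' multiples of it.
#'
#' @return data.frame with columns `outcome`, `mean`, `sd`.
#' @export
default_outcome_marginals <- function() {
  data.frame(
    outcome = c("vl_mean", "vl_median", "vl_sd",
                "dm_mean", "dm_median", "dm_sd",
                "vti_mean", "vti_median", "vti_sd"),
    mean = c(18.5, 17.8, 4.0, 1.20, 1.18, 0.08, 2.3, 2.0, 0.9),
    sd   = c(3.3, 3.3, 1.0, 0.08, 0.08, 0.03, 0.7, 0.7, 0.3))
}

#' Default artery-diameter marginals (mm)
#' @return data.frame with columns `artery`, `mean`, `sd`.
#' @export
default_diameter_marginals <- function() {
  data.frame(artery = c("ica", "ba", "aca", "mca", "pca"),
             mean = c(4.5, 3.2, 2.1, 2.8, 2.1),
             sd = c(0.5, 0.4, 0.3, 0.3, 0.3))
}

#' Configure a simulated cohort
#'
#' Bundles sample size, risk-factor prevalences, standardized effect
#' sizes, diameter-outcome rank-correlation targets and a seed into a
#' validated configuration for [generate_cohort()].
#'
#' Defaults emulate the reference cohort: n = 125, prevalences 40.8%
#' (hypertension), 15.2% (diabetes), 14.4% (hyperlipidemia), 28.8%
#' (smoking); smokers get shorter and straighter LSAs, hypertensives
#' lower VTI; the MCA diameter correlates positively with LSA count and
#' negatively with median VTI; the PCA diameter correlates positively
#' with tortuosity and length summaries.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param prevalences Named probabilities in `[0, 1]` for hypertension,
#'   diabetes, hyperlipidemia, smoking.
#' @param effect_sizes Named list: one entry per risk factor, each a
#'   named vector of standardized mean differences (in units of the
#'   outcome's `noise_sd`) applied additively to subjects carrying the
#'   factor.
#' @param diameter_correlations Named list: one entry per artery, each a
#'   named vector of target Spearman correlations with outcomes
#'   (including `lsa_count`), induced via a Gaussian copula on ranks.
#' @param noise_sd Optional named overrides of outcome SDs.
#' @param seed Integer seed; the whole table is reproducible from it.
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(n_subjects = 125L,
                          prevalences = c(hypertension = 0.408,
                                          diabetes = 0.152,
                                          hyperlipidemia = 0.144,
                                          smoking = 0.288),
                          effect_sizes = list(
                            smoking = c(vl_median = -0.5, dm_median = -0.5,
                                        vti_median = -0.55),
                            hypertension = c(vti_median = -0.4)),
                          diameter_correlations = list(
                            mca = c(lsa_count = 0.278, vti_median = -0.252),
                            pca = c(dm_median = 0.317, vti_mean = 0.333,
                                    vl_mean = 0.274, vl_median = 0.306)),
                          noise_sd = NULL,
                          seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (any(prevalences < 0 | prevalences > 1))
    stop("prevalences must be probabilities in [0, 1]")
  marg <- default_outcome_marginals()
  outcomes <- c(marg$outcome, "lsa_count")
  for (rf in names(effect_sizes))
    if (!all(names(effect_sizes[[rf]]) %in% outcomes))
      stop("unknown outcome in effect_sizes for ", rf)
  for (a in names(diameter_correlations)) {
    if (!a %in% default_diameter_marginals()$artery)
      stop("unknown artery in diameter_correlations: ", a)
    if (!all(names(diameter_correlations[[a]]) %in% outcomes))
      stop("unknown outcome in diameter_correlations for ", a)
    if (any(abs(diameter_correlations[[a]]) >= 1))
      stop("correlation targets must lie in (-1, 1)")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 prevalences = prevalences, effect_sizes = effect_sizes,
                 diameter_correlations = diameter_correlations,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "effect_config")
}

#' Null cohort configuration
#'
#' Convenience wrapper: all effect sizes and correlation targets zeroed,
#' for type-I-error calibration runs.
#'
#' @inheritParams effect_config
#' @return An `effect_config`.
#' @export
null_effect_config <- function(n_subjects = 125L, seed = 1L) {
  effect_config(n_subjects = n_subjects, effect_sizes = list(),
                diameter_correlations = list(), seed = seed)
}

# truncated-normal draws via inverse CDF
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a simulated cohort table
#'
#' Draws a per-subject cohort emulating a community-dwelling elderly
#' sample: demographics (age truncated-normal 59.9 +/- 7.1 on [50, 82],
#' balanced sex, education, ICV), independent Bernoulli risk factors,
#' artery diameters, CSVD markers, and per-subject morphometry
#' summaries. Diameter-outcome dependence is induced with a Gaussian
#' copula whose latent Pearson correlations are chosen so the target
#' Spearman values hold (r_latent = 2 sin(pi r_s / 6)); risk-factor
#' effects are then added on the subject-level summaries as multiples of
#' each outcome's SD.
#'
#' @param config An [effect_config()].
#' @return A `data.frame` cohort table, one row per subject, with the
#'   columns required by [run_full_analysis()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "effect_config"))
  n <- config$n_subjects
  set.seed(config$seed)
  marg <- default_outcome_marginals()
  if (!is.null(config$noise_sd)) {
    i <- match(names(config$noise_sd), marg$outcome)
    if (anyNA(i)) stop("noise_sd names must be outcome names")
    marg$sd[i] <- config$noise_sd
  }
  diam <- default_diameter_marginals()
  vars <- c(diam$artery, marg$outcome, "lsa_count")
  p <- length(vars)
  # latent correlation matrix from Spearman targets
  R <- diag(p)
  for (a in names(config$diameter_correlations)) {
    tv <- config$diameter_correlations[[a]]
    i <- match(a, vars)
    j <- match(names(tv), vars)
    R[i, j] <- R[j, i] <- 2 * sin(pi * tv / 6)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("infeasible correlation targets: latent matrix not positive definite")
  Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
  U <- stats::pnorm(Z)
  colnames(U) <- vars

  tab <- data.frame(id = sprintf("sub%03d", seq_len(n)))
  tab$age <- .rtnorm(n, 59.9, 7.1, 50, 82)
  tab$sex <- stats::rbinom(n, 1L, 0.5)          # 1 = female
  tab$education <- pmax(0, stats::rnorm(n, 7.6, 4.0))
  tab$icv <- stats::rnorm(n, 1450, 130)
  for (rf in names(config$prevalences))
    tab[[rf]] <- stats::rbinom(n, 1L, config$prevalences[[rf]])
  for (k in seq_len(nrow(diam)))
    tab[[diam$artery[k]]] <- stats::qnorm(U[, diam$artery[k]],
                                          diam$mean[k], diam$sd[k])
  # CSVD markers: mild burden (median WMH 1.5 mL, IQR 0.8-2.8; mostly
  # zero lacunes/microbleeds; low ordinal PVS scores)
  tab$wmh_volume <- stats::qlnorm(stats::runif(n), log(1.5), 0.92)
  tab$pvs_bg <- sample(0:4, n, replace = TRUE,
                       prob = c(0.15, 0.55, 0.2, 0.07, 0.03))
  tab$pvs_dwm <- sample(0:4, n, replace = TRUE,
                        prob = c(0.1, 0.5, 0.3, 0.07, 0.03))
  tab$lacune_count <- stats::rpois(n, 0.15)
  tab$microbleed_count <- stats::rpois(n, 0.15)

  # morphometry summaries: copula marginals ...
  for (k in seq_len(nrow(marg)))
    tab[[marg$outcome[k]]] <- stats::qnorm(U[, marg$outcome[k]],
                                           marg$mean[k], marg$sd[k])
  # discrete LSA count: median 8, IQR ~7-9
  count_latent <- stats::qnorm(U[, "lsa_count"], 8, 1.6)
  # ... plus additive risk-factor effects in units of the outcome SD
  for (rf in names(config$effect_sizes)) {
    es <- config$effect_sizes[[rf]]
    for (oc in names(es)) {
      if (oc == "lsa_count") {
        count_latent <- count_latent + es[[oc]] * 1.6 * tab[[rf]]
      } else {
        sd_oc <- marg$sd[match(oc, marg$outcome)]
        tab[[oc]] <- tab[[oc]] + es[[oc]] * sd_oc * tab[[rf]]
      }
    }
  }
  tab$lsa_count <- pmax(1L, as.integer(round(count_latent)))
  tab$vti_mean <- pmax(0, tab$vti_mean)
  tab$vti_median <- pmax(0, tab$vti_median)
  tab$vti_sd <- pmax(0, tab$vti_sd)
  tab$dm_mean <- pmax(1, tab$dm_mean)
  tab$dm_median <- pmax(1, tab$dm_median)
  tab
}
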