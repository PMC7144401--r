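.group_params <- list(
  female_prob = c(HC = 0.61, OB = 0.79, DEP = 0.44, OBDEP = 0.72),
  age_mean = c(HC = 34, OB = 39, DEP = 38, OBDEP = 41),
  bmi_mean = c(HC = 24, OB = 43, DEP = 24, OBDEP = 45),
  bmi_sd = c(HC = 2.9, OB = 7.5, DEP = 3, OBDEP = 8.9),
  bdi_mean = c(HC = 4.4, OB = 5.4, DEP = 24, OBDEP = 24),
  bdi_sd = c(HC = 4.5, OB = 4.0, DEP = 8.2, OBDEP = 8.8),
  ssd_mean = c(HC = 432, OB = 427, DEP = 462, OBDEP = 436)
)

# inverse-CDF truncated normal: a fixed number of uniforms per call keeps the
# generator's RNG stream length deterministic
rtnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

clampi <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

#' Simulate a full sleepiness cohort
#'
#' Generates one subject per simulated individual: demographics (age,
#' gender), BMI and BDI-II drawn consistently with the subject's subgroup
#' (obese iff BMI >= 30, depressed iff BDI-II >= 14, so the group label is
#' recomputable via [classify_group()]), all questionnaire instruments, a
#' latent per-second vigilance trajectory, and the objective arousal
#' summaries of that trajectory.
#'
#' The generative model: a standard-normal latent sleepiness trait per
#' subject loads (with correlation `coupling`) on the latent response of
#' every sleepiness instrument, and tilts the vigilance trajectory's Markov
#' drift toward lower stages (see [sim_config()]).  Group effects enter as
#' additive shifts on the questionnaire latents (depressed groups report
#' more sleepiness at equal trait).  ASLEEP — the self-report of having
#' fallen asleep — is an ordinal discretization of a latent that mixes the
#' trajectory's true drowsy/sleep time share (weight `coupling`) with noise.
#' Raw EEG is not synthesized here; pass any subject's `trajectory` to
#' [synthesize_recording()] when signal-level analysis is needed.
#'
#' Deterministic given `config$seed` (bitwise-identical cohorts).
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (tibble, one row per subject:
#'   demographics, raw questionnaire items, scored instruments, group label,
#'   arousal summaries) and `ground_truth` (tibble with `id`, `trait`,
#'   `group` and a `trajectory` list-column; for generator validation only —
#'   the analysis functions never consume it).
#' @examples
#' sim <- simulate_cohort(sim_config(group_sizes = c(HC = 3, OB = 3,
#'                                                   DEP = 3, OBDEP = 3),
#'                                   duration = 120, seed = 7))
#' dim(sim$cohort)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- config$group_sizes
  groups <- factor(rep(names(sizes), times = sizes),
                   levels = c("HC", "OB", "DEP", "OBDEP"))
  n <- length(groups)
  if (n == 0L) {
    empty <- tibble::tibble(id = character())
    return(list(cohort = empty,
                ground_truth = tibble::tibble(id = character(),
                                              trait = numeric())))
  }
  gp <- .group_params
  g <- as.character(groups)
  cpl <- config$coupling
  shift <- unname(config$group_effects[g])

  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  trait <- rnorm(n)
  gender <- ifelse(rbinom(n, 1, gp$female_prob[g]) == 1, "female", "male")
  age <- clampi(rtnorm(n, gp$age_mean[g], 12.5, 18, 70), 18, 70)
  obese <- g %in% c("OB", "OBDEP")
  bmi <- round(rtnorm(n, gp$bmi_mean[g], gp$bmi_sd[g],
                      ifelse(obese, 30, 17), ifelse(obese, 75, 29.9)), 1)
  depressed <- g %in% c("DEP", "OBDEP")
  bdi <- clampi(rtnorm(n, gp$bdi_mean[g], gp$bdi_sd[g],
                       ifelse(depressed, 14, 0), ifelse(depressed, 55, 13.4)),
                0, 63)

  # latent questionnaire responses: shared trait loading + independent noise
  resid <- sqrt(1 - cpl^2)
  latent <- function() cpl * trait + resid * rnorm(n)
  kss_pre <- clampi(3.4 + 1.6 * (latent() + shift), 1, 10)
  kss_post <- clampi(3.4 + 1.6 * (latent() + 0.6 * shift), 1, 10)
  sss_pre <- clampi(2.1 + 1.0 * (latent() + shift), 1, 7)
  sss_post <- clampi(2.1 + 1.0 * (latent() + 0.6 * shift), 1, 7)
  vas_pre <- clampi(30 + 24 * latent() + 16 * shift, 0, 100)
  vas_post <- clampi(30 + 24 * latent() + 10 * shift, 0, 100)
  ess_items <- matrix(0L, n, 8)
  for (j in 1:8) {
    ess_items[, j] <- clampi(1.0 + 0.35 * (cpl * trait + shift) +
                               0.9 * rnorm(n), 0, 3)
  }
  rest_items <- matrix(0L, n, 8)
  for (j in 1:8) {
    rest_items[, j] <- clampi(3.3 - 0.5 * (cpl * trait + shift) +
                                0.8 * rnorm(n), 1, 5)
  }
  ssd <- clampi(rnorm(n, gp$ssd_mean[g], 75), 120, 780)
  asleep_noise <- rnorm(n)

  trajectories <- lapply(seq_len(n), function(i) {
    simulate_vigilance_trajectory(config, trait = trait[i],
                                  seed = subject_seeds[i])
  })
  summaries <- dplyr::bind_rows(lapply(trajectories, arousal_summary))

  # ASLEEP: discretized mix of the true drowsy/sleep-onset time share and
  # noise; at coupling = 0 it is pure noise (null of no objective link)
  p_bc <- summaries$prop_b + summaries$prop_c
  z_bc <- if (n > 1 && sd(p_bc) > 0) as.numeric(scale(p_bc)) else rep(0, n)
  z_asleep <- cpl * z_bc + resid * asleep_noise
  asleep <- 4L - findInterval(z_asleep, c(-0.1, 0.385, 1.13))

  ids <- sprintf("S%03d", seq_len(n))
  cohort <- tibble::tibble(
    id = ids, group = groups, age = age, gender = gender,
    bmi = bmi, bdi = bdi
  )
  colnames(ess_items) <- paste0("ess_", 1:8)
  colnames(rest_items) <- paste0("rest_", 1:8)
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(ess_items),
                             tibble::as_tibble(rest_items))
  ess <- score_ess(ess_items)
  cohort$ess_total <- ess$ess_total
  cohort$eds <- ess$eds
  cohort$ssq <- compute_ssq(rest_items)
  cohort$kss_pre <- kss_pre; cohort$kss_post <- kss_post
  cohort$sss_pre <- sss_pre; cohort$sss_post <- sss_post
  cohort$vas_pre <- vas_pre; cohort$vas_post <- vas_post
  cohort$d_kss <- delta_scores(kss_pre, kss_post, "kss")
  cohort$d_sss <- delta_scores(sss_pre, sss_post, "sss")
  cohort$d_vas <- delta_scores(vas_pre, vas_post, "vas")
  cohort$asleep <- asleep
  cohort$ssd <- ssd
  cohort <- dplyr::bind_cols(cohort, summaries)

  stopifnot(identical(as.character(classify_group(cohort$bmi, cohort$bdi)),
                      as.character(cohort$group)))
  list(
    cohort = cohort,
    ground_truth = tibble::tibble(id = ids, trait = trait, group = groups,
                                  seed = subject_seeds,
                                  trajectory = trajectories)
  )
}
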