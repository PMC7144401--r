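#' Default per-second stage transition model
#'
#' First-order Markov chain over the seven vigilance stages ordered from
#' highest arousal (`0`) to sleep onset (`C`).  Rows are current stage,
#' columns the next second's stage.  The default favours staying in place
#' with a mild net downward drift (downward steps slightly more likely than
#' upward), entry into C is rare and C is left quickly, emulating the shallow
#' sleep-onset episodes seen in 20-minute eyes-closed recordings.
#'
#' @return 7 x 7 row-stochastic matrix with stage dimnames.
#' @export
default_transition_matrix <- function() {
  st <- vigilance_stages()
  m <- matrix(0, 7, 7, dimnames = list(st, st))
  for (i in 1:7) {
    stay <- 0.95; down <- 0.03; up <- 0.02
    if (i == 1) { stay <- 0.97; up <- 0 }                 # stage 0: top
    if (i == 6) { stay <- 0.955; down <- 0.005; up <- 0.04 } # B2/3 -> C rare
    if (i == 7) { stay <- 0.85; down <- 0; up <- 0.15 }   # C is shallow
    m[i, i] <- stay
    if (i < 7) m[i, i + 1] <- down
    if (i > 1) m[i, i - 1] <- up
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  m
}

#' Default initial stage distribution
#'
#' Recordings start awake: probability mass on stage 0 and the A stages.
#' @return named probability vector over the seven stages.
#' @export
default_initial_probs <- function() {
  p <- c(0.25, 0.45, 0.15, 0.07, 0.08, 0, 0)
  names(p) <- vigilance_stages()
  p / sum(p)
}

#' Configuration for the synthetic sleepiness cohort generator
#'
#' Bundles every tunable of the simulator: cohort composition, recording
#' geometry, the latent Markov vigilance-trajectory model, the coupling
#' between the latent sleepiness trait and both the trajectory drift and the
#' questionnaire responses, group-level questionnaire shifts, and the
#' microvolt amplitudes of each synthesized EEG feature.
#'
#' The latent model: each subject carries a standard-normal trait
#' (higher = sleepier).  The trait tilts the per-second transition matrix —
#' downward transition weights are multiplied by
#' `exp(drift_scale * coupling * trait)` and upward weights by its inverse —
#' and loads on every questionnaire's latent response with correlation
#' `coupling`.  `coupling = 0` severs both links (the null of no
#' subjective-objective association); `coupling = 1` makes the questionnaire
#' latents equal to the trait.
#'
#' @param group_sizes named integer vector of subjects per subgroup
#'   (defaults 66/68/16/43 for HC/OB/DEP/OBDEP).
#' @param duration recording length in seconds (default 1200 = 20 min).
#' @param sampling_rate sampling rate in Hz (default 200; 1000 supported).
#' @param transition_matrix 7 x 7 row-stochastic per-second transition
#'   matrix; rows must sum to 1 within 1e-12.
#' @param initial_probs initial stage distribution.
#' @param coupling subjective-objective coupling in \[-1, 1\] (default 0.5).
#' @param drift_scale log-scale strength of the trait's tilt on the
#'   transition matrix (default 0.6 per trait SD).
#' @param group_effects named numeric vector of additive sleepiness shifts
#'   (in trait SD units) applied to the questionnaire latents per group.
#' @param noise_scales named list of synthesis amplitudes in microvolts:
#'   `background` (Gaussian sd per scalp channel), `alpha` (dominant-region
#'   alpha burst), `alpha_other` (alpha elsewhere), `delta`, `theta` (B2/3
#'   slow-wave components), `spindle`, `kcomplex`, `sem` (EOG deflection).
#' @param seed integer root seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(group_sizes = c(HC = 66, OB = 68, DEP = 16, OBDEP = 43),
                       duration = 1200,
                       sampling_rate = 200,
                       transition_matrix = default_transition_matrix(),
                       initial_probs = default_initial_probs(),
                       coupling = 0.5,
                       drift_scale = 0.6,
                       group_effects = c(HC = 0, OB = 0.15,
                                         DEP = 0.9, OBDEP = 1.1),
                       noise_scales = list(background = 5, alpha = 30,
                                           alpha_other = 6, delta = 20,
                                           theta = 20, spindle = 25,
                                           kcomplex = 45, sem = 100),
                       seed = 1L) {
  if (any(group_sizes < 0)) abort("group sizes must be >= 0")
  if (duration <= 0 || sampling_rate <= 0) {
    abort("duration and sampling_rate must be positive")
  }
  if (!is.matrix(transition_matrix) ||
      !all(dim(transition_matrix) == c(7, 7)) ||
      any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    abort("transition_matrix must be 7 x 7 with rows summing to 1 (1e-12)")
  }
  if (abs(sum(initial_probs) - 1) > 1e-12 || any(initial_probs < 0)) {
    abort("initial_probs must be a probability vector over the 7 stages")
  }
  if (coupling < -1 || coupling > 1) abort("coupling must lie in [-1, 1]")
  structure(
    list(group_sizes = group_sizes, duration = duration,
         sampling_rate = sampling_rate,
         transition_matrix = transition_matrix,
         initial_probs = initial_probs,
         coupling = coupling, drift_scale = drift_scale,
         group_effects = group_effects, noise_scales = noise_scales,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default 10-20 montage of the simulator
#'
#' Twelve scalp channels spanning the frontal, temporal-parietal and
#' occipital regions, plus one EOG channel.
#'
#' @return tibble with columns `channel` and `region`.
#' @export
default_montage <- function() {
  tibble::tibble(
    channel = c("Fp1", "F3", "Fz", "F4", "C3", "Cz", "C4",
                "P3", "Pz", "P4", "O1", "O2", "EOG"),
    region = c(rep("frontal", 4), rep("temporal-parietal", 6),
               rep("occipital", 2), "eog")
  )
}
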