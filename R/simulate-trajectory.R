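#' Tilt a transition matrix toward lower stages
#'
#' Multiplies each row's downward-step weights by
#' `exp(drift_scale * coupling * trait)` and the upward weights by the
#' inverse, then renormalizes, so a sleepier latent trait produces a
#' monotonically stronger drift toward drowsiness and sleep onset.
#'
#' @param transition_matrix 7 x 7 row-stochastic matrix.
#' @param tilt log-scale tilt (`drift_scale * coupling * trait`).
#' @return tilted row-stochastic matrix.
#' @keywords internal
tilt_transition_matrix <- function(transition_matrix, tilt) {
  if (tilt == 0) return(transition_matrix)
  m <- transition_matrix
  for (i in 1:7) {
    w <- m[i, ]
    j <- seq_len(7)
    w[j > i] <- w[j > i] * exp(tilt)
    w[j < i] <- w[j < i] * exp(-tilt)
    m[i, ] <- w / sum(w)
  }
  m
}

#' Simulate a latent vigilance trajectory
#'
#' Draws a per-second stage sequence from the configured first-order Markov
#' chain, with the subject's latent sleepiness trait tilting the transition
#' probabilities toward lower stages (see [sim_config()]).  Deterministic
#' given `seed`.
#'
#' @param config a [sim_config()].
#' @param trait latent sleepiness trait in SD units (0 = cohort average).
#' @param seed integer seed.
#' @return a [stage_sequence()] of `config$duration` seconds, no artifacts.
#' @examples
#' cfg <- sim_config(duration = 120)
#' simulate_vigilance_trajectory(cfg, trait = 0, seed = 1)
#' @export
simulate_vigilance_trajectory <- function(config, trait = 0, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$duration < 60) abort("duration must be at least 60 seconds")
  m <- tilt_transition_matrix(config$transition_matrix,
                              config$drift_scale * config$coupling * trait)
  cum <- t(apply(m, 1, cumsum))
  cum_init <- cumsum(config$initial_probs)
  n <- as.integer(config$duration)
  out <- integer(n)
  set.seed(seed)
  u <- runif(n)
  out[1] <- findInterval(u[1], cum_init) + 1L
  for (t in 2:n) {
    out[t] <- findInterval(u[t], cum[out[t - 1L], ]) + 1L
  }
  stage_sequence(vigilance_stages()[out])
}
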