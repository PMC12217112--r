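# Shared fixtures: all data are generated in code at test time.

# A 3-ward table with a bit of everything: wins both ways and ties.
tiny_table <- function() {
  wins <- matrix(0L, 3, 3)
  wins[1, 2] <- 2L
  wins[2, 1] <- 1L
  wins[1, 3] <- 1L
  ties <- matrix(0L, 3, 3)
  ties[1, 2] <- ties[2, 1] <- 1L
  ties[2, 3] <- ties[3, 2] <- 2L
  comparison_table(wins, ties, ward_labels = c("A", "B", "C"))
}

# Random small table simulated from the model.
random_table <- function(n_wards = 4, n_comparisons = 30, delta = 0.4,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lambda <- stats::rnorm(n_wards)
  names(lambda) <- paste0("w", seq_len(n_wards))
  simulate_comparisons(lambda, delta, n_comparisons)
}

# Independent likelihood oracle: brute-force product of per-outcome
# probabilities over unordered pairs, one factor per observed outcome.
brute_force_loglik <- function(data, lambda, delta) {
  total <- 0
  for (i in seq_len(data$n_wards - 1)) {
    for (j in (i + 1):data$n_wards) {
      p <- outcome_probabilities(lambda[i], lambda[j], delta)
      if (data$wins[i, j] > 0) {
        total <- total + data$wins[i, j] * log(p$p_i_beats_j)
      }
      if (data$wins[j, i] > 0) {
        total <- total + data$wins[j, i] * log(p$p_j_beats_i)
      }
      if (data$ties[i, j] > 0) {
        total <- total + data$ties[i, j] * log(p$p_tie)
      }
    }
  }
  total
}

# Short sampler settings for smoke-level fits.
quick_config <- function(seed = 1, ...) {
  sampler_config(n_iterations = 400, burn_in = 100, seed = seed, ...)
}
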