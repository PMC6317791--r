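# Shared fixtures: small weight builders, synthetic trial records, and a
# cache of simulated trials reused across test files.

gaussian_weights_for_test <- function(n_pre, n_post, sigma, amplitude) {
  i <- seq_len(n_pre) / n_pre
  j <- seq_len(n_post) / n_post
  amplitude * exp(-(outer(i, j, "-") / sigma)^2)
}

# Minimal synthetic trial record for analysis-level tests (no simulation).
fake_trial_record <- function(eye, target = rep(0, length(eye)),
                              mln_sum = NULL, kind = "none", strength = 1,
                              seed = 1, task = "smooth_pursuit", fs = 400) {
  n <- length(eye)
  if (is.null(mln_sum)) mln_sum <- rnorm(n)
  structure(list(time = (seq_len(n) - 1) / fs, eye = eye, target = target,
                 distractor = rep(NA_real_, n), mln_sum = mln_sum,
                 p_t = matrix(1, 1, n),
                 raster = data.frame(time = numeric(0), pop = character(0),
                                     neuron = integer(0)),
                 task = list(kind = task, duration = n / fs),
                 perturbation = list(kind = kind, strength = strength),
                 seed = seed, record_rate = fs),
            class = "trial_record")
}

# Trial cache: full 8 s trials are expensive, so each (task, kind, strength,
# seed) cell is simulated once and reused by every test that needs it.
.trial_cache <- new.env(parent = emptyenv())

cached_trial <- function(task = "smooth_pursuit", kind = "none",
                         strength = 1, seed = 1) {
  key <- paste(task, kind, strength, seed, sep = "|")
  if (!exists(key, envir = .trial_cache)) {
    perturb <- if (kind == "none") perturbation_spec("none")
               else perturbation_spec(kind, strength)
    assign(key, run_trial(task_spec(task), perturb, seed = seed),
           envir = .trial_cache)
  }
  get(key, envir = .trial_cache)
}
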