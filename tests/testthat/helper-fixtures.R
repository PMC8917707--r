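# Shared fixtures: small simulator configs and a brute-force AUC oracle kept
# deliberately independent of the package's rank/component implementation.

quiet_cfg <- function(seed = 1L, ...) sim_config(noise_sd = 0, seed = seed, ...)

# Small but non-degenerate study session: 6 subjects (2 children), 3 reps.
small_study <- function(seed = 1L, cfg = sim_config(seed = seed)) {
  simulate_study(n_subjects = 6, child_fraction = 1 / 3, reps = 3, cfg = cfg)
}

# O(m*n) double-loop Mann-Whitney AUC: the enumeration oracle.
brute_force_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# A tiny perfectly separable labelled feature table: each class sits at its
# own location in feature space with negligible jitter.
separable_table <- function(n_per_class = 12, seed = 99L) {
  withr::with_seed(seed, {
    labs <- rep(c("sleep", "net_up", "net_down_active"), each = n_per_class)
    centers <- c(sleep = 0, net_up = 5, net_down_active = -5)
    data.frame(f1 = centers[labs] + rnorm(length(labs), 0, 1e-3),
               f2 = rnorm(length(labs), 0, 1e-3),
               label = factor(labs, levels = names(centers)),
               stringsAsFactors = FALSE)
  })
}
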