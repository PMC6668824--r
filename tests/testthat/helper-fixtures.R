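# Shared fixtures, all built in code.

# A tiny hand-written cohort with valid ranges for IO and validation tests.
tiny_cohort <- function(n = 3L) {
  syn <- generate_cohort(synthetic_config(
    n_young = max(2L, ceiling(n / 2)), n_old = max(2L, floor(n / 2)),
    old_cluster_sizes = c(1L, 1L), crossover_young_into_cluster2 = 0L,
    seed = 42L))
  cohort <- syn$cohort[seq_len(n), , drop = FALSE]
  validate_cohort(cohort)
}

# Default-condition synthetic cohort, cached per seed within a test run.
default_cohort <- local({
  cache <- list()
  function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_cohort(synthetic_config(seed = seed))
    }
    cache[[key]]
  }
})

# Fast training settings for simulation-heavy tests: decisions (output
# signs) stabilize long before the squared error fully converges.
fast_config <- function(seed = 1L, max_epochs = 2000L) {
  training_config(seed = seed, max_epochs = max_epochs)
}

# Random small network for gradient checks (wide init so the units are
# away from the linear regime).
random_params <- function(p, h, seed) {
  init_network(p, h, training_config(seed = seed, init_range = 0.5))
}

# Finite-difference gradient of the total squared error.
fd_gradient <- function(params, x, targets, eps = 1e-6) {
  err_at <- function(par) {
    f <- nn_forward(par, x)
    sum((targets - f$output)^2)
  }
  perturb <- function(field, idx) {
    up <- params; dn <- params
    up[[field]][idx] <- up[[field]][idx] + eps
    dn[[field]][idx] <- dn[[field]][idx] - eps
    (err_at(up) - err_at(dn)) / (2 * eps)
  }
  list(gW1 = matrix(vapply(seq_along(params$W1), function(i) {
         perturb("W1", i)
       }, numeric(1L)), nrow = params$h),
       gb1 = vapply(seq_along(params$b1), function(i) perturb("b1", i),
                    numeric(1L)),
       gw2 = vapply(seq_along(params$w2), function(i) perturb("w2", i),
                    numeric(1L)),
       gb2 = perturb("b2", 1L))
}
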