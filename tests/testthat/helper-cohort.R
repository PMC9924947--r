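# Small cohort configurations used across the suite. Kept deliberately tiny:
# 4 mutant strains, a few hundred genes, ~45 worms per arm.

tiny_cfg <- function(seed = 1, ...) {
  sim_config(
    n_mutant_strains = 4,
    strain_longevity_effects = c(0.3, 0.5, 0.9, 1.3),
    n_genes = 300,
    module_sizes = c(shared_driver = 30, lifespan_only = 15,
                     stress_specific = 5),
    n_worms_per_assay_arm = 45,
    alt_control_strain = 4,
    seed = seed,
    ...
  )
}

# Panel with fully shared stress traits (every stress trait equals the
# longevity effect), used for parameter-recovery and planted-effect tests.
shared_panel <- function() {
  p <- default_assay_panel()
  for (i in seq_along(p)) p[[i]]$shared_weight <- 1
  p
}

# Direct two-arm survival data for test scenarios.
two_arm <- function(n, scale_a, scale_b, shape = 3) {
  list(a = stats::rweibull(n, shape, scale_a),
       b = stats::rweibull(n, shape, scale_b))
}
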