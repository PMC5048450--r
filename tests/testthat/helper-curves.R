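# Shared fixtures: reference parameter sets and seeded noisy curves.

ref_kidney <- function() ivim_params(1000, 0.269, 1.245e-3, 4.0e-2)

noisy_dwi_curve <- function(truth = ref_kidney(), sigma = 13.5, seed = 1) {
  b <- dwi_b_scheme()
  set.seed(seed)
  decay_curve(b, ivim_signal(truth, b) + rnorm(length(b), 0, sigma))
}

noisy_bold_curve <- function(truth = t2star_params(1000, 32.8),
                             sigma = 14.8, seed = 1) {
  te <- bold_te_scheme()
  set.seed(seed)
  decay_curve(te, t2star_signal(truth, te) + rnorm(length(te), 0, sigma),
              kind = "bold")
}

# Uniform-truth phantom used by the recovery and repeatability checks.
uniform_phantom <- function(...) {
  make_phantom(phantom_spec(region_params = default_kidney_params(uniform = TRUE),
                            ...))
}

whole_kidney_median <- function(summaries, parameter) {
  summaries$median[summaries$region == "whole_kidney" &
                     summaries$parameter == parameter]
}
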