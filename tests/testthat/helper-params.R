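## shared fixtures: parameter builders and a fast solve wrapper

default_params <- function(jc = 0.6, kc = 1e-3, alpha = 0, ...) {
  ccm_params(membrane = membrane_params(jc = jc, alpha = alpha, ...),
             shell = shell_params(kc = kc))
}

## effectively enzyme-free kinetics (constructors require positive rates)
dead_enzymes <- function() {
  list(ca = ca_kinetics(Vca = 1e-30, Vba = 1e-30, Kca = 1, Kba = 1),
       rubisco = rubisco_kinetics(Vmax = 1e-30, VmaxO = 1e-30))
}

fast_solve <- function(p, ...) solve_ccm_numeric(p, n = 200, ...)
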