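# Shared fixtures for the suite. Everything is built in code; no data files.

usp_times <- c(1, 2, 4, 6, 8, 12, 16, 20, 24)

# small, fast-to-integrate compound for solver-oracle tests
oracle_compound <- function(clint = 5.8, ka = 1, v = 50, renal = 0) {
  compound_params(volume_of_distribution = v, ka = ka, fraction_absorbed = 1,
                  fu_plasma = 1, hepatic_blood_flow = 90, clint_total = clint,
                  renal_cl = renal)
}

# closed-form Bateman profile (ng/mL) for bolus-into-gut absorption
bateman <- function(t, dose, ka, ke, v)
  dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t)) * 1000

ref_weibull <- function() weibull_params(fmax = 90, lag = 0.5, alpha = 8, beta = 1.2)
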