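# shared helpers for the zaipp test-suite

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# continuous-column ZA kinetics and Model 1 antigen parameters
za_cont <- function() za_params(kZY = 0.007, kXY = 0.004, kYZ = 0.001,
                                rhoZY = 25.46, kXZ = 0)
ag1_cont <- function() model1_ag_params(kXG = 0.101, kXGZ = 13.25,
                                        lambdaGZ = 0.195, G0 = 12.71)
ag2_cont <- function() model2_ag_params(kXG = 0.081, kXGU = 0.051,
                                        lambdaUBG = 1.806, kBUZ = 0.099,
                                        kUBG = 0.168, G0 = 27.32)

# random but physically plausible ZA kinetic draws for property tests
random_za <- function() {
  za_params(kZY = runif(1, 1e-3, 0.7), kXY = runif(1, 1e-3, 0.05),
            kYZ = runif(1, 1e-4, 1), rhoZY = runif(1, 1, 30),
            kXZ = runif(1, 0, 0.05))
}

# noiseless observation set for a scenario
noiseless_obs <- function(name, step = 0.01) {
  sc <- scenario_truth(name)
  generate_observations(sc$model_id, sc$za, sc$ag, sc$design,
                        sigma_Z = 0, sigma_G = 0, step = step)
}

scenario_theta <- function(name) {
  sc <- scenario_truth(name)
  th <- c(unlist(sc$za), unlist(sc$ag))
  th[model_param_names(sc$model_id)]
}
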