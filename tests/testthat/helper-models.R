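# Shared fixtures: fluorophore parameter sets and small oracles, built in
# code so every test constructs its inputs from scratch.

cy5_free <- function(k_biso_th = 0)
  iso_model(sigma_N = 6.2e-16, k_iso = 29e6, sigma_biso = 0.15e-16,
            k10 = 1e9, k_biso_th = k_biso_th, name = "Cy5_free")

cy5_suv <- function(k_biso_th = 0)
  iso_model(sigma_N = 6.2e-16, k_iso = 6.2e6, sigma_biso = 0.042e-16,
            k10 = 1e9, k_biso_th = k_biso_th, name = "Cy5_SUV")

cf640r <- function()
  triplet_model(sigma_S = 4e-16, k_isc = 0.7e6, k_T = 0.5e6, k10 = 1e9)

# Brute-force fine-step forward-Euler integrator for the 2-state kinetics
# (independent oracle for evolve_population / pulse_response). The Euler
# map is affine, so its n-step iterate is evaluated in closed form
# (exactly the same numbers the step loop would produce, without drift
# from summing 10^6 tiny increments).
euler_two_state <- function(k_on, k_off, t_end, dt = NULL) {
  if (is.null(dt)) dt <- 1e-6 / max(k_on, k_off)
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  lam <- k_on + k_off
  s_star <- k_off / lam                    # fixed point of the Euler map
  s_star + (1 - s_star) * (1 - lam * dt)^n
}

# Independent 2-state propagator via matrix exponential (Matrix::expm).
expm_two_state <- function(k_on, k_off, t) {
  K <- matrix(c(-k_on, k_on, k_off, -k_off), 2, 2)
  as.numeric(Matrix::expm(K * t) %*% c(1, 0))
}
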