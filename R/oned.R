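#' Langevin dynamics on a 1D polynomial potential
#'
#' BAOAB integration of a single particle (unit mass) on
#' `V(x) = sum(coeffs[k+1] * x^k)`. Used with the closed-form oracle
#' systems from [make_oracle_system()] to validate the thermostat and the
#' reweighting machinery; the umbrella bias `(k/2)(x - c)^2` is itself a
#' polynomial and can be added through `bias_k` / `bias_center`.
#'
#' @param coeffs Polynomial coefficients, constant term first.
#' @param x0,v0 Initial position and velocity.
#' @param kT Thermal energy (same units as V).
#' @param gamma Friction (1/time); 0 gives microcanonical velocity Verlet.
#' @param dt Time step.
#' @param n_steps Steps.
#' @param stride Recording stride.
#' @param seed RNG seed (counter-based; same seed, same trajectory).
#' @param step_offset Global step offset for seamless continuation.
#' @param bias_k,bias_center Optional harmonic umbrella bias.
#' @return List with `x`, `v` series and final state.
#' @export
run_langevin_1d <- function(coeffs, x0 = 0, v0 = 0, kT = 1, gamma = 1,
                            dt = 0.01, n_steps = 1000, stride = 1,
                            seed = 1, step_offset = 0,
                            bias_k = 0, bias_center = 0) {
  cf <- as.numeric(coeffs)
  if (bias_k != 0) {
    # (k/2)(x - c)^2 = k c^2/2 - k c x + (k/2) x^2
    add <- c(bias_k * bias_center^2 / 2, -bias_k * bias_center, bias_k / 2)
    n <- max(length(cf), 3L)
    cf <- c(cf, numeric(n - length(cf)))
    cf[1:3] <- cf[1:3] + add
  }
  run_poly1d_cpp(x0, v0, cf, kT, gamma, dt, as.integer(n_steps),
                 as.integer(stride), seed, step_offset)
}
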