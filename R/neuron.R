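# Conductance-based single-compartment model of caudal mesopallium (CM)
# neurons, adapted from the ventral cochlear nucleus family of channel
# models.  The low-threshold potassium conductance g_KLT controls whether
# the cell fires tonically (sustained spiking to a depolarizing step) or
# phasically (spikes only at step onset).

.param_names <- c("C", "g_lk", "E_lk", "g_Na", "E_Na", "g_KA", "g_KHT",
                  "g_KLT", "E_K", "g_h", "E_h", "phi")
.state_names <- c("V", "m", "h", "n", "p", "w", "z", "a", "b", "c", "r")

#' Construct a neuron parameter set
#'
#' Builds a complete parameter set for the single-compartment model. All
#' conductances in nS, reversal potentials in mV, capacitance in pF.
#'
#' @param C membrane capacitance (pF)
#' @param g_lk,E_lk leak conductance (nS) and reversal (mV)
#' @param g_Na,E_Na fast sodium conductance and reversal
#' @param g_KA transient (A-type) potassium conductance
#' @param g_KHT high-threshold potassium conductance
#' @param g_KLT low-threshold potassium conductance; 0 gives tonic firing,
#'   large values phasic (onset-only) firing
#' @param E_K potassium reversal potential (mV)
#' @param g_h,E_h hyperpolarization-activated cation conductance and reversal
#' @param phi gating-rate scale factor applied to every channel time
#'   constant (Q10-style temperature correction of the reference-temperature
#'   kinetics; larger = faster gating)
#' @return an object of class `neuron_params` (named numeric vector)
#' @export
neuron_params <- function(C = 60, g_lk = 1.3, E_lk = -75, g_Na = 750,
                          E_Na = 55, g_KA = 30, g_KHT = 95, g_KLT = 0,
                          E_K = -82, g_h = 0.5, E_h = -43, phi = 1) {
  p <- c(C = C, g_lk = g_lk, E_lk = E_lk, g_Na = g_Na, E_Na = E_Na,
         g_KA = g_KA, g_KHT = g_KHT, g_KLT = g_KLT, E_K = E_K,
         g_h = g_h, E_h = E_h, phi = phi)
  if (p[["C"]] <= 0) stop("capacitance must be positive")
  gs <- p[grep("^g_", names(p))]
  if (any(gs < 0)) stop("conductances must be non-negative")
  structure(p, class = "neuron_params")
}

#' Tonic and phasic reference parameter sets
#'
#' The two consensus CM parameter sets: the tonic cell has no low-threshold
#' potassium current (g_KLT = 0 nS, C = 60 pF); the phasic cell expresses
#' it strongly (g_KLT = 50 nS, C = 40 pF). All other parameters are shared.
#'
#' @return a `neuron_params` object
#' @export
tonic_params <- function() neuron_params(C = 60, g_KLT = 0)

#' @rdname tonic_params
#' @export
phasic_params <- function() neuron_params(C = 40, g_KLT = 50)

#' Parameter sets along a g_KLT gradient
#'
#' Copies of the phasic parameter set (C = 40 pF) differing only in the
#' low-threshold potassium conductance, for dose-response sweeps.
#'
#' @param values g_KLT values in nS (non-negative)
#' @return list of `neuron_params`
#' @export
gklt_sweep_params <- function(values) {
  if (any(values < 0)) stop("g_KLT values must be non-negative")
  lapply(values, function(g) {
    p <- phasic_params()
    p[["g_KLT"]] <- g
    p
  })
}

#' Model state time-derivatives
#'
#' Evaluates the vector field of the membrane equation and the ten
#' first-order gating relaxations at a given state and injected current.
#' Mainly useful for testing and external integrators.
#'
#' @param state named numeric vector (V, m, h, n, p, w, z, a, b, c, r);
#'   V in mV, gating variables in \[0, 1\]
#' @param params a `neuron_params` object
#' @param i_total injected current (pA)
#' @return named numeric vector of derivatives (per ms)
#' @export
neuron_derivatives <- function(state, params, i_total = 0) {
  state <- state[.state_names]
  if (anyNA(state)) stop("state must contain V and all ten gating variables")
  d <- cpp_derivatives(as.numeric(state), as.numeric(params[.param_names]),
                       i_total)
  names(d) <- .state_names
  d
}

#' Steady-state gating values at a holding potential
#'
#' @param V membrane potential (mV)
#' @return named vector of the ten gating steady states
#' @export
gating_steady_state <- function(V) cpp_gating_inf(V)

#' Resting state of the model
#'
#' Relaxes the model from -70 mV (gating at steady state) with zero input
#' until transients decay, yielding the deterministic initial condition
#' used for all simulations: trial-to-trial variability then comes only
#' from the noise current.
#'
#' @param params a `neuron_params` object
#' @param t_settle relaxation time (ms)
#' @param tol integrator error tolerance
#' @return named state vector at rest
#' @export
rest_state <- function(params, t_settle = 1000, tol = 1e-5) {
  y <- cpp_rest_state(as.numeric(params[.param_names]), t_settle, tol)
  names(y) <- .state_names
  y
}

#' Simulate the model response to an injected current
#'
#' Integrates the model with an adaptive 5th-order Runge-Kutta scheme
#' (error tolerance 1e-5 by default) and reports the voltage on a uniform
#' 0.025 ms grid. Input currents are sampled every `dt_in` seconds and
#' linearly interpolated between samples.
#'
#' @param params a `neuron_params` object
#' @param i_stim stimulus-driven current trace (pA), sampled at `dt_in`
#' @param i_noise optional noise current trace (pA), same sampling; added
#'   to `i_stim`
#' @param dt_in input sample interval (s); default 1 ms
#' @param dt_out output voltage sample interval (s); default 0.025 ms
#' @param tol adaptive error tolerance
#' @param init initial state; default the model's resting state
#' @return object of class `sim_result`: list with `times` (s), `voltage`
#'   (mV), `dt` (s), integrator statistics and the parameter set
#' @export
simulate_neuron <- function(params, i_stim, i_noise = NULL, dt_in = 1e-3,
                            dt_out = 2.5e-5, tol = 1e-5, init = NULL) {
  i_inj <- as.numeric(i_stim)
  if (!is.null(i_noise)) {
    if (length(i_noise) != length(i_inj))
      stop("i_stim and i_noise must have equal length")
    i_inj <- i_inj + as.numeric(i_noise)
  }
  if (any(!is.finite(i_inj))) stop("injected current must be finite")
  if (is.null(init)) init <- rest_state(params, tol = tol)
  res <- cpp_simulate(as.numeric(params[.param_names]), i_inj,
                      dt_in * 1000, dt_out * 1000, tol,
                      as.numeric(init[.state_names]))
  v <- res$voltage
  structure(list(times = (seq_along(v) - 1) * dt_out, voltage = v,
                 dt = dt_out, final_state = res$final_state,
                 n_steps = res$n_steps, n_rejected = res$n_rejected,
                 params = params),
            class = "sim_result")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  print(unclass(x))
  invisible(x)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %.3f s at dt = %g ms, %d samples, %d steps\n",
              max(x$times), x$dt * 1000, length(x$voltage), x$n_steps))
  invisible(x)
}
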