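count_spikes <- function(v, thr = -20) sum(v[-1] >= thr & v[-length(v)] < thr)

step_current <- function(amp, pre = 50, on = 500, post = 50) {
  c(rep(0, pre), rep(amp, on), rep(0, post))
}

test_that("reference parameter sets carry the published values", {
  tt <- tonic_params()
  pp <- phasic_params()
  expect_equal(tt[["C"]], 60)
  expect_equal(tt[["g_KLT"]], 0)
  expect_equal(pp[["C"]], 40)
  expect_equal(pp[["g_KLT"]], 50)
  for (p in list(tt, pp)) {
    expect_equal(p[["g_lk"]], 1.3)
    expect_equal(p[["E_lk"]], -75)
    expect_equal(p[["g_Na"]], 750)
    expect_equal(p[["E_Na"]], 55)
    expect_equal(p[["g_KA"]], 30)
    expect_equal(p[["g_KHT"]], 95)
    expect_equal(p[["E_K"]], -82)
    expect_equal(p[["g_h"]], 0.5)
    expect_equal(p[["E_h"]], -43)
  }
  expect_error(neuron_params(C = -1), "capacitance")
  expect_error(neuron_params(g_Na = -5), "non-negative")
})

test_that("gKLT gradient reuses the phasic base", {
  sw <- gklt_sweep_params(seq(0, 50, 10))
  expect_length(sw, 6)
  expect_equal(sw[[6]], phasic_params())
  expect_equal(sw[[1]][["C"]], 40)          # not the tonic cell
  expect_false(isTRUE(all.equal(sw[[1]], tonic_params())))
  expect_error(gklt_sweep_params(c(-1, 10)), "non-negative")
})

test_that("vector field has the expected structure at special points", {
  p <- neuron_params(g_Na = 0, g_KA = 0, g_KHT = 0, g_KLT = 0, g_h = 0)
  st <- c(V = -75, gating_steady_state(-75))
  names(st) <- c("V", "m", "h", "n", "p", "w", "z", "a", "b", "c", "r")
  d <- neuron_derivatives(st, p, i_total = 0)
  expect_equal(unname(d["V"]), 0, tolerance = 1e-12)   # leak equilibrium
  expect_equal(unname(max(abs(d[-1]))), 0, tolerance = 1e-12)

  # injected current enters linearly as I/C
  p2 <- tonic_params()
  st2 <- c(V = -60, gating_steady_state(-60))
  names(st2) <- names(st)
  d0 <- neuron_derivatives(st2, p2, 0)
  d100 <- neuron_derivatives(st2, p2, 100)
  expect_equal(unname(d100["V"] - d0["V"]), 100 / 60, tolerance = 1e-12)
  expect_equal(unname(d100[-1]), unname(d0[-1]))
  expect_error(neuron_derivatives(st * NA, p2), "state")
})

test_that("rest is stable and deterministic", {
  for (p in list(tonic_params(), phasic_params())) {
    r <- rest_state(p)
    expect_true(all(r[-1] >= 0 & r[-1] <= 1))
    s <- simulate_neuron(p, numeric(1000), init = r)
    expect_equal(count_spikes(s$voltage), 0)
    expect_lt(diff(range(s$voltage)), 0.5)
    expect_equal(length(s$voltage), 1000 / 0.025 + 1)
    expect_equal(s$times[2] - s$times[1], 2.5e-5)
  }
})

test_that("phasic/tonic step dichotomy at 1.5x rheobase", {
  rheobase <- function(p, r) {
    lo <- 5; hi <- 600
    for (k in 1:10) {
      mid <- (lo + hi) / 2
      n <- count_spikes(simulate_neuron(p, step_current(mid),
                                        init = r)$voltage)
      if (n >= 1) hi <- mid else lo <- mid
    }
    hi
  }
  tt <- tonic_params(); rt <- rest_state(tt)
  pp <- phasic_params(); rp <- rest_state(pp)
  rh_t <- rheobase(tt, rt)
  rh_p <- rheobase(pp, rp)
  n_t <- count_spikes(simulate_neuron(tt, step_current(1.5 * rh_t),
                                      init = rt)$voltage)
  n_p <- count_spikes(simulate_neuron(pp, step_current(1.5 * rh_p),
                                      init = rp)$voltage)
  expect_gte(n_t, 10)    # sustained firing throughout the step
  expect_lte(n_p, 2)     # onset-only firing
  # phasic spikes are confined to the step onset
  sim_p <- simulate_neuron(pp, step_current(1.5 * rh_p), init = rp)
  k <- detect_spikes(sim_p$voltage, sim_p$dt)
  expect_true(all(k$times < 0.05 + 0.05))   # within 50 ms of onset
})

test_that("rheobase is non-decreasing in g_KLT", {
  rheobase <- function(p) {
    r <- rest_state(p)
    lo <- 5; hi <- 600
    for (k in 1:9) {
      mid <- (lo + hi) / 2
      n <- count_spikes(simulate_neuron(p, step_current(mid),
                                        init = r)$voltage)
      if (n >= 1) hi <- mid else lo <- mid
    }
    hi
  }
  rh <- vapply(gklt_sweep_params(c(0, 25, 50)), rheobase, numeric(1))
  expect_true(all(diff(rh) >= 0))
})

test_that("gating variables stay in [0,1] under strong noisy drive", {
  set.seed(6)
  i_stim <- 400 * sin(2 * pi * 30 * (0:499) / 1000)
  i_noise <- make_noise(500, 1e-3, noise_spec(2, 2, 3), signal_rms = 300)
  for (p in list(tonic_params(), phasic_params())) {
    s <- simulate_neuron(p, i_stim, i_noise)
    expect_true(all(is.finite(s$voltage)))
    fs <- s$final_state
    expect_true(all(fs[-1] >= 0 & fs[-1] <= 1))
  }
})

test_that("adaptive integration matches an independent stiff solver", {
  skip_if_not_installed("deSolve")
  # independent R implementation of the vector field (same published
  # kinetics written from the closed forms, integrated by lsoda)
  kin <- function(V) {
    hs <- 10; ks <- 15; tsc <- 0.5
    Vh <- V - hs; Vk <- V + ks
    list(
      minf = 1 / (1 + exp(-(V + 38) / 7)),
      taum = tsc * (10 / (5 * exp((V + 60) / 18) +
                            36 * exp(-(V + 60) / 25)) + 0.04),
      hinf = 1 / (1 + exp((Vh + 65) / 6)),
      tauh = tsc * (100 / (7 * exp((Vh + 60) / 11) +
                             10 * exp(-(Vh + 60) / 25)) + 0.6),
      ninf = (1 + exp(-(Vk + 15) / 5))^-0.5,
      taun = tsc * (100 / (11 * exp((Vk + 60) / 24) +
                             21 * exp(-(Vk + 60) / 23)) + 0.7),
      pinf = 1 / (1 + exp(-(Vk + 23) / 6)),
      taup = tsc * (100 / (4 * exp((Vk + 60) / 32) +
                             5 * exp(-(Vk + 60) / 22)) + 5),
      winf = (1 + exp(-(V + 48) / 6))^-0.25,
      tauw = tsc * (100 / (6 * exp((V + 60) / 6) +
                             16 * exp(-(V + 60) / 45)) + 1.5),
      zinf = 0.5 + 0.5 / (1 + exp((V + 71) / 10)),
      tauz = tsc * (1000 / (exp((V + 60) / 20) +
                              exp(-(V + 60) / 8)) + 50),
      ainf = (1 + exp(-(V + 31) / 6))^-0.25,
      taua = tsc * (100 / (7 * exp((V + 60) / 14) +
                             29 * exp(-(V + 60) / 24)) + 0.1),
      binf = (1 + exp((V + 66) / 7))^-0.5,
      taub = tsc * (1000 / (14 * exp((V + 60) / 27) +
                              29 * exp(-(V + 60) / 24)) + 1),
      cinf = (1 + exp((V + 66) / 7))^-0.5,
      tauc = tsc * (90 / (1 + exp(-(V + 66) / 17)) + 10),
      rinf = 1 / (1 + exp((V + 76) / 7)),
      taur = tsc * (1e5 / (237 * exp((V + 60) / 12) +
                             17 * exp(-(V + 60) / 14)) + 25))
  }
  p <- tonic_params()
  i_inj <- 60 + 40 * sin(2 * pi * 7 * (0:199) / 1000)   # 200 ms fragment
  rhs <- function(t, y, parms) {
    V <- y[1]
    g <- pmin(pmax(y[2:11], 0), 1)
    k <- kin(V)
    iNa <- p[["g_Na"]] * g[1]^3 * g[2] * (V - p[["E_Na"]])
    iKHT <- p[["g_KHT"]] * (0.85 * g[3]^2 + 0.15 * g[4]) * (V - p[["E_K"]])
    iKLT <- p[["g_KLT"]] * g[5]^4 * g[6] * (V - p[["E_K"]])
    iKA <- p[["g_KA"]] * g[7]^4 * g[8] * g[9] * (V - p[["E_K"]])
    ih <- p[["g_h"]] * g[10] * (V - p[["E_h"]])
    ilk <- p[["g_lk"]] * (V - p[["E_lk"]])
    # same linear interpolation of the 1 ms input samples
    x <- t; i0 <- floor(x); f <- x - i0
    idx <- min(i0 + 1, length(i_inj))
    idx2 <- min(i0 + 2, length(i_inj))
    I <- i_inj[idx] * (1 - f) + i_inj[idx2] * f
    inf <- c(k$minf, k$hinf, k$ninf, k$pinf, k$winf, k$zinf, k$ainf,
             k$binf, k$cinf, k$rinf)
    tau <- c(k$taum, k$tauh, k$taun, k$taup, k$tauw, k$tauz, k$taua,
             k$taub, k$tauc, k$taur)
    list(c((-iNa - iKHT - iKLT - iKA - ih - ilk + I) / p[["C"]],
           (inf - g) / tau))
  }
  init <- rest_state(p)
  ref <- deSolve::lsoda(unname(init), seq(0, 200, by = 0.025), rhs, NULL,
                        rtol = 1e-8, atol = 1e-8)
  sim <- simulate_neuron(p, i_inj, init = init)
  v_ref <- ref[, 2]
  v_sim <- sim$voltage[seq_along(v_ref)]
  # mask 2 ms around spikes: tiny phase shifts there dominate RMS
  spk <- which(v_ref > -20)
  mask <- rep(TRUE, length(v_ref))
  for (s in spk) mask[max(1, s - 80):min(length(mask), s + 80)] <- FALSE
  rms <- sqrt(mean((v_ref[mask] - v_sim[mask])^2))
  expect_lt(rms, 0.5)
})

test_that("fixed-step RK4 agrees with the adaptive integrator", {
  p <- phasic_params()
  init <- rest_state(p)
  i_inj <- c(rep(0, 20), rep(300, 80))
  ada <- simulate_neuron(p, i_inj, init = init)
  rk4 <- strfcascade:::cpp_simulate_rk4(
    as.numeric(p[strfcascade:::.param_names]), i_inj, 1, 0.001, 0.025,
    as.numeric(init))
  n <- min(length(ada$voltage), length(rk4))
  v1 <- ada$voltage[1:n]; v2 <- rk4[1:n]
  mask <- v1 < -20 & v2 < -20
  expect_lt(sqrt(mean((v1[mask] - v2[mask])^2)), 0.5)
})
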