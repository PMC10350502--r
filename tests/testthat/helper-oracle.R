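# Independent fixed-step 4th-order Runge-Kutta integrator, used as an
# oracle against the adaptive solver. Pure R, no deSolve.
rk4_integrate <- function(params, pump, t_end = pump_end(pump), dt = 0.01,
                          init = steady_state(params, pump$mu0)) {
  spont <- function(G) {
    if (params$spontaneous == "quadratic") params$beta * (G + params$eta)^2
    else params$beta * (G + params$eta)
  }
  f <- function(y, mu1) {
    c(y[1] * (y[2] - y[3] - 1) + spont(y[2]),
      params$gamma_G * (mu1 - y[2] * (1 + y[1])),
      params$gamma_Q * (params$mu2 - y[3] * (1 + params$s * y[1])))
  }
  n <- ceiling(t_end / dt)
  keep <- max(1L, round(0.5 / dt))  # record every 0.5 time units
  y <- c(init$I, init$G, init$Q)
  m <- n %/% keep + 1L
  times <- numeric(m); I <- numeric(m)
  times[1] <- 0; I[1] <- y[1]; j <- 1L
  for (i in seq_len(n)) {
    t0 <- (i - 1) * dt
    # evaluate strictly inside the step so stages never read the pump
    # level of the next boxcar segment (edges are step-aligned)
    m1 <- pump_level(pump, t0)
    m2 <- pump_level(pump, t0 + dt / 2)
    m3 <- pump_level(pump, t0 + dt * (1 - 1e-9))
    k1 <- f(y, m1)
    k2 <- f(y + dt / 2 * k1, m2)
    k3 <- f(y + dt / 2 * k2, m2)
    k4 <- f(y + dt * k3, m3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% keep == 0L) {
      j <- j + 1L
      times[j] <- i * dt
      I[j] <- y[1]
    }
  }
  list(times = times[1:j], I = I[1:j], final = y)
}

# Brute-force minimal-subset oracle: tests every subset (no size-ordered
# early exit) and returns the smallest achieving unique codes.
brute_min_subset <- function(code_matrix) {
  nf <- nrow(code_matrix)
  best <- NULL
  for (m in seq_len(2^nf - 1)) {
    s <- which(bitwAnd(m, 2^(seq_len(nf) - 1)) > 0)
    codes <- apply(code_matrix[s, , drop = FALSE], 2, paste, collapse = "-")
    if (!anyDuplicated(codes) &&
        (is.null(best) || length(s) < length(best))) {
      best <- s
    }
  }
  best
}
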