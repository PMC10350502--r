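#' Right-hand side of the Yamada rate equations
#'
#' Evaluates the instantaneous rates \eqn{(\dot I, \dot G, \dot Q)} of the
#' three-variable laser-with-saturable-absorber model at a given state and
#' pump value. The intensity grows while the net gain `R = G - Q - 1` is
#' positive; the spontaneous-emission source keeps `I` strictly positive so
#' that a spike can ignite once `R` crosses zero.
#'
#' @param state a [laser_state()], or a named list with `I`, `G`, `Q`.
#' @param mu1 instantaneous pump value.
#' @param params a [laser_params()] object.
#' @return Named numeric vector `c(dI, dG, dQ)`.
#' @examples
#' p <- laser_params()
#' yamada_rates(laser_state(I = 0, G = 1.25, Q = 2), mu1 = 1.25, p)
#' @export
yamada_rates <- function(state, mu1, params = laser_params()) {
  stopifnot(inherits(params, "laser_params"))
  I <- state$I; G <- state$G; Q <- state$Q
  if (!all(is.finite(c(I, G, Q, mu1)))) {
    stop("state and pump must be finite", call. = FALSE)
  }
  sp <- spont_source(G, params)
  c(dI = I * (G - Q - 1) + sp,
    dG = params$gamma_G * (mu1 - G * (1 + I)),
    dQ = params$gamma_Q * (params$mu2 - Q * (1 + params$s * I)))
}

spont_source <- function(G, params) {
  if (params$spontaneous == "quadratic") {
    params$beta * (G + params$eta)^2
  } else {
    params$beta * (G + params$eta)
  }
}

#' Quiet steady state of the laser at constant pump
#'
#' Finds the non-lasing fixed point of the model at constant pump `mu0`,
#' i.e. the state the neuron rests in between stimuli. Substituting the
#' nullclines `G = mu0 / (1 + I)` and `Q = mu2 / (1 + s I)` reduces the
#' problem to a one-dimensional root of \eqn{\dot I(I) = 0}. Near the
#' self-pulsing onset up to three fixed points coexist; the quiet state is
#' the one with the smallest intensity, so the root search scans upward from
#' `I = 0` and takes the first sign change (bracket `[0, 10]`, expanded on
#' failure). The root is polished by Newton steps so that the residual rates
#' are at the level of floating-point noise.
#'
#' @param params a [laser_params()] object.
#' @param mu0 constant pump value; must be below the self-pulsing onset.
#' @return A [laser_state()] at the quiet fixed point.
#' @examples
#' st <- steady_state(laser_params(), 1.25)
#' yamada_rates(st, 1.25)  # all rates at solver-noise level
#' @export
steady_state <- function(params = laser_params(), mu0) {
  stopifnot(inherits(params, "laser_params"), is.finite(mu0), mu0 >= 0)
  f <- function(I) {
    G <- mu0 / (1 + I)
    Q <- params$mu2 / (1 + params$s * I)
    I * (G - Q - 1) + spont_source(G, params)
  }
  hi <- 10
  root <- smallest_root(f, hi)
  while (is.null(root) && hi < 1e6) {
    hi <- hi * 10
    root <- smallest_root(f, hi)
  }
  if (!is.null(root)) {
    # distinguish the quiet branch (spontaneous-emission-dominated, net
    # gain R clearly negative) from the cw lasing branch (R ~ 0), which the
    # upward scan finds once the quiet root has folded away
    R <- mu0 / (1 + root) - params$mu2 / (1 + params$s * root) - 1
    if (R > -1e-3) root <- NULL
  }
  if (is.null(root)) {
    stop("no quiet state: pump too high for the excitable regime",
         call. = FALSE)
  }
  I <- root
  for (k in 1:6) {  # Newton polish
    h <- max(1e-10, abs(I) * 1e-7)
    d <- (f(I + h) - f(I - h)) / (2 * h)
    if (!is.finite(d) || d == 0) break
    step <- f(I) / d
    if (!is.finite(step)) break
    I <- I - step
  }
  laser_state(I = I, G = mu0 / (1 + I), Q = params$mu2 / (1 + params$s * I))
}

# first sign change of f on (0, hi], scanned on a log-spaced grid
smallest_root <- function(f, hi) {
  gr <- c(0, 10^seq(-9, log10(hi), by = 0.01))
  fv <- vapply(gr, f, 0)
  k <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (!length(k)) return(NULL)
  k <- k[1]
  stats::uniroot(f, c(gr[k], gr[k + 1]), tol = 1e-14)$root
}

#' Integrate the laser equations under a pump program
#'
#' Solves the Yamada equations driven by the piecewise-constant pump of a
#' [pump_program()]. Because the pump is a sum of boxcars, the trajectory is
#' integrated segment by segment between pump switching times with `lsoda`
#' (adaptive, stiffness-switching), which handles the slow-fast structure
#' (relaxation rates of 0.005 against O(1) intensity dynamics) without any
#' step-size tuning. Output is sampled densely (default every 0.5 time
#' units) so that no intensity pulse, whose width is tens of time units, can
#' fall between samples.
#'
#' @param params a [laser_params()] object.
#' @param pump a [pump_program()].
#' @param t_span integration interval; defaults to `c(0, pump_end(pump))`.
#' @param init initial [laser_state()]; defaults to the quiet steady state
#'   at the program's base pump `mu0`.
#' @param dt_sample output sampling interval.
#' @param rtol,atol relative and absolute solver tolerances.
#' @return An object of class `laser_trajectory` with fields `times`, `I`,
#'   `G`, `Q` and the derived net gain `R = G - Q - 1` at every sample.
#' @examples
#' p <- laser_params()
#' pr <- pump_program("00111", mu0 = 1.25, c = 6, t_pad = 500)
#' tr <- integrate_laser(p, pr)
#' max(tr$I) > 1  # three summed perturbations elicit a spike
#' @export
integrate_laser <- function(params, pump, t_span = NULL, init = NULL,
                            dt_sample = 0.5, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "laser_params"), inherits(pump, "pump_program"))
  if (is.null(t_span)) t_span <- c(0, pump_end(pump))
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1])
  if (is.null(init)) init <- steady_state(params, pump$mu0)
  stopifnot(inherits(init, "laser_state"))

  br <- pump_breakpoints(pump)
  br <- sort(unique(c(t_span, br[br > t_span[1] & br < t_span[2]])))
  y <- c(I = init$I, G = init$G, Q = init$Q)
  times <- I <- G <- Q <- numeric(0)

  rhs <- function(t, y, p) {
    sp <- spont_source(y[2], params)
    list(c(y[1] * (y[2] - y[3] - 1) + sp,
           params$gamma_G * (p$mu1 - y[2] * (1 + y[1])),
           params$gamma_Q * (params$mu2 - y[3] * (1 + params$s * y[1]))))
  }

  for (k in seq_len(length(br) - 1)) {
    tt <- unique(c(seq(br[k], br[k + 1], by = dt_sample), br[k + 1]))
    mu1 <- pump_level(pump, br[k] + min(dt_sample, diff(br)[k]) * 1e-6)
    sol <- deSolve::ode(y, tt, rhs, parms = list(mu1 = mu1),
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf(paste0("integration failed in segment [%g, %g] ",
                          "(state I=%g G=%g Q=%g)"),
                   br[k], br[k + 1], y[1], y[2], y[3]), call. = FALSE)
    }
    keep <- if (k == 1) seq_len(nrow(sol)) else seq(2, nrow(sol))
    times <- c(times, sol[keep, 1])
    I <- c(I, sol[keep, 2]); G <- c(G, sol[keep, 3]); Q <- c(Q, sol[keep, 4])
    y <- sol[nrow(sol), 2:4]
  }
  I <- pmax(I, 0)  # clip solver noise at the positivity boundary
  structure(list(times = times, I = I, G = G, Q = Q, R = G - Q - 1,
                 params = params, pump = pump),
            class = "laser_trajectory")
}

#' @export
as.data.frame.laser_trajectory <- function(x, ...) {
  data.frame(t = x$times, I = x$I, G = x$G, Q = x$Q, R = x$R)
}

#' @export
print.laser_trajectory <- function(x, ...) {
  cat(sprintf("<laser_trajectory> %d samples on [%g, %g], max I = %.4g\n",
              length(x$times), min(x$times), max(x$times), max(x$I)))
  invisible(x)
}
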