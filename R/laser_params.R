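#' Physical parameters of the microlaser neuron
#'
#' Parameters of the dimensionless Yamada-type rate equations for a
#' semiconductor micropillar laser with intracavity saturable absorber:
#'
#' \deqn{\dot I = I (G - Q - 1) + \beta (G + \eta)^2}
#' \deqn{\dot G = \gamma_G (\mu_1(t) - G (1 + I))}
#' \deqn{\dot Q = \gamma_Q (\mu_2 - Q (1 + s I))}
#'
#' where `I` is the intracavity intensity, `G` the gain, `Q` the saturable
#' absorption and `mu_1(t)` the pump. All rates are scaled to the cavity
#' photon lifetime (about 1--2 ps in physical units for these devices); every
#' quantity handled by this package is dimensionless.
#'
#' The defaults are typical semiconductor values: slow gain and absorber
#' recombination (`gamma_G = gamma_Q = 0.005`, giving the slow-fast character
#' of the system), linear unsaturated absorption `mu2 = 2`, absorber
#' saturation parameter `s = 10`, spontaneous-emission coupling
#' `beta = 1e-4` with offset `eta = 1.4`.
#'
#' Two forms of the spontaneous-emission source are in circulation for this
#' model family; the quadratic form `beta * (G + eta)^2` is the default and
#' the linear form `beta * (G + eta)` can be selected with
#' `spontaneous = "linear"`.
#'
#' @param gamma_G gain relaxation rate (per cavity photon lifetime).
#' @param gamma_Q absorber relaxation rate.
#' @param mu2 linear unsaturated absorption.
#' @param s absorber saturation parameter.
#' @param beta spontaneous-emission coupling.
#' @param eta spontaneous-emission offset.
#' @param spontaneous functional form of the spontaneous-emission source.
#'
#' @return An object of class `laser_params`.
#' @seealso [laser_threshold()], [steady_state()], [integrate_laser()]
#' @examples
#' p <- laser_params()
#' laser_threshold(p)  # mu_1 threshold: 1 + mu2 = 3
#' @export
laser_params <- function(gamma_G = 0.005, gamma_Q = 0.005, mu2 = 2, s = 10,
                         beta = 1e-4, eta = 1.4,
                         spontaneous = c("quadratic", "linear")) {
  spontaneous <- match.arg(spontaneous)
  vals <- c(gamma_G = gamma_G, gamma_Q = gamma_Q, mu2 = mu2, s = s,
            beta = beta, eta = eta)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all laser parameters must be finite and positive", call. = FALSE)
  }
  structure(list(gamma_G = gamma_G, gamma_Q = gamma_Q, mu2 = mu2, s = s,
                 beta = beta, eta = eta, spontaneous = spontaneous),
            class = "laser_params")
}

#' Laser threshold pump value
#'
#' The pump value `mu_1,th = 1 + mu2` above which the constant-pump laser is
#' in the self-pulsing regime proper. The excitable regime studied by this
#' package sits below this threshold.
#'
#' @param params a [laser_params()] object.
#' @return The threshold pump (dimensionless).
#' @export
laser_threshold <- function(params) {
  stopifnot(inherits(params, "laser_params"))
  1 + params$mu2
}

#' @export
print.laser_params <- function(x, ...) {
  cat("<laser_params>\n")
  cat(sprintf("  gamma_G = %g, gamma_Q = %g, mu2 = %g, s = %g\n",
              x$gamma_G, x$gamma_Q, x$mu2, x$s))
  cat(sprintf("  beta = %g, eta = %g, spontaneous term: %s\n",
              x$beta, x$eta, x$spontaneous))
  cat(sprintf("  laser threshold mu_1,th = %g\n", 1 + x$mu2))
  invisible(x)
}

#' Read laser parameters from a key-value configuration file
#'
#' Reads a flat `key: value` (or `key = value`) text file and returns a
#' [laser_params()] object. Unknown keys are an error. The bare preset name
#' `"micropillar"` returns the package defaults without reading a file.
#'
#' @param file path to a configuration file, or `"micropillar"`.
#' @return A [laser_params()] object.
#' @export
read_laser_config <- function(file) {
  if (identical(file, "micropillar")) return(laser_params())
  kv <- read_key_values(file)
  known <- c("gamma_G", "gamma_Q", "mu2", "s", "beta", "eta", "spontaneous")
  bad <- setdiff(names(kv), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  num <- setdiff(names(kv), "spontaneous")
  kv[num] <- lapply(kv[num], as.numeric)
  do.call(laser_params, kv)
}

# flat "key: value" / "key = value" parser; '#' starts a comment
read_key_values <- function(file) {
  ln <- readLines(file, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*[:=]\\s*(.*)$", ln))
  if (any(lengths(m) != 3)) stop("malformed key-value line in ", file, call. = FALSE)
  stats::setNames(lapply(m, function(x) trimws(x[3])), vapply(m, `[`, "", 2))
}

#' Instantaneous state of the laser
#'
#' @param I intracavity intensity (non-negative).
#' @param G gain.
#' @param Q saturable absorption.
#' @param t time, in cavity-lifetime units.
#' @return An object of class `laser_state`.
#' @export
laser_state <- function(I, G, Q, t = 0) {
  v <- c(t = t, I = I, G = G, Q = Q)
  if (!all(is.finite(v))) stop("laser state must be finite", call. = FALSE)
  if (I < 0) stop("intensity must be non-negative", call. = FALSE)
  structure(list(t = t, I = I, G = G, Q = Q), class = "laser_state")
}

#' @export
print.laser_state <- function(x, ...) {
  cat(sprintf("<laser_state> t = %g: I = %.6g, G = %.6g, Q = %.6g\n",
              x$t, x$I, x$G, x$Q))
  invisible(x)
}
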