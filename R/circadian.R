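## Light-entrained circadian pacemaker: a van der Pol-type oscillator with
## cubic nonlinearity driven through a Process-L light-transduction stage.
## Time unit is hours throughout; light enters in lux.

#' Construct circadian oscillator parameters
#'
#' Defaults: `mu = 0.23` (best-fit stiffness), `tauX = 24.2` h intrinsic
#' period, Process-L constants `alpha0 = 0.05 /min`, `beta = 0.0075 /min`,
#' `I0 = 9500` lux, `p = 0.5`, drive gain `G = 33.75`, and a direct-light
#' coupling `kB = 1` multiplying the drive in the `x_c` equation.
#'
#' @param mu,tauX,kB,lightGain,alpha0,beta,i0,pExp see
#'   [CircadianParams-class].
#' @return a validated [CircadianParams-class].
#' @export
circadianParams <- function(mu = 0.23, tauX = 24.2, kB = 1,
                            lightGain = 33.75, alpha0 = 0.05, beta = 0.0075,
                            i0 = 9500, pExp = 0.5) {
  new("CircadianParams", mu = mu, tauX = tauX, kB = kB,
      lightGain = lightGain, alpha0 = alpha0, beta = beta, i0 = i0,
      pExp = pExp)
}

#' Integrate the light-driven circadian oscillator
#'
#' Fixed-step classical 4th-order Runge-Kutta integration (via
#' \pkg{deSolve}, method `"rk4"`) of the coupled system
#' \deqn{dx/dt = (\pi/12)(x_c + B)}
#' \deqn{dx_c/dt = (\pi/12)[\mu(x_c - 4x_c^3/3) - x(24/(0.99669\,\tau_x))^2 + k_B B]}
#' with the Process-L drive
#' \eqn{\alpha(I) = \alpha_0 (I/I_0)^p},
#' \eqn{dn/dt = 60[\alpha(I)(1-n) - \beta n]},
#' \eqn{B = G\,\alpha(I)(1-n)(1-0.4x)(1-0.4x_c)}.
#' With no light (`B = 0`) the origin is an exact fixed point and the
#' free-running period is `0.99669 * tauX` to first order.
#'
#' @param light numeric lux series sampled every `dt` seconds (recycled as a
#'   step function; a scalar gives constant light).
#' @param params a [CircadianParams-class].
#' @param init named numeric `c(x=, xc=, n=)` initial state.
#' @param dt integration step, seconds (<= 60).
#' @param durationHours total simulated time, hours; defaults to the span of
#'   `light`.
#' @return `data.frame` with columns `tHours`, `x`, `xc`, `n`, `B`. `x` is
#'   the circadian-drive feature channel.
#' @export
integrateCircadian <- function(light, params = circadianParams(),
                               init = c(x = 0, xc = 0, n = 0),
                               dt = 60, durationHours = NULL) {
  stopifnot(is(params, "CircadianParams"), dt <= 60, dt > 0)
  validObject(params)
  if (is.null(durationHours)) durationHours <- length(light) * dt / 3600
  times <- seq(0, durationHours, by = dt / 3600)
  lightAt <- if (length(light) == 1L) function(t) light else {
    lt <- (seq_along(light) - 1L) * dt / 3600
    approxfun(lt, light, method = "constant", rule = 2)
  }
  omega2 <- (24 / (0.99669 * params@tauX))^2
  deriv <- function(t, state, parms) {
    I <- max(0, lightAt(t))
    alpha <- if (I > 0) params@alpha0 * (I / params@i0)^params@pExp else 0
    B <- params@lightGain * alpha * (1 - state[3]) *
      (1 - 0.4 * state[1]) * (1 - 0.4 * state[2])
    dx <- pi / 12 * (state[2] + B)
    dxc <- pi / 12 * (params@mu * (state[2] - 4 * state[2]^3 / 3) -
                        state[1] * omega2 + params@kB * B)
    dn <- 60 * (alpha * (1 - state[3]) - params@beta * state[3])
    list(c(dx, dxc, dn), B = B)
  }
  sol <- deSolve::ode(y = unname(init[c("x", "xc", "n")]), times = times,
                      func = deriv, parms = NULL, method = "rk4")
  out <- as.data.frame(sol)
  names(out) <- c("tHours", "x", "xc", "n", "B")
  bad <- which(!is.finite(out$x) | !is.finite(out$xc))
  if (length(bad))
    stop("non-finite circadian state at step ", bad[1])
  out
}

#' Free-running period from upward zero crossings
#'
#' Measures the oscillation period of a trajectory as the mean spacing of
#' linearly interpolated upward zero crossings of `x`.
#'
#' @param traj `data.frame` from [integrateCircadian()].
#' @param skipHours initial transient to discard (default 24 h).
#' @return period in hours (`NA` if fewer than two crossings).
#' @export
freeRunningPeriod <- function(traj, skipHours = 24) {
  tr <- traj[traj$tHours >= skipHours, ]
  x <- tr$x; t <- tr$tHours
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  if (length(up) < 2L) return(NA_real_)
  cross <- t[up] + (t[up + 1] - t[up]) * (-x[up]) / (x[up + 1] - x[up])
  mean(diff(cross))
}
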