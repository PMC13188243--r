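#' @include AllClasses.R
NULL

# in-process registry; populated with the built-in systems at load time
.odeRegistry <- new.env(parent = emptyenv())

#' SIR epidemic model right-hand side
#'
#' Frequency-dependent susceptible-infected-recovered dynamics:
#' \deqn{dS/dt = -\beta S I / N,\quad dI/dt = \beta S I / N - \gamma I,\quad
#'   dR/dt = \gamma I.}
#' The three components sum to zero by construction, so the total population
#' is conserved along any noiseless trajectory.
#'
#' @param state numeric vector \code{(S, I, R)} of compartment sizes
#'   (individuals), all nonnegative.
#' @param t time (unused; the system is autonomous).
#' @param theta named numeric vector with \code{beta} (transmission rate,
#'   1/time), \code{gamma} (recovery rate, 1/time) and \code{N} (population
#'   size, must be positive).
#' @return derivative vector \code{(dS, dI, dR)}.
#' @examples
#' sirRHS(c(S = 990, I = 10, R = 0), 0,
#'        c(beta = 0.3, gamma = 0.1, N = 1000))
#' @export
sirRHS <- function(state, t = 0, theta) {
  if (!is.finite(theta[["N"]]) || theta[["N"]] <= 0)
    stop("invalid parameter: population size N must be positive")
  S <- state[[1L]]; I <- state[[2L]]
  inc <- theta[["beta"]] * S * I / theta[["N"]]
  rec <- theta[["gamma"]] * I
  # dI is the exact negative of dS + dR so that (dS + dR) + dI == 0 holds
  # bit-for-bit, not merely to rounding
  dS <- -inc
  dR <- rec
  c(dS, -(dS + dR), dR)
}

#' Lotka-Volterra predator-prey right-hand side
#'
#' \deqn{dx/dt = \alpha x - \beta x y,\quad dy/dt = \delta x y - \gamma y}
#' with prey \code{x} and predator \code{y}. The coexistence equilibrium is
#' \code{(gamma/delta, alpha/beta)}.
#'
#' @param state numeric vector \code{(x, y)} of population counts.
#' @param t time (unused).
#' @param theta named numeric vector with \code{alpha} (prey growth),
#'   \code{beta} (predation), \code{delta} (predator efficiency),
#'   \code{gamma} (predator death).
#' @return derivative vector \code{(dx, dy)}.
#' @examples
#' lvRHS(c(x = 10, y = 5), 0,
#'       c(alpha = 1.1, beta = 0.4, delta = 0.1, gamma = 0.4))
#' @export
lvRHS <- function(state, t = 0, theta) {
  x <- state[[1L]]; y <- state[[2L]]
  c(theta[["alpha"]] * x - theta[["beta"]] * x * y,
    theta[["delta"]] * x * y - theta[["gamma"]] * y)
}

#' Substrate-algae-rotifers chemostat right-hand side
#'
#' Three-state Monod chemostat extending predator-prey dynamics: dissolved
#' substrate (nitrogen) \code{Sn} flows in at dilution rate \code{delta_d},
#' algae \code{A} take it up with Monod kinetics, rotifers \code{Rt} graze
#' the algae with Monod kinetics and die at rate \code{m} on top of washout:
#' \deqn{dS_n/dt = \delta_d (S_{in} - S_n) - \mu_A S_n/(K_A+S_n) A /
#'   \epsilon_A}
#' \deqn{dA/dt = \mu_A S_n/(K_A+S_n) A - \mu_R A/(K_R+A) R_t / \epsilon_R -
#'   \delta_d A}
#' \deqn{dR_t/dt = \mu_R A/(K_R+A) R_t - (\delta_d + m) R_t.}
#'
#' @param state numeric vector \code{(Sn, A, Rt)} of concentrations, all
#'   nonnegative.
#' @param t time (unused).
#' @param theta named numeric vector with \code{delta_d} (dilution rate),
#'   \code{S_in} (inflow substrate concentration), \code{mu_A}, \code{K_A}
#'   (algal Monod uptake), \code{eps_A} (algal yield), \code{mu_R},
#'   \code{K_R} (rotifer Monod grazing), \code{eps_R} (rotifer yield),
#'   \code{m} (rotifer mortality). All must be positive; in particular the
#'   half-saturation constants \code{K_A}, \code{K_R}.
#' @return derivative vector \code{(dSn, dA, dRt)}.
#' @export
sarRHS <- function(state, t = 0, theta) {
  if (theta[["K_A"]] <= 0 || theta[["K_R"]] <= 0)
    stop("invalid parameter: half-saturation constants K_A/K_R must be positive")
  Sn <- state[[1L]]; A <- state[[2L]]; Rt <- state[[3L]]
  uptake  <- theta[["mu_A"]] * Sn / (theta[["K_A"]] + Sn) * A
  grazing <- theta[["mu_R"]] * A  / (theta[["K_R"]] + A) * Rt
  c(theta[["delta_d"]] * (theta[["S_in"]] - Sn) - uptake / theta[["eps_A"]],
    uptake - grazing / theta[["eps_R"]] - theta[["delta_d"]] * A,
    grazing - (theta[["delta_d"]] + theta[["m"]]) * Rt)
}

#' Register an ODE system in the in-process registry
#'
#' The registry is extensible: user-defined systems registered here become
#' available to the generator, the calibration baseline and the grid runner
#' by name.
#'
#' @param system an [OdeSystem-class] object.
#' @param overwrite replace an existing registration of the same name?
#' @return the registered system, invisibly.
#' @export
registerOdeSystem <- function(system, overwrite = FALSE) {
  stopifnot(is(system, "OdeSystem"))
  validObject(system)
  if (!overwrite && exists(system@name, envir = .odeRegistry))
    stop("system '", system@name,
         "' is already registered (use overwrite = TRUE)")
  assign(system@name, system, envir = .odeRegistry)
  invisible(system)
}

#' Look up a registered ODE system by name
#'
#' @param name system identifier; the built-ins are \code{"sir"},
#'   \code{"lv"} and \code{"sar"}.
#' @return the [OdeSystem-class] object.
#' @examples
#' getOdeSystem("sir")
#' @export
getOdeSystem <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !exists(name, envir = .odeRegistry))
    stop("unknown ODE system '", paste(name, collapse = ","),
         "'; available: ", paste(listOdeSystems(), collapse = ", "))
  get(name, envir = .odeRegistry)
}

#' @rdname getOdeSystem
#' @export
listOdeSystems <- function() sort(ls(envir = .odeRegistry))

.registerBuiltins <- function() {
  registerOdeSystem(new("OdeSystem",
    name = "sir",
    variables = c("S", "I", "R"),
    parameters = c("beta", "gamma", "N"),
    rhs = sirRHS,
    defaultCenters = c(S = 989, I = 10, R = 1,
                       beta = 0.3, gamma = 0.1, N = 1000),
    nonneg = TRUE), overwrite = TRUE)
  registerOdeSystem(new("OdeSystem",
    name = "lv",
    variables = c("x", "y"),
    parameters = c("alpha", "beta", "delta", "gamma"),
    rhs = lvRHS,
    defaultCenters = c(x = 10, y = 5,
                       alpha = 1.1, beta = 0.4, delta = 0.1, gamma = 0.4),
    nonneg = TRUE), overwrite = TRUE)
  registerOdeSystem(new("OdeSystem",
    name = "sar",
    variables = c("Sn", "A", "Rt"),
    parameters = c("delta_d", "S_in", "mu_A", "K_A", "eps_A",
                   "mu_R", "K_R", "eps_R", "m"),
    rhs = sarRHS,
    defaultCenters = c(Sn = 2, A = 1, Rt = 1,
                       delta_d = 0.3, S_in = 80, mu_A = 3.3, K_A = 4.3,
                       eps_A = 0.25, mu_R = 2.25, K_R = 15, eps_R = 0.25,
                       m = 0.055),
    nonneg = TRUE), overwrite = TRUE)
}

.onLoad <- function(libname, pkgname) {
  .registerBuiltins()
}
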