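#' Growth-model parameter bundle
#'
#' Bundles the parameters of the stochastic tip-complex growth model:
#' `M` independent complexes, each a product of `N` regulator concentration
#' fluctuations, every regulator relaxing as an Ornstein-Uhlenbeck (OU)
#' process with rate `theta` and stationary fluctuation SD `eta` around its
#' baseline concentration.
#'
#' @param M Number of additive complex terms (>= 1).
#' @param N Number of multiplicative factors per complex (>= 1).
#' @param theta OU relaxation rate of each regulator, in 1/min (> 0).
#' @param eta Stationary fluctuation SD of each regulator, in concentration
#'   units (>= 0). The OU driving noise obeys
#'   \eqn{\langle W(t)W(s)\rangle = 2\theta\eta^2\delta(t-s)}.
#' @param baselines Baseline concentrations, one per regulator (length
#'   `M * N`, all >= 0). A scalar is recycled.
#' @param dt Integration step of the Euler-Maruyama scheme, in seconds
#'   (default 1).
#' @param duration Total simulated time, in minutes.
#' @param seed Integer seed for reproducible simulation.
#'
#' @details The explicit scheme requires `theta * dt < 1` with `dt`
#'   expressed in minutes; the constructor rejects parameter sets violating
#'   this stability bound. Default `theta` and `eta` reflect the regime in
#'   which fitted relaxation rates are of order 10/min and simulated
#'   20-minute lengths populate the 5-20 um analysis window.
#'
#' @return An object of class `growth_model_params`.
#' @export
growth_model_params <- function(M = 2L, N = 2L, theta = 11, eta = 2,
                                baselines = 10, dt = 1, duration = 20,
                                seed = 1L) {
  M <- as.integer(M); N <- as.integer(N)
  stopifnot(M >= 1L, N >= 1L)
  if (!is.numeric(theta) || theta <= 0) stop("theta must be > 0 (1/min)")
  if (!is.numeric(eta) || eta < 0) stop("eta must be >= 0")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0 (seconds)")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0 (minutes)")
  K <- M * N
  baselines <- rep_len(as.numeric(baselines), K)
  if (any(baselines < 0)) stop("baselines must be >= 0")
  if (theta * dt / 60 >= 1)
    stop("unstable discretization: theta * dt (dt in minutes) must be < 1")
  structure(
    list(M = M, N = N, theta = theta, eta = eta, baselines = baselines,
         dt = dt, duration = duration, seed = as.integer(seed)),
    class = "growth_model_params"
  )
}

#' @export
print.growth_model_params <- function(x, ...) {
  cat(sprintf(
    "Growth model: M = %d complexes x N = %d factors (K = %d regulators)\n",
    x$M, x$N, x$M * x$N))
  cat(sprintf("  theta = %g /min, eta = %g, dt = %g s, duration = %g min, seed = %d\n",
              x$theta, x$eta, x$dt, x$duration, x$seed))
  invisible(x)
}

#' Reaction-network parameter bundle
#'
#' Parameters of the mass-action reduction of the growth model: 2M species
#' produced at rate `sigma`, pairing at rate `rho` into M complexes that
#' decay at rate `eta_decay`. Species concentrations fluctuate around the
#' steady state \eqn{\sqrt{\sigma/\rho}} with OU dynamics (relaxation
#' `theta_a`, SD `eta_a`) reflected at zero so concentrations stay
#' non-negative.
#'
#' @param sigma Production rate (> 0).
#' @param rho Pairing rate (> 0).
#' @param eta_decay Complex decay rate (> 0). Named to avoid collision with
#'   the OU noise amplitude `eta` of [growth_model_params()].
#' @param M Number of complexes (>= 1).
#' @param theta_a OU relaxation rate of the species fluctuations (1/min).
#' @param eta_a Stationary SD of the species fluctuations. The default is
#'   large relative to the mean \eqn{\sqrt{\sigma/\rho}}, i.e. the
#'   large-variance regime in which the cross terms are negligible and the
#'   velocity distribution approaches a Laplace.
#' @return An object of class `reaction_network_params`.
#' @export
reaction_network_params <- function(sigma = 1, rho = 1, eta_decay = 3,
                                    M = 2L, theta_a = 6, eta_a = NULL) {
  stopifnot(sigma > 0, rho > 0, eta_decay > 0, M >= 1)
  if (is.null(eta_a)) eta_a <- 10 * sqrt(sigma / rho)
  stopifnot(theta_a > 0, eta_a >= 0)
  structure(
    list(sigma = sigma, rho = rho, eta_decay = eta_decay, M = as.integer(M),
         theta_a = theta_a, eta_a = eta_a),
    class = "reaction_network_params"
  )
}

#' Read growth-model parameters from a YAML config
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [growth_model_params()].
#' @return A `growth_model_params` object.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(growth_model_params, cfg)
}

#' Write growth-model parameters to a YAML config
#'
#' @param params A `growth_model_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "growth_model_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
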