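#' Diffusion parameters for the aggregate adoption recurrence
#'
#' Bundles the two rates of the difference-equation adoption model:
#' `alpha`, the rate of behavior contraction by spontaneous or environmental
#' factors, and `beta`, the rate of contraction by social interaction and
#' imitation.  Both are per unit time and non-negative.
#'
#' @param alpha Spontaneous/environmental contraction rate (>= 0).
#' @param beta Social/imitation contraction rate (>= 0).
#' @return An object of class `diffusion_params`.
#' @examples
#' diffusion_params(alpha = 0.05, beta = 0.3)
#' @export
diffusion_params <- function(alpha, beta) {
  stopifnot_scalar(alpha, "alpha", lower = 0)
  stopifnot_scalar(beta, "beta", lower = 0)
  structure(list(alpha = alpha, beta = beta), class = "diffusion_params")
}

#' One step of the discrete adoption recurrence
#'
#' Advances the adopted fraction by
#' `S(t) = S(t-1) + alpha (1 - S(t-1)) + beta (1 - S(t-1)) S(t-1)`,
#' clipped to \[0, 1\] (large `alpha + beta` can overshoot 1 in the raw
#' recurrence; the model works on fractions).
#'
#' @param s_prev Adopted fraction at the previous step, in \[0, 1\].
#' @param params A [diffusion_params()] object.
#' @return The adopted fraction after one step.
#' @examples
#' step_discrete_adoption(0.5, diffusion_params(0.1, 0.4)) # 0.65
#' @export
step_discrete_adoption <- function(s_prev, params) {
  stopifnot(inherits(params, "diffusion_params"))
  stopifnot_scalar(s_prev, "s_prev", lower = 0, upper = 1)
  s <- s_prev + params$alpha * (1 - s_prev) +
    params$beta * (1 - s_prev) * s_prev
  min(max(s, 0), 1)
}

#' Simulate the discrete adoption recurrence
#'
#' @param params A [diffusion_params()] object.
#' @param s0 Initial adopted fraction (default 0).
#' @param n_steps Number of steps (>= 1).
#' @return A data frame with columns `time` (0..n_steps) and `fraction`.
#' @examples
#' simulate_discrete_adoption(diffusion_params(0.05, 0.3), n_steps = 10)
#' @export
simulate_discrete_adoption <- function(params, s0 = 0, n_steps) {
  stopifnot(inherits(params, "diffusion_params"))
  stopifnot_scalar(s0, "s0", lower = 0, upper = 1)
  stopifnot_scalar(n_steps, "n_steps", lower = 1, integer = TRUE)
  s <- numeric(n_steps + 1L)
  s[1L] <- s0
  for (t in seq_len(n_steps))
    s[t + 1L] <- step_discrete_adoption(s[t], params)
  data.frame(time = 0:n_steps, fraction = s)
}

#' Closed-form solution of the continuous adoption model
#'
#' Evaluates the solution of `dS/dt = (alpha + beta S)(1 - S)` with
#' `S(0) = 0`,
#' `S(t) = (1 - exp(-(alpha+beta) t)) / (1 + (beta/alpha) exp(-(alpha+beta) t))`.
#' The closed form assumes `alpha > 0`; `alpha = 0` is rejected.  Starting
#' fractions other than 0 are handled by numerical integration of the ODE,
#' not by this closed form.
#'
#' @param params A [diffusion_params()] object with `alpha > 0`.
#' @param t Vector of non-negative times.
#' @return Adopted fractions at `t`.
#' @examples
#' adoption_closed_form(diffusion_params(0.5, 0.5), 1) # 0.46212
#' @export
adoption_closed_form <- function(params, t) {
  stopifnot(inherits(params, "diffusion_params"))
  if (params$alpha <= 0)
    stop("closed form requires alpha > 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and >= 0", call. = FALSE)
  e <- exp(-(params$alpha + params$beta) * t)
  (1 - e) / (1 + (params$beta / params$alpha) * e)
}

#' System-dynamics adoption model parameters
#'
#' Fixed factors of the stock-and-flow adoption model: `TotalPopulation`,
#' `ContactRate` (contacts per person per unit time), `AdoptionFraction`
#' (probability a contact with an adopter yields adoption) and
#' `ImitationEffectiveness` (per-unit-time hazard of contact-free adoption).
#' The naming is kept as in the stock-and-flow formulation:
#' `AdoptionFromImitation = PotentialAdopters * ImitationEffectiveness` and
#' `AdoptionFromWOM = Adopters * PotentialAdopters * ContactRate *
#' AdoptionFraction / TotalPopulation`.
#'
#' @param total_population Population size (> 0).
#' @param contact_rate Contacts per person per unit time (>= 0).
#' @param adoption_fraction Probability a contact yields adoption, in \[0, 1\].
#' @param imitation_effectiveness Per-unit-time hazard, in \[0, 1\].
#' @return An object of class `sd_adoption_params`.
#' @export
sd_adoption_params <- function(total_population, contact_rate,
                               adoption_fraction, imitation_effectiveness) {
  stopifnot_scalar(total_population, "total_population", lower = 1e-12)
  stopifnot_scalar(contact_rate, "contact_rate", lower = 0)
  stopifnot_scalar(adoption_fraction, "adoption_fraction", 0, 1)
  stopifnot_scalar(imitation_effectiveness, "imitation_effectiveness", 0, 1)
  structure(list(total_population = total_population,
                 contact_rate = contact_rate,
                 adoption_fraction = adoption_fraction,
                 imitation_effectiveness = imitation_effectiveness),
            class = "sd_adoption_params")
}

sd_flows <- function(potential, params) {
  adopters <- params$total_population - potential
  imitation <- potential * params$imitation_effectiveness
  wom <- adopters * potential * params$contact_rate *
    params$adoption_fraction / params$total_population
  list(imitation = imitation, wom = wom, rate = imitation + wom)
}

#' Simulate the system-dynamics adoption model
#'
#' Integrates `d(PotentialAdopters)/dt = -(AdoptionFromImitation +
#' AdoptionFromWOM)` with an adaptive solver (the model is non-stiff at
#' typical parameter values) and reports stocks and flows at fixed output
#' times.  `Adopters = TotalPopulation - PotentialAdopters` throughout.
#'
#' @param params An [sd_adoption_params()] object.
#' @param adopters0 Initial adopter count (default 0).
#' @param horizon End time of the simulation.
#' @param dt Output sampling interval (> 0 and < `horizon`); the internal
#'   integration step is adaptive.
#' @param rtol,atol Solver tolerances.
#' @return A data frame with columns `time`, `potential_adopters`,
#'   `adopters`, `adoption_from_imitation`, `adoption_from_wom`,
#'   `adoption_rate`.
#' @examples
#' p <- sd_adoption_params(1e6, 100, 0.015, 0.011)
#' traj <- simulate_sd_adoption(p, horizon = 10, dt = 0.1)
#' @export
simulate_sd_adoption <- function(params, adopters0 = 0, horizon, dt,
                                 rtol = 1e-10, atol = 1e-8) {
  stopifnot(inherits(params, "sd_adoption_params"))
  stopifnot_scalar(adopters0, "adopters0", 0, params$total_population)
  stopifnot_scalar(horizon, "horizon", lower = 1e-12)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0 || dt >= horizon)
    stop("`dt` must be positive and smaller than `horizon`", call. = FALSE)
  times <- seq(0, horizon, by = dt)
  deriv <- function(t, y, parms) {
    list(-sd_flows(y[["potential"]], params)$rate)
  }
  sol <- deSolve::ode(y = c(potential = params$total_population - adopters0),
                      times = times, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  potential <- pmin(pmax(sol[, "potential"], 0), params$total_population)
  fl <- sd_flows(potential, params)
  data.frame(time = sol[, "time"],
             potential_adopters = potential,
             adopters = params$total_population - potential,
             adoption_from_imitation = fl$imitation,
             adoption_from_wom = fl$wom,
             adoption_rate = fl$rate)
}

#' SIR model parameters
#'
#' Accepts either the stock-and-flow parameterisation (`contact_rate_c`,
#' `infectivity`, `avg_duration`, `total_population`, `initial_infectious`)
#' with `InfectionRate = ContactRateC * InfectivityI * S * I / N` and
#' `RecoveryRate = I / AverageDurationOfIllnessD`, or the normalised form
#' with transmission rate `rho` and `recovery_rate`.  Internally
#' `rho = contact_rate_c * infectivity` and `recovery_rate = 1/avg_duration`.
#'
#' @param contact_rate_c Contacts per person per unit time.
#' @param infectivity Per-contact transmission probability, in \[0, 1\].
#' @param avg_duration Mean duration of the infectious behavior state (> 0).
#' @param total_population Population size (default 1, i.e. fractions).
#' @param initial_infectious Initially infectious count (>= 0, <= N).
#' @param initial_recovered Initially recovered count (default 0).
#' @param rho Normalised transmission rate (alternative form).
#' @param recovery_rate Normalised recovery rate (alternative form).
#' @return An object of class `sir_params`.
#' @export
sir_params <- function(contact_rate_c = NULL, infectivity = NULL,
                       avg_duration = NULL, total_population = 1,
                       initial_infectious = 0, initial_recovered = 0,
                       rho = NULL, recovery_rate = NULL) {
  if (is.null(rho)) {
    stopifnot_scalar(contact_rate_c, "contact_rate_c", lower = 0)
    stopifnot_scalar(infectivity, "infectivity", 0, 1)
    rho <- contact_rate_c * infectivity
  } else stopifnot_scalar(rho, "rho", lower = 0)
  if (is.null(recovery_rate)) {
    stopifnot_scalar(avg_duration, "avg_duration", lower = 1e-12)
    recovery_rate <- 1 / avg_duration
  } else stopifnot_scalar(recovery_rate, "recovery_rate", lower = 0)
  stopifnot_scalar(total_population, "total_population", lower = 1e-12)
  stopifnot_scalar(initial_infectious, "initial_infectious", 0,
                   total_population)
  stopifnot_scalar(initial_recovered, "initial_recovered", 0,
                   total_population - initial_infectious)
  structure(list(rho = rho, recovery_rate = recovery_rate,
                 total_population = total_population,
                 initial_infectious = initial_infectious,
                 initial_recovered = initial_recovered),
            class = "sir_params")
}

#' Simulate the SIR model
#'
#' Integrates `dS/dt = -rho S I`, `dI/dt = rho S I - a I`, `dR/dt = a I`
#' on compartment fractions (`S + I + R = 1`), with
#' `S(0) = N - I0 - R0`, `R(0) = R0` scaled by the population size.
#'
#' @param params A [sir_params()] object.
#' @param horizon End time.
#' @param dt Output sampling interval.
#' @param rtol,atol Solver tolerances (defaults keep the compartment total
#'   conserved to ~1e-10).
#' @return A data frame with columns `time`, `s`, `i`, `r` (fractions); the
#'   population size is attached as attribute `total_population`.
#' @examples
#' traj <- simulate_sir(sir_params(rho = 0.5, recovery_rate = 0.2,
#'                                 initial_infectious = 0.01),
#'                      horizon = 50, dt = 0.5)
#' @export
simulate_sir <- function(params, horizon, dt, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "sir_params"))
  stopifnot_scalar(horizon, "horizon", lower = 1e-12)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0 || dt >= horizon)
    stop("`dt` must be positive and smaller than `horizon`", call. = FALSE)
  N <- params$total_population
  i0 <- params$initial_infectious / N
  r0 <- params$initial_recovered / N
  y0 <- c(s = 1 - i0 - r0, i = i0, r = r0)
  deriv <- function(t, y, p) {
    inf <- params$rho * y[["s"]] * y[["i"]]
    rec <- params$recovery_rate * y[["i"]]
    list(c(-inf, inf - rec, rec))
  }
  sol <- deSolve::ode(y = y0, times = seq(0, horizon, by = dt), func = deriv,
                      parms = NULL, rtol = rtol, atol = atol)
  if (min(sol[, c("s", "i", "r")]) < -1e-8)
    stop("negative compartment during integration; reduce `dt` or tolerances",
         call. = FALSE)
  out <- data.frame(time = sol[, "time"], s = sol[, "s"], i = sol[, "i"],
                    r = sol[, "r"])
  attr(out, "total_population") <- N
  out
}

#' First crossing time of an adoption level
#'
#' Returns the first time a trajectory reaches `level`, linearly
#' interpolated between output points, or `NA` if the level is never
#' reached.
#'
#' @param traj A data frame with a time column and a value column (for
#'   example from [simulate_discrete_adoption()] or
#'   [simulate_sd_adoption()]).
#' @param level Target level, strictly between the trajectory's scale
#'   bounds (for fractions, in (0, 1)).
#' @param value_col,time_col Column names (defaults `"fraction"`,
#'   `"time"`).
#' @return A time, or `NA_real_` if never crossed.
#' @examples
#' traj <- data.frame(time = 1:2, fraction = c(0.4, 0.6))
#' time_to_adoption(traj, 0.5) # 1.5
#' @export
time_to_adoption <- function(traj, level, value_col = "fraction",
                             time_col = "time") {
  if (!is.data.frame(traj) || nrow(traj) == 0L)
    stop("`traj` must be a non-empty data frame", call. = FALSE)
  if (!all(c(value_col, time_col) %in% names(traj)))
    stop(sprintf("`traj` must have columns `%s` and `%s`",
                 time_col, value_col), call. = FALSE)
  stopifnot_scalar(level, "level")
  v <- traj[[value_col]]
  t <- traj[[time_col]]
  hit <- which(v >= level)
  if (length(hit) == 0L) return(NA_real_)
  k <- hit[1L]
  if (k == 1L || v[k] == level) return(t[k])
  # linear interpolation between the bracketing output points
  t[k - 1L] + (level - v[k - 1L]) / (v[k] - v[k - 1L]) * (t[k] - t[k - 1L])
}
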