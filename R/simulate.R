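#' Simulation specification
#'
#' Bundles everything one integration needs: strategy, parameters, initial
#' state, time horizon, output sampling, the fraction of the run discarded as
#' transient before attractor-level analysis, and integrator tolerances.
#'
#' Defaults: a 43,800 h (five-year) horizon with the final 20\% analysed,
#' hourly output, and relative/absolute tolerances of 1e-8. The long horizon
#' lets slow forcing periods (up to one year) express several cycles; the
#' hourly sampling resolves day-scale oscillations.
#'
#' @param strategy One of \code{\link{PHAGE_STRATEGIES}}.
#' @param params A \code{\link{phage_params}} object.
#' @param initial_state Named state vector (\code{\link{phage_state}}); by
#'   default the reference initial condition with \code{N(0) = N0}.
#' @param t_end Simulated duration, h (> 0).
#' @param output_step Output sampling interval, h.
#' @param transient_fraction Fraction of \code{t_end} discarded before
#'   analysis, in [0, 1).
#' @param rel_tol,abs_tol Integrator tolerances (> 0).
#' @return An object of class \code{simulation_spec}.
#' @examples
#' simulation_spec("lytic", phage_params(), t_end = 1000)
#' @export
simulation_spec <- function(strategy, params = phage_params(),
                            initial_state = phage_state(N = params$N0),
                            t_end = 43800, output_step = 1,
                            transient_fraction = 0.8,
                            rel_tol = 1e-8, abs_tol = 1e-8) {
  strategy <- match.arg(strategy, PHAGE_STRATEGIES)
  stopifnot(inherits(params, "phage_params"))
  if (!identical(names(initial_state), STATE_VARS))
    stop("initial_state must be a named vector with components ",
         paste(STATE_VARS, collapse = ", "), call. = FALSE)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (output_step <= 0 || output_step > t_end)
    stop("output_step must lie in (0, t_end]", call. = FALSE)
  if (transient_fraction < 0 || transient_fraction >= 1)
    stop("transient_fraction must lie in [0, 1)", call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  structure(list(strategy = strategy, params = params,
                 initial_state = initial_state, t_end = t_end,
                 output_step = output_step,
                 transient_fraction = transient_fraction,
                 rel_tol = rel_tol, abs_tol = abs_tol),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec>", x$strategy, "strategy,",
      "t_end =", x$t_end, "h, output every", x$output_step, "h\n")
  cat("  N0 =", x$params$N0, " a =", x$params$a,
      if (x$params$a > 0) paste(" T =", x$params$T, "h") else "", "\n")
  invisible(x)
}

#' Integrate the model over time
#'
#' Runs the chemostat ODEs from t = 0 to \code{t_end} with an adaptive
#' embedded Runge-Kutta 5(4) scheme (Cash-Karp pair) acting on the compiled
#' right-hand side, sampling the solution every \code{output_step} hours.
#' With the \code{"none"} strategy the infected and phage compartments stay
#' identically zero.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return A \code{phage_trajectory}: a data frame with columns
#'   \code{time_h}, \code{B1}, \code{B2}, \code{I1}, \code{I2}, \code{P1},
#'   \code{P2}, \code{N}, carrying \code{spec} as an attribute.
#' @examples
#' traj <- run_simulation(simulation_spec("lytic", t_end = 500))
#' tail(traj, 3)
#' @export
run_simulation <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  times <- seq(0, spec$t_end, by = spec$output_step)
  if (spec$strategy == "none") {
    # phage-free scenario: infected and phage compartments held at zero
    spec$initial_state[c("I1", "I2", "P1", "P2")] <- 0
  }
  pvec <- params_to_cvec(spec$params, spec$strategy)
  sol <- deSolve::ode(
    y = spec$initial_state, times = times,
    func = "phagestrat_derivs", parms = pvec,
    dllname = "phagestrat", initfunc = "phagestrat_init",
    method = deSolve::rkMethod("rk45ck"),
    rtol = spec$rel_tol, atol = spec$abs_tol,
    maxsteps = 1e6)
  if (attr(sol, "istate")[1] < 0 || !all(is.finite(sol)))
    stop("integration failed near t = ", max(sol[is.finite(sol[, 1]), 1]),
         " h (", spec$strategy, " strategy, N0 = ", spec$params$N0, ")",
         call. = FALSE)
  out <- as.data.frame(sol)
  names(out) <- c("time_h", STATE_VARS)
  structure(out, spec = spec,
            class = c("phage_trajectory", "data.frame"))
}

#' Restrict a trajectory to its post-transient window
#'
#' Keeps the samples with \code{t >= transient_fraction * t_end}, the window
#' on which attractor-level quantities (extrema, persistence) are measured.
#'
#' @param traj A \code{phage_trajectory}.
#' @return The restricted trajectory (same class and \code{spec} attribute).
#' @examples
#' traj <- run_simulation(simulation_spec("none", t_end = 100,
#'                                        transient_fraction = 0.5))
#' range(final_window(traj)$time_h)
#' @export
final_window <- function(traj) {
  stopifnot(inherits(traj, "phage_trajectory"))
  spec <- attr(traj, "spec")
  keep <- traj$time_h >= spec$transient_fraction * spec$t_end
  if (!any(keep))
    stop("post-transient window is empty", call. = FALSE)
  structure(traj[keep, , drop = FALSE], spec = spec,
            class = class(traj))
}

#' Write / read a trajectory as CSV
#'
#' Plain CSV with header \code{time_h,B1,B2,I1,I2,P1,P2,N} in normalized
#' units; optionally a companion file with bacterial and phage densities
#' converted back to particles/mL (columns suffixed
#' \code{_particles_per_ml}).
#'
#' @param traj A \code{phage_trajectory}.
#' @param path Output CSV path.
#' @param denormalized Also write the particles/mL companion file
#'   (\code{<path stem>_particles_per_ml.csv})?
#' @param raw A \code{\link{raw_quantities}} object for the conversion.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, denormalized = FALSE,
                             raw = raw_quantities()) {
  stopifnot(inherits(traj, "phage_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (denormalized) {
    dn <- as.data.frame(traj)
    for (v in c("B1", "B2", "I1", "I2"))
      dn[[v]] <- denormalize_abundance(dn[[v]], "bacteria", raw)
    for (v in c("P1", "P2"))
      dn[[v]] <- denormalize_abundance(dn[[v]], "phage", raw)
    names(dn) <- c("time_h", paste0(STATE_VARS, "_particles_per_ml"))
    p2 <- paste0(tools::file_path_sans_ext(path), "_particles_per_ml.csv")
    utils::write.csv(dn, p2, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @param spec The \code{\link{simulation_spec}} to re-attach on read (CSV
#'   does not carry it).
#' @export
read_trajectory <- function(path, spec) {
  out <- utils::read.csv(path)
  if (!identical(names(out), c("time_h", STATE_VARS)))
    stop("not a trajectory CSV: ", path, call. = FALSE)
  structure(out, spec = spec, class = c("phage_trajectory", "data.frame"))
}
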