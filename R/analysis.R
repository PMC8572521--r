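# Trajectory-level analysis: persistence classification, extrema detection,
# bifurcation scans over nutrient supply, 2-D fluctuation sweeps, and
# bisection estimates of survival thresholds.

#' Classify the persistence state of a trajectory
#'
#' A component survives iff its maximum over the post-transient window
#' reaches the extinction threshold (the maximum, not the final value, so
#' oscillating populations that dip low are not misclassified). Each phage
#' and its infected compartment count as one "infection" state, which
#' survives only if both \code{I_k} and \code{P_k} do. The code is the count
#' of surviving states among \{fast grower, its infection, slow grower, its
#' infection\}: 0 none ... 4 all. The canonical ladder is 1 = fast grower
#' only, 2 = fast grower + its infection, 3 = both bacteria + the fast
#' grower's infection, 4 = everything; off-ladder flag combinations keep
#' their flags and map to the code by count.
#'
#' @param traj A \code{phage_trajectory} covering the post-transient window.
#' @param extinction_threshold Normalized density below which a component is
#'   counted extinct. Default 1e-6 (about 10 bacteria particles/mL): far
#'   below every attractor scale of the model, far above integrator noise.
#' @return An object of class \code{persistence_state}: list with integer
#'   \code{code} and named logical \code{survived} =
#'   \code{c(B1, inf1, B2, inf2)}.
#' @examples
#' traj <- run_simulation(simulation_spec("lytic", t_end = 2000))
#' classify_persistence(traj)
#' @export
classify_persistence <- function(traj, extinction_threshold = 1e-6) {
  w <- final_window(traj)
  alive <- function(v) max(w[[v]]) >= extinction_threshold
  survived <- c(B1 = alive("B1"),
                inf1 = alive("I1") && alive("P1"),
                B2 = alive("B2"),
                inf2 = alive("I2") && alive("P2"))
  structure(list(code = as.integer(sum(survived)), survived = survived),
            class = "persistence_state")
}

#' @export
print.persistence_state <- function(x, ...) {
  cat("<persistence_state> code", x$code, "|",
      paste(names(x$survived)[x$survived], collapse = " "), "\n")
  invisible(x)
}

#' Post-transient local extrema of a scalar series
#'
#' Interior local minima and maxima found by sign changes of the discrete
#' differences, with a relative-amplitude floor: the series counts as
#' oscillating only if \code{(max - min) / max} exceeds \code{rel_floor};
#' otherwise it is steady and its mean is returned as the single extremum.
#' Plateau samples (zero difference) are carried through so flat-topped
#' oscillations are still detected.
#'
#' @param series Numeric vector (at least 3 samples).
#' @param rel_floor Relative amplitude below which the series is steady.
#' @return List with \code{oscillating} (logical), \code{minima} and
#'   \code{maxima} (numeric vectors of extremal values; for a steady series
#'   both hold the mean).
#' @examples
#' detect_extrema(sin(seq(0, 6 * pi, by = 0.01)))
#' detect_extrema(rep(1, 10))
#' @export
detect_extrema <- function(series, rel_floor = 1e-3) {
  n <- length(series)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  lo <- min(series); hi <- max(series)
  if (hi <= 0 || (hi - lo) / hi <= rel_floor) {
    m <- mean(series)
    return(list(oscillating = FALSE, minima = m, maxima = m))
  }
  d <- sign(diff(series))
  # carry the previous slope across plateaus so flat tops register once
  for (i in seq_along(d)[-1]) if (d[i] == 0) d[i] <- d[i - 1]
  turn <- diff(d)
  idx <- which(turn != 0) + 1L
  maxima <- series[idx[turn[idx - 1L] < 0]]
  minima <- series[idx[turn[idx - 1L] > 0]]
  if (!length(maxima)) maxima <- hi
  if (!length(minima)) minima <- lo
  list(oscillating = TRUE, minima = minima, maxima = maxima)
}

#' Bifurcation scan over the nutrient supply concentration
#'
#' Runs one simulation per value of \code{N0} (all other parameters fixed)
#' and records, for every state variable, the post-transient extrema — a
#' single value where the attractor is a steady state, the set of cycle
#' minima/maxima where it oscillates — together with the persistence
#' classification. The fluctuating variant applies sinusoidal turnover
#' forcing with the given amplitude and period.
#'
#' @param strategy One of \code{\link{PHAGE_STRATEGIES}}.
#' @param params Base \code{\link{phage_params}}; its \code{N0}, \code{a}
#'   and \code{T} are overridden per scan point.
#' @param N0_grid Supply concentrations to scan (within [0.6, 30]).
#' @param fluctuating Apply forcing? If \code{TRUE}, uses \code{a} and
#'   \code{T_h} below.
#' @param a,T_h Forcing amplitude and period (defaults 0.5 and 7 days).
#' @param extinction_threshold Passed to \code{\link{classify_persistence}}.
#' @param t_end,output_step,transient_fraction,rel_tol,abs_tol Simulation
#'   settings (see \code{\link{simulation_spec}}).
#' @return An object of class \code{bifurcation_diagram}: list with the
#'   grid, per-point extrema (list of per-variable results), persistence
#'   codes, survival flags, and any per-point integration errors.
#' @export
bifurcation_scan <- function(strategy, params = phage_params(), N0_grid,
                             fluctuating = FALSE, a = 0.5, T_h = 168,
                             extinction_threshold = 1e-6,
                             t_end = 43800, output_step = 1,
                             transient_fraction = 0.8,
                             rel_tol = 1e-6, abs_tol = 1e-8) {
  strategy <- match.arg(strategy, PHAGE_STRATEGIES)
  pts <- vector("list", length(N0_grid))
  codes <- integer(length(N0_grid))
  flags <- matrix(NA, length(N0_grid), 4,
                  dimnames = list(NULL, c("B1", "inf1", "B2", "inf2")))
  errors <- character(length(N0_grid))
  for (j in seq_along(N0_grid)) {
    p <- params
    p$N0 <- N0_grid[j]
    p$a <- if (fluctuating) a else 0
    if (fluctuating) p$T <- T_h
    res <- tryCatch({
      spec <- simulation_spec(strategy, p,
                              initial_state = phage_state(N = p$N0),
                              t_end = t_end, output_step = output_step,
                              transient_fraction = transient_fraction,
                              rel_tol = rel_tol, abs_tol = abs_tol)
      traj <- run_simulation(spec)
      w <- final_window(traj)
      ext <- lapply(STATE_VARS, function(v) detect_extrema(w[[v]]))
      names(ext) <- STATE_VARS
      ps <- classify_persistence(traj, extinction_threshold)
      list(ext = ext, ps = ps, err = "")
    }, error = function(e) list(ext = NULL, ps = NULL,
                                err = conditionMessage(e)))
    pts[[j]] <- res$ext
    errors[j] <- res$err
    if (!is.null(res$ps)) {
      codes[j] <- res$ps$code
      flags[j, ] <- res$ps$survived
    } else codes[j] <- NA_integer_
  }
  structure(list(strategy = strategy, N0 = N0_grid, extrema = pts,
                 codes = codes, survived = flags, errors = errors,
                 fluctuating = fluctuating,
                 a = if (fluctuating) a else 0,
                 T_h = if (fluctuating) T_h else NA_real_,
                 extinction_threshold = extinction_threshold),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram>", x$strategy, "strategy,",
      length(x$N0), "N0 points in [", min(x$N0), ",", max(x$N0), "]",
      if (x$fluctuating) sprintf("forced (a = %g, T = %g h)", x$a, x$T_h)
      else "constant supply", "\n")
  cat("  persistence codes:", paste(x$codes, collapse = " "), "\n")
  invisible(x)
}

#' Smallest N0 on a scan with at least a given persistence code
#'
#' @param bd A \code{bifurcation_diagram}.
#' @param min_code Persistence code to reach (default 3 = bacterial
#'   coexistence).
#' @return The smallest grid \code{N0} whose code is \code{>= min_code}, or
#'   \code{NA} if none.
#' @export
coexistence_onset <- function(bd, min_code = 3) {
  stopifnot(inherits(bd, "bifurcation_diagram"))
  hit <- which(!is.na(bd$codes) & bd$codes >= min_code)
  if (!length(hit)) NA_real_ else min(bd$N0[hit])
}

#' Two-dimensional fluctuation sweep
#'
#' Classifies the persistence state on a grid of forcing intensity versus
#' nutrient supply, one simulation per cell: either relative amplitude
#' \code{a} (period fixed, default 30 days) or period \code{T} (amplitude
#' fixed, default 0.9) against \code{N0}.
#'
#' @param strategy One of \code{\link{PHAGE_STRATEGIES}}.
#' @param params Base \code{\link{phage_params}}.
#' @param axis \code{"amplitude"} or \code{"period"}.
#' @param axis_grid Values of the forcing axis: amplitudes in [0, 0.99] or
#'   periods in hours within [24, 8760].
#' @param N0_grid Supply concentrations (within [0.6, 8] for the reference
#'   sweeps).
#' @param fixed_T_h Period used when sweeping amplitude, h.
#' @param fixed_a Amplitude used when sweeping period.
#' @param extinction_threshold Passed to \code{\link{classify_persistence}}.
#' @param t_end,output_step,transient_fraction,rel_tol,abs_tol Simulation
#'   settings per cell.
#' @return An object of class \code{sweep_result}: list with the grids, an
#'   integer \code{codes} matrix (rows = forcing axis, columns = N0), a
#'   4-slice logical \code{survived} array, and an \code{errors} character
#'   matrix.
#' @export
sweep_2d <- function(strategy, params = phage_params(),
                     axis = c("amplitude", "period"),
                     axis_grid, N0_grid,
                     fixed_T_h = 720, fixed_a = 0.9,
                     extinction_threshold = 1e-6,
                     t_end = 43800, output_step = 2,
                     transient_fraction = 0.8,
                     rel_tol = 1e-6, abs_tol = 1e-8) {
  strategy <- match.arg(strategy, PHAGE_STRATEGIES)
  axis <- match.arg(axis)
  nr <- length(axis_grid); nc <- length(N0_grid)
  codes <- matrix(NA_integer_, nr, nc)
  survived <- array(NA, c(nr, nc, 4),
                    dimnames = list(NULL, NULL,
                                    c("B1", "inf1", "B2", "inf2")))
  errors <- matrix("", nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      p <- params
      p$N0 <- N0_grid[j]
      if (axis == "amplitude") {
        p$a <- axis_grid[i]; p$T <- fixed_T_h
      } else {
        p$a <- fixed_a; p$T <- axis_grid[i]
      }
      res <- tryCatch({
        spec <- simulation_spec(strategy, p,
                                initial_state = phage_state(N = p$N0),
                                t_end = t_end, output_step = output_step,
                                transient_fraction = transient_fraction,
                                rel_tol = rel_tol, abs_tol = abs_tol)
        classify_persistence(run_simulation(spec), extinction_threshold)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[i, j] <- conditionMessage(res)
      } else {
        codes[i, j] <- res$code
        survived[i, j, ] <- res$survived
      }
    }
  }
  structure(list(strategy = strategy, axis = axis, axis_grid = axis_grid,
                 N0 = N0_grid, codes = codes, survived = survived,
                 errors = errors,
                 fixed_T_h = if (axis == "amplitude") fixed_T_h else NA_real_,
                 fixed_a = if (axis == "period") fixed_a else NA_real_,
                 extinction_threshold = extinction_threshold),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", x$strategy, "strategy,", x$axis, "x N0 grid",
      nrow(x$codes), "x", ncol(x$codes), "\n")
  m <- x$codes
  dimnames(m) <- list(signif(x$axis_grid, 3), signif(x$N0, 3))
  print(m)
  invisible(x)
}

#' Bisect the nutrient supply at a survival transition
#'
#' Finds the \code{N0} at which a component (or a minimum persistence code)
#' switches between surviving and extinct, by bisection of the survival
#' predicate evaluated on full simulations. The bracket must straddle the
#' transition: the predicate must differ between its two ends.
#'
#' @param strategy One of \code{\link{PHAGE_STRATEGIES}}.
#' @param params Base \code{\link{phage_params}}.
#' @param component One of \code{"B1"}, \code{"inf1"}, \code{"B2"},
#'   \code{"inf2"} (survival flag of \code{\link{classify_persistence}}),
#'   or \code{"code>=k"} for k in 1..4 (e.g. \code{"code>=3"} for the
#'   bacterial-coexistence onset).
#' @param bracket Length-2 numeric \code{c(N0_lo, N0_hi)}.
#' @param tolerance Bracket width at which bisection stops; the midpoint of
#'   the final bracket is returned.
#' @param survives Optional predicate \code{function(N0) -> logical}
#'   replacing the simulation-based one (used to test the bisection
#'   machinery against closed-form transitions).
#' @param extinction_threshold,t_end,output_step,transient_fraction,rel_tol,abs_tol
#'   Simulation settings for the default predicate.
#' @return The estimated transition \code{N0}.
#' @export
find_critical_N0 <- function(strategy, params = phage_params(),
                             component = "B1", bracket, tolerance = 0.05,
                             survives = NULL,
                             extinction_threshold = 1e-6,
                             t_end = 43800, output_step = 1,
                             transient_fraction = 0.8,
                             rel_tol = 1e-6, abs_tol = 1e-8) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2], tolerance > 0)
  if (is.null(survives)) {
    strategy <- match.arg(strategy, PHAGE_STRATEGIES)
    code_min <- if (grepl("^code>=[1-4]$", component))
      as.integer(sub("code>=", "", component)) else NA_integer_
    if (is.na(code_min) &&
        !component %in% c("B1", "inf1", "B2", "inf2"))
      stop("unknown component: ", component, call. = FALSE)
    survives <- function(N0) {
      p <- params
      p$N0 <- N0
      spec <- simulation_spec(strategy, p,
                              initial_state = phage_state(N = p$N0),
                              t_end = t_end, output_step = output_step,
                              transient_fraction = transient_fraction,
                              rel_tol = rel_tol, abs_tol = abs_tol)
      ps <- classify_persistence(run_simulation(spec), extinction_threshold)
      if (is.na(code_min)) unname(ps$survived[component])
      else ps$code >= code_min
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  s_lo <- survives(lo); s_hi <- survives(hi)
  if (identical(s_lo, s_hi))
    stop("bracket does not straddle a survival transition (predicate is ",
         s_lo, " at both ends)", call. = FALSE)
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (identical(survives(mid), s_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Write analysis results to disk
#'
#' \code{write_bifurcation} writes a long-format CSV with columns
#' \code{N0,variable,extremum_type,value} (\code{extremum_type} is
#' \code{"steady"}, \code{"min"} or \code{"max"}).
#' \code{write_sweep} writes the persistence-code matrix as TSV (rows =
#' forcing axis, columns = N0) and a companion long-format CSV
#' (\code{<stem>_flags.csv}) with the four survival flags per cell.
#'
#' @param bd A \code{bifurcation_diagram}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bifurcation <- function(bd, path) {
  stopifnot(inherits(bd, "bifurcation_diagram"))
  rows <- list()
  for (j in seq_along(bd$N0)) {
    ext <- bd$extrema[[j]]
    if (is.null(ext)) next
    for (v in names(ext)) {
      e <- ext[[v]]
      rows[[length(rows) + 1L]] <- if (!e$oscillating)
        data.frame(N0 = bd$N0[j], variable = v, extremum_type = "steady",
                   value = e$maxima)
      else rbind(
        data.frame(N0 = bd$N0[j], variable = v, extremum_type = "min",
                   value = e$minima),
        data.frame(N0 = bd$N0[j], variable = v, extremum_type = "max",
                   value = e$maxima))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bifurcation
#' @param sw A \code{sweep_result}.
#' @export
write_sweep <- function(sw, path) {
  stopifnot(inherits(sw, "sweep_result"))
  m <- as.data.frame(sw$codes)
  names(m) <- format(sw$N0, trim = TRUE)
  m <- cbind(stats::setNames(data.frame(sw$axis_grid), sw$axis), m)
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  long <- expand.grid(axis_value = sw$axis_grid, N0 = sw$N0,
                      KEEP.OUT.ATTRS = FALSE)
  long$code <- as.vector(sw$codes)
  for (f in dimnames(sw$survived)[[3]])
    long[[f]] <- as.vector(sw$survived[, , f])
  names(long)[1] <- sw$axis
  p2 <- paste0(tools::file_path_sans_ext(path), "_flags.csv")
  utils::write.csv(long, p2, row.names = FALSE)
  invisible(path)
}
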