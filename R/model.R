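#' Phage infection strategies
#'
#' The model distinguishes four infection modes, selected by a strategy tag:
#' \describe{
#'   \item{"none"}{no phage: the infected and phage compartments are held at
#'     zero and bacteria compete for the nutrient alone.}
#'   \item{"lytic"}{purely lytic infection with a constant lysis rate
#'     \code{s_max}; infected cells never reproduce.}
#'   \item{"ptw"}{Piggyback-the-Winner: a temperate phage whose lysis rate
#'     decreases with total host density, so lysogeny (and host growth)
#'     dominates when hosts are abundant.}
#'   \item{"ptl"}{Piggyback-the-Loser: a temperate phage whose lysis rate
#'     increases sigmoidally with host density, so lysogeny dominates when
#'     hosts are rare.}
#' }
#'
#' @format Character vector of the four valid strategy tags.
#' @export
PHAGE_STRATEGIES <- c("none", "lytic", "ptw", "ptl")

strategy_code <- function(strategy) {
  strategy <- match.arg(strategy, PHAGE_STRATEGIES)
  match(strategy, PHAGE_STRATEGIES) - 1L
}

#' Model parameters in normalized units
#'
#' Builds and validates the full parameter set of the chemostat model. All
#' densities are normalized biovolume (dimensionless after division by the
#' bacterial half-saturation biovolume), all rates are per hour. Defaults are
#' the reference parameterisation used throughout: metabolic rate
#' \code{x = 0.0206}, scaling constants \code{y1 = 7.5} (fast grower) and
#' \code{y2 = 4} (slow grower), normalized adsorption rate
#' \code{i_norm = 5.23}, burst volume fraction \code{n = 0.02}, maximum lysis
#' rate \code{s_max = 0.33}, phage decay \code{d = 0.0866}, mean turnover
#' \code{D = 1/24}, supply concentration \code{N0 = 2}, PtL half-saturation
#' \code{SH = 4}, PtW correction parameters \code{r = 0.5}, \code{H = 1}, and
#' growth-switch lysis rate \code{s_switch = 0.0033} (1\% of \code{s_max}).
#'
#' @param x Metabolic rate shared by both species, 1/h.
#' @param y1,y2 Dimensionless metabolic scaling constants; must satisfy
#'   \code{y1 > y2 > 1} so both species can grow at nutrient saturation and
#'   species 1 is the faster grower.
#' @param N_H Half-saturation density (1 by construction of the units).
#' @param i_norm Normalized adsorption rate, 1/h (see
#'   \code{\link{normalize_adsorption}}).
#' @param c Phage/bacteria biovolume conversion factor, dimensionless.
#' @param n Phage burst volume fraction in (0, 1]: the fraction of lysed host
#'   biovolume converted into phage particles; the remainder \code{1 - n}
#'   returns to the nutrient pool as the viral shunt.
#' @param s_max Maximum lysis rate, 1/h.
#' @param d Phage decay rate, 1/h.
#' @param D Mean chemostat turnover rate, 1/h.
#' @param N0 Supply concentration, normalized.
#' @param SH Half-saturation (squared-density offset) of the PtL lysis law.
#' @param r,H Correction parameters of the PtW lysis law.
#' @param s_switch Lysis rate at which infected-cell growth toggles between
#'   lysogenic (on, below) and lytic (off, above); must be below \code{s_max}.
#' @param a Relative amplitude of the sinusoidal turnover forcing, in [0, 1).
#' @param T Forcing period, h (required positive when \code{a > 0}).
#' @param shunt_enabled Include the viral-shunt term in the nutrient balance?
#'
#' @return An object of class \code{phage_params} (a named list).
#' @examples
#' p <- phage_params()
#' p$s_max
#' phage_params(N0 = 10, a = 0.5, T = 7 * 24)
#' @export
phage_params <- function(x = 0.0206, y1 = 7.5, y2 = 4, N_H = 1,
                         i_norm = 5.23, c = 3.14e-4, n = 0.02,
                         s_max = 0.33, d = 0.0866, D = 1 / 24, N0 = 2,
                         SH = 4, r = 0.5, H = 1, s_switch = 0.0033,
                         a = 0, T = 720, shunt_enabled = TRUE) {
  p <- list(x = x, y1 = y1, y2 = y2, N_H = N_H, i_norm = i_norm, c = c,
            n = n, s_max = s_max, d = d, D = D, N0 = N0, SH = SH, r = r,
            H = H, s_switch = s_switch, a = a, T = T,
            shunt_enabled = isTRUE(shunt_enabled))
  validate_phage_params(p)
  structure(p, class = "phage_params")
}

validate_phage_params <- function(p) {
  num <- p[setdiff(names(p), "shunt_enabled")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1))))
    stop("all parameters must be finite numeric scalars", call. = FALSE)
  rates <- c("x", "N_H", "i_norm", "c", "n", "s_max", "d", "D", "N0",
             "SH", "r", "H", "s_switch")
  bad <- rates[vapply(rates, function(f) p[[f]] < 0, logical(1))]
  if (length(bad))
    stop("negative parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (p$a < 0 || p$a >= 1)
    stop("fluctuation amplitude 'a' must lie in [0, 1) to keep the ",
         "turnover rate positive", call. = FALSE)
  if (p$a > 0 && p$T <= 0)
    stop("fluctuation period 'T' must be positive when a > 0", call. = FALSE)
  if (p$n <= 0 || p$n > 1)
    stop("burst volume fraction 'n' must lie in (0, 1]", call. = FALSE)
  if (!(p$y1 > p$y2 && p$y2 > 1))
    stop("metabolic scaling constants must satisfy y1 > y2 > 1", call. = FALSE)
  if (p$s_switch >= p$s_max)
    stop("growth-switch rate 's_switch' must be below 's_max'", call. = FALSE)
  invisible(p)
}

#' @export
print.phage_params <- function(x, ...) {
  cat("<phage_params>\n")
  num <- unlist(x[setdiff(names(x), "shunt_enabled")])
  cat(paste0("  ", format(names(num), width = 10), " ",
             format(num, digits = 6)), sep = "\n")
  cat("  shunt_enabled", if (x$shunt_enabled) "TRUE" else "FALSE", "\n")
  invisible(x)
}

STATE_VARS <- c("B1", "B2", "I1", "I2", "P1", "P2", "N")

#' System state vector
#'
#' Assembles the seven state variables as a named numeric vector of
#' normalized biovolume densities: uninfected bacteria \code{B1}, \code{B2},
#' infected bacteria \code{I1}, \code{I2}, free phages \code{P1}, \code{P2},
#' and nutrient \code{N}. Defaults are the reference initial condition:
#' bacteria 0.83, infected 0.17, phage 3.1e-4 per species.
#'
#' @param B1,B2 Uninfected bacteria densities (fast / slow grower).
#' @param I1,I2 Infected bacteria densities.
#' @param P1,P2 Free phage densities.
#' @param N Nutrient density; defaults to the supply concentration of the
#'   reference parameterisation.
#' @return Named numeric vector of length 7.
#' @examples
#' phage_state()
#' phage_state(N = 10)
#' @export
phage_state <- function(B1 = 0.83, B2 = 0.83, I1 = 0.17, I2 = 0.17,
                        P1 = 3.1e-4, P2 = 3.1e-4, N = 2) {
  s <- c(B1 = B1, B2 = B2, I1 = I1, I2 = I2, P1 = P1, P2 = P2, N = N)
  if (!all(is.finite(s)))
    stop("state components must be finite", call. = FALSE)
  if (any(s < 0))
    stop("state components must be non-negative", call. = FALSE)
  s
}

#' Per-capita bacterial growth rate (Type-2 functional response)
#'
#' Monod/Holling type-2 uptake: \code{x * y_k * N / (N + N_H)}. Strictly
#' increasing in the nutrient density and saturating at \code{x * y_k}.
#'
#' @param N Nutrient density, normalized (non-negative).
#' @param y_k Metabolic scaling constant of the species.
#' @param params A \code{\link{phage_params}} object (supplies \code{x} and
#'   \code{N_H}).
#' @return Growth rate, 1/h.
#' @examples
#' growth_rate(1, 7.5, phage_params())  # 0.07725
#' @export
growth_rate <- function(N, y_k, params) {
  if (any(N < 0)) stop("nutrient density must be non-negative", call. = FALSE)
  params$x * y_k * N / (N + params$N_H)
}

#' Strategy-dependent lysis (phage induction) rate
#'
#' The lytic strategy lyses at the constant rate \code{s_max}. The temperate
#' strategies make the rate a function of total host density
#' \code{B_k + I_k}: Piggyback-the-Loser uses the increasing sigmoid
#' \code{s_max * h^2 / (h^2 + SH)} (lysis grows with host abundance), while
#' Piggyback-the-Winner uses the decreasing law
#' \code{s_max / ((h * r)^2 + H)} (lysis suppressed when hosts abound).
#'
#' @param strategy One of \code{\link{PHAGE_STRATEGIES}}.
#' @param B_k,I_k Uninfected and infected host density (non-negative);
#'   vectorised over density.
#' @param params A \code{\link{phage_params}} object.
#' @return Lysis rate, 1/h.
#' @examples
#' p <- phage_params()
#' lysis_rate("ptl", 0.2010076, 0, p)  # the 0.0033 switching point
#' lysis_rate("ptw", 19.89975, 0, p)   # likewise from above
#' @export
lysis_rate <- function(strategy, B_k, I_k, params) {
  strategy <- match.arg(strategy, PHAGE_STRATEGIES)
  if (any(B_k < 0) || any(I_k < 0))
    stop("host densities must be non-negative", call. = FALSE)
  h <- B_k + I_k
  switch(strategy,
    none  = 0 * h,
    lytic = rep_len(params$s_max, length(h)),
    ptw   = params$s_max / ((h * params$r)^2 + params$H),
    ptl   = params$s_max * h^2 / (h^2 + params$SH)
  )
}

#' Is infected-cell growth switched on (lysogenic state)?
#'
#' Temperate strategies toggle infected-bacteria growth by comparing the
#' current induction rate to the switching point \code{s_switch}: growth (and
#' nutrient consumption) is on exactly while the lysis rate is at or below
#' the switch. Because the PtL rate increases and the PtW rate decreases with
#' host density, this single rule yields lysogeny-when-rare for PtL and
#' lysogeny-when-abundant for PtW. Purely lytic infections never grow.
#'
#' @param strategy One of \code{\link{PHAGE_STRATEGIES}}.
#' @param current_lysis_rate Lysis rate at the current state, 1/h;
#'   vectorised.
#' @param params A \code{\link{phage_params}} object.
#' @return Logical.
#' @export
growth_enabled <- function(strategy, current_lysis_rate, params) {
  strategy <- match.arg(strategy, PHAGE_STRATEGIES)
  if (any(current_lysis_rate < 0))
    stop("lysis rate must be non-negative", call. = FALSE)
  if (strategy %in% c("ptw", "ptl"))
    current_lysis_rate <= params$s_switch
  else
    rep_len(FALSE, length(current_lysis_rate))
}

#' Host density at which a temperate strategy crosses the growth switch
#'
#' Inverts the lysis law at \code{s_switch}: for PtL the density below which
#' lysogeny holds, for PtW the density above which it holds.
#'
#' @param strategy \code{"ptl"} or \code{"ptw"}.
#' @param params A \code{\link{phage_params}} object.
#' @return Total host density (normalized) at the switching point.
#' @examples
#' switch_density("ptl", phage_params())  # 0.2010076
#' switch_density("ptw", phage_params())  # 19.89975
#' @export
switch_density <- function(strategy, params) {
  strategy <- match.arg(strategy, c("ptl", "ptw"))
  s <- params$s_switch
  if (strategy == "ptl") {
    # s = s_max h^2/(h^2 + SH)  =>  h = sqrt(s*SH/(s_max - s))
    sqrt(s * params$SH / (params$s_max - s))
  } else {
    # s = s_max/((h r)^2 + H)   =>  h = sqrt(s_max/s - H)/r
    sqrt(params$s_max / s - params$H) / params$r
  }
}

#' Chemostat turnover rate, optionally sinusoidally forced
#'
#' Returns \code{a * D * sin(2 * pi * t / T) + D}: a sine modulation of the
#' mean turnover rate with relative amplitude \code{a} and period \code{T}.
#' The mean over one period is \code{D} and positivity is guaranteed by the
#' constraint \code{a < 1}.
#'
#' @param t Time, h; vectorised.
#' @param params A \code{\link{phage_params}} object.
#' @return Turnover rate, 1/h.
#' @examples
#' p <- phage_params(a = 0.5, T = 24)
#' turnover_rate(6, p)  # 1.5/24
#' @export
turnover_rate <- function(t, params) {
  if (params$a == 0) return(rep_len(params$D, length(t)))
  params$a * params$D * sin(2 * pi * t / params$T) + params$D
}

#' Time derivative of the system state
#'
#' Evaluates the full right-hand side of the chemostat model at one state.
#' For each species k the per-capita growth \code{G_k(N)} follows the Type-2
#' response, infection transfers biovolume \code{(1 + c) * i * B_k * P_k}
#' into the infected pool, lysis at the strategy-dependent rate \code{s_k}
#' releases a fraction \code{n} as phage and (when the shunt is enabled)
#' \code{1 - n} back into the nutrient pool, and phages decay at rate
#' \code{d}. Infected bacteria grow and consume nutrient only while the
#' growth switch is on (see \code{\link{growth_enabled}}); consumption and
#' shunt release sum over both species since the nutrient pool is shared.
#' Components pushed slightly negative by an integrator are treated as zero
#' for rate evaluation.
#'
#' The signature is the one \code{deSolve} expects; \code{parms} carries the
#' strategy alongside the \code{\link{phage_params}}. The package's
#' simulations use a compiled C translation of this function; this R version
#' is the readable reference and the two are tested to agree.
#'
#' @param t Time, h.
#' @param state Named state vector as from \code{\link{phage_state}}.
#' @param parms List with elements \code{params} (a \code{phage_params}) and
#'   \code{strategy}.
#' @return A list whose first element is the derivative vector (deSolve
#'   convention).
#' @examples
#' f <- phage_derivs(0, phage_state(), list(params = phage_params(),
#'                                          strategy = "lytic"))
#' f[[1]]
#' @export
phage_derivs <- function(t, state, parms) {
  p <- parms$params
  strategy <- match.arg(parms$strategy, PHAGE_STRATEGIES)
  if (!all(is.finite(state)))
    stop("non-finite state at t = ", t, call. = FALSE)
  s <- pmax(state, 0)
  B <- s[1:2]; I <- s[3:4]; P <- s[5:6]; N <- s[[7]]
  yk <- c(p$y1, p$y2)

  G <- p$x * yk * N / (N + p$N_H)
  Dt <- turnover_rate(t, p)

  if (strategy == "none") {
    dB <- G * B - p$x * B
    dN <- Dt * (p$N0 - N) - sum(G * B)
    return(list(c(dB, 0, 0, 0, 0, dN)))
  }

  sk <- lysis_rate(strategy, B, I, p)
  grow <- growth_enabled(strategy, sk, p)
  inf <- p$i_norm * B * P

  dB <- G * B - p$x * B - inf
  dI <- (1 + p$c) * inf + ifelse(grow, G * I, 0) - p$x * I - sk * I
  dP <- p$n * sk * I - p$c * inf - p$d * P
  dN <- Dt * (p$N0 - N) - sum(G * B) - sum(G * I * grow) +
    if (p$shunt_enabled) sum((1 - p$n) * sk * I) else 0

  list(c(dB, dI, dP, dN))
}

# Flat parameter vector in the order the C right-hand side expects.
params_to_cvec <- function(params, strategy) {
  c(params$x, params$y1, params$y2, params$N_H, params$i_norm, params$c,
    params$n, params$s_max, params$d, params$D, params$N0, params$SH,
    params$r, params$H, params$s_switch, params$a, params$T,
    as.numeric(params$shunt_enabled), strategy_code(strategy))
}
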