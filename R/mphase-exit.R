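## M-phase-exit desequestration scenarios: how fast PP2A-B55 is freed
## from pEndos sequestration once Greatwall switches off.  Three regimes:
## PP2A-B55 alone consuming its inhibitor; PP2A-B55 helped by a second
## phosphatase PPX; and the counterfactual in which pEndos is a pure
## dead-end inhibitor that only PPX can destroy.

#' Configuration of an M-phase-exit scenario
#'
#' @param N_T0 initial total pEndos (nM).
#' @param P_T total PP2A-B55 (nM), constant (no degradation here).
#' @param Km_P pEndos Michaelis constant for PP2A-B55 (nM).
#' @param kcat_P pEndos turnover by PP2A-B55 (s^-1).
#' @param mode_P `"substrate"` (PP2A-B55 consumes pEndos) or
#'   `"dead_end"` (binding only; `kcat_P` is forced to 0 and `Kd_P`
#'   replaces `Km_P`).
#' @param Kd_P dissociation constant (nM) used in `dead_end` mode.
#' @param X_T total secondary phosphatase PPX (nM); 0 disables it.
#' @param Km_X,kcat_X PPX kinetic constants (nM, s^-1).
#' @param kon association rate for the pEndos/PP2A-B55 complex
#'   (nM^-1 s^-1), used by the mass-action cross-check and the validity
#'   diagnostics.
#' @return An object of class `scenario_config`.
#' @seealso [mphase_scenario()] for the canonical parameterisations.
#' @export
scenario_config <- function(N_T0, P_T, Km_P = 1, kcat_P = 0.05,
                            mode_P = c("substrate", "dead_end"),
                            Kd_P = NULL, X_T = 0, Km_X = 85e3,
                            kcat_X = 22.5, kon = 0.057) {
  mode_P <- match.arg(mode_P)
  for (nm in c("N_T0", "P_T", "X_T")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single nonnegative number", call. = FALSE)
  }
  if (mode_P == "dead_end") {
    if (is.null(Kd_P)) stop("dead_end mode requires Kd_P", call. = FALSE)
    kcat_P <- 0
  }
  structure(list(N_T0 = N_T0, P_T = P_T, Km_P = Km_P, kcat_P = kcat_P,
                 mode_P = mode_P, Kd_P = Kd_P, X_T = X_T, Km_X = Km_X,
                 kcat_X = kcat_X, kon = kon),
            class = "scenario_config")
}

#' Canonical M-phase-exit scenarios
#'
#' The three parameterisations explored in the theory: 250 nM total
#' PP2A-B55 facing 1 uM pEndos (Km 1 nM, kcat 0.05 s^-1), optionally
#' joined by 250 nM of a CDKS-like secondary phosphatase PPX (Km 85 uM,
#' kcat 22.5 s^-1), or with pEndos demoted to a pure dead-end inhibitor
#' (Kd 0.12 nM, from the thiophosphorylated-Endos dose response) that
#' only PPX can dephosphorylate.
#'
#' @param which `"pp2a_only"`, `"with_ppx"` or `"dead_end"`.
#' @return A [scenario_config()].
#' @examples
#' half_desequestration_time(simulate_tqssa(mphase_scenario("pp2a_only")))
#' @export
mphase_scenario <- function(which = c("pp2a_only", "with_ppx",
                                      "dead_end")) {
  which <- match.arg(which)
  switch(which,
    pp2a_only = scenario_config(N_T0 = 1000, P_T = 250, Km_P = 1,
                                kcat_P = 0.05),
    with_ppx = scenario_config(N_T0 = 1000, P_T = 250, Km_P = 1,
                               kcat_P = 0.05, X_T = 250),
    dead_end = scenario_config(N_T0 = 1000, P_T = 250,
                               mode_P = "dead_end", Kd_P = 0.12,
                               X_T = 250))
}

## binding constant used for the P-N pair in the current mode
.KbindP <- function(config)
  if (config$mode_P == "dead_end") config$Kd_P else config$Km_P

.default_horizon <- function(config)
  if (config$mode_P == "dead_end") 2e4 else 600

## Free pEndos at given totals: root of
##   N (1 + P_T/(KmP + N) + X_T/(KmX + N)) = N_T,  monotone in N.
.solve_free <- function(N_T, config) {
  KmP <- .KbindP(config)
  if (N_T <= 0)
    return(list(N = 0, P = config$P_T, X = config$X_T))
  f <- function(N) N * (1 + config$P_T / (KmP + N) +
                          config$X_T / (config$Km_X + N)) - N_T
  N <- stats::uniroot(f, c(0, N_T), tol = 1e-13)$root
  list(N = N,
       P = config$P_T * KmP / (KmP + N),
       X = if (config$X_T > 0) config$X_T * config$Km_X /
         (config$Km_X + N) else 0)
}

#' Total-QSSA simulation of PP2A-B55 desequestration
#'
#' Integrates the total quasi-steady-state system
#' \deqn{[N] = \frac{N_T}{1+[P]/K_m^P+[X]/K_m^X},\quad
#'   [P] = \frac{P_T}{1+[N]/K_m^P},\quad
#'   [X] = \frac{X_T}{1+[N]/K_m^X},}
#' \deqn{\frac{dN_T}{dt} = -\left(k_{cat}^P \frac{[P]}{K_m^P} +
#'   k_{cat}^X \frac{[X]}{K_m^X}\right)[N],}
#' on a dense time grid, with root detection for the 50%
#' free-enzyme crossing (stored in the `crossing_time` attribute).
#' In `dead_end` mode the PP2A-B55 branch uses `Kd_P` and contributes no
#' catalysis.  The validity diagnostics of [tqssa_validity()] are
#' checked first; a warning is issued if epsilon exceeds its threshold.
#'
#' @param config a [scenario_config()].
#' @param horizon simulation end time (s); defaults to 600 s
#'   (substrate modes) or 20000 s (dead-end).
#' @param dt output step (s); default `horizon/6000`.
#' @return A [kin_trajectory()] with columns `t`, `N_T`, `N`, `P`, `X`,
#'   `phospho_fraction` (= N_T/N_T(0), non-increasing) and
#'   `free_P_fraction` (= P/P_T, non-decreasing).
#' @export
simulate_tqssa <- function(config, horizon = .default_horizon(config),
                           dt = horizon / 6000) {
  stopifnot(inherits(config, "scenario_config"))
  val <- tqssa_validity(config)
  if (!val$valid)
    warning("tQSSA validity parameter epsilon = ", signif(val$epsilon, 3),
            " exceeds threshold; interpret with care", call. = FALSE)
  deriv <- function(t, y, parms) {
    fr <- .solve_free(y[1L], config)
    v <- config$kcat_P * fr$P / .KbindP(config) * fr$N
    if (config$X_T > 0)
      v <- v + config$kcat_X * fr$X / config$Km_X * fr$N
    list(-v)
  }
  rootfun <- function(t, y, parms)
    .solve_free(y[1L], config)$P / config$P_T - 0.5
  tg <- seq(0, horizon, by = dt)
  out <- deSolve::ode(c(N_T = config$N_T0), tg, deriv, parms = NULL,
                      method = "lsodar", rtol = 1e-8, atol = 1e-12,
                      rootfun = rootfun,
                      events = list(func = function(t, y, p) y,
                                    root = TRUE))
  if (attr(out, "istate")[1L] < 0)
    stop("ODE integration failed in simulate_tqssa", call. = FALSE)
  NT <- pmax(as.numeric(out[, "N_T"]), 0)
  fr <- lapply(NT, .solve_free, config = config)
  tt <- as.numeric(out[, 1L])
  ## event handling can duplicate the root time point; keep unique times
  keep <- !duplicated(tt)
  troot <- attr(out, "troot")
  kin_trajectory(
    data.frame(t = tt[keep], N_T = NT[keep],
               N = vapply(fr, `[[`, numeric(1), "N")[keep],
               P = vapply(fr, `[[`, numeric(1), "P")[keep],
               X = vapply(fr, `[[`, numeric(1), "X")[keep],
               phospho_fraction = (NT / config$N_T0)[keep],
               free_P_fraction =
                 (vapply(fr, `[[`, numeric(1), "P") / config$P_T)[keep]),
    config = config,
    crossing_time = if (length(troot)) troot[1L] else NULL)
}

#' Explicit mass-action simulation (tQSSA cross-check)
#'
#' Full ODE system for free pEndos, free PP2A-B55 and the transient
#' complex:
#' \deqn{dN/dt = -k_{on} N P + k_{off}[NP] - v_X(N),\quad
#'   dP/dt = -k_{on} N P + (k_{off}+k_{cat}^P)[NP],}
#' \deqn{d[NP]/dt = k_{on} N P - (k_{off}+k_{cat}^P)[NP],}
#' starting from fully unbound species.  PPX (Km far above all
#' concentrations) enters as the Michaelis flux
#' \eqn{v_X = k_{cat}^X X_T N/(K_m^X+N)}.  The dissociation rate follows
#' the Briggs-Haldane convention \eqn{k_{off} = k_{on} K_m - k_{cat}}
#' in substrate mode and \eqn{k_{off} = k_{on} K_d} in dead-end mode,
#' which reproduces the measured pair (kon 0.057 nM^-1 s^-1,
#' koff 0.0068 s^-1).  Apart from an initial transient of duration
#' `t_c` (see [tqssa_validity()]) the result is expected to match
#' [simulate_tqssa()].
#'
#' @inheritParams simulate_tqssa
#' @return A [kin_trajectory()] with columns `t`, `N_T`, `N`, `P`, `NP`,
#'   `X`, `phospho_fraction`, `free_P_fraction`.
#' @export
simulate_mass_action <- function(config,
                                 horizon = .default_horizon(config),
                                 dt = horizon / 6000) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(config$kon))
    stop("mass-action mode requires kon", call. = FALSE)
  kon <- config$kon
  koff <- if (config$mode_P == "dead_end") kon * config$Kd_P
          else kon * config$Km_P - config$kcat_P
  if (koff <= 0)
    stop("Briggs-Haldane koff = kon*Km - kcat is nonpositive; ",
         "kon too small for this (Km, kcat)", call. = FALSE)
  deriv <- function(t, y, parms) {
    N <- y[1L]; P <- y[2L]; NP <- y[3L]
    vX <- if (config$X_T > 0)
      config$kcat_X * config$X_T * N / (config$Km_X + N) else 0
    bind <- kon * N * P - koff * NP
    list(c(-bind - vX,
           -bind + config$kcat_P * NP,
           bind - config$kcat_P * NP,
           config$kcat_P * NP + vX))
  }
  tg <- seq(0, horizon, by = dt)
  out <- deSolve::lsoda(c(N = config$N_T0, P = config$P_T, NP = 0,
                          released = 0), tg,
                        deriv, parms = NULL, rtol = 1e-10, atol = 1e-10)
  if (attr(out, "istate")[1L] < 0)
    stop("stiff integration failed in simulate_mass_action; consider ",
         "loosening tolerances", call. = FALSE)
  N <- as.numeric(out[, "N"]); P <- as.numeric(out[, "P"])
  NP <- as.numeric(out[, "NP"])
  X <- if (config$X_T > 0)
    config$X_T * config$Km_X / (config$Km_X + N) else rep(0, length(N))
  kin_trajectory(
    data.frame(t = tg, N_T = N + NP, N = N, P = P, NP = NP, X = X,
               released = as.numeric(out[, "released"]),
               phospho_fraction = (N + NP) / config$N_T0,
               free_P_fraction = P / config$P_T),
    config = config)
}

#' Time of 50% PP2A-B55 desequestration
#'
#' First time at which the free-enzyme fraction crosses 0.5.  Uses the
#' integrator's root detection when available (attribute
#' `crossing_time`), otherwise monotone linear interpolation on the
#' dense output.
#'
#' @param traj a [kin_trajectory()] with column `free_P_fraction`.
#' @return Time (s); 0 if the trajectory starts at or above 0.5, `Inf`
#'   ("beyond horizon") if 0.5 is never reached.
#' @export
half_desequestration_time <- function(traj) {
  stopifnot(inherits(traj, "kin_trajectory"),
            "free_P_fraction" %in% names(traj))
  if (traj$free_P_fraction[1L] >= 0.5) return(0)
  ct <- attr(traj, "crossing_time")
  if (!is.null(ct)) return(ct)
  f <- traj$free_P_fraction
  above <- which(f >= 0.5)
  if (!length(above)) return(Inf)
  i <- above[1L]
  stats::approx(f[(i - 1L):i], traj$t[(i - 1L):i], xout = 0.5)$y
}

#' Fractional dephosphorylation velocities of the two phosphatases
#'
#' At each total pEndos concentration the free species are solved from
#' the two-enzyme tQSSA algebra and the instantaneous velocities
#' \eqn{v_P = k_{cat}^P [P][N]/K_m^P},
#' \eqn{v_X = k_{cat}^X [X][N]/K_m^X} are split into fractions
#' \eqn{f_P = v_P/(v_P+v_X)}, \eqn{f_X = v_X/(v_P+v_X)} (summing to 1
#' exactly).  Once total pEndos drops below total PP2A-B55 nearly all of
#' it is sequestered and protected, so PPX's share collapses.
#'
#' @param N_T0 vector of total pEndos concentrations (nM).
#' @param config a [scenario_config()] with both enzymes present
#'   (`X_T > 0`) and `mode_P = "substrate"`.
#' @return data.frame with columns `N_T0`, `f_P`, `f_X`.
#' @export
fractional_velocities <- function(N_T0, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$X_T <= 0)
    stop("fractional velocities require both enzymes (X_T > 0)",
         call. = FALSE)
  if (config$mode_P != "substrate")
    stop("fractional velocities are defined for substrate mode",
         call. = FALSE)
  res <- t(vapply(N_T0, function(nt) {
    fr <- .solve_free(nt, config)
    vP <- config$kcat_P * fr$P * fr$N / config$Km_P
    vX <- config$kcat_X * fr$X * fr$N / config$Km_X
    tot <- vP + vX
    if (tot == 0)
      stop("both velocities are zero (no free substrate); fractions ",
           "undefined", call. = FALSE)
    c(vP / tot, vX / tot)
  }, numeric(2)))
  data.frame(N_T0 = N_T0, f_P = res[, 1L], f_X = res[, 2L])
}

#' tQSSA validity diagnostics
#'
#' Two readings of the perturbation parameter are reported, reflecting a
#' units ambiguity in its printed form: `epsilon`
#' \eqn{= k_{cat} P_T / \{k_{on}(N_T(0)+P_T+K_m)^2\}} (dimensionless)
#' and `epsilon_per_nM` \eqn{= k_{cat}/\{k_{on}(N_T(0)+P_T+K_m)^2\}}
#' (nM^-1), which omits the enzyme total.  Both are far below 1 in the
#' scenarios of interest, so the conclusion does not depend on the
#' reading.  The approximation is expected to fail only during an
#' initial transient of duration
#' \eqn{t_c = 1/\{k_{on}(N_T(0)+K_m)\}}.
#'
#' @param config a [scenario_config()] with `kon` present.
#' @param threshold validity threshold on `epsilon` (default 1e-2).
#' @return List with `epsilon`, `epsilon_per_nM`, `t_c` (s) and logical
#'   `valid`.
#' @examples
#' tqssa_validity(mphase_scenario("pp2a_only"))  # t_c ~ 0.02 s
#' @export
tqssa_validity <- function(config, threshold = 1e-2) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(config$kon)) stop("kon required", call. = FALSE)
  Km <- .KbindP(config)
  s2 <- (config$N_T0 + config$P_T + Km)^2
  eps <- config$kcat_P * config$P_T / (config$kon * s2)
  list(epsilon = eps,
       epsilon_per_nM = config$kcat_P / (config$kon * s2),
       t_c = 1 / (config$kon * (config$N_T0 + Km)),
       valid = eps < threshold)
}
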