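## The "automatic reset" model: PP2A-B55, pre-loaded with unlabeled
## pEndos, must dephosphorylate (and thereby destroy) its own inhibitor
## before its activity toward a CDK-site reporter substrate reappears.
## Enzyme activity also decays slowly during the long incubation
## (first-order rate kdeg), which the model carries explicitly.

#' Configuration of an automatic-reset simulation
#'
#' @param P_T0 initial total enzyme (nM).
#' @param N_T0 initial total pEndos (nM); 0 for the control.
#' @param pC_T total reporter substrate (nM).  The reporter is far below
#'   its own Km (tens of uM), so it binds a negligible fraction of the
#'   enzyme and only its second-order efficiency matters.
#' @param Km Michaelis constant of pEndos (nM).
#' @param kcat turnover number for pEndos (s^-1).
#' @param eff_C reporter catalytic efficiency kcat/Km (uM^-1 s^-1).
#' @param kdeg first-order enzyme decay rate (min^-1).
#' @param deg_onset time at which decay begins (s).  Default 1500 s for
#'   inhibited samples; controls use 0.  The asymmetry mirrors the
#'   observation that enzyme emerging from pEndos sequestration is more
#'   active than the decayed control, as if sequestration were
#'   protective.
#' @param inhibitor_mode `"substrate"` (pEndos is consumed) or
#'   `"dead_end"` (pure inhibitor, no catalysis; requires `Kd_dead`).
#' @param Kd_dead dissociation constant (nM) used in `dead_end` mode.
#' @return An object of class `reset_config`.
#' @examples
#' reset_config(P_T0 = 0.25, N_T0 = 16, pC_T = 470,
#'              Km = 0.47, kcat = 0.03, eff_C = 0.52, kdeg = 0.020)
#' @export
reset_config <- function(P_T0, N_T0, pC_T, Km, kcat,
                         eff_C, kdeg, deg_onset = 1500,
                         inhibitor_mode = c("substrate", "dead_end"),
                         Kd_dead = NULL) {
  inhibitor_mode <- match.arg(inhibitor_mode)
  num1 <- function(x, nm, min = 0) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
      stop("'", nm, "' must be a single number >= ", min, call. = FALSE)
  }
  num1(P_T0, "P_T0"); num1(N_T0, "N_T0"); num1(pC_T, "pC_T")
  num1(Km, "Km"); num1(kcat, "kcat"); num1(eff_C, "eff_C")
  num1(kdeg, "kdeg"); num1(deg_onset, "deg_onset")
  if (inhibitor_mode == "dead_end") {
    if (is.null(Kd_dead)) stop("dead_end mode requires Kd_dead",
                               call. = FALSE)
    num1(Kd_dead, "Kd_dead")
  }
  structure(list(P_T0 = P_T0, N_T0 = N_T0, pC_T = pC_T, Km = Km,
                 kcat = kcat, eff_C = eff_C, kdeg = kdeg,
                 deg_onset = deg_onset, inhibitor_mode = inhibitor_mode,
                 Kd_dead = Kd_dead),
            class = "reset_config")
}

## reporter release rate: eff_C [uM^-1 s^-1] * pC_T [nM -> uM] * P [nM]
.reporter_rate <- function(config, P_free)
  config$eff_C * nM_to_uM(config$pC_T) * P_free

#' Closed-form reporter release for the no-inhibitor control
#'
#' With no pEndos present and the enzyme decaying as
#' \eqn{P_T(t) = P_T(0) e^{-k_{deg} t}}, the released reporter product is
#' \deqn{[^{32}P](t) = \frac{k_{cat}}{K_m}\,pC_T\,P_T(0)\,
#'   \frac{1-e^{-k_{deg} t}}{k_{deg}},}
#' i.e. the time integral of a first-order-decaying linear rate.  The
#' \eqn{k_{deg} \to 0} limit is the linear form \eqn{rate_0 \cdot t}.
#' Decay onset is 0 for controls regardless of `deg_onset`.
#'
#' @param config a [reset_config()] (its `N_T0` is ignored; must be the
#'   control, i.e. `N_T0 = 0`, for this closed form to describe the
#'   data).
#' @param t time(s) (s); vectorised.
#' @return Released product (nM).
#' @examples
#' cfg <- reset_config(P_T0 = 0.25, N_T0 = 0, pC_T = 470, Km = 0.47,
#'                     kcat = 0.03, eff_C = 0.52, kdeg = 0.020)
#' control_release_curve(cfg, 600)  # 33.23 nM
#' @export
control_release_curve <- function(config, t) {
  stopifnot(inherits(config, "reset_config"))
  if (config$N_T0 != 0)
    stop("control closed form requires N_T0 = 0", call. = FALSE)
  rate0 <- .reporter_rate(config, config$P_T0)
  kd <- per_min_to_per_s(config$kdeg)
  if (kd < 1e-15) rate0 * t
  else rate0 * (1 - exp(-kd * t)) / kd
}

#' Simulate the automatic-reset time course
#'
#' Integrates pEndos depletion under the total QSSA with a
#' time-decaying enzyme pool:
#' \deqn{P_T(t) = P_T(0)\,e^{-k_{deg}\max(0, t-t_{onset})},\qquad
#'   \frac{dN_T}{dt} = -k_{cat}\,[NP](N_T, P_T(t)),}
#' where \eqn{[NP]} is the tight-binding complex of [bound_complex()]
#' (with `Kd_dead` in place of Km and no catalysis in `dead_end` mode),
#' together with reporter release
#' \eqn{d[^{32}P]/dt = (k_{cat}/K_m)_{pC}\; pC_T\,(P_T(t)-[NP])}.
#'
#' @param config a [reset_config()].
#' @param t_grid increasing vector of output times (s) starting at 0.
#' @return A [kin_trajectory()] with columns `t`, `N_T`, `P_T`,
#'   `released`, `reporter_rate`.
#' @export
simulate_reset <- function(config, t_grid) {
  stopifnot(inherits(config, "reset_config"))
  if (t_grid[1L] != 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing and start at 0",
         call. = FALSE)
  kd <- per_min_to_per_s(config$kdeg)
  dead <- config$inhibitor_mode == "dead_end"
  Kbind <- if (dead) config$Kd_dead else config$Km
  deriv <- function(t, y, parms) {
    PTt <- config$P_T0 * exp(-kd * max(0, t - config$deg_onset))
    np <- bound_complex(max(y[1L], 0), PTt, Kbind)
    dN <- if (dead) 0 else -config$kcat * np
    list(c(dN, .reporter_rate(config, PTt - np)))
  }
  out <- deSolve::lsoda(c(N_T = config$N_T0, released = 0), t_grid,
                        deriv, parms = NULL, rtol = 1e-10, atol = 1e-12)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE integration failed in simulate_reset", call. = FALSE)
  NT <- pmax(as.numeric(out[, "N_T"]), 0)
  PTt <- config$P_T0 * exp(-kd * pmax(0, t_grid - config$deg_onset))
  np <- vapply(seq_along(t_grid),
               function(i) bound_complex(NT[i], PTt[i], Kbind),
               numeric(1))
  kin_trajectory(
    data.frame(t = t_grid, N_T = NT, P_T = PTt,
               released = as.numeric(out[, "released"]),
               reporter_rate = .reporter_rate(config, PTt - np)),
    config = config)
}

#' Lag in reporter dephosphorylation relative to a matched control
#'
#' The delay imposed by pEndos, defined as the first time at which the
#' inhibited sample's instantaneous reporter rate reaches 50% of the
#' control's instantaneous rate at the same time, located by linear
#' interpolation on the common time grid.  Rates come from the model
#' trajectories, not finite differences of data.
#'
#' @param traj inhibited-sample [kin_trajectory()] (column
#'   `reporter_rate`).
#' @param control matched control trajectory on the same time grid.
#' @return Lag time (s); 0 if the ratio starts at or above 50%, `Inf`
#'   ("beyond horizon") if the threshold is never reached on the grid.
#' @export
lag_time <- function(traj, control) {
  stopifnot(inherits(traj, "kin_trajectory"),
            inherits(control, "kin_trajectory"))
  if (!isTRUE(all.equal(traj$t, control$t)))
    stop("trajectories must share a common time grid", call. = FALSE)
  ratio <- traj$reporter_rate / control$reporter_rate
  if (ratio[1L] >= 0.5) return(0)
  above <- which(ratio >= 0.5)
  if (!length(above)) return(Inf)
  i <- above[1L]
  stats::approx(ratio[(i - 1L):i], traj$t[(i - 1L):i], xout = 0.5)$y
}

#' Two-stage fit of the automatic-reset model
#'
#' Stage 1 fits the control time course (no pEndos) to the closed form
#' of [control_release_curve()], estimating the reporter efficiency
#' `eff_C` and the enzyme decay rate `kdeg`.  Stage 2 fixes those and
#' fits the inhibited time course with [simulate_reset()] for the pEndos
#' constants `Km` and `kcat`.  Both stages use equal-fractional-error
#' weighting; the `t = 0` points (zero release by construction) are
#' excluded.
#'
#' @param control data.frame with columns `t` (s) and `released` (nM)
#'   for the no-pEndos control.
#' @param inhibited data.frame with the same columns for the
#'   pEndos-containing sample.
#' @param config a [reset_config()] providing the known quantities
#'   (`P_T0`, `N_T0`, `pC_T`, `deg_onset`); its `eff_C`, `kdeg`, `Km`,
#'   `kcat` serve as starting guesses.
#' @return List with elements `control` and `inhibited`, each a
#'   [fit_result()] (`eff_C` in uM^-1 s^-1 and `kdeg` in min^-1;
#'   `Km` in nM and `kcat` in s^-1).
#' @export
fit_reset <- function(control, inhibited, config) {
  stopifnot(inherits(config, "reset_config"),
            all(c("t", "released") %in% names(control)),
            all(c("t", "released") %in% names(inhibited)))
  ctl <- control[control$t > 0, ]
  base_ctl <- reset_config(P_T0 = config$P_T0, N_T0 = 0,
                           pC_T = config$pC_T, Km = config$Km,
                           kcat = config$kcat, eff_C = config$eff_C,
                           kdeg = config$kdeg, deg_onset = 0)
  ctl_fn <- function(th) {
    cfg <- base_ctl
    cfg$eff_C <- th[["eff_C"]]; cfg$kdeg <- th[["kdeg"]]
    control_release_curve(cfg, ctl$t)
  }
  fit_ctl <- .fractional_fit(ctl$released, ctl_fn,
                             c(eff_C = config$eff_C, kdeg = config$kdeg))
  fit_ctl$weighting <- "equal fractional errors"

  eff_hat <- fit_ctl$estimates$value[fit_ctl$estimates$parameter == "eff_C"]
  kdeg_hat <- fit_ctl$estimates$value[fit_ctl$estimates$parameter == "kdeg"]
  inh <- inhibited[inhibited$t > 0, ]
  ## replicates share time points: integrate once on the unique grid
  tu <- sort(unique(inh$t))
  tg <- if (tu[1L] > 0) c(0, tu) else tu
  idx <- match(inh$t, tg)
  inh_fn <- function(th) {
    cfg <- config
    cfg$Km <- th[["Km"]]; cfg$kcat <- th[["kcat"]]
    cfg$eff_C <- eff_hat; cfg$kdeg <- kdeg_hat
    simulate_reset(cfg, tg)$released[idx]
  }
  fit_inh <- .fractional_fit(inh$released, inh_fn,
                             c(Km = config$Km, kcat = config$kcat))
  fit_inh$weighting <- "equal fractional errors"
  list(control = fit_ctl, inhibited = fit_inh)
}

## dose-response -----------------------------------------------------------

#' Construct a dose-response dataset
#'
#' Fractional enzyme activity versus inhibitor concentration, measured
#' against a reporter substrate.
#'
#' @param data data.frame with columns `conc` (inhibitor, nM) and
#'   `activity` (fraction of uninhibited activity; values up to 1.2
#'   tolerated as noise).
#' @param P_T total enzyme (nM).
#' @param substrate_conc reporter substrate concentration (nM).
#' @param substrate_Km reporter substrate Km (nM).
#' @param incubation_time assay incubation (s), metadata only.
#' @return A data.frame of class `dose_response_dataset`.
#' @export
dose_response_dataset <- function(data, P_T, substrate_conc = 0,
                                  substrate_Km = Inf,
                                  incubation_time = NA_real_) {
  stopifnot(is.data.frame(data),
            all(c("conc", "activity") %in% names(data)))
  if (any(data$conc < 0)) stop("conc must be >= 0", call. = FALSE)
  if (any(data$activity < 0 | data$activity > 1.2))
    stop("activity must lie in [0, 1.2]", call. = FALSE)
  structure(data, P_T = P_T, substrate_conc = substrate_conc,
            substrate_Km = substrate_Km,
            incubation_time = incubation_time,
            class = c("dose_response_dataset", "data.frame"))
}

#' Read a dose-response dataset from CSV
#'
#' Expected columns: `inhibitor_nM`, `activity_fraction`.
#'
#' @param path CSV file path.
#' @inheritParams dose_response_dataset
#' @return A [dose_response_dataset()].
#' @export
read_dose_response_csv <- function(path, P_T, substrate_conc = 0,
                                   substrate_Km = Inf,
                                   incubation_time = NA_real_) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("inhibitor_nM", "activity_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  dose_response_dataset(
    data.frame(conc = df$inhibitor_nM, activity = df$activity_fraction),
    P_T = P_T, substrate_conc = substrate_conc,
    substrate_Km = substrate_Km, incubation_time = incubation_time)
}

#' Fit a dose-response curve and report the IC50
#'
#' For tight-binding inhibitors the activity curve is the free-enzyme
#' fraction of the Morrison quadratic,
#' \eqn{a(I) = top \cdot (P_T - [PI](I; K_d^{app}))/P_T}, with the
#' apparent dissociation constant \eqn{K_d^{app}} (which absorbs
#' competition by the reporter substrate) as the fitted shape parameter.
#' For weak inhibitors a logistic curve
#' \eqn{a(I) = top/(1+(I/IC_{50})^h)} is fitted instead.  The IC50 is
#' the dose at which the fitted curve reaches 50% of its upper plateau,
#' located numerically on the fitted curve (never the nearest measured
#' dose).  Residuals are unweighted: activity fractions carry roughly
#' additive error.
#'
#' @param data a [dose_response_dataset()], or a plain data.frame with
#'   columns `conc`, `activity` plus a `P_T` argument.
#' @param P_T total enzyme (nM); taken from `data` when omitted.
#' @param model `"tight_binding"` (default) or `"logistic"`.
#' @return List with `IC50` (nM), `se` (nM), and the underlying
#'   [fit_result()].  Warns if the IC50 lies outside the measured dose
#'   range.
#' @export
fit_dose_response <- function(data, P_T = attr(data, "P_T"),
                              model = c("tight_binding", "logistic")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data),
            all(c("conc", "activity") %in% names(data)))
  if (length(unique(data$conc)) < 6L)
    stop("need >= 6 dose levels bracketing the midpoint", call. = FALSE)
  conc <- data$conc; act <- data$activity

  if (model == "tight_binding") {
    if (is.null(P_T)) stop("P_T required for tight-binding model",
                           call. = FALSE)
    model_fn <- function(th) {
      bnd <- bound_complex(conc, P_T, th[["Kd_app"]])
      th[["top"]] * (P_T - bnd) / P_T
    }
    ## midpoint guess: dose nearest half activity, corrected for titration
    Kd0 <- max(stats::approx(act, conc, xout = 0.5, ties = mean)$y -
                 P_T / 2, P_T / 10, na.rm = TRUE)
    start <- c(Kd_app = Kd0, top = max(mean(act[conc == min(conc)]), 0.5))
  } else {
    model_fn <- function(th)
      th[["top"]] / (1 + (conc / th[["IC50"]])^th[["hill"]])
    IC0 <- stats::approx(act, conc, xout = 0.5, ties = mean)$y
    if (is.na(IC0)) IC0 <- stats::median(conc[conc > 0])
    start <- c(IC50 = IC0, hill = 1,
               top = max(mean(act[conc == min(conc)]), 0.5))
  }
  fit <- .fractional_fit(act, model_fn, start, weighting = "absolute")
  th <- coef(fit)
  curve_fn <- function(x) {
    if (model == "tight_binding")
      th[["top"]] * (P_T - bound_complex(x, P_T, th[["Kd_app"]])) / P_T
    else th[["top"]] / (1 + (x / th[["IC50"]])^th[["hill"]])
  }
  half <- th[["top"]] / 2
  hi <- max(conc[conc > 0]) * 1e3
  ic50 <- stats::uniroot(function(x) curve_fn(x) - half,
                         lower = 1e-9, upper = hi, tol = 1e-12)$root
  if (ic50 > max(conc) || ic50 < min(conc[conc > 0]))
    warning("fitted IC50 lies outside the measured dose range ",
            "(extrapolation)", call. = FALSE)
  se <- if (model == "tight_binding")
    fit$estimates$se[fit$estimates$parameter == "Kd_app"]
  else fit$estimates$se[fit$estimates$parameter == "IC50"]
  list(IC50 = ic50, se = se, fit = fit)
}

#' Convert a tight-binding IC50 to a dissociation constant
#'
#' Standard tight-binding competitive correction
#' \deqn{K_d = \frac{IC_{50} - P_T/2}{1 + S/K_m^S}:}
#' the enzyme-titration term \eqn{P_T/2} removes the stoichiometric part
#' of the IC50 and the Cheng-Prusoff factor removes competition by the
#' assay substrate.
#'
#' @param IC50 measured IC50 (nM).
#' @param P_T total enzyme in the assay (nM).
#' @param S assay substrate concentration (any unit shared with
#'   `Km_S`).
#' @param Km_S assay substrate Michaelis constant (same unit as `S`).
#' @return Kd (nM).  Errors if `IC50 <= P_T/2` (stoichiometric
#'   titration: affinity unresolvable).
#' @examples
#' ic50_to_kd(0.197, P_T = 0.125, S = 5, Km_S = 85)  # 0.127 nM
#' @export
ic50_to_kd <- function(IC50, P_T, S = 0, Km_S = Inf) {
  if (IC50 <= P_T / 2)
    stop("IC50 <= P_T/2: stoichiometric titration, Kd unresolvable",
         call. = FALSE)
  (IC50 - P_T / 2) / (1 + S / Km_S)
}
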