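## Closed-form tight-binding algebra shared by all fitting and simulation
## code.  Everything here works in nM and seconds.

#' Kinetic parameter set
#'
#' Container for the rate and binding constants of one enzyme-substrate
#' (or enzyme-inhibitor) pair.  All concentrations are nM, all rates per
#' second.
#'
#' @param Km Michaelis constant (nM).
#' @param kcat catalytic turnover number (s^-1).
#' @param kon association rate constant (nM^-1 s^-1), optional.
#' @param koff dissociation rate constant (s^-1), optional.
#' @param Kd equilibrium dissociation constant (nM), optional.  When
#'   `kon`, `koff` and `Kd` are all supplied they must satisfy
#'   `Kd = koff/kon` to a relative tolerance of 1e-6.
#'
#' @details `Km >= Kd` is deliberately not enforced: a Km describes a
#'   substrate while a Kd may describe a dead-end inhibitor, and the two
#'   may live in separate parameter sets.
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(Km = 1, kcat = 0.05, kon = 0.057)
#' @export
kinetic_params <- function(Km, kcat, kon = NULL, koff = NULL, Kd = NULL) {
  vals <- list(Km = Km, kcat = kcat, kon = kon, koff = koff, Kd = Kd)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.null(v)) {
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
        stop("'", nm, "' must be a single strictly positive number",
             call. = FALSE)
    }
  }
  if (!is.null(kon) && !is.null(koff) && !is.null(Kd)) {
    if (abs(Kd - koff / kon) > 1e-6 * Kd)
      stop("inconsistent constants: Kd must equal koff/kon ",
           "(got Kd = ", Kd, ", koff/kon = ", koff / kon, ")",
           call. = FALSE)
  }
  structure(vals, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (nM, s):\n")
  for (nm in names(x))
    if (!is.null(x[[nm]])) cat(sprintf("  %-5s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Total species concentrations
#'
#' Totals (free + bound) of the species that appear in the sequestration
#' models: pEndos (`N_T`), PP2A-B55 (`P_T`), a dead-end competitor such
#' as okadaic acid (`O_T`), a secondary phosphatase (`X_T`) and a
#' reporter substrate (`pC_T`).  All in nM.
#'
#' @param N_T total phospho-substrate/inhibitor (nM).
#' @param P_T total primary enzyme (nM).
#' @param O_T total dead-end competitor (nM), default 0.
#' @param X_T total secondary enzyme (nM), default 0.
#' @param pC_T total reporter substrate (nM), default 0.
#' @return An object of class `species_totals`.
#' @export
species_totals <- function(N_T, P_T, O_T = 0, X_T = 0, pC_T = 0) {
  vals <- list(N_T = N_T, P_T = P_T, O_T = O_T, X_T = X_T, pC_T = pC_T)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single nonnegative number", call. = FALSE)
  }
  structure(vals, class = "species_totals")
}

#' Equilibrium/QSS concentration of the enzyme-substrate complex
#'
#' Smaller root of the tight-binding conservation quadratic
#' \deqn{[NP]^2 - (N_T + P_T + K_m)[NP] + N_T P_T = 0,}
#' i.e. the complex concentration implied by mass conservation plus the
#' quasi-steady-state relation \eqn{[NP] = (N_T-[NP])(P_T-[NP])/K_m}.
#' Evaluated in the conjugate form
#' \eqn{2 N_T P_T / (s + \sqrt{s^2 - 4 N_T P_T})}, \eqn{s = N_T+P_T+K_m},
#' which avoids catastrophic cancellation when \eqn{4 N_T P_T \ll s^2}.
#'
#' @param N_T total substrate (nM); may be a vector.
#' @param P_T total enzyme (nM).
#' @param Km Michaelis (or dissociation) constant (nM).
#' @return Complex concentration (nM), in `[0, min(N_T, P_T)]`.
#' @examples
#' bound_complex(1, 0.5, 1)      # 0.2192 nM
#' bound_complex(1100, 0.5, 1)   # ~ P_T: saturation
#' @export
bound_complex <- function(N_T, P_T, Km) {
  if (any(!is.finite(N_T)) || any(N_T < 0) ||
      !is.finite(P_T) || P_T < 0 || !is.finite(Km) || Km <= 0)
    stop("bound_complex: N_T, P_T must be >= 0 and Km > 0", call. = FALSE)
  np <- numeric(length(N_T))
  nz <- N_T > 0 & P_T > 0
  if (any(nz)) {
    s <- N_T[nz] + P_T + Km
    disc <- s^2 - 4 * N_T[nz] * P_T
    disc[disc < 0] <- 0            # roundoff guard; analytically >= Km^2 > 0
    np[nz] <- 2 * N_T[nz] * P_T / (s + sqrt(disc))
  }
  pmin(np, pmin(N_T, P_T))
}

#' Morrison tight-binding initial velocity
#'
#' Initial rate of product release when the enzyme concentration is not
#' negligible relative to the substrate or Km:
#' \deqn{v = \frac{k_{cat}}{2}\left[(P_T+N_T+K_m) -
#'   \sqrt{(P_T+N_T+K_m)^2 - 4 P_T N_T}\right] = k_{cat}\,[NP].}
#' Reduces to the classic Michaelis-Menten rate
#' \eqn{k_{cat} P_T N_T/(K_m+N_T)} in the dilute-enzyme limit.
#'
#' @param N_T total substrate (nM); may be a vector.
#' @param P_T total enzyme (nM).
#' @param params a [kinetic_params()] with `Km` and `kcat`.
#' @return Velocity (nM s^-1).
#' @examples
#' p <- kinetic_params(Km = 1, kcat = 0.03)
#' morrison_velocity(1, 0.5, p)     # 0.006576 nM/s
#' morrison_velocity(1100, 0.5, p)  # ~ Vmax = 0.015 nM/s
#' @export
morrison_velocity <- function(N_T, P_T, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(params$kcat)) stop("params$kcat required", call. = FALSE)
  params$kcat * bound_complex(N_T, P_T, params$Km)
}

#' Free concentrations under competitive binding of a dead-end inhibitor
#'
#' Solves the coupled quasi-steady-state relations for pEndos (N), a
#' dead-end active-site competitor such as okadaic acid (O), and the
#' enzyme (P):
#' \deqn{[N] = \frac{N_T}{1+[P]/K_m},\quad
#'       [O] = \frac{O_T}{1+[P]/K_{dO}},\quad
#'       [P] = \frac{P_T}{1+[O]/K_{dO}+[N]/K_m},}
#' under the approximation \eqn{[N] \approx N_T}, valid when the
#' substrate is in large excess over the enzyme.  With that substitution
#' the system collapses to the quadratic
#' \deqn{a[P]^2 + (a K_{dO} + O_T - P_T)[P] - P_T K_{dO} = 0,
#'       \quad a = 1 + N_T/K_m,}
#' whose positive root is returned (evaluated in a cancellation-safe
#' form).
#'
#' @param totals a [species_totals()] with `N_T`, `P_T`, `O_T`.
#' @param Km Michaelis constant of the substrate (nM).
#' @param KdO dissociation constant of the competitor (nM), default 30.
#' @return List with free concentrations `N`, `O`, `P` (nM).
#' @examples
#' tot <- species_totals(N_T = 50, P_T = 0.25, O_T = 30)
#' free_concentrations_competitive(tot, Km = 1, KdO = 30)
#' @export
free_concentrations_competitive <- function(totals, Km, KdO = 30) {
  stopifnot(inherits(totals, "species_totals"))
  if (Km <= 0 || KdO <= 0) stop("Km and KdO must be > 0", call. = FALSE)
  N_T <- totals$N_T; P_T <- totals$P_T; O_T <- totals$O_T
  if (N_T < 100 * P_T)
    stop("validity: requires N_T >= 100 * P_T (substrate excess; got ",
         "N_T/P_T = ", signif(if (P_T > 0) N_T / P_T else Inf, 4), ")",
         call. = FALSE)
  if (P_T == 0) return(list(N = N_T, O = O_T, P = 0))
  a <- 1 + N_T / Km
  b <- a * KdO + O_T - P_T
  disc <- sqrt(b^2 + 4 * a * P_T * KdO)
  ## b > 0 here (KdO*a alone exceeds P_T in the validity regime), so the
  ## conjugate form is the stable one
  P <- 2 * P_T * KdO / (b + disc)
  O <- O_T / (1 + P / KdO)
  list(N = N_T, O = O, P = P)
}

#' Free enzyme and free substrate under the total QSSA
#'
#' Simultaneous solution of
#' \eqn{[N] = N_T/(1+[P]/K_m)} and \eqn{[P] = P_T/(1+[N]/K_m)}
#' without assuming substrate excess: both relations imply the same
#' complex concentration, the tight-binding quadratic root of
#' [bound_complex()], so \eqn{N = N_T - [NP]}, \eqn{P = P_T - [NP]}.
#' Valid even when enzyme and substrate totals are comparable -- the
#' regime in which PP2A-B55 sequesters most pEndos.
#'
#' @inheritParams bound_complex
#' @return List with free concentrations `N` and `P` (nM).
#' @examples
#' tqssa_free_pair(1000, 250, 1)  # deep sequestration: P ~ 0.33 nM
#' @export
tqssa_free_pair <- function(N_T, P_T, Km) {
  np <- bound_complex(N_T, P_T, Km)
  list(N = pmax(N_T - np, 0), P = pmax(P_T - np, 0))
}

## unit helpers -------------------------------------------------------------

#' Unit conversions to canonical nM / s
#'
#' Small helpers used at I/O boundaries; all internal computation is in
#' nM and seconds.
#'
#' @param x numeric value(s).
#' @return Converted numeric value(s).
#' @name units
NULL

#' @rdname units
#' @export
uM_to_nM <- function(x) x * 1e3

#' @rdname units
#' @export
nM_to_uM <- function(x) x / 1e3

#' @rdname units
#' @export
per_min_to_per_s <- function(x) x / 60
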