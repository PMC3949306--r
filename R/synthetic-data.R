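## Seeded generators for the three assay-table designs, with known
## ground truth embedded as metadata so every fitting stage can be
## exercised round-trip.  All generators are pure functions of
## (truth, design, seed): the global RNG state is saved and restored.

#' Noise model for synthetic assays
#'
#' Identically distributed fractional (multiplicative) errors, matching
#' the weighting assumption of the fitters.  Default: Gaussian factor
#' `1 + cv * z`, truncated at zero; a lognormal option with the same
#' log-scale sd is available.
#'
#' @param cv fractional standard deviation (default 0.10).
#' @param replicates technical replicates per design point (default 3).
#' @param seed RNG seed (integer).
#' @param dist `"gaussian"` (default) or `"lognormal"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.10, replicates = 3L, seed = 1L,
                        dist = c("gaussian", "lognormal")) {
  dist <- match.arg(dist)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  structure(list(cv = cv, replicates = as.integer(replicates),
                 seed = as.integer(seed), dist = dist),
            class = "noise_model")
}

## evaluate expr with a local RNG stream seeded from `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.apply_noise <- function(x, noise) {
  if (noise$cv == 0) return(x)
  n <- length(x)
  if (noise$dist == "gaussian")
    pmax(x * (1 + noise$cv * stats::rnorm(n)), 0)
  else
    x * stats::rlnorm(n, meanlog = -noise$cv^2 / 2, sdlog = noise$cv)
}

#' Generate a synthetic initial-velocity dataset
#'
#' Emulates a tight-binding initial-rate titration: a fixed enzyme
#' concentration (default 0.5 nM) against a substrate grid spanning
#' below-Km to deep saturation (default 1-1100 nM), with identically
#' distributed fractional noise on the Morrison velocities.
#'
#' @param truth a [kinetic_params()] with the generating `Km`, `kcat`.
#' @param P_T enzyme concentration (nM).
#' @param N_T_grid substrate concentrations (nM).
#' @param noise a [noise_model()].
#' @param incubation_time optional assay time (s); when given, design
#'   points whose implied conversion exceeds 20% trigger a warning.
#' @return A [velocity_dataset()] carrying `truth` in an attribute.
#' @export
gen_velocity_dataset <- function(truth, P_T = 0.5,
                                 N_T_grid = c(1, 2, 5, 10, 25, 50, 110,
                                              1100),
                                 noise = noise_model(),
                                 incubation_time = NA_real_) {
  stopifnot(inherits(truth, "kinetic_params"),
            inherits(noise, "noise_model"))
  if (any(N_T_grid <= 0)) stop("N_T_grid must be > 0", call. = FALSE)
  v_true <- morrison_velocity(N_T_grid, P_T, truth)
  if (!is.na(incubation_time)) {
    conv <- v_true * incubation_time / N_T_grid
    if (any(conv > 0.2))
      warning(sum(conv > 0.2), " design point(s) imply > 20% conversion ",
              "at the stated incubation time", call. = FALSE)
  }
  df <- .with_seed(noise$seed, {
    reps <- lapply(seq_len(noise$replicates), function(r)
      data.frame(N_T = N_T_grid, v = .apply_noise(v_true, noise),
                 replicate_id = r, experiment_id = 1L))
    do.call(rbind, reps)
  })
  out <- velocity_dataset(df, P_T = P_T)
  attr(out, "truth") <- list(Km = truth$Km, kcat = truth$kcat)
  attr(out, "noise") <- noise
  out
}

#' Generate a synthetic okadaic-acid competition dataset
#'
#' Emulates the competition design: fixed substrate (default 50 nM) and
#' enzyme (default 0.25 nM), a competitor dose grid spanning several
#' decades and bracketing the half-competition dose (of order
#' `KdO * N_T0 / Km` for a sub-nanomolar Km, i.e. a few uM here), and a
#' fixed incubation chosen so that even the uninhibited release stays
#' below 20% of input (the generator refuses designs that violate
#' this).
#'
#' @param truth a [kinetic_params()] with the generating `Km`, `kcat`.
#' @param N_T0 substrate concentration (nM).
#' @param P_T enzyme concentration (nM).
#' @param t_end incubation time (s).
#' @param O_T_grid competitor doses (nM).
#' @param KdO competitor dissociation constant (nM).
#' @param noise a [noise_model()].
#' @return A [competition_dataset()] carrying `truth` in an attribute.
#' @export
gen_competition_dataset <- function(truth, N_T0 = 50, P_T = 0.25,
                                    t_end = 600,
                                    O_T_grid = c(0, 30, 100, 300, 1e3,
                                                 3e3, 1e4, 3e4),
                                    KdO = 30, noise = noise_model()) {
  stopifnot(inherits(truth, "kinetic_params"),
            inherits(noise, "noise_model"))
  f_true <- predict_release(N_T0, P_T, O_T_grid, KdO, truth, t_end)
  if (max(f_true) >= 0.2)
    stop("design invalid: uninhibited release ", signif(max(f_true), 3),
         " >= 20% of input; shorten t_end or dilute the enzyme",
         call. = FALSE)
  df <- .with_seed(noise$seed, {
    reps <- lapply(seq_len(noise$replicates), function(r)
      data.frame(O_T = O_T_grid,
                 released_fraction = pmin(.apply_noise(f_true, noise), 1),
                 replicate_id = r, experiment_id = 1L))
    do.call(rbind, reps)
  })
  out <- competition_dataset(df, N_T0 = N_T0, P_T = P_T, t_end = t_end,
                             KdO = KdO)
  attr(out, "truth") <- list(Km = truth$Km, kcat = truth$kcat)
  attr(out, "noise") <- noise
  out
}

#' Generate paired control/inhibited reset time courses
#'
#' Emulates the automatic-reset experiment: a no-pEndos control and an
#' inhibited sample followed over two hours at roughly ten-minute
#' spacing, in technical replicates with fractional noise on the
#' released product.
#'
#' @param config a [reset_config()] giving the generating truth; the
#'   control uses the same enzyme and reporter with `N_T0 = 0` and decay
#'   onset 0.
#' @param t_grid sampling times (s), starting at 0.
#' @param noise a [noise_model()].
#' @return List with data.frames `control` and `inhibited` (columns
#'   `t`, `released`, `replicate_id`), plus the truth in an attribute.
#' @export
gen_reset_timecourses <- function(config,
                                  t_grid = seq(0, 7200, by = 600),
                                  noise = noise_model()) {
  stopifnot(inherits(config, "reset_config"),
            inherits(noise, "noise_model"))
  ctl_cfg <- config
  ctl_cfg$N_T0 <- 0; ctl_cfg$deg_onset <- 0
  ctl_true <- simulate_reset(ctl_cfg, t_grid)$released
  inh_true <- simulate_reset(config, t_grid)$released
  out <- .with_seed(noise$seed, {
    mk <- function(y) do.call(rbind, lapply(
      seq_len(noise$replicates), function(r)
        data.frame(t = t_grid, released = .apply_noise(y, noise),
                   replicate_id = r)))
    list(control = mk(ctl_true), inhibited = mk(inh_true))
  })
  attr(out, "truth") <- list(Km = config$Km, kcat = config$kcat,
                             eff_C = config$eff_C, kdeg = config$kdeg)
  attr(out, "noise") <- noise
  out
}
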