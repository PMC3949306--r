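## Time-indexed concentration trajectories shared by the reset and
## M-phase-exit simulators.

#' Trajectory container
#'
#' A data.frame of time-indexed concentrations (nM) and derived
#' fractions, with simulation metadata in attributes.  Column `t` is in
#' seconds; other columns depend on the producing simulator.
#'
#' @param df data.frame with a numeric `t` column.
#' @param ... metadata stored as attributes (e.g. the generating
#'   configuration).
#' @return A data.frame of class `kin_trajectory`.
#' @export
kin_trajectory <- function(df, ...) {
  stopifnot(is.data.frame(df), "t" %in% names(df))
  if (is.unsorted(df$t, strictly = TRUE))
    stop("time grid must be strictly increasing", call. = FALSE)
  meta <- list(...)
  for (nm in names(meta)) attr(df, nm) <- meta[[nm]]
  class(df) <- c("kin_trajectory", "data.frame")
  df
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat("Kinetic trajectory: ", nrow(x), " time points over [",
      min(x$t), ", ", max(x$t), "] s\n", sep = "")
  cat("columns:", paste(names(x), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' Plot phospho-substrate and free-enzyme fractions of a trajectory
#'
#' @param x a `kin_trajectory` with columns `phospho_fraction` and
#'   `free_P_fraction`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.kin_trajectory <- function(x, ...) {
  stopifnot(all(c("phospho_fraction", "free_P_fraction") %in% names(x)))
  graphics::matplot(x$t, cbind(x$phospho_fraction, x$free_P_fraction),
                    type = "l", lty = 1, lwd = 2,
                    col = c("purple", "orange"),
                    xlab = "time (s)", ylab = "fraction", ylim = c(0, 1),
                    ...)
  graphics::legend("right", c("pEndos still phosphorylated",
                              "PP2A-B55 desequestered"),
                   col = c("purple", "orange"), lty = 1, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns are suffixed with their units (`t_s`, concentrations `_nM`,
#' fractions unsuffixed).
#'
#' @param traj a `kin_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "kin_trajectory"))
  df <- as.data.frame(traj)
  nm <- names(df)
  nm[nm == "t"] <- "t_s"
  conc <- nm %in% c("N_T", "N", "P", "X", "NP", "P_T", "released")
  nm[conc] <- paste0(nm[conc], "_nM")
  names(df) <- nm
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
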