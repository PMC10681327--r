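#' Direct repeated-optimization DFBA (validation oracle)
#'
#' Simulates the same community dynamics by the textbook route: at every
#' integrator evaluation each organism's growth LP is solved afresh at the
#' current metabolite state and the instantaneous rates are used as the ODE
#' right-hand side. This is orders of magnitude slower than basis tracking
#' and provides no network interpretation; it exists purely as an
#' independent cross-check of [simulate_community()].
#'
#' @param models A `dfba_model` or list of them.
#' @param env An [environment_spec()].
#' @param x0 Initial biomass per organism.
#' @param t_final Horizon (hours).
#' @param config A [dfba_config()]; `n_samples`, `rtol`, `atol` and
#'   `refine_policy` are honoured.
#' @return `list(trajectory = data.frame(time, x_*, y_*), status)`.
#' @export
direct_dfba_oracle <- function(models, env, x0, t_final,
                               config = dfba_config()) {
  if (inherits(models, "dfba_model")) models <- list(models)
  al <- align_environment(models, env)
  models <- al$models; env <- al$env
  ids <- vapply(models, `[[`, character(1), "id")
  p <- length(models); m <- length(env$metabolite_ids)
  x <- stats::setNames(rep_len(as.numeric(x0), p), ids)
  systems <- lapply(models, assemble_lp, env = env)
  refine <- config$refine_policy != "never"

  rhs_fun <- function(t, s, parms) {
    xv <- pmax(s[seq_len(p)], 0)
    yv <- pmax(s[p + seq_len(m)], 0)
    dy <- unname(env$inflow)
    dx <- numeric(p)
    for (i in seq_len(p)) {
      sol <- solve_fba(systems[[i]], yv)
      if (sol$status != "optimal") next
      if (refine)
        sol <- suppressWarnings(
          parsimonious_refine(systems[[i]], yv, sol,
                              config$optimality_tol))
      dx[i] <- xv[i] * sol$objective_value
      dy <- dy - xv[i] * unname(sol$exchange_rates)
    }
    list(c(dx, dy))
  }

  times <- seq(0, t_final, length.out = config$n_samples)
  s0 <- c(x, env$initial_amounts)
  out <- deSolve::ode(y = s0, times = times, func = rhs_fun, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10,
                      maxsteps = 100000L)
  traj <- as.data.frame(unclass(out))
  names(traj) <- trajectory_names(ids, env$metabolite_ids)
  rownames(traj) <- NULL
  list(trajectory = traj, status = "reached_t_final")
}

#' Maximum state-normalized difference between two trajectories
#'
#' Compares two simulations of the same community on a shared time grid:
#' for every state column, the maximum absolute difference divided by the
#' larger of the two trajectories' overall maximum magnitude for that
#' column (columns that stay at zero in both are skipped).
#'
#' @param trajA,trajB Trajectory data frames with a shared `time` grid.
#' @return A single scalar relative error.
#' @export
trajectory_rel_error <- function(trajA, trajB) {
  common <- intersect(names(trajA), names(trajB))
  common <- setdiff(common, "time")
  tt <- intersect(round(trajA$time, 10), round(trajB$time, 10))
  ia <- match(tt, round(trajA$time, 10))
  ib <- match(tt, round(trajB$time, 10))
  worst <- 0
  for (cn in common) {
    a <- trajA[[cn]][ia]; b <- trajB[[cn]][ib]
    scale <- max(abs(a), abs(b))
    if (scale == 0) next
    worst <- max(worst, max(abs(a - b)) / scale)
  }
  worst
}
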