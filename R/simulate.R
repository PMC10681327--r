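#' Integrate one smooth DFBA segment up to its first constraint event
#'
#' Integrates the segment ODE with `deSolve`'s `lsodar` (adaptive, with
#' built-in root localization). The event condition is the earliest time at
#' which any monitored non-basic constraint residual crosses
#' `-active_tol`, or any metabolite amount crosses `-active_tol`; the
#' trajectory is truncated at the event.
#'
#' @param segment A `dfba_segment` from [build_segment()].
#' @param state A [community_state()] at `segment$t_start`.
#' @param t_max Upper integration limit.
#' @param config A [dfba_config()].
#' @param times Optional sample times (default: 50 points over the span).
#' @return `list(trajectory = data.frame(time, x_*, y_*), event = NULL` or
#'   `list(time, kind, microbe, constraint))`.
#' @export
integrate_segment <- function(segment, state, t_max, config = dfba_config(),
                              times = NULL) {
  env <- segment$env
  p <- length(state$x); m <- length(env$metabolite_ids)
  t0 <- state$time
  if (t_max <= t0)
    return(list(trajectory = empty_trajectory(segment$model_ids,
                                              env$metabolite_ids),
                event = NULL))
  if (is.null(times)) times <- seq(t0, t_max, length.out = 50L)
  times <- sort(unique(c(t0, times[times > t0 & times < t_max], t_max)))
  s0 <- c(state$x, pmax(state$y, 0))

  rhs_fun <- function(t, s, parms) {
    x <- s[seq_len(p)]; y <- s[p + seq_len(m)]
    r <- segment_rhs(segment, x, y)
    list(c(r$dx, r$dy))
  }

  # monitored roots: per organism non-basic bound rows, then y >= 0
  mon <- segment$validity
  root_map <- do.call(rbind, c(
    lapply(seq_along(mon), function(i)
      if (length(mon[[i]]) == 0L) NULL
      else data.frame(kind = "constraint", microbe = i, row = mon[[i]])),
    list(data.frame(kind = "nonneg", microbe = NA_integer_,
                    row = seq_len(m)))))
  slack_vec <- function(y) {
    v <- unlist(lapply(seq_along(mon), function(i) {
      rows <- mon[[i]]
      if (length(rows) == 0L) return(numeric())
      sys <- segment$systems[[i]]
      psi <- basis_solve(segment$bases[[i]], y)
      rhs <- rhs_at(sys, pmax(y, 0))
      ax <- as.vector(sys$coeff[rows, , drop = FALSE] %*% psi)
      ifelse(sys$kind[rows] == "upper", rhs[rows] - ax, ax - rhs[rows])
    }))
    if (is.null(v)) numeric(0) else v
  }
  slack0 <- slack_vec(unname(state$y))
  offset <- config$active_tol +
    pmax(0, -slack0 + config$active_tol)   # guard rows already at the edge
  root_fun <- function(t, s, parms) {
    y <- s[p + seq_len(m)]
    c(slack_vec(y) + offset, y + config$active_tol)
  }

  out <- deSolve::lsodar(y = s0, times = times, func = rhs_fun, parms = NULL,
                         rootfunc = root_fun, rtol = config$rtol,
                         atol = config$atol, maxsteps = 100000L)
  troot <- attr(out, "troot")
  event <- NULL
  if (length(troot) > 0 && is.finite(troot[1])) {
    ir <- which(attr(out, "iroot") != 0)
    nslack <- length(slack0)
    ev_rows <- root_map[ir, , drop = FALSE]
    constraint <- vapply(seq_len(nrow(ev_rows)), function(k) {
      if (ev_rows$kind[k] == "nonneg")
        paste0("nonneg:", env$metabolite_ids[ev_rows$row[k]])
      else segment$systems[[ev_rows$microbe[k]]]$label[ev_rows$row[k]]
    }, character(1))
    event <- list(time = troot[1],
                  kind = ev_rows$kind,
                  microbe = ifelse(is.na(ev_rows$microbe), NA_character_,
                                   segment$model_ids[ev_rows$microbe]),
                  constraint = constraint)
  }
  traj <- as.data.frame(unclass(out))
  names(traj) <- trajectory_names(segment$model_ids,
                                  env$metabolite_ids)
  rownames(traj) <- NULL
  list(trajectory = traj, event = event)
}

# paste0 recycles zero-length inputs to "", so guard empty communities
prefix0 <- function(prefix, ids) {
  if (length(ids) == 0L) character(0) else paste0(prefix, ids)
}

trajectory_names <- function(model_ids, met_ids)
  c("time", prefix0("x_", model_ids), prefix0("y_", met_ids))

empty_trajectory <- function(model_ids, met_ids) {
  df <- as.data.frame(matrix(numeric(), 0L,
                             1L + length(model_ids) + length(met_ids)))
  names(df) <- trajectory_names(model_ids, met_ids)
  df
}

#' Simulate a microbial community with basis-tracked DFBA
#'
#' Runs the full hybrid simulation: at the start and after every constraint
#' event each organism's growth LP is solved (and, per
#' `config$refine_policy`, parsimoniously refined), a forward-compatible
#' active-constraint basis is selected, the resulting smooth ODE segment is
#' integrated until its first event, and the loop repeats until the horizon
#' is reached, dynamics freeze (stationary phase), or the transition cap is
#' hit.
#'
#' @param models A `dfba_model` or list of them.
#' @param env A [environment_spec()]; models are aligned to it internally.
#' @param x0 Initial biomass (gDW), recycled/named per model id.
#' @param t_final Simulation horizon (hours), `> 0`.
#' @param config A [dfba_config()].
#' @return A `dfba_result`: `segments` (list of `dfba_segment` with closed
#'   `t_end`), `trajectory` (data frame `time`, `x_<id>`, `y_<met>`),
#'   `transitions` (data frame `time`, `microbe`, `constraint`, `action`),
#'   `status` (`reached_t_final`/`stationary`/`failed`), plus the aligned
#'   `models` and `env`.
#' @examples
#' fx <- capped_growth()
#' res <- simulate_community(fx$model, fx$env, x0 = 0.1, t_final = 1)
#' length(res$segments)   # 2: growth-capped epoch, then uptake-limited
#' @export
simulate_community <- function(models, env, x0, t_final,
                               config = dfba_config()) {
  if (inherits(models, "dfba_model")) models <- list(models)
  stopifnot(t_final > 0)
  al <- align_environment(models, env)
  models <- al$models; env <- al$env
  ids <- vapply(models, `[[`, character(1), "id")
  p <- length(models); m <- length(env$metabolite_ids)
  x <- stats::setNames(rep_len(as.numeric(x0), p), ids)
  y <- env$initial_amounts
  systems <- lapply(models, assemble_lp, env = env)
  grid <- seq(0, t_final, length.out = config$n_samples)

  t <- 0
  segments <- list()
  traj <- list()
  transitions <- data.frame(time = numeric(), microbe = character(),
                            constraint = character(), action = character())
  status <- "reached_t_final"
  n_trans <- 0L
  halvings <- 0L
  delta <- t_final * 1e-3

  repeat {
    # fresh per-organism LP solves at the current state
    sols <- vector("list", p)
    for (i in seq_len(p)) {
      sol <- solve_fba(systems[[i]], pmax(y, 0))
      if (sol$status == "optimal" && config$refine_policy != "never" &&
          (config$refine_policy == "always" || t == 0))
        sol <- parsimonious_refine(systems[[i]], pmax(y, 0), sol,
                                   config$optimality_tol)
      sols[[i]] <- sol
    }
    psis <- lapply(seq_len(p), function(i)
      if (sols[[i]]$status == "optimal") unname(sols[[i]]$fluxes)
      else numeric(length(systems[[i]]$reaction_ids)))
    ydot <- unname(env$inflow)
    for (i in seq_len(p))
      ydot <- ydot - x[i] * as.vector(models[[i]]$exchange_stoich %*%
                                        psis[[i]])
    growth <- vapply(seq_len(p), function(i)
      sum(models[[i]]$objective * psis[[i]]), numeric(1))

    # frozen dynamics => stationary phase: pad the trajectory and stop
    if (all(abs(x * growth) < config$stationary_tol) &&
        all(abs(ydot) < config$stationary_tol) && length(segments) > 0L) {
      status <- "stationary"
      pad_t <- unique(c(t, grid[grid > t], t_final))
      pad <- data.frame(time = pad_t)
      for (i in seq_len(p)) pad[[paste0("x_", ids[i])]] <- x[i]
      for (j in seq_len(m))
        pad[[paste0("y_", env$metabolite_ids[j])]] <- y[j]
      traj[[length(traj) + 1L]] <- pad
      segments[[length(segments)]]$t_end <- t_final
      break
    }

    # select forward-compatible bases
    bases <- vector("list", p)
    reduced <- FALSE
    for (i in seq_len(p)) {
      if (sols[[i]]$status != "optimal") next
      cands <- enumerate_bases(systems[[i]], pmax(y, 0), sols[[i]], config)
      fb <- forward_basis(systems[[i]], pmax(y, 0), ydot, cands, config)
      if (fb$action == "step_reduced") { reduced <- TRUE; break }
      bases[[i]] <- fb$basis
    }

    if (reduced) {
      # protective step: advance by explicit step on the instantaneous
      # rates, then retry with fresh FBA; halve delta on repeats
      halvings <- halvings + 1L
      if (halvings > config$max_step_halvings) { status <- "failed"; break }
      delta_i <- delta / 2^(halvings - 1L)
      transitions <- rbind(transitions, data.frame(
        time = t, microbe = ids[i], constraint = "forward basis",
        action = "step_reduced"))
      x <- pmax(x + delta_i * x * growth, 0)
      y <- pmax(y + delta_i * ydot, 0)
      t <- t + delta_i
      if (t >= t_final) break
      next
    }
    halvings <- 0L

    seg <- build_segment(models, bases, env, community_state(t, x, y),
                         t, systems = systems)
    res_i <- integrate_segment(seg, community_state(t, x, y), t_final,
                               config, times = grid)
    traj[[length(traj) + 1L]] <- res_i$trajectory
    if (is.null(res_i$event)) {
      seg$t_end <- t_final
      segments[[length(segments) + 1L]] <- seg
      break
    }
    ev <- res_i$event
    seg$t_end <- ev$time
    segments[[length(segments) + 1L]] <- seg
    n_trans <- n_trans + 1L
    if (n_trans > config$max_transitions) { status <- "failed"; break }
    transitions <- rbind(transitions, data.frame(
      time = ev$time,
      microbe = ifelse(is.na(ev$microbe), "(environment)", ev$microbe),
      constraint = ev$constraint, action = "new_basis"))
    last <- res_i$trajectory[nrow(res_i$trajectory), ]
    t <- ev$time
    x <- stats::setNames(pmax(as.numeric(last[paste0("x_", ids)]), 0), ids)
    y <- stats::setNames(
      pmax(as.numeric(last[paste0("y_", env$metabolite_ids)]), 0),
      env$metabolite_ids)
    if (t >= t_final - config$time_tol) break
  }

  trajectory <- do.call(rbind, traj)
  if (!is.null(trajectory) && nrow(trajectory) > 0L) {
    trajectory <- trajectory[!duplicated(round(trajectory$time, 12)), ]
    rownames(trajectory) <- NULL
  } else {
    trajectory <- empty_trajectory(ids, env$metabolite_ids)
  }
  structure(list(segments = segments, trajectory = trajectory,
                 transitions = transitions, status = status,
                 models = models, env = env, config = config),
            class = "dfba_result")
}

#' @export
print.dfba_result <- function(x, ...) {
  cat(sprintf(
    "<dfba_result: %d segment(s), %d transition(s), status %s>\n",
    length(x$segments), nrow(x$transitions), x$status))
  invisible(x)
}
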