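#' Build a smooth ODE segment from per-organism bases
#'
#' Within one segment each organism's flux is the affine-in-bounds solution
#' `psi_i = B_i^{-1} cbar_i(y)`, so the community dynamics can be arranged
#' into closed form. Writing `g_i = gamma_i' B_i^{-1}` and
#' `E_i = exchange_stoich_i %*% B_i^{-1}`, the coefficients are
#'
#' * `C_i` (intrinsic growth, 1/h): sum of `g_i[r] * rhs_r` over basis rows
#'   with constant right-hand side;
#' * `a_ij`: sum of `g_i[r]` over basis rows referencing the uptake bound
#'   `c2_ij` of metabolite `j`;
#' * `D_il`: sum of `E_i[l, r] * rhs_r` over constant rows;
#' * `b_ijl`: sum of `E_i[l, r]` over rows referencing `c2_ij`,
#'
#' and the segment dynamics are
#' `dx_i/dt = x_i (C_i + sum_j a_ij c2_ij(y_j))` and
#' `dy_l/dt = inflow_l - sum_i x_i (D_il + sum_j b_ijl c2_ij(y_j))`.
#'
#' @param models List of aligned `dfba_model`s.
#' @param bases List of `dfba_basis`, one per model (NULL for an organism
#'   with no feasible growth LP: it contributes nothing to the dynamics).
#' @param env The shared [environment_spec()].
#' @param state A [community_state()] at segment start.
#' @param t_start Segment start time.
#' @param systems Optional list of matching `dfba_lp` systems (for event
#'   monitoring); rebuilt from the models if omitted.
#' @return A `dfba_segment` holding interval, bases, coefficients and the
#'   monitored non-basic constraint list.
#' @export
build_segment <- function(models, bases, env, state, t_start,
                          systems = NULL) {
  if (is.null(systems))
    systems <- lapply(models, assemble_lp, env = env)
  m <- length(env$metabolite_ids)
  coeffs <- vector("list", length(models))
  names(coeffs) <- vapply(models, `[[`, character(1), "id")
  for (i in seq_along(models)) {
    mod <- models[[i]]
    bas <- bases[[i]]
    if (is.null(bas)) {
      coeffs[[i]] <- list(C = 0, a = numeric(m), D = numeric(m),
                          b = matrix(0, m, m), funs = mod$exchange_upper,
                          active_j = integer())
      next
    }
    g <- as.vector(mod$objective %*% bas$Binv)
    E <- mod$exchange_stoich %*% bas$Binv
    C <- 0; a <- numeric(m); D <- numeric(m); b <- matrix(0, m, m)
    for (r in seq_along(bas$rows)) {
      if (is.null(bas$fun[[r]])) {
        C <- C + g[r] * bas$rhs[r]
        D <- D + E[, r] * bas$rhs[r]
      } else {
        j <- bas$met_index[r]
        if (is.na(j))
          stop("basis row references a metabolite absent from environment")
        a[j] <- a[j] + g[r]
        b[j, ] <- b[j, ] + E[, r]
      }
    }
    dimnames(b) <- list(env$metabolite_ids, env$metabolite_ids)
    names(a) <- names(D) <- env$metabolite_ids
    C <- unname(C)
    coeffs[[i]] <- list(C = C, a = a, D = D, b = b,
                        funs = mod$exchange_upper,
                        active_j = which(a != 0 | rowSums(b != 0) > 0))
  }
  structure(list(
    t_start = t_start, t_end = NA_real_,
    model_ids = names(coeffs),
    bases = bases, coeffs = coeffs, env = env,
    systems = systems,
    validity = monitored_rows(systems, bases)),
    class = "dfba_segment")
}

# Non-basic bound rows of each organism: these are exactly the ways the
# basis solution can stop obeying the problem constraints.
monitored_rows <- function(systems, bases) {
  lapply(seq_along(systems), function(i) {
    sys <- systems[[i]]; bas <- bases[[i]]
    if (is.null(bas)) return(integer())
    setdiff(which(sys$kind != "eq"), bas$rows)
  })
}

#' @export
print.dfba_segment <- function(x, ...) {
  cat(sprintf("<dfba_segment [%0.6g, %s): %d organisms, %d metabolites>\n",
              x$t_start, ifelse(is.na(x$t_end), "?", format(x$t_end)),
              length(x$coeffs), length(x$env$metabolite_ids)))
  invisible(x)
}

# Segment right-hand side at state (x, y). Returns list(dx, dy, growth).
segment_rhs <- function(segment, x, y) {
  env <- segment$env
  m <- length(env$metabolite_ids)
  dy <- unname(env$inflow)
  dx <- numeric(length(x))
  growth <- numeric(length(x))
  for (i in seq_along(segment$coeffs)) {
    cf <- segment$coeffs[[i]]
    c2 <- numeric(m)
    for (j in cf$active_j) c2[j] <- bf_eval(cf$funs[[j]], y[j])
    gi <- cf$C + sum(cf$a * c2)
    growth[i] <- gi
    dx[i] <- x[i] * gi
    v <- cf$D + as.vector(c2 %*% cf$b)   # sum_j b[j, l] * c2[j]
    dy <- dy - x[i] * v
  }
  list(dx = unname(dx), dy = unname(dy), growth = growth)
}

#' Select a forward-compatible basis at a (possibly degenerate) vertex
#'
#' At a degenerate optimum several invertible bases reproduce the same flux
#' vector, but most of them immediately violate a constraint when the
#' simulation moves on. A candidate basis is *admissible* when every
#' non-basic active constraint has slack time-derivative `>= -deriv_tol`
#' under the induced dynamics (with the environment's drift `ydot`
#' estimated from the whole community). Among admissible candidates the one
#' maximizing the minimum slack derivative is chosen — locally, the basis
#' expected to stay valid longest — with ties broken by the fixed
#' lowest-row-index ordering.
#'
#' @param system A `dfba_lp`.
#' @param y Metabolite state at the vertex.
#' @param ydot_estimate Estimated `dy/dt` of the community at the vertex.
#' @param candidates List of `dfba_basis` (e.g. from the internal basis
#'   enumeration); all must reproduce the optimal flux at `y`.
#' @param config A [dfba_config()].
#' @return `list(basis =, action =)` with `action` `"new_basis"`, or
#'   `action = "step_reduced"` (and `basis = NULL`) when no candidate is
#'   admissible so the caller must take a protective step.
#' @export
forward_basis <- function(system, y, ydot_estimate, candidates,
                          config = dfba_config()) {
  if (length(candidates) == 0L)
    stop("no invertible candidate basis for model '", system$model_id, "'")
  if (length(candidates) == 1L)
    return(list(basis = candidates[[1L]], action = "new_basis"))
  y <- pmax(y_for_system(system, y), 0)
  rhs <- rhs_at(system, y)
  best <- NULL; best_score <- -Inf
  for (bas in candidates) {
    psi <- basis_solve(bas, y)
    cbar_dot <- basis_rhs_dot(bas, y, ydot_estimate)
    psi_dot <- as.vector(bas$Binv %*% cbar_dot)
    others <- setdiff(which(system$kind != "eq"), bas$rows)
    ax <- as.vector(system$coeff[others, , drop = FALSE] %*% psi)
    slack <- ifelse(system$kind[others] == "upper",
                    rhs[others] - ax, ax - rhs[others])
    act <- others[slack < config$active_tol]
    if (length(act) == 0L) { score <- Inf } else {
      ax_dot <- as.vector(system$coeff[act, , drop = FALSE] %*% psi_dot)
      rhs_dot <- vapply(act, function(r) {
        if (is.null(system$fun[[r]])) 0
        else bf_deriv(system$fun[[r]], y[system$met_index[r]]) *
          ydot_estimate[system$met_index[r]]
      }, numeric(1))
      sdot <- ifelse(system$kind[act] == "upper",
                     rhs_dot - ax_dot, ax_dot - rhs_dot)
      score <- min(sdot)
    }
    if (score > best_score + config$deriv_tol) {
      best <- bas; best_score <- score
    }
  }
  if (best_score < -config$deriv_tol)
    return(list(basis = NULL, action = "step_reduced"))
  list(basis = best, action = "new_basis")
}
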