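#' Extract an invertible active-constraint basis at an optimal vertex
#'
#' By the fundamental theorem of linear programming an optimal solution can
#' be represented as the solution of a square invertible subsystem of
#' constraints: `B %*% psi = cbar(y)`. The basis is built from a maximal
#' linearly independent set of internal balance equalities plus active bound
#' rows (residual below `active_tol`), completed to exactly `n_reactions`
#' rows. Degenerate vertices (more active rows than needed) are resolved by
#' a Bland-style lowest-row-index preference over the fixed row ordering, so
#' repeated calls give identical bases.
#'
#' @param system A `dfba_lp`.
#' @param y Metabolite state.
#' @param solution An optimal (ideally parsimoniously refined) `dfba_flux`.
#' @param config A [dfba_config()].
#' @return A `dfba_basis`: ordered `rows` (indices into the constraint
#'   system), the square matrix `B` and its inverse, and per-row right-hand
#'   side references.
#' @export
extract_basis <- function(system, y, solution, config = dfba_config()) {
  cands <- enumerate_bases(system, y, solution, config, max_bases = 1L)
  if (length(cands) == 0L)
    stop("cannot complete an invertible basis for model '", system$model_id,
         "'; active rows: ",
         paste(system$label[active_rows(system, y, solution, config)],
               collapse = ", "))
  cands[[1L]]
}

# Indices of rows active at the solution (equalities always; bound rows by
# residual).
active_rows <- function(system, y, solution, config) {
  y <- pmax(y_for_system(system, y), 0)
  rhs <- rhs_at(system, y)
  ax <- as.vector(system$coeff %*% solution$fluxes)
  resid <- abs(ax - rhs)
  which(system$kind == "eq" | resid < config$active_tol)
}

# Enumerate invertible active-row bases in deterministic lexicographic
# order. Equality rows contribute a fixed maximal independent subset;
# remaining slots are filled from active bound rows. Candidates are kept
# only when dual feasible: the basis multipliers gamma' B^{-1} must be
# >= 0 on upper rows and <= 0 on lower rows, otherwise the basis solution
# stops being optimal the moment the vertex moves. Returns up to
# `max_bases` dfba_basis objects (all reproduce the current solution).
enumerate_bases <- function(system, y, solution, config = dfba_config(),
                            max_bases = Inf) {
  n <- length(system$reaction_ids)
  act <- active_rows(system, y, solution, config)
  eq_act <- act[system$kind[act] == "eq"]
  bd_act <- act[system$kind[act] != "eq"]
  # maximal independent set of equality rows, lowest index first
  eq_keep <- integer()
  M <- matrix(0, 0L, n)
  for (r in eq_act) {
    M2 <- rbind(M, system$coeff[r, ])
    if (qr(M2)$rank > nrow(M)) { M <- M2; eq_keep <- c(eq_keep, r) }
  }
  k <- n - length(eq_keep)
  if (k < 0L) stop("more independent equality rows than reactions")
  if (k > length(bd_act)) return(list())
  combos <- if (k == 0L) list(integer())
            else if (length(bd_act) == k) list(bd_act)
            else if (choose(length(bd_act), k) <= config$enumeration_cap)
              utils::combn(bd_act, k, simplify = FALSE)
            else greedy_completions(system, bd_act, M, k)
  out <- list(); fallback <- list()
  dual_tol <- 10 * config$optimality_tol
  for (cmb in combos) {
    rows <- c(eq_keep, cmb)
    B <- system$coeff[rows, , drop = FALSE]
    if (rcond(B) < 1 / config$cond_max) next
    bas <- new_basis(system, rows, B)
    mult <- as.vector(system$objective %*% bas$Binv)
    kinds <- system$kind[rows]
    dual_ok <- all(mult[kinds == "upper"] >= -dual_tol) &&
      all(mult[kinds == "lower"] <= dual_tol)
    if (dual_ok) {
      out[[length(out) + 1L]] <- bas
      if (length(out) >= max_bases) break
    } else if (length(fallback) == 0L) {
      fallback[[1L]] <- bas
    }
  }
  if (length(out) == 0L && length(fallback) > 0L) {
    warning("no dual-feasible basis found for model '", system$model_id,
            "'; falling back to a primal-only basis")
    out <- fallback
  }
  out
}

# Fallback when the degenerate active set is too large to enumerate: a
# single greedy completion, lowest row index first.
greedy_completions <- function(system, bd_act, M_eq, k) {
  keep <- integer(); M <- M_eq
  for (r in bd_act) {
    if (length(keep) == k) break
    M2 <- rbind(M, system$coeff[r, ])
    if (qr(M2)$rank > nrow(M)) { M <- M2; keep <- c(keep, r) }
  }
  if (length(keep) == k) list(keep) else list()
}

new_basis <- function(system, rows, B = NULL) {
  if (is.null(B)) B <- system$coeff[rows, , drop = FALSE]
  structure(list(
    model_id = system$model_id,
    rows = as.integer(rows),
    B = B,
    Binv = solve(B),
    rhs = system$rhs[rows],
    fun = system$fun[rows],
    met_index = system$met_index[rows],
    label = system$label[rows]),
    class = "dfba_basis")
}

#' @export
print.dfba_basis <- function(x, ...) {
  cat(sprintf("<dfba_basis '%s': rows {%s}>\n", x$model_id,
              paste(x$label, collapse = ", ")))
  invisible(x)
}

#' Solve the basis linear system at a metabolite state
#'
#' Computes `psi = B^{-1} cbar(y)` with the basis right-hand sides (constant
#' or uptake bound functions) evaluated at `y`. No feasibility check is
#' performed: detecting when this solution stops obeying the non-basic
#' constraints is the integrator's event condition.
#'
#' @param basis A `dfba_basis`.
#' @param y Metabolite vector in environment order (or named).
#' @return Numeric flux vector.
#' @export
basis_solve <- function(basis, y) {
  stopifnot(inherits(basis, "dfba_basis"))
  as.vector(basis$Binv %*% basis_rhs(basis, y))
}

basis_rhs <- function(basis, y) {
  r <- basis$rhs
  for (i in seq_along(r))
    if (!is.null(basis$fun[[i]]))
      r[i] <- bf_eval(basis$fun[[i]], y[basis$met_index[i]])
  r
}

# d cbar / d t given ydot (chain rule through the bound functions).
basis_rhs_dot <- function(basis, y, ydot) {
  r <- numeric(length(basis$rhs))
  for (i in seq_along(r))
    if (!is.null(basis$fun[[i]])) {
      j <- basis$met_index[i]
      r[i] <- bf_deriv(basis$fun[[i]], y[j]) * ydot[j]
    }
  r
}
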