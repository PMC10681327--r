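#' Assemble the growth linear program of one organism
#'
#' Stacks the constraint rows of the flux balance LP in a fixed,
#' deterministic order: all internal balance equalities (internal metabolite
#' order), then per environmental metabolite (environment order) the
#' exchange lower and upper rows, then per reaction the constant flux lower
#' and upper rows. Exchange upper rows carry a reference to the model's
#' uptake bound function instead of a constant right-hand side; rows with an
#' infinite right-hand side or an all-zero coefficient vector are omitted
#' (they can never be active).
#'
#' @param model A `dfba_model`, aligned to `env` (see [align_environment()]).
#' @param env The shared [environment_spec()].
#' @return A `dfba_lp` constraint system: coefficient matrix, row kinds
#'   (`eq`/`upper`/`lower`), constant right-hand sides (`NA` where a bound
#'   function applies), bound-function references, source tags and labels.
#' @export
assemble_lp <- function(model, env) {
  if (!identical(rownames(model$exchange_stoich), env$metabolite_ids))
    stop("model '", model$id, "' is not aligned to the environment; ",
         "call align_environment() first")
  n <- length(model$reaction_ids)
  rows_coeff <- list(); kind <- character(); rhs <- numeric()
  fun <- list(); met <- character(); src <- character(); lab <- character()
  add_row <- function(coeff, k, r, f, mt, s, l) {
    rows_coeff[[length(rows_coeff) + 1L]] <<- coeff
    kind <<- c(kind, k); rhs <<- c(rhs, r)
    fun <<- c(fun, list(f))
    met <<- c(met, mt); src <<- c(src, s); lab <<- c(lab, l)
  }
  ist <- model$internal_stoich
  if (nrow(ist) > 0L) {
    imets <- rownames(ist)
    if (is.null(imets)) imets <- paste0("internal_", seq_len(nrow(ist)))
    for (r in seq_len(nrow(ist)))
      add_row(ist[r, ], "eq", 0, NULL, NA_character_, "balance",
              paste0("balance:", imets[r]))
  }
  ex <- model$exchange_stoich
  for (j in seq_along(env$metabolite_ids)) {
    mj <- env$metabolite_ids[j]
    if (all(ex[j, ] == 0)) next
    if (is.finite(model$exchange_lower[j]))
      add_row(ex[j, ], "lower", model$exchange_lower[j], NULL, mj,
              "exchange", paste0("exchange_lower:", mj))
    add_row(ex[j, ], "upper", NA_real_, model$exchange_upper[[j]], mj,
            "exchange", paste0("exchange_upper:", mj))
  }
  for (r in seq_len(n)) {
    e_r <- numeric(n); e_r[r] <- 1
    rid <- model$reaction_ids[r]
    if (is.finite(model$lower_flux[r]))
      add_row(e_r, "lower", model$lower_flux[r], NULL, NA_character_,
              "flux", paste0("flux_lower:", rid))
    if (is.finite(model$upper_flux[r]))
      add_row(e_r, "upper", model$upper_flux[r], NULL, NA_character_,
              "flux", paste0("flux_upper:", rid))
  }
  coeff <- do.call(rbind, rows_coeff)
  if (is.null(coeff)) coeff <- matrix(0, 0L, n)
  colnames(coeff) <- model$reaction_ids
  rownames(coeff) <- lab
  structure(list(
    model_id = model$id,
    reaction_ids = model$reaction_ids,
    coeff = coeff, kind = kind, rhs = rhs, fun = fun,
    met = met, source = src, label = lab,
    met_index = match(met, env$metabolite_ids),
    objective = model$objective,
    exchange_stoich = model$exchange_stoich,
    exchange_upper = model$exchange_upper,
    metabolite_ids = env$metabolite_ids),
    class = "dfba_lp")
}

#' @export
print.dfba_lp <- function(x, ...) {
  cat(sprintf("<dfba_lp '%s': %d rows x %d reactions (%d eq, %d functional)>\n",
              x$model_id, length(x$kind), length(x$reaction_ids),
              sum(x$kind == "eq"), sum(!vapply(x$fun, is.null, logical(1)))))
  invisible(x)
}

# Evaluate all right-hand sides of a constraint system at metabolite state y.
rhs_at <- function(system, y) {
  r <- system$rhs
  idx <- which(!vapply(system$fun, is.null, logical(1)))
  for (i in idx)
    r[i] <- bf_eval(system$fun[[i]], y[system$met_index[i]])
  r
}

# Narrow LP backend contract: optimize obj.x subject to row constraints
#   coeff[kind=="eq"]    %*% x == rhs
#   coeff[kind=="upper"] %*% x <= rhs
#   coeff[kind=="lower"] %*% x >= rhs
# over free x. Backed by the deterministic dense simplex in R/simplex.R;
# `cost` optionally overrides the objective applied to the split variables
# (p, q) — used by the parsimonious total-flux refinement. Returns
# list(status, x, value); status optimal / infeasible / unbounded / error.
lp_backend <- function(obj, coeff, kind, rhs, maximize = TRUE,
                       cost = NULL) {
  simplex_rows(obj, coeff, kind, rhs, maximize = maximize, cost = cost)
}

#' Solve the flux balance LP at a given metabolite state
#'
#' Evaluates all metabolite-dependent bound functions at `y` and maximizes
#' the growth objective over fluxes subject to the assembled constraints.
#'
#' @param system A `dfba_lp` from [assemble_lp()].
#' @param y Named (or environment-ordered) metabolite vector; negative
#'   entries are clipped to 0 with a warning.
#' @param objective Optional objective override (defaults to the model's).
#' @return A `dfba_flux` solution: `fluxes`, `objective_value` (growth rate,
#'   1/h), `exchange_rates` (`exchange_stoich %*% fluxes`, mmol/gDW/h,
#'   positive = uptake) and `status` (`optimal`/`infeasible`/`unbounded`).
#' @export
solve_fba <- function(system, y, objective = NULL) {
  stopifnot(inherits(system, "dfba_lp"))
  if (is.null(objective)) objective <- system$objective
  y <- y_for_system(system, y)
  if (any(y < 0)) {
    warning("negative metabolite amounts clipped to 0 before LP solve")
    y <- pmax(y, 0)
  }
  rhs <- rhs_at(system, y)
  res <- lp_backend(objective, system$coeff, system$kind, rhs)
  if (res$status == "error")
    stop("LP solver failure for model '", system$model_id, "': ",
         res$message)
  if (res$status != "optimal")
    return(flux_solution(system, rep(NA_real_, length(objective)),
                         res$status))
  flux_solution(system, res$x, "optimal")
}

flux_solution <- function(system, psi, status) {
  ex <- if (all(is.na(psi))) rep(NA_real_, nrow(system$exchange_stoich))
        else as.vector(system$exchange_stoich %*% psi)
  structure(list(
    fluxes = stats::setNames(psi, system$reaction_ids),
    objective_value = if (all(is.na(psi))) NA_real_
                      else sum(system$objective * psi),
    exchange_rates = stats::setNames(ex, system$metabolite_ids),
    status = status),
    class = "dfba_flux")
}

#' @export
print.dfba_flux <- function(x, ...) {
  cat(sprintf("<dfba_flux: status %s, growth %.6g>\n", x$status,
              x$objective_value))
  invisible(x)
}

# Accept y as named vector or in environment order.
y_for_system <- function(system, y) {
  mets <- system$metabolite_ids
  if (!is.null(names(y)) && all(mets %in% names(y))) return(unname(y[mets]))
  if (length(y) != length(mets))
    stop("metabolite state has wrong length and no usable names")
  unname(y)
}

#' Parsimonious refinement of an optimal flux solution
#'
#' Among the (possibly non-unique) optima of the growth LP, selects one
#' minimizing total flux `sum(|psi|)`, implemented as a secondary LP with
#' the growth objective pinned at its optimum and absolute values handled by
#' variable splitting. Futile internal cycles, which inflate total flux
#' without changing growth, are removed by this step.
#'
#' @param system A `dfba_lp`.
#' @param y Metabolite state at which `solution` was computed.
#' @param solution An optimal `dfba_flux` from [solve_fba()].
#' @param optimality_tol Allowed change in the growth objective.
#' @return A `dfba_flux` with the same objective value and minimal total
#'   flux; if the secondary LP fails, the input solution with a warning.
#' @export
parsimonious_refine <- function(system, y, solution,
                                optimality_tol = 1e-7) {
  stopifnot(inherits(solution, "dfba_flux"))
  if (solution$status != "optimal") stop("solution must be optimal")
  y <- pmax(y_for_system(system, y), 0)
  rhs <- rhs_at(system, y)
  n <- length(system$reaction_ids)
  coeff <- rbind(system$coeff, system$objective)
  kind <- c(system$kind, "eq")
  rhs2 <- c(rhs, solution$objective_value)
  res <- lp_backend(rep(0, n), coeff, kind, rhs2, maximize = FALSE,
                    cost = rep(1, 2L * n))
  if (res$status != "optimal") {
    warning("parsimonious refinement LP failed; returning input solution")
    return(solution)
  }
  refined <- flux_solution(system, res$x, "optimal")
  if (abs(refined$objective_value - solution$objective_value) >
      max(optimality_tol, optimality_tol * abs(solution$objective_value))) {
    warning("parsimonious refinement changed the objective; ",
            "returning input solution")
    return(solution)
  }
  refined
}
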