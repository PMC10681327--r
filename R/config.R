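#' Numerical and policy configuration for DFBA simulation
#'
#' All tolerances in one place, with standard double-precision LP defaults.
#'
#' @param active_tol Constraint residual below which a row counts as active.
#' @param feasibility_tol Allowed constraint/state violation.
#' @param optimality_tol Allowed objective slack in optimality checks.
#' @param deriv_tol Allowed negative slack derivative when accepting a
#'   forward basis.
#' @param time_tol Event-time localization tolerance (hours).
#' @param cond_max Maximum acceptable condition estimate for a basis matrix.
#' @param stationary_tol Growth rate (1/h) below which the community counts
#'   as stationary.
#' @param stationary_window Time window (h) used when labelling stationarity.
#' @param max_transitions Hard cap on basis transitions (guards cycling).
#' @param max_step_halvings Cap on protective-step halvings when no forward
#'   basis is admissible.
#' @param refine_policy `"always"`, `"initial"` or `"never"`: when to apply
#'   parsimonious (total-flux-minimizing) refinement after the growth LP.
#' @param n_samples Number of trajectory sample points over the horizon.
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @param weight_eps Edges with `|weight|` below this are dropped.
#' @param include_self_loops Keep `j == l` self-loops in
#'   metabolite-metabolite networks.
#' @param mediated_in_heuristic Include mediated microbe-to-metabolite edges
#'   when aggregating weights for the species-species heuristic.
#' @param enumeration_cap Maximum number of candidate active-row subsets
#'   enumerated when completing a degenerate basis.
#' @return A named list of class `dfba_config`.
#' @export
dfba_config <- function(active_tol = 1e-7,
                        feasibility_tol = 1e-7,
                        optimality_tol = 1e-7,
                        deriv_tol = 1e-9,
                        time_tol = 1e-8,
                        cond_max = 1e12,
                        stationary_tol = 1e-6,
                        stationary_window = 0.1,
                        max_transitions = 500L,
                        max_step_halvings = 40L,
                        refine_policy = c("always", "initial", "never"),
                        n_samples = 201L,
                        rtol = 1e-9,
                        atol = 1e-10,
                        weight_eps = 1e-10,
                        include_self_loops = TRUE,
                        mediated_in_heuristic = TRUE,
                        enumeration_cap = 2000L) {
  refine_policy <- match.arg(refine_policy)
  structure(as.list(environment()), class = "dfba_config")
}
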