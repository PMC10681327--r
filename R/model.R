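#' Construct a metabolic model
#'
#' A metabolic model holds the data of one organism's growth linear program:
#' internal stoichiometry (steady-state balance rows), exchange stoichiometry
#' (rows mapping fluxes to environmental metabolite exchange), a growth
#' objective over reactions, constant flux bounds, and per-metabolite uptake
#' bound functions.
#'
#' Sign convention: exchange rows are oriented so that a positive exchange
#' rate `(exchange_stoich %*% psi)[j] > 0` means the organism removes
#' metabolite `j` from the environment (uptake). The minus sign of the
#' community metabolite dynamics is applied in the dynamics only, never
#' stored in the matrix.
#'
#' @param id Character label for the organism.
#' @param reaction_ids Character vector of reaction names (defines flux order).
#' @param internal_stoich Numeric matrix, internal metabolites x reactions
#'   (may have zero rows). Row names are internal metabolite ids.
#' @param exchange_stoich Numeric matrix, environmental metabolites x
#'   reactions. Row names are environmental metabolite ids (required).
#' @param objective Numeric growth objective over reactions; at least one
#'   nonzero entry.
#' @param lower_flux,upper_flux Constant flux bounds (may be +/-Inf).
#' @param exchange_lower Numeric vector of constant lower exchange bounds,
#'   one per exchange row (default 0: no secretion cap / no forced uptake).
#' @param exchange_upper List of [bound_function()]s, one per exchange row,
#'   giving the metabolite-dependent uptake cap. Defaults to linear kinetics
#'   with slope 1 per hour per gDW for every exchange row.
#' @return Object of class `dfba_model`.
#' @examples
#' m <- monod_linear()$model
#' m$reaction_ids
#' @export
metabolic_model <- function(id, reaction_ids, internal_stoich,
                            exchange_stoich, objective,
                            lower_flux, upper_flux,
                            exchange_lower = NULL,
                            exchange_upper = NULL) {
  n <- length(reaction_ids)
  internal_stoich <- as.matrix(internal_stoich)
  exchange_stoich <- as.matrix(exchange_stoich)
  if (nrow(internal_stoich) == 0L)
    internal_stoich <- matrix(0, 0L, n)
  if (is.null(rownames(exchange_stoich)))
    stop("exchange_stoich must have row names (environment metabolite ids)")
  m <- nrow(exchange_stoich)
  if (is.null(exchange_lower)) exchange_lower <- rep(0, m)
  if (is.null(exchange_upper))
    exchange_upper <- rep(list(bound_function("linear", kappa = 1)), m)
  model <- structure(list(
    id = as.character(id),
    reaction_ids = as.character(reaction_ids),
    internal_stoich = internal_stoich,
    exchange_stoich = exchange_stoich,
    objective = as.numeric(objective),
    lower_flux = as.numeric(lower_flux),
    upper_flux = as.numeric(upper_flux),
    exchange_lower = as.numeric(exchange_lower),
    exchange_upper = exchange_upper),
    class = "dfba_model")
  validate_model(model)
}

#' Validate a metabolic model's structural invariants
#'
#' Checks dimension agreement, bound ordering `lower <= upper`, presence of
#' a nonzero objective, and one bound function per exchange row. Called by
#' [metabolic_model()] and the model readers.
#'
#' @param model A `dfba_model`.
#' @return The model, invisibly-validated (errors on violation).
#' @export
validate_model <- function(model) {
  n <- length(model$reaction_ids)
  if (anyDuplicated(model$reaction_ids))
    stop("duplicate reaction ids in model '", model$id, "'")
  if (ncol(model$internal_stoich) != n || ncol(model$exchange_stoich) != n)
    stop("stoichiometry column count must equal number of reactions")
  if (length(model$objective) != n || length(model$lower_flux) != n ||
      length(model$upper_flux) != n)
    stop("objective and flux bounds must have one entry per reaction")
  if (any(model$lower_flux > model$upper_flux))
    stop("lower flux bound exceeds upper flux bound in model '",
         model$id, "'")
  if (all(model$objective == 0))
    stop("model '", model$id, "' has no objective (all coefficients zero)")
  m <- nrow(model$exchange_stoich)
  if (anyDuplicated(rownames(model$exchange_stoich)))
    stop("each exchange row must map to exactly one environment metabolite")
  if (length(model$exchange_lower) != m || length(model$exchange_upper) != m)
    stop("exchange bounds must have one entry per exchange row")
  ok <- vapply(model$exchange_upper, inherits, logical(1), "dfba_bound")
  if (!all(ok))
    stop("every exchange upper bound must be a bound_function")
  model
}

#' @export
print.dfba_model <- function(x, ...) {
  cat(sprintf("<dfba_model '%s': %d reactions, %d internal, %d exchange>\n",
              x$id, length(x$reaction_ids), nrow(x$internal_stoich),
              nrow(x$exchange_stoich)))
  invisible(x)
}

#' Construct an environment specification
#'
#' The shared metabolite pool a community grows in: an ordered metabolite id
#' list, initial amounts, optional constant inflow rates (e.g. to keep a
#' simulation aerobic by flowing in oxygen), and the relative-change
#' threshold used when reporting significantly produced/consumed
#' metabolites.
#'
#' @param metabolite_ids Character vector of environmental metabolite ids.
#' @param initial_amounts Non-negative amounts at time zero (mmol).
#' @param inflow Constant source rates (mmol/h), default 0.
#' @param significance_threshold Relative-change fraction for
#'   [significant_metabolites()] (default 0.01).
#' @return Object of class `dfba_env`.
#' @export
environment_spec <- function(metabolite_ids, initial_amounts,
                             inflow = 0, significance_threshold = 0.01) {
  m <- length(metabolite_ids)
  initial_amounts <- rep_len(as.numeric(initial_amounts), m)
  inflow <- rep_len(as.numeric(inflow), m)
  if (any(initial_amounts < 0)) stop("initial amounts must be >= 0")
  if (any(!is.finite(inflow))) stop("inflow rates must be finite")
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids")
  structure(list(metabolite_ids = as.character(metabolite_ids),
                 initial_amounts = stats::setNames(initial_amounts,
                                                   metabolite_ids),
                 inflow = stats::setNames(inflow, metabolite_ids),
                 significance_threshold = significance_threshold),
            class = "dfba_env")
}

#' @export
print.dfba_env <- function(x, ...) {
  cat(sprintf("<dfba_env: %d metabolites>\n", length(x$metabolite_ids)))
  invisible(x)
}

#' Snapshot of a community state
#'
#' @param time Time (hours).
#' @param x Named biomass vector (gDW), one entry per organism.
#' @param y Named metabolite vector (mmol), one entry per env metabolite.
#' @return Object of class `dfba_state`.
#' @export
community_state <- function(time, x, y) {
  if (any(x < 0)) stop("biomass must be >= 0")
  structure(list(time = time, x = x, y = y), class = "dfba_state")
}

#' Align model exchange rows to a shared environment
#'
#' Community coupling requires every organism's exchange rows to use one
#' shared metabolite index. This reindexes each model's `exchange_stoich`
#' (and exchange bounds) to `env$metabolite_ids`, inserting all-zero rows for
#' metabolites a model does not touch. With `strict = FALSE` (default),
#' metabolites a model exchanges but the environment lacks are appended to
#' the environment with initial amount 0.
#'
#' The operation is idempotent: aligning already-aligned models is a no-op.
#'
#' @param models List of `dfba_model`.
#' @param env A [environment_spec()].
#' @param strict If `TRUE`, a model metabolite missing from `env` is an error.
#' @return `list(models = aligned models, env = possibly grown env)`.
#' @export
align_environment <- function(models, env, strict = FALSE) {
  if (inherits(models, "dfba_model")) models <- list(models)
  all_mets <- env$metabolite_ids
  for (mod in models) {
    extra <- setdiff(rownames(mod$exchange_stoich), all_mets)
    if (length(extra) && strict)
      stop("model '", mod$id, "' exchanges metabolite(s) not in environment: ",
           paste(extra, collapse = ", "))
    all_mets <- c(all_mets, extra)
  }
  if (length(all_mets) > length(env$metabolite_ids)) {
    grown <- setdiff(all_mets, env$metabolite_ids)
    env <- environment_spec(
      all_mets,
      c(env$initial_amounts, stats::setNames(rep(0, length(grown)), grown)),
      c(env$inflow, stats::setNames(rep(0, length(grown)), grown)),
      env$significance_threshold)
  }
  m <- length(all_mets)
  models <- lapply(models, function(mod) {
    n <- length(mod$reaction_ids)
    ex <- matrix(0, m, n, dimnames = list(all_mets, mod$reaction_ids))
    lower <- stats::setNames(rep(0, m), all_mets)
    upper <- stats::setNames(
      rep(list(bound_function("constant", value = 0)), m), all_mets)
    old <- rownames(mod$exchange_stoich)
    ex[old, ] <- mod$exchange_stoich
    lower[old] <- mod$exchange_lower
    upper[old] <- mod$exchange_upper
    mod$exchange_stoich <- ex
    mod$exchange_lower <- lower
    mod$exchange_upper <- upper
    validate_model(mod)
  })
  list(models = models, env = env)
}
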