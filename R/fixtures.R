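#' Analytic single-organism fixture: linear-uptake Monod-like growth
#'
#' One organism, two reactions `u` (glucose uptake) and `g` (growth), one
#' internal balance `u - 2 g = 0` (yield one half), growth objective on
#' `g`, exchange row `(1, 0)` on glucose, and a linear uptake bound
#' `u <= kappa * y`. Closed-form expectations (at `kappa = 1`,
#' `yield = 1/2`): the segment dynamics are `dx/dt = 0.5 * kappa * x * y`,
#' `dy/dt = -kappa * x * y`, so `x + y/2` is conserved and all biomass ends
#' at `x0 + y0/2`.
#'
#' @param kappa Linear uptake slope (1/h per gDW), default 1.
#' @param y0 Initial glucose amount (mmol), default 10.
#' @param flux_cap Constant cap on both fluxes, default 10.
#' @return `list(model, env)`.
#' @export
monod_linear <- function(kappa = 1, y0 = 10, flux_cap = 10) {
  model <- metabolic_model(
    id = "M",
    reaction_ids = c("u", "g"),
    internal_stoich = matrix(c(1, -2), 1, 2,
                             dimnames = list("carbon", c("u", "g"))),
    exchange_stoich = matrix(c(1, 0), 1, 2,
                             dimnames = list("glc", c("u", "g"))),
    objective = c(0, 1),
    lower_flux = c(0, 0),
    upper_flux = c(flux_cap, flux_cap),
    exchange_lower = 0,
    exchange_upper = list(bound_function("linear", kappa = kappa)))
  env <- environment_spec("glc", y0)
  list(model = model, env = env)
}

#' Analytic fixture: linear uptake with a growth cap
#'
#' [monod_linear()] plus a constant cap `g <= cap`. While glucose is
#' abundant (`kappa * y > 2 * cap`) growth is intrinsic (`C = cap`) and
#' uptake constant at `2 * cap`; when glucose falls to `2 * cap / kappa`
#' the uptake bound becomes binding and the dynamics switch to the
#' Monod-like segment. With `kappa = 1`, `cap = 10`, `x0 = 0.1`,
#' `y0 = 30`: `x(t) = 0.1 exp(10 t)`, `y(t) = 30 - 0.2 (exp(10 t) - 1)`,
#' the transition is at `t* = log(51)/10`, and total biomass tends to
#' `x0 + y0/2 = 15.1`.
#'
#' @param kappa Linear uptake slope, default 1.
#' @param cap Growth flux cap (1/h), default 10.
#' @param y0 Initial glucose (mmol), default 30.
#' @return `list(model, env)`.
#' @export
capped_growth <- function(kappa = 1, cap = 10, y0 = 30) {
  fx <- monod_linear(kappa = kappa, y0 = y0, flux_cap = 1000)
  fx$model$upper_flux <- c(1000, cap)
  fx$model <- validate_model(fx$model)
  fx
}

#' Analytic fixture: two substrates sharing one uptake capacity (diauxie)
#'
#' One organism with substrate uptakes `u1` (glucose, yield 1) and `u2`
#' (acetate, yield 1/2) feeding a common carbon pool, a capacity reaction
#' `s` with `u1 + u2 = s <= U`, and growth `g`. While
#' `kappa * y_glc > U` the organism runs entirely on glucose at constant
#' rate `U`; once glucose becomes rate-limiting the basis rewires, acetate
#' uptake fills the spare capacity `U - kappa * y_glc`, growth becomes
#' glucose-dependent, and a positive mediated glucose-to-acetate edge
#' appears (more glucose spares acetate).
#'
#' @param U Shared uptake capacity (mmol/gDW/h), default 10.
#' @param kappa Linear uptake slope for both substrates, default 1.
#' @param y0 Initial amounts, named or length-2 `(glc, ace)`, default
#'   `c(20, 40)`.
#' @return `list(model, env)`.
#' @export
diauxie <- function(U = 10, kappa = 1, y0 = c(20, 40)) {
  rxn <- c("u1", "u2", "s", "g")
  internal <- rbind(
    carbon   = c(1, 0.5, 0, -1),   # glucose worth 1, acetate 1/2
    capacity = c(1, 1, -1, 0))
  colnames(internal) <- rxn
  exchange <- rbind(glc = c(1, 0, 0, 0), ace = c(0, 1, 0, 0))
  colnames(exchange) <- rxn
  model <- metabolic_model(
    id = "M",
    reaction_ids = rxn,
    internal_stoich = internal,
    exchange_stoich = exchange,
    objective = c(0, 0, 0, 1),
    lower_flux = c(0, 0, 0, 0),
    upper_flux = c(1000, 1000, U, 1000),
    exchange_lower = c(0, 0),
    exchange_upper = list(bound_function("linear", kappa = kappa),
                          bound_function("linear", kappa = kappa)))
  env <- environment_spec(c("glc", "ace"), y0)
  list(model = model, env = env)
}

#' Two-organism cross-feeding fixture
#'
#' Organism `A` grows on glucose and secretes acetate in fixed proportion
#' to growth (`secretion = 0.5 * growth`); organism `B`'s sole carbon
#' source is acetate. The expected species-species heuristic edge
#' `A -> B` is positive (cross-feeding: `A`'s positive effect on the
#' acetate pool times acetate's positive effect on `B`'s growth).
#'
#' @param kappa Linear uptake slope for both organisms, default 1.
#' @param y0_glc Initial glucose, default 10.
#' @param y0_ace Initial acetate, default 0.
#' @return `list(models, env)`.
#' @export
crossfeed_pair <- function(kappa = 1, y0_glc = 10, y0_ace = 0) {
  rxnA <- c("uA", "gA", "sA")
  internalA <- rbind(
    carbon = c(1, -1, -1),     # uptake feeds growth + secretion
    link   = c(0, 0.5, -1))    # secretion tied to growth: sA = 0.5 gA
  colnames(internalA) <- rxnA
  exchangeA <- rbind(glc = c(1, 0, 0), ace = c(0, 0, -1))
  colnames(exchangeA) <- rxnA
  A <- metabolic_model(
    id = "A", reaction_ids = rxnA,
    internal_stoich = internalA, exchange_stoich = exchangeA,
    objective = c(0, 1, 0),
    lower_flux = c(0, 0, 0), upper_flux = c(1000, 1000, 1000),
    exchange_lower = c(0, -1000),   # acetate row: secretion allowed
    exchange_upper = list(bound_function("linear", kappa = kappa),
                          bound_function("linear", kappa = kappa)))
  rxnB <- c("uB", "gB")
  B <- metabolic_model(
    id = "B", reaction_ids = rxnB,
    internal_stoich = matrix(c(1, -2), 1, 2,
                             dimnames = list("carbon", rxnB)),
    exchange_stoich = matrix(c(1, 0), 1, 2,
                             dimnames = list("ace", rxnB)),
    objective = c(0, 1),
    lower_flux = c(0, 0), upper_flux = c(1000, 1000),
    exchange_lower = 0,
    exchange_upper = list(bound_function("linear", kappa = kappa)))
  env <- environment_spec(c("glc", "ace"), c(y0_glc, y0_ace))
  list(models = list(A, B), env = env)
}

#' Two-organism resource-competition fixture
#'
#' Two organisms with the same Monod-like metabolism consume one shared
#' rate-limiting glucose pool. Both species-species heuristic weights are
#' expected negative (each depletes the resource limiting the other's
#' growth), and with identical models the matrix is symmetric.
#'
#' @param kappa1,kappa2 Uptake slopes of the two organisms, default 1.
#' @param y0 Initial glucose, default 10.
#' @return `list(models, env)`.
#' @export
competition_pair <- function(kappa1 = 1, kappa2 = 1, y0 = 10) {
  mk <- function(id, kappa) {
    fx <- monod_linear(kappa = kappa, flux_cap = 1000)
    fx$model$id <- id
    fx$model
  }
  env <- environment_spec("glc", y0)
  list(models = list(mk("P", kappa1), mk("Q", kappa2)), env = env)
}

#' Seeded random small community generator (property testing only)
#'
#' Draws a community of 1-3 organisms over a pool of 2-4 metabolites.
#' Each organism consumes one randomly chosen substrate with Monod-like
#' linear-uptake metabolism (random slope and yield, optional growth cap)
#' and with probability 0.4 secretes a byproduct into another pool slot.
#' All fluxes are capped, so every growth LP is bounded. Used for
#' property-style tests (forward invariance, oracle agreement); never for
#' the analytic fixture expectations.
#'
#' @param seed Integer seed.
#' @return `list(models, env, x0)`.
#' @export
random_community <- function(seed) {
  set.seed(seed)
  m <- sample(2:4, 1)
  mets <- paste0("met", seq_len(m))
  p <- sample(1:3, 1)
  models <- lapply(seq_len(p), function(i) {
    substrate <- sample(mets, 1)
    kappa <- stats::runif(1, 0.5, 2)
    yield <- stats::runif(1, 0.3, 0.7)
    secrete <- stats::runif(1) < 0.4 && m > 1L
    id <- paste0("sp", i)
    if (!secrete) {
      rxn <- c("u", "g")
      model <- metabolic_model(
        id = id, reaction_ids = rxn,
        internal_stoich = matrix(c(1, -1 / yield), 1, 2,
                                 dimnames = list("carbon", rxn)),
        exchange_stoich = matrix(c(1, 0), 1, 2,
                                 dimnames = list(substrate, rxn)),
        objective = c(0, 1),
        lower_flux = c(0, 0),
        upper_flux = c(50, stats::runif(1, 2, 20)),
        exchange_lower = 0,
        exchange_upper = list(bound_function("linear", kappa = kappa)))
    } else {
      product <- sample(setdiff(mets, substrate), 1)
      frac <- stats::runif(1, 0.2, 0.6)
      rxn <- c("u", "g", "s")
      internal <- rbind(carbon = c(1, -1 / yield, -1),
                        link = c(0, frac, -1))
      colnames(internal) <- rxn
      exchange <- matrix(0, 2, 3,
                         dimnames = list(c(substrate, product), rxn))
      exchange[substrate, "u"] <- 1
      exchange[product, "s"] <- -1
      model <- metabolic_model(
        id = id, reaction_ids = rxn,
        internal_stoich = internal, exchange_stoich = exchange,
        objective = c(0, 1, 0),
        lower_flux = c(0, 0, 0),
        upper_flux = c(50, stats::runif(1, 2, 20), 50),
        exchange_lower = c(0, -50),
        exchange_upper = list(bound_function("linear", kappa = kappa),
                              bound_function("linear", kappa = 1)))
    }
    model
  })
  env <- environment_spec(mets, stats::runif(m, 2, 15))
  list(models = models, env = env,
       x0 = stats::runif(p, 0.05, 0.5))
}
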