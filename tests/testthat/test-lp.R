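test_that("constraint rows are stacked in a fixed deterministic order", {
  fx <- monod_linear()
  al <- align_environment(fx$model, fx$env)
  sys <- assemble_lp(al$models[[1]], al$env)
  expect_identical(sys$label,
                   c("balance:carbon", "exchange_lower:glc",
                     "exchange_upper:glc", "flux_lower:u", "flux_upper:u",
                     "flux_lower:g", "flux_upper:g"))
  expect_equal(sum(sys$kind == "eq"), 1L)
  expect_equal(sum(!vapply(sys$fun, is.null, logical(1))), 1L)
  sys2 <- assemble_lp(al$models[[1]], al$env)
  expect_identical(sys$label, sys2$label)
  expect_identical(sys$coeff, sys2$coeff)
})

test_that("a model with no internal metabolites has no equality rows", {
  m <- metabolic_model(
    id = "toy", reaction_ids = "r",
    internal_stoich = matrix(0, 0, 1),
    exchange_stoich = matrix(1, 1, 1, dimnames = list("s", "r")),
    objective = 1, lower_flux = 0, upper_flux = 4)
  al <- align_environment(m, environment_spec("s", 10))
  sys <- assemble_lp(al$models[[1]], al$env)
  expect_equal(sum(sys$kind == "eq"), 0L)
})

test_that("FBA solves the analytic fixtures at their known vertices", {
  fx <- monod_linear()
  al <- align_environment(fx$model, fx$env)
  sys <- assemble_lp(al$models[[1]], al$env)
  sol <- solve_fba(sys, c(glc = 2))
  expect_equal(unname(sol$fluxes), c(2, 1), tolerance = 1e-9)
  expect_equal(sol$objective_value, 1.0, tolerance = 1e-9)
  expect_equal(unname(sol$exchange_rates["glc"]), 2, tolerance = 1e-9)

  expect_equal(solve_fba(sys, c(glc = 0))$objective_value, 0,
               tolerance = 1e-12)

  fc <- capped_growth()
  alc <- align_environment(fc$model, fc$env)
  sysc <- assemble_lp(alc$models[[1]], alc$env)
  solc <- solve_fba(sysc, c(glc = 30))
  expect_equal(solc$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(solc$fluxes["u"]), 20, tolerance = 1e-9)
})

test_that("negative metabolite amounts are clipped with a warning", {
  fx <- monod_linear()
  al <- align_environment(fx$model, fx$env)
  sys <- assemble_lp(al$models[[1]], al$env)
  expect_warning(sol <- solve_fba(sys, c(glc = -0.5)), "clipped")
  expect_equal(sol$objective_value, 0, tolerance = 1e-12)
})

test_that("solver agrees with an independent LP implementation", {
  skip_if_not_installed("pracma")
  set.seed(11)
  for (rep in 1:10) {
    cm <- random_community(rep + 300)
    al <- align_environment(cm$models, cm$env)
    y <- runif(length(al$env$metabolite_ids), 0, 12)
    for (i in seq_along(al$models)) {
      sys <- assemble_lp(al$models[[i]], al$env)
      sol <- solve_fba(sys, y)
      rhs <- dfbanet:::rhs_at(sys, y)
      up <- sys$kind == "upper"; lo <- sys$kind == "lower"
      eq <- sys$kind == "eq"
      A <- rbind(sys$coeff[up, , drop = FALSE],
                 -sys$coeff[lo, , drop = FALSE])
      b <- c(rhs[up], -rhs[lo])
      ref <- pracma::linprog(cc = -sys$objective, A = A, b = b,
                             Aeq = sys$coeff[eq, , drop = FALSE],
                             beq = rhs[eq], maxiter = 200)
      expect_equal(sol$objective_value, -ref$fval, tolerance = 1e-6)
    }
  }
})

test_that("parsimonious refinement zeroes a futile internal cycle", {
  rxn <- c("u", "g", "c1", "c2")
  internal <- rbind(carbon = c(1, -2, 0, 0),
                    loopmet = c(0, 0, 1, -1))
  colnames(internal) <- rxn
  m <- metabolic_model(
    id = "cycle", reaction_ids = rxn,
    internal_stoich = internal,
    exchange_stoich = matrix(c(1, 0, 0, 0), 1, 4,
                             dimnames = list("glc", rxn)),
    objective = c(0, 1, 0, 0),
    lower_flux = c(0, 0, 0, 0), upper_flux = c(10, 10, 5, 5))
  al <- align_environment(m, environment_spec("glc", 10))
  sys <- assemble_lp(al$models[[1]], al$env)
  sol <- solve_fba(sys, c(glc = 2))
  # force the cycle on: same growth, larger total flux
  forced <- sol
  forced$fluxes[c("c1", "c2")] <- 5
  refined <- parsimonious_refine(sys, c(glc = 2), forced)
  expect_equal(unname(refined$fluxes[c("c1", "c2")]), c(0, 0),
               tolerance = 1e-9)
  expect_equal(refined$objective_value, sol$objective_value,
               tolerance = 1e-9)
})

test_that("refinement leaves a unique optimum unchanged and zeroes flux at
           zero growth", {
  fx <- monod_linear()
  al <- align_environment(fx$model, fx$env)
  sys <- assemble_lp(al$models[[1]], al$env)
  sol <- solve_fba(sys, c(glc = 2))
  refined <- parsimonious_refine(sys, c(glc = 2), sol)
  expect_equal(unname(refined$fluxes), unname(sol$fluxes),
               tolerance = 1e-9)
  s0 <- parsimonious_refine(sys, c(glc = 0), solve_fba(sys, c(glc = 0)))
  expect_equal(unname(s0$fluxes), c(0, 0), tolerance = 1e-12)
})

test_that("refinement never increases total flux on random systems", {
  set.seed(5)
  for (rep in 1:8) {
    cm <- random_community(rep + 40)
    al <- align_environment(cm$models, cm$env)
    y <- runif(length(al$env$metabolite_ids), 0, 10)
    sys <- assemble_lp(al$models[[1]], al$env)
    sol <- solve_fba(sys, y)
    refined <- parsimonious_refine(sys, y, sol)
    expect_lte(sum(abs(refined$fluxes)), sum(abs(sol$fluxes)) + 1e-8)
    expect_equal(refined$objective_value, sol$objective_value,
                 tolerance = 1e-7)
  }
})

test_that("infeasible and unbounded problems are reported as such", {
  # forced uptake of 5 against an uptake capacity of 0
  m <- metabolic_model(
    id = "inf", reaction_ids = c("u", "g"),
    internal_stoich = matrix(c(1, -2), 1, 2,
                             dimnames = list("c", c("u", "g"))),
    exchange_stoich = matrix(c(1, 0), 1, 2,
                             dimnames = list("glc", c("u", "g"))),
    objective = c(0, 1), lower_flux = c(5, 0), upper_flux = c(10, 10))
  al <- align_environment(m, environment_spec("glc", 0))
  sys <- assemble_lp(al$models[[1]], al$env)
  expect_equal(solve_fba(sys, c(glc = 0))$status, "infeasible")

  # growth unconstrained from above
  m2 <- metabolic_model(
    id = "unb", reaction_ids = "g",
    internal_stoich = matrix(0, 0, 1),
    exchange_stoich = matrix(0, 1, 1, dimnames = list("glc", "g")),
    objective = 1, lower_flux = 0, upper_flux = Inf,
    exchange_upper = list(bound_function("constant", value = 1)))
  al2 <- align_environment(m2, environment_spec("glc", 1))
  sys2 <- assemble_lp(al2$models[[1]], al2$env)
  expect_equal(solve_fba(sys2, c(glc = 1))$status, "unbounded")
})
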