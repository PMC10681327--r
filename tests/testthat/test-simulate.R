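test_that("growth-cap fixture transitions at the analytic event time", {
  fc <- capped_growth()
  res <- simulate_quiet(fc$model, fc$env, x0 = 0.1, t_final = 5)
  expect_equal(res$status, "reached_t_final")
  expect_length(res$segments, 2L)
  expect_equal(nrow(res$transitions), 1L)
  expect_equal(res$transitions$time[1], log(51) / 10, tolerance = 1e-6)
  expect_match(res$transitions$constraint[1], "exchange_upper:glc")
  expect_equal(res$transitions$action[1], "new_basis")
  # conserved x + y/2 = 15.1 and glucose depletion drive x -> 15.1
  xT <- res$trajectory$x_M[nrow(res$trajectory)]
  expect_equal(xT, 15.1, tolerance = 1e-3)
})

test_that("the conserved quantity of the linear-uptake fixture drifts
           below 1e-8 and biomass reaches its closed-form limit", {
  fx <- monod_linear()
  res <- simulate_quiet(fx$model, fx$env, x0 = 0.1, t_final = 5)
  expect_length(res$segments, 1L)
  tr <- res$trajectory
  drift <- max(abs(tr$x_M + tr$y_glc / 2 - (0.1 + 10 / 2)))
  expect_lt(drift, 1e-8)
  expect_equal(tr$x_M[nrow(tr)], 5.1, tolerance = 1e-3)
})

test_that("diauxie rewires the basis when glucose becomes rate-limiting", {
  fd <- diauxie()
  res <- simulate_quiet(fd$model, fd$env, x0 = 0.1, t_final = 5)
  expect_gte(length(res$segments), 2L)
  sm1 <- species_metabolite_network(res$segments[[1]])
  sm2 <- species_metabolite_network(res$segments[[2]])
  growth_sources <- function(net)
    net$edges$source[net$edges$term_kind == "growth"]
  expect_false("glc" %in% growth_sources(sm1))
  expect_true("glc" %in% growth_sources(sm2))
})

test_that("a zero-biomass community leaves the environment constant", {
  fx <- monod_linear()
  res <- simulate_quiet(fx$model, fx$env, x0 = 0, t_final = 2)
  expect_length(res$segments, 1L)
  expect_equal(nrow(res$transitions), 0L)
  expect_true(all(abs(res$trajectory$y_glc - 10) < 1e-12))
  expect_true(all(res$trajectory$x_M == 0))
})

test_that("integration over an empty span returns an empty trajectory", {
  fx <- monod_linear()
  al <- align_environment(fx$model, fx$env)
  sys <- assemble_lp(al$models[[1]], al$env)
  sol <- parsimonious_refine(sys, 10, solve_fba(sys, 10))
  bas <- extract_basis(sys, 10, sol)
  st <- community_state(1, c(M = 0.1), c(glc = 10))
  seg <- build_segment(al$models, list(bas), al$env, st, 1,
                       systems = list(sys))
  out <- integrate_segment(seg, st, t_max = 1)
  expect_equal(nrow(out$trajectory), 0L)
  expect_null(out$event)
})

test_that("trajectories stay in the non-negative orthant", {
  for (fx in list(monod_linear(), capped_growth(), diauxie())) {
    res <- simulate_quiet(fx$model, fx$env, x0 = 0.1, t_final = 5)
    expect_gte(min_state(res$trajectory), -1e-7)
  }
  for (fx in list(crossfeed_pair(), competition_pair())) {
    res <- simulate_quiet(fx$models, fx$env, x0 = c(0.1, 0.1),
                          t_final = 5)
    expect_gte(min_state(res$trajectory), -1e-7)
  }
  for (seed in 1:20) {
    cm <- random_community(seed)
    res <- simulate_quiet(cm$models, cm$env, x0 = cm$x0, t_final = 3)
    expect_gte(min_state(res$trajectory), -1e-7)
    expect_true(res$status %in% c("reached_t_final", "stationary"))
  }
})

test_that("interior segment states solve the LP as well as a fresh FBA", {
  fd <- diauxie()
  res <- simulate_quiet(fd$model, fd$env, x0 = 0.1, t_final = 5)
  tr <- res$trajectory
  for (seg in res$segments) {
    ts <- seq(seg$t_start, seg$t_end, length.out = 7)[2:6]
    for (t in ts) {
      row <- tr[which.min(abs(tr$time - t)), ]
      y <- as.numeric(row[paste0("y_", seg$env$metabolite_ids)])
      if (any(y < 0)) next
      psi <- basis_solve(seg$bases[[1]], y)
      fresh <- solve_fba(seg$systems[[1]], y)
      expect_equal(sum(seg$systems[[1]]$objective * psi),
                   fresh$objective_value, tolerance = 1e-6)
    }
  }
})

test_that("basis tracking matches the direct repeated-LP oracle", {
  cfg <- dfba_config(n_samples = 81L)
  cases <- list(
    list(monod_linear(), 0.1),
    list(capped_growth(), 0.1),
    list(diauxie(), 0.1),
    list(crossfeed_pair(), c(0.1, 0.1)),
    list(competition_pair(), c(0.1, 0.1)))
  for (case in cases) {
    fx <- case[[1]]
    models <- if (!is.null(fx[["model"]])) list(fx[["model"]]) else fx$models
    res <- simulate_quiet(models, fx$env, case[[2]], t_final = 3, cfg)
    orc <- suppressWarnings(
      direct_dfba_oracle(models, fx$env, case[[2]], t_final = 3, cfg))
    expect_lt(trajectory_rel_error(res$trajectory, orc$trajectory), 1e-3)
  }
})

test_that("the oracle sees the same transition region as basis tracking", {
  fc <- capped_growth()
  cfg <- dfba_config(n_samples = 501L)
  orc <- suppressWarnings(
    direct_dfba_oracle(fc$model, fc$env, 0.1, t_final = 1, cfg))
  tr <- orc$trajectory
  # growth rate drops from 10 when the uptake bound binds (y = 20)
  below <- tr$time[tr$y_glc < 20]
  expect_equal(min(below), log(51) / 10, tolerance = 5e-3)
})

test_that("identical configurations reproduce bit-for-bit", {
  fd <- diauxie()
  r1 <- simulate_quiet(fd$model, fd$env, x0 = 0.1, t_final = 5)
  r2 <- simulate_quiet(fd$model, fd$env, x0 = 0.1, t_final = 5)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$transitions, r2$transitions)
  expect_identical(lapply(r1$segments, function(s)
    lapply(s$bases, `[[`, "rows")),
    lapply(r2$segments, function(s) lapply(s$bases, `[[`, "rows")))
})

test_that("a zero-biomass community with no inflow also satisfies the
           oracle equivalence trivially", {
  fx <- monod_linear()
  res <- simulate_quiet(fx$model, fx$env, 0, t_final = 2)
  orc <- direct_dfba_oracle(fx$model, fx$env, 0, t_final = 2)
  expect_lt(trajectory_rel_error(res$trajectory, orc$trajectory), 1e-12)
})
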