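fixture_segment <- function(fx, x0 = 0.1, t_final = 5) {
  models <- if (!is.null(fx[["model"]])) list(fx[["model"]]) else fx$models
  x0 <- rep_len(x0, length(models))
  simulate_quiet(models, fx$env, x0, t_final)
}

test_that("the term-to-edge mapping reproduces the fixture networks", {
  res <- fixture_segment(monod_linear())
  sm <- species_metabolite_network(res$segments[[1]])
  expect_equal(nrow(sm$edges), 2L)
  gr <- sm$edges[sm$edges$term_kind == "growth", ]
  expect_equal(gr$source, "glc"); expect_equal(gr$target, "M")
  expect_equal(gr$weight, 0.5, tolerance = 1e-9)
  cons <- sm$edges[sm$edges$term_kind == "self_mediated", ]
  expect_equal(cons$source, "M"); expect_equal(cons$target, "glc")
  expect_equal(cons$weight, -1.0, tolerance = 1e-9)
  expect_equal(cons$raw_coeff, 1.0, tolerance = 1e-9)

  resc <- fixture_segment(capped_growth())
  sm1 <- species_metabolite_network(resc$segments[[1]])
  expect_false("growth" %in% sm1$edges$term_kind)  # intrinsic growth only
  ce <- sm1$edges[sm1$edges$term_kind == "constant_exchange", ]
  expect_equal(ce$weight, -20, tolerance = 1e-9)
})

test_that("all-zero coefficients give an empty edge list", {
  env <- environment_spec("glc", 5)
  seg <- build_segment(list(), list(), env,
                       community_state(0, numeric(), env$initial_amounts),
                       0, systems = list())
  expect_equal(nrow(species_metabolite_network(seg)$edges), 0L)
  expect_equal(nrow(metabolite_metabolite_network(seg)$edges), 0L)
})

test_that("metabolite-metabolite edges carry mediator and microbe labels", {
  res <- fixture_segment(monod_linear())
  mm <- metabolite_metabolite_network(res$segments[[1]])
  expect_equal(nrow(mm$edges), 1L)
  expect_equal(mm$edges$source, "glc")
  expect_equal(mm$edges$target, "glc")
  expect_equal(mm$edges$weight, -1, tolerance = 1e-9)
  expect_equal(mm$edges$microbe, "M")
  mm2 <- metabolite_metabolite_network(res$segments[[1]],
                                       include_self_loops = FALSE)
  expect_equal(nrow(mm2$edges), 0L)
})

test_that("spared acetate appears as a positive glucose-to-acetate edge", {
  res <- fixture_segment(diauxie())
  seg2 <- res$segments[[2]]
  mm <- metabolite_metabolite_network(seg2)
  e <- mm$edges[mm$edges$source == "glc" & mm$edges$target == "ace", ]
  expect_equal(nrow(e), 1L)
  expect_gt(e$weight, 0)
  expect_equal(e$microbe, "M")
  # sign oracle: d(dy_ace/dt)/d c2_glc under the segment coefficients
  cf <- seg2$coeffs$M
  expect_lt(cf$b["glc", "ace"], 0)   # dy_ace gains from glucose bound
})

test_that("species-species weights follow the length-two path formula", {
  edges <- rbind(sm_edge("A", "m1", -1, "constant_exchange"),
                 sm_edge("m1", "B", 0.5, "growth"))
  net <- make_sm_network(edges, c("A", "B"), "m1")
  ss <- species_species_network(net)
  expect_equal(nrow(ss$edges), 1L)
  expect_equal(ss$edges$weight, -0.5)
  expect_equal(ss$edges$mediator, "m1")

  # exact cancellation drops the edge
  edges2 <- rbind(sm_edge("A", "m1", -1, "constant_exchange"),
                  sm_edge("m1", "B", 0.5, "growth"),
                  sm_edge("A", "m2", 2, "constant_exchange"),
                  sm_edge("m2", "B", 0.25, "growth"))
  net2 <- make_sm_network(edges2, c("A", "B"), c("m1", "m2"))
  ss2 <- species_species_network(net2)
  expect_equal(nrow(ss2$edges[ss2$edges$source == "A" &
                                ss2$edges$target == "B", ]), 0L)
})

test_that("species-species equals exhaustive path enumeration on random
           networks", {
  for (seed in 1:100) {
    net <- random_sm_network(seed)
    ss <- species_species_network(net)
    ref <- brute_force_species_species(net)
    got <- matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
    for (r in seq_len(nrow(ss$edges)))
      got[ss$edges$source[r], ss$edges$target[r]] <- ss$edges$weight[r]
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("fixture sign semantics: competition negative, cross-feeding
           positive, symmetric for identical competitors", {
  rescf <- fixture_segment(crossfeed_pair())
  ss <- species_species_network(
    species_metabolite_network(rescf$segments[[1]]))
  ab <- ss$edges[ss$edges$source == "A" & ss$edges$target == "B", ]
  expect_equal(nrow(ab), 1L)
  expect_gt(ab$weight, 0)

  rescp <- fixture_segment(competition_pair())
  sscp <- species_species_network(
    species_metabolite_network(rescp$segments[[1]]))
  e <- sscp$edges
  pq <- e$weight[e$source == "P" & e$target == "Q"]
  qp <- e$weight[e$source == "Q" & e$target == "P"]
  expect_lt(pq, 0); expect_lt(qp, 0)
  expect_equal(pq, qp, tolerance = 1e-9)
})

test_that("duration-weighted mean and variance follow the worked algebra", {
  mk <- function(w, t0, t1) {
    edges <- sm_edge("A", "m1", w, "constant_exchange")
    net <- make_sm_network(edges, "A", "m1")
    net$interval <- c(t0, t1); net$duration <- t1 - t0
    net
  }
  series1 <- list(networks = list(mk(3, 0, 2)), durations = 2)
  s1 <- summarize_series(series1)
  expect_equal(s1$mean$edges$weight, 3)
  expect_equal(s1$variance$edges$weight, 0)

  series2 <- list(networks = list(mk(1, 0, 1), mk(3, 1, 2)),
                  durations = c(1, 1))
  s2 <- summarize_series(series2)
  expect_equal(s2$mean$edges$weight, 2)
  expect_equal(s2$variance$edges$weight, 1)

  series3 <- list(networks = list(mk(4, 0, 1), mk(0, 1, 4)),
                  durations = c(1, 3))
  s3 <- summarize_series(series3)
  expect_equal(s3$mean$edges$weight, 1)      # (1*4 + 3*0) / 4
  expect_equal(s3$variance$edges$weight, 3)  # (1*9 + 3*1) / 4
  expect_equal(s3$variance$edges$sign_mean, 1)
  expect_error(summarize_series(list(networks = list(), durations = numeric())),
               "empty")
})

test_that("an edge absent from one interval counts as weight zero", {
  mkA <- function(w, t0, t1, target) {
    edges <- sm_edge("A", target, w, "constant_exchange")
    net <- make_sm_network(edges, "A", c("m1", "m2"))
    net$interval <- c(t0, t1); net$duration <- t1 - t0
    net
  }
  series <- list(networks = list(mkA(2, 0, 1, "m1"), mkA(6, 1, 2, "m2")),
                 durations = c(1, 1))
  s <- summarize_series(series)
  w <- s$mean$edges$weight[s$mean$edges$target == "m1"]
  expect_equal(w, 1)                         # (2 + 0) / 2
  v <- s$variance$edges$weight[s$variance$edges$target == "m2"]
  expect_equal(v, 9)                         # mean 3, (9 + 9) / 2
})

test_that("network differences and exclusions are reported edgewise", {
  e1 <- sm_edge("A", "m1", -2, "constant_exchange")
  e2 <- sm_edge("A", "m1", -0.5, "constant_exchange")
  n1 <- make_sm_network(e1, "A", "m1")
  n2 <- make_sm_network(e2, "A", "m1")
  d <- network_difference(n1, n2)
  expect_equal(d$difference$signed_diff, 1.5)
  expect_equal(d$difference$magnitude, 1.5)

  dd <- network_difference(n1, n1)
  expect_true(all(dd$difference$signed_diff == 0))

  n3 <- make_sm_network(sm_edge("A", "m1", 1, "growth"), "A", "m1")
  d2 <- network_difference(n1, n3)
  expect_equal(nrow(d2$difference), 0L)
  expect_equal(nrow(d2$only_a), 1L)
  expect_equal(nrow(d2$only_b), 1L)

  n4 <- n3; n4$type <- "species_species"
  expect_error(network_difference(n1, n4), "types")
})

test_that("connection shifts average |w_A| - |w_B| over shared edges", {
  eA <- rbind(sm_edge("A", "m1", 1, "constant_exchange"),
              sm_edge("A", "m2", -2, "constant_exchange"))
  eB <- rbind(sm_edge("A", "m1", 0.5, "constant_exchange"),
              sm_edge("A", "m2", -1, "constant_exchange"))
  nA <- make_sm_network(eA, "A", c("m1", "m2"))
  nB <- make_sm_network(eB, "A", c("m1", "m2"))
  expect_equal(connection_shift("A", nA, nB), 0.75)
  expect_equal(connection_shift("A", nA, nA), 0)
  expect_error(connection_shift("Z", nA, nB), "not present")
  nC <- make_sm_network(sm_edge("A", "m1", 1, "growth"), "A", "m1")
  expect_error(connection_shift("A", nA, nC), "undefined")
})

test_that("the single-point FBA baseline network marks every consumed
           metabolite", {
  fx <- monod_linear()
  net <- fba_direct_network(fx$model, fx$env, y = c(glc = 2))
  flux <- net$edges[net$edges$term_kind == "flux", ]
  expect_equal(flux$source, "M"); expect_equal(flux$target, "glc")
  expect_equal(flux$weight, -2, tolerance = 1e-9)
  marker <- net$edges[net$edges$term_kind == "consumption_marker", ]
  expect_equal(marker$source, "glc"); expect_equal(marker$target, "M")

  # a metabolite no model touches stays an isolated node
  env2 <- environment_spec(c("glc", "inert"), c(2, 7))
  net2 <- fba_direct_network(fx$model, env2)
  expect_true("inert" %in% net2$nodes$id)
  expect_false("inert" %in% c(net2$edges$source, net2$edges$target))
})

test_that("the FBA baseline has at least as many metabolite-to-microbe
           edges as basis-derived growth edges", {
  for (fx in list(monod_linear(), capped_growth(), diauxie(),
                  crossfeed_pair(), competition_pair())) {
    models <- if (!is.null(fx[["model"]])) list(fx[["model"]]) else fx$models
    res <- simulate_quiet(models, fx$env, rep_len(0.1, length(models)), 5)
    tr <- res$trajectory
    for (seg in res$segments) {
      # evaluate the single-point FBA network just inside the interval
      # (at the boundary itself secreted pools can still be empty)
      row <- tr[which(tr$time > seg$t_start)[1], ]
      y <- pmax(as.numeric(row[paste0("y_", seg$env$metabolite_ids)]), 0)
      names(y) <- seg$env$metabolite_ids
      direct <- fba_direct_network(models, fx$env, y = y)
      n_marker <- sum(direct$edges$term_kind == "consumption_marker")
      sm <- species_metabolite_network(seg)
      n_growth <- sum(sm$edges$term_kind == "growth")
      expect_gte(n_marker, n_growth)
    }
  }
  # strict excess on the first diauxie epoch: glucose is consumed but
  # growth is capacity-limited, so no growth edge exists
  fd <- diauxie()
  resd <- simulate_quiet(fd$model, fd$env, 0.1, 5)
  smd <- species_metabolite_network(resd$segments[[1]])
  directd <- fba_direct_network(fd$model, fd$env)
  expect_gt(sum(directd$edges$term_kind == "consumption_marker"),
            sum(smd$edges$term_kind == "growth"))
})

test_that("candidate mediators are ranked by path-product strength", {
  res <- fixture_segment(crossfeed_pair())
  sm <- species_metabolite_network(res$segments[[1]])
  pos <- candidate_mediators(sm, "A", "B", +1)
  expect_equal(pos$metabolite, "ace")
  neg <- candidate_mediators(sm, "A", "B", -1)
  expect_equal(nrow(neg), 0L)
  expect_error(candidate_mediators(sm, "nope", "B", 1), "unknown")

  edges <- rbind(sm_edge("A", "m1", 0.6, "constant_exchange"),
                 sm_edge("m1", "B", 0.5, "growth"),
                 sm_edge("A", "m2", 1.6, "constant_exchange"),
                 sm_edge("m2", "B", 0.5, "growth"))
  net <- make_sm_network(edges, c("A", "B"), c("m1", "m2"))
  ranked <- candidate_mediators(net, "A", "B", +1)
  expect_equal(ranked$metabolite, c("m2", "m1"))
})

test_that("significant metabolites partition into produced and consumed", {
  traj <- data.frame(time = c(0, 1),
                     x_M = c(0.1, 1),
                     y_stable = c(5, 5),
                     y_eaten = c(10, 9.85),
                     y_made = c(0, 0.5))
  sig <- significant_metabolites(traj, threshold = 0.01)
  expect_setequal(sig$metabolite, c("eaten", "made"))
  expect_equal(sig$direction[sig$metabolite == "eaten"], "consumed")
  expect_equal(sig$direction[sig$metabolite == "made"], "produced")
})

test_that("network edges reconstruct the segment dynamics exactly", {
  set.seed(314)
  for (fx in list(monod_linear(), capped_growth(), diauxie(),
                  crossfeed_pair(), competition_pair())) {
    models <- if (!is.null(fx[["model"]])) list(fx[["model"]]) else fx$models
    res <- simulate_quiet(models, fx$env, rep_len(0.1, length(models)), 4)
    for (seg in res$segments) {
      sm <- species_metabolite_network(seg, weight_eps = 0)
      p <- length(seg$model_ids)
      m <- length(seg$env$metabolite_ids)
      for (draw in 1:3) {
        x <- runif(p, 0.05, 1)
        y <- pmax(unname(seg$env$initial_amounts) * runif(m, 0.3, 1),
                  1e-3)
        want <- dfbanet:::segment_rhs(seg, x, y)
        got <- rhs_from_networks(seg, sm, x, y)
        expect_equal(unname(got$dx), want$dx, tolerance = 1e-9)
        expect_equal(unname(got$dy), want$dy, tolerance = 1e-9)
      }
    }
  }
})

test_that("network builders are pure: same segment, identical edges", {
  res <- fixture_segment(diauxie())
  seg <- res$segments[[2]]
  expect_identical(species_metabolite_network(seg)$edges,
                   species_metabolite_network(seg)$edges)
  expect_identical(metabolite_metabolite_network(seg)$edges,
                   metabolite_metabolite_network(seg)$edges)
})

test_that("microbes that net-consume a metabolite have negative outgoing
           weight sums toward it", {
  for (fx in list(monod_linear(), diauxie(), competition_pair())) {
    models <- if (!is.null(fx[["model"]])) list(fx[["model"]]) else fx$models
    res <- simulate_quiet(models, fx$env, rep_len(0.1, length(models)), 4)
    tr <- res$trajectory
    sig <- significant_metabolites(tr)
    consumed <- sig$metabolite[sig$direction == "consumed"]
    for (seg in res$segments) {
      sm <- species_metabolite_network(seg)
      for (met in consumed) {
        for (mic in seg$model_ids) {
          w <- sum(sm$edges$weight[sm$edges$source == mic &
                                     sm$edges$target == met])
          if (w != 0) expect_lt(w, 0)
        }
      }
    }
  }
})
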