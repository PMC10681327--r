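# Shared test helpers: manual network construction, brute-force path
# oracle, and RHS reconstruction from network edges.

make_sm_network <- function(edges, microbes, mets) {
  nodes <- data.frame(id = c(microbes, mets),
                      type = c(rep("microbe", length(microbes)),
                               rep("metabolite", length(mets))),
                      stringsAsFactors = FALSE)
  dfbanet:::new_network("species_metabolite", nodes, edges,
                        interval = c(0, 1))
}

sm_edge <- function(source, target, weight, term_kind,
                    mediator = NA_character_) {
  dfbanet:::edge_frame(source, target, weight, weight, term_kind,
                       mediator, NA_character_, 1L)
}

# random species-metabolite network for path-heuristic property tests
random_sm_network <- function(seed, n_microbes = 3, n_mets = 4) {
  set.seed(seed)
  microbes <- paste0("sp", seq_len(n_microbes))
  mets <- paste0("m", seq_len(n_mets))
  rows <- list()
  for (i in microbes) for (l in mets) {
    for (tk in c("constant_exchange", "self_mediated", "cross_mediated"))
      if (runif(1) < 0.35)
        rows[[length(rows) + 1L]] <- sm_edge(
          i, l, round(runif(1, -2, 2), 3), tk,
          if (tk == "cross_mediated") sample(setdiff(mets, l), 1)
          else NA_character_)
    if (runif(1) < 0.5)
      rows[[length(rows) + 1L]] <- sm_edge(
        l, i, round(runif(1, -1, 1), 3), "growth")
  }
  edges <- if (length(rows)) do.call(rbind, rows)
           else dfbanet:::edge_frame()
  make_sm_network(edges, microbes, mets)
}

# independent oracle: species-species weights by exhaustive enumeration of
# all pairs of edge rows forming a length-two path i -> l -> j
brute_force_species_species <- function(net) {
  e <- net$edges
  microbes <- net$nodes$id[net$nodes$type == "microbe"]
  mets <- net$nodes$id[net$nodes$type == "metabolite"]
  out <- matrix(0, length(microbes), length(microbes),
                dimnames = list(microbes, microbes))
  for (r1 in seq_len(nrow(e))) {
    if (!(e$source[r1] %in% microbes)) next
    for (r2 in seq_len(nrow(e))) {
      if (e$term_kind[r2] != "growth") next
      if (e$source[r2] != e$target[r1]) next
      out[e$source[r1], e$target[r2]] <-
        out[e$source[r1], e$target[r2]] + e$weight[r1] * e$weight[r2]
    }
  }
  out
}

# reconstruct the segment right-hand side from network edges (+ intrinsic
# growth and inflow), for the network/ODE consistency checks
rhs_from_networks <- function(segment, sm_net, x, y) {
  env <- segment$env
  mets <- env$metabolite_ids
  e <- sm_net$edges
  dx <- numeric(length(x))
  names(dx) <- segment$model_ids
  dy <- unname(env$inflow)
  names(dy) <- mets
  for (i in seq_along(segment$model_ids)) {
    id <- segment$model_ids[i]
    cf <- segment$coeffs[[i]]
    gi <- cf$C
    gr <- e[e$term_kind == "growth" & e$target == id, , drop = FALSE]
    for (r in seq_len(nrow(gr))) {
      j <- match(gr$source[r], mets)
      gi <- gi + gr$weight[r] * dfbanet::bf_eval(cf$funs[[j]], y[j])
    }
    dx[i] <- x[i] * gi
    ex <- e[e$source == id & e$term_kind != "growth", , drop = FALSE]
    for (r in seq_len(nrow(ex))) {
      l <- match(ex$target[r], mets)
      driver <- switch(ex$term_kind[r],
        constant_exchange = 1,
        self_mediated = dfbanet::bf_eval(cf$funs[[l]], y[l]),
        cross_mediated = {
          j <- match(ex$mediator[r], mets)
          dfbanet::bf_eval(cf$funs[[j]], y[j])
        })
      dy[l] <- dy[l] + x[i] * ex$weight[r] * driver
    }
  }
  list(dx = dx, dy = dy)
}

min_state <- function(trajectory) {
  cols <- setdiff(names(trajectory), "time")
  min(vapply(cols, function(cc) min(trajectory[[cc]]), numeric(1)))
}

simulate_quiet <- function(...) suppressWarnings(simulate_community(...))
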