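#' Interaction networks from DFBA segments
#'
#' Networks are directed multigraphs stored as an edge table plus a typed
#' node table. Edge weights are *effect-signed*: each edge's weight is the
#' signed contribution to `d(target)/dt` per unit driver, so consumption
#' edges are negative and production edges positive. The raw segment
#' coefficient (`a`, `D` or `b` exactly as it appears in the segment ODE,
#' where the metabolite equation carries an overall minus) is kept in
#' `raw_coeff`; for microbe-to-metabolite edges `weight = -raw_coeff`.
#'
#' @name dfba_network
NULL

new_network <- function(type, nodes, edges, interval = c(NA_real_, NA_real_),
                        segment_index = NA_integer_) {
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  if (nrow(edges) > 0L) {
    missing_nodes <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing_nodes) > 0L)
      stop("edge endpoint(s) not in node set: ",
           paste(missing_nodes, collapse = ", "))
  }
  structure(list(type = type, nodes = nodes, edges = edges,
                 interval = interval,
                 duration = interval[2] - interval[1],
                 segment_index = segment_index),
            class = "dfba_network")
}

edge_frame <- function(source = character(), target = character(),
                       weight = numeric(), raw_coeff = numeric(),
                       term_kind = character(), mediator = character(),
                       microbe = character(),
                       segment_index = integer()) {
  data.frame(source = source, target = target, weight = weight,
             raw_coeff = raw_coeff, term_kind = term_kind,
             mediator = mediator, microbe = microbe,
             segment_index = segment_index, stringsAsFactors = FALSE)
}

#' @export
print.dfba_network <- function(x, ...) {
  cat(sprintf("<dfba_network %s: %d nodes, %d edges, interval [%s, %s]>\n",
              x$type, nrow(x$nodes), nrow(x$edges),
              format(x$interval[1]), format(x$interval[2])))
  invisible(x)
}

segment_nodes <- function(segment) {
  data.frame(id = c(segment$model_ids, segment$env$metabolite_ids),
             type = c(rep("microbe", length(segment$model_ids)),
                      rep("metabolite", length(segment$env$metabolite_ids))),
             stringsAsFactors = FALSE)
}

#' Species-metabolite network of one segment
#'
#' Maps the segment ODE term by term to edges:
#' * growth terms `a_ij`: edge metabolite `j` -> microbe `i`, weight `a_ij`
#'   (a metabolite has an edge into a microbe only when it is
#'   rate-limiting, i.e. its uptake bound row is in the basis);
#' * constant exchange `D_il`: edge microbe `i` -> metabolite `l`, weight
#'   `-D_il`;
#' * self-mediated `b_ill`: edge `i -> l`, weight `-b_ill`;
#' * cross-mediated `b_ijl` (`j != l`): edge `i -> l`, weight `-b_ijl`,
#'   annotated with mediator `j`.
#'
#' Edges with `|weight| < weight_eps` are dropped.
#'
#' @param segment A `dfba_segment`.
#' @param weight_eps Drop threshold for near-zero weights.
#' @return A `dfba_network` of type `"species_metabolite"`.
#' @export
species_metabolite_network <- function(segment, weight_eps = 1e-10) {
  stopifnot(inherits(segment, "dfba_segment"))
  mets <- segment$env$metabolite_ids
  seg_i <- segment$segment_index
  if (is.null(seg_i)) seg_i <- NA_integer_
  rows <- list()
  for (i in seq_along(segment$coeffs)) {
    id <- segment$model_ids[i]
    cf <- segment$coeffs[[i]]
    for (j in which(abs(cf$a) >= weight_eps))
      rows[[length(rows) + 1L]] <- edge_frame(
        mets[j], id, cf$a[j], cf$a[j], "growth", NA_character_, id, seg_i)
    for (l in which(abs(cf$D) >= weight_eps))
      rows[[length(rows) + 1L]] <- edge_frame(
        id, mets[l], -cf$D[l], cf$D[l], "constant_exchange",
        NA_character_, id, seg_i)
    bnz <- which(abs(cf$b) >= weight_eps, arr.ind = TRUE)
    if (nrow(bnz) > 0L)
      for (r in seq_len(nrow(bnz))) {
        j <- bnz[r, 1L]; l <- bnz[r, 2L]
        rows[[length(rows) + 1L]] <- edge_frame(
          id, mets[l], -cf$b[j, l], cf$b[j, l],
          if (j == l) "self_mediated" else "cross_mediated",
          if (j == l) NA_character_ else mets[j], id, seg_i)
      }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else edge_frame()
  new_network("species_metabolite", segment_nodes(segment), edges,
              c(segment$t_start, segment$t_end), seg_i)
}

#' Metabolite-metabolite network of one segment
#'
#' Reinterprets each mediated term `b_ijl x_i c2_ij(y_j)` as metabolite `j`
#' acting on metabolite `l` through the metabolism of microbe `i`: edge
#' `j -> l`, weight `-b_ijl` (per unit biomass of the mediating microbe,
#' which labels the edge). Parallel edges from different microbes are kept
#' separate.
#'
#' @param segment A `dfba_segment`.
#' @param include_self_loops Keep `j == l` edges (default `TRUE`).
#' @param weight_eps Drop threshold.
#' @return A `dfba_network` of type `"metabolite_metabolite"`.
#' @export
metabolite_metabolite_network <- function(segment, include_self_loops = TRUE,
                                          weight_eps = 1e-10) {
  stopifnot(inherits(segment, "dfba_segment"))
  mets <- segment$env$metabolite_ids
  seg_i <- segment$segment_index
  if (is.null(seg_i)) seg_i <- NA_integer_
  rows <- list()
  for (i in seq_along(segment$coeffs)) {
    id <- segment$model_ids[i]
    cf <- segment$coeffs[[i]]
    bnz <- which(abs(cf$b) >= weight_eps, arr.ind = TRUE)
    if (nrow(bnz) > 0L)
      for (r in seq_len(nrow(bnz))) {
        j <- bnz[r, 1L]; l <- bnz[r, 2L]
        if (j == l && !include_self_loops) next
        rows[[length(rows) + 1L]] <- edge_frame(
          mets[j], mets[l], -cf$b[j, l], cf$b[j, l],
          if (j == l) "self_mediated" else "cross_mediated",
          mets[j], id, seg_i)
      }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else edge_frame()
  nodes <- data.frame(id = mets,
                      type = rep("metabolite", length(mets)),
                      stringsAsFactors = FALSE)
  new_network("metabolite_metabolite", nodes, edges,
              c(segment$t_start, segment$t_end), seg_i)
}

#' Species-species heuristic network from a species-metabolite network
#'
#' The emergent effect of microbe `i` on microbe `j` is the sum over all
#' length-two paths `i -> metabolite l -> j` of the products of the two
#' edge weights: `w_ij = sum_l w_il * w_lj`, where `w_il` aggregates all
#' microbe-to-metabolite edges (constant, self- and cross-mediated; the
#' mediated ones excludable) and `w_lj` aggregates growth edges. A
#' negative product reads as competition (`i` depletes a resource limiting
#' `j`), a positive one as cross-feeding.
#'
#' @param net A `"species_metabolite"` `dfba_network`.
#' @param mediated Include mediated microbe-to-metabolite edges in `w_il`.
#' @param weight_eps Drop threshold for composite weights.
#' @return A `dfba_network` of type `"species_species"`; each edge's
#'   contributing metabolites and per-metabolite path products are in
#'   `attr(net$edges, "paths")` and summarized in the `mediator` column
#'   (comma-joined metabolite list).
#' @export
species_species_network <- function(net, mediated = TRUE,
                                    weight_eps = 1e-10) {
  stopifnot(inherits(net, "dfba_network"))
  if (net$type != "species_metabolite")
    stop("species_species_network expects a species_metabolite network")
  microbes <- net$nodes$id[net$nodes$type == "microbe"]
  mets <- net$nodes$id[net$nodes$type == "metabolite"]
  e <- net$edges
  out_e <- e[e$source %in% microbes &
               (mediated | e$term_kind == "constant_exchange" |
                  e$term_kind == "self_mediated"), , drop = FALSE]
  gr_e <- e[e$term_kind == "growth", , drop = FALSE]
  w_out <- matrix(0, length(microbes), length(mets),
                  dimnames = list(microbes, mets))
  for (r in seq_len(nrow(out_e)))
    w_out[out_e$source[r], out_e$target[r]] <-
      w_out[out_e$source[r], out_e$target[r]] + out_e$weight[r]
  w_gr <- matrix(0, length(mets), length(microbes),
                 dimnames = list(mets, microbes))
  for (r in seq_len(nrow(gr_e)))
    w_gr[gr_e$source[r], gr_e$target[r]] <-
      w_gr[gr_e$source[r], gr_e$target[r]] + gr_e$weight[r]
  rows <- list(); paths <- list()
  for (i in microbes) for (j in microbes) {
    prods <- w_out[i, ] * w_gr[, j]
    nz <- which(prods != 0)
    w <- sum(prods)
    if (length(nz) == 0L || abs(w) < weight_eps) next
    rows[[length(rows) + 1L]] <- edge_frame(
      i, j, w, w, "path_product",
      paste(mets[nz], collapse = ","), i,
      if (is.null(net$segment_index)) NA_integer_ else net$segment_index)
    paths[[length(paths) + 1L]] <- data.frame(
      source = i, target = j, metabolite = mets[nz],
      product = unname(prods[nz]), stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else edge_frame()
  attr(edges, "paths") <- if (length(paths)) do.call(rbind, paths)
                          else NULL
  nodes <- data.frame(id = microbes,
                      type = rep("microbe", length(microbes)),
                      stringsAsFactors = FALSE)
  new_network("species_species", nodes, edges, net$interval,
              net$segment_index)
}

#' Build the per-segment network series of a simulation
#'
#' @param result A `dfba_result` from [simulate_community()].
#' @param builder One of `"species_metabolite"`, `"metabolite_metabolite"`,
#'   `"species_species"`.
#' @param ... Passed to the per-segment builder.
#' @return A `dfba_network_series`: list of networks with durations.
#' @export
network_series <- function(result,
                           builder = c("species_metabolite",
                                       "metabolite_metabolite",
                                       "species_species"), ...) {
  stopifnot(inherits(result, "dfba_result"))
  builder <- match.arg(builder)
  nets <- lapply(seq_along(result$segments), function(k) {
    seg <- result$segments[[k]]
    seg$segment_index <- k
    switch(builder,
      species_metabolite = species_metabolite_network(seg, ...),
      metabolite_metabolite = metabolite_metabolite_network(seg, ...),
      species_species =
        species_species_network(species_metabolite_network(seg), ...))
  })
  durations <- vapply(nets, function(n) n$duration, numeric(1))
  structure(list(networks = nets, durations = durations,
                 total_time = sum(durations), type = builder),
            class = "dfba_network_series")
}

#' @export
print.dfba_network_series <- function(x, ...) {
  cat(sprintf("<dfba_network_series %s: %d network(s), total time %.4g>\n",
              x$type, length(x$networks), x$total_time))
  invisible(x)
}

edge_key <- function(e) {
  paste(e$source, e$target, e$term_kind,
        ifelse(is.na(e$mediator), "", e$mediator),
        ifelse(is.na(e$microbe), "", e$microbe), sep = "\r")
}

#' Duration-weighted mean and variance networks of a series
#'
#' Edges are matched across the series by (source, target, term kind,
#' mediator, microbe); an edge absent from a network counts as weight 0
#' there. The mean network carries the duration-weighted mean weight
#' `wbar = sum_k dt_k w_k / sum_k dt_k`; the variance network carries the
#' duration-weighted population variance, with the sign of the mean kept
#' in `sign_mean` (display convention: color by time-averaged sign,
#' thickness by variance).
#'
#' @param series A `dfba_network_series` (or list of networks plus
#'   durations).
#' @param weight_eps Drop threshold applied to the mean network.
#' @return `list(mean = dfba_network, variance = dfba_network)`.
#' @export
summarize_series <- function(series, weight_eps = 1e-10) {
  nets <- series$networks
  durations <- series$durations
  if (length(nets) == 0L) stop("empty network series")
  if (any(durations <= 0)) stop("segment durations must be positive")
  total <- sum(durations)
  all_edges <- do.call(rbind, lapply(seq_along(nets), function(k) {
    e <- nets[[k]]$edges
    attr(e, "paths") <- NULL
    if (nrow(e) == 0L) return(NULL)
    e$k <- k
    e
  }))
  nodes <- unique(do.call(rbind, lapply(nets, `[[`, "nodes")))
  rownames(nodes) <- NULL
  interval <- c(nets[[1L]]$interval[1],
                nets[[length(nets)]]$interval[2])
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    empty <- new_network(nets[[1L]]$type, nodes, edge_frame(), interval)
    return(list(mean = empty, variance = empty))
  }
  keys <- edge_key(all_edges)
  mean_rows <- list(); var_rows <- list()
  for (key in unique(keys)) {
    sub <- all_edges[keys == key, , drop = FALSE]
    w <- numeric(length(nets))
    w[sub$k] <- sub$weight
    wbar <- sum(durations * w) / total
    wvar <- sum(durations * (w - wbar)^2) / total
    proto <- sub[1L, c("source", "target", "raw_coeff", "term_kind",
                       "mediator", "microbe")]
    if (abs(wbar) >= weight_eps || wvar > 0) {
      mr <- proto; mr$weight <- wbar; mr$segment_index <- NA_integer_
      vr <- proto; vr$weight <- wvar; vr$sign_mean <- sign(wbar)
      vr$segment_index <- NA_integer_
      mean_rows[[length(mean_rows) + 1L]] <- mr
      var_rows[[length(var_rows) + 1L]] <- vr
    }
  }
  mean_edges <- do.call(rbind, mean_rows)
  var_edges <- do.call(rbind, var_rows)
  col_order <- c("source", "target", "weight", "raw_coeff", "term_kind",
                 "mediator", "microbe", "segment_index")
  mean_edges <- mean_edges[, col_order]
  var_edges <- var_edges[, c(col_order, "sign_mean")]
  rownames(mean_edges) <- rownames(var_edges) <- NULL
  mean_net <- new_network(nets[[1L]]$type, nodes, mean_edges, interval)
  var_net <- new_network(paste0(nets[[1L]]$type, "_variance"), nodes,
                         var_edges, interval)
  list(mean = mean_net, variance = var_net)
}

#' Signed difference of two same-type networks
#'
#' Over edges present (same key) in both networks, reports
#' `|w_A| - |w_B|` (`signed_diff`: positive when the interaction is
#' stronger in A) and its absolute value (`magnitude`). Edges present in
#' only one network are excluded from the difference and listed in the
#' exclusion report.
#'
#' @param netA,netB Two `dfba_network`s of the same type.
#' @return `list(difference = data.frame, only_a, only_b)`.
#' @export
network_difference <- function(netA, netB) {
  if (!identical(netA$type, netB$type))
    stop("cannot difference networks of types '", netA$type, "' and '",
         netB$type, "'")
  ea <- netA$edges; eb <- netB$edges
  ka <- edge_key(ea); kb <- edge_key(eb)
  shared <- intersect(ka, kb)
  rows <- lapply(shared, function(key) {
    wa <- sum(ea$weight[ka == key]); wb <- sum(eb$weight[kb == key])
    proto <- ea[which(ka == key)[1L],
                c("source", "target", "term_kind", "mediator", "microbe")]
    proto$weight_a <- wa; proto$weight_b <- wb
    proto$signed_diff <- abs(wa) - abs(wb)
    proto$magnitude <- abs(abs(wa) - abs(wb))
    proto
  })
  diff <- if (length(rows)) do.call(rbind, rows)
          else cbind(edge_frame()[, c("source", "target", "term_kind",
                                      "mediator", "microbe")],
                     data.frame(weight_a = numeric(), weight_b = numeric(),
                                signed_diff = numeric(),
                                magnitude = numeric()))
  rownames(diff) <- NULL
  list(difference = diff,
       only_a = ea[!(ka %in% kb), , drop = FALSE],
       only_b = eb[!(kb %in% ka), , drop = FALSE])
}

#' Average shift in connection strength of one taxon between two networks
#'
#' For every connection (incident edge, keyed by direction, endpoint, term
#' kind and mediator) that `taxon` has in *both* networks, computes
#' `|w_A| - |w_B|` and returns the mean. A positive value means the taxon
#' is on average more strongly connected in network A.
#'
#' @param taxon Microbe node id.
#' @param netA,netB Two same-type `dfba_network`s containing `taxon`.
#' @return Scalar mean shift.
#' @export
connection_shift <- function(taxon, netA, netB) {
  for (net in list(netA, netB))
    if (!(taxon %in% net$nodes$id))
      stop("taxon '", taxon, "' not present in both networks")
  ea <- netA$edges; eb <- netB$edges
  ia <- ea$source == taxon | ea$target == taxon
  ib <- eb$source == taxon | eb$target == taxon
  ka <- edge_key(ea[ia, , drop = FALSE])
  kb <- edge_key(eb[ib, , drop = FALSE])
  shared <- intersect(ka, kb)
  if (length(shared) == 0L)
    stop("taxon '", taxon, "' has no connections shared by both networks; ",
         "the shift is undefined")
  wa <- vapply(shared, function(k)
    sum(ea$weight[ia][ka == k]), numeric(1))
  wb <- vapply(shared, function(k)
    sum(eb$weight[ib][kb == k]), numeric(1))
  mean(abs(wa) - abs(wb))
}

#' Baseline network built directly from single-point FBA fluxes
#'
#' The comparison baseline: one (refined) FBA solve per organism at a fixed
#' metabolite state; every nonzero exchange flux becomes a microbe ->
#' metabolite edge with effect-signed weight `-v_l` (consumption
#' negative), and every *consumed* metabolite gets a marker edge
#' metabolite -> microbe with weight +1 (FBA alone cannot quantify the
#' effect of a metabolite on growth, so these are presence markers, not
#' rate sensitivities; unlike basis-derived growth edges they appear for
#' every consumed metabolite whether or not it is rate-limiting).
#'
#' @param models A `dfba_model` or list of them.
#' @param env An [environment_spec()].
#' @param y Metabolite state at which to solve (default: env initial
#'   amounts).
#' @param flux_eps Exchange rates with `|v|` below this are treated as 0.
#' @return A `dfba_network` of type `"fba_direct"`.
#' @export
fba_direct_network <- function(models, env, y = NULL, flux_eps = 1e-10) {
  if (inherits(models, "dfba_model")) models <- list(models)
  al <- align_environment(models, env)
  models <- al$models; env <- al$env
  if (is.null(y)) y <- env$initial_amounts
  rows <- list()
  for (mod in models) {
    sys <- assemble_lp(mod, env)
    sol <- solve_fba(sys, pmax(y, 0))
    if (sol$status != "optimal") next
    sol <- suppressWarnings(parsimonious_refine(sys, pmax(y, 0), sol))
    v <- sol$exchange_rates
    for (l in which(abs(v) >= flux_eps)) {
      rows[[length(rows) + 1L]] <- edge_frame(
        mod$id, env$metabolite_ids[l], -v[l], v[l], "flux",
        NA_character_, mod$id, NA_integer_)
      if (v[l] > 0)
        rows[[length(rows) + 1L]] <- edge_frame(
          env$metabolite_ids[l], mod$id, 1, 1, "consumption_marker",
          NA_character_, mod$id, NA_integer_)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else edge_frame()
  nodes <- data.frame(
    id = c(vapply(models, `[[`, character(1), "id"), env$metabolite_ids),
    type = c(rep("microbe", length(models)),
             rep("metabolite", length(env$metabolite_ids))),
    stringsAsFactors = FALSE)
  new_network("fba_direct", nodes, edges)
}

#' Rank candidate metabolites mediating a microbe-microbe interaction
#'
#' Given a (typically time-averaged) species-metabolite network and a
#' directed pair of microbes, lists the metabolites `l` whose length-two
#' path product `w_il * w_lj` has the required sign, strongest first —
#' the candidates for mediating an observed positive (cross-feeding) or
#' negative (competition) interaction.
#'
#' @param sm_net A `"species_metabolite"` `dfba_network`.
#' @param microbe_i Source microbe id (the acting organism).
#' @param microbe_j Target microbe id (the affected organism).
#' @param required_sign `+1` or `-1`.
#' @return `data.frame(metabolite, product)` ranked by `|product|`
#'   descending; zero rows when no metabolite qualifies.
#' @export
candidate_mediators <- function(sm_net, microbe_i, microbe_j,
                                required_sign) {
  stopifnot(inherits(sm_net, "dfba_network"),
            sm_net$type == "species_metabolite")
  microbes <- sm_net$nodes$id[sm_net$nodes$type == "microbe"]
  if (!(microbe_i %in% microbes) || !(microbe_j %in% microbes))
    stop("unknown microbe id")
  e <- sm_net$edges
  mets <- sm_net$nodes$id[sm_net$nodes$type == "metabolite"]
  prods <- vapply(mets, function(l) {
    w_il <- sum(e$weight[e$source == microbe_i & e$target == l])
    w_lj <- sum(e$weight[e$source == l & e$target == microbe_j &
                           e$term_kind == "growth"])
    w_il * w_lj
  }, numeric(1))
  keep <- which(sign(prods) == required_sign & prods != 0)
  out <- data.frame(metabolite = mets[keep],
                    product = unname(prods[keep]),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$product)), , drop = FALSE]
}

#' Metabolites significantly produced or consumed over a trajectory
#'
#' @param trajectory Trajectory data frame (`time`, `x_*`, `y_*` columns)
#'   from [simulate_community()] or the direct oracle.
#' @param threshold Relative-change threshold (default 0.01: more than 1%).
#' @param floor_eps Floor for the relative-change denominator, guarding
#'   metabolites that start at 0.
#' @return `data.frame(metabolite, initial, final, change, direction)` with
#'   `direction` `"produced"` or `"consumed"`, restricted to metabolites
#'   whose relative change exceeds `threshold`.
#' @export
significant_metabolites <- function(trajectory, threshold = 0.01,
                                    floor_eps = 1e-9) {
  stopifnot(nrow(trajectory) > 0L)
  ycols <- grep("^y_", names(trajectory), value = TRUE)
  y0 <- as.numeric(trajectory[1L, ycols])
  y1 <- as.numeric(trajectory[nrow(trajectory), ycols])
  rel <- abs(y1 - y0) / pmax(y0, floor_eps)
  keep <- which(rel > threshold)
  data.frame(metabolite = sub("^y_", "", ycols[keep]),
             initial = y0[keep], final = y1[keep],
             change = (y1 - y0)[keep],
             direction = ifelse(y1[keep] > y0[keep], "produced",
                                "consumed"),
             stringsAsFactors = FALSE)
}
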