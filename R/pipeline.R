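#' Run the full simulation-to-networks pipeline
#'
#' Loads models and environment from a configuration (a YAML file path or
#' an equivalent named list), simulates the community, and writes the
#' complete output bundle to a directory:
#'
#' * `trajectory.csv` — time, biomass and metabolite columns;
#' * `transitions.tsv` — one row per basis change / protective step;
#' * `segments.json` — per segment: interval, per-organism basis row
#'   labels and coefficient tables;
#' * `networks/` — per-segment species-metabolite and
#'   metabolite-metabolite networks (TSV + GraphML), per-segment and
#'   time-averaged species-species networks, duration-weighted mean and
#'   variance summary networks;
#' * `manifest.json` — config echo, package version, segment table, file
#'   list and a timestamp.
#'
#' Configuration keys: `models` (list of `path`/`dialect` or
#' `fixture` name), `environment` (`metabolites`, `initial`, `inflow`),
#' `x0`, `t_final`, `out_dir`, and optional tolerance/flag overrides
#' matching [dfba_config()] argument names. Unknown keys are rejected.
#'
#' @param config YAML file path or named list.
#' @return Invisibly, a list with the `dfba_result` and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("models", "environment", "x0", "t_final", "out_dir",
             "config")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$models) || is.null(cfg$t_final) || is.null(cfg$out_dir))
    stop("configuration requires 'models', 't_final' and 'out_dir'")
  sim_config <- do.call(dfba_config, as.list(cfg$config))

  loaded <- lapply(cfg$models, function(mspec) {
    if (!is.null(mspec$fixture)) {
      fx <- switch(mspec$fixture,
                   monod_linear = monod_linear(),
                   capped_growth = capped_growth(),
                   diauxie = diauxie(),
                   crossfeed_pair = crossfeed_pair(),
                   competition_pair = competition_pair(),
                   stop("unknown fixture: ", mspec$fixture))
      if (!is.null(fx[["model"]]))
        list(models = list(fx[["model"]]), env = fx$env)
      else list(models = fx$models, env = fx$env)
    } else {
      dialect <- if (is.null(mspec$dialect)) "auto" else mspec$dialect
      list(models = list(read_model(mspec$path, dialect)), env = NULL)
    }
  })
  models <- do.call(c, lapply(loaded, `[[`, "models"))
  env <- NULL
  if (!is.null(cfg$environment)) {
    es <- cfg$environment
    env <- environment_spec(
      unlist(es$metabolites),
      if (is.null(es$initial)) 0 else unlist(es$initial),
      if (is.null(es$inflow)) 0 else unlist(es$inflow))
  } else {
    for (l in loaded) if (!is.null(l$env)) { env <- l$env; break }
    if (is.null(env))
      env <- environment_spec(character(), numeric())
  }
  x0 <- if (is.null(cfg$x0)) 0.1 else unlist(cfg$x0)

  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)

  result <- simulate_community(models, env, x0, cfg$t_final, sim_config)

  files <- character()
  emit <- function(rel) files <<- c(files, rel)

  traj <- result$trajectory
  num_cols <- names(traj)
  traj_out <- traj
  for (cc in num_cols) traj_out[[cc]] <- fmt9(traj[[cc]])
  utils::write.csv(traj_out, file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE, quote = FALSE)
  emit("trajectory.csv")

  tr <- result$transitions
  tr$time <- fmt9(tr$time)
  utils::write.table(tr, file.path(out_dir, "transitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("transitions.tsv")

  seg_json <- lapply(seq_along(result$segments), function(k) {
    seg <- result$segments[[k]]
    list(index = k, t_start = seg$t_start, t_end = seg$t_end,
         organisms = lapply(seq_along(seg$coeffs), function(i) {
           cf <- seg$coeffs[[i]]
           list(id = seg$model_ids[i],
                basis_rows = if (is.null(seg$bases[[i]])) character()
                             else seg$bases[[i]]$label,
                intrinsic_growth = cf$C,
                growth_coeffs = as.list(cf$a[cf$a != 0]),
                constant_exchange = as.list(cf$D[cf$D != 0]),
                mediated_exchange = b_triplets(cf$b))
         }))
  })
  jsonlite::write_json(seg_json, file.path(out_dir, "segments.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit("segments.json")

  sm_series <- network_series(result, "species_metabolite",
                              weight_eps = sim_config$weight_eps)
  mm_series <- network_series(result, "metabolite_metabolite",
                              include_self_loops =
                                sim_config$include_self_loops,
                              weight_eps = sim_config$weight_eps)
  ss_series <- network_series(result, "species_species")
  any_edges <- any(vapply(sm_series$networks, function(n)
    nrow(n$edges) > 0L, logical(1)))
  write_series <- function(series, stem) {
    for (k in seq_along(series$networks)) {
      for (ext in c("tsv", "graphml")) {
        rel <- file.path("networks",
                         sprintf("%s_segment%02d.%s", stem, k, ext))
        write_network(series$networks[[k]], file.path(out_dir, rel), ext)
        emit(rel)
      }
    }
    summ <- summarize_series(series, sim_config$weight_eps)
    for (which_n in c("mean", "variance")) {
      rel <- file.path("networks",
                       sprintf("%s_%s.tsv", stem, which_n))
      write_network(summ[[which_n]], file.path(out_dir, rel), "tsv")
      emit(rel)
    }
    summ
  }
  if (any_edges) {
    sm_summ <- write_series(sm_series, "species_metabolite")
    write_series(mm_series, "metabolite_metabolite")
    write_series(ss_series, "species_species")
  } else {
    sm_summ <- list(mean = NULL)
    warning("no interaction edges found; writing trajectory only")
  }

  manifest <- list(
    package = "dfbanet",
    version = as.character(utils::packageVersion("dfbanet")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[setdiff(names(cfg), "out_dir")],
    status = result$status,
    n_segments = length(result$segments),
    segments = lapply(result$segments, function(s)
      list(t_start = s$t_start, t_end = s$t_end)),
    n_transitions = nrow(result$transitions),
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(result = result, manifest = manifest,
                 time_averaged = sm_summ$mean))
}

b_triplets <- function(b) {
  nz <- which(b != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(list())
  lapply(seq_len(nrow(nz)), function(r) list(
    mediator = rownames(b)[nz[r, 1]],
    metabolite = colnames(b)[nz[r, 2]],
    coef = b[nz[r, 1], nz[r, 2]]))
}

#' Compare two pipeline runs
#'
#' Builds the duration-weighted time-averaged species-metabolite networks
#' of two simulation results and reports (i) the signed difference over
#' shared edges plus the non-shared edges of each run, and (ii) the
#' average connection-strength shift of each requested taxon.
#'
#' @param resultA,resultB `dfba_result` objects (e.g. `$result` from
#'   [run_pipeline()] or the return of [simulate_community()]).
#' @param taxa Character vector of microbe ids to compute shifts for;
#'   each must be present in both runs.
#' @return `list(difference, only_a, only_b, shifts)` where `shifts` is a
#'   `data.frame(taxon, shift)`.
#' @export
compare_runs <- function(resultA, resultB, taxa = character()) {
  avg <- function(res)
    summarize_series(network_series(res, "species_metabolite"))$mean
  netA <- avg(resultA); netB <- avg(resultB)
  for (tx in taxa)
    if (!(tx %in% netA$nodes$id) || !(tx %in% netB$nodes$id))
      stop("taxon '", tx, "' absent from one of the runs")
  nd <- network_difference(netA, netB)
  shifts <- data.frame(
    taxon = taxa,
    shift = vapply(taxa, function(tx)
      connection_shift(tx, netA, netB), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(shifts) <- NULL
  c(nd, list(shifts = shifts, netA = netA, netB = netB))
}
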