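#' Read a metabolic model from file
#'
#' Two dialects are supported:
#'
#' * `"json"`: the package's JSON model dialect — objects `id`,
#'   `reactions` (id, lower, upper, objective), `metabolites` (id, type
#'   `internal`/`exchange`), `stoichiometry` (metabolite, reaction, coef,
#'   in *uptake-positive* orientation for exchange rows), and
#'   `exchange_bounds` (metabolite, lower, upper = bound-function spec).
#' * `"sbml"`: a subset of SBML Level 3 with the FBC package. Species with
#'   `boundaryCondition="true"` are environmental metabolites; each
#'   reaction touching a boundary species contributes to that metabolite's
#'   exchange row with sign flipped to uptake-positive (an uptake reaction
#'   consuming `glc_e` has SBML stoichiometry -1 and exchange-row entry
#'   +1). Objective coefficients come from the active FBC objective, flux
#'   bounds from FBC bound parameters. Metabolite-dependent uptake bounds
#'   have no SBML field and are carried in a package annotation
#'   (`uptakeBound` elements); exchange rows without one default to linear
#'   kinetics with slope 1.
#'
#' Metabolites referenced by no reaction are dropped with a warning.
#'
#' @param path File path.
#' @param dialect `"json"` or `"sbml"` (default: by file extension).
#' @return A validated `dfba_model`.
#' @export
read_model <- function(path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(dialect, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' @rdname read_model
#' @export
load_model <- read_model

#' Write a metabolic model to file
#'
#' Inverse of [read_model()]; both dialects round-trip all matrices,
#' bounds and bound-function parameters exactly (to the precision of the
#' decimal representation; the JSON writer uses 17 significant digits).
#'
#' @param model A `dfba_model`.
#' @param path Output path.
#' @param dialect `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  validate_model(model)
  switch(dialect,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

bf_to_list <- function(f) c(list(kind = f$kind), f$params)

bf_from_list <- function(x) do.call(bound_function, x)

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$reactions) || length(doc$reactions) == 0L)
    stop("JSON model has no reactions: ", path)
  rxn <- vapply(doc$reactions, `[[`, character(1), "id")
  lower <- vapply(doc$reactions, function(r)
    parse_inf(r$lower), numeric(1))
  upper <- vapply(doc$reactions, function(r)
    parse_inf(r$upper), numeric(1))
  objective <- vapply(doc$reactions, function(r)
    if (is.null(r$objective)) 0 else as.numeric(r$objective), numeric(1))
  met_ids <- vapply(doc$metabolites, `[[`, character(1), "id")
  met_type <- vapply(doc$metabolites, `[[`, character(1), "type")
  used <- unique(vapply(doc$stoichiometry, `[[`, character(1),
                        "metabolite"))
  unused <- setdiff(met_ids, used)
  if (length(unused) > 0L) {
    warning("dropping metabolite(s) referenced by no reaction: ",
            paste(unused, collapse = ", "))
    keep <- met_ids %in% used
    met_ids <- met_ids[keep]; met_type <- met_type[keep]
  }
  internal_ids <- met_ids[met_type == "internal"]
  exchange_ids <- met_ids[met_type == "exchange"]
  ist <- matrix(0, length(internal_ids), length(rxn),
                dimnames = list(internal_ids, rxn))
  ex <- matrix(0, length(exchange_ids), length(rxn),
               dimnames = list(exchange_ids, rxn))
  for (s in doc$stoichiometry) {
    if (s$metabolite %in% internal_ids)
      ist[s$metabolite, s$reaction] <- as.numeric(s$coef)
    else ex[s$metabolite, s$reaction] <- as.numeric(s$coef)
  }
  ex_lower <- stats::setNames(rep(0, length(exchange_ids)), exchange_ids)
  ex_upper <- stats::setNames(
    rep(list(bound_function("linear", kappa = 1)), length(exchange_ids)),
    exchange_ids)
  for (b in doc$exchange_bounds) {
    if (!b$metabolite %in% exchange_ids) next
    if (!is.null(b$lower)) ex_lower[b$metabolite] <- parse_inf(b$lower)
    if (!is.null(b$upper)) ex_upper[[b$metabolite]] <- bf_from_list(b$upper)
  }
  metabolic_model(id = if (is.null(doc$id)) "model" else doc$id,
                  reaction_ids = rxn, internal_stoich = ist,
                  exchange_stoich = ex, objective = objective,
                  lower_flux = lower, upper_flux = upper,
                  exchange_lower = ex_lower, exchange_upper = ex_upper)
}

parse_inf <- function(x) {
  if (is.null(x)) return(Inf)
  if (is.character(x))
    return(switch(x, "inf" = , "Inf" = , "+Inf" = Inf,
                  "-inf" = , "-Inf" = -Inf, as.numeric(x)))
  as.numeric(x)
}

fmt_inf <- function(x) {
  if (is.infinite(x)) return(if (x > 0) "Inf" else "-Inf")
  x
}

write_model_json <- function(model, path) {
  ex_ids <- rownames(model$exchange_stoich)
  in_ids <- rownames(model$internal_stoich)
  if (is.null(in_ids) && nrow(model$internal_stoich) > 0L)
    in_ids <- paste0("internal_", seq_len(nrow(model$internal_stoich)))
  stoich <- list()
  add <- function(mat, ids) {
    for (r in seq_len(nrow(mat))) for (cc in which(mat[r, ] != 0))
      stoich[[length(stoich) + 1L]] <<- list(
        metabolite = ids[r], reaction = model$reaction_ids[cc],
        coef = mat[r, cc])
  }
  add(model$internal_stoich, in_ids)
  add(model$exchange_stoich, ex_ids)
  doc <- list(
    id = model$id,
    reactions = lapply(seq_along(model$reaction_ids), function(i) list(
      id = model$reaction_ids[i],
      lower = fmt_inf(model$lower_flux[i]),
      upper = fmt_inf(model$upper_flux[i]),
      objective = model$objective[i])),
    metabolites = c(
      lapply(in_ids, function(m) list(id = m, type = "internal")),
      lapply(ex_ids, function(m) list(id = m, type = "exchange"))),
    stoichiometry = stoich,
    exchange_bounds = lapply(seq_along(ex_ids), function(j) list(
      metabolite = ex_ids[j],
      lower = fmt_inf(model$exchange_lower[j]),
      upper = bf_to_list(model$exchange_upper[[j]]))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- SBML L3 + FBC subset ------------------------------------------------

sbml_ns <- c(
  s = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  up = "https://dfbanet.r-pkg/uptake-bounds")

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- sbml_ns
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(sp, "id")
  sp_boundary <- xml2::xml_attr(sp, "boundaryCondition") %in%
    c("true", "1")
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0L) stop("SBML model has no reactions: ", path)
  rxn <- xml2::xml_attr(rx, "id")
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  lower <- vapply(rx, function(r) {
    p <- xml2::xml_attr(r, "lowerFluxBound")
    if (is.na(p)) -Inf else pval[[p]]
  }, numeric(1))
  upper <- vapply(rx, function(r) {
    p <- xml2::xml_attr(r, "upperFluxBound")
    if (is.na(p)) Inf else pval[[p]]
  }, numeric(1))
  obj_refs <- xml2::xml_find_all(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- stats::setNames(numeric(length(rxn)), rxn)
  if (length(obj_refs) > 0L)
    objective[xml2::xml_attr(obj_refs, "reaction")] <-
      as.numeric(xml2::xml_attr(obj_refs, "coefficient"))
  if (all(objective == 0))
    stop("SBML model '", path, "' has no objective")
  # stoichiometry; boundary species go to the exchange block, sign-flipped
  # so positive exchange = uptake
  stoich <- matrix(0, length(sp_id), length(rxn),
                   dimnames = list(sp_id, rxn))
  for (k in seq_along(rx)) {
    for (ref in xml2::xml_find_all(rx[[k]], "./s:listOfReactants/s:speciesReference", ns))
      stoich[xml2::xml_attr(ref, "species"), k] <-
        stoich[xml2::xml_attr(ref, "species"), k] -
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    for (ref in xml2::xml_find_all(rx[[k]], "./s:listOfProducts/s:speciesReference", ns))
      stoich[xml2::xml_attr(ref, "species"), k] <-
        stoich[xml2::xml_attr(ref, "species"), k] +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
  }
  used <- rowSums(stoich != 0) > 0
  if (any(!used)) {
    warning("dropping metabolite(s) referenced by no reaction: ",
            paste(sp_id[!used], collapse = ", "))
    stoich <- stoich[used, , drop = FALSE]
    sp_boundary <- sp_boundary[used]
    sp_id <- sp_id[used]
  }
  ist <- stoich[!sp_boundary, , drop = FALSE]
  ex <- -stoich[sp_boundary, , drop = FALSE]
  ex_ids <- sp_id[sp_boundary]
  ex_lower <- stats::setNames(rep(0, length(ex_ids)), ex_ids)
  ex_upper <- stats::setNames(
    rep(list(bound_function("linear", kappa = 1)), length(ex_ids)), ex_ids)
  for (ub in xml2::xml_find_all(doc, ".//up:uptakeBound", ns)) {
    met <- xml2::xml_attr(ub, "metabolite")
    if (!met %in% ex_ids) next
    kind <- xml2::xml_attr(ub, "kind")
    lw <- xml2::xml_attr(ub, "lower")
    if (!is.na(lw)) ex_lower[met] <- parse_inf(lw)
    pr <- list(kind = kind)
    for (pn in c("value", "kappa", "Vmax", "K")) {
      v <- xml2::xml_attr(ub, pn)
      if (!is.na(v)) pr[[pn]] <- as.numeric(v)
    }
    ex_upper[[met]] <- bf_from_list(pr)
  }
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  metabolic_model(id = if (is.na(mid)) "model" else mid,
                  reaction_ids = rxn, internal_stoich = ist,
                  exchange_stoich = ex, objective = unname(objective),
                  lower_flux = lower, upper_flux = upper,
                  exchange_lower = ex_lower, exchange_upper = ex_upper)
}

num17 <- function(x) formatC(x, digits = 17, format = "g")

write_model_sbml <- function(model, path) {
  non_const <- vapply(model$exchange_upper, function(f)
    f$kind != "constant", logical(1))
  if (any(non_const))
    warning("SBML has no field for metabolite-dependent flux bounds; ",
            "uptake bound kinetics stored as package annotation")
  ex_ids <- rownames(model$exchange_stoich)
  in_ids <- rownames(model$internal_stoich)
  if (is.null(in_ids) && nrow(model$internal_stoich) > 0L)
    in_ids <- paste0("internal_", seq_len(nrow(model$internal_stoich)))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  ln <- character()
  w <- function(...) ln <<- c(ln, paste0(...))
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', sbml_ns[["s"]], '" xmlns:fbc="', sbml_ns[["fbc"]],
    '" xmlns:up="', sbml_ns[["up"]],
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(model$id), '" fbc:strict="false">')
  w('    <listOfCompartments>')
  w('      <compartment id="c" constant="true"/>')
  w('      <compartment id="e" constant="true"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (m in in_ids)
    w('      <species id="', esc(m), '" compartment="c" ',
      'boundaryCondition="false" hasOnlySubstanceUnits="false" ',
      'constant="false"/>')
  for (m in ex_ids)
    w('      <species id="', esc(m), '" compartment="e" ',
      'boundaryCondition="true" hasOnlySubstanceUnits="false" ',
      'constant="false"/>')
  w('    </listOfSpecies>')
  w('    <listOfParameters>')
  bnd_id <- function(i, side) paste0("fb_", side, "_", i)
  for (i in seq_along(model$reaction_ids)) {
    if (is.finite(model$lower_flux[i]))
      w('      <parameter id="', bnd_id(i, "lo"), '" value="',
        num17(model$lower_flux[i]), '" constant="true"/>')
    if (is.finite(model$upper_flux[i]))
      w('      <parameter id="', bnd_id(i, "up"), '" value="',
        num17(model$upper_flux[i]), '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (i in seq_along(model$reaction_ids)) {
    rid <- model$reaction_ids[i]
    attrs <- ""
    if (is.finite(model$lower_flux[i]))
      attrs <- paste0(attrs, ' lowerFluxBound="', bnd_id(i, "lo"), '"')
    if (is.finite(model$upper_flux[i]))
      attrs <- paste0(attrs, ' upperFluxBound="', bnd_id(i, "up"), '"')
    w('      <reaction id="', esc(rid),
      '" reversible="true" fast="false"', attrs, '>')
    # internal rows keep their sign; exchange rows are uptake-positive,
    # so an exchange entry +1 is an SBML reactant with stoichiometry 1
    reac <- character(); prod <- character()
    emit <- function(mids, coefs) {
      for (k in seq_along(mids)) {
        cstr <- paste0('          <speciesReference species="',
                       esc(mids[k]), '" stoichiometry="',
                       num17(abs(coefs[k])), '" constant="true"/>')
        if (coefs[k] < 0) reac <<- c(reac, cstr) else prod <<- c(prod, cstr)
      }
    }
    if (length(in_ids)) {
      nz <- which(model$internal_stoich[, i] != 0)
      emit(in_ids[nz], model$internal_stoich[nz, i])
    }
    nz <- which(model$exchange_stoich[, i] != 0)
    emit(ex_ids[nz], -model$exchange_stoich[nz, i])
    if (length(reac)) {
      w('        <listOfReactants>'); for (s in reac) w(s)
      w('        </listOfReactants>')
    }
    if (length(prod)) {
      w('        <listOfProducts>'); for (s in prod) w(s)
      w('        </listOfProducts>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w('        <fbc:listOfFluxObjectives>')
  for (i in which(model$objective != 0))
    w('          <fbc:fluxObjective fbc:reaction="',
      esc(model$reaction_ids[i]), '" fbc:coefficient="',
      num17(model$objective[i]), '"/>')
  w('        </fbc:listOfFluxObjectives>')
  w('      </fbc:objective>')
  w('    </fbc:listOfObjectives>')
  w('    <annotation>')
  for (j in seq_along(ex_ids)) {
    f <- model$exchange_upper[[j]]
    pr <- paste(vapply(names(f$params), function(pn)
      paste0(pn, '="', num17(f$params[[pn]]), '"'), character(1)),
      collapse = " ")
    w('      <up:uptakeBound metabolite="', esc(ex_ids[j]), '" kind="',
      f$kind, '" lower="', fmt_inf(model$exchange_lower[j]), '" ', pr,
      '/>')
  }
  w('    </annotation>')
  w('  </model>')
  w('</sbml>')
  writeLines(ln, path)
  invisible(path)
}
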