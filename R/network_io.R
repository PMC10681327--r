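#' Write an interaction network to file
#'
#' Two formats:
#' * `"tsv"`: edge list with fixed column order `source, target, weight,
#'   raw_coeff, term_kind, mediator, microbe, segment, t_start, t_end`
#'   (floating point printed with 9 significant digits); node types are
#'   recoverable from the edge context plus a `# nodes:` header comment.
#' * `"graphml"`: via igraph, with a typed `kind` node attribute
#'   (microbe/metabolite) and all edge attributes.
#'
#' @param net A `dfba_network`.
#' @param path Output path.
#' @param fmt `"tsv"` or `"graphml"` (default: by extension).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, fmt = c("auto", "tsv", "graphml")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
           else "tsv"
  stopifnot(inherits(net, "dfba_network"))
  if (fmt == "tsv") write_network_tsv(net, path)
  else write_network_graphml(net, path)
  invisible(path)
}

net_cols <- c("source", "target", "weight", "raw_coeff", "term_kind",
              "mediator", "microbe", "segment", "t_start", "t_end")

fmt9 <- function(x) {
  out <- formatC(x, digits = 9, format = "g")
  out[is.na(x)] <- "NA"
  out
}

export_edges <- function(net) {
  e <- net$edges
  data.frame(
    source = e$source, target = e$target,
    weight = e$weight, raw_coeff = e$raw_coeff,
    term_kind = e$term_kind, mediator = e$mediator, microbe = e$microbe,
    segment = if (nrow(e)) e$segment_index else integer(),
    t_start = rep(net$interval[1], nrow(e)),
    t_end = rep(net$interval[2], nrow(e)),
    stringsAsFactors = FALSE)
}

write_network_tsv <- function(net, path) {
  df <- export_edges(net)
  for (cc in c("weight", "raw_coeff", "t_start", "t_end"))
    df[[cc]] <- fmt9(df[[cc]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# network_type: ", net$type), con)
  writeLines(paste0("# nodes: ",
                    paste(net$nodes$id, net$nodes$type, sep = ":",
                          collapse = ",")), con)
  utils::write.table(df[, net_cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a network written by [write_network()] (TSV or GraphML)
#'
#' @param path File path.
#' @param fmt `"tsv"` or `"graphml"` (default: by extension).
#' @return A `dfba_network`.
#' @export
read_network <- function(path, fmt = c("auto", "tsv", "graphml")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
           else "tsv"
  if (fmt == "tsv") read_network_tsv(path) else read_network_graphml(path)
}

read_network_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  type <- sub("^# network_type: ", "", hdr[1])
  nodes_spec <- strsplit(sub("^# nodes: ", "", hdr[2]), ",")[[1]]
  parts <- strsplit(nodes_spec, ":")
  nodes <- data.frame(id = vapply(parts, `[`, character(1), 1),
                      type = vapply(parts, `[`, character(1), 2),
                      stringsAsFactors = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2L,
                          stringsAsFactors = FALSE,
                          colClasses = c(
                            source = "character", target = "character",
                            mediator = "character",
                            microbe = "character"))
  interval <- if (nrow(df)) c(df$t_start[1], df$t_end[1])
              else c(NA_real_, NA_real_)
  edges <- edge_frame(df$source, df$target, df$weight, df$raw_coeff,
                      df$term_kind, df$mediator, df$microbe,
                      if (nrow(df)) df$segment else integer())
  new_network(type, nodes, edges, interval)
}

net_as_igraph <- function(net) {
  df <- export_edges(net)
  for (cc in c("mediator", "microbe"))
    df[[cc]][is.na(df[[cc]])] <- ""
  g <- igraph::graph_from_data_frame(
    df, directed = TRUE,
    vertices = data.frame(name = net$nodes$id, kind = net$nodes$type,
                          stringsAsFactors = FALSE))
  igraph::graph_attr(g, "network_type") <- net$type
  g
}

write_network_graphml <- function(net, path) {
  igraph::write_graph(net_as_igraph(net), path, format = "graphml")
}

read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(g, "vertices")
  ed <- igraph::as_data_frame(g, "edges")
  nodes <- data.frame(id = vd$name, type = vd$kind,
                      stringsAsFactors = FALSE)
  med <- ed$mediator; med[med == ""] <- NA_character_
  mic <- ed$microbe; mic[mic == ""] <- NA_character_
  interval <- if (nrow(ed)) c(ed$t_start[1], ed$t_end[1])
              else c(NA_real_, NA_real_)
  edges <- edge_frame(ed$from, ed$to, ed$weight, ed$raw_coeff,
                      ed$term_kind, med, mic,
                      if (nrow(ed)) as.integer(ed$segment) else integer())
  type <- igraph::graph_attr(g, "network_type")
  new_network(if (is.null(type)) "unknown" else type, nodes, edges,
              interval)
}
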