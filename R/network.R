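#' Assemble the species association network
#'
#' Nodes are the RAI-selected species (plus any focal species), carrying
#' abundance, occupancy and breadth attributes. Undirected edges come from
#' the pairwise Phi / chi-square table and are kept only when the
#' significance class is not `"none"` (set `all_pairs = TRUE` to keep every
#' tested pair); significant negative-phi edges are retained and flagged by
#' their `sign`. Directed edges come from the lambda table and are kept only
#' when the bootstrap lower prediction limit is positive, i.e. a significant
#' asymmetric (commensal-type) dependence of the predicted species on the
#' predictor.
#'
#' @param abundance Abundance table from [rai()].
#' @param associations Pairwise table from [pair_associations()].
#' @param lambdas Directed lambda table from [lambda_table()].
#' @param breadth Optional breadth table from [niche_breadth()].
#' @param focal Optional focal species always included as a node.
#' @param all_pairs Keep non-significant undirected edges too?
#' @return List of class `association_network`: `nodes` (data frame),
#'   `edges` (undirected, data frame), `directed` (data frame).
#' @export
build_network <- function(abundance, associations, lambdas = NULL,
                          breadth = NULL, focal = NULL, all_pairs = FALSE) {
  nodes <- abundance[abundance$selected | abundance$species %in% focal, ,
                     drop = FALSE]
  nodes <- nodes[order(nodes$species), , drop = FALSE]
  if (!is.null(breadth)) {
    nodes <- merge(nodes, breadth, by = "species", all.x = TRUE, sort = TRUE)
  }
  rownames(nodes) <- NULL
  known <- nodes$species

  check_species <- function(x, what) {
    bad <- setdiff(x, known)
    if (length(bad)) {
      stop(what, " reference species outside the node set: ",
           paste(sort(unique(bad)), collapse = ", "))
    }
  }

  edges <- associations
  check_species(c(edges$species_a, edges$species_b), "association table")
  edges <- edges[!is.na(edges$class) & (all_pairs | edges$class != "none"), ,
                 drop = FALSE]
  edges <- edges[order(edges$species_a, edges$species_b), , drop = FALSE]
  rownames(edges) <- NULL

  directed <- if (is.null(lambdas)) {
    data.frame(predictor = character(), predicted = character(),
               lambda = numeric(), upper = numeric(), lower = numeric(),
               p = numeric(), significant = logical(),
               stringsAsFactors = FALSE)
  } else {
    check_species(c(lambdas$predictor, lambdas$predicted), "lambda table")
    d <- lambdas[!is.na(lambdas$significant) & lambdas$significant, ,
                 drop = FALSE]
    d <- d[order(d$predictor, d$predicted), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  structure(list(nodes = nodes, edges = edges, directed = directed),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("association_network: %d nodes, %d undirected edges, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$directed)))
  invisible(x)
}

#' Degree of one species in the undirected association layer
#' @param network An `association_network`.
#' @param species Species name.
#' @return Integer count of significant partners.
#' @export
network_degree <- function(network, species) {
  sum(network$edges$species_a == species | network$edges$species_b == species)
}

#' Export an association network
#'
#' Always writes an edge-list CSV (undirected and directed layers, with a
#' `layer` column) and a node-attribute CSV; with `format = "graphml"` also
#' writes a GraphML file with typed node/edge attributes that round-trips
#' through [read_network_graphml()].
#'
#' @param network An `association_network`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"graphml"` (GraphML is written in addition to
#'   the CSVs).
#' @return Named character vector of the files written.
#' @export
export_network <- function(network, dir, format = c("csv", "graphml")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  und <- network$edges
  und_out <- data.frame(from = und$species_a, to = und$species_b,
                        layer = rep("undirected", nrow(und)),
                        phi = und$phi, chi2 = und$chi2, sign = und$sign,
                        class = und$class,
                        lambda = rep(NA_real_, nrow(und)),
                        lower = rep(NA_real_, nrow(und)),
                        upper = rep(NA_real_, nrow(und)),
                        stringsAsFactors = FALSE)
  dd <- network$directed
  dir_out <- data.frame(from = dd$predictor, to = dd$predicted,
                        layer = rep("directed", nrow(dd)),
                        phi = rep(NA_real_, nrow(dd)),
                        chi2 = rep(NA_real_, nrow(dd)),
                        sign = rep(NA_character_, nrow(dd)),
                        class = rep(NA_character_, nrow(dd)),
                        lambda = dd$lambda, lower = dd$lower, upper = dd$upper,
                        stringsAsFactors = FALSE)
  files <- c(edges = file.path(dir, "network_edges.csv"),
             nodes = file.path(dir, "network_nodes.csv"))
  utils::write.csv(rbind(und_out, dir_out), files["edges"], row.names = FALSE)
  utils::write.csv(network$nodes, files["nodes"], row.names = FALSE)
  if (format == "graphml") {
    files <- c(files, graphml = file.path(dir, "network.graphml"))
    igraph::write_graph(as_igraph(network), files["graphml"],
                        format = "graphml")
  }
  files
}

#' Convert an association network to an igraph object
#'
#' Both layers are merged into one directed igraph graph; undirected
#' associations are stored as single arcs flagged `layer = "undirected"`.
#'
#' @param network An `association_network`.
#' @return An igraph graph.
#' @export
as_igraph <- function(network) {
  und <- network$edges
  dd <- network$directed
  ed <- rbind(
    if (nrow(und)) data.frame(from = und$species_a, to = und$species_b,
                              layer = "undirected", weight = und$phi,
                              chi2 = und$chi2, class = und$class,
                              stringsAsFactors = FALSE),
    if (nrow(dd)) data.frame(from = dd$predictor, to = dd$predicted,
                             layer = "directed", weight = dd$lambda,
                             chi2 = NA_real_, class = "lambda",
                             stringsAsFactors = FALSE))
  if (is.null(ed)) ed <- data.frame(from = character(), to = character(),
                                    layer = character(), weight = numeric(),
                                    chi2 = numeric(), class = character(),
                                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = network$nodes)
  g
}

#' Read back a GraphML network export
#' @param path GraphML file from [export_network()].
#' @return An igraph graph.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
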