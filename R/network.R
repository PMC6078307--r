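# Tripartite network assembly, first-neighbor extraction, direct/indirect
# effect classification, and graph export.

record_node_id <- function(block, variable, modality) {
  ifelse(block == "brain" & !is.na(modality),
         paste0(variable, "|", substr(modality, 1, 4)), variable)
}

# Inclusion honouring "< bound" p-values printed in reference tables
# (carried as `*_lt` flags): a row printed as "p < 0.05" passes a p < .05
# threshold even though its stored numeric bound equals 0.05.
passes_threshold <- function(val, lt, alpha) {
  lt <- if (is.null(lt)) rep(FALSE, length(val)) else (lt %in% TRUE)
  (val < alpha) | (lt & val <= alpha)
}

#' Build the tripartite association network
#'
#' Creates a typed node for every variable appearing in a passing record and
#' an edge per passing cross-block association. Two threshold modes are
#' first-class: the visualization network (`mode = "p"`, all associations
#' with p below `alpha`) and the significant network (`mode = "q"`,
#' FDR-corrected). Each edge carries its statistics and a tier flag
#' (`"q<alpha"` vs `"p<alpha"` only). Duplicate rows for the same unordered
#' variable pair (and modality) keep the first occurrence.
#'
#' @param records Association records (see [block_correlations()]); at
#'   minimum columns `block_a`, `block_b`, `variable_a`, `variable_b`,
#'   `modality`, `r`, `p`, `q` (optional `p_lt`/`q_lt` flags mark values
#'   stored as upper bounds).
#' @param mode Threshold on `"p"` (default) or `"q"`.
#' @param alpha Inclusion threshold in (0, 1).
#' @return An object of class `tripartite_network`: data.frames `nodes`
#'   (`id`, `label`, `type`, `modality`) and `edges` (`from`, `to`, `r`,
#'   `p`, `q`, `modality`, `tier`), plus `mode` and `alpha`.
#' @export
build_network <- function(records, mode = c("p", "q"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  empty <- structure(
    list(nodes = data.frame(id = character(0), label = character(0),
                            type = character(0), modality = character(0),
                            stringsAsFactors = FALSE),
         edges = data.frame(from = character(0), to = character(0),
                            r = numeric(0), p = numeric(0), q = numeric(0),
                            modality = character(0), tier = character(0),
                            stringsAsFactors = FALSE),
         mode = mode, alpha = alpha),
    class = "tripartite_network")
  if (is.null(records) || !nrow(records)) return(empty)
  if (any(records$block_a == records$block_b)) {
    stop("within-block records are not admissible in a tripartite network")
  }
  val <- if (mode == "p") records$p else records$q
  lt <- if (mode == "p") records$p_lt else records$q_lt
  keep <- passes_threshold(val, lt, alpha)
  rec <- records[keep, , drop = FALSE]
  if (!nrow(rec)) return(empty)

  id_a <- record_node_id(rec$block_a, rec$variable_a, rec$modality)
  id_b <- record_node_id(rec$block_b, rec$variable_b, rec$modality)
  pair_key <- paste(pmin(id_a, id_b), pmax(id_a, id_b))
  first <- !duplicated(pair_key)
  rec <- rec[first, , drop = FALSE]
  id_a <- id_a[first]
  id_b <- id_b[first]

  nodes <- unique(data.frame(
    id = c(id_a, id_b),
    label = c(rec$variable_a, rec$variable_b),
    type = c(rec$block_a, rec$block_b),
    modality = c(ifelse(rec$block_a == "brain", rec$modality, NA_character_),
                 ifelse(rec$block_b == "brain", rec$modality, NA_character_)),
    stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  q_pass <- passes_threshold(rec$q, rec$q_lt, alpha)
  edges <- data.frame(
    from = id_a, to = id_b, r = rec$r, p = rec$p, q = rec$q,
    modality = ifelse(is.na(rec$modality), NA_character_, rec$modality),
    tier = ifelse(q_pass, paste0("q<", alpha), paste0("p<", alpha)),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, mode = mode, alpha = alpha),
            class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf("Tripartite network (%s < %g): %d nodes, %d edges\n",
              x$mode, x$alpha, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    tb <- table(x$nodes$type)
    cat("  nodes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

neighbors_of <- function(net, ids) {
  e <- net$edges
  unique(c(e$to[e$from %in% ids], e$from[e$to %in% ids]))
}

#' Metabolite first-neighbor subnetwork
#'
#' Restricts the network to the metabolite nodes, their first neighbors, and
#' all adjacent edges: every edge with at least one endpoint among the
#' retained nodes is kept, together with its other endpoint. Clinical
#' variables linked to a metabolite's brain neighbors therefore stay in the
#' subnetwork — these edges carry the indirect (brain-mediated) paths.
#'
#' @param net A `tripartite_network`.
#' @return A `tripartite_network` on the retained nodes.
#' @export
metabolite_first_neighbors <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  mets <- net$nodes$id[net$nodes$type == "metabolite"]
  if (!length(mets)) {
    warning("network contains no metabolite nodes; returning an empty network")
    nodes <- net$nodes[0, , drop = FALSE]
    edges <- net$edges[0, , drop = FALSE]
    rownames(nodes) <- rownames(edges) <- NULL
    return(structure(list(nodes = nodes, edges = edges, mode = net$mode,
                          alpha = net$alpha),
                     class = "tripartite_network"))
  }
  retained <- union(mets, neighbors_of(net, mets))
  adj <- net$edges$from %in% retained | net$edges$to %in% retained
  edges <- net$edges[adj, , drop = FALSE]
  keep <- union(retained, unique(c(edges$from, edges$to)))
  nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, mode = net$mode,
                 alpha = net$alpha),
            class = "tripartite_network")
}

#' Classify direct and indirect metabolite effects
#'
#' For every metabolite x clinical-variable pair in the network: the effect
#' is *direct* when the two share an edge, *indirect* when they do not but
#' at least one brain-metric node is adjacent to both (the mediating
#' length-2 path), and *none* otherwise. Brain mediators adjacent to both
#' endpoints are always reported, including for direct pairs, since a pair
#' can be directly associated and brain-mediated at the same time.
#'
#' @param net A `tripartite_network` (typically the first-neighbor network
#'   at p < 0.05).
#' @param metabolites,targets Optional node labels; default to all
#'   metabolite / clinical nodes in `net`.
#' @return A data.frame: `metabolite`, `target`, `status`
#'   (direct/indirect/none), `direct` (logical), `mediators`
#'   (comma-separated brain variable labels, `""` if none),
#'   `mediator_modalities`.
#' @export
classify_effects <- function(net, metabolites = NULL, targets = NULL) {
  stopifnot(inherits(net, "tripartite_network"))
  nd <- net$nodes
  if (is.null(metabolites)) metabolites <- nd$label[nd$type == "metabolite"]
  if (is.null(targets)) targets <- nd$label[nd$type == "clinical"]
  if (!length(metabolites) || !length(targets)) {
    return(data.frame(metabolite = character(0), target = character(0),
                      status = character(0), direct = logical(0),
                      mediators = character(0),
                      mediator_modalities = character(0),
                      stringsAsFactors = FALSE))
  }
  brain_ids <- nd$id[nd$type == "brain"]
  grid <- expand.grid(metabolite = metabolites, target = targets,
                      stringsAsFactors = FALSE)
  out <- grid
  out$status <- "none"
  out$direct <- FALSE
  out$mediators <- ""
  out$mediator_modalities <- ""
  for (i in seq_len(nrow(grid))) {
    m <- grid$metabolite[i]
    tg <- grid$target[i]
    if (!(m %in% nd$id)) next
    nb_m <- neighbors_of(net, m)
    nb_t <- if (tg %in% nd$id) neighbors_of(net, tg) else character(0)
    direct <- tg %in% nb_m
    med <- intersect(intersect(nb_m, nb_t), brain_ids)
    out$direct[i] <- direct
    out$status[i] <- if (direct) "direct" else if (length(med)) "indirect" else "none"
    if (length(med)) {
      out$mediators[i] <- paste(nd$label[match(med, nd$id)], collapse = ",")
      out$mediator_modalities[i] <- paste(nd$modality[match(med, nd$id)],
                                          collapse = ",")
    }
  }
  out
}

as_igraph <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  nodes$modality[is.na(nodes$modality)] <- ""
  edges$modality[is.na(edges$modality)] <- ""
  edges$sign <- ifelse(edges$r < 0, "neg", "pos")
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a tripartite network to file
#'
#' Supported formats: `"graphml"` (node type/label/modality and edge
#' statistics as attributes; round-trips losslessly through
#' [read_graphml_network()]), `"sif"` (`node  pos|neg  node`, the
#' interaction token given by the sign of r), and `"tsv"` (edge list with
#' statistics).
#'
#' @param net A `tripartite_network`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "sif", "tsv")) {
  stopifnot(inherits(net, "tripartite_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(net$edges)) {
      paste(net$edges$from, ifelse(net$edges$r < 0, "neg", "pos"),
            net$edges$to, sep = "\t")
    } else {
      character(0)
    }
    writeLines(lines, path)
  } else {
    df <- net$edges
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  }
  invisible(path)
}

#' Read back a GraphML export
#'
#' @param path A GraphML file written by [export_graph()].
#' @return A list with `nodes` and `edges` data.frames carrying the same
#'   attributes as the exported network.
#' @export
read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' @describeIn build_network Plot method: force-directed layout with node
#'   colours by block type and dashed edges for negative correlations.
#' @param x,... Plot method arguments.
#' @export
plot.tripartite_network <- function(x, ...) {
  if (!nrow(x$nodes)) {
    plot.new()
    title("empty tripartite network")
    return(invisible(x))
  }
  g <- as_igraph(x)
  cols <- c(metabolite = "#66c2a5", clinical = "#fc8d62", brain = "#8da0cb")
  igraph::V(g)$color <- cols[igraph::V(g)$type]
  igraph::E(g)$lty <- ifelse(igraph::E(g)$sign == "neg", 2, 1)
  graphics::plot(g,
                 vertex.label = igraph::V(g)$label,
                 vertex.label.cex = 0.7, vertex.size = 14,
                 edge.width = 1 + 3 * abs(igraph::E(g)$r), ...)
  invisible(x)
}
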