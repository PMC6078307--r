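# Node centrality metrics on weighted connectivity matrices.
#
# Both indices are computed on the whole network and reported for the ROI
# nodes. Shortest paths use an edge distance that decreases with connection
# weight: d = 1/w by default (d = -log(w) selectable for weights < 1).
# Betweenness is unnormalized, excludes endpoints, counts each unordered
# pair once, and splits credit fractionally across tied shortest paths
# (Brandes convention); path-length ties are compared with tolerance 1e-9.

check_weight_matrix <- function(W) {
  W <- unclass(W)
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be a square matrix")
  if (!all(is.finite(W))) stop("W must be finite")
  if (any(W < 0)) stop("negative weights are not allowed")
  if (max(abs(W - t(W))) > 1e-9) stop("W must be symmetric")
  W
}

node_index <- function(W, node) {
  if (is.character(node)) {
    idx <- match(node, rownames(W))
    if (anyNA(idx)) stop("unknown node label: ", paste(node[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(node)
    if (any(idx < 1 | idx > nrow(W))) stop("node index out of range")
    idx
  }
}

edge_distances <- function(W, distance = c("inverse", "neglog")) {
  distance <- match.arg(distance)
  D <- matrix(Inf, nrow(W), ncol(W))
  pos <- W > 0
  if (distance == "inverse") {
    D[pos] <- 1 / W[pos]
  } else {
    if (any(W[pos] >= 1)) stop("neglog distances require all weights < 1")
    D[pos] <- -log(W[pos])
  }
  diag(D) <- Inf
  D
}

#' Degree strength (weighted degree)
#'
#' Sum of the weights of all edges incident to a node.
#'
#' @param W Symmetric nonnegative weight matrix (zero diagonal).
#' @param node Optional node index or label; all nodes if `NULL`.
#' @return Named numeric vector (or scalar) of strengths.
#' @export
degree_strength <- function(W, node = NULL) {
  W <- check_weight_matrix(W)
  diag(W) <- 0
  s <- rowSums(W)
  names(s) <- rownames(W)
  if (is.null(node)) s else s[node_index(W, node)]
}

#' Betweenness centrality on a weighted graph
#'
#' Unnormalized shortest-path betweenness: for each node, the sum over
#' unordered pairs of other nodes of the fraction of shortest paths between
#' them that pass through the node. Edges with weight 0 are absent;
#' disconnected pairs contribute nothing. Computed by Dijkstra search with
#' Brandes' dependency accumulation.
#'
#' @inheritParams degree_strength
#' @param distance Edge-distance transform: `"inverse"` (d = 1/w, default)
#'   or `"neglog"` (d = -log(w), weights < 1 only).
#' @param tol Tolerance for treating path lengths as tied.
#' @return Named numeric vector (or scalar) of betweenness values.
#' @examples
#' W <- matrix(0, 5, 5)           # star: node 1 is the hub
#' W[1, 2:5] <- W[2:5, 1] <- 1
#' betweenness(W)                 # hub: choose(4, 2) = 6, leaves: 0
#' @export
betweenness <- function(W, node = NULL, distance = "inverse", tol = 1e-9) {
  W <- check_weight_matrix(W)
  bc <- brandes_betweenness_dense(edge_distances(W, distance), tol)
  names(bc) <- rownames(W)
  if (is.null(node)) bc else bc[node_index(W, node)]
}

#' Betweenness by exhaustive path enumeration (test oracle)
#'
#' Enumerates every simple path between every node pair, finds the minimal
#' total distance, and counts tied shortest paths, giving fractional credit
#' to interior nodes. Same contract as [betweenness()] but exponential in
#' the node count; restricted to graphs with at most 9 nodes.
#'
#' @inheritParams betweenness
#' @return Named numeric vector (or scalar) of betweenness values.
#' @export
brute_force_betweenness <- function(W, node = NULL, distance = "inverse",
                                    tol = 1e-9) {
  W <- check_weight_matrix(W)
  n <- nrow(W)
  if (n > 9) stop("graph too large for exhaustive enumeration (> 9 nodes)")
  D <- edge_distances(W, distance)
  bc <- numeric(n)
  if (n >= 2) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        paths <- enumerate_simple_paths(D, s, t)
        if (!length(paths$dist)) next
        dmin <- min(paths$dist)
        sel <- which(paths$dist <= dmin + tol)
        credit <- 1 / length(sel)
        for (j in sel) {
          for (u in paths$interior[[j]]) bc[u] <- bc[u] + credit
        }
      }
    }
  }
  names(bc) <- rownames(W)
  if (is.null(node)) bc else bc[node_index(W, node)]
}

enumerate_simple_paths <- function(D, s, t) {
  n <- nrow(D)
  dists <- numeric(0)
  interior <- list()
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  recurse <- function(u, d, path_interior) {
    for (v in seq_len(n)) {
      if (visited[v] || !is.finite(D[u, v])) next
      if (v == t) {
        dists[[length(dists) + 1]] <<- d + D[u, v]
        interior[[length(interior) + 1]] <<- path_interior
      } else {
        visited[v] <<- TRUE
        recurse(v, d + D[u, v], c(path_interior, v))
        visited[v] <<- FALSE
      }
    }
  }
  recurse(s, 0, integer(0))
  list(dist = dists, interior = interior)
}

#' Node-metric table for a set of connectomes
#'
#' Computes degree strength and betweenness for every ROI node, modality and
#' subject, in long format. Variable labels follow the `metric_hemi_region`
#' scheme (e.g. `B_R_NAcc` = betweenness of the right nucleus accumbens,
#' `S_L_Amg` = strength of the left amygdala). Subjects missing a modality
#' (e.g. an excluded anatomical scan) contribute no rows for it.
#'
#' @param connectomes A `bgm_connectomes` object from [build_connectomes()],
#'   or a list with elements `functional` and/or `anatomical` (named lists of
#'   weight matrices) plus `regions`.
#' @param regions Region table; defaults to `connectomes$regions`.
#' @param rois ROI labels; defaults to the flagged ROIs of `regions`.
#' @param distance Edge-distance transform for betweenness.
#' @return A data.frame: `subject_id`, `modality`, `region`, `metric`
#'   (`"strength"`/`"betweenness"`), `variable`, `value`.
#' @export
metrics_table <- function(connectomes, regions = NULL, rois = NULL,
                          distance = "inverse") {
  if (is.null(regions)) regions <- connectomes$regions
  if (is.null(rois)) rois <- roi_labels(regions)
  idx <- restrict_to_rois(NULL, regions, rois)$roi_indices
  all_subj <- unique(c(names(connectomes$functional), names(connectomes$anatomical)))
  chunks <- list()
  for (mod in c("functional", "anatomical")) {
    mats <- connectomes[[mod]]
    if (!length(mats)) next
    missing <- setdiff(all_subj, names(mats))
    if (length(missing)) {
      message(length(missing), " subject(s) lack a ", mod,
              " matrix and are omitted for that modality: ",
              paste(missing, collapse = ", "))
    }
    for (id in names(mats)) {
      W <- mats[[id]]
      s <- degree_strength(W)[idx]
      b <- betweenness(W, distance = distance)[idx]
      chunks[[length(chunks) + 1]] <- data.frame(
        subject_id = id, modality = mod,
        region = rep(rois, 2),
        metric = rep(c("strength", "betweenness"), each = length(rois)),
        variable = c(paste0("S_", rois), paste0("B_", rois)),
        value = c(s, b), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}
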