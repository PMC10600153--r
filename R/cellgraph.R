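# Multilevel pairwise kNN graphs between cell types and per-cell topology.

.type_letter <- c(tumor = "T", inflammatory = "I", stroma = "S")

#' Canonical labels of the six pairwise graphs
#' @return Character vector: T-T, I-I, S-S, T-I, T-S, I-S.
#' @export
graph_labels <- function() c("T-T", "I-I", "S-S", "T-I", "T-S", "I-S")

# canonical (type1, type2) for a label
#' @keywords internal
label_types <- function(label) {
  lt <- strsplit(label, "-", fixed = TRUE)[[1]]
  rev_map <- stats::setNames(names(.type_letter), .type_letter)
  unname(rev_map[lt])
}

#' @keywords internal
canonical_label <- function(c1, c2) {
  lab <- paste0(.type_letter[[c1]], "-", .type_letter[[c2]])
  if (lab %in% graph_labels()) lab
  else paste0(.type_letter[[c2]], "-", .type_letter[[c1]])
}

#' Build one pairwise cell graph
#'
#' For the typed graph Graph_C1-C2, every cell of type C1 proposes edges to
#' its \code{k} nearest cells of type C2 (Euclidean centroid distance) and,
#' for heterotypic pairs, symmetrically from C2 to C1; proposals longer than
#' \code{threshold_px} are deleted (strict \code{<}) and the union is
#' deduplicated into an undirected edge set. Neighbor searches are within
#' the partner type only, and distance ties are broken by nucleus id order
#' for determinism.
#'
#' @param ns A \code{nucleus_set} (dead/normal cells are ignored).
#' @param c1,c2 Cell types from \code{profiled_types()}.
#' @param k Neighbors per cell (default 5).
#' @param threshold_px Maximum edge length in pixels (default 100, i.e.
#'   25 um at 0.25 um/px).
#' @return An \code{edge_set}: list with \code{graph_label}, \code{edges}
#'   (data.frame source_id, target_id, length_px), \code{types}, \code{k},
#'   \code{threshold_px}.
#' @export
build_pairwise_graph <- function(ns, c1, c2, k = 5, threshold_px = 100) {
  if (!c1 %in% profiled_types() || !c2 %in% profiled_types())
    stop("unknown or unprofiled cell type: ", c1, " / ", c2)
  stopifnot(k >= 1, threshold_px > 0)
  label <- canonical_label(c1, c2)
  tys <- label_types(label)
  a <- ns$cells[ns$cells$type == tys[1], c("id", "x", "y")]
  b <- ns$cells[ns$cells$type == tys[2], c("id", "x", "y")]
  prop <- rbind(knn_proposals(a, b, k, threshold_px, same = tys[1] == tys[2]),
                if (tys[1] != tys[2])
                  knn_proposals(b, a, k, threshold_px, same = FALSE)[, c(2, 1, 3)])
  if (is.null(prop) || nrow(prop) == 0) {
    edges <- data.frame(source_id = character(), target_id = character(),
                        length_px = numeric(), stringsAsFactors = FALSE)
  } else {
    names(prop) <- c("from", "to", "length_px")
    # orient: source on the label's first type side (min id for homotypic)
    if (tys[1] == tys[2]) {
      s <- pmin(prop$from, prop$to); t <- pmax(prop$from, prop$to)
    } else {
      flip <- prop$from %in% b$id
      s <- ifelse(flip, prop$to, prop$from)
      t <- ifelse(flip, prop$from, prop$to)
    }
    key <- paste(s, t, sep = "\r")
    keep <- !duplicated(key)
    edges <- data.frame(source_id = s[keep], target_id = t[keep],
                        length_px = prop$length_px[keep],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$source_id, edges$target_id, method = "radix"), ]
    rownames(edges) <- NULL
  }
  structure(list(graph_label = label, edges = edges, types = tys,
                 k = k, threshold_px = threshold_px),
            class = "edge_set")
}

# directed kNN edge proposals from rows of `a` into candidate set `b`
#' @keywords internal
knn_proposals <- function(a, b, k, threshold_px, same) {
  if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
  bxy <- as.matrix(b[, c("x", "y")])
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    d <- dist_to(c(a$x[i], a$y[i]), bxy)
    ids <- b$id
    if (same) {
      self <- ids == a$id[i]
      d <- d[!self]; ids <- ids[!self]
    }
    if (length(d) == 0) next
    o <- order_dist_id(d, ids)[seq_len(min(k, length(d)))]
    sel <- o[d[o] < threshold_px]
    if (length(sel))
      out[[i]] <- data.frame(from = a$id[i], to = ids[sel],
                             length_px = d[sel], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Combine edge sets into one edge table
#' @param edge_sets List of \code{edge_set} objects.
#' @return data.frame source_id, target_id, graph_label, length_px.
#' @export
combine_edges <- function(edge_sets) {
  tabs <- lapply(edge_sets, function(es) {
    if (nrow(es$edges) == 0)
      return(data.frame(source_id = character(), target_id = character(),
                        graph_label = character(), length_px = numeric(),
                        stringsAsFactors = FALSE))
    data.frame(source_id = es$edges$source_id, target_id = es$edges$target_id,
               graph_label = es$graph_label, length_px = es$edges$length_px,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, tabs)
}

#' Build all six pairwise graphs of a slide
#' @inheritParams build_pairwise_graph
#' @return Named list of \code{edge_set}s, one per \code{graph_labels()}.
#' @export
build_all_graphs <- function(ns, k = 5, threshold_px = 100) {
  out <- lapply(graph_labels(), function(lab) {
    tys <- label_types(lab)
    build_pairwise_graph(ns, tys[1], tys[2], k = k, threshold_px = threshold_px)
  })
  stats::setNames(out, graph_labels())
}

#' Per-cell topological features of one pairwise graph
#'
#' Every cell of the graph's types appears as a vertex (including isolated
#' ones). Features: \code{Nsubgraph} (size of the cell's connected
#' component), \code{MinEdgeLength}/\code{MeanEdgeLength} over incident
#' edges (isolated cells get the threshold value, 100 px, the upper limit of
#' a connectable distance), \code{Degrees}, \code{Coreness} (k-core number),
#' \code{Eccentricity} within the component, \code{Eccentricity_normed}
#' (divided by the component diameter, 0 for singletons),
#' \code{HarmonicCentrality}, \code{Closeness} (0 for isolated cells),
#' \code{Betweenness} and \code{Betweenness_normed} (divided by
#' (n-1)(n-2)/2 within the component, 0 when n < 3), and for homotypic
#' graphs \code{ClusteringCoefficient} (local transitivity, 0 for cells with
#' degree < 2). Heterotypic graphs omit ClusteringCoefficient.
#'
#' @param es An \code{edge_set}.
#' @param ns The \code{nucleus_set} it was built from.
#' @return data.frame keyed by \code{id} with unprefixed topology columns.
#' @export
compute_topology <- function(es, ns) {
  ids <- ns$cells$id[ns$cells$type %in% es$types]
  homotypic <- es$types[1] == es$types[2]
  g <- igraph::graph_from_data_frame(
    es$edges[, c("source_id", "target_id")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  nsub <- comp$csize[comp$membership]
  deg <- igraph::degree(g)
  ecc <- igraph::eccentricity(g, mode = "all")
  diam_by_comp <- tapply(ecc, comp$membership, max)
  diam <- as.numeric(diam_by_comp[as.character(comp$membership)])
  ecc_norm <- ifelse(diam > 0, ecc / diam, 0)
  harm <- igraph::harmonic_centrality(g, mode = "all", normalized = FALSE)
  clo <- suppressWarnings(igraph::closeness(g, mode = "all"))
  clo[!is.finite(clo)] <- 0
  btw <- igraph::betweenness(g, directed = FALSE)
  pairs <- (nsub - 1) * (nsub - 2) / 2
  btw_norm <- ifelse(pairs > 0, btw / pairs, 0)
  core <- igraph::coreness(g)
  # incident edge-length stats; sentinel = threshold for isolated cells
  minl <- rep(es$threshold_px, length(ids))
  meanl <- rep(es$threshold_px, length(ids))
  if (nrow(es$edges) > 0) {
    lens <- c(es$edges$length_px, es$edges$length_px)
    at <- c(es$edges$source_id, es$edges$target_id)
    agg_min <- tapply(lens, at, min)
    agg_mean <- tapply(lens, at, mean)
    hit <- match(ids, names(agg_min))
    minl[!is.na(hit)] <- agg_min[hit[!is.na(hit)]]
    meanl[!is.na(hit)] <- agg_mean[hit[!is.na(hit)]]
  }
  out <- data.frame(
    id = ids, Nsubgraph = as.numeric(nsub),
    MinEdgeLength = as.numeric(minl), MeanEdgeLength = as.numeric(meanl),
    Degrees = as.numeric(deg), Coreness = as.numeric(core),
    Eccentricity = as.numeric(ecc), Eccentricity_normed = as.numeric(ecc_norm),
    HarmonicCentrality = as.numeric(harm), Closeness = as.numeric(clo),
    Betweenness = as.numeric(btw), Betweenness_normed = as.numeric(btw_norm),
    stringsAsFactors = FALSE)
  if (homotypic)
    out$ClusteringCoefficient <- {
      cc <- igraph::transitivity(g, type = "local", isolates = "zero")
      cc[deg < 2] <- 0
      as.numeric(cc)
    }
  rownames(out) <- NULL
  out
}

#' Stromal-barrier feature for inflammatory cells
#'
#' For each inflammatory cell, its \code{k} nearest tumor cells within a
#' search radius are taken and, for every straight segment from the
#' inflammatory cell to such a tumor cell, the stroma-cell centroids lying
#' within a corridor of half-width \code{corridor_px} of the segment are
#' counted. StromaBlocker is the mean count over those segments, and 0 when
#' no tumor cell lies within the radius. This corridor-count definition is a
#' configurable reconstruction of the feature.
#'
#' @param ns A \code{nucleus_set}.
#' @param k Tumor targets per inflammatory cell (default 5).
#' @param radius_px Search radius for tumor cells (default 300).
#' @param corridor_px Corridor half-width (default 15).
#' @return data.frame with columns id (inflammatory cells), StromaBlocker.
#' @export
compute_stroma_blocker <- function(ns, k = 5, radius_px = 300,
                                   corridor_px = 15) {
  infl <- ns$cells[ns$cells$type == "inflammatory", ]
  tum <- ns$cells[ns$cells$type == "tumor", ]
  str <- ns$cells[ns$cells$type == "stroma", ]
  sb <- numeric(nrow(infl))
  txy <- as.matrix(tum[, c("x", "y")])
  sxy <- as.matrix(str[, c("x", "y")])
  for (i in seq_len(nrow(infl))) {
    p <- c(infl$x[i], infl$y[i])
    if (nrow(tum) == 0) next
    d <- dist_to(p, txy)
    within <- d <= radius_px
    if (!any(within)) next
    o <- order_dist_id(d, tum$id)
    o <- o[d[o] <= radius_px][seq_len(min(k, sum(within)))]
    counts <- vapply(o, function(j) {
      if (nrow(str) == 0) return(0)
      sum(segment_distance(sxy, p, txy[j, ]) <= corridor_px)
    }, numeric(1))
    sb[i] <- mean(counts)
  }
  data.frame(id = infl$id, StromaBlocker = sb, stringsAsFactors = FALSE)
}

# distance from points (matrix) to segment a-b
#' @keywords internal
segment_distance <- function(pts, a, b) {
  if (nrow(pts) == 0) return(numeric(0))
  v <- b - a
  L2 <- sum(v^2)
  t <- if (L2 == 0) rep(0, nrow(pts)) else
    pmin(1, pmax(0, ((pts[, 1] - a[1]) * v[1] + (pts[, 2] - a[2]) * v[2]) / L2))
  sqrt((pts[, 1] - (a[1] + t * v[1]))^2 + (pts[, 2] - (a[2] + t * v[2]))^2)
}

# graph membership of each cell type
#' @keywords internal
graphs_of_type <- function(type) {
  switch(type,
         tumor = c("T-T", "T-I", "T-S"),
         inflammatory = c("I-I", "T-I", "I-S"),
         stroma = c("S-S", "T-S", "I-S"))
}

#' Assemble the per-cell feature table of a slide
#'
#' Concatenates, for every tumor, inflammatory and stroma cell, its
#' morphological (and texture) features with the topological features of the
#' three graphs it appears in, prefixed by graph label (e.g.
#' \code{T-I_Degrees}); inflammatory cells additionally carry
#' \code{StromaBlocker}. Columns of graphs a cell does not belong to are NA.
#'
#' @param ns A \code{nucleus_set} (dead cells filtered).
#' @param edge_sets Named list from \code{\link{build_all_graphs}}; built
#'   with defaults when NULL.
#' @param nucleus_features Output of \code{\link{compute_nucleus_features}};
#'   computed when NULL.
#' @param k,threshold_px Graph parameters used when building.
#' @param blocker List of StromaBlocker parameters
#'   (\code{k}, \code{radius_px}, \code{corridor_px}).
#' @return data.frame: id, x, y, cell_type, morphology, texture,
#'   graph-prefixed topology, StromaBlocker.
#' @export
assemble_cell_features <- function(ns, edge_sets = NULL,
                                   nucleus_features = NULL,
                                   k = 5, threshold_px = 100,
                                   blocker = list(k = 5, radius_px = 300,
                                                  corridor_px = 15)) {
  if (is.null(edge_sets)) edge_sets <- build_all_graphs(ns, k, threshold_px)
  if (is.null(nucleus_features)) nucleus_features <- compute_nucleus_features(ns)
  cells <- ns$cells[ns$cells$type %in% profiled_types(), ]
  out <- data.frame(id = cells$id, x = cells$x, y = cells$y,
                    cell_type = cells$type, stringsAsFactors = FALSE)
  m <- match(out$id, nucleus_features$id)
  if (anyNA(m)) stop("nucleus_features does not cover all profiled cells")
  out <- cbind(out, nucleus_features[m, -1, drop = FALSE])
  for (lab in graph_labels()) {
    topo <- compute_topology(edge_sets[[lab]], ns)
    tcols <- setdiff(names(topo), "id")
    block <- as.data.frame(matrix(NA_real_, nrow(out), length(tcols)))
    names(block) <- paste0(lab, "_", tcols)
    hit <- match(out$id, topo$id)
    ok <- !is.na(hit)
    block[ok, ] <- topo[hit[ok], tcols]
    out <- cbind(out, block)
  }
  sb <- compute_stroma_blocker(ns, k = blocker$k, radius_px = blocker$radius_px,
                               corridor_px = blocker$corridor_px)
  out$StromaBlocker <- sb$StromaBlocker[match(out$id, sb$id)]
  rownames(out) <- NULL
  out
}

#' Columns applicable to each profiled cell type
#'
#' Used when writing per-type tables: each type keeps id, x, y, the
#' morphology/texture features and the topology of its own three graphs;
#' StromaBlocker is inflammatory-only.
#'
#' @param features Assembled feature table.
#' @param type One of \code{profiled_types()}.
#' @return Character vector of column names.
#' @export
feature_columns_for_type <- function(features, type) {
  labs <- graphs_of_type(type)
  keep <- c("id", "x", "y",
            intersect(c(morphology_feature_names(), texture_feature_names()),
                      names(features)))
  topo <- names(features)[grepl("^[TIS]-[TIS]_", names(features))]
  topo <- topo[sub("_.*$", "", topo) %in% labs]
  keep <- c(keep, topo)
  if (type == "inflammatory" && "StromaBlocker" %in% names(features))
    keep <- c(keep, "StromaBlocker")
  keep
}
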