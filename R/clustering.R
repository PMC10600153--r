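# Per-type cell sampling, preprocessing, Leiden clustering, fixed-membership
# extrapolation and cluster-abundance summaries.

.type_prefix <- c(tumor = "TUM", inflammatory = "INF", stroma = "STR")

#' Subsample cells per slide and pool them
#'
#' Uniform without-replacement sampling of a fixed fraction of cells from
#' each slide (at least one cell per nonempty slide), pooled with a
#' slide-of-origin column. The discovery-cohort default fraction is 0.005
#' (0.5 percent); validation cohorts conventionally use 0.10.
#'
#' @param tables Named list (by slide id) of per-cell feature data.frames
#'   with an \code{id} column.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return One pooled data.frame with a leading \code{slide_id} column.
#' @export
sample_cells <- function(tables, fraction = 0.005, seed = 0) {
  stopifnot(fraction > 0, fraction <= 1)
  set.seed(seed)
  out <- lapply(names(tables), function(sid) {
    tab <- tables[[sid]]
    n <- nrow(tab)
    if (n == 0) return(NULL)
    m <- max(1L, round(n * fraction))
    take <- sort(sample.int(n, m))
    cbind(data.frame(slide_id = sid, stringsAsFactors = FALSE),
          tab[take, , drop = FALSE])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Preprocess a feature matrix for clustering
#'
#' Columns containing missing values are dropped (texture columns when no
#' image was supplied), each feature is shifted by its pooled minimum where
#' negative so log1p is defined, log1p-transformed, centered and scaled to
#' unit variance (zero-variance features dropped with a warning), and
#' projected onto the leading principal components. All parameters are
#' stored so the identical transform can be re-applied.
#'
#' @param mat Numeric matrix or data.frame of cells x features.
#' @param n_pcs Number of principal components (default 50, capped at
#'   feature count - 1 and cell count - 1).
#' @return List of class \code{preprocess_model}: \code{scores} (cells x
#'   PCs), \code{scaled}, \code{features}, \code{shift}, \code{center},
#'   \code{scale}, \code{rotation}.
#' @export
preprocess_features <- function(mat, n_pcs = 50) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("F", seq_len(ncol(mat)))
  keep <- colSums(!is.finite(mat)) == 0
  if (!all(keep))
    warning("dropping ", sum(!keep), " features with missing values: ",
            paste(utils::head(colnames(mat)[!keep]), collapse = ", "))
  mat <- mat[, keep, drop = FALSE]
  shift <- pmin(apply(mat, 2, min), 0)
  lg <- log1p(sweep(mat, 2, shift))
  ctr <- colMeans(lg)
  scl <- apply(lg, 2, stats::sd)
  zv <- scl < 1e-12
  if (any(zv)) {
    warning("dropping ", sum(zv), " zero-variance features: ",
            paste(utils::head(colnames(mat)[zv]), collapse = ", "))
    lg <- lg[, !zv, drop = FALSE]
    shift <- shift[!zv]; ctr <- ctr[!zv]; scl <- scl[!zv]
  }
  if (ncol(lg) == 0) stop("no usable features after preprocessing")
  sc <- sweep(sweep(lg, 2, ctr), 2, scl, "/")
  k <- min(n_pcs, ncol(sc) - 1, nrow(sc) - 1)
  k <- max(k, 1)
  pc <- stats::prcomp(sc, center = FALSE, scale. = FALSE, rank. = k)
  structure(list(scores = pc$x, scaled = sc, features = colnames(sc),
                 shift = shift, center = ctr, scale = scl,
                 rotation = pc$rotation, n_pcs = k),
            class = "preprocess_model")
}

# kNN similarity graph (undirected union) in a reduced space
#' @keywords internal
knn_graph <- function(x, k = 15) {
  n <- nrow(x)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(x))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    o <- order(d[i, -i])[seq_len(k)]
    nb <- setdiff(seq_len(n), i)[o]
    from <- c(from, rep(i, k)); to <- c(to, nb)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::simplify(g)
}

#' Leiden clustering of a reduced feature matrix
#'
#' Builds an unweighted k-nearest-neighbor graph in the reduced space and
#' partitions it with the Leiden algorithm (modularity objective).
#' Deterministic for a fixed seed.
#'
#' @param reduced Cells x dimensions matrix (e.g. PCA scores).
#' @param resolution Leiden resolution (default 1).
#' @param seed Integer seed.
#' @param nn_k Neighbors of the graph (default 15).
#' @param cell_type Optional cell type; sets the cluster-name prefix
#'   (tumor TUM, inflammatory INF, stroma STR).
#' @param preprocess Optional \code{preprocess_model} to store in the model.
#' @return List of class \code{cluster_model}: \code{labels} (integer,
#'   0-based, ordered by decreasing cluster size), \code{cluster_names},
#'   \code{reference}, \code{preprocess}, parameters.
#' @export
leiden_cluster <- function(reduced, resolution = 1, seed = 0, nn_k = 15,
                           cell_type = NULL, preprocess = NULL) {
  reduced <- as.matrix(reduced)
  stopifnot(nrow(reduced) >= 2)
  g <- knn_graph(reduced, nn_k)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  raw <- as.integer(igraph::membership(cl))
  # relabel 0-based by decreasing size (stable by first occurrence on ties)
  sizes <- table(raw)
  ord <- names(sizes)[order(-as.integer(sizes), as.integer(names(sizes)))]
  labels <- match(as.character(raw), ord) - 1L
  prefix <- if (!is.null(cell_type)) .type_prefix[[cell_type]] else "C"
  structure(list(cell_type = cell_type, labels = labels,
                 cluster_names = paste0(prefix, sort(unique(labels))),
                 reference = reduced,
                 scaled = preprocess$scaled %||% reduced,
                 preprocess = preprocess,
                 nn_k = nn_k, resolution = resolution, seed = seed,
                 prefix = prefix),
            class = "cluster_model")
}

#' Fit a cluster model from raw features
#'
#' Convenience wrapper: \code{\link{preprocess_features}} then
#' \code{\link{leiden_cluster}}.
#'
#' @param mat Cells x features matrix (raw feature values).
#' @param cell_type Optional type for cluster naming.
#' @inheritParams leiden_cluster
#' @inheritParams preprocess_features
#' @return A \code{cluster_model}.
#' @export
fit_cluster_model <- function(mat, cell_type = NULL, resolution = 1,
                              seed = 0, n_pcs = 50, nn_k = 15) {
  pp <- preprocess_features(mat, n_pcs = n_pcs)
  leiden_cluster(pp$scores, resolution = resolution, seed = seed,
                 nn_k = nn_k, cell_type = cell_type, preprocess = pp)
}

#' Cluster labels as names (e.g. INF0, INF1, ...)
#' @param model A \code{cluster_model}.
#' @param labels Optional integer labels; default the model's own.
#' @return Character vector.
#' @export
cluster_label_names <- function(model, labels = model$labels) {
  paste0(model$prefix, labels)
}

#' Extrapolate a fixed clustering onto new cells
#'
#' Joint clustering over the reference and new cells in which the reference
#' memberships are held fixed and only the new cells may move, so every new
#' cell receives exactly one existing cluster label. The new cohort is
#' preprocessed with its own log/scale statistics over the model's feature
#' set (the reference parameters can be reused via
#' \code{reuse_reference_scaling}), the joint reduced space is recomputed on
#' the concatenated scaled matrix, and a seeded constrained local-move pass
#' (modularity gain on the joint kNN graph, reference vertices frozen)
#' assigns new cells, starting from random existing labels and iterating to
#' convergence.
#'
#' @param model A \code{cluster_model}.
#' @param new_mat New cells x features matrix sharing the model's feature
#'   schema (superset of columns allowed).
#' @param seed Integer seed.
#' @param reuse_reference_scaling Apply the reference shift/center/scale
#'   instead of the new cohort's own statistics.
#' @return Integer labels for the new cells (same coding as
#'   \code{model$labels}).
#' @export
extrapolate_clusters <- function(model, new_mat, seed = 0,
                                 reuse_reference_scaling = FALSE) {
  new_mat <- as.matrix(new_mat)
  if (is.null(colnames(new_mat)))
    colnames(new_mat) <- paste0("F", seq_len(ncol(new_mat)))
  pp <- model$preprocess
  if (is.null(pp)) stop("model carries no preprocessing parameters")
  missing_feats <- setdiff(pp$features, colnames(new_mat))
  if (length(missing_feats))
    stop("new cells lack model features: ",
         paste(utils::head(missing_feats), collapse = ", "))
  x <- new_mat[, pp$features, drop = FALSE]
  if (reuse_reference_scaling) {
    lg <- log1p(sweep(x, 2, pp$shift))
    sc <- sweep(sweep(lg, 2, pp$center), 2, pp$scale, "/")
  } else {
    shift <- pmin(apply(x, 2, min), 0)
    lg <- log1p(sweep(x, 2, shift))
    ctr <- colMeans(lg)
    scl <- apply(lg, 2, stats::sd)
    scl[scl < 1e-12] <- 1
    sc <- sweep(sweep(lg, 2, ctr), 2, scl, "/")
  }
  joint <- rbind(model$scaled, sc)
  k <- min(ncol(joint) - 1, nrow(joint) - 1, pp$n_pcs %||% 50)
  red <- stats::prcomp(joint, center = FALSE, scale. = FALSE, rank. = max(k, 1))$x
  n_ref <- nrow(model$scaled)
  n_new <- nrow(sc)
  g <- knn_graph(red, model$nn_k)
  labels <- c(model$labels, rep(NA_integer_, n_new))
  existing <- sort(unique(model$labels))
  set.seed(seed)
  labels[n_ref + seq_len(n_new)] <- sample(existing, n_new, replace = TRUE)
  adj <- igraph::as_adj_list(g, mode = "all")
  deg <- igraph::degree(g)
  two_m <- 2 * igraph::ecount(g)
  ktot <- vapply(existing, function(cl) sum(deg[labels == cl]), numeric(1))
  names(ktot) <- existing
  for (pass in seq_len(50)) {
    moved <- 0L
    for (v in n_ref + seq_len(n_new)) {
      nb <- as.integer(adj[[v]])
      if (length(nb) == 0) next
      cur <- labels[v]
      nb_lab <- labels[nb]
      cand <- sort(unique(c(cur, nb_lab)))
      e_in <- vapply(cand, function(cl) sum(nb_lab == cl), numeric(1))
      kc <- ktot[as.character(cand)]
      kc[cand == cur] <- kc[cand == cur] - deg[v]
      gain <- e_in - model$resolution * deg[v] * kc / two_m
      best <- cand[which.max(gain)]
      if (best != cur) {
        ktot[as.character(cur)] <- ktot[as.character(cur)] - deg[v]
        ktot[as.character(best)] <- ktot[as.character(best)] + deg[v]
        labels[v] <- best
        moved <- moved + 1L
      }
    }
    if (moved == 0L) break
  }
  labels[n_ref + seq_len(n_new)]
}

#' Within-type cluster abundance per sample
#'
#' Fraction of each sample's cells (of one type) falling in each cluster;
#' rows sum to 1 for samples with at least one cell.
#'
#' @param sample_ids Character vector, one entry per cell.
#' @param labels Cluster labels per cell (any atomic type).
#' @param all_clusters Optional fixed cluster universe for the columns.
#' @return Numeric matrix samples x clusters of fractions.
#' @export
cluster_abundance <- function(sample_ids, labels, all_clusters = NULL) {
  stopifnot(length(sample_ids) == length(labels))
  labs <- as.character(labels)
  lev <- all_clusters %||% sort(unique(labs))
  tab <- table(factor(sample_ids), factor(labs, levels = lev))
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  sweep(m, 1, rowSums(m), "/")
}

#' Aggregated inflammatory cell abundance (AIC) score
#'
#' Sum of the abundances of the locally aggregated inflammatory cell
#' clusters (by default INF0, INF1, INF6, INF7) per sample. Samples with no
#' inflammatory cells yield NA.
#'
#' @param abundance Samples x clusters abundance matrix (rows sum to 1), or
#'   a single named row.
#' @param clusters Names of the aggregated clusters.
#' @return Named numeric vector in [0, 1].
#' @export
aic_score <- function(abundance, clusters = c("INF0", "INF1", "INF6", "INF7")) {
  if (is.null(dim(abundance))) abundance <- t(as.matrix(abundance))
  present <- intersect(clusters, colnames(abundance))
  s <- if (length(present))
    rowSums(abundance[, present, drop = FALSE]) else
    stats::setNames(rep(0, nrow(abundance)), rownames(abundance))
  s[!is.finite(rowSums(abundance, na.rm = FALSE))] <- NA_real_
  s
}
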