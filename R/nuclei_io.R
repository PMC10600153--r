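# Data model for segmented nuclei and the segmentation JSON dialect.

#' Nuclear cell types
#'
#' The five-class nuclear taxonomy used throughout: tumor, inflammatory,
#' stroma, normal (non-neoplastic epithelial) and dead (necrotic).
#' Feature profiling and graph construction are restricted to
#' \code{profiled_types()}; normal cells are kept for composition summaries
#' only and dead cells are excluded from all analyses.
#'
#' @return Character vector of type names.
#' @export
cell_types <- function() c("tumor", "inflammatory", "stroma", "normal", "dead")

#' @rdname cell_types
#' @export
profiled_types <- function() c("tumor", "inflammatory", "stroma")

# segmentation integer codes (PanNuke convention)
.type_codes <- c(tumor = 1L, inflammatory = 2L, stroma = 3L, dead = 4L, normal = 5L)

#' Construct a set of segmented nuclei for one slide
#'
#' The central container of the package: per-nucleus centroids, bounding
#' boxes, cell types and contour polygons, plus slide metadata. Coordinates
#' are 0-based pixels, x rightward, y downward; all distances are Euclidean
#' in pixels.
#'
#' @param slide_id Slide identifier.
#' @param cells data.frame with columns \code{id} (unique character),
#'   \code{x}, \code{y} (centroid, px), \code{xmin}, \code{ymin},
#'   \code{xmax}, \code{ymax} (bounding box, px) and \code{type}
#'   (one of \code{cell_types()}).
#' @param contours Named list (by id) of n x 2 matrices of polygon vertices
#'   (x, y), at least 3 per nucleus.
#' @param mpp Microns per pixel; default 0.25 so that 100 px = 25 um.
#' @param patches Optional named list (by id) of integer grayscale matrices
#'   (rows = y, cols = x) cropped to each nucleus bounding box; used for
#'   texture features.
#' @return An object of class \code{nucleus_set}.
#' @export
nucleus_set <- function(slide_id, cells, contours, mpp = 0.25, patches = NULL) {
  stopifnot(is.character(slide_id), length(slide_id) == 1, mpp > 0)
  cells$id <- as.character(cells$id)
  if (anyDuplicated(cells$id)) stop("nucleus ids must be unique within a slide")
  bad_type <- setdiff(unique(cells$type), cell_types())
  if (length(bad_type)) stop("unknown cell type: ", paste(bad_type, collapse = ", "))
  if (!setequal(names(contours), cells$id) && nrow(cells) > 0)
    stop("contours must be named by nucleus id and cover every nucleus")
  contours <- contours[cells$id]
  for (i in seq_along(contours)) {
    ct <- contours[[i]]
    if (!is.matrix(ct) || ncol(ct) != 2 || nrow(ct) < 3)
      stop("contour of nucleus ", cells$id[i], " must be an n x 2 matrix with n >= 3")
  }
  if (!is.null(patches)) patches <- patches[intersect(names(patches), cells$id)]
  structure(
    list(slide_id = slide_id, mpp = mpp, cells = cells,
         contours = contours, patches = patches),
    class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat("<nucleus_set> slide", x$slide_id, "-", nrow(x$cells), "nuclei, mpp",
      x$mpp, "\n")
  if (nrow(x$cells)) print(table(x$cells$type))
  invisible(x)
}

#' Number of nuclei in a set
#' @param ns A \code{nucleus_set}.
#' @return Integer count.
#' @export
n_cells <- function(ns) nrow(ns$cells)

#' Read a segmentation JSON file into a nucleus_set
#'
#' Consumes the per-nucleus record dialect emitted by nuclear
#' segmentation/classification networks: a JSON map from nucleus id to
#' \code{{bbox, centroid, contour, type}}, where \code{centroid} is
#' \code{[x, y]}, \code{bbox} is \code{[xmin, ymin, xmax, ymax]},
#' \code{contour} is a list of \code{[x, y]} vertices and \code{type} is an
#' integer code (1 tumor, 2 inflammatory, 3 stroma, 4 dead, 5 normal).
#' Code 0 (unlabelled) records are dropped with a warning giving the count.
#'
#' @param path Path to the JSON file.
#' @param slide_id Slide identifier; default the file name without extension.
#' @param mpp Microns per pixel.
#' @return A \code{nucleus_set}.
#' @export
read_segmentation <- function(path, slide_id = NULL,
                              mpp = 0.25) {
  if (!file.exists(path)) stop("file not found: ", path)
  slide_id <- slide_id %||% sub("\\.[^.]*$", "", basename(path))
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(recs) == 0) {
    return(nucleus_set(slide_id, empty_cells_df(), list(), mpp = mpp))
  }
  code2type <- stats::setNames(names(.type_codes), .type_codes)
  n <- length(recs)
  ids <- names(recs)
  rows <- vector("list", n)
  contours <- vector("list", n)
  keep <- logical(n)
  n_dropped <- 0L
  for (i in seq_len(n)) {
    r <- recs[[i]]
    id <- ids[i]
    if (is.null(r$centroid) || is.null(r$contour) || is.null(r$bbox) ||
        is.null(r$type))
      stop("malformed record for nucleus ", id,
           ": needs bbox, centroid, contour, type")
    code <- as.integer(r$type)
    if (code == 0L) { n_dropped <- n_dropped + 1L; next }
    if (!code %in% .type_codes)
      stop("unknown type code ", code, " for nucleus ", id)
    ct <- do.call(rbind, lapply(r$contour, function(v) as.numeric(v)))
    if (is.null(ct) || ncol(ct) != 2 || nrow(ct) < 3)
      stop("malformed contour for nucleus ", id)
    bb <- as.numeric(unlist(r$bbox))
    cen <- as.numeric(unlist(r$centroid))
    rows[[i]] <- data.frame(
      id = id, x = cen[1], y = cen[2],
      xmin = bb[1], ymin = bb[2], xmax = bb[3], ymax = bb[4],
      type = unname(code2type[as.character(code)]),
      stringsAsFactors = FALSE)
    contours[[i]] <- ct
    keep[i] <- TRUE
  }
  if (n_dropped > 0)
    warning("dropped ", n_dropped, " unlabelled (type 0) nuclei")
  if (!any(keep)) return(nucleus_set(slide_id, empty_cells_df(), list(), mpp = mpp))
  cells <- do.call(rbind, rows[keep])
  contours <- stats::setNames(contours[keep], cells$id)
  nucleus_set(slide_id, cells, contours, mpp = mpp)
}

#' @keywords internal
empty_cells_df <- function() {
  data.frame(id = character(), x = numeric(), y = numeric(),
             xmin = numeric(), ymin = numeric(), xmax = numeric(),
             ymax = numeric(), type = character(), stringsAsFactors = FALSE)
}

#' Write a nucleus_set back to the segmentation JSON dialect
#'
#' Inverse of \code{\link{read_segmentation}}; a written set reads back
#' identically (id, centroid, contour, bbox, type).
#'
#' @param ns A \code{nucleus_set}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_segmentation <- function(ns, path) {
  recs <- lapply(seq_len(nrow(ns$cells)), function(i) {
    r <- ns$cells[i, ]
    ct <- ns$contours[[r$id]]
    list(bbox = c(r$xmin, r$ymin, r$xmax, r$ymax),
         centroid = c(r$x, r$y),
         contour = lapply(seq_len(nrow(ct)), function(j) ct[j, ]),
         type = unname(.type_codes[[r$type]]))
  })
  names(recs) <- ns$cells$id
  jsonlite::write_json(recs, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Remove necrotic (dead) nuclei
#'
#' Dead nuclei are excluded from all profiling; this filter is idempotent and
#' order-stable.
#'
#' @param ns A \code{nucleus_set}.
#' @return A \code{nucleus_set} without dead cells.
#' @export
filter_non_necrotic <- function(ns) {
  keep <- ns$cells$type != "dead"
  subset_ns(ns, keep)
}

#' @keywords internal
subset_ns <- function(ns, keep) {
  cells <- ns$cells[keep, , drop = FALSE]
  rownames(cells) <- NULL
  nucleus_set(ns$slide_id, cells, ns$contours[cells$id], mpp = ns$mpp,
              patches = if (!is.null(ns$patches)) ns$patches[intersect(names(ns$patches), cells$id)])
}

#' Cell composition of a slide
#'
#' Counts and percentages of tumor, inflammatory, stroma and normal cells.
#' Percentages are over the non-necrotic total; with zero cells the
#' percentages are NA and the summary is flagged undefined.
#'
#' @param ns A \code{nucleus_set} (dead cells are ignored if present).
#' @return List with \code{counts}, \code{percent} (both named by type),
#'   \code{total} and \code{defined}.
#' @export
compute_composition <- function(ns) {
  types <- setdiff(cell_types(), "dead")
  tab <- table(factor(ns$cells$type[ns$cells$type != "dead"], levels = types))
  counts <- stats::setNames(as.integer(tab), types)
  total <- sum(counts)
  percent <- if (total > 0) 100 * counts / total else stats::setNames(rep(NA_real_, length(types)), types)
  list(counts = counts, percent = percent, total = total, defined = total > 0)
}

#' Write the four per-slide feature/edge tables
#'
#' The per-slide output contract: one feature table per profiled cell type
#' (tumor, inflammatory, stroma; columns id, x, y then all features) and one
#' edge table (source_id, target_id, graph_label, length_px). Files are CSV
#' and re-read losslessly by \code{\link{read_feature_tables}}.
#'
#' @param ns A \code{nucleus_set}.
#' @param features Per-cell feature data.frame with an \code{id} column, as
#'   produced by \code{\link{assemble_cell_features}}.
#' @param edges Edge data.frame (or a list of \code{edge_set}s) with columns
#'   source_id, target_id, graph_label, length_px.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_feature_tables <- function(ns, features, edges, out_dir) {
  if (!all(features$id %in% ns$cells$id))
    stop("feature rows reference unknown nucleus ids: ",
         paste(utils::head(setdiff(features$id, ns$cells$id)), collapse = ", "))
  if (is.list(edges) && !is.data.frame(edges)) edges <- combine_edges(edges)
  eids <- unique(c(edges$source_id, edges$target_id))
  if (!all(eids %in% ns$cells$id))
    stop("edge rows reference unknown nucleus ids")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tumor = file.path(out_dir, paste0(ns$slide_id, "_tumor.csv")),
             inflammatory = file.path(out_dir, paste0(ns$slide_id, "_inflammatory.csv")),
             stroma = file.path(out_dir, paste0(ns$slide_id, "_stroma.csv")),
             edges = file.path(out_dir, paste0(ns$slide_id, "_edges.csv")))
  type_of <- stats::setNames(ns$cells$type, ns$cells$id)
  for (ty in profiled_types()) {
    tab <- features[type_of[features$id] == ty, , drop = FALSE]
    cols <- intersect(feature_columns_for_type(features, ty), names(features))
    data.table::fwrite(tab[, cols, drop = FALSE], paths[[ty]])
  }
  data.table::fwrite(edges[, c("source_id", "target_id", "graph_label", "length_px")],
                     paths[["edges"]])
  invisible(paths)
}

#' Read back the four per-slide tables
#' @param out_dir Directory written by \code{\link{write_feature_tables}}.
#' @param slide_id Slide identifier used in the file names.
#' @return List with \code{tumor}, \code{inflammatory}, \code{stroma} and
#'   \code{edges} data.frames.
#' @export
read_feature_tables <- function(out_dir, slide_id) {
  rd <- function(f) {
    t <- as.data.frame(data.table::fread(
      file.path(out_dir, paste0(slide_id, "_", f, ".csv")),
      colClasses = list(character = 1)))
    for (j in setdiff(names(t), "id")) t[[j]] <- as.numeric(t[[j]])
    t
  }
  out <- list(tumor = rd("tumor"), inflammatory = rd("inflammatory"),
              stroma = rd("stroma"))
  e <- as.data.frame(data.table::fread(
    file.path(out_dir, paste0(slide_id, "_edges.csv")),
    colClasses = list(character = c("source_id", "target_id", "graph_label"))))
  e$length_px <- as.numeric(e$length_px)
  out$edges <- e
  out
}

#' Exhaustive nearest-neighbor query by centroid distance
#'
#' Returns the ids of the \code{k} nuclei nearest to a given nucleus
#' (excluding itself), sorted by Euclidean centroid distance with ties broken
#' by id order.
#'
#' @param ns A \code{nucleus_set}.
#' @param id Query nucleus id.
#' @param k Number of neighbors.
#' @param type Optional cell type restricting the candidate set.
#' @return data.frame with columns \code{id} and \code{dist}.
#' @export
nearest_neighbors <- function(ns, id, k, type = NULL) {
  stopifnot(id %in% ns$cells$id)
  cand <- ns$cells[ns$cells$id != id, , drop = FALSE]
  if (!is.null(type)) cand <- cand[cand$type == type, , drop = FALSE]
  if (nrow(cand) == 0) return(data.frame(id = character(), dist = numeric()))
  p <- unlist(ns$cells[ns$cells$id == id, c("x", "y")])
  d <- dist_to(p, as.matrix(cand[, c("x", "y")]))
  o <- order_dist_id(d, cand$id)[seq_len(min(k, nrow(cand)))]
  data.frame(id = cand$id[o], dist = d[o], stringsAsFactors = FALSE)
}
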