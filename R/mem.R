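# Spot tessellation, multivariate spatial correlation, Moran's I and
# micro-ecological module (MEM) discovery.

#' Tessellate a slide into square spots and count cells per cluster
#'
#' Non-overlapping square spots of side \code{spot_um} (default 200 um).
#' Each cell at pixel (x, y) falls in spot (floor(y/s), floor(x/s)) with
#' s = spot_um / mpp pixels; intervals are half-open, so a cell exactly on a
#' boundary belongs to the higher-index spot. The grid covers the whole
#' slide rectangle, so empty spots are retained (they become Module0_NC at
#' scoring time).
#'
#' @param cells data.frame with columns \code{x}, \code{y} (px) and
#'   \code{cluster} (label per cell).
#' @param spot_um Spot side length in microns.
#' @param mpp Microns per pixel.
#' @param slide_px Optional \code{c(width, height)} in pixels fixing the
#'   grid extent; default the cells' extent.
#' @param slide_id Slide identifier.
#' @param clusters Optional fixed cluster universe for the count columns.
#' @return List of class \code{spot_matrix}: \code{counts} (spots x
#'   clusters), \code{spots} (row, col, center_x, center_y), grid dims,
#'   \code{spot_px}.
#' @export
tessellate <- function(cells, spot_um = 200, mpp = 0.25, slide_px = NULL,
                       slide_id = "slide", clusters = NULL) {
  stopifnot(spot_um > 0, mpp > 0)
  s <- spot_um / mpp
  if (is.null(slide_px)) {
    slide_px <- c(max(cells$x, 0) + 1e-9, max(cells$y, 0) + 1e-9)
  }
  ncol_g <- max(1L, ceiling(slide_px[1] / s))
  nrow_g <- max(1L, ceiling(slide_px[2] / s))
  row <- pmin(floor(cells$y / s), nrow_g - 1)
  col <- pmin(floor(cells$x / s), ncol_g - 1)
  lev <- clusters %||% sort(unique(as.character(cells$cluster)))
  spot_idx <- row * ncol_g + col  # row-major spot index, 0-based
  all_spots <- 0:(nrow_g * ncol_g - 1)
  tab <- table(factor(spot_idx, levels = all_spots),
               factor(as.character(cells$cluster), levels = lev))
  counts <- matrix(as.numeric(tab), length(all_spots), length(lev),
                   dimnames = list(NULL, lev))
  spots <- data.frame(row = all_spots %/% ncol_g, col = all_spots %% ncol_g)
  spots$center_x <- (spots$col + 0.5) * s
  spots$center_y <- (spots$row + 0.5) * s
  structure(list(slide_id = slide_id, spot_px = s, spot_um = spot_um,
                 mpp = mpp, nrow = nrow_g, ncol = ncol_g,
                 counts = counts, spots = spots),
            class = "spot_matrix")
}

#' Rook-adjacency spatial weights of a spot grid
#'
#' Binary weights: w_ij = 1 when spot j is one of the (up to four)
#' orthogonal grid neighbors of spot i, 0 otherwise; w_ii = 0. Symmetric.
#'
#' @param sm A \code{spot_matrix}.
#' @return List of class \code{spatial_weights}: \code{w} (matrix),
#'   \code{W} (sum of weights), \code{scheme}.
#' @export
spot_weights_rook <- function(sm) {
  n <- nrow(sm$spots)
  w <- matrix(0, n, n)
  idx <- function(r, c) r * sm$ncol + c + 1
  for (i in seq_len(n)) {
    r <- sm$spots$row[i]; c <- sm$spots$col[i]
    if (r > 0) w[i, idx(r - 1, c)] <- 1
    if (r < sm$nrow - 1) w[i, idx(r + 1, c)] <- 1
    if (c > 0) w[i, idx(r, c - 1)] <- 1
    if (c < sm$ncol - 1) w[i, idx(r, c + 1)] <- 1
  }
  structure(list(w = w, W = sum(w), scheme = "rook"),
            class = "spatial_weights")
}

#' Multivariate spatial correlation of two spot fields
#'
#' Wartenberg-style bivariate extension of Moran's I:
#' C = (N_s / W) * sum_ij w_ij (x_i - xbar)(y_j - ybar) /
#'     ( sqrt(sum (x - xbar)^2) * sqrt(sum (y - ybar)^2) ).
#' With y = x this equals Moran's I. When either field has zero variance
#' the value is 0 and the \code{degenerate} attribute is TRUE.
#'
#' @param x,y Numeric spot fields (same length and ordering as the weights).
#' @param w A \code{spatial_weights}.
#' @return Scalar with attribute \code{degenerate}.
#' @export
spatial_correlation <- function(x, y, w) {
  n <- length(x)
  stopifnot(length(y) == n, nrow(w$w) == n, n >= 2)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0 || w$W == 0)
    return(structure(0, degenerate = TRUE))
  val <- (n / w$W) * as.numeric(t(xc) %*% w$w %*% yc) / (sx * sy)
  structure(val, degenerate = FALSE)
}

#' Moran's I of a spot field
#'
#' I = (N_s / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2 with binary neighbor weights. Near 1: aggregated; near 0:
#' random; near -1: checkerboard. Zero-variance fields give 0 with the
#' \code{degenerate} attribute set.
#'
#' @param x Numeric spot field.
#' @param w A \code{spatial_weights}.
#' @return Scalar with attribute \code{degenerate}.
#' @export
morans_i <- function(x, w) {
  n <- length(x)
  stopifnot(nrow(w$w) == n, n >= 2)
  xc <- x - mean(x)
  s2 <- sum(xc^2)
  if (s2 == 0 || w$W == 0) return(structure(0, degenerate = TRUE))
  structure((n / w$W) * as.numeric(t(xc) %*% w$w %*% xc) / s2,
            degenerate = FALSE)
}

#' All pairwise cluster-cluster spatial correlations of one slide
#'
#' @param sm A \code{spot_matrix}.
#' @param w Optional \code{spatial_weights}; rook adjacency by default.
#' @return List with \code{C} (clusters x clusters) and \code{defined}
#'   (logical matrix; FALSE where a field was degenerate).
#' @export
spatial_correlation_matrix <- function(sm, w = NULL) {
  if (is.null(w)) w <- spot_weights_rook(sm)
  cl <- colnames(sm$counts)
  k <- length(cl)
  C <- matrix(0, k, k, dimnames = list(cl, cl))
  D <- matrix(TRUE, k, k, dimnames = list(cl, cl))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    v <- spatial_correlation(sm$counts[, i], sm$counts[, j], w)
    C[i, j] <- as.numeric(v)
    D[i, j] <- !attr(v, "degenerate")
  }
  list(C = C, defined = D)
}

#' Discover micro-ecological modules from per-sample correlation matrices
#'
#' The per-sample cluster x cluster spatial-correlation matrices are
#' averaged element-wise (degenerate entries ignored), symmetrized as
#' (C + t(C))/2, and the clusters are grouped by Ward hierarchical
#' clustering of the matrix rows (Euclidean distance between correlation
#' profiles), cut into \code{n_modules} modules.
#'
#' @param corr_list List of outputs of
#'   \code{\link{spatial_correlation_matrix}} (one per sample), or plain
#'   matrices.
#' @param n_modules Number of modules (default 8).
#' @param module_names Optional names; default Module1..ModuleK.
#' @return List of class \code{mem_model}: \code{mean_corr}, \code{tree},
#'   \code{modules} (named cluster -> module map), \code{n_modules}.
#' @export
build_mem_model <- function(corr_list, n_modules = 8, module_names = NULL) {
  stopifnot(length(corr_list) >= 1)
  norm <- lapply(corr_list, function(x) {
    if (is.list(x) && !is.null(x$C)) x
    else list(C = as.matrix(x),
              defined = matrix(TRUE, nrow(x), ncol(x), dimnames = dimnames(x)))
  })
  cl <- colnames(norm[[1]]$C)
  acc <- matrix(0, length(cl), length(cl), dimnames = list(cl, cl))
  cnt <- acc
  for (x in norm) {
    ok <- x$defined
    acc[ok] <- acc[ok] + x$C[ok]
    cnt <- cnt + ok
  }
  if (any(cnt == 0)) {
    bad <- which(cnt == 0, arr.ind = TRUE)
    stop("no defined correlation for cluster pair(s): ",
         paste(utils::head(paste(cl[bad[, 1]], cl[bad[, 2]], sep = "~")),
               collapse = ", "))
  }
  mean_corr <- acc / cnt
  mean_corr <- (mean_corr + t(mean_corr)) / 2
  n_modules <- min(n_modules, length(cl))
  tree <- stats::hclust(stats::dist(mean_corr), method = "ward.D2")
  cut <- stats::cutree(tree, k = n_modules)
  module_names <- module_names %||% paste0("Module", seq_len(n_modules))
  modules <- stats::setNames(module_names[cut], cl)
  structure(list(mean_corr = mean_corr, tree = tree, modules = modules,
                 n_modules = n_modules, module_names = module_names),
            class = "mem_model")
}

#' Score spots against a MEM model and assign each spot a module
#'
#' Per spot and module the score is the fraction of the spot's cells whose
#' cluster belongs to the module; scores over all modules sum to 1 for
#' nonempty spots. Each spot is assigned the module of its maximum score
#' (ties to the first module in model order); spots with no cells are
#' assigned \code{Module0_NC}.
#'
#' @param sm A \code{spot_matrix} whose clusters are covered by the model.
#' @param mm A \code{mem_model}.
#' @return data.frame: row, col, n_cells, one score column per module,
#'   \code{module} (assignment).
#' @export
score_spots <- function(sm, mm) {
  cl <- colnames(sm$counts)
  unknown <- setdiff(cl, names(mm$modules))
  if (length(unknown))
    stop("clusters absent from the MEM model: ",
         paste(unknown, collapse = ", "))
  tot <- rowSums(sm$counts)
  scores <- sapply(mm$module_names, function(m) {
    mem_cl <- intersect(names(mm$modules)[mm$modules == m], cl)
    if (length(mem_cl) == 0) return(rep(0, length(tot)))
    rowSums(sm$counts[, mem_cl, drop = FALSE]) / ifelse(tot > 0, tot, 1)
  })
  scores <- matrix(scores, nrow = length(tot),
                   dimnames = list(NULL, mm$module_names))
  assign <- mm$module_names[max.col(scores, ties.method = "first")]
  assign[tot == 0] <- "Module0_NC"
  out <- cbind(sm$spots[, c("row", "col")],
               data.frame(n_cells = tot), as.data.frame(scores))
  out$module <- assign
  out
}

#' Intra- and inter-MEM variation of cell-type proportions
#'
#' Quality metrics of a spot classification: for each cell type, intra-MEM
#' variation is the mean over modules of the (population) standard
#' deviation of the type's spot-level proportion within the module, and
#' inter-MEM variation is the standard deviation over modules of the
#' within-module mean proportion. Module0_NC spots are excluded; modules
#' with fewer than 2 spots contribute an SD of 0 with a warning.
#'
#' @param assignments Character module per spot.
#' @param proportions Spots x cell-types matrix of proportions.
#' @return data.frame(cell_type, intra, inter).
#' @export
mem_variation <- function(assignments, proportions) {
  proportions <- as.matrix(proportions)
  keep <- assignments != "Module0_NC"
  assignments <- assignments[keep]
  proportions <- proportions[keep, , drop = FALSE]
  mems <- sort(unique(assignments))
  if (length(mems) == 0) stop("no classified spots")
  small <- mems[table(factor(assignments, levels = mems)) < 2]
  if (length(small))
    warning("MEM(s) with fewer than 2 spots contribute SD 0: ",
            paste(small, collapse = ", "))
  out <- lapply(colnames(proportions), function(ty) {
    p <- proportions[, ty]
    sds <- vapply(mems, function(m) {
      v <- p[assignments == m]
      if (length(v) < 2) 0 else pop_sd(v)
    }, numeric(1))
    means <- vapply(mems, function(m) mean(p[assignments == m]), numeric(1))
    data.frame(cell_type = ty, intra = mean(sds), inter = pop_sd(means),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
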