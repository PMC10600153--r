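# GLCM texture and intensity features within the nuclear mask.

#' Texture feature names
#' @return Character vector of the 9 texture column names.
#' @export
texture_feature_names <- function() {
  c("ASM", "Contrast", "Correlation", "Entropy", "Homogeneity",
    "IntensityMean", "IntensityStd", "IntensityMax", "IntensityMin")
}

# the four symmetric unit offsets (dy, dx): 0, 45, 90, 135 degrees
.glcm_offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

# co-occurrence counts for one offset, restricted to mask pairs
#' @keywords internal
glcm_counts <- function(q, mask, offset, n_levels) {
  nr <- nrow(q); nc <- ncol(q)
  dy <- offset[1]; dx <- offset[2]
  r1 <- max(1, 1 - dy):min(nr, nr - dy)
  c1 <- max(1, 1 - dx):min(nc, nc - dx)
  if (length(r1) == 0 || length(c1) == 0)
    return(matrix(0, n_levels, n_levels))
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dy, c1 + dx, drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dy, c1 + dx, drop = FALSE]
  if (!any(ok)) return(matrix(0, n_levels, n_levels))
  tab <- table(factor(a[ok], levels = 0:(n_levels - 1)),
               factor(b[ok], levels = 0:(n_levels - 1)))
  m <- matrix(as.numeric(tab), n_levels, n_levels)
  m + t(m)  # symmetric
}

#' @keywords internal
glcm_props <- function(p) {
  n <- nrow(p)
  lv <- seq_len(n) - 1
  i <- matrix(lv, n, n)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (sd_i > 0 && sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j) else 0
  nz <- p[p > 0]
  c(ASM = sum(p^2),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    Entropy = -sum(nz * log2(nz)),
    Homogeneity = sum(p / (1 + (i - j)^2)))
}

#' Compute texture features of one nucleus
#'
#' GLCM features of the grayscale patch restricted to the nuclear mask:
#' the 8-bit patch is quantized to \code{n_levels} gray levels, symmetric
#' co-occurrence matrices are tabulated at unit offsets of 0, 45, 90 and
#' 135 degrees (only pixel pairs with both pixels inside the mask count),
#' each is normalized, and ASM, Contrast, Correlation, Entropy (bits) and
#' Homogeneity are averaged over the four angles. Correlation of a
#' zero-variance patch is defined as 0. Intensity statistics (mean,
#' population SD, max, min) are taken over masked pixels only.
#'
#' @param patch Integer/numeric matrix of gray values in 0..255
#'   (rows = y, cols = x).
#' @param mask Logical matrix of the same shape; must contain TRUE pixels.
#' @param n_levels Number of quantization levels (default 32).
#' @return Named numeric vector of the 9 features.
#' @export
compute_texture <- function(patch, mask, n_levels = 32) {
  if (!all(dim(patch) == dim(mask))) stop("patch and mask shapes differ")
  if (!any(mask)) stop("empty mask")
  vals <- patch[mask]
  q <- matrix(pmin(n_levels - 1L, floor(patch / (256 / n_levels))),
              nrow(patch), ncol(patch))
  per_angle <- list()
  for (off in .glcm_offsets) {
    cnt <- glcm_counts(q, mask, off, n_levels)
    tot <- sum(cnt)
    if (tot > 0) per_angle[[length(per_angle) + 1]] <- glcm_props(cnt / tot)
  }
  glcm <- if (length(per_angle)) Reduce(`+`, per_angle) / length(per_angle)
    else c(ASM = 1, Contrast = 0, Correlation = 0, Entropy = 0, Homogeneity = 1)
  c(glcm,
    IntensityMean = mean(vals), IntensityStd = pop_sd(vals),
    IntensityMax = max(vals), IntensityMin = min(vals))
}

#' Compute morphology (and optionally texture) for every profiled cell
#'
#' Convenience wrapper running \code{\link{compute_morphology}} (and
#' \code{\link{compute_texture}} when the set carries patches) over all
#' tumor, inflammatory and stroma nuclei of a slide.
#'
#' @param ns A \code{nucleus_set}.
#' @param with_texture Compute texture features when patches are present.
#' @return data.frame with columns id, then the morphology (and texture)
#'   features; texture columns are NA when no patch is available.
#' @export
compute_nucleus_features <- function(ns, with_texture = TRUE) {
  cells <- ns$cells[ns$cells$type %in% profiled_types(), , drop = FALSE]
  ids <- cells$id
  morph <- matrix(NA_real_, length(ids), length(morphology_feature_names()),
                  dimnames = list(NULL, morphology_feature_names()))
  tex <- matrix(NA_real_, length(ids), length(texture_feature_names()),
                dimnames = list(NULL, texture_feature_names()))
  for (i in seq_along(ids)) {
    id <- ids[i]
    row <- cells[i, ]
    bbox <- c(row$xmin, row$ymin, row$xmax, row$ymax)
    morph[i, ] <- compute_morphology(ns$contours[[id]], bbox = bbox, id = id)
    if (with_texture && !is.null(ns$patches) && !is.null(ns$patches[[id]])) {
      ras <- rasterize_contour(ns$contours[[id]], bbox = bbox)
      patch <- ns$patches[[id]]
      if (!all(dim(patch) == dim(ras$mask)))
        stop("patch of nucleus ", id, " does not match its bounding box")
      tex[i, ] <- compute_texture(patch, ras$mask)
    }
  }
  cbind(data.frame(id = ids, stringsAsFactors = FALSE),
        as.data.frame(morph), as.data.frame(tex))
}
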