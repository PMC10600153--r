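# Seeded generation of synthetic nucleus fields, patches and cohorts with
# planted spatial, cluster and ecotype structure.

#' Specify a per-type spatial point process
#'
#' @param process "poisson" (homogeneous), "thomas" (Neyman-Scott cluster
#'   process: Poisson parents, Gaussian-displaced offspring) or "regions"
#'   (homogeneous within a rectangle).
#' @param intensity Expected cells per mm^2 (over the slide for poisson and
#'   thomas; within the rectangle for regions).
#' @param parents_per_mm2 Thomas parent intensity.
#' @param sigma_um Thomas offspring displacement SD (microns).
#' @param rect_um Region rectangle \code{c(x0, y0, x1, y1)} in microns.
#' @return List describing the process.
#' @export
type_process <- function(process = c("poisson", "thomas", "regions"),
                         intensity = 300, parents_per_mm2 = 5,
                         sigma_um = 30, rect_um = NULL) {
  process <- match.arg(process)
  stopifnot(intensity > 0)
  list(process = process, intensity = intensity,
       parents_per_mm2 = parents_per_mm2, sigma_um = sigma_um,
       rect_um = rect_um)
}

# draw centroids (px) for one process; returns list(xy, parent)
#' @keywords internal
draw_points <- function(p, slide_um, mpp) {
  area_mm2 <- prod(slide_um) / 1e6
  to_px <- 1 / mpp
  if (p$process == "poisson") {
    n <- stats::rpois(1, p$intensity * area_mm2)
    xy <- cbind(stats::runif(n, 0, slide_um[1]), stats::runif(n, 0, slide_um[2]))
    parent <- rep(NA_integer_, n)
  } else if (p$process == "thomas") {
    npar <- max(1, stats::rpois(1, p$parents_per_mm2 * area_mm2))
    px <- stats::runif(npar, 0, slide_um[1])
    py <- stats::runif(npar, 0, slide_um[2])
    mu <- p$intensity * area_mm2 / npar
    noff <- stats::rpois(npar, mu)
    parent <- rep(seq_len(npar), noff)
    xy <- cbind(px[parent] + stats::rnorm(sum(noff), 0, p$sigma_um),
                py[parent] + stats::rnorm(sum(noff), 0, p$sigma_um))
    keep <- xy[, 1] >= 0 & xy[, 1] < slide_um[1] &
      xy[, 2] >= 0 & xy[, 2] < slide_um[2]
    xy <- xy[keep, , drop = FALSE]; parent <- parent[keep]
  } else {
    r <- p$rect_um
    stopifnot(length(r) == 4)
    area_mm2 <- (r[3] - r[1]) * (r[4] - r[2]) / 1e6
    n <- stats::rpois(1, p$intensity * area_mm2)
    xy <- cbind(stats::runif(n, r[1], r[3]), stats::runif(n, r[2], r[4]))
    parent <- rep(NA_integer_, n)
  }
  list(xy = xy * to_px, parent = parent)
}

# elliptical contour with radial Fourier perturbation, centered at (cx, cy)
#' @keywords internal
make_contour <- function(cx, cy, r_px, axis_ratio_sd, perturb_amp,
                         n_vertices) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ratio <- exp(stats::rnorm(1, 0, axis_ratio_sd))
  phi <- stats::runif(1, 0, pi)
  harm <- 2:4
  c_h <- stats::rnorm(length(harm), 0, perturb_amp)
  ph_h <- stats::runif(length(harm), 0, 2 * pi)
  pert <- 1 + colSums(c_h * cos(outer(harm, th) + ph_h))
  pert <- pmax(pert, 0.2)
  ex <- r_px * ratio * cos(th) * pert
  ey <- (r_px / ratio) * sin(th) * pert
  x <- cx + ex * cos(phi) - ey * sin(phi)
  y <- cy + ex * sin(phi) + ey * cos(phi)
  cbind(x, y)
}

#' Simulate a synthetic nucleus field
#'
#' Generates one slide's nuclei: centroids from per-type spatial point
#' processes (homogeneous Poisson, Thomas cluster, or region-restricted),
#' polygonal nuclear contours (ellipses with radial Fourier perturbation;
#' the perturbation amplitude controls morphological dispersion and hence
#' planted MITH), and optional 8-bit grayscale patches with per-type mean
#' gray level and optional stripe texture. Identical seeds give identical
#' output. Ground truth (per-cell parent assignment) is returned alongside.
#'
#' @param processes Named list (by cell type) of \code{\link{type_process}}
#'   specifications.
#' @param slide_um Slide width/height in microns.
#' @param mpp Microns per pixel (default 0.25).
#' @param seed Integer seed.
#' @param shape List: \code{radius_um} (mean nuclear radius),
#'   \code{axis_ratio_sd} (log-scale SD of the axis ratio),
#'   \code{perturb_amp} (radial perturbation amplitude),
#'   \code{n_vertices} (contour vertices).
#' @param texture List: \code{mean} (named per-type gray level), \code{sd}
#'   (pixel noise SD), \code{stripe_period_px}, \code{stripe_amp}.
#' @param with_patches Generate grayscale patches (default FALSE).
#' @return List: \code{ns} (a \code{nucleus_set}), \code{truth}
#'   (data.frame id, type, parent).
#' @export
simulate_field <- function(processes, slide_um = c(1000, 1000), mpp = 0.25,
                           seed = 1,
                           shape = list(radius_um = 3, axis_ratio_sd = 0.15,
                                        perturb_amp = 0.05, n_vertices = 32),
                           texture = list(mean = c(tumor = 110,
                                                   inflammatory = 70,
                                                   stroma = 150,
                                                   normal = 140, dead = 90),
                                          sd = 12, stripe_period_px = 0,
                                          stripe_amp = 0),
                           with_patches = FALSE) {
  stopifnot(all(names(processes) %in% cell_types()))
  set.seed(seed)
  rows <- list(); contours <- list(); patches <- list(); truth <- list()
  counter <- 0L
  for (ty in names(processes)) {
    pts <- draw_points(processes[[ty]], slide_um, mpp)
    n <- nrow(pts$xy)
    if (n == 0) next
    for (i in seq_len(n)) {
      counter <- counter + 1L
      id <- sprintf("c%06d", counter)
      ct <- make_contour(pts$xy[i, 1], pts$xy[i, 2],
                         shape$radius_um / mpp, shape$axis_ratio_sd,
                         shape$perturb_amp, shape$n_vertices)
      bb <- c(floor(min(ct[, 1])), floor(min(ct[, 2])),
              ceiling(max(ct[, 1])), ceiling(max(ct[, 2])))
      rows[[counter]] <- data.frame(
        id = id, x = pts$xy[i, 1], y = pts$xy[i, 2],
        xmin = bb[1], ymin = bb[2], xmax = bb[3], ymax = bb[4],
        type = ty, stringsAsFactors = FALSE)
      contours[[id]] <- ct
      truth[[counter]] <- data.frame(id = id, type = ty,
                                     parent = pts$parent[i],
                                     stringsAsFactors = FALSE)
      if (with_patches) {
        nx <- bb[3] - bb[1] + 1; ny <- bb[4] - bb[2] + 1
        base <- texture$mean[[ty]] %||% 120
        patch <- matrix(stats::rnorm(ny * nx, base, texture$sd), ny, nx)
        if ((texture$stripe_period_px %||% 0) > 0) {
          xs <- matrix(rep(bb[1]:bb[3], each = ny), ny, nx)
          patch <- patch + texture$stripe_amp *
            sin(2 * pi * xs / texture$stripe_period_px)
        }
        patches[[id]] <- matrix(as.integer(pmin(255, pmax(0, round(patch)))),
                                ny, nx)
      }
    }
  }
  cells <- if (counter > 0) do.call(rbind, rows) else empty_cells_df()
  ns <- nucleus_set("synthetic", cells, contours, mpp = mpp,
                    patches = if (with_patches) patches)
  list(ns = ns, truth = if (counter > 0) do.call(rbind, truth) else NULL)
}

#' Simulate a field of clustered cells with planted colocalization
#'
#' Region-restricted marked point pattern: each region definition places
#' Poisson-distributed cells of the named cell clusters (with their cell
#' types) uniformly inside its rectangle, planting the colocalization
#' structure that spot-level spatial correlation should recover.
#'
#' @param regions List of region definitions: each a list with
#'   \code{rect_um} = c(x0, y0, x1, y1), \code{clusters} = named vector of
#'   intensities (cells/mm^2) by cluster label, and \code{types} = named
#'   map cluster label -> cell type.
#' @param slide_um Slide size (microns).
#' @param mpp Microns per pixel.
#' @param seed Integer seed.
#' @return data.frame: id, x, y (px), type, cluster, region.
#' @export
simulate_cluster_field <- function(regions, slide_um = c(1600, 1600),
                                   mpp = 0.25, seed = 1) {
  set.seed(seed)
  rows <- list()
  counter <- 0L
  for (ri in seq_along(regions)) {
    rg <- regions[[ri]]
    for (cl in names(rg$clusters)) {
      p <- type_process("regions", intensity = rg$clusters[[cl]],
                        rect_um = rg$rect_um)
      pts <- draw_points(p, slide_um, mpp)
      n <- nrow(pts$xy)
      if (n == 0) next
      idx <- counter + seq_len(n)
      counter <- counter + n
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("c%06d", idx), x = pts$xy[, 1], y = pts$xy[, 2],
        type = rg$types[[cl]] %||% "tumor", cluster = cl, region = ri,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the default planted module catalogue of the cohort generator:
# four modules of two clusters each, with their cell types
#' @keywords internal
default_module_catalogue <- function() {
  list(
    Module1 = list(clusters = c(K1 = 500, K2 = 500),
                   types = c(K1 = "tumor", K2 = "tumor")),
    Module2 = list(clusters = c(K3 = 500, K4 = 500),
                   types = c(K3 = "tumor", K4 = "stroma")),
    Module3 = list(clusters = c(K5 = 500, K6 = 500),
                   types = c(K5 = "inflammatory", K6 = "stroma")),
    Module4 = list(clusters = c(K7 = 500, K8 = 500),
                   types = c(K7 = "inflammatory", K8 = "inflammatory")))
}

#' Configure a synthetic cohort with planted ecotypes
#'
#' Each sample's slide is tiled into square blocks (default two spots
#' across); each block hosts one micro-ecological module, drawn from the
#' sample's archetype-specific module mixture, and is populated by the
#' module's two cell clusters. Archetype mixtures are one-dominant
#' compositions perturbed by per-sample noise, so MEM composition vectors
#' cluster into the planted ecotypes.
#'
#' @param n_samples Number of samples (default 40).
#' @param n_archetypes Number of planted ecotypes (default 4; at most the
#'   number of modules in the catalogue).
#' @param dominant_weight Mixture weight of the archetype's own module.
#' @param noise SD of the log-normal perturbation of mixture weights.
#' @param slide_um Slide size (microns).
#' @param spot_um Spot side (microns, default 200).
#' @param block_spots Block side in spots (default 2).
#' @param mpp Microns per pixel.
#' @param seed Integer seed.
#' @return List of class \code{cohort_config}.
#' @export
cohort_config <- function(n_samples = 40, n_archetypes = 4,
                          dominant_weight = 0.7, noise = 0.1,
                          slide_um = c(1600, 1600), spot_um = 200,
                          block_spots = 2, mpp = 0.25, seed = 1) {
  catalogue <- default_module_catalogue()
  stopifnot(n_archetypes <= length(catalogue), n_samples >= n_archetypes)
  structure(list(n_samples = n_samples, n_archetypes = n_archetypes,
                 dominant_weight = dominant_weight, noise = noise,
                 slide_um = slide_um, spot_um = spot_um,
                 block_spots = block_spots, mpp = mpp, seed = seed,
                 catalogue = catalogue),
            class = "cohort_config")
}

#' Simulate a cohort of slides with planted ecotype structure
#'
#' @param cc A \code{cohort_config}.
#' @return List: \code{samples} (named list of cell data.frames with
#'   cluster labels), \code{ecotype} (named ground-truth archetype per
#'   sample), \code{module_truth} (named cluster -> module map),
#'   \code{config}.
#' @export
simulate_cohort <- function(cc) {
  stopifnot(inherits(cc, "cohort_config"))
  set.seed(cc$seed)
  modules <- names(cc$catalogue)[seq_len(cc$n_archetypes)]
  archetype <- rep(seq_len(cc$n_archetypes), length.out = cc$n_samples)
  block_um <- cc$spot_um * cc$block_spots
  nbx <- floor(cc$slide_um[1] / block_um)
  nby <- floor(cc$slide_um[2] / block_um)
  samples <- list()
  for (s in seq_len(cc$n_samples)) {
    w <- rep((1 - cc$dominant_weight) / (length(modules) - 1), length(modules))
    w[archetype[s]] <- cc$dominant_weight
    w <- w * exp(stats::rnorm(length(w), 0, cc$noise))
    w <- w / sum(w)
    rows <- list()
    counter <- 0L
    for (bx in seq_len(nbx) - 1) for (by in seq_len(nby) - 1) {
      m <- sample(modules, 1, prob = w)
      spec <- cc$catalogue[[m]]
      rect <- c(bx * block_um, by * block_um,
                (bx + 1) * block_um, (by + 1) * block_um)
      for (cl in names(spec$clusters)) {
        p <- type_process("regions", intensity = spec$clusters[[cl]],
                          rect_um = rect)
        pts <- draw_points(p, cc$slide_um, cc$mpp)
        n <- nrow(pts$xy)
        if (n == 0) next
        idx <- counter + seq_len(n)
        counter <- counter + n
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("s%02d_c%06d", s, idx),
          x = pts$xy[, 1], y = pts$xy[, 2],
          type = spec$types[[cl]], cluster = cl,
          stringsAsFactors = FALSE)
      }
    }
    samples[[sprintf("sample%02d", s)]] <- do.call(rbind, rows)
  }
  module_truth <- unlist(lapply(modules, function(m)
    stats::setNames(rep(m, length(cc$catalogue[[m]]$clusters)),
                    names(cc$catalogue[[m]]$clusters))))
  list(samples = samples,
       ecotype = stats::setNames(archetype, names(samples)),
       module_truth = module_truth, config = cc)
}
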