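# End-to-end orchestration: extract -> cluster -> mith -> mem -> ecotype.

#' Default pipeline configuration
#'
#' Parameters, with the conventional defaults: 0.25 um/px, k = 5 neighbors,
#' 100 px edge threshold, 0.5 percent cell sampling, Leiden resolution 1,
#' 200 um spots, 8 modules, ecotype k range 2..10.
#'
#' @param ... Overrides of any default field.
#' @return Named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(mpp = 0.25, k = 5, threshold_px = 100, fraction = 0.005,
              resolution = 1, nn_k = 15, n_pcs = 50, spot_um = 200,
              n_modules = 8, ecotype_k_min = 2, ecotype_k_max = 10,
              seed = 0, input_dir = NULL, out_dir = "scmtop_out",
              synthetic = NULL, with_texture = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  num <- c("mpp", "k", "threshold_px", "fraction", "resolution", "nn_k",
           "n_pcs", "spot_um", "n_modules")
  for (f in num) if (cfg[[f]] <= 0) stop("config field ", f, " must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read/write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param cfg A \code{pipeline_config}.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full profiling pipeline
#'
#' Executes extract (segmentation -> features and graphs -> four tables per
#' slide), cluster (per-type Leiden on sampled cells, extrapolated to all
#' cells), mith, mem (spot tessellation, spatial correlation, module
#' discovery, Moran's I) and ecotype (when at least 4 samples), writing all
#' stage outputs under \code{cfg$out_dir} plus a JSON run manifest recording
#' package version, seeds, the config hash and per-stage output paths.
#' Inputs are either segmentation JSON files (\code{cfg$input_dir}) or, when
#' \code{cfg$synthetic} is a list of \code{\link{simulate_field}} arguments
#' plus \code{n_slides}, freshly simulated slides written to the same
#' dialect first.
#'
#' @param cfg A \code{pipeline_config}, or a YAML path.
#' @return The manifest (list), invisibly; also written to
#'   \code{out_dir/manifest.json}.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[scmtop] ", ...)

  # ---- inputs ----
  if (!is.null(cfg$synthetic)) {
    sim_dir <- file.path(out, "segmentation")
    dir.create(sim_dir, showWarnings = FALSE)
    n_slides <- cfg$synthetic$n_slides %||% 3
    for (i in seq_len(n_slides)) {
      args <- cfg$synthetic
      args$n_slides <- NULL
      args$seed <- (cfg$seed + i) %% .Machine$integer.max
      args$with_patches <- cfg$with_texture
      if (is.null(args$processes))
        args$processes <- list(
          tumor = type_process("poisson", intensity = 350),
          inflammatory = type_process("thomas", intensity = 250,
                                      parents_per_mm2 = 8, sigma_um = 40),
          stroma = type_process("poisson", intensity = 250))
      fld <- do.call(simulate_field, args)
      write_segmentation(fld$ns, file.path(sim_dir, sprintf("slide%02d.json", i)))
    }
    cfg$input_dir <- sim_dir
    synthetic_patches <- cfg$with_texture
  } else synthetic_patches <- FALSE
  if (is.null(cfg$input_dir) || !dir.exists(cfg$input_dir))
    stop("input directory not found: ", cfg$input_dir %||% "<missing>")
  json_files <- sort(list.files(cfg$input_dir, pattern = "\\.json$",
                                full.names = TRUE))
  if (length(json_files) == 0) stop("no segmentation JSON in ", cfg$input_dir)

  # ---- stage 1: extract ----
  tab_dir <- file.path(out, "tables")
  slides <- sub("\\.json$", "", basename(json_files))
  features <- list()
  for (i in seq_along(json_files)) {
    ns <- read_segmentation(json_files[i], mpp = cfg$mpp)
    ns <- filter_non_necrotic(ns)
    comp <- compute_composition(ns)
    log_msg(slides[i], ": ", n_cells(ns), " non-necrotic cells (",
            paste(names(comp$counts), comp$counts, sep = "=", collapse = ", "),
            ")")
    if (synthetic_patches && is.null(ns$patches))
      ns$patches <- regenerate_patches(ns, seed = cfg$seed + i)
    es <- build_all_graphs(ns, k = cfg$k, threshold_px = cfg$threshold_px)
    feat <- assemble_cell_features(ns, edge_sets = es)
    write_feature_tables(ns, feat, es, tab_dir)
    feat$slide_id <- slides[i]
    features[[slides[i]]] <- feat
  }

  # ---- stage 2: cluster per type ----
  feature_cols <- function(df) {
    cols <- c(morphology_feature_names(), texture_feature_names(),
              grep("^[TIS]-[TIS]_", names(df), value = TRUE))
    intersect(cols, names(df))
  }
  all_cells <- do.call(rbind, features)
  labels <- rep(NA_character_, nrow(all_cells))
  models <- list()
  for (ty in profiled_types()) {
    sel <- all_cells$cell_type == ty
    sub <- all_cells[sel, , drop = FALSE]
    if (nrow(sub) < 10) next
    cols <- feature_cols(sub)
    cols <- cols[colSums(!is.finite(as.matrix(sub[, cols]))) == 0]
    tabs <- split(sub[, c("id", cols)], sub$slide_id)
    pool <- sample_cells(tabs, fraction = max(cfg$fraction, 50 / nrow(sub)),
                         seed = cfg$seed)
    model <- fit_cluster_model(as.matrix(pool[, cols]), cell_type = ty,
                               resolution = cfg$resolution, seed = cfg$seed,
                               n_pcs = cfg$n_pcs, nn_k = cfg$nn_k)
    ext <- extrapolate_clusters(model, as.matrix(sub[, cols]),
                                seed = cfg$seed)
    labels[sel] <- cluster_label_names(model, ext)
    models[[ty]] <- model
    log_msg(ty, ": ", length(model$cluster_names), " clusters on ",
            nrow(pool), " sampled cells")
  }
  all_cells$cluster <- labels
  data.table::fwrite(all_cells[, c("slide_id", "id", "cell_type", "x", "y",
                                   "cluster")],
                     file.path(out, "cell_clusters.csv"))

  # ---- stage 3: MITH ----
  tum <- all_cells[all_cells$cell_type == "tumor", , drop = FALSE]
  mith <- NULL
  if (nrow(tum) >= 2) {
    fcols <- intersect(c(morphology_feature_names(), texture_feature_names()),
                       names(tum))
    mith <- mith_table(as.matrix(tum[, fcols]), tum$slide_id)
    data.table::fwrite(mith, file.path(out, "mith.csv"))
  }

  # ---- stage 4: MEM ----
  clusters_all <- sort(unique(stats::na.omit(all_cells$cluster)))
  spot_mats <- list(); corr <- list()
  for (sid in slides) {
    cells <- all_cells[all_cells$slide_id == sid & !is.na(all_cells$cluster), ]
    sm <- tessellate(cells, spot_um = cfg$spot_um, mpp = cfg$mpp,
                     slide_id = sid, clusters = clusters_all)
    spot_mats[[sid]] <- sm
    corr[[sid]] <- spatial_correlation_matrix(sm)
  }
  mm <- build_mem_model(corr, n_modules = min(cfg$n_modules,
                                              length(clusters_all)))
  spot_tabs <- lapply(slides, function(sid) {
    st <- score_spots(spot_mats[[sid]], mm)
    cbind(data.frame(slide_id = sid), st)
  })
  spot_tab <- do.call(rbind, spot_tabs)
  data.table::fwrite(spot_tab, file.path(out, "spots.csv"))
  w_moran <- lapply(slides, function(sid) {
    st <- score_spots(spot_mats[[sid]], mm)
    w <- spot_weights_rook(spot_mats[[sid]])
    data.frame(slide_id = sid, module = mm$module_names,
               morans_i = vapply(mm$module_names, function(m)
                 as.numeric(morans_i(st[[m]], w)), numeric(1)))
  })
  data.table::fwrite(do.call(rbind, w_moran), file.path(out, "morans_i.csv"))

  # ---- stage 5: ecotype ----
  eco <- NULL
  comp <- mem_composition(spot_tab$slide_id, spot_tab$module,
                          module_names = mm$module_names)
  utils::write.csv(comp, file.path(out, "mem_composition.csv"))
  if (length(slides) >= 4 &&
      max(stats::dist(comp[stats::complete.cases(comp), , drop = FALSE])) > 1e-12) {
    eco <- tryCatch(
      cluster_ecotypes(comp, k_range = cfg$ecotype_k_min:cfg$ecotype_k_max,
                       seed = cfg$seed),
      error = function(e) { log_msg("ecotype stage skipped: ", conditionMessage(e)); NULL })
    if (!is.null(eco))
      data.table::fwrite(data.frame(sample_id = rownames(comp),
                                    ecotype = eco$labels),
                         file.path(out, "ecotypes.csv"))
  } else log_msg("ecotype stage skipped: needs >= 4 distinguishable samples")

  # ---- manifest ----
  cfg_path <- file.path(out, "config.yaml")
  write_pipeline_config(cfg, cfg_path)
  manifest <- list(
    package = "scmtop",
    version = as.character(utils::packageVersion("scmtop")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_slides = length(slides),
    slides = slides,
    n_cells = nrow(all_cells),
    n_clusters = length(clusters_all),
    n_modules = mm$n_modules,
    ecotype_k = if (!is.null(eco)) eco$k else NA,
    outputs = list(tables = tab_dir,
                   cell_clusters = file.path(out, "cell_clusters.csv"),
                   mith = if (!is.null(mith)) file.path(out, "mith.csv"),
                   spots = file.path(out, "spots.csv"),
                   morans_i = file.path(out, "morans_i.csv"),
                   mem_composition = file.path(out, "mem_composition.csv"),
                   ecotypes = if (!is.null(eco)) file.path(out, "ecotypes.csv")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# deterministic texture patches for synthetic slides read back from JSON
# (the segmentation dialect carries no image data)
#' @keywords internal
regenerate_patches <- function(ns, seed = 0,
                               means = c(tumor = 110, inflammatory = 70,
                                         stroma = 150, normal = 140),
                               sd = 12) {
  set.seed(seed)
  patches <- list()
  for (i in seq_len(nrow(ns$cells))) {
    r <- ns$cells[i, ]
    if (!r$type %in% profiled_types()) next
    nx <- r$xmax - r$xmin + 1; ny <- r$ymax - r$ymin + 1
    patch <- matrix(stats::rnorm(ny * nx, means[[r$type]] %||% 120, sd), ny, nx)
    patches[[r$id]] <- matrix(as.integer(pmin(255, pmax(0, round(patch)))),
                              ny, nx)
  }
  patches
}
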