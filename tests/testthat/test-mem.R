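grid_weights <- function(nr, nc) {
  sm <- list(nrow = nr, ncol = nc,
             spots = data.frame(row = rep(0:(nr - 1), each = nc),
                                col = rep(0:(nc - 1), nr)))
  class(sm) <- "spot_matrix"
  spot_weights_rook(sm)
}

test_that("tessellation assigns cells by half-open floor arithmetic", {
  # 200-um spots at 0.25 um/px = 800 px; cells at 10 um and 790 um
  cells <- data.frame(x = c(10, 790) / 0.25, y = c(10, 10) / 0.25,
                      cluster = "K1")
  sm <- tessellate(cells, spot_um = 200, mpp = 0.25)
  occupied <- sm$spots[rowSums(sm$counts) > 0, ]
  expect_equal(occupied$row, c(0, 0))
  expect_equal(occupied$col, c(0, 3))
  # a cell exactly on a boundary belongs to the higher-index spot
  cells2 <- data.frame(x = 800, y = 0, cluster = "K1")
  sm2 <- tessellate(cells2, spot_um = 200, mpp = 0.25,
                    slide_px = c(1600, 800))
  expect_equal(unname(sm2$counts[sm2$spots$row == 0 & sm2$spots$col == 1, "K1"]), 1)
  expect_equal(sum(sm2$counts), 1)
})

test_that("spot counts conserve the cell total", {
  set.seed(14)
  cells <- data.frame(x = runif(500, 0, 6000), y = runif(500, 0, 4000),
                      cluster = sample(c("K1", "K2", "K3"), 500, replace = TRUE))
  sm <- tessellate(cells, spot_um = 200, mpp = 0.25,
                   slide_px = c(6000, 4000))
  expect_equal(sum(sm$counts), 500)
  for (cl in c("K1", "K2", "K3"))
    expect_equal(sum(sm$counts[, cl]), sum(cells$cluster == cl))
  expect_equal(nrow(sm$spots), sm$nrow * sm$ncol)
})

test_that("bivariate spatial correlation reduces to Moran's I when y = x", {
  w <- grid_weights(5, 5)
  set.seed(15)
  for (rep in 1:10) {
    x <- rnorm(25)
    expect_equal(as.numeric(spatial_correlation(x, x, w)),
                 as.numeric(morans_i(x, w)), tolerance = 1e-10)
  }
  # zero-variance field is flagged degenerate
  z <- spatial_correlation(rep(1, 25), rnorm(25), w)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
})

test_that("spatial statistics match double-loop brute force", {
  w <- grid_weights(4, 6)
  set.seed(16)
  for (rep in 1:6) {
    x <- rpois(24, 5); y <- rpois(24, 3)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(as.numeric(spatial_correlation(x, y, w)),
                 oracle_spatial_corr(x, y, w$w), tolerance = 1e-10)
    expect_equal(as.numeric(morans_i(x, w)), oracle_morans(x, w$w),
                 tolerance = 1e-10)
  }
})

test_that("Moran's I gives the analytic values on canonical 4x4 fields", {
  w <- grid_weights(4, 4)
  checker <- as.numeric((outer(0:3, 0:3, `+`) %% 2) == 0)
  # row-major flattening to match the weight ordering
  checker_rm <- as.numeric(t(matrix(checker, 4, 4)))
  expect_equal(as.numeric(morans_i(checker_rm, w)), -1, tolerance = 1e-12)
  expect_equal(oracle_morans(checker_rm, w$w), -1, tolerance = 1e-12)
  half <- as.numeric(t(cbind(matrix(1, 4, 2), matrix(0, 4, 2))))
  expect_equal(as.numeric(morans_i(half, w)), 2 / 3, tolerance = 1e-12)
  expect_equal(oracle_morans(half, w$w), 2 / 3, tolerance = 1e-12)
  const <- morans_i(rep(3, 16), w)
  expect_equal(as.numeric(const), 0)
  expect_true(attr(const, "degenerate"))
})

test_that("planted colocalization blocks are recovered as modules", {
  cells <- simulate_cluster_field(coloc_regions(), seed = 17)
  sm <- tessellate(cells, spot_um = 200, mpp = 0.25, slide_px = c(6400, 6400))
  cm <- spatial_correlation_matrix(sm)
  mm <- build_mem_model(list(cm), n_modules = 2)
  expect_equal(unname(mm$modules["A"]), unname(mm$modules["B"]))
  expect_equal(unname(mm$modules["C"]), unname(mm$modules["D"]))
  expect_false(mm$modules[["A"]] == mm$modules[["C"]])
  # maximal cut gives singletons; permuting clusters relabels only
  mm4 <- build_mem_model(list(cm), n_modules = 4)
  expect_equal(length(unique(mm4$modules)), 4)
  perm <- c("C", "A", "D", "B")
  cmp <- list(C = cm$C[perm, perm], defined = cm$defined[perm, perm])
  mmp <- build_mem_model(list(cmp), n_modules = 2)
  expect_equal(unname(mmp$modules["A"] == mmp$modules["B"]), TRUE)
  expect_equal(unname(mmp$modules["C"] == mmp$modules["D"]), TRUE)
})

test_that("spot scores partition to 1 and empty spots become Module0_NC", {
  cells <- simulate_cluster_field(coloc_regions(), seed = 18)
  # grid wider than the populated area: right margin spots stay empty
  sm <- tessellate(cells, spot_um = 200, mpp = 0.25, slide_px = c(8000, 6400))
  mm <- build_mem_model(list(spatial_correlation_matrix(
    tessellate(cells, spot_um = 200, mpp = 0.25, slide_px = c(6400, 6400)))),
    n_modules = 2)
  st <- score_spots(sm, mm)
  nonempty <- st$n_cells > 0
  expect_equal(unname(rowSums(st[nonempty, mm$module_names])),
               rep(1, sum(nonempty)), tolerance = 1e-9)
  expect_true(all(st$module[!nonempty] == "Module0_NC"))
  expect_false(any(st$module[nonempty] == "Module0_NC"))
  # a spot whose cells all sit in one module's clusters scores 1 there
  pure <- which(st$Module1 == 1)
  expect_true(length(pure) > 0)
  expect_true(all(st$module[pure] == "Module1"))
  # unknown clusters are rejected
  sm_bad <- sm; colnames(sm_bad$counts)[1] <- "Zz"
  expect_error(score_spots(sm_bad, mm), "absent from the MEM model")
})

test_that("intra/inter-MEM variation matches a direct two-pass computation", {
  # identical proportions within every MEM: intra = 0
  assign <- rep(c("Module1", "Module2"), each = 4)
  props <- matrix(rep(c(0.2, 0.7), each = 4), ncol = 1,
                  dimnames = list(NULL, "tumor"))
  v <- mem_variation(assign, props)
  expect_equal(v$intra, 0)
  expect_equal(v$inter, sqrt(mean((c(0.2, 0.7) - 0.45)^2)))
  # equal MEM means: inter = 0
  props2 <- matrix(c(0.1, 0.3, 0.1, 0.3, 0.3, 0.1, 0.3, 0.1), ncol = 1,
                   dimnames = list(NULL, "tumor"))
  expect_equal(mem_variation(assign, props2)$inter, 0)
  # random case against a direct two-pass oracle; Module0_NC excluded
  set.seed(19)
  a <- c(sample(paste0("Module", 1:3), 60, replace = TRUE),
         rep("Module0_NC", 5))
  p <- matrix(runif(65 * 2), 65, 2, dimnames = list(NULL, c("tumor", "stroma")))
  got <- mem_variation(a, p)
  keep <- a != "Module0_NC"
  for (ty in c("tumor", "stroma")) {
    sds <- means <- numeric(0)
    for (m in sort(unique(a[keep]))) {
      v <- p[keep & a == m, ty]
      sds <- c(sds, sqrt(mean((v - mean(v))^2)))
      means <- c(means, mean(v))
    }
    expect_equal(got$intra[got$cell_type == ty], mean(sds), tolerance = 1e-12)
    expect_equal(got$inter[got$cell_type == ty],
                 sqrt(mean((means - mean(means))^2)), tolerance = 1e-12)
  }
})
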