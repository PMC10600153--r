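test_that("segmentation JSON reads with the correct type mapping", {
  f <- withr::local_tempfile(fileext = ".json")
  recs <- list(
    a = list(bbox = c(0, 0, 10, 10), centroid = c(5, 5),
             contour = list(c(0, 0), c(10, 0), c(5, 10)), type = 1),
    b = list(bbox = c(20, 20, 30, 30), centroid = c(25, 25),
             contour = list(c(20, 20), c(30, 20), c(25, 30)), type = 2),
    c = list(bbox = c(40, 40, 50, 50), centroid = c(45, 45),
             contour = list(c(40, 40), c(50, 40), c(45, 50)), type = 4))
  jsonlite::write_json(recs, f, auto_unbox = FALSE)
  ns <- read_segmentation(f)
  expect_equal(n_cells(ns), 3)
  expect_equal(ns$cells$type, c("tumor", "inflammatory", "dead"))
  expect_equal(ns$cells$id, c("a", "b", "c"))
})

test_that("empty record map gives an empty set without error", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", f)
  ns <- read_segmentation(f)
  expect_equal(n_cells(ns), 0)
})

test_that("unlabelled records are dropped with a warning and bad input errors", {
  f <- withr::local_tempfile(fileext = ".json")
  recs <- list(
    a = list(bbox = c(0, 0, 10, 10), centroid = c(5, 5),
             contour = list(c(0, 0), c(10, 0), c(5, 10)), type = 0),
    b = list(bbox = c(0, 0, 10, 10), centroid = c(5, 5),
             contour = list(c(0, 0), c(10, 0), c(5, 10)), type = 3))
  jsonlite::write_json(recs, f, auto_unbox = FALSE)
  expect_warning(ns <- read_segmentation(f), "dropped 1")
  expect_equal(ns$cells$id, "b")

  recs$a$type <- 9
  jsonlite::write_json(recs, f, auto_unbox = FALSE)
  expect_error(read_segmentation(f), "unknown type code 9.*nucleus a")

  recs$a <- list(centroid = c(1, 1))
  jsonlite::write_json(recs, f, auto_unbox = FALSE)
  expect_error(read_segmentation(f), "malformed record for nucleus a")
})

test_that("write_segmentation round-trips losslessly", {
  fld <- simulate_field(list(tumor = type_process("poisson", intensity = 150),
                             dead = type_process("poisson", intensity = 60)),
                        slide_um = c(400, 400), seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_segmentation(fld$ns, f)
  ns2 <- read_segmentation(f, slide_id = fld$ns$slide_id)
  expect_equal(ns2$cells$id, fld$ns$cells$id)
  expect_equal(ns2$cells$type, fld$ns$cells$type)
  expect_equal(ns2$cells$x, fld$ns$cells$x)
  expect_equal(ns2$cells$y, fld$ns$cells$y)
  for (id in fld$ns$cells$id)
    expect_equal(unname(ns2$contours[[id]]), unname(fld$ns$contours[[id]]))
})

test_that("filter_non_necrotic removes exactly the dead cells, idempotently", {
  cells <- random_cells(1000, seed = 2,
                        types = c("tumor", "inflammatory", "stroma", "dead"))
  ns <- make_point_ns(cells)
  filt <- filter_non_necrotic(ns)
  expect_equal(n_cells(filt), 1000 - sum(cells$type == "dead"))
  expect_false(any(filt$cells$type == "dead"))
  # order stability and idempotence
  expect_equal(filt$cells$id, cells$id[cells$type != "dead"])
  expect_equal(filter_non_necrotic(filt)$cells, filt$cells)
})

test_that("composition percentages match brute-force tallies and sum to 100", {
  cells <- data.frame(
    id = as.character(1:100),
    x = 0, y = 0,
    type = rep(c("tumor", "inflammatory", "stroma", "normal"),
               c(47, 16, 35, 2)), stringsAsFactors = FALSE)
  comp <- compute_composition(make_point_ns(cells))
  expect_equal(unname(comp$percent), c(47, 16, 35, 2))
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)

  rnd <- random_cells(500, seed = 9,
                      types = c("tumor", "inflammatory", "stroma", "normal", "dead"))
  ns <- filter_non_necrotic(make_point_ns(rnd))
  comp2 <- compute_composition(ns)
  for (ty in c("tumor", "inflammatory", "stroma", "normal"))
    expect_equal(unname(comp2$counts[ty]), sum(rnd$type == ty))
  expect_equal(sum(comp2$percent), 100, tolerance = 1e-9)
  expect_equal(comp2$total, sum(rnd$type != "dead"))

  empty <- compute_composition(make_point_ns(random_cells(0, seed = 1)[0, ]))
  expect_false(empty$defined)
  expect_true(all(is.na(empty$percent)))
})

test_that("all-tumor slides give 100 percent tumor", {
  cells <- random_cells(30, seed = 4, types = "tumor")
  comp <- compute_composition(make_point_ns(cells))
  expect_equal(unname(comp$percent["tumor"]), 100)
})

test_that("the four per-slide tables write and read back losslessly", {
  cells <- data.frame(id = c("t1", "t2", "s1"),
                      x = c(0, 50, 200), y = c(0, 50, 200),
                      type = c("tumor", "tumor", "stroma"),
                      stringsAsFactors = FALSE)
  ns <- make_point_ns(cells)
  feat <- assemble_cell_features(ns, nucleus_features = local({
    df <- compute_nucleus_features(ns)
    df
  }))
  edges <- combine_edges(build_all_graphs(ns))
  d <- withr::local_tempdir()
  write_feature_tables(ns, feat, edges, d)
  tabs <- read_feature_tables(d, "test")
  expect_equal(nrow(tabs$tumor), 2)
  expect_equal(nrow(tabs$stroma), 1)
  expect_equal(nrow(tabs$inflammatory), 0)
  expect_equal(nrow(tabs$edges), nrow(edges))
  # tumor tables carry no I-S topology columns
  expect_false(any(grepl("^I-S_", names(tabs$tumor))))
  expect_true(any(grepl("^T-T_", names(tabs$tumor))))
  # lossless numeric round-trip for the tumor table
  cols <- feature_columns_for_type(feat, "tumor")
  orig <- feat[feat$cell_type == "tumor", cols]
  rownames(orig) <- NULL
  expect_equal(tabs$tumor, orig, tolerance = 1e-12)
})

test_that("dangling feature ids error and empty slides give empty tables", {
  cells <- random_cells(3, seed = 3)
  ns <- make_point_ns(cells)
  feat <- data.frame(id = "ghost", x = 0, y = 0)
  expect_error(write_feature_tables(ns, feat, list(), withr::local_tempdir()),
               "unknown nucleus ids")
  ns0 <- make_point_ns(random_cells(0, seed = 1)[0, ])
  feat0 <- assemble_cell_features(ns0)
  d <- withr::local_tempdir()
  write_feature_tables(ns0, feat0, combine_edges(build_all_graphs(ns0)), d)
  tabs <- read_feature_tables(d, "test")
  expect_equal(nrow(tabs$tumor), 0)
  expect_equal(nrow(tabs$edges), 0)
})

test_that("neighbor queries equal the exhaustive distance sort", {
  cells <- random_cells(80, seed = 12, side = 300)
  ns <- make_point_ns(cells)
  for (qi in c(1, 40, 80)) {
    got <- nearest_neighbors(ns, cells$id[qi], k = 10)
    d <- sqrt((cells$x - cells$x[qi])^2 + (cells$y - cells$y[qi])^2)
    o <- order(d, cells$id, method = "radix")
    o <- o[o != qi][1:10]
    expect_equal(got$id, cells$id[o])
    expect_equal(got$dist, d[o])
  }
})
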