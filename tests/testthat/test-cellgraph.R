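two_cell_ns <- function(dist_px) {
  make_point_ns(data.frame(id = c("a", "b"), x = c(0, dist_px), y = 0,
                           type = "tumor", stringsAsFactors = FALSE))
}

test_that("edge construction honors the 100-px threshold", {
  es1 <- build_pairwise_graph(two_cell_ns(80), "tumor", "tumor")
  expect_equal(nrow(es1$edges), 1)
  expect_equal(es1$edges$length_px, 80)
  es2 <- build_pairwise_graph(two_cell_ns(120), "tumor", "tumor")
  expect_equal(nrow(es2$edges), 0)
  # a single cell has no neighbors
  one <- make_point_ns(data.frame(id = "a", x = 0, y = 0, type = "tumor"))
  expect_equal(nrow(build_pairwise_graph(one, "tumor", "tumor")$edges), 0)
  expect_error(build_pairwise_graph(one, "tumor", "dead"), "unprofiled")
})

test_that("all six graphs equal the exhaustive kNN + filter oracle", {
  pairs <- list(c("tumor", "tumor"), c("inflammatory", "inflammatory"),
                c("stroma", "stroma"), c("tumor", "inflammatory"),
                c("tumor", "stroma"), c("inflammatory", "stroma"))
  for (seed in 1:20) {
    n <- sample(c(50, 150, 300, 500), 1)
    cells <- random_cells(n, seed = seed, side = sqrt(n) * 60)
    ns <- make_point_ns(cells)
    for (p in pairs) {
      es <- build_pairwise_graph(ns, p[1], p[2])
      expect_identical(edge_keys(es), oracle_graph_keys(cells, p[1], p[2]),
                       label = paste("seed", seed, p[1], p[2]))
    }
  }
})

test_that("every edge respects the invariants", {
  cells <- random_cells(400, seed = 31, side = 1200)
  ns <- make_point_ns(cells)
  type_of <- setNames(cells$type, cells$id)
  for (es in build_all_graphs(ns)) {
    if (nrow(es$edges) == 0) next
    expect_true(all(es$edges$length_px < es$threshold_px))
    expect_true(all(es$edges$source_id != es$edges$target_id))
    key <- paste(pmin(es$edges$source_id, es$edges$target_id),
                 pmax(es$edges$source_id, es$edges$target_id))
    expect_false(any(duplicated(key)))
    expect_true(all(type_of[es$edges$source_id] == es$types[1]))
    expect_true(all(type_of[es$edges$target_id] == es$types[2]))
  }
})

test_that("topology of hand-enumerable graphs is exact", {
  # K3 triangle, 60 px sides
  tri <- make_point_ns(data.frame(id = c("a", "b", "c"),
                                  x = c(0, 60, 30), y = c(0, 0, 60 * sin(pi / 3)),
                                  type = "tumor", stringsAsFactors = FALSE))
  topo <- compute_topology(build_pairwise_graph(tri, "tumor", "tumor"), tri)
  expect_equal(topo$Degrees, rep(2, 3))
  expect_equal(topo$Nsubgraph, rep(3, 3))
  expect_equal(topo$ClusteringCoefficient, rep(1, 3))
  expect_equal(topo$Coreness, rep(2, 3))

  # 5-path a-b-c-d-e at 80 px spacing: only consecutive cells within 100 px
  path <- make_point_ns(data.frame(id = letters[1:5], x = (0:4) * 80, y = 0,
                                   type = "inflammatory",
                                   stringsAsFactors = FALSE))
  es <- build_pairwise_graph(path, "inflammatory", "inflammatory")
  expect_equal(nrow(es$edges), 4)
  topo <- compute_topology(es, path)
  rownames(topo) <- topo$id
  expect_equal(topo["c", "Betweenness"], 4)
  expect_equal(topo["a", "Betweenness"], 0)
  d <- oracle_shortest_paths(letters[1:5], es$edges)
  expect_equal(topo$Eccentricity, unname(apply(d, 1, max)))
  expect_equal(topo$Closeness, unname(1 / rowSums(d)))
  expect_equal(topo$HarmonicCentrality,
               unname(sapply(1:5, function(i) sum(1 / d[i, -i]))))
  expect_equal(topo$Betweenness, unname(oracle_betweenness(letters[1:5], es$edges)))
  expect_equal(topo$Betweenness_normed, topo$Betweenness / (4 * 3 / 2))
  expect_equal(topo$Eccentricity_normed, topo$Eccentricity / 4)
  expect_equal(topo$ClusteringCoefficient, rep(0, 5))
  expect_equal(topo$MeanEdgeLength, c(80, 80, 80, 80, 80))
})

test_that("isolated cells carry the sentinel conventions", {
  iso <- make_point_ns(data.frame(id = c("i1", "i2"), x = c(0, 500), y = 0,
                                  type = "inflammatory",
                                  stringsAsFactors = FALSE))
  topo <- compute_topology(build_pairwise_graph(iso, "inflammatory",
                                                "inflammatory"), iso)
  expect_equal(topo$Degrees, c(0, 0))
  expect_equal(topo$Nsubgraph, c(1, 1))
  expect_equal(topo$MinEdgeLength, c(100, 100))
  expect_equal(topo$MeanEdgeLength, c(100, 100))
  expect_equal(topo$Closeness, c(0, 0))
  expect_equal(topo$ClusteringCoefficient, c(0, 0))
  expect_equal(topo$Eccentricity_normed, c(0, 0))
})

test_that("centralities match exhaustive shortest-path oracles on random fields", {
  for (seed in c(3, 11)) {
    cells <- random_cells(60, seed = seed, side = 500)
    ns <- make_point_ns(cells)
    es <- build_pairwise_graph(ns, "tumor", "stroma")
    ids <- cells$id[cells$type %in% c("tumor", "stroma")]
    topo <- compute_topology(es, ns)
    expect_equal(topo$id, ids)
    d <- oracle_shortest_paths(ids, es$edges)
    conn <- is.finite(d)
    expect_equal(topo$Nsubgraph, unname(rowSums(conn)))
    ecc_o <- vapply(seq_along(ids), function(i) {
      dd <- d[i, conn[i, ]]
      if (length(dd) > 1) max(dd) else 0
    }, numeric(1))
    expect_equal(topo$Eccentricity, ecc_o)
    clo_o <- vapply(seq_along(ids), function(i) {
      dd <- d[i, conn[i, ] & seq_along(ids) != i]
      if (length(dd) == 0) 0 else 1 / sum(dd)
    }, numeric(1))
    expect_equal(topo$Closeness, clo_o)
    expect_equal(topo$Betweenness, unname(oracle_betweenness(ids, es$edges)),
                 tolerance = 1e-9)
    # degrees equal incident-edge counts; edge-length stats bounded
    inc <- table(factor(c(es$edges$source_id, es$edges$target_id), levels = ids))
    expect_equal(topo$Degrees, unname(as.numeric(inc)))
    expect_true(all(topo$MeanEdgeLength >= topo$MinEdgeLength - 1e-12))
    expect_true(all(topo$MeanEdgeLength <= 100))
    # heterotypic graphs carry no clustering coefficient
    expect_false("ClusteringCoefficient" %in% names(topo))
  }
})

test_that("StromaBlocker counts corridor stroma cells", {
  # stroma cell exactly on the midpoint of a 60-px tumor-inflammatory segment
  cells <- data.frame(id = c("i", "t", "s"),
                      x = c(0, 60, 30), y = 0,
                      type = c("inflammatory", "tumor", "stroma"),
                      stringsAsFactors = FALSE)
  sb <- compute_stroma_blocker(make_point_ns(cells))
  expect_equal(sb$StromaBlocker, 1)
  # no stroma cells at all
  sb0 <- compute_stroma_blocker(make_point_ns(cells[1:2, ]))
  expect_equal(sb0$StromaBlocker, 0)
  # no tumor cell within the radius
  far <- cells; far$x[2] <- 1000
  expect_equal(compute_stroma_blocker(make_point_ns(far))$StromaBlocker, 0)
})

test_that("StromaBlocker equals the geometric brute-force enumeration", {
  for (seed in c(5, 23)) {
    cells <- random_cells(150, seed = seed, side = 600)
    ns <- make_point_ns(cells)
    got <- compute_stroma_blocker(ns, k = 5, radius_px = 300, corridor_px = 15)
    infl <- cells[cells$type == "inflammatory", ]
    tum <- cells[cells$type == "tumor", ]
    str <- cells[cells$type == "stroma", ]
    for (r in seq_len(nrow(infl))) {
      d <- sqrt((tum$x - infl$x[r])^2 + (tum$y - infl$y[r])^2)
      o <- order(d, tum$id, method = "radix")
      o <- o[d[o] <= 300]
      o <- o[seq_len(min(5, length(o)))]
      want <- if (length(o) == 0) 0 else mean(vapply(o, function(j) {
        a <- c(infl$x[r], infl$y[r]); b <- c(tum$x[j], tum$y[j])
        v <- b - a; L2 <- sum(v^2)
        tpar <- pmin(1, pmax(0, ((str$x - a[1]) * v[1] + (str$y - a[2]) * v[2]) / L2))
        dd <- sqrt((str$x - (a[1] + tpar * v[1]))^2 +
                   (str$y - (a[2] + tpar * v[2]))^2)
        sum(dd <= 15)
      }, numeric(1)))
      expect_equal(got$StromaBlocker[got$id == infl$id[r]], want)
    }
  }
})

test_that("assembled feature tables have the membership-correct columns", {
  cells <- data.frame(id = c("t1", "i1", "s1"),
                      x = c(0, 50, 90), y = 0,
                      type = c("tumor", "inflammatory", "stroma"),
                      stringsAsFactors = FALSE)
  ns <- make_point_ns(cells)
  feat <- assemble_cell_features(ns)
  expect_equal(nrow(feat), 3)
  expect_true(all(c("T-T_Degrees", "T-I_Degrees", "T-S_Degrees",
                    "I-I_ClusteringCoefficient", "StromaBlocker")
                  %in% names(feat)))
  expect_false("T-I_ClusteringCoefficient" %in% names(feat))
  # tumor row has its three graphs populated, I-S absent (NA)
  trow <- feat[feat$cell_type == "tumor", ]
  expect_false(anyNA(trow[, c("T-T_Degrees", "T-I_Degrees", "T-S_Degrees")]))
  expect_true(is.na(trow[["I-S_Degrees"]]))
  # inflammatory row carries StromaBlocker; tumor row does not
  expect_false(is.na(feat$StromaBlocker[feat$cell_type == "inflammatory"]))
  expect_true(is.na(feat$StromaBlocker[feat$cell_type == "tumor"]))
})

test_that("clustered fields are denser than Poisson fields of equal intensity", {
  mean_ii <- function(proc, seed) {
    fld <- simulate_field(list(inflammatory = proc), slide_um = c(800, 800),
                          seed = seed)
    topo <- compute_topology(
      build_pairwise_graph(fld$ns, "inflammatory", "inflammatory"), fld$ns)
    c(deg = mean(topo$Degrees), minl = mean(topo$MinEdgeLength))
  }
  th <- mean_ii(type_process("thomas", intensity = 250, parents_per_mm2 = 6,
                             sigma_um = 20), seed = 8)
  po <- mean_ii(type_process("poisson", intensity = 250), seed = 8)
  expect_gt(th["deg"], po["deg"])
  expect_lt(th["minl"], po["minl"])
})
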