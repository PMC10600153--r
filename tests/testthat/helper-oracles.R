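# Independent brute-force oracles and tiny fixture builders shared by the
# suite. Oracles are deliberately naive (full enumeration, double loops) and
# never call the code paths they check.

# random mixed-type cell table (px coordinates)
random_cells <- function(n, seed, side = 2000,
                         types = c("tumor", "inflammatory", "stroma")) {
  set.seed(seed)
  data.frame(id = sprintf("n%04d", seq_len(n)),
             x = runif(n, 0, side), y = runif(n, 0, side),
             type = sample(types, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# wrap a point table into a nucleus_set with dummy triangular contours
make_point_ns <- function(cells, mpp = 0.25) {
  contours <- lapply(seq_len(nrow(cells)), function(i)
    cbind(cells$x[i] + c(-1, 1, 0), cells$y[i] + c(-1, -1, 1)))
  names(contours) <- cells$id
  cells$xmin <- cells$x - 1; cells$xmax <- cells$x + 1
  cells$ymin <- cells$y - 1; cells$ymax <- cells$y + 1
  nucleus_set("test", cells, contours, mpp = mpp)
}

# exhaustive kNN + threshold pairwise-graph oracle; returns sorted pair keys
oracle_graph_keys <- function(cells, c1, c2, k = 5, threshold = 100) {
  a <- cells[cells$type == c1, ]
  b <- cells[cells$type == c2, ]
  keys <- character(0)
  add_dir <- function(src, dst) {
    for (i in seq_len(nrow(src))) {
      d <- sqrt((dst$x - src$x[i])^2 + (dst$y - src$y[i])^2)
      ids <- dst$id
      self <- ids == src$id[i]
      d <- d[!self]; ids <- ids[!self]
      if (length(d) == 0) next
      o <- order(d, ids, method = "radix")[seq_len(min(k, length(d)))]
      sel <- o[d[o] < threshold]
      if (length(sel))
        keys <<- c(keys, paste(pmin(src$id[i], ids[sel]),
                               pmax(src$id[i], ids[sel]), sep = "|"))
    }
  }
  add_dir(a, b)
  if (!identical(c1, c2)) add_dir(b, a)
  sort(unique(keys))
}

edge_keys <- function(es) {
  if (nrow(es$edges) == 0) return(character(0))
  sort(paste(pmin(es$edges$source_id, es$edges$target_id),
             pmax(es$edges$source_id, es$edges$target_id), sep = "|"))
}

# all-pairs shortest hop counts by repeated BFS over an edge list
oracle_shortest_paths <- function(ids, edges) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    adj[edges$source_id[r], edges$target_id[r]] <- TRUE
    adj[edges$target_id[r], edges$source_id[r]] <- TRUE
  }
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  d[adj] <- 1
  for (via in seq_len(n)) for (i in seq_len(n))
    d[i, ] <- pmin(d[i, ], d[i, via] + d[via, ])
  d
}

# brute-force betweenness by enumerating all shortest paths (tiny graphs)
oracle_betweenness <- function(ids, edges) {
  n <- length(ids)
  d <- oracle_shortest_paths(ids, edges)
  adj <- d == 1
  # count shortest paths by DP over hop distance
  nsp <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(nsp) <- 1
  for (L in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (is.finite(d[s, t]) && d[s, t] == L) {
        pred <- which(adj[, t] & d[s, ] == L - 1)
        nsp[s, t] <- sum(nsp[s, pred])
      }
    }
  }
  btw <- numeric(n); names(btw) <- ids
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || s == v || t == v) next
    if (!is.finite(d[s, t]) || nsp[s, t] == 0) next
    if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
        d[s, v] + d[v, t] == d[s, t])
      btw[v] <- btw[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
  }
  btw
}

# pair-counting GLCM oracle for one offset (dy, dx), symmetric, normalized
oracle_glcm <- function(q, mask, dy, dx, n_levels) {
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
    r2 <- r + dy; c2 <- c + dx
    if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
    if (!mask[r, c] || !mask[r2, c2]) next
    counts[q[r, c] + 1, q[r2, c2] + 1] <- counts[q[r, c] + 1, q[r2, c2] + 1] + 1
    counts[q[r2, c2] + 1, q[r, c] + 1] <- counts[q[r2, c2] + 1, q[r, c] + 1] + 1
  }
  counts
}

oracle_glcm_features <- function(patch, mask, n_levels = 32) {
  q <- matrix(pmin(n_levels - 1, floor(patch / (256 / n_levels))),
              nrow(patch), ncol(patch))
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  acc <- NULL
  n_used <- 0
  for (o in offs) {
    cnt <- oracle_glcm(q, mask, o[1], o[2], n_levels)
    if (sum(cnt) == 0) next
    p <- cnt / sum(cnt)
    lv <- 0:(n_levels - 1)
    i <- matrix(lv, n_levels, n_levels); j <- t(i)
    mi <- sum(i * p); mj <- sum(j * p)
    si <- sqrt(sum((i - mi)^2 * p)); sj <- sqrt(sum((j - mj)^2 * p))
    nz <- p[p > 0]
    f <- c(ASM = sum(p^2), Contrast = sum((i - j)^2 * p),
           Correlation = if (si > 0 && sj > 0)
             sum((i - mi) * (j - mj) * p) / (si * sj) else 0,
           Entropy = -sum(nz * log2(nz)),
           Homogeneity = sum(p / (1 + (i - j)^2)))
    acc <- if (is.null(acc)) f else acc + f
    n_used <- n_used + 1
  }
  acc / n_used
}

# double-loop Moran's I / bivariate spatial correlation oracles
oracle_morans <- function(x, w) {
  n <- length(x); xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(w)) * num / sum((x - xb)^2)
}

oracle_spatial_corr <- function(x, y, w) {
  n <- length(x); xb <- mean(x); yb <- mean(y)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (x[i] - xb) * (y[j] - yb)
  (n / sum(w)) * num / (sqrt(sum((x - xb)^2)) * sqrt(sum((y - yb)^2)))
}

# direct evaluation of the MITH formula
oracle_mith <- function(x) {
  N <- ncol(x); M <- nrow(x)
  s <- 0
  for (i in seq_len(N)) {
    xi <- x[, i]
    s <- s + sqrt(sum((xi - mean(xi))^2) / M)
  }
  s / N
}

# a wiggly closed test contour (ellipse + harmonics), deterministic per seed
random_blob_contour <- function(seed, cx = 40, cy = 40, r = 12,
                                n_vertices = 64) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ratio <- exp(rnorm(1, 0, 0.2))
  pert <- 1 + 0.15 * rnorm(1) * cos(2 * th + runif(1, 0, 2 * pi)) +
    0.1 * rnorm(1) * cos(3 * th + runif(1, 0, 2 * pi))
  pert <- pmax(pert, 0.3)
  cbind(cx + r * ratio * cos(th) * pert, cy + (r / ratio) * sin(th) * pert)
}

# the two-regime colocalization slide used by MEM recovery checks
coloc_regions <- function(intensity = 400) {
  list(list(rect_um = c(0, 0, 800, 1600),
            clusters = c(A = intensity, B = intensity),
            types = c(A = "tumor", B = "stroma")),
       list(rect_um = c(800, 0, 1600, 1600),
            clusters = c(C = intensity, D = intensity),
            types = c(C = "inflammatory", D = "stroma")))
}
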