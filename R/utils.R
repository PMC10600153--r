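# internal helpers shared across modules

#' @keywords internal
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(sum((x - m)^2) / length(x))
}

# Euclidean distances from one point to many (row-wise matrix of x,y)
#' @keywords internal
dist_to <- function(p, xy) {
  sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)
}

# deterministic order: by value, ties by id (character sort)
#' @keywords internal
order_dist_id <- function(d, ids) order(d, ids, method = "radix")

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# weighted F1 over a confusion of factor-coded truth/prediction
#' @keywords internal
weighted_f1 <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  w <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1 * w) / sum(w)
}

# Calinski-Harabasz index for a labelled numeric matrix
#' @keywords internal
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(x)
  bss <- 0
  wss <- 0
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    ci <- colMeans(xi)
    bss <- bss + nrow(xi) * sum((ci - grand)^2)
    wss <- wss + sum(sweep(xi, 2, ci)^2)
  }
  if (wss == 0) return(Inf)
  (bss / (k - 1)) / (wss / (n - k))
}
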