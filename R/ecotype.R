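# Sample-level MEM composition, ecotype discovery and SVM classification.

#' Per-sample MEM composition
#'
#' Fraction of each sample's classified spots assigned to each module.
#' Module0_NC (no-cell) spots are excluded from the denominator by default.
#'
#' @param sample_ids Sample id per spot.
#' @param modules Assigned module per spot.
#' @param module_names Optional fixed module universe for the columns.
#' @param drop_nc Exclude Module0_NC spots (default TRUE).
#' @return Samples x modules matrix of fractions (rows sum to 1); a sample
#'   with zero classified spots has an all-NaN row.
#' @export
mem_composition <- function(sample_ids, modules, module_names = NULL,
                            drop_nc = TRUE) {
  stopifnot(length(sample_ids) == length(modules))
  if (drop_nc) {
    keep <- modules != "Module0_NC"
    sample_ids_kept <- sample_ids[keep]
    modules <- modules[keep]
  } else sample_ids_kept <- sample_ids
  lev <- module_names %||% sort(unique(modules))
  tab <- table(factor(sample_ids_kept, levels = unique(sample_ids)),
               factor(modules, levels = lev))
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  frac <- sweep(m, 1, rowSums(m), "/")
  empty <- rowSums(m) == 0
  if (any(empty))
    warning("sample(s) with zero classified spots: ",
            paste(rownames(m)[empty], collapse = ", "))
  frac
}

#' Cluster samples into ecotypes by their MEM composition
#'
#' Ward hierarchical clustering of the composition vectors. The number of
#' ecotypes is chosen over \code{k_range} by maximizing the mean Silhouette
#' coefficient, with ties broken by the Calinski-Harabasz index.
#'
#' @param composition Samples x modules matrix (rows sum to 1).
#' @param k_range Candidate numbers of ecotypes (default 2:10, clipped to
#'   samples - 1).
#' @param seed Integer seed (kept for interface symmetry; the procedure is
#'   deterministic).
#' @return List of class \code{ecotype_model}: \code{composition},
#'   \code{tree}, \code{k}, \code{labels} (1..k per sample),
#'   \code{selection} (per-k silhouette and CH table), \code{seed}.
#' @export
cluster_ecotypes <- function(composition, k_range = 2:10, seed = 0) {
  composition <- as.matrix(composition)
  n <- nrow(composition)
  stopifnot(n >= 4)
  if (max(stats::dist(composition)) < 1e-12)
    stop("all sample compositions are identical; ecotypes are undefined")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  stopifnot(length(k_range) >= 1)
  d <- stats::dist(composition)
  tree <- stats::hclust(d, method = "ward.D2")
  sel <- data.frame(k = k_range, silhouette = NA_real_, ch = NA_real_)
  for (i in seq_along(k_range)) {
    lab <- stats::cutree(tree, k = k_range[i])
    sil <- cluster::silhouette(lab, d)
    sel$silhouette[i] <- mean(sil[, "sil_width"])
    sel$ch[i] <- calinski_harabasz(composition, lab)
  }
  best <- order(-sel$silhouette, -sel$ch)[1]
  k <- sel$k[best]
  labels <- stats::cutree(tree, k = k)
  structure(list(composition = composition, tree = tree, k = k,
                 labels = labels, selection = sel, seed = seed),
            class = "ecotype_model")
}

#' @export
print.ecotype_model <- function(x, ...) {
  cat("<ecotype_model>", nrow(x$composition), "samples,", x$k, "ecotypes\n")
  print(table(x$labels))
  invisible(x)
}

#' Stratified train/test split indices
#' @keywords internal
stratified_split <- function(labels, train_frac, seed) {
  set.seed(seed)
  train <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    m <- round(length(idx) * train_frac)
    m <- min(max(m, 1), length(idx) - 1)
    train <- c(train, sort(sample(idx, m)))
  }
  sort(train)
}

#' Train an SVM ecotype classifier on MEM compositions
#'
#' Stratified split of the samples into a training set (default 80 percent)
#' and a test set, radial-basis SVM on the composition vectors, and the
#' weighted F1 score on the held-out test set.
#'
#' @param em An \code{ecotype_model}.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed for the split.
#' @param kernel SVM kernel (default "radial").
#' @param cost SVM regularization parameter.
#' @return List of class \code{ecotype_classifier}: \code{svm},
#'   \code{train_idx}, \code{test_idx}, \code{weighted_f1},
#'   \code{module_names}.
#' @export
train_ecotype_classifier <- function(em, train_frac = 0.8, seed = 0,
                                     kernel = "radial", cost = 1) {
  labels <- factor(em$labels)
  if (any(table(labels) < 2))
    stop("every ecotype needs at least 2 samples to split; ",
         "merge small classes or evaluate without a held-out set")
  train <- stratified_split(em$labels, train_frac, seed)
  test <- setdiff(seq_along(labels), train)
  x <- em$composition
  fit <- e1071::svm(x = x[train, , drop = FALSE], y = labels[train],
                    kernel = kernel, cost = cost)
  pred <- stats::predict(fit, x[test, , drop = FALSE])
  f1 <- weighted_f1(labels[test], pred)
  structure(list(svm = fit, train_idx = train, test_idx = test,
                 weighted_f1 = f1, module_names = colnames(x),
                 classes = levels(labels)),
            class = "ecotype_classifier")
}

#' Classify a sample's ecotype from its MEM composition
#'
#' @param clf An \code{ecotype_classifier}.
#' @param composition Named composition vector (or matrix of rows) matching
#'   the training schema; each row must sum to about 1.
#' @return Ecotype label(s) as character.
#' @export
classify_ecotype <- function(clf, composition) {
  if (is.null(dim(composition))) composition <- t(as.matrix(composition))
  if (!all(clf$module_names %in% colnames(composition)))
    stop("composition lacks module columns: ",
         paste(setdiff(clf$module_names, colnames(composition)), collapse = ", "))
  x <- composition[, clf$module_names, drop = FALSE]
  if (any(abs(rowSums(x) - 1) > 0.01))
    stop("composition rows must sum to 1")
  as.character(stats::predict(clf$svm, x))
}
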