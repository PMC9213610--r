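#' Clustering purity of sample labels
#'
#' Unsupervised hierarchical clustering of the samples (average
#' linkage on the correlation distance `1 - Pearson` between beta
#' profiles), cut to `k` clusters; purity is the fraction of samples
#' falling in their cluster's majority label,
#' `sum_c max_label |c intersect label| / n`. Samples clustering
#' cleanly by tissue (purity 1) is the integrity check run before any
#' modeling.
#'
#' @param beta Probes x samples beta matrix (no missing values).
#' @param labels Per-sample labels aligned with `colnames(beta)`.
#' @param k Number of clusters (default: number of distinct labels).
#' @return Purity fraction in \[0, 1\], with the cluster assignment as
#'   attribute `"clusters"`.
#' @export
cluster_purity <- function(beta, labels, k = length(unique(labels))) {
  stopifnot(ncol(beta) == length(labels))
  if (ncol(beta) < k) stop("fewer samples than clusters")
  if (length(unique(labels)) < 2L && k > 1L) stop("need at least 2 distinct labels")
  d <- stats::as.dist(1 - stats::cor(beta))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  purity <- sum(vapply(split(labels, cl),
                       function(l) max(table(l)), numeric(1L))) / length(labels)
  structure(purity, clusters = cl)
}

#' Out-of-bag classification error for sample labels
#'
#' Random-forest classifier (bagged trees, sqrt(p) candidate features
#' per split, unrestricted depth) of a per-sample label from the beta
#' profiles; the out-of-bag error is the fraction of samples
#' misclassified by the majority vote of the trees whose bootstrap
#' sample excluded them. Zero OOB error on tissue and sex is the
#' platemap-integrity check.
#'
#' @param beta Probes x samples beta matrix (no missing values).
#' @param labels Per-sample class labels (>= 2 classes, each with >= 3
#'   samples).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return OOB error fraction in \[0, 1\].
#' @export
oob_classifier_error <- function(beta, labels, n_trees = 500L, seed = 1L) {
  stopifnot(ncol(beta) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes")
  if (any(tab < 3L)) stop("every class needs at least 3 samples")
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = t(beta), y = factor(labels),
                                   ntree = n_trees)
  pred <- rf$predicted
  mean(pred != factor(labels))
}

#' Sample-integrity QC report
#'
#' Runs [cluster_purity()] and [oob_classifier_error()] for each label
#' type present (tissue; sex when recorded) and returns a
#' JSON-serializable summary.
#'
#' @param beta Probes x samples beta matrix.
#' @param samples Sample sheet aligned with `colnames(beta)`.
#' @param n_trees,seed Passed to [oob_classifier_error()].
#' @return List with `clustering_purity` and `oob_error` per label
#'   type, plus the parameters used.
#' @export
qc_report <- function(beta, samples, n_trees = 500L, seed = 1L) {
  samples <- align_samples(beta, samples)
  label_types <- list(tissue = samples$tissue)
  if (!all(is.na(samples$sex)) && length(unique(samples$sex)) > 1L) {
    label_types$sex <- samples$sex
  }
  purity <- lapply(label_types, function(l) as.numeric(cluster_purity(beta, l)))
  oob <- lapply(label_types, function(l) {
    tab <- table(l)
    if (length(tab) < 2L || any(tab < 3L)) return(NA_real_)
    oob_classifier_error(beta, l, n_trees = n_trees, seed = seed)
  })
  list(clustering_purity = purity, oob_error = oob,
       parameters = list(distance = "1 - Pearson", linkage = "average",
                         n_trees = n_trees, seed = as.integer(seed)))
}
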