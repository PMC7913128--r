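# Cluster-consensus analysis of high-BEDROC models: target relevance,
# global desirability of a drug library, overlap and correlation summaries.

#' Select models above a fitness threshold
#'
#' Keeps every model with fitness at or above the threshold (inclusive).
#' Duplicate masks are retained: their multiplicity carries information
#' about GA convergence and weights the relevance profile.
#'
#' @param models a `ga_result`, or a list with elements `masks` (0/1 matrix,
#'   one model per row) and `fitness`.
#' @param threshold minimum fitness (default 0.15).
#' @return list of class `model_population` with `masks`, `fitness`,
#'   `threshold`.
#' @export
select_models <- function(models, threshold = 0.15) {
  if (inherits(models, "ga_result")) {
    masks <- models$population; fitness <- models$fitness
  } else {
    masks <- as.matrix(models$masks); fitness <- models$fitness
  }
  stopifnot(nrow(masks) == length(fitness))
  keep <- fitness >= threshold
  if (!any(keep)) {
    stop("no model reaches fitness ", threshold,
         "; consider lowering the threshold")
  }
  structure(list(masks = masks[keep, , drop = FALSE],
                 fitness = fitness[keep], threshold = threshold),
            class = "model_population")
}

#' @export
print.model_population <- function(x, ...) {
  cat("model_population:", nrow(x$masks), "models with fitness >=",
      x$threshold, "\n")
  invisible(x)
}

#' Cluster selected models by their mask fingerprints
#'
#' Agglomerative clustering of the model bit vectors under Euclidean
#' distance, cut into `k` clusters. Ward linkage (`"ward.D2"`) is the
#' default; `"average"` is available for reproduction against externally
#' clustered model sets.
#'
#' @param models a `model_population` from [select_models()].
#' @param k number of clusters, `1 <= k <=` number of models.
#' @param method linkage method passed to [stats::hclust()].
#' @return list of class `cluster_assignment` with `cluster` (integer per
#'   model), `k`, `method` and the `hclust` tree.
#' @export
cluster_models <- function(models, k, method = "ward.D2") {
  stopifnot(inherits(models, "model_population"), k >= 1)
  m <- nrow(models$masks)
  if (k > m) stop("k (", k, ") exceeds the number of models (", m, ")")
  hc <- stats::hclust(stats::dist(models$masks, method = "euclidean"),
                      method = method)
  cl <- stats::cutree(hc, k = k)
  structure(list(cluster = as.integer(cl), k = as.integer(k),
                 method = method, hclust = hc),
            class = "cluster_assignment")
}

#' Per-cluster target relevance
#'
#' The relevance S of target i within a cluster is the fraction of the
#' cluster's models whose mask includes target i (the normalized selection
#' frequency).
#'
#' @param models a `model_population`.
#' @param clusters optional `cluster_assignment`; omitted, all models form
#'   one cluster.
#' @return matrix of class `relevance_profile` (targets x clusters, values
#'   in \[0, 1\]) with the per-cluster model counts in attribute `"m"`.
#' @export
target_relevance <- function(models, clusters = NULL) {
  stopifnot(inherits(models, "model_population"))
  cl <- if (is.null(clusters)) rep(1L, nrow(models$masks)) else clusters$cluster
  stopifnot(length(cl) == nrow(models$masks))
  ks <- sort(unique(cl))
  S <- vapply(ks, function(g) colMeans(models$masks[cl == g, , drop = FALSE]),
              numeric(ncol(models$masks)))
  S <- matrix(S, ncol = length(ks),
              dimnames = list(colnames(models$masks), paste0("C", ks)))
  structure(S, m = vapply(ks, function(g) sum(cl == g), integer(1)),
            class = c("relevance_profile", class(S)))
}

#' Global desirability of a drug library under clustered models
#'
#' For every cluster, the global desirability GD of a library compound is
#' the mean of its desirability over all of that cluster's model masks --
#' the cluster-consensus repurposing score. Invalid masks (selecting no
#' target or no off-target) are skipped with a warning.
#'
#' @param pm a [probability_matrix()] of the drug library (columns must
#'   match the mask length).
#' @param models a `model_population`.
#' @param clusters optional `cluster_assignment`; omitted, one cluster.
#' @return matrix (compounds x clusters, values in \[0, 1\]) with cluster
#'   model counts in attribute `"m"`.
#' @export
global_desirability <- function(pm, models, clusters = NULL) {
  stopifnot(inherits(pm, "prob_matrix"), inherits(models, "model_population"))
  if (ncol(models$masks) != ncol(pm$P)) {
    stop("mask length (", ncol(models$masks),
         ") does not match the library's column count (", ncol(pm$P), ")")
  }
  cl <- if (is.null(clusters)) rep(1L, nrow(models$masks)) else clusters$cluster
  ks <- sort(unique(cl))
  is_t <- pm$roles == "target"
  A <- pm$P[, is_t, drop = FALSE]
  B <- 1 - pm$P[, !is_t, drop = FALSE]
  skipped <- 0L
  GD <- vapply(ks, function(g) {
    masks <- models$masks[cl == g, , drop = FALSE]
    nt <- rowSums(masks[, is_t, drop = FALSE])
    no <- rowSums(masks[, !is_t, drop = FALSE])
    ok <- nt > 0 & no > 0
    skipped <<- skipped + sum(!ok)
    if (!any(ok)) stop("cluster ", g, " contains no valid mask")
    masks <- masks[ok, , drop = FALSE]
    PT <- sweep(A %*% t(masks[, is_t, drop = FALSE]), 2, nt[ok], "/")
    PO <- sweep(B %*% t(masks[, !is_t, drop = FALSE]), 2, no[ok], "/")
    rowMeans(PT * PO)
  }, numeric(nrow(pm$P)))
  if (skipped > 0) warning(skipped, " invalid mask(s) skipped")
  GD <- matrix(GD, ncol = length(ks),
               dimnames = list(rownames(pm$P), paste0("C", ks)))
  attr(GD, "m") <- vapply(ks, function(g) sum(cl == g), integer(1))
  GD
}

#' Top-list overlap across clusters
#'
#' Extracts the `top_n` compounds per cluster by global desirability (ties
#' broken by compound id) and summarizes how the per-cluster lists overlap:
#' union size, all-cluster intersection size, and the full Venn counts (one
#' count per non-empty cluster-membership pattern).
#'
#' @param gd matrix from [global_desirability()].
#' @param top_n list depth per cluster (default 50).
#' @return list with `top` (list of per-cluster id vectors), `union_size`,
#'   `intersection_size`, and `venn` (named integer vector; names are
#'   membership patterns like `"C1&C3"`).
#' @export
top_overlap <- function(gd, top_n = 50) {
  gd <- as.matrix(gd)
  stopifnot(top_n >= 1, top_n <= nrow(gd))
  ids <- rownames(gd)
  top <- lapply(seq_len(ncol(gd)), function(j) {
    ids[order(-gd[, j], ids)][seq_len(top_n)]
  })
  names(top) <- colnames(gd)
  all_ids <- sort(unique(unlist(top)))
  membership <- vapply(top, function(t) all_ids %in% t, logical(length(all_ids)))
  membership <- matrix(membership, nrow = length(all_ids),
                       dimnames = list(all_ids, colnames(gd)))
  pattern <- apply(membership, 1, function(r) {
    paste(colnames(membership)[r], collapse = "&")
  })
  venn <- table(pattern)
  list(top = top,
       union_size = length(all_ids),
       intersection_size = sum(rowSums(membership) == ncol(gd)),
       venn = stats::setNames(as.integer(venn), names(venn)))
}

#' Pairwise correlation of cluster consensus scores
#'
#' Correlates the per-cluster global-desirability vectors of the library
#' and summarizes the off-diagonal entries.
#'
#' @param gd matrix from [global_desirability()] with at least two columns.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `matrix` (symmetric, unit diagonal), `mean`, `min`,
#'   `max` over off-diagonal entries.
#' @export
cluster_correlation <- function(gd, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  gd <- as.matrix(gd)
  if (ncol(gd) < 2) stop("need at least two clusters to correlate")
  if (any(apply(gd, 2, stats::sd) == 0)) {
    stop("a cluster has zero-variance global desirability; correlation undefined")
  }
  cm <- stats::cor(gd, method = method)
  off <- cm[upper.tri(cm)]
  list(matrix = cm, mean = mean(off), min = min(off), max = max(off))
}

#' Count category codes over a drug list
#'
#' Tallies the frequency of each category code (e.g. ATC level 1/2 classes)
#' among the listed drugs. A drug with several codes counts once per
#' distinct code; drugs absent from the table count under `"unannotated"`.
#'
#' @param drugs character vector of drug ids.
#' @param categories data frame with columns `drug_id` and `code`.
#' @return named integer vector of counts, decreasing.
#' @export
category_counts <- function(drugs, categories) {
  stopifnot(is.data.frame(categories),
            all(c("drug_id", "code") %in% names(categories)))
  drugs <- as.character(drugs)
  if (!length(drugs)) return(stats::setNames(integer(), character()))
  counts <- integer()
  for (d in drugs) {
    codes <- unique(as.character(categories$code[categories$drug_id == d]))
    if (!length(codes)) codes <- "unannotated"
    for (cc in codes) counts[cc] <- (if (cc %in% names(counts)) counts[cc] else 0L) + 1L
  }
  sort(counts, decreasing = TRUE)
}
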