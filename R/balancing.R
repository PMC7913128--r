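# Class balancing by PCA + k-means + silhouette-guided proportional
# undersampling, and the external validation split.

#' Fingerprint table
#'
#' Container tying compound ids to their binary fingerprints and
#' active/inactive labels.
#'
#' @param compound_id character vector of compound ids (unique).
#' @param bits integer 0/1 matrix, one row per compound, equal-length rows.
#' @param label vector coercible to factor with levels active/inactive.
#' @return object of class `fp_table`.
#' @export
fp_table <- function(compound_id, bits, label) {
  compound_id <- as.character(compound_id)
  bits <- as.matrix(bits)
  label <- factor(as.character(label), levels = c("active", "inactive"))
  stopifnot(!anyDuplicated(compound_id),
            nrow(bits) == length(compound_id),
            length(label) == length(compound_id),
            !anyNA(label),
            all(bits %in% c(0L, 1L)))
  structure(list(compound_id = compound_id, bits = bits, label = label),
            class = "fp_table")
}

#' @export
print.fp_table <- function(x, ...) {
  cat("fp_table:", length(x$compound_id), "compounds x", ncol(x$bits), "bits;",
      sum(x$label == "active"), "active /", sum(x$label == "inactive"),
      "inactive\n")
  invisible(x)
}

# subset an fp_table by row index
fp_subset <- function(x, idx) {
  fp_table(x$compound_id[idx], x$bits[idx, , drop = FALSE], x$label[idx])
}

#' Largest-remainder apportionment
#'
#' Distributes an integer `quota` over groups proportionally to `sizes`,
#' flooring the proportional shares and assigning leftover units to the
#' largest fractional remainders (ties to the earlier group). Quotas never
#' exceed group sizes; overflow is reassigned to groups with spare capacity.
#'
#' @param sizes positive integer group sizes.
#' @param quota total to distribute, `0 <= quota <= sum(sizes)`.
#' @return integer vector of per-group quotas summing exactly to `quota`.
#' @examples
#' apportion_quota(c(60, 40), 50)  # 30 and 20
#' @export
apportion_quota <- function(sizes, quota) {
  sizes <- as.integer(sizes)
  stopifnot(all(sizes > 0), quota >= 0, quota <= sum(sizes))
  share <- quota * sizes / sum(sizes)
  q <- floor(share)
  left <- quota - sum(q)
  if (left > 0) {
    ord <- order(-(share - q), seq_along(sizes))
    q[ord[seq_len(left)]] <- q[ord[seq_len(left)]] + 1
  }
  # cap at group sizes, pushing any overflow to groups with room
  over <- q > sizes
  while (any(over)) {
    excess <- sum(q[over] - sizes[over])
    q[over] <- sizes[over]
    room <- which(q < sizes)
    ord <- room[order(-(share[room] - q[room]), room)]
    i <- 1
    while (excess > 0) {
      q[ord[i]] <- q[ord[i]] + 1
      excess <- excess - 1
      i <- if (i == length(ord)) 1 else i + 1
    }
    over <- q > sizes
  }
  as.integer(q)
}

#' Balance a two-class fingerprint dataset by clustered undersampling
#'
#' Reduces the majority class to the minority-class size. Principal
#' components are computed on the pooled fingerprint matrix and the smallest
#' number of components whose cumulative explained variance exceeds
#' `variance_goal` is retained (nPCA). The majority class is clustered in
#' that PCA space with k-means for every k in 3..(nPCA+1), k is chosen by the
#' maximum mean silhouette width (ties toward smaller k), and members are
#' sampled from each cluster proportionally to cluster size
#' (largest-remainder apportionment) until the majority count equals the
#' minority count. The minority class is untouched.
#'
#' When nPCA + 1 < 3 the clustered scheme is infeasible and plain seeded
#' random undersampling is used (recorded in `meta$fallback`).
#'
#' @param fp an [fp_table()].
#' @param variance_goal cumulative explained-variance threshold (default 0.9).
#' @param seed integer seed making the sampling reproducible.
#' @return list of class `balanced_dataset` with elements `table` (balanced
#'   [fp_table()]), `removed` (character ids of discarded majority
#'   compounds) and `meta` (n_components_kept, k_chosen, silhouette, seed,
#'   no_op, fallback).
#' @export
balance_dataset <- function(fp, variance_goal = 0.90, seed = 1L) {
  stopifnot(inherits(fp, "fp_table"), variance_goal > 0, variance_goal < 1)
  n_act <- sum(fp$label == "active")
  n_ina <- sum(fp$label == "inactive")
  stopifnot(n_act > 0, n_ina > 0)
  meta <- list(n_components_kept = NA_integer_, k_chosen = NA_integer_,
               silhouette = NA_real_, seed = as.integer(seed),
               no_op = FALSE, fallback = FALSE)
  if (n_act == n_ina) {
    meta$no_op <- TRUE
    return(structure(list(table = fp, removed = character(), meta = meta),
                     class = "balanced_dataset"))
  }
  majority <- if (n_act > n_ina) "active" else "inactive"
  n_min <- min(n_act, n_ina)
  maj_idx <- which(fp$label == majority)
  min_idx <- which(fp$label != majority)

  pca <- stats::prcomp(fp$bits, center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  npca <- which(cumvar > variance_goal)[1]
  meta$n_components_kept <- as.integer(npca)
  scores <- pca$x[maj_idx, seq_len(npca), drop = FALSE]

  k_max <- min(npca + 1, length(maj_idx) - 1)
  set.seed(seed)
  if (npca + 1 < 3 || k_max < 3) {
    meta$fallback <- TRUE
    keep_maj <- sort(sample(maj_idx, n_min))
  } else {
    ks <- 3:k_max
    d <- stats::dist(scores)
    sil <- rep(NA_real_, length(ks))
    fits <- vector("list", length(ks))
    for (i in seq_along(ks)) {
      fits[[i]] <- stats::kmeans(scores, centers = ks[i], nstart = 10,
                                 iter.max = 50)
      sil[i] <- mean(cluster::silhouette(fits[[i]]$cluster, d)[, "sil_width"])
    }
    best <- which.max(sil)  # ties resolved toward smaller k
    meta$k_chosen <- as.integer(ks[best])
    meta$silhouette <- sil[best]
    cl <- fits[[best]]$cluster
    sizes <- tabulate(cl, nbins = ks[best])
    quota <- apportion_quota(sizes, n_min)
    keep_maj <- sort(unlist(lapply(seq_len(ks[best]), function(g) {
      members <- maj_idx[cl == g]
      if (quota[g] == 0) return(integer())
      members[sample.int(length(members), quota[g])]
    })))
  }
  keep <- sort(c(min_idx, keep_maj))
  removed <- fp$compound_id[setdiff(maj_idx, keep_maj)]
  structure(list(table = fp_subset(fp, keep), removed = removed, meta = meta),
            class = "balanced_dataset")
}

#' @export
print.balanced_dataset <- function(x, ...) {
  cat("balanced_dataset:", length(x$table$compound_id), "kept,",
      length(x$removed), "removed",
      if (isTRUE(x$meta$no_op)) "(no-op: already balanced)" else
        sprintf("(nPCA=%s, k=%s, silhouette=%.3f)",
                x$meta$n_components_kept, x$meta$k_chosen, x$meta$silhouette),
      "\n")
  invisible(x)
}

#' Split off an external validation set
#'
#' Randomly separates a fraction of the compounds for external validation,
#' stratified by class so both parts preserve the class ratio. The external
#' size is `round(fraction * N)` with per-class quotas by largest-remainder
#' apportionment.
#'
#' @param fp an [fp_table()].
#' @param fraction external fraction in (0, 1); default 0.25.
#' @param seed integer seed.
#' @return list with `training` and `external` [fp_table()] objects, a
#'   disjoint partition of the input.
#' @export
split_external <- function(fp, fraction = 0.25, seed = 1L) {
  stopifnot(inherits(fp, "fp_table"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must lie in (0, 1)")
  n <- length(fp$compound_id)
  stopifnot(n >= 2)
  n_ext <- round(fraction * n)
  classes <- levels(fp$label)[table(fp$label) > 0]
  sizes <- as.integer(table(fp$label)[classes])
  quota <- apportion_quota(sizes, n_ext)
  set.seed(seed)
  ext_idx <- sort(unlist(lapply(seq_along(classes), function(i) {
    members <- which(fp$label == classes[i])
    if (quota[i] == 0) return(integer())
    members[sample.int(length(members), quota[i])]
  })))
  list(training = fp_subset(fp, setdiff(seq_len(n), ext_idx)),
       external = fp_subset(fp, ext_idx))
}
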