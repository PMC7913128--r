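# Desirability aggregation of per-target activity probabilities and ranking
# of a screening library.

#' Probability matrix of per-target activity predictions
#'
#' Holds the predicted probability of activity of M compounds (rows) against
#' T targets (columns), the role of each column (target or off_target) and
#' an optional set of known desirable compounds used only for metric
#' evaluation. Cells must be complete probabilities in \[0, 1\]; NA cells
#' are rejected.
#'
#' @param P numeric matrix with rownames (compound ids) and colnames
#'   (target ids).
#' @param roles character vector of length `ncol(P)` with values `"target"`
#'   or `"off_target"` (optionally named by target id).
#' @param actives character vector of compound ids flagged as known
#'   desirables; must be a subset of `rownames(P)`.
#' @return object of class `prob_matrix` with fields `P`, `roles` (factor)
#'   and `actives`.
#' @export
probability_matrix <- function(P, roles, actives = character()) {
  P <- as.matrix(P)
  if (is.null(rownames(P)) || is.null(colnames(P))) {
    stop("P needs rownames (compound ids) and colnames (target ids)")
  }
  if (anyDuplicated(rownames(P)) || anyDuplicated(colnames(P))) {
    stop("compound and target ids must be unique")
  }
  if (anyNA(P)) stop("probability matrix contains NA cells; predictions must be complete")
  if (!is.numeric(P) || any(P < 0) || any(P > 1)) {
    stop("all cells must be probabilities in [0, 1]")
  }
  if (!is.null(names(roles))) roles <- roles[colnames(P)]
  roles <- factor(as.character(roles), levels = c("target", "off_target"))
  if (length(roles) != ncol(P) || anyNA(roles)) {
    stop("roles must assign 'target' or 'off_target' to every column")
  }
  actives <- as.character(actives)
  if (!all(actives %in% rownames(P))) {
    stop("actives must be a subset of the compound ids")
  }
  structure(list(P = P, roles = roles, actives = actives),
            class = "prob_matrix")
}

#' @export
print.prob_matrix <- function(x, ...) {
  cat("prob_matrix:", nrow(x$P), "compounds x", ncol(x$P), "columns (",
      sum(x$roles == "target"), "targets,", sum(x$roles == "off_target"),
      "off-targets );", length(x$actives), "known actives\n")
  invisible(x)
}

# A model mask is a logical (or 0/1) vector over the matrix columns.
# Valid screening models select at least one target and one off-target.
as_mask <- function(mask, T_len) {
  if (is.numeric(mask)) mask <- mask != 0
  stopifnot(is.logical(mask), length(mask) == T_len, !anyNA(mask))
  mask
}

#' Is a model mask valid for screening?
#'
#' @param mask logical or 0/1 vector over matrix columns.
#' @param roles column roles (factor/character of target / off_target).
#' @return TRUE when at least one target and one off-target column are
#'   selected.
#' @export
valid_mask <- function(mask, roles) {
  mask <- as_mask(mask, length(roles))
  any(mask & roles == "target") && any(mask & roles == "off_target")
}

#' Desirability of one compound under one model mask
#'
#' The desirability `D = P_t * P_o` multiplies the mean predicted activity
#' probability over the selected target columns (`P_t`) with the mean
#' predicted inactivity probability over the selected off-target columns
#' (`P_o`). Both factors, and hence `D`, lie in \[0, 1\].
#'
#' @param p_row numeric probability vector for one compound (length = number
#'   of columns).
#' @param mask logical or 0/1 model mask.
#' @param roles column roles.
#' @return named numeric vector `c(D, P_t, P_o)`.
#' @examples
#' compound_desirability(c(0.9, 0.7, 0.2), c(1, 1, 1),
#'                       c("target", "target", "off_target"))
#' @export
compound_desirability <- function(p_row, mask, roles) {
  roles <- factor(as.character(roles), levels = c("target", "off_target"))
  mask <- as_mask(mask, length(roles))
  stopifnot(length(p_row) == length(roles))
  if (!valid_mask(mask, roles)) {
    stop("invalid model mask: must select at least one target and one off-target")
  }
  pt <- mean(p_row[mask & roles == "target"])
  po <- mean(1 - p_row[mask & roles == "off_target"])
  c(D = pt * po, P_t = pt, P_o = po)
}

#' Desirability scores for every compound in a probability matrix
#'
#' Vectorized application of [compound_desirability()] over the rows of a
#' probability matrix.
#'
#' @param pm a [probability_matrix()].
#' @param mask logical or 0/1 model mask over the matrix columns.
#' @return data frame with columns `compound_id`, `D`, `P_t`, `P_o`.
#' @export
desirability_scores <- function(pm, mask) {
  stopifnot(inherits(pm, "prob_matrix"))
  mask <- as_mask(mask, ncol(pm$P))
  if (!valid_mask(mask, pm$roles)) {
    stop("invalid model mask: must select at least one target and one off-target")
  }
  sel_t <- mask & pm$roles == "target"
  sel_o <- mask & pm$roles == "off_target"
  pt <- rowMeans(pm$P[, sel_t, drop = FALSE])
  po <- rowMeans(1 - pm$P[, sel_o, drop = FALSE])
  data.frame(compound_id = rownames(pm$P), D = pt * po, P_t = pt, P_o = po,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank a screening library by desirability
#'
#' Sorts the compounds by decreasing desirability under the given model
#' mask (ties broken by compound id) and returns a [ranked_screen()] whose
#' active flags come from the matrix's known desirables.
#'
#' @param pm a [probability_matrix()] with a non-empty `actives` set.
#' @param mask logical or 0/1 model mask.
#' @return a [ranked_screen()].
#' @export
rank_by_desirability <- function(pm, mask) {
  d <- desirability_scores(pm, mask)
  ranked_screen(d$compound_id, actives = pm$actives, scores = d$D)
}

#' Read a probability matrix from a delimited file
#'
#' Reads the whitespace/tab-delimited dialect used for per-target screening
#' predictions: a header row of target ids and one row per compound whose
#' first field is the compound id.
#'
#' @param file path to the matrix file.
#' @param roles named character vector (target id -> role), an unnamed
#'   vector in column order, or the path of a two-column TSV
#'   (`target_id`, `role`).
#' @param actives character vector of active compound ids, or the path of a
#'   one-id-per-line file.
#' @return a [probability_matrix()].
#' @export
read_probability_matrix <- function(file, roles, actives = character()) {
  df <- utils::read.table(file, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  P <- as.matrix(df[, -1, drop = FALSE])
  rownames(P) <- as.character(df[[1]])
  if (is.character(roles) && length(roles) == 1 && file.exists(roles)) {
    rt <- utils::read.table(roles, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    roles <- stats::setNames(rt$role, rt$target_id)
  }
  if (is.character(actives) && length(actives) == 1 && file.exists(actives)) {
    actives <- readLines(actives)
    actives <- actives[nzchar(actives)]
  }
  probability_matrix(P, roles, actives)
}

#' Write a probability matrix (and its sidecars) to delimited files
#'
#' @param pm a [probability_matrix()].
#' @param file output path for the matrix (TSV, header of target ids, first
#'   column `compound_id`).
#' @param roles_file optional path for the target-role table.
#' @param actives_file optional path for the one-id-per-line actives list.
#' @return `file`, invisibly.
#' @export
write_probability_matrix <- function(pm, file, roles_file = NULL,
                                     actives_file = NULL) {
  stopifnot(inherits(pm, "prob_matrix"))
  df <- data.frame(compound_id = rownames(pm$P), pm$P, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roles_file)) {
    utils::write.table(
      data.frame(target_id = colnames(pm$P), role = as.character(pm$roles)),
      roles_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(actives_file)) writeLines(pm$actives, actives_file)
  invisible(file)
}
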