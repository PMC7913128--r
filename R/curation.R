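# Bioactivity curation: activity labeling, replicate consensus, dataset
# filters and target/off-target role assignment.

MEASURE_TYPES <- c("IC50", "Ki", "EC50", "GI50")

#' Convert concentration values to micromolar
#'
#' Helper for callers holding nM/uM/mM/M measurements; all downstream
#' curation assumes micromolar.
#'
#' @param value numeric vector of concentrations.
#' @param unit character vector (recycled) among `"nM"`, `"uM"`, `"mM"`, `"M"`.
#' @return numeric vector in micromolar.
#' @examples
#' to_micromolar(c(500, 2), c("nM", "uM"))
#' @export
to_micromolar <- function(value, unit) {
  factors <- c(nM = 1e-3, uM = 1, mM = 1e3, M = 1e6)
  unit <- rep_len(as.character(unit), length(value))
  bad <- !unit %in% names(factors)
  if (any(bad)) {
    stop("unknown concentration unit(s): ", paste(unique(unit[bad]), collapse = ", "))
  }
  value * unname(factors[unit])
}

#' Label activity records as active or inactive
#'
#' Each measured compound-target interaction is labeled active when its
#' potency value (IC50, Ki, EC50 or GI50, in micromolar) lies strictly below
#' `threshold_um`, and inactive otherwise. Records with non-positive values
#' or an unknown measurement type are rejected, not labeled.
#'
#' @param records data frame with columns `compound_id`, `target_id`,
#'   `measure_type` (one of IC50, Ki, EC50, GI50) and `value_um`
#'   (concentration in micromolar); a `smiles` column is carried through if
#'   present.
#' @param threshold_um activity cutoff in micromolar (default 10).
#' @return data frame with columns `compound_id`, `target_id`, `label`
#'   (factor active/inactive), one row per accepted record, with the rejected
#'   records (plus a `reason` column) attached as attribute `"rejected"`.
#' @examples
#' rec <- data.frame(compound_id = "c1", target_id = "t1",
#'                   measure_type = "IC50", value_um = 5)
#' label_activity(rec)
#' @export
label_activity <- function(records, threshold_um = 10) {
  stopifnot(is.data.frame(records), threshold_um > 0)
  needed <- c("compound_id", "target_id", "measure_type", "value_um")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  value <- as.numeric(records$value_um)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(value) | value <= 0] <- "non-positive or missing value"
  bad_type <- !records$measure_type %in% MEASURE_TYPES
  reason[bad_type & is.na(reason)] <- "unknown measure_type"
  keep <- is.na(reason)
  labeled <- data.frame(
    compound_id = as.character(records$compound_id[keep]),
    target_id = as.character(records$target_id[keep]),
    label = factor(ifelse(value[keep] < threshold_um, "active", "inactive"),
                   levels = c("active", "inactive")),
    stringsAsFactors = FALSE
  )
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  attr(labeled, "rejected") <- rejected
  labeled
}

#' Resolve replicated interaction reports into consensus labels
#'
#' Multiple reports for the same (compound, target) pair are reduced to one
#' consensus label when the modal label's share of reports reaches the
#' agreement threshold; otherwise the pair is discarded. Single-report pairs
#' pass through unchanged.
#'
#' @param labeled data frame with columns `compound_id`, `target_id`, `label`
#'   (as from [label_activity()]).
#' @param agreement minimum share of reports that must carry the modal label,
#'   in (0.5, 1]. Default 0.75.
#' @return list with `consensus` (one row per kept pair) and `discarded`
#'   (data frame of `compound_id`, `target_id` for pairs failing agreement).
#' @examples
#' x <- data.frame(compound_id = "c", target_id = "t",
#'                 label = c("active", "active", "active", "inactive"))
#' resolve_replicates(x)$consensus  # 3/4 = 75% agreement: kept as active
#' @export
resolve_replicates <- function(labeled, agreement = 0.75) {
  stopifnot(is.data.frame(labeled), agreement > 0.5, agreement <= 1)
  empty <- data.frame(compound_id = character(), target_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(labeled) == 0) {
    return(list(consensus = cbind(empty, label = factor(character(),
                                                        levels = c("active", "inactive"))),
                discarded = empty))
  }
  lab <- as.character(labeled$label)
  key <- paste(labeled$compound_id, labeled$target_id, sep = "\r")
  n_active <- rowsum(as.integer(lab == "active"), key)
  n_total <- rowsum(rep(1L, length(key)), key)
  keys <- rownames(n_active)
  share_active <- n_active[, 1] / n_total[, 1]
  modal_share <- pmax(share_active, 1 - share_active)
  keep <- modal_share >= agreement
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  consensus <- data.frame(
    compound_id = parts[keep, 1],
    target_id = parts[keep, 2],
    label = factor(ifelse(share_active[keep] > 0.5, "active", "inactive"),
                   levels = c("active", "inactive")),
    stringsAsFactors = FALSE, row.names = NULL
  )
  discarded <- data.frame(
    compound_id = parts[!keep, 1],
    target_id = parts[!keep, 2],
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(consensus = consensus, discarded = discarded)
}

#' Filter targets by minimum class counts
#'
#' Keeps only targets having at least `min_active` active and `min_inactive`
#' inactive consensus interactions (both bounds inclusive), the prerequisite
#' for training a balanced per-target classifier.
#'
#' @param consensus consensus interactions (data frame with `compound_id`,
#'   `target_id`, `label`).
#' @param min_active,min_inactive minimum class counts (defaults 100).
#' @return list with character vectors `kept` and `dropped` of target ids.
#' @export
filter_targets <- function(consensus, min_active = 100, min_inactive = 100) {
  stopifnot(is.data.frame(consensus))
  targets <- unique(as.character(consensus$target_id))
  if (!length(targets)) return(list(kept = character(), dropped = character()))
  tab <- table(factor(as.character(consensus$target_id), levels = targets),
               factor(as.character(consensus$label), levels = c("active", "inactive")))
  ok <- tab[, "active"] >= min_active & tab[, "inactive"] >= min_inactive
  list(kept = targets[ok], dropped = targets[!ok])
}

#' Remove blocklisted compounds from a consensus table
#'
#' Used to exclude approved drugs and the seed drugs that defined the
#' target/off-target groups from classifier training data.
#'
#' @param consensus consensus interactions data frame.
#' @param blocklist character vector of compound ids to remove.
#' @return the consensus data frame without blocklisted compounds.
#' @export
exclude_compounds <- function(consensus, blocklist) {
  stopifnot(is.data.frame(consensus))
  consensus[!consensus$compound_id %in% blocklist, , drop = FALSE]
}

#' Assign target / off-target roles
#'
#' Proteins appearing in both the target-derived and off-target-derived sets
#' are kept in the target group (flagged `was_common`); proteins only in the
#' off-target set keep the off-target role.
#'
#' @param target_set,off_target_set non-empty character vectors of target ids.
#' @return data frame with columns `target_id`, `role` (factor
#'   target/off_target) and `was_common` (logical).
#' @examples
#' assign_roles(c("A", "B", "C"), c("C", "D"))
#' @export
assign_roles <- function(target_set, off_target_set) {
  target_set <- unique(as.character(target_set))
  off_target_set <- unique(as.character(off_target_set))
  stopifnot(length(target_set) > 0, length(off_target_set) > 0)
  common <- intersect(target_set, off_target_set)
  off_only <- setdiff(off_target_set, target_set)
  if (!length(off_only)) {
    warning("all off-targets are shared with the target set; ",
            "the screening objective is degenerate (no off-target group)")
  }
  ids <- c(target_set, off_only)
  data.frame(
    target_id = ids,
    role = factor(c(rep("target", length(target_set)),
                    rep("off_target", length(off_only))),
                  levels = c("target", "off_target")),
    was_common = ids %in% common,
    stringsAsFactors = FALSE
  )
}

#' Read an activity record table
#'
#' Expects a delimited text file with header columns `compound_id`,
#' `target_id`, `measure_type`, `value_um` and optionally `smiles`.
#' Delimiter is inferred from the extension (`.csv` comma, otherwise tab).
#'
#' @param path file path.
#' @return data frame of activity records.
#' @export
read_activity_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("compound_id", "target_id", "measure_type", "value_um")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("activity table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write a discard log
#'
#' @param discarded data frame of discarded pairs or rejected records.
#' @param path output TSV path.
#' @param reason single reason string used when the table has no
#'   `reason` column.
#' @return `path`, invisibly.
#' @export
write_discard_log <- function(discarded, path, reason = "agreement below threshold") {
  if (!"reason" %in% names(discarded) && nrow(discarded) >= 0) {
    discarded$reason <- if (nrow(discarded)) reason else character(0)
  }
  utils::write.table(discarded, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
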