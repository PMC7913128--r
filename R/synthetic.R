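# Synthetic benchmark generator with planted ground truth, emulating the
# shapes of real screening data: a probability matrix with informative and
# uninformative target columns, planted desirable compounds, and replicated
# activity records with controllable disagreement.

#' Specification of a synthetic benchmark
#'
#' Defaults describe the reference planted testbed: 2000 compounds scored
#' against 20 columns (14 targets / 6 off-targets, of which 12 and 4 are
#' informative), 20 planted desirable compounds with signal level 0.9.
#'
#' All cells are Beta draws parameterized by a mean and a concentration
#' (larger concentration = tighter around the mean; `Inf` = deterministic).
#' Planted desirable compounds score around `p_signal` on informative
#' targets and around `1 - p_signal` on informative off-targets, with
#' concentration `conc_signal`. Background compounds score around `p_noise`
#' on informative columns with the small concentration `conc_background`:
#' heavy-tailed, independent per cell, emulating the overconfident
#' probabilities real per-target classifiers assign to decoys. Because the
#' cells are independent, averaging over every informative column is what
#' suppresses decoy intrusion into the top ranks -- each informative column
#' carries complementary information and the full planted set is the
#' early-recognition optimum. Uninformative columns are the same
#' heavy-tailed noise around `p_noise` for every compound (concentration
#' `conc_noise`): including them only dilutes the actives' signal.
#'
#' @param M number of compounds.
#' @param n_targets,n_off_targets column counts per role (total T columns).
#' @param n_informative_targets,n_informative_off_targets planted
#'   informative column counts per role (the first columns of each role).
#' @param n_actives number of planted desirable compounds (< M).
#' @param p_signal probability level of actives on informative targets (and
#'   `1 - p_signal` on informative off-targets), in (p_noise, 1].
#' @param p_noise background probability level in \[0, p_signal).
#' @param conc_signal Beta concentration of the actives' informative cells
#'   (default 10).
#' @param conc_background Beta concentration of background informative
#'   cells (default 0.5; heavy-tailed).
#' @param conc_noise Beta concentration of uninformative cells, all
#'   compounds (default 0.5).
#' @param n_decoys_per_column selective decoys planted per informative
#'   column (default 3): compounds with an active-like profile on every
#'   informative column except one, where they behave like the opposite
#'   class (for a target column, inactive there; for an off-target column,
#'   active there). They emulate close analogs with single-target activity
#'   cliffs; a ranking only separates them from the true actives while
#'   their discriminating column stays in the model, which is what makes
#'   every informative column individually necessary.
#' @param replicate_count reports per compound-target pair in activity-record
#'   fixtures.
#' @param disagreement_rate probability that one replicate lands on the wrong
#'   side of the 10 uM activity cutoff.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(M = 2000, n_targets = 14, n_off_targets = 6,
                           n_informative_targets = 12,
                           n_informative_off_targets = 4,
                           n_actives = 20, p_signal = 0.9, p_noise = 0.5,
                           conc_signal = 10, conc_background = 0.5,
                           conc_noise = 0.5, n_decoys_per_column = 3,
                           replicate_count = 3, disagreement_rate = 0.1,
                           seed = 1L) {
  stopifnot(M >= 2, n_targets >= 1, n_off_targets >= 1,
            n_informative_targets >= 1,
            n_informative_targets <= n_targets,
            n_informative_off_targets >= 1,
            n_informative_off_targets <= n_off_targets,
            n_actives >= 1,
            p_noise >= 0, p_noise < p_signal, p_signal <= 1,
            conc_signal > 0, conc_background > 0, conc_noise > 0,
            n_decoys_per_column >= 0,
            replicate_count >= 1,
            disagreement_rate >= 0, disagreement_rate <= 1)
  if (n_actives >= M) stop("n_actives must be smaller than M")
  n_inf <- n_informative_targets + n_informative_off_targets
  if (n_actives + n_decoys_per_column * n_inf > M) {
    stop("n_actives plus planted decoys exceed M")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# Beta draw parameterized by mean and concentration; conc = Inf degenerates
# to the mean, as do means of exactly 0 or 1.
rbeta_mean <- function(n, mean, conc) {
  if (!is.finite(conc) || mean <= 0 || mean >= 1) return(rep(mean, n))
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Generate a probability matrix with planted ground truth
#'
#' Draws an M x T probability matrix per the spec: planted desirable
#' compounds score around `p_signal` on informative targets and around
#' `1 - p_signal` on informative off-targets; background compounds draw
#' independent heavy-tailed noise around `p_noise` on informative columns;
#' uninformative columns are noise for everyone. Deterministic under the
#' spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (a [probability_matrix()] whose `actives` are
#'   the planted compounds) and `truth` (list: `planted_mask` named logical
#'   over columns, `active_ids`, `decoys` data frame of decoy compound ids
#'   with their discriminating column, `spec`).
#' @export
gen_probability_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  M <- spec$M
  t_ids <- sprintf("T%02d", seq_len(spec$n_targets))
  o_ids <- sprintf("O%02d", seq_len(spec$n_off_targets))
  cols <- c(t_ids, o_ids)
  roles <- stats::setNames(rep(c("target", "off_target"),
                               c(spec$n_targets, spec$n_off_targets)), cols)
  planted <- stats::setNames(rep(FALSE, length(cols)), cols)
  planted[t_ids[seq_len(spec$n_informative_targets)]] <- TRUE
  planted[o_ids[seq_len(spec$n_informative_off_targets)]] <- TRUE
  ids <- sprintf("cpd%05d", seq_len(M))
  inf_cols <- which(planted)
  n_dec <- spec$n_decoys_per_column * length(inf_cols)
  special <- sample.int(M, spec$n_actives + n_dec)
  act <- sort(special[seq_len(spec$n_actives)])
  dec <- special[spec$n_actives + seq_len(n_dec)]
  dec_col <- rep(inf_cols, each = spec$n_decoys_per_column)
  bg <- setdiff(seq_len(M), c(act, dec))

  sig <- function(n) rbeta_mean(n, spec$p_signal, spec$conc_signal)
  antisig <- function(n) rbeta_mean(n, 1 - spec$p_signal, spec$conc_signal)
  noise_bg <- function(n) rbeta_mean(n, spec$p_noise, spec$conc_background)

  P <- matrix(NA_real_, M, length(cols), dimnames = list(ids, cols))
  for (j in which(planted & roles == "target")) {
    P[bg, j] <- noise_bg(length(bg))
    P[act, j] <- sig(length(act))
    P[dec, j] <- sig(length(dec))          # active-like by default ...
  }
  for (j in which(planted & roles == "off_target")) {
    P[bg, j] <- noise_bg(length(bg))
    P[act, j] <- antisig(length(act))
    P[dec, j] <- antisig(length(dec))
  }
  # ... except on each decoy's own discriminating column, where it behaves
  # like the opposite class (the single-target activity cliff).
  for (i in seq_along(dec)) {
    j <- dec_col[i]
    P[dec[i], j] <- if (roles[j] == "target") antisig(1) else sig(1)
  }
  for (j in which(!planted)) {
    P[, j] <- rbeta_mean(M, spec$p_noise, spec$conc_noise)
  }
  pm <- probability_matrix(P, roles, actives = ids[act])
  list(matrix = pm,
       truth = list(planted_mask = planted, active_ids = ids[act],
                    decoys = data.frame(compound_id = ids[dec],
                                        column = cols[dec_col],
                                        stringsAsFactors = FALSE),
                    spec = spec))
}

#' Generate replicated activity records with planted truth labels
#'
#' For every compound-target pair a ground-truth label is drawn (active with
#' probability 1/2), then `replicate_count` potency records are emitted whose
#' values fall on the matching side of the 10 uM cutoff; each replicate
#' independently lands on the wrong side with probability
#' `disagreement_rate`. Values are log-uniform within (0.001, 10) uM for
#' active reports and (10, 1000) uM for inactive reports; measurement types
#' rotate through IC50/Ki/EC50/GI50.
#'
#' The compound/target counts are kept small (`min(M, 50)` compounds against
#' all targets) since these fixtures exercise the curation stage, not the
#' screening stage.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `records` (activity record data frame) and `truth`
#'   (data frame `compound_id`, `target_id`, `label`).
#' @export
gen_activity_records <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  n_cpd <- min(spec$M, 50L)
  cpds <- sprintf("cpd%05d", seq_len(n_cpd))
  tgts <- c(sprintf("T%02d", seq_len(spec$n_targets)),
            sprintf("O%02d", seq_len(spec$n_off_targets)))
  pairs <- expand.grid(compound_id = cpds, target_id = tgts,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth_active <- stats::runif(nrow(pairs)) < 0.5
  rep_rows <- pairs[rep(seq_len(nrow(pairs)), each = spec$replicate_count), ]
  rep_truth <- rep(truth_active, each = spec$replicate_count)
  flip <- stats::runif(length(rep_truth)) < spec$disagreement_rate
  rep_active <- xor(rep_truth, flip)
  value <- ifelse(rep_active,
                  10^stats::runif(length(rep_active), -3, log10(10)),
                  10^stats::runif(length(rep_active), log10(10), 3))
  # active reports must be strictly below the cutoff
  value[rep_active] <- pmin(value[rep_active], 10 - 1e-9)
  records <- data.frame(
    compound_id = rep_rows$compound_id,
    target_id = rep_rows$target_id,
    measure_type = rep(c("IC50", "Ki", "EC50", "GI50"),
                       length.out = nrow(rep_rows)),
    value_um = value,
    stringsAsFactors = FALSE, row.names = NULL)
  truth <- data.frame(
    compound_id = pairs$compound_id,
    target_id = pairs$target_id,
    label = factor(ifelse(truth_active, "active", "inactive"),
                   levels = c("active", "inactive")),
    stringsAsFactors = FALSE, row.names = NULL)
  list(records = records, truth = truth)
}

#' Write a synthetic benchmark to disk
#'
#' Emits the probability matrix, role table, actives list and a ground-truth
#' JSON sidecar in the dialects consumed by [read_probability_matrix()].
#'
#' @param gen output of [gen_probability_matrix()].
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("probabilities.tsv", "roles.tsv", "actives.txt",
                            "truth.json"))
  write_probability_matrix(gen$matrix, paths[1], roles_file = paths[2],
                           actives_file = paths[3])
  truth <- gen$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
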