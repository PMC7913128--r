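# End-to-end pipeline orchestration: curation -> (balancing) -> GA ->
# selection -> clustering -> relevance -> global desirability ->
# overlap/correlation, driven by a declarative config.

#' Read a pipeline run configuration
#'
#' The configuration is a single YAML file; see [run_pipeline()] for the
#' recognized keys. Unset numeric parameters fall back to the package
#' defaults.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

# Per-stage seeds derived deterministically from the master seed so a single
# knob reproduces a whole run. Offsets are fixed per stage name.
stage_seed <- function(seed, stage) {
  offsets <- c(curate = 1L, balance = 2L, ga = 3L, consensus = 4L, synth = 5L)
  as.integer(seed) + unname(offsets[stage])
}

default_config <- function() {
  list(
    activity_file = NULL, blocklist_file = NULL,
    fingerprint_file = NULL,
    matrix_file = NULL, roles_file = NULL, actives_file = NULL,
    threshold_um = 10, agreement = 0.75,
    min_active = 100, min_inactive = 100,
    variance_goal = 0.90, external_fraction = 0.25,
    population_size = 4000, generations = 3000,
    mutation_prob = 0.4, crossover_prob = 0.6, tournament_size = 3,
    restarts = 1,
    alpha = 160.9, theta = NULL, z = NULL,
    model_threshold = 0.15, k_clusters = 4, top_n = 50,
    chi = 0.01, seed = 1
  )
}

#' Run the screening pipeline end to end
#'
#' Executes the stages the config enables, in order: curation (when
#' `activity_file` is set), balancing (when `fingerprint_file` is set; the
#' classifier training that would follow is outside the pipeline's
#' boundary), then -- when `matrix_file`/`roles_file`/`actives_file` are set
#' -- GA model selection, model selection at the fitness threshold,
#' hierarchical clustering, target relevance, global desirability, top-list
#' overlap and cluster correlation. Every output lands in `out_dir`
#' alongside `config_resolved.yaml`; reruns with the same config and seed
#' are reproducible.
#'
#' When `theta` and `z` are both set, `alpha` is recalibrated with
#' [solve_alpha()] before the GA.
#'
#' @param config named list (see [read_run_config()] and
#'   `moscreen:::default_config()` for keys) or the path of a YAML config.
#' @param out_dir artifact directory, created if needed.
#' @param dry_run validate inputs and print the stage plan without
#'   computing.
#' @return invisibly, a named list of output file paths (empty for dry
#'   runs).
#' @export
run_pipeline <- function(config, out_dir = "moscreen_out", dry_run = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  stages <- character()
  if (!is.null(cfg$activity_file)) stages <- c(stages, "curate")
  if (!is.null(cfg$fingerprint_file)) stages <- c(stages, "balance")
  if (!is.null(cfg$matrix_file)) {
    if (is.null(cfg$roles_file) || is.null(cfg$actives_file)) {
      stop("matrix_file requires roles_file and actives_file")
    }
    stages <- c(stages, "ga", "consensus")
  }
  if (!length(stages)) stop("config enables no stage")
  for (f in c("activity_file", "fingerprint_file", "matrix_file",
              "roles_file", "actives_file", "blocklist_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("input file for ", f, " does not exist: ", cfg[[f]])
    }
  }
  if (dry_run) {
    cat("stage plan:", paste(stages, collapse = " -> "), "\n")
    return(invisible(list()))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  log <- function(...) message("[moscreen] ", ...)

  if ("curate" %in% stages) {
    records <- read_activity_table(cfg$activity_file)
    labeled <- label_activity(records, cfg$threshold_um)
    res <- resolve_replicates(labeled, cfg$agreement)
    consensus <- res$consensus
    log("curate: ", nrow(records), " records -> ", nrow(consensus),
        " consensus pairs (", nrow(res$discarded), " discarded)")
    if (!is.null(cfg$blocklist_file)) {
      blocklist <- readLines(cfg$blocklist_file)
      consensus <- exclude_compounds(consensus, blocklist)
      log("curate: ", length(blocklist), " blocklisted compounds removed")
    }
    ft <- filter_targets(consensus, cfg$min_active, cfg$min_inactive)
    consensus <- consensus[consensus$target_id %in% ft$kept, , drop = FALSE]
    log("curate: ", length(ft$kept), " targets kept, ",
        length(ft$dropped), " dropped")
    out$consensus <- file.path(out_dir, "consensus.tsv")
    utils::write.table(consensus, out$consensus, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$discard_log <- file.path(out_dir, "discarded.tsv")
    write_discard_log(res$discarded, out$discard_log)
  }

  if ("balance" %in% stages) {
    tab <- utils::read.table(cfg$fingerprint_file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    bits <- if ("smiles" %in% names(tab)) {
      featurize(stats::setNames(tab$smiles, tab$compound_id))
    } else {
      do.call(rbind, lapply(strsplit(tab$bits, ""), as.integer))
    }
    fp <- fp_table(tab$compound_id, bits, tab$label)
    bal <- balance_dataset(fp, cfg$variance_goal,
                           seed = stage_seed(cfg$seed, "balance"))
    sp <- split_external(bal$table, cfg$external_fraction,
                         seed = stage_seed(cfg$seed, "balance"))
    log("balance: ", length(fp$compound_id), " compounds -> ",
        length(sp$training$compound_id), " training / ",
        length(sp$external$compound_id), " external (",
        length(bal$removed), " removed)")
    for (part in c("training", "external")) {
      p <- file.path(out_dir, paste0(part, ".tsv"))
      utils::write.table(
        data.frame(compound_id = sp[[part]]$compound_id,
                   label = as.character(sp[[part]]$label),
                   bits = apply(sp[[part]]$bits, 1, paste, collapse = "")),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      out[[part]] <- p
    }
    out$balance_meta <- file.path(out_dir, "balance_meta.json")
    jsonlite::write_json(bal$meta, out$balance_meta, auto_unbox = TRUE,
                         digits = NA)
  }

  if ("ga" %in% stages) {
    pm <- read_probability_matrix(cfg$matrix_file, cfg$roles_file,
                                  cfg$actives_file)
    alpha <- if (!is.null(cfg$theta) && !is.null(cfg$z)) {
      solve_alpha(cfg$theta, cfg$z)
    } else cfg$alpha
    ga <- run_ga(pm, ga_config(
      population_size = cfg$population_size, generations = cfg$generations,
      mutation_prob = cfg$mutation_prob, crossover_prob = cfg$crossover_prob,
      tournament_size = cfg$tournament_size, alpha = alpha,
      seed = stage_seed(cfg$seed, "ga"), restarts = cfg$restarts))
    log("ga: best BEDROC ", format(ga$best_fitness, digits = 4),
        " over ", nrow(ga$population), " final individuals")
    out$ga <- file.path(out_dir, "ga_out.tsv")
    write_ga_output(ga, out$ga)
    best <- rank_by_desirability(pm, ga$best_mask)
    out$best_metrics <- file.path(out_dir, "best_metrics.json")
    jsonlite::write_json(list(
      bedroc = bedroc(best, alpha), auac = auac(best),
      ef = enrichment_factor(best, cfg$chi), alpha = alpha, chi = cfg$chi,
      n = best$n, N = best$N),
      out$best_metrics, auto_unbox = TRUE, digits = NA)

    sel <- select_models(ga, cfg$model_threshold)
    log("consensus: ", nrow(sel$masks), " of ", nrow(ga$population),
        " models at BEDROC >= ", cfg$model_threshold)
    k <- min(cfg$k_clusters, nrow(sel$masks))
    cl <- cluster_models(sel, k)
    rel <- target_relevance(sel, cl)
    out$relevance <- file.path(out_dir, "relevance.tsv")
    utils::write.table(
      data.frame(target_id = rownames(rel),
                 role = as.character(pm$roles[rownames(rel)]),
                 as.data.frame(unclass(rel)), check.names = FALSE),
      out$relevance, sep = "\t", quote = FALSE, row.names = FALSE)
    gd <- global_desirability(pm, sel, cl)
    out$global_desirability <- file.path(out_dir, "global_desirability.tsv")
    utils::write.table(
      data.frame(compound_id = rownames(gd), as.data.frame(gd),
                 check.names = FALSE),
      out$global_desirability, sep = "\t", quote = FALSE, row.names = FALSE)
    ov <- top_overlap(gd, min(cfg$top_n, nrow(gd)))
    out$venn <- file.path(out_dir, "venn.json")
    jsonlite::write_json(
      list(top_n = min(cfg$top_n, nrow(gd)), union = ov$union_size,
           intersection = ov$intersection_size, venn = as.list(ov$venn)),
      out$venn, auto_unbox = TRUE, digits = NA)
    if (ncol(gd) >= 2) {
      cc <- cluster_correlation(gd)
      out$correlation <- file.path(out_dir, "correlation.json")
      jsonlite::write_json(
        list(mean = cc$mean, min = cc$min, max = cc$max,
             matrix = as.data.frame(cc$matrix)),
        out$correlation, auto_unbox = TRUE, digits = NA)
    }
  }

  out$config <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(cfg, out$config)
  invisible(out)
}
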