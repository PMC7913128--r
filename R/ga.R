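# Genetic-algorithm search over model masks maximizing the BEDROC of the
# desirability ranking.

#' Genetic algorithm configuration
#'
#' Defaults follow the standard bit-string GA used for target/off-target
#' model selection: 4000 individuals evolving for 3000 generations with a
#' per-individual mutation probability of 0.4 (each bit inside a mutated
#' individual flips with probability `per_bit_flip`, default 1/T), two-point
#' crossover with probability 0.6, tournament selection of size 3, one-elite
#' preservation, and BEDROC fitness at `alpha = 160.9`.
#'
#' @param population_size individuals per generation (>= 2).
#' @param generations number of generations (0 evaluates only the initial
#'   population).
#' @param mutation_prob per-individual mutation probability in \[0, 1\].
#' @param crossover_prob per-pair crossover probability in \[0, 1\].
#' @param tournament_size tournament size for selection.
#' @param alpha BEDROC early-recognition weight.
#' @param seed integer seed; restart r uses `seed + r - 1`.
#' @param restarts number of independent runs from distinct random initial
#'   populations.
#' @param per_bit_flip per-bit flip probability inside a mutated individual;
#'   `NULL` (default) means 1/T where T is the mask length.
#' @param elite number of top individuals copied unchanged into the next
#'   generation.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 4000, generations = 3000,
                      mutation_prob = 0.4, crossover_prob = 0.6,
                      tournament_size = 3, alpha = 160.9, seed = 1L,
                      restarts = 1L, per_bit_flip = NULL, elite = 1L) {
  stopifnot(population_size >= 2, generations >= 0,
            mutation_prob >= 0, mutation_prob <= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            tournament_size >= 1, alpha > 0, restarts >= 1, elite >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_prob = mutation_prob,
                 crossover_prob = crossover_prob,
                 tournament_size = as.integer(tournament_size),
                 alpha = alpha, seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 per_bit_flip = per_bit_flip, elite = as.integer(elite)),
            class = "ga_config")
}

#' GA fitness of a model mask
#'
#' BEDROC (at `alpha`) of the desirability ranking induced by `mask` on the
#' probability matrix. Masks selecting no target or no off-target column are
#' invalid screening models and receive `-Inf`, so the GA can traverse the
#' invalid region without ever reporting it as a solution.
#'
#' @param mask logical or 0/1 model mask.
#' @param pm a [probability_matrix()] with known actives.
#' @param alpha BEDROC weight (default 160.9).
#' @return BEDROC in \[0, 1\], or `-Inf` for invalid masks.
#' @export
ga_fitness <- function(mask, pm, alpha = 160.9) {
  stopifnot(inherits(pm, "prob_matrix"))
  mask <- as_mask(mask, ncol(pm$P))
  if (!valid_mask(mask, pm$roles)) return(-Inf)
  bedroc(rank_by_desirability(pm, mask), alpha)
}

# Precomputed evaluation context: target / off-target submatrices, active
# flags in id-tie-break order, and BEDROC constants.
ga_context <- function(pm, alpha) {
  is_t <- pm$roles == "target"
  ids <- rownames(pm$P)
  list(A = pm$P[, is_t, drop = FALSE],
       B = 1 - pm$P[, !is_t, drop = FALSE],
       is_t = is_t, ids = ids,
       act = ids %in% pm$actives,
       N = nrow(pm$P), n = sum(ids %in% pm$actives), alpha = alpha)
}

# BEDROC of score vector d (descending, ties by id) within a context.
ctx_bedroc <- function(ctx, d) {
  ord <- order(-d, ctx$ids)
  x <- which(ctx$act[ord]) / ctx$N
  num <- mean(exp(-ctx$alpha * x))
  den <- (1 / ctx$N) * (-expm1(-ctx$alpha)) / expm1(ctx$alpha / ctx$N)
  b <- rie_bounds(ctx$N, ctx$n, ctx$alpha)
  v <- unname((num / den - b["min"]) / (b["max"] - b["min"]))
  min(max(v, 0), 1)
}

# Evaluate a population matrix (individuals in rows, T columns), with
# memoization in `cache` (an environment keyed by the packed bit string).
# Desirability for all masks at once via two matrix products.
eval_population <- function(pop, ctx, cache = NULL) {
  keys <- apply(pop, 1, function(b) rawToChar(as.raw(b + 48L)))
  fit <- rep(NA_real_, nrow(pop))
  if (!is.null(cache)) {
    hit <- vapply(keys, function(k) !is.null(cache[[k]]), logical(1))
    fit[hit] <- vapply(keys[hit], function(k) cache[[k]], numeric(1))
  }
  todo <- which(is.na(fit))
  if (length(todo)) {
    Mt <- t(pop[todo, ctx$is_t, drop = FALSE])
    Mo <- t(pop[todo, !ctx$is_t, drop = FALSE])
    nt <- colSums(Mt)
    no <- colSums(Mo)
    ok <- nt > 0 & no > 0
    if (any(ok)) {
      PT <- sweep(ctx$A %*% Mt[, ok, drop = FALSE], 2, nt[ok], "/")
      PO <- sweep(ctx$B %*% Mo[, ok, drop = FALSE], 2, no[ok], "/")
      D <- PT * PO
      vals <- vapply(seq_len(ncol(D)), function(j) ctx_bedroc(ctx, D[, j]),
                     numeric(1))
      fit[todo[ok]] <- vals
    }
    fit[todo[!ok]] <- -Inf
    if (!is.null(cache)) {
      for (i in todo) cache[[keys[i]]] <- fit[i]
    }
  }
  fit
}

# Ensure an individual selects both roles by switching on one random bit of
# any missing role (used only for the initial population).
repair_mask <- function(bits, is_t) {
  if (!any(bits & is_t)) bits[sample(which(is_t), 1)] <- 1L
  if (!any(bits & !is_t)) bits[sample(which(!is_t), 1)] <- 1L
  bits
}

#' Run the genetic algorithm for model-mask selection
#'
#' Evolves bit-string individuals (one bit per probability-matrix column)
#' maximizing [ga_fitness()]. Individuals in the initial population are
#' repaired to select both roles; during evolution invalid individuals
#' simply carry `-Inf` fitness. With `restarts > 1` independent runs start
#' from distinct seeded random populations and the final populations are
#' concatenated.
#'
#' @param pm a [probability_matrix()] with known actives.
#' @param config a [ga_config()].
#' @return object of class `ga_result`: `population` (0/1 matrix, one row
#'   per final individual, colnames = target ids), `fitness`, `best_mask`
#'   (named logical), `best_fitness`, `trace` (list per restart of
#'   per-generation best fitness, generation 0 first) and `config`.
#' @export
run_ga <- function(pm, config = ga_config()) {
  stopifnot(inherits(pm, "prob_matrix"), inherits(config, "ga_config"))
  if (!length(pm$actives)) stop("the probability matrix has no known actives to rank")
  Tlen <- ncol(pm$P)
  pbf <- if (is.null(config$per_bit_flip)) 1 / Tlen else config$per_bit_flip
  ctx <- ga_context(pm, config$alpha)
  cache <- new.env(parent = emptyenv())
  pops <- list(); fits <- list(); traces <- list()

  for (r in seq_len(config$restarts)) {
    set.seed(config$seed + r - 1L)
    np <- config$population_size
    pop <- matrix(sample(0:1, np * Tlen, replace = TRUE), nrow = np)
    pop <- t(apply(pop, 1, repair_mask, is_t = ctx$is_t))
    fit <- eval_population(pop, ctx, cache)
    trace <- max(fit)
    for (gen in seq_len(config$generations)) {
      # tournament selection
      idx <- matrix(sample.int(np, np * config$tournament_size, replace = TRUE),
                    nrow = np)
      winners <- idx[cbind(seq_len(np), max.col(matrix(fit[idx], nrow = np),
                                                ties.method = "first"))]
      nxt <- pop[winners, , drop = FALSE]
      # two-point crossover on consecutive pairs
      for (i in seq(1, np - 1, by = 2)) {
        if (stats::runif(1) < config$crossover_prob && Tlen >= 2) {
          cut <- sort(sample.int(Tlen - 1, 2, replace = TRUE))
          if (cut[1] < cut[2]) {
            seg <- (cut[1] + 1):cut[2]
            tmp <- nxt[i, seg]
            nxt[i, seg] <- nxt[i + 1, seg]
            nxt[i + 1, seg] <- tmp
          }
        }
      }
      # per-individual mutation with per-bit flips
      mut <- which(stats::runif(np) < config$mutation_prob)
      for (i in mut) {
        flip <- stats::runif(Tlen) < pbf
        nxt[i, flip] <- 1L - nxt[i, flip]
      }
      # elitism: best individuals survive unchanged
      if (config$elite > 0) {
        eliten <- min(config$elite, np)
        nxt[seq_len(eliten), ] <- pop[order(-fit)[seq_len(eliten)], ,
                                      drop = FALSE]
      }
      pop <- nxt
      fit <- eval_population(pop, ctx, cache)
      trace <- c(trace, max(fit))
    }
    pops[[r]] <- pop; fits[[r]] <- fit; traces[[r]] <- trace
  }
  population <- do.call(rbind, pops)
  colnames(population) <- colnames(pm$P)
  fitness <- unlist(fits)
  best <- which.max(fitness)
  best_mask <- stats::setNames(population[best, ] == 1L, colnames(pm$P))
  structure(list(population = population, fitness = fitness,
                 best_mask = best_mask, best_fitness = fitness[best],
                 trace = traces, config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("ga_result:", nrow(x$population), "final individuals,",
      "best BEDROC =", format(x$best_fitness, digits = 4),
      "selecting", sum(x$best_mask), "of", ncol(x$population), "columns\n")
  invisible(x)
}

#' Write a GA final population as a TSV
#'
#' One row per final individual: the mask as a bit string plus its fitness.
#'
#' @param result a `ga_result` from [run_ga()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ga_output <- function(result, path) {
  stopifnot(inherits(result, "ga_result"))
  df <- data.frame(
    mask = apply(result$population, 1, paste, collapse = ""),
    fitness = result$fitness, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GA output TSV (bit string + fitness per row)
#'
#' @param path TSV with columns `mask` (bit string) and `fitness`.
#' @param target_ids optional column names for the mask matrix.
#' @return list with `masks` (0/1 matrix) and `fitness` (numeric).
#' @export
read_ga_output <- function(path, target_ids = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
  masks <- do.call(rbind, lapply(strsplit(df$mask, ""), as.integer))
  if (!is.null(target_ids)) colnames(masks) <- target_ids
  list(masks = masks, fitness = df$fitness)
}
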