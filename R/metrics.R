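# Early-recognition metrics on a ranked screen: AUAC, enrichment factor,
# RIE, BEDROC, and the alpha calibration solver.
#
# Conventions: ranks are 1-based, best first; the relative rank of an active
# at rank r is x = r/N. Exponential terms are evaluated with expm1 and
# negative exponents only, so alpha of order 10^2 (e.g. 160.9) is safe.

#' Construct a ranked screen
#'
#' A ranked screen is an ordered compound list with known actives flagged.
#' Either pass `ids` already in rank order (best first), or pass `scores`
#' and the constructor sorts by decreasing score, breaking ties
#' deterministically by compound id.
#'
#' @param ids character vector of unique compound ids.
#' @param actives character vector of ids flagged as active/desirable.
#' @param scores optional numeric scores aligned with `ids`; larger is
#'   better.
#' @return object of class `ranked_screen` with fields `ids`,
#'   `active_flags`, `N`, `n`, `ranks` (ranks of the actives) and `x`
#'   (relative ranks of the actives).
#' @examples
#' s <- ranked_screen(c("a", "b", "c", "d"), actives = "b",
#'                    scores = c(0.2, 0.9, 0.5, 0.1))
#' s$ranks  # b ranks first
#' @export
ranked_screen <- function(ids, actives, scores = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(ids), !anyNA(scores))
    ord <- order(-scores, ids)
    ids <- ids[ord]
  }
  flags <- ids %in% as.character(actives)
  N <- length(ids)
  n <- sum(flags)
  if (n < 1) stop("a ranked screen needs at least one active")
  if (n >= N) stop("a ranked screen needs at least one inactive (n < N)")
  ranks <- which(flags)
  structure(list(ids = ids, active_flags = flags, N = N, n = n,
                 ranks = ranks, x = ranks / N),
            class = "ranked_screen")
}

#' @export
print.ranked_screen <- function(x, ...) {
  cat("ranked_screen: N =", x$N, "compounds,", x$n, "actives; best active at rank",
      min(x$ranks), "\n")
  invisible(x)
}

#' Area under the accumulation curve
#'
#' AUAC = 1 - mean relative rank of the actives: 1 for actives packed at the
#' very top, approaching 0 when they sit at the bottom.
#'
#' @param screen a [ranked_screen()].
#' @return AUAC in \[0, 1\].
#' @export
auac <- function(screen) {
  stopifnot(inherits(screen, "ranked_screen"))
  1 - mean(screen$x)
}

#' Enrichment factor at a top fraction
#'
#' Number of actives retrieved in the top fraction `chi` of the list,
#' relative to the random expectation. The cutoff is `ceiling(chi * N)`
#' positions, and the effective fraction `chi_eff = ceiling(chi * N) / N` is
#' used as normalizer, so EF attains exactly `1 / chi_eff` when every
#' retrieved top-list member is active.
#'
#' @param screen a [ranked_screen()].
#' @param chi top fraction in (0, 1].
#' @return EF >= 0.
#' @export
enrichment_factor <- function(screen, chi) {
  stopifnot(inherits(screen, "ranked_screen"), chi > 0, chi <= 1)
  cutoff <- ceiling(chi * screen$N)
  chi_eff <- cutoff / screen$N
  hits <- sum(screen$active_flags[seq_len(cutoff)])
  hits / (chi_eff * screen$n)
}

#' Robust initial enhancement
#'
#' Exponentially rank-weighted retrieval statistic: the mean of
#' `exp(-alpha * x_i)` over actives, normalized by its expectation under a
#' uniformly random ranking. Values above 1 indicate better-than-random
#' early placement.
#'
#' @param screen a [ranked_screen()].
#' @param alpha early-recognition weight, > 0.
#' @return RIE value.
#' @export
rie <- function(screen, alpha) {
  stopifnot(inherits(screen, "ranked_screen"), alpha > 0)
  num <- mean(exp(-alpha * screen$x))
  den <- (1 / screen$N) * (-expm1(-alpha)) / expm1(alpha / screen$N)
  num / den
}

# RIE bounds for n actives among N compounds at weight alpha (actives packed
# first / last). Written with non-positive exponents only: stable for large
# alpha.
rie_bounds <- function(N, n, alpha) {
  Ra <- n / N
  if (Ra >= 1) stop("RIE bounds are undefined when every compound is active")
  rie_min <- (exp(alpha * (Ra - 1)) - exp(-alpha)) / (Ra * (-expm1(-alpha)))
  rie_max <- (-expm1(-alpha * Ra)) / (Ra * (-expm1(-alpha)))
  c(min = rie_min, max = rie_max)
}

#' Boltzmann-enhanced discrimination of ROC
#'
#' Min-max normalization of [rie()] to \[0, 1\]: 0 for actives packed at the
#' bottom of the ranking, 1 for actives packed at the top. The weight
#' `alpha` controls how strongly early ranks dominate; `alpha = 160.9`
#' concentrates 80% of the weight in the top 1% (see [solve_alpha()]).
#'
#' @param screen a [ranked_screen()].
#' @param alpha early-recognition weight, > 0.
#' @return BEDROC in \[0, 1\].
#' @export
bedroc <- function(screen, alpha) {
  stopifnot(inherits(screen, "ranked_screen"), alpha > 0)
  b <- rie_bounds(screen$N, screen$n, alpha)
  v <- unname((rie(screen, alpha) - b["min"]) / (b["max"] - b["min"]))
  # guard against floating-point overshoot just outside [0, 1]
  min(max(v, 0), 1)
}

#' Calibrate the early-recognition weight alpha
#'
#' Solves `theta * (1 - exp(-alpha)) - 1 + exp(-alpha * z) = 0` for its
#' positive root: the alpha at which a fraction `theta` of the BEDROC weight
#' falls in the top fraction `z` of the ranked list. For `theta = 0.8`,
#' `z = 0.01` this gives alpha of about 160.9 (80% of the weight in the top
#' 1%).
#'
#' @param theta weight of the early segment, in (0, 1); must exceed `z`.
#' @param z early segment size as a fraction of the list, in (0, 1).
#' @return the positive root, with residual below 1e-10.
#' @examples
#' solve_alpha(0.8, 0.01)
#' @export
solve_alpha <- function(theta, z) {
  stopifnot(theta > 0, theta < 1, z > 0, z < 1)
  if (theta <= z) {
    stop("no positive root: theta must exceed z for early enrichment to have weight")
  }
  f <- function(a) theta * (-expm1(-a)) - 1 + exp(-a * z)
  upper <- 1
  while (f(upper) > 0 && upper < 1e12) upper <- upper * 2
  if (f(upper) > 0) stop("no sign change found while bracketing the root")
  root <- stats::uniroot(f, c(1e-12, upper), tol = 1e-14)$root
  # one Newton polish for residual tightness
  fp <- function(a) theta * exp(-a) - z * exp(-a * z)
  root <- root - f(root) / fp(root)
  if (abs(f(root)) >= 1e-10) stop("root residual exceeds 1e-10")
  root
}
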