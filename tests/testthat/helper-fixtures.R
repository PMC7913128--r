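# Shared fixture builders; everything is generated in code.

# activity records covering the labeling edge cases
make_activity_df <- function() {
  data.frame(
    compound_id = c("c1", "c1", "c2", "c2", "c3", "c4"),
    target_id   = c("t1", "t1", "t1", "t2", "t2", "t1"),
    measure_type = c("IC50", "Ki", "EC50", "GI50", "IC50", "IC50"),
    value_um = c(5, 8, 1000, 10, 0.2, 2),
    stringsAsFactors = FALSE
  )
}

# a ranked screen from an ordered active-flag vector
screen_from_flags <- function(flags) {
  ids <- sprintf("c%03d", seq_along(flags))
  ranked_screen(ids, actives = ids[flags])
}

# random screen: n actives at random ranks among N
rand_flags <- function(N, n) {
  flags <- rep(FALSE, N)
  flags[sample.int(N, n)] <- TRUE
  flags
}

# random probability matrix with roles, known actives
rand_pm <- function(M = 30, n_t = 4, n_o = 2, n_act = 3) {
  P <- matrix(stats::runif(M * (n_t + n_o)), M,
              dimnames = list(sprintf("m%03d", seq_len(M)),
                              c(sprintf("T%d", seq_len(n_t)),
                                sprintf("O%d", seq_len(n_o)))))
  probability_matrix(P, rep(c("target", "off_target"), c(n_t, n_o)),
                     actives = sprintf("m%03d", seq_len(n_act)))
}

# scalar double-loop desirability oracle (independent of the vectorized path)
oracle_desirability <- function(P, mask, roles) {
  vapply(seq_len(nrow(P)), function(i) {
    st <- 0; nt <- 0; so <- 0; no <- 0
    for (j in seq_len(ncol(P))) {
      if (!mask[j]) next
      if (roles[j] == "target") { st <- st + P[i, j]; nt <- nt + 1 }
      else { so <- so + (1 - P[i, j]); no <- no + 1 }
    }
    (st / nt) * (so / no)
  }, numeric(1))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# small binary fingerprint table with a built-in class imbalance
make_fp_table <- function(n_active = 30, n_inactive = 60, nbits = 32, seed = 42) {
  set.seed(seed)
  n <- n_active + n_inactive
  bits <- matrix(rbinom(n * nbits, 1, 0.3), n, nbits)
  fp_table(sprintf("f%03d", seq_len(n)), bits,
           rep(c("active", "inactive"), c(n_active, n_inactive)))
}
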