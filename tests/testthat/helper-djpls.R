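# Shared fixtures, built in code once per test run.

# the canonical noiseless trial (defaults: 0.3 m drop, 0.22 s contact,
# 0.33 m jump) and its full analysis
ref_trial <- generate_trial()
ref_analysis <- analyze_trial(ref_trial$recording)

# a full one-frame marker set at given joint-centre positions, for COM toys
toy_markers <- function(p = c(0, 0, 1)) {
  at <- function(v) matrix(v, 1, 3, byrow = TRUE)
  nm <- c("HEEL_L", "TOE_L", "HEEL_R", "TOE_R",
          "LMAL_L", "MMAL_L", "LMAL_R", "MMAL_R",
          "LEPI_L", "MEPI_L", "LEPI_R", "MEPI_R",
          "TROCH_L", "TROCH_R", "ASIS_L", "ASIS_R", "C7")
  out <- lapply(nm, function(x) at(p))
  names(out) <- nm
  out
}

# brute-force VIF by direct regression, independent of compute_vifs()
oracle_vif <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    df <- data.frame(y = X[, j], X[, -j, drop = FALSE])
    r2 <- summary(stats::lm(y ~ ., data = df))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

# explore every processing order of the above-threshold pairs under the
# "drop the member with larger mean |r|" rule; returns all reachable final
# retained sets
oracle_corr_filter_all_orders <- function(X, threshold = 0.95) {
  explore <- function(keep) {
    C <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(C) <- 0
    pairs <- which(C > threshold, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (nrow(pairs) == 0) return(list(sort(keep)))
    res <- list()
    for (r in seq_len(nrow(pairs))) {
      pr <- keep[pairs[r, ]]
      mean_r <- vapply(pr, function(v)
        mean(abs(stats::cor(X[, v], X[, setdiff(keep, v), drop = FALSE]))),
        numeric(1))
      drop_v <- pr[which.max(mean_r)]
      res <- c(res, explore(setdiff(keep, drop_v)))
    }
    unique(res)
  }
  explore(colnames(X))
}

vec_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

g_const <- 9.81
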