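# Population-level simulation: cohorts of drop-jump trials, and tabular
# datasets with known latent structure for validating the PLS machinery.

#' Simulate a cohort of drop-jump participants
#'
#' Draws participant-level anthropometry and movement-strategy parameters
#' from the population the package targets (male collegiate athletes:
#' height 1.74 +/- 0.07 m, mass 79 +/- 12 kg, contact time 0.22 +/- 0.04 s
#' truncated to [0.16, 0.38], jump height 0.33 +/- 0.05 m truncated to
#' [0.25, 0.51]) and generates `n_trials` drop jumps per participant with
#' small within-participant jitter.
#'
#' @param n_participants number of participants (default 43).
#' @param n_trials trials per participant (default 3).
#' @param seed integer seed; every downstream draw derives from it.
#' @param noise_sd marker noise SD passed to [generate_trial()].
#' @return list of participants, each a list of `dj_trial` objects; the
#'   participant parameters are attached as attribute `params`.
#' @export
simulate_cohort <- function(n_participants = 43, n_trials = 3, seed = 1L,
                            noise_sd = 0) {
  set.seed(as.integer(seed))
  rtrunc <- function(n, mean, sd, lo, hi)
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
  pars <- data.frame(
    height_m = rtrunc(n_participants, 1.74, 0.07, 1.55, 1.95),
    mass_kg = rtrunc(n_participants, 79, 12, 55, 115),
    contact_time = rtrunc(n_participants, 0.22, 0.04, 0.16, 0.38),
    jump_height = rtrunc(n_participants, 0.33, 0.05, 0.25, 0.51),
    crouch_pre = rtrunc(n_participants, 0.12, 0.03, 0.06, 0.22),
    knee_valgus_dev_m = rtrunc(n_participants, 0.015, 0.005, 0.004, 0.03),
    hip_rot_deg = rtrunc(n_participants, 7, 2, 2, 13),
    shank_rot_deg = rtrunc(n_participants, 5, 1.5, 1.5, 9),
    trunk_sway_m = rtrunc(n_participants, 0.02, 0.006, 0.005, 0.04),
    baseline_knee_dev_m = rtrunc(n_participants, 0.01, 0.004, 0, 0.025),
    baseline_rot_deg = rtrunc(n_participants, 5, 2, 0, 11),
    baseline_lean_deg = rtrunc(n_participants, 2, 1, 0, 5)
  )
  trial_seeds <- matrix(
    sample.int(2^31 - 2, n_participants * n_trials),
    n_participants, n_trials)
  cohort <- lapply(seq_len(n_participants), function(i) {
    lapply(seq_len(n_trials), function(j) {
      jit <- function(x, s, lo, hi)
        pmin(hi, pmax(lo, x * (1 + stats::rnorm(1, 0, s))))
      prof <- dj_profile(
        contact_time = jit(pars$contact_time[i], 0.02, 0.16, 0.38),
        jump_height = jit(pars$jump_height[i], 0.02, 0.2, 0.55),
        crouch_pre = jit(pars$crouch_pre[i], 0.03, 0.05, 0.25),
        knee_valgus_dev_m = pars$knee_valgus_dev_m[i],
        hip_rot_deg = pars$hip_rot_deg[i],
        shank_rot_deg = pars$shank_rot_deg[i],
        trunk_sway_m = pars$trunk_sway_m[i],
        baseline_knee_dev_m = pars$baseline_knee_dev_m[i],
        baseline_rot_deg = pars$baseline_rot_deg[i],
        baseline_lean_deg = pars$baseline_lean_deg[i])
      generate_trial(prof,
                     anthropometry = list(height_m = pars$height_m[i],
                                          mass_kg = pars$mass_kg[i]),
                     noise_sd = noise_sd, seed = trial_seeds[i, j])
    })
  })
  attr(cohort, "params") <- pars
  cohort
}

#' Analyze a simulated cohort into a feature table
#'
#' Convenience wrapper: runs [analyze_trial()] on every trial of a cohort
#' from [simulate_cohort()] and assembles the feature table.
#'
#' @param cohort result of [simulate_cohort()].
#' @param ... passed to [analyze_trial()].
#' @param aggregate trial aggregation, see [assemble_feature_table()].
#' @param include_joint_work keep auxiliary joint-work columns.
#' @return feature table data.frame.
#' @export
analyze_cohort <- function(cohort, ..., aggregate = "mean",
                           include_joint_work = FALSE) {
  analyses <- lapply(cohort, function(trials)
    lapply(trials, function(tr) analyze_trial(tr$recording, ...)))
  assemble_feature_table(analyses, aggregate = aggregate,
                         include_joint_work = include_joint_work)
}

#' Specification of a latent-structure tabular dataset
#'
#' Describes the ground truth of a synthetic predictor table with
#' low-dimensional latent structure: `X = T P' + E`, `y = T q + f`, the
#' stand-in for a participants x biomechanical-variables table.
#'
#' @param n_samples observations (default 43).
#' @param n_predictors predictors (default 44).
#' @param n_latent latent components (default 3).
#' @param loading_matrix optional `n_predictors x n_latent` loadings; by
#'   default block-structured: each latent loads on its own block of
#'   predictors (correlated blocks, as phase-grouped biomechanical variables
#'   are), remaining predictors load on nothing. Blocks have unequal sizes
#'   and decaying loading scale so that the latent dimension is identifiable
#'   by cross-validation: with symmetric blocks and equal response
#'   coefficients a single X-direction would already carry the whole
#'   response.
#' @param response_coefficients length-`n_latent` q; defaults to an
#'   alternating-sign sequence (1, -1, 1, ...).
#' @param noise_sd SD of the predictor noise E (default 0.1).
#' @param response_noise_sd SD of the response noise f; the default is set
#'   so the population R2 of y on the latent scores is 0.9.
#' @param n_active_per_latent block size for the default loading matrix.
#' @param seed integer seed.
#' @return list of class `latent_truth`.
#' @export
latent_truth <- function(n_samples = 43, n_predictors = 44, n_latent = 3,
                         loading_matrix = NULL, response_coefficients = NULL,
                         noise_sd = 0.1, response_noise_sd = NULL,
                         n_active_per_latent = 4, seed = 1L) {
  if (n_samples < n_latent + 2)
    stop("need n_samples >= n_latent + 2")
  if (is.null(response_coefficients))
    response_coefficients <- (-1)^(seq_len(n_latent) - 1)
  if (length(response_coefficients) != n_latent)
    stop("response_coefficients must have length n_latent")
  if (is.null(loading_matrix)) {
    sizes <- rep_len(n_active_per_latent, n_latent)
    if (length(n_active_per_latent) == 1 && n_latent > 1)
      sizes <- pmax(2, floor(n_active_per_latent * 3.5 *
                               0.5^(seq_len(n_latent) - 1)))
    scales <- seq(1, 0.35, length.out = n_latent)
    loading_matrix <- matrix(0, n_predictors, n_latent)
    ofs <- 0
    for (a in seq_len(n_latent)) {
      idx <- ofs + seq_len(sizes[a])
      if (max(idx) > n_predictors)
        stop("too many active predictors for n_predictors")
      loading_matrix[idx, a] <- scales[a]
      ofs <- ofs + sizes[a]
    }
  }
  if (nrow(loading_matrix) != n_predictors ||
      ncol(loading_matrix) != n_latent)
    stop("loading matrix dimensions do not match n_predictors x n_latent")
  if (is.null(response_noise_sd)) {
    # population R2 = |q|^2 / (|q|^2 + sigma_f^2) = 0.9
    q2 <- sum(response_coefficients^2)
    response_noise_sd <- sqrt(q2 * (1 / 0.9 - 1))
  }
  structure(list(n_samples = n_samples, n_predictors = n_predictors,
                 n_latent = n_latent, loading_matrix = loading_matrix,
                 response_coefficients = response_coefficients,
                 noise_sd = noise_sd, response_noise_sd = response_noise_sd,
                 seed = as.integer(seed)),
            class = "latent_truth")
}

#' Generate a predictor table and response with known latent structure
#'
#' Draws latent scores `T` (i.i.d. standard normal), builds
#' `X = T P' + E` and `y = T q + f`, deterministic under the stored seed.
#'
#' @param truth a `latent_truth`.
#' @return list `X` (matrix with column names), `y`, `scores` (T), `truth`;
#'   `active` gives the indices of truly loading predictors.
#' @export
generate_pls_dataset <- function(truth) {
  stopifnot(inherits(truth, "latent_truth"))
  set.seed(truth$seed)
  n <- truth$n_samples; p <- truth$n_predictors; a <- truth$n_latent
  Tm <- matrix(stats::rnorm(n * a), n, a)
  E <- matrix(stats::rnorm(n * p, 0, truth$noise_sd), n, p)
  X <- Tm %*% t(truth$loading_matrix) + E
  colnames(X) <- paste0("x", seq_len(p))
  y <- as.numeric(Tm %*% truth$response_coefficients) +
    stats::rnorm(n, 0, truth$response_noise_sd)
  active <- which(rowSums(abs(truth$loading_matrix)) > 0)
  list(X = X, y = y, scores = Tm, active = active, truth = truth)
}

#' Population R2 implied by a latent truth
#' @param truth a `latent_truth`.
#' @return population proportion of response variance explained by the
#'   latent scores.
#' @export
population_r2 <- function(truth) {
  q2 <- sum(truth$response_coefficients^2)
  q2 / (q2 + truth$response_noise_sd^2)
}
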