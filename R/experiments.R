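#' Producer-fixation phase diagram over diffusion length and benefit
#'
#' For each `(lambda, alpha)` cell, runs `reps` competition simulations from
#' a random 50-50 mixed initial condition and estimates the probability that
#' producers fix, with Wilson 95% intervals.
#'
#' @param lambdas,alphas Numeric grids of diffusion lengths and benefit
#'   values (non-empty).
#' @param L Linear lattice size (default 32, the full experiment scale).
#' @param reps Replicates per cell (`>= 1`).
#' @param seed Base seed; every run draws a distinct derived seed.
#' @param g0,kappa Growth parameters (cost defaults to `g0`).
#' @return An object of class `phase_diagram`: list with matrices `prob`,
#'   `ci_low`, `ci_high` (rows = lambdas, cols = alphas) and the grids.
#' @export
phase_diagram <- function(lambdas, alphas, L = 32, reps = 20, seed = 1,
                          g0 = 1, kappa = g0) {
  stopifnot(length(lambdas) > 0, length(alphas) > 0, reps >= 1)
  prob <- lo <- hi <- matrix(NA_real_, length(lambdas), length(alphas),
                             dimnames = list(lambda = lambdas, alpha = alphas))
  run_id <- 0
  for (i in seq_along(lambdas)) for (j in seq_along(alphas)) {
    wins <- 0L
    for (k in seq_len(reps)) {
      run_id <- run_id + 1
      sim <- run_until_fixation(L = L, variant = "competition",
                                lambda = lambdas[i], alpha = alphas[j],
                                kappa = kappa, g0 = g0,
                                init = "mixed_50_50",
                                seed = (seed + run_id) %% .Machine$integer.max)
      if (!sim$absorbed) stop("phase_diagram run hit max_events before fixation")
      wins <- wins + (sim$winner == "P")
    }
    prob[i, j] <- wins / reps
    ci <- wilson_ci(wins, reps)
    lo[i, j] <- ci[1L]; hi[i, j] <- ci[2L]
  }
  structure(list(lambdas = lambdas, alphas = alphas, prob = prob,
                 ci_low = lo, ci_high = hi, reps = reps, L = L),
            class = "phase_diagram")
}

#' Estimate producer fixation probability at one parameter point
#' @noRd
p_fixation_probe <- function(alpha, lambda, L, reps, seed, g0 = 1, kappa = g0) {
  wins <- 0L
  for (k in seq_len(reps)) {
    sim <- run_until_fixation(L = L, variant = "competition", lambda = lambda,
                              alpha = alpha, kappa = kappa, g0 = g0,
                              init = "mixed_50_50",
                              seed = (seed + k) %% .Machine$integer.max)
    if (!sim$absorbed) stop("probe run hit max_events before fixation")
    wins <- wins + (sim$winner == "P")
  }
  ci <- wilson_ci(wins, reps)
  c(p = wins / reps, lo = ci[1L], hi = ci[2L])
}

#' Critical benefit value by bisection on producer-fixation probability
#'
#' Finds the benefit coefficient `alpha*` at which producer and nonproducer
#' fixation are equally probable from a 50-50 mixed initial condition, by
#' bisection against the estimated producer-fixation probability. Each probe
#' runs `reps_per_probe` simulations; the side is chosen by the point
#' estimate, and the search stops once the probe's Wilson interval straddles
#' 0.5 and the bracket is narrower than `tol` (relative), or after
#' `max_probes` probes. Deterministic given `seed`.
#'
#' The default bracket is `[0, 4 * kappa * max(1, lambda^2) * gamma / p]`:
#' mean concentration at 50-50 is `p / (2 gamma)`, so the benefit must reach
#' about `2 kappa gamma / p` to offset the cost, while in the private-
#' resource limit (`lambda -> 0`) balance sits near `kappa gamma / p`.
#'
#' @param lambda Diffusion length.
#' @param L Linear lattice size.
#' @param tol Relative bracket width at which an unresolvable probe stops
#'   the search.
#' @param reps_per_probe Simulations per probe point.
#' @param bracket Length-2 initial bracket for `alpha` (see Details for the
#'   default).
#' @param seed Base seed.
#' @param g0,kappa,gamma,p Model parameters.
#' @param max_probes Probe budget for the bisection.
#' @param check_ends If `TRUE` (default) the bracket ends are probed first
#'   and a bracket failure (both ends on the same side of 0.5) is an error.
#' @return An object of class `critical_alpha`: list with `alpha_star`,
#'   `bracket`, and a data frame `probes` (`alpha`, `p_hat`, `ci_low`,
#'   `ci_high`, `n`).
#' @export
critical_alpha <- function(lambda, L = 32, tol = 0.1, reps_per_probe = 40,
                           bracket = NULL, seed = 1, g0 = 1, kappa = g0,
                           gamma = 1, p = 1, max_probes = 12,
                           check_ends = TRUE) {
  if (is.null(bracket))
    bracket <- c(0, 4 * kappa * max(1, lambda^2) * gamma / p)
  lo <- bracket[1L]; hi <- bracket[2L]
  probes <- list()
  probe <- function(a, s) {
    pr <- p_fixation_probe(a, lambda, L, reps_per_probe, s, g0, kappa)
    probes[[length(probes) + 1L]] <<- data.frame(alpha = a, p_hat = pr["p"],
                                                 ci_low = pr["lo"],
                                                 ci_high = pr["hi"],
                                                 n = reps_per_probe)
    pr
  }
  if (check_ends) {
    plo <- probe(lo, seed)
    phi <- probe(hi, seed + 1000L)
    if (plo["p"] >= 0.5 && plo["lo"] > 0.5)
      stop("bracket failure: producer fixation already above 0.5 at alpha = ", lo)
    if (phi["p"] <= 0.5 && phi["hi"] < 0.5)
      stop("bracket failure: producer fixation still below 0.5 at alpha = ", hi)
    if (plo["p"] >= 0.5 || phi["p"] <= 0.5)
      stop("bracket failure: fixation probability on the same side of 0.5 at both ends")
  }
  for (it in seq_len(max_probes)) {
    mid <- (lo + hi) / 2
    pr <- probe(mid, seed + 1000L * (it + 1L))
    ambiguous <- pr["lo"] < 0.5 && pr["hi"] > 0.5
    if (ambiguous && (hi - lo) <= tol * max(mid, .Machine$double.eps)) break
    if (pr["p"] >= 0.5) hi <- mid else lo <- mid
    if ((hi - lo) <= tol * max((hi + lo) / 2, .Machine$double.eps)) break
  }
  probes <- do.call(rbind, probes)
  rownames(probes) <- NULL
  structure(list(alpha_star = (lo + hi) / 2, bracket = c(lo, hi),
                 probes = probes, lambda = lambda, L = L,
                 reps_per_probe = reps_per_probe),
            class = "critical_alpha")
}

#' @exportS3Method base::print
print.critical_alpha <- function(x, ...) {
  cat(sprintf("Critical benefit search (lambda = %g, L = %d)\n", x$lambda, x$L))
  cat(sprintf("  alpha* = %.4g  (bracket [%.4g, %.4g], %d probes of %d runs)\n",
              x$alpha_star, x$bracket[1L], x$bracket[2L], nrow(x$probes),
              x$reps_per_probe))
  invisible(x)
}

#' Invader fixation probability and time across system sizes
#'
#' For each `L`, runs `reps` simulations from a single invading cell and
#' reports the invader's fixation probability (Wilson 95% CI) and mean
#' fixation time conditional on invader fixation. Under the neutral variant
#' the probability is `1/L^2` (one neutral cell out of `L^2` equivalent
#' cells).
#'
#' @param Ls Integer vector of linear sizes.
#' @param variant Model variant.
#' @param reps Replicates per size.
#' @param seed Base seed.
#' @param invader_type Invading cell type.
#' @param lambda,alpha,kappa,g0 Model parameters (ignored where the variant
#'   ignores them).
#' @return A data frame with one row per `L`: `L`, `estimate`, `ci_low`,
#'   `ci_high`, `n_wins`, `n`, `conditional_time`.
#' @export
size_scaling <- function(Ls, variant = "neutral", reps = 1000, seed = 1,
                         invader_type = "NP", lambda = 10, alpha = 0,
                         kappa = NULL, g0 = 1) {
  rows <- lapply(seq_along(Ls), function(i) {
    L <- Ls[i]
    sims <- lapply(seq_len(reps), function(k)
      run_until_fixation(L = L, variant = variant, lambda = lambda,
                         alpha = alpha, kappa = kappa, g0 = g0,
                         init = "single_invader", invader_type = invader_type,
                         seed = (seed + (i - 1L) * reps + k) %% .Machine$integer.max))
    st <- fixation_statistics(sims, invader_type)
    data.frame(L = L, estimate = st$estimate, ci_low = st$ci_low,
               ci_high = st$ci_high, n_wins = st$n_wins, n = st$n,
               conditional_time = st$conditional_time)
  })
  do.call(rbind, rows)
}

#' Time series of a single run, with periodic snapshots
#'
#' Runs one simulation recording the grid at every multiple of
#' `snapshot_dt`. If `out_dir` is given, each snapshot is written as a
#' plain-text 0/1 matrix (filename carrying event index and time) together
#' with a companion mask flagging boundary cells, plus the trajectory CSV.
#'
#' @param config A [sim_config()]; its `snapshot_dt` is overridden.
#' @param snapshot_dt Simulation-time interval between snapshots.
#' @param out_dir Optional output directory.
#' @return The `moran_sim`, invisibly if `out_dir` is given.
#' @export
time_series <- function(config, snapshot_dt, out_dir = NULL) {
  config$snapshot_dt <- snapshot_dt
  sim <- run_until_fixation(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- attr(sim$snapshots, "meta")
    for (i in seq_along(sim$snapshots)) {
      stem <- sprintf("snapshot_e%07d_t%012.4f", meta$event_index[i], meta$time[i])
      write_snapshot(sim$snapshots[[i]], file.path(out_dir, paste0(stem, ".txt")))
      bmask <- matrix(0L, config$L, config$L)
      bs <- boundary_sites(sim$snapshots[[i]])
      bmask[bs[, 1L] + 1L + config$L * bs[, 2L]] <- 1L
      write_snapshot(bmask, file.path(out_dir, paste0(stem, "_boundary.txt")))
    }
    write_trajectory(sim, file.path(out_dir, "trajectory.csv"))
    return(invisible(sim))
  }
  sim
}

#' Mutualism positive control: persistence and spatial structure
#'
#' Measures the mean neutral absorption time at the same `L` (from a 50-50
#' mixed start), sets the persistence horizon to `horizon_mult` times that,
#' and runs `reps` mutualism simulations capped at the horizon. Reports the
#' fraction of runs in which both types survive to the horizon, and the
#' pooled radial distribution function of the surviving final states.
#'
#' @param lambda,alpha Mutualism resource parameters. Defaults (`lambda = 2`,
#'   `alpha = 10`) sit well inside the coexistence regime: kin domains a few
#'   cells across, benefit strong enough that growth is dominated by the
#'   complementary type's resource.
#' @param L Linear lattice size.
#' @param reps Mutualism replicates.
#' @param horizon_mult Horizon in units of the measured neutral mean
#'   absorption time.
#' @param neutral_reps Neutral runs used to measure the absorption time.
#' @param seed Base seed.
#' @param g0 Basal growth rate; the production cost is fixed at `g0`
#'   (both types pay it).
#' @return An object of class `mutualism_experiment`: list with
#'   `survival_fraction`, `horizon_time`, `neutral_mean_absorption`,
#'   `neutral_absorbed_by_horizon`, `rdf` (over surviving final grids), and
#'   the final NP fractions.
#' @export
mutualism_experiment <- function(lambda = 2, alpha = 10, L = 32, reps = 20,
                                 horizon_mult = 10, neutral_reps = 20,
                                 seed = 1, g0 = 1) {
  neutral <- lapply(seq_len(neutral_reps), function(k)
    run_until_fixation(L = L, variant = "neutral", init = "mixed_50_50",
                       seed = (seed + k) %% .Machine$integer.max))
  ntimes <- vapply(neutral, function(s) s$fixation_time, numeric(1))
  horizon <- horizon_mult * mean(ntimes)
  sims <- lapply(seq_len(reps), function(k)
    run_until_fixation(L = L, variant = "mutualism", lambda = lambda,
                       alpha = alpha, kappa = g0, g0 = g0,
                       init = "mixed_50_50", t_max = horizon,
                       seed = (seed + neutral_reps + k) %% .Machine$integer.max))
  survived <- vapply(sims, function(s) !s$absorbed, logical(1))
  finals <- lapply(sims[survived], function(s) s$final_grid)
  rdf <- if (length(finals) > 0) radial_distribution(finals, "A") else NULL
  structure(list(survival_fraction = mean(survived),
                 horizon_time = horizon,
                 neutral_mean_absorption = mean(ntimes),
                 neutral_absorbed_by_horizon = mean(ntimes < horizon),
                 rdf = rdf,
                 final_np_fraction = vapply(sims, function(s)
                   sum(s$final_grid == 0L) / L^2, numeric(1)),
                 lambda = lambda, alpha = alpha, L = L, reps = reps),
            class = "mutualism_experiment")
}

#' @exportS3Method base::print
print.mutualism_experiment <- function(x, ...) {
  cat(sprintf("Mutualism control (lambda = %g, alpha = %g, %d x %d)\n",
              x$lambda, x$alpha, x$L, x$L))
  cat(sprintf("  horizon = %.4g (10x-style multiple of neutral mean absorption %.4g)\n",
              x$horizon_time, x$neutral_mean_absorption))
  cat(sprintf("  both types survived to horizon in %.0f%% of %d runs\n",
              100 * x$survival_fraction, x$reps))
  invisible(x)
}
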