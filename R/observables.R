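#' Selection bias of the next replacement event
#'
#' The probability that the next event is a nonproducer replacing a producer:
#' the summed rate of NP-divides-into-P events over the total rate. A value
#' of 0.5 indicates neutral dynamics; balancing selection would require the
#' bias to favor the under-represented type. On a uniform grid the quantity
#' is undefined and an error is raised.
#'
#' @param table An [build_event_table()] result.
#' @return A probability in `[0, 1]`.
#' @export
selection_bias <- function(table) {
  stopifnot(inherits(table, "event_table"))
  if (table$total_rate <= 0)
    stop("selection bias is undefined on a uniform grid (total rate 0)")
  sum(table$events$rate[table$events$divider_type == 0L]) / table$total_rate
}

#' Radial distribution function of a cell type
#'
#' For every cell of the reference type, the fraction of cells at (minimal-
#' image Euclidean) distance `r` that share the reference type, pooled over
#' all reference centers in all supplied grids. Pooling centers across
#' configurations weights each configuration by its number of reference
#' cells. Computed exactly via circular autocorrelation of the type
#' indicator (FFT), so every displacement class is counted without sampling.
#'
#' @param grids A cell grid or list of cell grids (all the same `L`).
#' @param reference_type Label of the reference type (default `"NP"`).
#' @param binwidth Width of the distance bins (default 1 cell length,
#'   centered at integers `1..L/2`), or `NULL` to group by exact distance.
#'   Distances beyond `L/2` are dropped.
#' @return A data frame of class `rdf_curve` with columns `r` (bin center or
#'   exact distance), `fraction`, and `n_obs` (number of center/site pairs in
#'   the bin). Zero rows if no grid contains a reference cell.
#' @export
radial_distribution <- function(grids, reference_type = "NP", binwidth = 1) {
  if (is.matrix(grids)) grids <- list(grids)
  ref <- type_code(reference_type)
  L <- nrow(grids[[1L]])
  # displacement-class geometry (shared by all grids)
  d <- ifelse(0:(L - 1L) <= L / 2, 0:(L - 1L), 0:(L - 1L) - L)
  rdist <- sqrt(outer(d^2, d^2, `+`))
  pair_counts <- matrix(0, L, L)
  n_centers <- 0
  for (g in grids) {
    ind <- matrix(as.numeric(g == ref), L, L)
    nr <- sum(ind)
    if (nr == 0) next
    fh <- stats::fft(ind)
    cc <- Re(stats::fft(fh * Conj(fh), inverse = TRUE)) / (L * L)
    pair_counts <- pair_counts + round(cc)  # ref-ref pairs per displacement
    n_centers <- n_centers + nr
  }
  if (n_centers == 0)
    return(structure(data.frame(r = numeric(0), fraction = numeric(0),
                                n_obs = numeric(0)), class = c("rdf_curve", "data.frame")))
  keep <- rdist > 0 & rdist <= L / 2
  r <- rdist[keep]
  num <- pair_counts[keep]            # same-type pairs, pooled over grids
  den <- n_centers                    # one observation per center per displacement
  key <- if (is.null(binwidth)) round(r, 9) else round(r / binwidth) * binwidth
  agg_num <- tapply(num, key, sum)
  agg_n <- tapply(rep(den, length(key)), key, sum)
  out <- data.frame(r = as.numeric(names(agg_num)),
                    fraction = as.numeric(agg_num) / as.numeric(agg_n),
                    n_obs = as.numeric(agg_n))
  out <- out[out$r > 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("rdf_curve", "data.frame"))
}

#' Radial profile of a field about the lattice origin
#'
#' Mean field value per minimal-image-distance bin, for profiles of a
#' [single_source_kernel()] and decay-length fits.
#'
#' @param field An `L x L` numeric matrix with its source at site `(0, 0)`
#'   (matrix element `[1, 1]`).
#' @param binwidth Distance bin width (default 1), or `NULL` for exact
#'   distances. Distances beyond `L/2` are dropped.
#' @return A data frame with columns `r`, `value`, `n_obs`.
#' @export
radial_profile <- function(field, binwidth = 1) {
  L <- nrow(field)
  d <- ifelse(0:(L - 1L) <= L / 2, 0:(L - 1L), 0:(L - 1L) - L)
  rdist <- sqrt(outer(d^2, d^2, `+`))
  keep <- rdist > 0 & rdist <= L / 2
  r <- rdist[keep]; v <- field[keep]
  key <- if (is.null(binwidth)) round(r, 9) else round(r / binwidth) * binwidth
  out <- data.frame(r = as.numeric(names(tapply(v, key, mean))),
                    value = as.numeric(tapply(v, key, mean)),
                    n_obs = as.numeric(tapply(v, key, length)))
  out <- out[out$r > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit an exponential decay length to a radial curve
#'
#' Least-squares fit of `log(value - plateau)` against `r` over the window
#' `[r_min, r_max]`; the decay length is `-1 / slope`. The long-range
#' plateau, unless given, is estimated as the mean of the outer quartile of
#' the curve's bins (largest `r`).
#'
#' @param curve An [radial_distribution()] / [radial_profile()] data frame,
#'   or anything with columns `r` and `fraction` or `value`.
#' @param r_min,r_max Fit window (inclusive).
#' @param plateau Optional long-range plateau to subtract.
#' @return An object of class `decay_fit`: list with `decay_length`,
#'   `slope`, `plateau`, `n_bins`, `r_min`, `r_max`.
#' @export
fit_exponential_decay <- function(curve, r_min, r_max, plateau = NULL) {
  r <- curve$r
  y <- if (!is.null(curve$fraction)) curve$fraction else curve$value
  if (is.null(y)) stop("curve must have a `fraction` or `value` column")
  if (is.null(plateau)) {
    outer_q <- r >= stats::quantile(r, 0.75)
    plateau <- mean(y[outer_q])
  }
  win <- r >= r_min & r <= r_max
  excess <- y[win] - plateau
  if (sum(excess > 0) < 3L)
    stop("fewer than 3 bins with positive excess over the plateau in the window")
  ok <- excess > 0
  fit <- stats::lm(log(excess[ok]) ~ r[win][ok])
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) stop("no decay: fitted slope is non-negative")
  structure(list(decay_length = -1 / slope, slope = slope, plateau = plateau,
                 n_bins = sum(ok), r_min = r_min, r_max = r_max),
            class = "decay_fit")
}

#' @exportS3Method base::print
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit over r in [%g, %g] (%d bins)\n",
              x$r_min, x$r_max, x$n_bins))
  cat(sprintf("  decay length = %.4g, plateau = %.4g\n", x$decay_length, x$plateau))
  invisible(x)
}

#' Fixation statistics over a set of completed runs
#'
#' Point estimate and Wilson 95% confidence interval for the probability that
#' `target` fixes, plus the mean fixation time conditional on `target`
#' winning. All runs must be absorbed; unabsorbed runs are an error, never
#' silently dropped.
#'
#' @param results A list of `moran_sim` objects (or lists with elements
#'   `winner`, `fixation_time`, `absorbed`).
#' @param target Cell-type label whose fixation is counted.
#' @return A list with `estimate`, `ci_low`, `ci_high`, `n`, `n_wins`, and
#'   `conditional_time` (`NA` if the target never fixed).
#' @export
fixation_statistics <- function(results, target) {
  absorbed <- vapply(results, function(x) isTRUE(x$absorbed), logical(1))
  if (!all(absorbed))
    stop(sum(!absorbed), " run(s) did not reach absorption")
  winners <- vapply(results, function(x) x$winner, character(1))
  times <- vapply(results, function(x) x$fixation_time, numeric(1))
  n <- length(results)
  wins <- winners == target
  ci <- wilson_ci(sum(wins), n)
  list(estimate = mean(wins), ci_low = ci[1L], ci_high = ci[2L],
       n = n, n_wins = sum(wins),
       conditional_time = if (any(wins)) mean(times[wins]) else NA_real_)
}

#' Wilson score interval for a binomial proportion
#' @noRd
wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Selection bias as a function of nonproducer fraction
#'
#' Runs `reps` replicate simulations of the given configuration and pools
#' the per-event selection bias, conditioned on the NP fraction at the
#' moment of each event. Raw conditioning bins have width `1/L^2` (one per
#' NP count) and are aggregated to about `display_bins` bins; pooling
#' weights by event counts.
#'
#' @param config A [sim_config()].
#' @param reps Number of replicate runs.
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @param display_bins Approximate number of output bins.
#' @return A data frame of class `bias_curve` with columns `np_fraction`,
#'   `bias`, `n_obs`.
#' @export
bias_vs_fraction <- function(config, reps = 1, seed = NULL, display_bins = 50) {
  N <- config$L^2
  sum_bias <- rep(0, N + 1)
  n_obs <- rep(0, N + 1)
  for (i in seq_len(reps)) {
    cfg <- config
    cfg$seed <- if (is.null(seed)) NULL else seed + i - 1
    sim <- run_until_fixation(cfg)
    idx <- sim$bias$np_count + 1L
    sum_bias[idx] <- sum_bias[idx] + sim$bias$mean_bias * sim$bias$n_obs
    n_obs[idx] <- n_obs[idx] + sim$bias$n_obs
  }
  frac <- (0:N) / N
  nb <- min(display_bins, N + 1L)
  key <- round(frac * nb) / nb
  agg_b <- tapply(sum_bias, key, sum)
  agg_n <- tapply(n_obs, key, sum)
  out <- data.frame(np_fraction = as.numeric(names(agg_b)),
                    bias = as.numeric(agg_b) / pmax(as.numeric(agg_n), 1),
                    n_obs = as.numeric(agg_n))
  out <- out[out$n_obs > 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("bias_curve", "data.frame"))
}
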