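#' Simulation configuration
#'
#' Collects everything a run needs: lattice size, model variant, growth and
#' resource parameters, initial condition, seed, and stopping/recording
#' controls. Time is measured in units of `1 / g0`.
#'
#' @param L Linear lattice size.
#' @param variant Model variant; see [growth_params()].
#' @param lambda Diffusion length (cell lengths); ignored for `neutral`.
#' @param alpha Benefit per unit resource concentration.
#' @param kappa Production cost; defaults to `g0` for non-neutral variants.
#' @param g0 Basal growth rate.
#' @param p Production flux per producer.
#' @param gamma Resource decay rate.
#' @param Ks Saturation constant (`Inf` = linear uptake).
#' @param init Initial condition kind, an [initial_condition()], or an
#'   explicit 0/1 cell-grid matrix (e.g. a [read_snapshot()] result) to
#'   resume from; a matrix must be `L x L`.
#' @param invader_type Invader label for `single_invader`.
#' @param seed Integer RNG seed (all randomness flows from it).
#' @param max_events Event cap; default `50 * L^4`, comfortably above
#'   neutral absorption times.
#' @param t_max Simulation-time cap (default none).
#' @param record_stride Trajectory recording stride in events (default
#'   `L^2`).
#' @param snapshot_fractions NP fractions at which to record the grid the
#'   first time each is reached.
#' @param snapshot_dt If `> 0`, also record the grid at every multiple of
#'   this simulation time.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(L, variant = "competition", lambda = 10, alpha = 0,
                       kappa = NULL, g0 = 1, p = 1, gamma = 1, Ks = Inf,
                       init = "mixed_50_50", invader_type = "NP", seed = NULL,
                       max_events = NULL, t_max = Inf, record_stride = NULL,
                       snapshot_fractions = NULL, snapshot_dt = 0) {
  growth <- growth_params(variant, g0 = g0, kappa = kappa, alpha = alpha)
  resource <- if (growth$variant == "neutral") NULL else
    resource_params(lambda, p = p, gamma = gamma, Ks = Ks)
  if (is.character(init)) init <- initial_condition(init, invader_type)
  L <- as.integer(L)
  if (is.matrix(init)) {
    if (!all(dim(init) == L)) stop("matrix init must be L x L")
    if (!all(init %in% c(0L, 1L))) stop("matrix init entries must be 0 or 1")
    storage.mode(init) <- "integer"
  }
  cfg <- structure(list(
    L = L, growth = growth, resource = resource, init = init, seed = seed,
    max_events = if (is.null(max_events)) 50 * as.numeric(L)^4 else max_events,
    t_max = t_max,
    record_stride = if (is.null(record_stride)) L^2 else record_stride,
    snapshot_fractions = snapshot_fractions,
    snapshot_dt = snapshot_dt), class = "sim_config")
  cfg
}

#' Cheap deterministic fingerprint of a configuration (not cryptographic):
#' two position-weighted polynomial sums over the deparsed config, mod a
#' 32-bit prime. Stable across sessions; excludes the seed so replicate runs
#' of one configuration share a hash.
#' @noRd
config_hash <- function(cfg) {
  s <- utf8ToInt(paste(deparse(cfg[setdiff(names(cfg), "seed")]), collapse = "\n"))
  i <- seq_along(s)
  pr <- 4294967291
  h1 <- sum((s * i) %% pr) %% pr
  h2 <- sum((s * (i^2 %% pr)) %% pr) %% pr
  sprintf("%08x%08x", as.integer(h1 %% 2^31), as.integer(h2 %% 2^31))
}

#' Type labels for a variant: position 1 = code 1, position 2 = code 0
#' @noRd
variant_labels <- function(variant) {
  if (variant == "mutualism") c("A", "B") else c("P", "NP")
}

#' Run the spatial Moran process to fixation
#'
#' The replacement loop: build the event table on the current grid, sample
#' the next event and its exact Doob-Gillespie waiting time, apply the
#' replacement, and update the steady-state resource field(s) by kernel
#' superposition. The loop stops at absorption (a uniform grid), at
#' `max_events`, or at `t_max`; hitting a cap is reported explicitly via
#' `absorbed = FALSE`.
#'
#' @param config A [sim_config()]; alternatively pass its arguments via
#'   `...`.
#' @param ... Arguments forwarded to [sim_config()] when `config` is `NULL`.
#' @return An object of class `moran_sim` with elements `winner` (label, or
#'   `NA` if not absorbed), `fixation_time`, `event_count`, `absorbed`,
#'   `final_grid`, `trajectory` (data frame: `event_index`, `time`,
#'   `np_fraction`, `total_rate`, `divider_type`), `bias` (mean selection
#'   bias binned by NP count), `snapshots`, `field`(s), `config`, `seed`,
#'   `config_hash`.
#' @examples
#' sim <- run_until_fixation(L = 8, variant = "neutral", seed = 1)
#' sim
#' @export
run_until_fixation <- function(config = NULL, ...) {
  cfg <- if (is.null(config)) sim_config(...) else config
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- cfg$L
  if (is.matrix(cfg$init)) {
    grid <- cfg$init
  } else {
    init <- cfg$init; init$seed <- NULL  # RNG already seeded once, above
    grid <- make_grid(L, init)
  }
  variant <- cfg$growth$variant

  if (variant == "competition_saturating")
    return(run_saturating_r(cfg, grid))

  vcode <- match(variant, c("neutral", "competition", "mutualism")) - 1L
  empty <- matrix(0, 1, 1)
  if (vcode == 0L) {
    kernel <- empty; fP <- empty; fB <- empty
  } else {
    kernel <- single_source_kernel(L, cfg$resource)
    fP <- steady_state_field(grid, cfg$resource)
    fB <- if (vcode == 2L) steady_state_field(1L - grid, cfg$resource) else empty
  }
  snap_counts <- if (is.null(cfg$snapshot_fractions)) integer(0) else
    as.integer(round(cfg$snapshot_fractions * L^2))

  res <- .sim_run_cpp(grid, kernel, fP, fB,
                      cfg$growth$g0, cfg$growth$kappa, cfg$growth$alpha, vcode,
                      cfg$max_events, cfg$t_max, cfg$record_stride,
                      snap_counts, cfg$snapshot_dt)
  labels <- variant_labels(variant)
  traj <- as.data.frame(res$trajectory)
  names(traj) <- c("event_index", "time", "np_fraction", "total_rate", "divider_type")
  traj$divider_type <- ifelse(is.na(traj$divider_type), NA_character_,
                              ifelse(traj$divider_type == 1, labels[1L], labels[2L]))
  nb <- res$bias_n
  keep <- which(nb > 0)
  bias <- data.frame(np_count = keep - 1L,
                     np_fraction = (keep - 1L) / L^2,
                     mean_bias = res$bias_sum[keep] / nb[keep],
                     n_obs = nb[keep])
  snaps <- res$snapshots
  attr(snaps, "meta") <- data.frame(time = res$snapshot_time,
                                    event_index = res$snapshot_event,
                                    np_fraction = res$snapshot_np_fraction)
  structure(list(
    winner = if (res$absorbed) labels[if (res$np_count == 0L) 1L else 2L] else NA_character_,
    fixation_time = res$time,
    event_count = res$event_count,
    absorbed = res$absorbed,
    final_grid = res$grid,
    trajectory = traj,
    bias = bias,
    snapshots = snaps,
    field = if (vcode > 0L) res$field else NULL,
    field_other = if (vcode == 2L) res$field_other else NULL,
    config = cfg, seed = cfg$seed, config_hash = config_hash(cfg)),
    class = "moran_sim")
}

#' Pure-R replacement loop for the saturating-uptake variant
#'
#' The nonlinear field has no superposition property, so the steady state is
#' re-solved after every replacement (warm-started fixed point). Intended
#' for small lattices.
#' @noRd
run_saturating_r <- function(cfg, grid) {
  L <- cfg$L
  labels <- variant_labels(cfg$growth$variant)
  time <- 0; events <- 0
  nbias <- rep(0, L^2 + 1); sbias <- rep(0, L^2 + 1)
  traj <- list()
  rec <- function(ev, t, npf, total, dt)
    list(event_index = ev, time = t, np_fraction = npf, total_rate = total,
         divider_type = dt)
  np <- sum(grid == 0L)
  absorbed <- np == 0L || np == L^2
  field <- NULL
  first <- TRUE
  while (!absorbed && events < cfg$max_events && time < cfg$t_max) {
    field <- steady_state_field_saturating(grid, cfg$resource)
    tab <- build_event_table(grid, cfg$growth, field, Ks = cfg$resource$Ks)
    if (first) { traj[[length(traj) + 1L]] <- rec(0, 0, np / L^2, tab$total_rate, NA); first <- FALSE }
    if (tab$total_rate <= 0) break
    sbias[np + 1L] <- sbias[np + 1L] +
      sum(tab$events$rate[tab$events$divider_type == 0L]) / tab$total_rate
    nbias[np + 1L] <- nbias[np + 1L] + 1
    st <- sample_step(tab)
    if (time + st$tau > cfg$t_max) { time <- cfg$t_max; break }
    time <- time + st$tau
    grid <- apply_event(grid, st$event)$grid
    np <- sum(grid == 0L)
    events <- events + 1
    absorbed <- np == 0L || np == L^2
    if (events %% cfg$record_stride == 0 || absorbed)
      traj[[length(traj) + 1L]] <- rec(events, time, np / L^2, tab$total_rate,
                                       if (st$event$divider_type == 1L) labels[1L] else labels[2L])
  }
  traj <- do.call(rbind, lapply(traj, as.data.frame))
  keep <- which(nbias > 0)
  structure(list(
    winner = if (absorbed) labels[if (np == 0L) 1L else 2L] else NA_character_,
    fixation_time = time, event_count = events, absorbed = absorbed,
    final_grid = grid, trajectory = traj,
    bias = data.frame(np_count = keep - 1L, np_fraction = (keep - 1L) / L^2,
                      mean_bias = sbias[keep] / nbias[keep], n_obs = nbias[keep]),
    snapshots = list(), field = field, field_other = NULL,
    config = cfg, seed = cfg$seed, config_hash = config_hash(cfg)),
    class = "moran_sim")
}

#' @exportS3Method base::print
print.moran_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Spatial Moran simulation (%s), %d x %d lattice\n",
              cfg$growth$variant, cfg$L, cfg$L))
  if (!is.null(cfg$resource))
    cat(sprintf("  lambda = %g, alpha = %g, kappa = %g, g0 = %g\n",
                cfg$resource$lambda, cfg$growth$alpha, cfg$growth$kappa,
                cfg$growth$g0))
  if (x$absorbed)
    cat(sprintf("  absorbed: %s fixed at t = %.4g after %s events\n",
                x$winner, x$fixation_time, format(x$event_count, big.mark = ",")))
  else
    cat(sprintf("  NOT absorbed (stopped at t = %.4g, %s events)\n",
                x$fixation_time, format(x$event_count, big.mark = ",")))
  invisible(x)
}

#' @exportS3Method base::summary
summary.moran_sim <- function(object, ...) {
  print(object)
  tr <- object$trajectory
  cat(sprintf("  final NP fraction: %.4f\n", tr$np_fraction[nrow(tr)]))
  cat(sprintf("  trajectory rows: %d; snapshots: %d\n",
              nrow(tr), length(object$snapshots)))
  if (nrow(object$bias) > 0)
    cat(sprintf("  mean selection bias over run: %.4f\n",
                stats::weighted.mean(object$bias$mean_bias, object$bias$n_obs)))
  invisible(object)
}

#' @exportS3Method base::plot
plot.moran_sim <- function(x, which = c("trajectory", "grid"), ...) {
  which <- match.arg(which)
  if (which == "trajectory") {
    tr <- x$trajectory
    graphics::plot(tr$time, tr$np_fraction, type = "l", ylim = c(0, 1),
                   xlab = "time (1/g0)", ylab = "NP fraction", ...)
    graphics::abline(h = c(0, 1), lty = 3, col = "grey")
  } else {
    graphics::image(t(x$final_grid)[, nrow(x$final_grid):1], axes = FALSE,
                    col = c("firebrick", "steelblue"), ...)
  }
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Columns `event_index`, `time`, `np_fraction`, `divider_type`.
#'
#' @param sim A `moran_sim`.
#' @param file Output path.
#' @export
write_trajectory <- function(sim, file) {
  utils::write.csv(sim$trajectory[, c("event_index", "time", "np_fraction",
                                      "divider_type")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export a fixation result as JSON
#'
#' Keys: `winner`, `fixation_time`, `event_count`, `absorbed`, `seed`,
#' `config_hash`.
#'
#' @param sim A `moran_sim`.
#' @param file Output path.
#' @export
write_fixation_json <- function(sim, file) {
  jsonlite::write_json(list(winner = sim$winner,
                            fixation_time = sim$fixation_time,
                            event_count = sim$event_count,
                            absorbed = sim$absorbed,
                            seed = if (is.null(sim$seed)) NA else sim$seed,
                            config_hash = sim$config_hash),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
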