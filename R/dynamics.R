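#' Growth-law parameters
#'
#' All cells share a basal growth rate `g0`; producers pay a production cost
#' `kappa` (so their basal rate is `g0 - kappa`), and resource access adds a
#' benefit `alpha * c` to the growth rate, with `c` the local steady-state
#' resource concentration. The cost may not exceed `g0`: producer growth
#' must stay non-negative even with no resource. The `neutral` variant
#' forces `kappa = 0` and `alpha = 0` (and no resource is produced), so all
#' replacement events are equally likely. The `mutualism` variant applies
#' the benefit from the *complementary* type's resource to both types
#' symmetrically. `competition_saturating` replaces the linear benefit
#' `alpha * c` with the Michaelis-Menten form `alpha * c * Ks / (Ks + c)`.
#'
#' @param variant One of `"competition"`, `"neutral"`, `"mutualism"`,
#'   `"competition_saturating"`.
#' @param g0 Basal growth rate (per unit time).
#' @param kappa Production cost (per unit time), in `[0, g0]`. Defaults to
#'   `g0` (the largest admissible cost) for the non-neutral variants.
#' @param alpha Benefit per unit resource concentration (per unit time per
#'   resource unit).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(variant = c("competition", "neutral", "mutualism",
                                      "competition_saturating"),
                          g0 = 1, kappa = NULL, alpha = 0) {
  variant <- match.arg(variant)
  if (g0 <= 0) stop("g0 must be > 0")
  if (variant == "neutral") {
    kappa <- 0; alpha <- 0
  } else if (is.null(kappa)) kappa <- g0
  if (kappa < 0 || kappa > g0) stop("kappa must lie in [0, g0]")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(variant = variant, g0 = g0, kappa = kappa, alpha = alpha),
            class = "growth_params")
}

#' Growth rate of a cell given local resource concentration
#'
#' Nonproducers grow at `g0 + alpha * c`; producers at
#' `g0 - kappa + alpha * c`. Vectorized over `type` and `c`.
#'
#' @param type Cell type(s): `"P"`/`"NP"` labels or 0/1 codes.
#' @param c Local resource concentration(s), `>= 0`.
#' @param params A [growth_params()].
#' @return Numeric growth rate(s), per unit time.
#' @export
growth_rate <- function(type, c, params) {
  if (any(c < 0)) stop("concentration must be >= 0")
  tc <- if (is.numeric(type)) as.integer(type) else type_code(type)
  params$g0 - params$kappa * (tc == 1L) + params$alpha * c
}

#' Growth rate in the mutualism model
#'
#' Both types obey the same law, `g0 - kappa + alpha * c_other`, where
#' `c_other` is the concentration of the resource produced by the
#' complementary cell type. The two types are equivalent but complementary.
#'
#' @param type Cell type label (ignored beyond validation; the law is
#'   symmetric).
#' @param c_other Concentration of the complementary type's resource.
#' @param params A [growth_params()].
#' @return Numeric growth rate(s).
#' @export
growth_rate_mutualism <- function(type, c_other, params) {
  if (any(c_other < 0)) stop("concentration must be >= 0")
  if (is.character(type)) type_code(type)
  params$g0 - params$kappa + params$alpha * c_other
}

#' Growth rate with saturating (Michaelis-Menten) resource uptake
#'
#' The linear benefit `alpha * c` is replaced by
#' `alpha * c * Ks / (Ks + c)`: it reverts to the linear law as
#' `Ks -> Inf` and saturates at `alpha * Ks` as `c -> Inf`.
#'
#' @inheritParams growth_rate
#' @param Ks Saturation constant (resource units), finite and `> 0`.
#' @return Numeric growth rate(s).
#' @export
growth_rate_saturating <- function(type, c, params, Ks) {
  if (any(c < 0)) stop("concentration must be >= 0")
  if (Ks <= 0) stop("Ks must be > 0")
  tc <- if (is.numeric(type)) as.integer(type) else type_code(type)
  benefit <- if (is.finite(Ks)) params$alpha * c * Ks / (Ks + c) else params$alpha * c
  params$g0 - params$kappa * (tc == 1L) + benefit
}

#' Build the table of admissible replacement events and their rates
#'
#' One event per directed cross-type adjacent pair; the rate of each event is
#' the dividing cell's growth rate divided by 4 (each cell can initiate up to
#' four events, so the factor normalizes the per-event rate to the per-cell
#' growth rate). Same-type replacements change nothing and are excluded from
#' both the event set and the clock.
#'
#' @param grid A cell grid.
#' @param growth A [growth_params()].
#' @param field Steady-state resource field aligned with `grid` (competition
#'   variants); for `mutualism`, a list with elements `A` and `B`, the fields
#'   produced by type-1 (A) and type-0 (B) cells respectively. Ignored for
#'   `neutral`.
#' @param Ks Saturation constant for `competition_saturating`.
#' @return An object of class `event_table`: a list with `events` (data frame
#'   of directed events and `rate`) and `total_rate`.
#' @export
build_event_table <- function(grid, growth, field = NULL, Ks = Inf) {
  ed <- cross_type_edges(grid)
  if (nrow(ed) == 0L) {
    ed$rate <- numeric(0)
    return(structure(list(events = ed, total_rate = 0), class = "event_table"))
  }
  L <- nrow(grid)
  di <- ed$divider_row + L * ed$divider_col + 1L
  cdiv <- switch(growth$variant,
    neutral = rep(0, nrow(ed)),
    competition = ,
    competition_saturating = {
      if (is.null(field)) stop("competition variants need the resource field")
      as.vector(field)[di]
    },
    mutualism = {
      if (!is.list(field) || is.null(field$A) || is.null(field$B))
        stop("mutualism needs both fields as list(A = , B = )")
      ifelse(ed$divider_type == 1L, as.vector(field$B)[di], as.vector(field$A)[di])
    })
  g <- switch(growth$variant,
    neutral = rep(growth$g0, nrow(ed)),
    competition = growth_rate(ed$divider_type, cdiv, growth),
    competition_saturating = growth_rate_saturating(ed$divider_type, cdiv, growth, Ks),
    mutualism = growth_rate_mutualism(ed$divider_type, cdiv, growth))
  ed$rate <- g / 4
  structure(list(events = ed, total_rate = sum(ed$rate)), class = "event_table")
}

#' Sample the next replacement event and its waiting time
#'
#' Exact Doob-Gillespie step: the waiting time is exponential with mean
#' `1 / total_rate`, and the event is chosen with probability proportional to
#' its rate. Draws from R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param table An [build_event_table()] result.
#' @return If the table is empty (uniform grid), `list(absorbed = TRUE)`.
#'   Otherwise `list(absorbed = FALSE, event = <one-row data frame>,`
#'   `index = <row>, tau = <waiting time>)`.
#' @export
sample_step <- function(table) {
  stopifnot(inherits(table, "event_table"))
  if (table$total_rate <= 0) return(list(absorbed = TRUE))
  tau <- stats::rexp(1L, rate = table$total_rate)
  u <- stats::runif(1L) * table$total_rate
  i <- findInterval(u, cumsum(table$events$rate), left.open = TRUE) + 1L
  i <- min(i, nrow(table$events))
  list(absorbed = FALSE, event = table$events[i, , drop = FALSE], index = i, tau = tau)
}

#' Apply a replacement event to a grid (and, optionally, its field)
#'
#' The target site adopts the divider's type. If `field` and `kernel` are
#' supplied, the steady-state field is updated by kernel superposition, which
#' reproduces a fresh solve on the new grid to numerical precision.
#'
#' @param grid A cell grid.
#' @param event A one-row data frame as produced by [build_event_table()]
#'   (or [sample_step()]).
#' @param field Optional resource field of the pre-event grid.
#' @param kernel Optional [single_source_kernel()] matching `field`.
#' @return A list with the updated `grid` (and `field` if supplied).
#' @export
apply_event <- function(grid, event, field = NULL, kernel = NULL) {
  tr <- event$target_row; tc <- event$target_col
  old <- grid[tr + 1L, tc + 1L]
  if (old == event$divider_type)
    stop("stale event: target already has the divider's type")
  grid[tr + 1L, tc + 1L] <- event$divider_type
  if (!is.null(field)) {
    if (is.null(kernel)) stop("field update requires the kernel")
    field <- update_field_incremental(field, c(tr, tc),
                                      if (event$divider_type == 1L) 1 else -1, kernel)
    return(list(grid = grid, field = field))
  }
  list(grid = grid)
}
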