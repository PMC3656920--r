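# Brute-force oracles, deliberately written with plain loops and independent
# of the package's vectorized / compiled code paths.

random_grid <- function(L, f = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(as.integer(runif(L * L) < f), L, L)
}

checkerboard_grid <- function(L) {
  outer(0:(L - 1L), 0:(L - 1L), function(r, c) as.integer((r + c) %% 2L))
}

naive_boundary_sites <- function(grid) {
  L <- nrow(grid)
  out <- NULL
  for (r in 0:(L - 1L)) for (co in 0:(L - 1L)) {
    t <- grid[r + 1L, co + 1L]
    nb <- c(grid[(r + 1L) %% L + 1L, co + 1L], grid[(r - 1L) %% L + 1L, co + 1L],
            grid[r + 1L, (co + 1L) %% L + 1L], grid[r + 1L, (co - 1L) %% L + 1L])
    if (any(nb != t)) out <- rbind(out, c(r, co))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

naive_cross_edges <- function(grid) {
  L <- nrow(grid)
  out <- NULL
  for (r in 0:(L - 1L)) for (co in 0:(L - 1L)) {
    t <- grid[r + 1L, co + 1L]
    for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nr <- (r + s[1L]) %% L; nc <- (co + s[2L]) %% L
      if (grid[nr + 1L, nc + 1L] != t)
        out <- rbind(out, c(r, co, nr, nc, t))
    }
  }
  out
}

# Dense base-R solve of the screened-diffusion steady state (tiny L only);
# a third route, independent of both the FFT and the Matrix sparse solver.
dense_field_solve <- function(grid, params) {
  L <- nrow(grid)
  n <- L * L
  A <- matrix(0, n, n)
  for (r in 0:(L - 1L)) for (co in 0:(L - 1L)) {
    i <- r + L * co + 1L
    A[i, i] <- params$gamma + 4 * params$D
    for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      j <- (r + s[1L]) %% L + L * ((co + s[2L]) %% L) + 1L
      A[i, j] <- A[i, j] - params$D
    }
  }
  matrix(solve(A, params$p * as.numeric(grid)), L, L)
}

# Event table recomputed from scratch with scalar growth-rate evaluations.
naive_event_table_total <- function(grid, growth, field) {
  ed <- naive_cross_edges(grid)
  total <- 0; np_to_p <- 0
  for (i in seq_len(nrow(ed))) {
    t <- ed[i, 5L]
    cc <- field[ed[i, 1L] + 1L, ed[i, 2L] + 1L]
    g <- growth$g0 - growth$kappa * (t == 1L) + growth$alpha * cc
    total <- total + g / 4
    if (t == 0L) np_to_p <- np_to_p + g / 4
  }
  list(total = total, np_to_p = np_to_p)
}

rotate90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

shift_grid <- function(m, dr, dc) {
  L <- nrow(m)
  m[(seq_len(L) - 1L - dr) %% L + 1L, (seq_len(L) - 1L - dc) %% L + 1L]
}
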