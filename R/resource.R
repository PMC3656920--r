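#' Resource-field parameters
#'
#' The diffusible resource is produced at flux `p` by each producer, diffuses
#' with constant `D` and undergoes first-order decay/consumption at rate
#' `gamma`. Because cell division is far slower than diffusion, the field is
#' always taken at its steady state, and `D` and `gamma` enter only through
#' the diffusion length `lambda = sqrt(D / gamma)` (in cell lengths): with
#' `gamma = 1`, `D = lambda^2`. A finite saturation constant `Ks` switches on
#' the Michaelis-Menten (saturating-uptake) variant; `Ks = Inf` is the linear
#' model.
#'
#' @param lambda Diffusion length in cell lengths (`> 0`).
#' @param p Production flux per producer cell (resource units per unit time).
#' @param gamma Decay/consumption rate (per unit time).
#' @param Ks Saturation constant (resource units); `Inf` for the linear model.
#' @return An object of class `resource_params` with fields `p`, `D`,
#'   `gamma`, `lambda`, `Ks`.
#' @export
resource_params <- function(lambda, p = 1, gamma = 1, Ks = Inf) {
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (p <= 0 || gamma <= 0 || Ks <= 0) stop("p, gamma and Ks must be > 0")
  structure(list(p = p, D = gamma * lambda^2, gamma = gamma,
                 lambda = lambda, Ks = Ks),
            class = "resource_params")
}

#' Eigenvalues of the negative discrete Laplacian on the L x L torus
#' @noRd
laplacian_eigenvalues <- function(L) {
  w <- 2 - 2 * cos(2 * pi * (0:(L - 1)) / L)
  outer(w, w, `+`)
}

#' Apply the 5-point discrete Laplacian with periodic wrap
#' @noRd
discrete_laplacian <- function(m) {
  up    <- rbind(m[-1L, , drop = FALSE], m[1L, , drop = FALSE])
  down  <- rbind(m[nrow(m), , drop = FALSE], m[-nrow(m), , drop = FALSE])
  left  <- cbind(m[, ncol(m), drop = FALSE], m[, -ncol(m), drop = FALSE])
  right <- cbind(m[, -1L, drop = FALSE], m[, 1L, drop = FALSE])
  up + down + left + right - 4 * m
}

#' Fourier multiplier of the screened-diffusion operator, p/(gamma + D mu)
#' @noRd
screened_multiplier <- function(L, params) {
  params$p / (params$gamma + params$D * laplacian_eigenvalues(L))
}

#' Steady-state resource field of a single producer at the origin
#'
#' Solves `p * delta_origin + D * Lap(c) - gamma * c = 0` exactly on the
#' `L x L` torus by diagonalizing the screened-diffusion operator in Fourier
#' space (linear model only). The field is maximal at the origin (matrix
#' element `[1, 1]`, site `(0, 0)`), decays with minimal-image distance with
#' characteristic length about `lambda`, and sums to `p / gamma` (flux
#' balance). The full field of any producer configuration is the
#' superposition of translates of this kernel.
#'
#' @param L Linear lattice size.
#' @param params A [resource_params()] with `Ks = Inf`.
#' @return An `L x L` numeric matrix of concentrations.
#' @export
single_source_kernel <- function(L, params) {
  stopifnot(inherits(params, "resource_params"))
  if (is.finite(params$Ks)) stop("single_source_kernel applies to the linear model (Ks = Inf)")
  khat <- screened_multiplier(L, params)
  Re(stats::fft(khat, inverse = TRUE)) / (L * L)
}

#' Steady-state resource field for a producer configuration (linear model)
#'
#' Exact superposition of single-source kernels over all producer sites,
#' computed as one circular convolution in Fourier space. Agrees with a
#' direct sparse solve of the full linear system to numerical precision
#' (see [steady_state_field_direct()]).
#'
#' @param grid A cell grid (1 = producer).
#' @param params A [resource_params()] with `Ks = Inf`.
#' @return An `L x L` numeric matrix of concentrations, aligned with `grid`.
#' @export
steady_state_field <- function(grid, params) {
  stopifnot(inherits(params, "resource_params"))
  if (is.finite(params$Ks)) stop("use steady_state_field_saturating for finite Ks")
  L <- nrow(grid)
  khat <- screened_multiplier(L, params)
  src <- matrix(as.numeric(grid), L, L)
  f <- Re(stats::fft(stats::fft(src) * khat, inverse = TRUE)) / (L * L)
  pmax(f, 0)
}

#' Steady-state resource field by direct sparse linear solve
#'
#' Independent route to the same steady state as [steady_state_field()]:
#' assembles the `L^2 x L^2` operator `gamma I - D Lap` as a sparse matrix
#' and solves it with \pkg{Matrix}. Used for cross-checking the spectral
#' solver; `O(L^4)`-ish, so intended for moderate `L`.
#'
#' @inheritParams steady_state_field
#' @return An `L x L` numeric matrix of concentrations.
#' @export
steady_state_field_direct <- function(grid, params) {
  stopifnot(inherits(params, "resource_params"))
  L <- nrow(grid)
  A <- screened_operator(L, params$D, rep(params$gamma, L * L))
  b <- params$p * as.numeric(grid)
  matrix(as.numeric(Matrix::solve(A, b)), L, L)
}

#' Sparse matrix of gamma_diag - D * Lap on the L x L torus (column-major)
#' @noRd
screened_operator <- function(L, D, gamma_diag) {
  n <- L * L
  idx <- seq_len(n) - 1L
  r <- idx %% L
  co <- idx %/% L
  nbr <- function(dr, dc) ((r + dr) %% L) + L * ((co + dc) %% L) + 1L
  i <- rep.int(seq_len(n), 5L)
  j <- c(seq_len(n), nbr(-1L, 0L), nbr(1L, 0L), nbr(0L, -1L), nbr(0L, 1L))
  x <- c(gamma_diag + 4 * D, rep.int(-D, 4L * n))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

#' Update a steady-state field after a single cell-type flip
#'
#' By linearity, flipping one site between producer and nonproducer adds or
#' subtracts one translated single-source kernel. The result is identical
#' (to numerical precision) to a fresh solve on the post-flip grid.
#'
#' @param field Steady-state field of the pre-flip grid.
#' @param site Length-2 integer `(row, col)`, 0-based, of the flipped cell.
#' @param flip `+1` if the site became a producer, `-1` if it stopped
#'   producing.
#' @param kernel The [single_source_kernel()] for the same `L` and parameters.
#' @return The updated `L x L` field.
#' @export
update_field_incremental <- function(field, site, flip, kernel) {
  L <- nrow(field)
  stopifnot(flip %in% c(-1, 1), length(site) == 2L)
  ri <- ((seq_len(L) - 1L - site[1L]) %% L) + 1L
  ci <- ((seq_len(L) - 1L - site[2L]) %% L) + 1L
  field + flip * kernel[ri, ci]
}

#' Steady-state field with saturating (Michaelis-Menten) uptake
#'
#' Solves the self-consistent nonlinear steady state
#' `p * 1_producer + D * Lap(c) - gamma * c * Ks / (Ks + c) = 0`
#' by damped Picard iteration: the consumption term is linearized at the
#' current iterate as an effective local rate `gamma * Ks / (Ks + c)`, the
#' resulting linear (spatially varying) screened problem is solved exactly
#' with a sparse factorization, and successive iterates are mixed with a
#' damping factor. As `Ks -> Inf` the equation and the solution revert to
#' the linear model; at small `Ks` uptake saturates near producers and the
#' field becomes more homogeneous than the linear one.
#'
#' @param grid A cell grid (1 = producer).
#' @param params A [resource_params()] with finite `Ks > 0`.
#' @param tol Convergence tolerance on the max-norm residual of the steady
#'   state equation.
#' @param max_iter Maximum fixed-point iterations.
#' @param damping Mixing weight in `(0, 1]` for the new iterate.
#' @return An `L x L` numeric matrix of concentrations.
#' @section Existence:
#' Saturating consumption is bounded by `gamma * Ks` per site, so a steady
#' state exists only while total production stays below total capacity,
#' `p * n_producers < gamma * Ks * L^2`; otherwise the resource grows
#' without bound and the solver stops with an error.
#' @export
steady_state_field_saturating <- function(grid, params, tol = 1e-10,
                                          max_iter = 10000L, damping = 0.5) {
  stopifnot(inherits(params, "resource_params"))
  if (!is.finite(params$Ks)) return(steady_state_field(grid, params))
  L <- nrow(grid)
  if (params$p * sum(grid == 1L) >= params$gamma * params$Ks * L * L)
    stop("no steady state: production p * n_producers = ",
         params$p * sum(grid == 1L), " reaches the saturated consumption ",
         "capacity gamma * Ks * L^2 = ", params$gamma * params$Ks * L * L)
  src <- params$p * as.numeric(grid)
  lin <- params; lin$Ks <- Inf
  cc <- as.vector(steady_state_field(grid, lin))  # linear warm start
  Ks <- params$Ks
  for (it in seq_len(max_iter)) {
    geff <- params$gamma * Ks / (Ks + cc)
    A <- screened_operator(L, params$D, geff)
    cnew <- pmax((1 - damping) * cc + damping * as.numeric(Matrix::solve(A, src)), 0)
    cm <- matrix(cnew, L, L)
    resid <- max(abs(matrix(src, L, L) + params$D * discrete_laplacian(cm) -
                     params$gamma * cm * Ks / (Ks + cm)))
    cc <- cnew
    if (resid < tol) return(cm)
  }
  stop(sprintf("saturating solver did not converge in %d iterations (residual %.3e)",
               max_iter, resid))
}

#' Dump a resource field as plain text
#'
#' Row-major `L x L` matrix of concentrations at full double precision, for
#' debugging and cross-implementation checks.
#'
#' @param field An `L x L` numeric matrix.
#' @param file Output path.
#' @export
write_field <- function(field, file) {
  utils::write.table(format(field, digits = 17, scientific = TRUE),
                     file, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}
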