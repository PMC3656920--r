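#' Cell grids
#'
#' A cell grid is an `L x L` integer matrix on a torus (periodic wrap in both
#' axes). Every site holds exactly one cell; there are no vacancies. Entries
#' are coded `1` for the producer type (P, or type A in the mutualism model)
#' and `0` for the nonproducer type (NP, or type B). The neighborhood is the
#' four cardinal neighbors (von Neumann), with periodic wrap.
#'
#' @name cell_grid
#' @keywords internal
NULL

#' Map character cell-type labels to the internal 0/1 coding
#' @noRd
type_code <- function(label) {
  lab <- toupper(as.character(label))
  out <- ifelse(lab %in% c("P", "A", "1"), 1L,
         ifelse(lab %in% c("NP", "B", "0"), 0L, NA_integer_))
  if (anyNA(out)) stop("unknown cell-type label: ", paste(lab[is.na(out)], collapse = ", "))
  out
}

#' Construct a lattice initial condition
#'
#' @param kind One of `"mixed_50_50"` (equal numbers of the two types placed
#'   uniformly at random), `"segregated_halves"` (two vertical blocks of
#'   `L x L/2` columns), or `"single_invader"` (one cell of `invader_type` in
#'   a sea of the other type).
#' @param invader_type Cell-type label for the invader (`"P"`/`"NP"` or
#'   `"A"`/`"B"`), used only by `"single_invader"`.
#' @param seed Integer RNG seed; placement is deterministic given the seed.
#' @return An object of class `initial_condition`.
#' @export
initial_condition <- function(kind = c("mixed_50_50", "segregated_halves", "single_invader"),
                              invader_type = "NP", seed = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, invader_type = invader_type, seed = seed),
            class = "initial_condition")
}

#' Build a cell grid from an initial condition
#'
#' On a grid of odd `L` (so `L^2` odd), `mixed_50_50` places
#' `floor(L^2 / 2)` producers; the extra cell goes to the nonproducer type.
#'
#' @param L Linear lattice size (integer, `>= 2`; even for
#'   `segregated_halves`).
#' @param init An [initial_condition()], or a string naming the kind (then
#'   `invader_type` and `seed` are taken from the extra arguments).
#' @param invader_type,seed Used when `init` is given as a string.
#' @return An `L x L` integer cell grid (see [cell_grid]).
#' @examples
#' g <- make_grid(8, initial_condition("mixed_50_50", seed = 1))
#' table(g)
#' @export
make_grid <- function(L, init = "mixed_50_50", invader_type = "NP", seed = NULL) {
  if (is.character(init)) init <- initial_condition(init, invader_type, seed)
  if (!inherits(init, "initial_condition")) stop("`init` must be an initial_condition")
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("L must be an integer >= 2")
  n <- L * L
  g <- matrix(0L, L, L)
  switch(init$kind,
    mixed_50_50 = {
      if (!is.null(init$seed)) set.seed(init$seed)
      idx <- sample.int(n, n %/% 2L)  # producers get floor(L^2/2) sites
      g[idx] <- 1L
    },
    segregated_halves = {
      if (L %% 2L != 0L) stop("segregated_halves requires even L")
      g[, seq_len(L %/% 2L)] <- 1L
    },
    single_invader = {
      inv <- type_code(init$invader_type)
      g[] <- 1L - inv
      if (!is.null(init$seed)) set.seed(init$seed)
      at <- if (is.null(init$seed)) 1L else sample.int(n, 1L)
      g[at] <- inv
    })
  g
}

#' Sites with at least one cardinal neighbor of differing type
#'
#' Only these "boundary" cells can divide: replacement of a cell by a same-type
#' daughter leaves the configuration unchanged, so all dynamics act at the
#' interface between the two types.
#'
#' @param grid A cell grid.
#' @return A two-column integer matrix of 0-based `(row, col)` coordinates,
#'   one row per boundary site (zero rows if the grid is uniform).
#' @export
boundary_sites <- function(grid) {
  d <- differing_neighbor_count(grid)
  idx <- which(d > 0L, arr.ind = TRUE)
  m <- cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Number of differing cardinal neighbors for every site
#' @noRd
differing_neighbor_count <- function(grid) {
  up    <- rbind(grid[-1L, , drop = FALSE], grid[1L, , drop = FALSE])
  down  <- rbind(grid[nrow(grid), , drop = FALSE], grid[-nrow(grid), , drop = FALSE])
  left  <- cbind(grid[, ncol(grid), drop = FALSE], grid[, -ncol(grid), drop = FALSE])
  right <- cbind(grid[, -1L, drop = FALSE], grid[, 1L, drop = FALSE])
  (grid != up) + (grid != down) + (grid != left) + (grid != right)
}

#' Directed replacement events admissible on a grid
#'
#' Every unordered pair of cardinally adjacent, differently typed sites yields
#' two directed events: each side can divide and replace the other with a
#' daughter of its own type.
#'
#' @param grid A cell grid.
#' @return A data frame with 0-based integer columns `divider_row`,
#'   `divider_col`, `target_row`, `target_col`, plus `divider_type` (0/1).
#' @export
cross_type_edges <- function(grid) {
  L <- nrow(grid)
  idx <- which(matrix(TRUE, L, L), arr.ind = TRUE)
  r <- idx[, 1L] - 1L; co <- idx[, 2L] - 1L
  t0 <- as.vector(grid)
  out <- vector("list", 4L)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (k in seq_along(shifts)) {
    nr <- (r + shifts[[k]][1L]) %% L
    nc <- (co + shifts[[k]][2L]) %% L
    tn <- t0[nr + L * nc + 1L]
    keep <- tn != t0
    out[[k]] <- data.frame(divider_row = r[keep], divider_col = co[keep],
                           target_row = nr[keep], target_col = nc[keep],
                           divider_type = t0[keep])
  }
  res <- do.call(rbind, out)
  res <- res[order(res$divider_row, res$divider_col, res$target_row, res$target_col), ]
  rownames(res) <- NULL
  res
}

#' Minimal-image Euclidean distance on the torus
#'
#' Coordinate differences are reduced to `[-L/2, L/2]` before applying the
#' Euclidean norm, in units of cell lengths.
#'
#' @param a,b Sites as length-2 integer vectors `(row, col)`, 0-based, or
#'   two-column matrices of sites.
#' @param L Linear lattice size.
#' @return Numeric distance(s).
#' @export
minimal_image_distance <- function(a, b, L) {
  a <- rbind(a); b <- rbind(b)
  d <- (a - b[rep_len(seq_len(nrow(b)), nrow(a)), , drop = FALSE]) %% L
  d <- abs(ifelse(d > L / 2, d - L, d))
  unname(sqrt(rowSums(d^2)))
}

#' Read and write plain-text grid snapshots
#'
#' Snapshots are one lattice row per line, space-separated integers,
#' `1` = producer (type A), `0` = nonproducer (type B).
#'
#' @param grid A cell grid.
#' @param file Path to a text file.
#' @return `write_snapshot` returns `file` invisibly; `read_snapshot` returns
#'   an integer cell grid.
#' @export
write_snapshot <- function(grid, file) {
  write.table(grid, file, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(file) {
  g <- as.matrix(read.table(file, header = FALSE))
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  if (nrow(g) != ncol(g)) stop("snapshot is not square")
  if (!all(g %in% c(0L, 1L))) stop("snapshot entries must be 0 or 1")
  g
}
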