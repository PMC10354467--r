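#' Uniform cell-centred finite-volume grid
#'
#' Two grid modes are supported: `"cartesian2d"`, an `nx` by `ny` grid of
#' square cells of side `h`, and `"radial1d"`, `nr` annular cells of radial
#' width `h` for radially symmetric problems (the first cell centre sits at
#' `h/2`; there is no node at `r = 0`).
#'
#' @param mode `"cartesian2d"` or `"radial1d"`.
#' @param h Grid spacing (mm), `> 0`.
#' @param nx,ny Cell counts (cartesian mode). `ny = 1` gives a planar 1D grid.
#' @param nr Cell count (radial mode).
#' @param origin Physical coordinate (mm) of the centre of cell (1, 1)
#'   (cartesian only). Defaults to `c(h/2, h/2)` so the domain corner is at
#'   the coordinate origin.
#' @return An object of class `fv_grid`.
#' @export
fv_grid <- function(mode = c("cartesian2d", "radial1d"), h,
                    nx = NULL, ny = NULL, nr = NULL, origin = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(h), length(h) == 1, is.finite(h), h > 0)
  if (mode == "cartesian2d") {
    stopifnot(!is.null(nx), !is.null(ny))
    nx <- as.integer(nx); ny <- as.integer(ny)
    stopifnot(nx >= 1, ny >= 1)
    if (is.null(origin)) origin <- c(h / 2, h / 2)
    stopifnot(length(origin) == 2)
    g <- list(mode = mode, h = h, nx = nx, ny = ny, origin = as.numeric(origin))
  } else {
    stopifnot(!is.null(nr))
    nr <- as.integer(nr)
    stopifnot(nr >= 1)
    g <- list(mode = mode, h = h, nx = nr, ny = 1L, origin = h / 2)
  }
  structure(g, class = "fv_grid")
}

#' @rdname fv_grid
#' @param domain_radius Radial domain size (mm); `nr = round(domain_radius/h)`.
#' @export
fv_grid_radial <- function(h, domain_radius) {
  fv_grid("radial1d", h = h, nr = round(domain_radius / h))
}

#' @export
print.fv_grid <- function(x, ...) {
  if (x$mode == "cartesian2d")
    cat(sprintf("<fv_grid> cartesian2d %d x %d cells, h = %g mm\n", x$nx, x$ny, x$h))
  else
    cat(sprintf("<fv_grid> radial1d %d cells, h = %g mm, extent %g mm\n",
                x$nx, x$h, x$nx * x$h))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid An [fv_grid()].
#' @return For cartesian grids a list with vectors `x` and `y` (mm); for
#'   radial grids a list with vector `r` (mm).
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "fv_grid"))
  if (grid$mode == "cartesian2d")
    list(x = grid$origin[1] + grid$h * (seq_len(grid$nx) - 1),
         y = grid$origin[2] + grid$h * (seq_len(grid$ny) - 1))
  else
    list(r = grid$h * (seq_len(grid$nx) - 0.5))
}

#' Cell volumes (areas) of a grid
#'
#' Cartesian cells have area `h^2`; radial cells are annuli of area
#' `2 pi r_c h`, so that summing `density * cell_volumes` gives the mass of
#' the corresponding radially symmetric 2D field.
#'
#' @param grid An [fv_grid()].
#' @return Numeric vector of cell areas (mm^2), in cell storage order.
#' @export
cell_volumes <- function(grid) {
  stopifnot(inherits(grid, "fv_grid"))
  if (grid$mode == "cartesian2d") rep(grid$h^2, grid$nx * grid$ny)
  else 2 * pi * grid_coords(grid)$r * grid$h
}

#' Multi-species density state on a grid
#'
#' A snapshot of one or more cell-density fields sharing a grid and a time
#' stamp. Densities are stored as an array with dimensions
#' `c(nx, ny, n_species)` (radial grids have `ny = 1`).
#'
#' @param grid An [fv_grid()].
#' @param rho Density values (cells mm^-2): an array `c(nx, ny, ns)`, a
#'   matrix (single species), or a vector (single species; recycled scalars
#'   allowed). Must be non-negative and finite.
#' @param time Time stamp (h).
#' @return An object of class `tissue_state`.
#' @export
tissue_state <- function(grid, rho, time = 0) {
  stopifnot(inherits(grid, "fv_grid"))
  ncell <- grid$nx * grid$ny
  if (is.null(dim(rho))) {
    if (length(rho) == 1) rho <- rep(rho, ncell)
    stopifnot(length(rho) == ncell)
    rho <- array(rho, dim = c(grid$nx, grid$ny, 1))
  } else if (length(dim(rho)) == 2) {
    stopifnot(nrow(rho) == grid$nx, ncol(rho) == grid$ny)
    rho <- array(rho, dim = c(grid$nx, grid$ny, 1))
  } else {
    stopifnot(length(dim(rho)) == 3, dim(rho)[1] == grid$nx, dim(rho)[2] == grid$ny)
  }
  if (any(!is.finite(rho))) stop("densities must be finite")
  if (any(rho < 0)) stop("densities must be >= 0")
  structure(list(grid = grid, rho = rho, time = as.numeric(time)),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("<tissue_state> t = %g h, %d species, mass = %s cells\n",
              x$time, n_species(x),
              paste(signif(state_mass(x), 6), collapse = " / ")))
  print(x$grid)
  invisible(x)
}

#' Number of species in a state
#' @param state A [tissue_state()].
#' @export
n_species <- function(state) dim(state$rho)[3]

#' Per-species total cell number
#'
#' @param state A [tissue_state()].
#' @return Numeric vector: \eqn{\sum_i \rho_i V_i} per species (cells).
#' @export
state_mass <- function(state) {
  stopifnot(inherits(state, "tissue_state"))
  vol <- cell_volumes(state$grid)
  vapply(seq_len(n_species(state)),
         function(s) sum(state$rho[, , s] * vol), numeric(1))
}

#' Total (summed over species) density field of a state
#' @param state A [tissue_state()].
#' @return Matrix `nx` by `ny` (cells mm^-2).
#' @export
total_density <- function(state) {
  stopifnot(inherits(state, "tissue_state"))
  m <- state$rho[, , 1]
  ns <- n_species(state)
  if (ns > 1) for (s in 2:ns) m <- m + state$rho[, , s]
  matrix(m, nrow = state$grid$nx)
}
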