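#' Tissue shape specification
#'
#' Describes one initially seeded tissue: a circle or an axis-aligned
#' rectangle with uniform cell density, assigned to a species (tissue
#' label). Species indices start at 0 and must be contiguous across a spec
#' list.
#'
#' @param shape `"circle"` or `"rectangle"`.
#' @param center Centre coordinate (mm), length 2.
#' @param size Radius (mm) for circles; `c(width, height)` (mm) for
#'   rectangles.
#' @param density Seeding density (cells mm^-2), `>= 0`.
#' @param species Species index, integer `>= 0`.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(shape = c("circle", "rectangle"), center, size,
                        density, species = 0L) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2, all(is.finite(center)),
            is.numeric(density), length(density) == 1, density >= 0,
            species >= 0)
  if (shape == "circle") {
    stopifnot(length(size) == 1, size > 0)
  } else {
    stopifnot(length(size) == 2, all(size > 0))
  }
  structure(list(shape = shape, center = as.numeric(center),
                 size = as.numeric(size), density = density,
                 species = as.integer(species)),
            class = "tissue_spec")
}

spec_bbox <- function(sp) {
  if (sp$shape == "circle")
    c(sp$center[1] - sp$size, sp$center[1] + sp$size,
      sp$center[2] - sp$size, sp$center[2] + sp$size)
  else
    c(sp$center[1] - sp$size[1] / 2, sp$center[1] + sp$size[1] / 2,
      sp$center[2] - sp$size[2] / 2, sp$center[2] + sp$size[2] / 2)
}

spec_inside <- function(sp, X, Y) {
  if (sp$shape == "circle")
    (X - sp$center[1])^2 + (Y - sp$center[2])^2 <= sp$size^2
  else
    abs(X - sp$center[1]) <= sp$size[1] / 2 &
    abs(Y - sp$center[2]) <= sp$size[2] / 2
}

# mean over ss x ss sample blocks: m is (nx*ss) x (ny*ss)
block_mean <- function(m, nx, ny, ss) {
  a <- array(m, dim = c(ss, nx, ss * ny))
  a <- colSums(a) / ss                       # nx x (ss*ny)
  a <- array(t(a), dim = c(ss, ny, nx))
  t(colSums(a) / ss)                         # nx x ny
}

#' Rasterise tissue specs onto a grid
#'
#' Builds the initial multi-species state: each grid cell receives the
#' density of the covering shape, area-weighted at shape edges by `ss` x
#' `ss` subcell supersampling (default 4, giving sub-1% mass accuracy at
#' typical spacings). Same-species shapes may touch or abut; shapes of
#' different species must not overlap (initially segregated tissues) and
#' all shapes must lie inside the grid.
#'
#' On radial grids only circles centred at the origin are representable;
#' their annulus coverage is computed exactly.
#'
#' @param specs List of [tissue_spec()] objects (possibly empty).
#' @param grid An [fv_grid()].
#' @param time Time stamp for the returned state (h).
#' @param ss Supersampling factor per axis.
#' @return A [tissue_state()] with `max(species) + 1` species (at least 1).
#' @export
build_state <- function(specs, grid, time = 0, ss = 4L) {
  stopifnot(inherits(grid, "fv_grid"), is.list(specs))
  if (inherits(specs, "tissue_spec")) specs <- list(specs)
  ns <- if (length(specs) == 0) 1L else max(vapply(specs, `[[`, 0L, "species")) + 1L
  if (length(specs) > 0) {
    sp_ids <- sort(unique(vapply(specs, `[[`, 0L, "species")))
    if (!identical(sp_ids, seq(0L, ns - 1L)))
      stop("species indices must be contiguous from 0")
  }

  if (grid$mode == "radial1d") {
    rho <- array(0, dim = c(grid$nx, 1, ns))
    r_in <- grid$h * (seq_len(grid$nx) - 1)
    r_out <- grid$h * seq_len(grid$nx)
    for (sp in specs) {
      if (sp$shape != "circle" || any(abs(sp$center) > 1e-12))
        stop("radial grids support only circles centred at the origin")
      if (sp$size > grid$nx * grid$h) stop("shape extends outside the domain")
      cov <- pmin(pmax((sp$size^2 - r_in^2) / (r_out^2 - r_in^2), 0), 1)
      rho[, 1, sp$species + 1] <- rho[, 1, sp$species + 1] + sp$density * cov
    }
    return(tissue_state(grid, rho, time))
  }

  ss <- as.integer(ss)
  co <- grid_coords(grid)
  xmin <- co$x[1] - grid$h / 2; xmax <- co$x[grid$nx] + grid$h / 2
  ymin <- co$y[1] - grid$h / 2; ymax <- co$y[grid$ny] + grid$h / 2
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * grid$h
  xs <- rep(co$x, each = ss) + off      # sample x coords, length nx*ss
  ys <- rep(co$y, each = ss) + off
  X <- matrix(xs, nrow = grid$nx * ss, ncol = grid$ny * ss)
  Y <- matrix(ys, nrow = grid$nx * ss, ncol = grid$ny * ss, byrow = TRUE)

  occ <- matrix(0L, nrow = grid$nx * ss, ncol = grid$ny * ss)
  rho <- array(0, dim = c(grid$nx, grid$ny, ns))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    bb <- spec_bbox(sp)
    if (bb[1] < xmin - 1e-12 || bb[2] > xmax + 1e-12 ||
        bb[3] < ymin - 1e-12 || bb[4] > ymax + 1e-12)
      stop(sprintf("shape %d extends outside the domain", k))
    inside <- spec_inside(sp, X, Y)
    clash <- inside & occ != 0L & occ != sp$species + 1L
    if (any(clash))
      stop(sprintf("shape %d (species %d) overlaps a shape of another species",
                   k, sp$species))
    occ[inside] <- sp$species + 1L
    cov <- block_mean(inside + 0, grid$nx, grid$ny, ss)
    rho[, , sp$species + 1] <- rho[, , sp$species + 1] + sp$density * cov
  }
  tissue_state(grid, rho, time)
}

#' Circular tissues on a hexagonal lattice
#'
#' Places `n` equal circles at the `n` triangular-lattice sites closest to
#' the origin (nearest-centre distance equal to `pitch`), with species
#' labels alternating 0/1 in placement order, emulating the two-colour
#' layout of multi-tissue collision experiments.
#'
#' @param n Number of circles.
#' @param radius Circle radius (mm).
#' @param pitch Lattice constant (mm); must exceed `2 * radius` so the
#'   tissues start separated.
#' @param density Seeding density (cells mm^-2).
#' @return A list of [tissue_spec()] objects.
#' @export
hex_circle_array <- function(n, radius, pitch, density) {
  stopifnot(n >= 1, radius > 0, density >= 0)
  if (pitch <= 2 * radius) stop("pitch must exceed 2 * radius (tissues must start apart)")
  jj <- -6:6
  pts <- do.call(rbind, lapply(jj, function(j)
    cbind(x = ((-6:6) + (j %% 2) / 2) * pitch, y = j * pitch * sqrt(3) / 2)))
  d <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  ang <- atan2(pts[, 2], pts[, 1])
  ord <- order(round(d / pitch, 9), ang)
  pts <- pts[ord[seq_len(n)], , drop = FALSE]
  lapply(seq_len(n), function(k)
    tissue_spec("circle", center = pts[k, ], size = radius,
                density = density, species = (k - 1L) %% 2L))
}
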