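#' Model parameters for continuum tissue growth
#'
#' Bundles the parameters of the Fisher-KPP (`family = "linear"`) and
#' Porous-Fisher (`family = "porous"`) reaction-diffusion models of an
#' expanding epithelial monolayer,
#' \deqn{\partial_t \rho = \nabla\cdot(D(\rho)\nabla\rho) + r\rho(1 - \rho/K),}
#' where the linear model has constant diffusivity \eqn{D(\rho) = D} and the
#' porous model has the degenerate, pressure-driven diffusivity
#' \eqn{D(\rho) = D\rho^{m-1}} arising from Darcy's law with the power-law
#' pressure \eqn{P(\rho) = D\rho^{m-1}}.
#'
#' Internally the package works in mm, hours and cells mm^-2; `D` is supplied
#' in the conventional experimental units and converted on input.
#'
#' @param family `"linear"` (Fisher-KPP) or `"porous"` (Porous-Fisher).
#' @param D Diffusion constant. Linear family: \eqn{\mu m^2 h^{-1}}. Porous
#'   family: \eqn{\mu m^2 (cells\, h)^{-1}}, i.e. the diffusivity at density
#'   \eqn{\rho} (cells mm^-2) is \eqn{D\rho\ \mu m^2 h^{-1}} when `m = 2`.
#' @param r Proliferation rate (h^-1), `r >= 0`.
#' @param K Carrying capacity (cells mm^-2).
#' @param m Pressure exponent (dimensionless, porous family only; must be
#'   `> 1`). Default 2, the volume-exclusion case.
#' @return An object of class `model_params` with the user-facing values and
#'   the internal-unit diffusion constant `D_int` (mm^2 h^-1, per cells mm^-2
#'   raised to `m - 1` for the porous family).
#' @examples
#' model_params("porous", D = 1.18, r = 0.214, K = 5319)
#' @export
model_params <- function(family = c("linear", "porous"), D, r, K, m = 2) {
  family <- match.arg(family)
  stopifnot(is.numeric(D), length(D) == 1, is.finite(D),
            is.numeric(r), length(r) == 1, is.finite(r),
            is.numeric(K), length(K) == 1, is.finite(K),
            is.numeric(m), length(m) == 1, is.finite(m))
  if (D <= 0) stop("D must be > 0")
  if (r < 0) stop("r must be >= 0")
  if (K <= 0) stop("K must be > 0")
  if (family == "porous" && m <= 1) stop("pressure exponent m must be > 1 for the porous family")
  if (family == "linear") m <- 1
  structure(list(family = family, D = D, r = r, K = K, m = m,
                 D_int = D * 1e-6),  # um^2 -> mm^2
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  unit <- if (x$family == "linear") "um^2 h^-1" else "um^2 (cells h)^-1"
  cat(sprintf("<model_params> %s family\n", x$family))
  cat(sprintf("  D = %g %s | r = %g h^-1 | K = %g cells mm^-2", x$D, unit, x$r, x$K))
  if (x$family == "porous") cat(sprintf(" | m = %g", x$m))
  cat("\n")
  invisible(x)
}

#' Logistic crowding function
#'
#' The contact-inhibition factor \eqn{f(\rho) = 1 - \rho/K} that scales net
#' proliferation; it is negative above carrying capacity (growth becomes a
#' sink there).
#'
#' @param rho Cell density (cells mm^-2), `>= 0`. Vectorised.
#' @param K Carrying capacity (cells mm^-2), `> 0`.
#' @return `1 - rho/K`, dimensionless.
#' @export
crowding_function <- function(rho, K) {
  stopifnot(is.numeric(rho), is.numeric(K), length(K) == 1)
  if (!all(is.finite(rho)) || !is.finite(K)) stop("non-finite inputs")
  if (K <= 0) stop("K must be > 0")
  if (any(rho < 0)) stop("rho must be >= 0")
  1 - rho / K
}

#' Density-dependent diffusivity
#'
#' Returns the diffusion coefficient at density `rho` in \eqn{\mu m^2 h^{-1}}:
#' the constant `D` for the linear family, and \eqn{D \rho^{m-1}} for the
#' porous family (which vanishes at vacuum, producing compactly supported
#' solutions with sharp fronts).
#'
#' @param rho Cell density (cells mm^-2), `>= 0`. Vectorised.
#' @param params A [model_params()] object.
#' @return Diffusivity in \eqn{\mu m^2 h^{-1}}.
#' @export
diffusivity <- function(rho, params) {
  stopifnot(inherits(params, "model_params"), is.numeric(rho))
  if (any(!is.finite(rho)) || any(rho < 0)) stop("rho must be finite and >= 0")
  if (params$family == "linear") rep(params$D, length(rho))
  else params$D * rho^(params$m - 1)
}

#' Hexagonal close-packing cell radius from carrying capacity
#'
#' Inverts the hexagonal close-packing relation \eqn{K = 1/(2\sqrt{3}a^2)}
#' linking the maximum theoretical monolayer density to the cell radius `a`,
#' giving \eqn{a = (2\sqrt{3}K)^{-1/2}}.
#'
#' @param K Carrying capacity (cells mm^-2), `> 0`. Vectorised.
#' @return Cell radius in \eqn{\mu m}, unrounded.
#' @examples
#' round(packing_radius(5319))  # ~7 um
#' @export
packing_radius <- function(K) {
  stopifnot(is.numeric(K))
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be finite and > 0")
  1000 / sqrt(2 * sqrt(3) * K)  # mm -> um
}

#' Derived biological quantities at a reference density
#'
#' Summarises a calibrated model at a bulk reference density `rho_bar`:
#' the effective (crowding-reduced) proliferation rate
#' \eqn{r(1 - \bar\rho/K)}, the implied division time (its reciprocal), the
#' average diffusivity \eqn{D(\bar\rho)} and the close-packing cell radius.
#'
#' `division_time_rounded` follows the convention of quoting the reciprocal of
#' the effective rate after rounding the rate to one significant figure, so
#' an effective rate of 0.119 h^-1 reads as a 10 h division time; the exact
#' reciprocal is reported alongside it.
#'
#' @param params A [model_params()] object.
#' @param rho_bar Reference density (cells mm^-2), `0 <= rho_bar`; the
#'   division time is undefined (`NA`) at or above `K`.
#' @return A list of class `derived_quantities` with fields `cell_radius`
#'   (um), `effective_rate` (h^-1), `division_time` and
#'   `division_time_rounded` (h), and `average_diffusivity` (um^2 h^-1).
#' @export
growth_summary <- function(params, rho_bar) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(rho_bar), length(rho_bar) == 1, is.finite(rho_bar))
  if (rho_bar < 0) stop("rho_bar must be >= 0")
  eff <- params$r * crowding_function(rho_bar, params$K)
  div <- if (rho_bar >= params$K || eff <= 0) NA_real_ else 1 / eff
  div_r <- if (is.na(div)) NA_real_ else 1 / signif(eff, 1)
  structure(list(cell_radius = packing_radius(params$K),
                 effective_rate = eff,
                 division_time = div,
                 division_time_rounded = div_r,
                 average_diffusivity = diffusivity(rho_bar, params)),
            class = "derived_quantities")
}

#' @export
print.derived_quantities <- function(x, ...) {
  cat("<derived_quantities>\n")
  cat(sprintf("  cell radius          %.2f um\n", x$cell_radius))
  cat(sprintf("  effective rate       %.4f h^-1\n", x$effective_rate))
  cat(sprintf("  division time        %.2f h (%.0f h at 1 s.f. rate)\n",
              x$division_time, x$division_time_rounded))
  cat(sprintf("  average diffusivity  %.1f um^2 h^-1\n", x$average_diffusivity))
  invisible(x)
}
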