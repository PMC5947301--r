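#' Build a grid of broadly tuned place-coding units
#'
#' A two-dimensional signal (a motor command or a visual hand position) is
#' represented by a population of units, each with a preferred vector and a
#' broad, truncated-cosine tuning curve. Preferred vectors are laid out on a
#' regular lattice that covers **twice** the definition range of the signal,
#' centered on the range midpoint and including both endpoints of the doubled
#' interval. Units whose preferred vector lies outside the definition range
#' are what keep the population readout honest at the edges: without them the
#' decoded vector is pulled toward the center of the space for inputs near an
#' edge.
#'
#' @param range a 2 x 2 matrix, one row per dimension, columns `c(lo, hi)`:
#'   the definition range of valid input vectors (not the doubled lattice
#'   span).
#' @param n_per_dim integer of length 2: number of preferred values along
#'   each dimension; the grid has `prod(n_per_dim)` units.
#' @param half_width numeric of length 2: tuning half-width per dimension.
#'   A unit's response to an offset `delta` along one dimension is
#'   `cos(90 * delta / half_width)` degrees for `|delta| < half_width` and 0
#'   beyond; responses multiply across the two dimensions.
#' @param dim_names character of length 2 labelling the dimensions.
#' @return an object of class `tuning_grid`: a list with the preferred-vector
#'   matrix (`prod(n_per_dim)` x 2, first dimension varying fastest), the
#'   per-dimension axes, and the constructor arguments.
#' @seealso [motor_grid()], [visual_grid()], [encode()], [decode()]
#' @export
build_grid <- function(range, n_per_dim, half_width,
                       dim_names = c("dim1", "dim2")) {
  range <- as.matrix(range)
  if (!is.numeric(range) || nrow(range) != 2L || ncol(range) != 2L ||
      any(!is.finite(range)) || any(range[, 2] <= range[, 1])) {
    stop("`range` must be a 2x2 numeric matrix of non-degenerate [lo, hi] rows",
         call. = FALSE)
  }
  n_per_dim <- as.integer(n_per_dim)
  if (length(n_per_dim) != 2L || any(is.na(n_per_dim)) || any(n_per_dim < 2L)) {
    stop("`n_per_dim` must be two integers >= 2", call. = FALSE)
  }
  if (length(half_width) != 2L || any(!is.finite(half_width)) ||
      any(half_width <= 0)) {
    stop("`half_width` must be two positive numbers", call. = FALSE)
  }
  mid <- rowMeans(range)
  len <- range[, 2] - range[, 1]
  axes <- lapply(1:2, function(d) {
    seq(mid[d] - len[d], mid[d] + len[d], length.out = n_per_dim[d])
  })
  names(axes) <- dim_names
  preferred <- as.matrix(expand.grid(axes[[1]], axes[[2]],
                                     KEEP.OUT.ATTRS = FALSE))
  dimnames(preferred) <- list(NULL, dim_names)
  structure(
    list(preferred = preferred, axes = axes, n_per_dim = n_per_dim,
         range = range, half_width = half_width, dim_names = dim_names),
    class = "tuning_grid"
  )
}

#' @export
print.tuning_grid <- function(x, ...) {
  cat(sprintf("tuning_grid: %d x %d units over (%s, %s)\n",
              x$n_per_dim[1], x$n_per_dim[2], x$dim_names[1], x$dim_names[2]))
  for (d in 1:2) {
    cat(sprintf("  %-9s range [%g, %g], preferred in [%g, %g], half-width %g\n",
                x$dim_names[d], x$range[d, 1], x$range[d, 2],
                min(x$axes[[d]]), max(x$axes[[d]]), x$half_width[d]))
  }
  invisible(x)
}

#' Default motor-command grid
#'
#' 10 x 10 units with preferred joint displacements covering twice the
#' `[-20, 20]` degree command range per joint (so `[-40, 40]`), tuning
#' half-width 20 degrees (half the range length) per joint.
#'
#' @param command_range half-width of the motor-command range in degrees.
#' @param n_per_dim units along each joint dimension.
#' @return a [build_grid()] `tuning_grid`.
#' @export
motor_grid <- function(command_range = 20, n_per_dim = c(10, 10)) {
  build_grid(rbind(c(-command_range, command_range),
                   c(-command_range, command_range)),
             n_per_dim, half_width = c(command_range, command_range),
             dim_names = c("d_alpha", "d_beta"))
}

#' Default visual grid
#'
#' 10 preferred distances x 20 preferred azimuths covering twice the visual
#' definition range (distance `[0, 3]` arm-segment units doubled to
#' `[-1.5, 4.5]`; azimuth `[-90, 90]` degrees doubled to `[-180, 180]`).
#' Tuning half-widths: 1.5 units in distance and 90 degrees in azimuth —
#' broad sensitivity equal to half the definition-range length.
#'
#' @param distance_range,azimuth_range definition ranges, `c(lo, hi)`.
#' @param n_per_dim units along (distance, azimuth).
#' @return a [build_grid()] `tuning_grid`.
#' @export
visual_grid <- function(distance_range = c(0, 3), azimuth_range = c(-90, 90),
                        n_per_dim = c(10, 20)) {
  build_grid(rbind(distance_range, azimuth_range), n_per_dim,
             half_width = c(diff(distance_range) / 2, diff(azimuth_range) / 2),
             dim_names = c("distance", "azimuth"))
}

#' Encode a 2-D vector as a population activation
#'
#' Each unit responds with the product, across the two dimensions, of a
#' truncated cosine of the offset between the input and its preferred vector:
#' `g(delta; w) = cos(90 * delta / w degrees)` for `|delta| < w`, else 0.
#' Activations lie in `[0, 1]` and a unit whose preferred vector equals the
#' input is maximally active (1). Inputs outside the definition range are
#' legal (the lattice extends beyond it) but are represented more weakly.
#'
#' @param v numeric of length 2, in the grid's dimension order.
#' @param grid a `tuning_grid`.
#' @return numeric activation vector of length `prod(grid$n_per_dim)`.
#' @export
encode <- function(v, grid) {
  stopifnot(inherits(grid, "tuning_grid"), is.numeric(v), length(v) == 2L,
            all(is.finite(v)))
  w <- grid$half_width
  d1 <- abs(v[1] - grid$preferred[, 1])
  d2 <- abs(v[2] - grid$preferred[, 2])
  g1 <- ifelse(d1 < w[1], cos(pi / 2 * d1 / w[1]), 0)
  g2 <- ifelse(d2 < w[2], cos(pi / 2 * d2 / w[2]), 0)
  g1 * g2
}

#' Decode a population activation back to a 2-D vector
#'
#' Population-vector readout: the activation-weighted mean (center of
#' gravity) of the preferred vectors. This is reporting/actuation plumbing —
#' learning happens entirely between population representations — but it is
#' also how a decoded command drives the physical arm.
#'
#' @param activations numeric activation vector over `grid`'s units.
#' @param grid the `tuning_grid` the activations are defined over.
#' @return numeric of length 2 (named by the grid's dimensions).
#' @export
decode <- function(activations, grid) {
  stopifnot(inherits(grid, "tuning_grid"),
            length(activations) == nrow(grid$preferred),
            all(is.finite(activations)))
  s <- sum(activations)
  if (s <= 0) {
    stop("cannot decode an all-zero population activation", call. = FALSE)
  }
  out <- as.numeric(crossprod(activations, grid$preferred)) / s
  names(out) <- grid$dim_names
  out
}
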