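# Digital tendon phantom: a curved band on a 2-D coronal grid whose voxels
# follow a piecewise-linear T2(x) profile along the band, flanked by a
# long-T2 fluid compartment on one side and a short-T2, low-signal bone
# compartment on the other, imaged as a multi-echo spin-echo magnitude
# series with Rician noise.

#' Default multi-echo spin-echo echo train
#'
#' Eight echo times in milliseconds, 11.4 to 91.2 ms in steps of 11.4 ms,
#' the echo train of a clinical coronal T2-mapping sequence.
#'
#' @return Numeric vector of 8 echo times (ms).
#' @export
default_echo_train <- function() {
  seq(11.4, 91.2, by = 11.4)
}

#' Piecewise-linear T2 profile presets
#'
#' Published per-segment regression parameters (slope in ms per percent of
#' tendon length, intercept in ms at the footprint, x = 0) for supraspinatus
#' tendon T2 distribution profiles: degenerative tendon (tendinosis) and
#' partially torn tendon before and after platelet-rich-plasma treatment,
#' and asymptomatic controls.  Intercepts use the global-x convention: every
#' segment's line is written as T2(x) = intercept + slope * x with x the
#' percent position along the whole tendon, so medial intercepts are
#' extrapolations back to x = 0.
#'
#' @param name One of \code{"tendinosis_before"}, \code{"tendinosis_after"},
#'   \code{"partial_tear_before"}, \code{"partial_tear_after"},
#'   \code{"asymptomatic"}.
#' @return A data frame with columns \code{segment}, \code{slope},
#'   \code{intercept} (rows lateral, middle, medial).
#' @export
#' @examples
#' profile_preset("asymptomatic")
profile_preset <- function(name = c("tendinosis_before", "tendinosis_after",
                                    "partial_tear_before", "partial_tear_after",
                                    "asymptomatic")) {
  name <- match.arg(name)
  p <- switch(name,
    tendinosis_before   = list(c(-0.268, 39.5), c(0.151, 28.4), c(-0.347, 70.1)),
    tendinosis_after    = list(c(-0.195, 34.6), c(0.572, 6.15), c(-0.359, 72.4)),
    partial_tear_before = list(c(-0.458, 43.8), c(0.264, 20.9), c(-0.135, 52.0)),
    partial_tear_after  = list(c(-0.187, 40.6), c(0.402, 16.0), c(-0.284, 64.2)),
    asymptomatic        = list(c(0.217, 24.5),  c(0.430, 12.4), c(-0.174, 51.4))
  )
  data.frame(
    segment   = c("lateral", "middle", "medial"),
    slope     = vapply(p, `[`, numeric(1), 1L),
    intercept = vapply(p, `[`, numeric(1), 2L),
    stringsAsFactors = FALSE
  )
}

#' Build a piecewise-linear T2(x) function over normalized tendon length
#'
#' The tendon length coordinate x runs from 0 % at the lateral (footprint)
#' end to 100 % at the medial (musculotendinous) end and is divided into
#' three equal thirds: lateral [0, 100/3), middle [100/3, 200/3), medial
#' [200/3, 100].  Each third carries its own line
#' T2(x) = intercept + slope * x in the global x coordinate; the segments
#' need not join at the boundaries.
#'
#' @param profile_spec Data frame with columns \code{segment} (lateral,
#'   middle, medial), \code{slope} (ms per percent) and \code{intercept}
#'   (ms at x = 0), as returned by \code{\link{profile_preset}}.
#' @return A vectorized function mapping x in [0, 100] to T2 in ms.
#' @export
#' @examples
#' f <- make_profile_function(profile_preset("tendinosis_before"))
#' f(0)   # lateral intercept, 39.5 ms
make_profile_function <- function(profile_spec) {
  spec <- validate_profile_spec(profile_spec)
  slopes <- spec$slope
  icepts <- spec$intercept
  breaks <- c(100 / 3, 200 / 3)
  function(x) {
    if (any(x < 0 | x > 100, na.rm = TRUE)) {
      stop("profile position x must lie in [0, 100] percent", call. = FALSE)
    }
    seg <- 1L + (x >= breaks[1]) + (x >= breaks[2])
    icepts[seg] + slopes[seg] * x
  }
}

validate_profile_spec <- function(profile_spec) {
  if (!is.data.frame(profile_spec) ||
      !all(c("segment", "slope", "intercept") %in% names(profile_spec))) {
    stop("profile_spec must be a data frame with columns segment, slope, intercept",
         call. = FALSE)
  }
  want <- c("lateral", "middle", "medial")
  idx <- match(want, profile_spec$segment)
  if (anyNA(idx)) {
    stop("profile_spec must contain segments lateral, middle and medial",
         call. = FALSE)
  }
  spec <- profile_spec[idx, , drop = FALSE]
  # each segment is linear, so positivity on its third holds iff it holds at
  # both ends of the third
  lo <- c(0, 100 / 3, 200 / 3)
  hi <- c(100 / 3, 200 / 3, 100)
  ends <- pmin(spec$intercept + spec$slope * lo,
               spec$intercept + spec$slope * hi)
  if (any(ends <= 0)) {
    bad <- want[ends <= 0]
    stop(sprintf("profile_spec yields T2 <= 0 ms inside segment(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  spec
}

#' Phantom configuration
#'
#' Bundles every knob of the digital tendon phantom.  Defaults emulate a
#' coronal-slice acquisition: a 96 x 96 grid at 140/256 mm in-plane spacing,
#' the eight-echo train of \code{\link{default_echo_train}}, a curved tendon
#' band 7 voxels thick whose T2 follows the pre-treatment tendinosis profile
#' preset, a 200 ms fluid compartment along its bursal side, a 2 ms bone
#' compartment at 5 % of tendon proton density along the other side, and
#' Rician noise.
#'
#' @param grid_shape Integer vector (rows, cols) of the voxel grid.
#' @param voxel_spacing In-plane voxel size in mm (scalar; isotropic).
#' @param echo_train Strictly increasing echo times in ms, length >= 3.
#' @param control_points 3 x 2 matrix of (row, col) quadratic-Bezier control
#'   points for the tendon centerline; the first point is the lateral
#'   (footprint) end.  \code{NULL} gives a default arc spanning the grid.
#' @param half_thickness Tendon band half-thickness in voxels (>= 1).
#' @param profile_spec Piecewise-linear T2(x) specification, see
#'   \code{\link{make_profile_function}}.
#' @param s0_tendon,s0_fluid,s0_bone Proton-density signal scale per
#'   compartment (arbitrary units).
#' @param t2_fluid,t2_bone Compartment T2 in ms.
#' @param rim_thickness Thickness in voxels of the fluid and bone rims.
#' @param noise_sigma Rician sigma in the same units as \code{s0_tendon}.
#' @param straight If \code{TRUE}, the centerline is a straight horizontal
#'   band (analytic-oracle geometry) regardless of \code{control_points}.
#' @param seed Integer seed controlling the noise realization.
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(grid_shape = c(96L, 96L),
                           voxel_spacing = 140 / 256,
                           echo_train = default_echo_train(),
                           control_points = NULL,
                           half_thickness = 3,
                           profile_spec = profile_preset("tendinosis_before"),
                           s0_tendon = 1000,
                           s0_fluid = 1500,
                           s0_bone = 50,
                           t2_fluid = 200,
                           t2_bone = 2,
                           rim_thickness = 3,
                           noise_sigma = 0,
                           straight = FALSE,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 16L),
            length(voxel_spacing) == 1L, voxel_spacing > 0,
            length(echo_train) >= 3L, all(diff(echo_train) > 0),
            half_thickness >= 1, rim_thickness >= 1,
            s0_tendon > 0, s0_fluid >= 0, s0_bone >= 0,
            t2_fluid > 0, t2_bone > 0, noise_sigma >= 0)
  validate_profile_spec(profile_spec)
  if (is.null(control_points)) {
    nr <- grid_shape[1]; nc <- grid_shape[2]
    control_points <- rbind(
      c(0.42 * nr, 0.10 * nc),
      c(0.16 * nr, 0.50 * nc),
      c(0.46 * nr, 0.90 * nc)
    )
  }
  control_points <- as.matrix(control_points)
  if (!identical(dim(control_points), c(3L, 2L))) {
    stop("control_points must be a 3 x 2 (row, col) matrix", call. = FALSE)
  }
  structure(list(
    grid_shape = grid_shape, voxel_spacing = voxel_spacing,
    echo_train = echo_train, control_points = control_points,
    half_thickness = half_thickness, profile_spec = profile_spec,
    s0_tendon = s0_tendon, s0_fluid = s0_fluid, s0_bone = s0_bone,
    t2_fluid = t2_fluid, t2_bone = t2_bone, rim_thickness = rim_thickness,
    noise_sigma = noise_sigma, straight = isTRUE(straight),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# Dense sampling of the centerline: quadratic Bezier through the control
# points, or a straight horizontal segment in straight mode.  Returns
# (row, col) sample coordinates plus cumulative arc length in voxel units.
sample_centerline <- function(config, n = 600L) {
  P <- config$control_points
  t <- seq(0, 1, length.out = n)
  if (config$straight) {
    r0 <- P[1, 1]
    pts <- cbind(rep(r0, n), P[1, 2] + t * (P[3, 2] - P[1, 2]))
  } else {
    b0 <- (1 - t)^2; b1 <- 2 * t * (1 - t); b2 <- t^2
    pts <- cbind(b0 * P[1, 1] + b1 * P[2, 1] + b2 * P[3, 1],
                 b0 * P[1, 2] + b1 * P[2, 2] + b2 * P[3, 2])
  }
  step <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(step))
  list(points = pts, arc = arc, total = arc[n])
}

#' Add Rician noise to a magnitude image
#'
#' Each voxel value v is replaced by sqrt((v + n1)^2 + n2^2) with n1, n2
#' independent zero-mean Gaussians of standard deviation \code{sigma} --
#' the magnitude of a complex signal whose real and imaginary channels
#' carry independent Gaussian noise.
#'
#' @param image Numeric array of magnitude values.
#' @param sigma Noise standard deviation, in the units of \code{image};
#'   must be >= 0.  \code{sigma = 0} returns the input unchanged.
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's random-number state is left untouched.
#' @return Array of the same shape with Rician-distorted magnitudes.
#' @export
add_rician_noise <- function(image, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("sigma must be a single non-negative number", call. = FALSE)
  }
  if (sigma == 0) {
    return(image)
  }
  draw <- function() {
    n1 <- rnorm(length(image), 0, sigma)
    n2 <- rnorm(length(image), 0, sigma)
    out <- sqrt((image + n1)^2 + n2^2)
    attributes(out) <- attributes(image)
    out
  }
  if (is.null(seed)) {
    draw()
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    draw()
  }
}

#' Generate a multi-echo digital tendon phantom
#'
#' Builds the compartment geometry (tendon band, fluid rim, bone rim) on the
#' configured grid, assigns every tendon voxel the ground-truth T2 given by
#' the piecewise-linear profile at its along-band position, simulates one
#' magnitude image per echo as S0 * exp(-TE / T2) per compartment, and
#' applies Rician noise.
#'
#' @param config A \code{\link{phantom_config}}.
#' @return A list with elements
#'   \describe{
#'     \item{image}{a \code{\link{multi_echo_image}} of noisy echoes;}
#'     \item{truth}{a \code{phantom_truth} list: \code{t2_field} (true T2 in
#'       ms, NA in background), \code{mask} (a \code{\link{tendon_mask}}),
#'       \code{compartments} (character matrix: background / tendon / fluid
#'       / bone), \code{position} (true percent position for tendon voxels,
#'       NA elsewhere), \code{true_profile} (the T2(x) function),
#'       \code{tendon_length_mm}, and \code{config}.}
#'   }
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cl <- sample_centerline(config)

  # nearest centerline sample for every voxel (voxel units)
  vox <- cbind(rep(seq_len(nr), times = nc), rep(seq_len(nc), each = nr))
  d2 <- outer(vox[, 1], cl$points[, 1], "-")^2 +
        outer(vox[, 2], cl$points[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  dist_vox <- sqrt(d2[cbind(seq_len(nrow(vox)), nearest)])

  # signed side of the centerline via the tangent cross product
  n_s <- nrow(cl$points)
  tangent <- rbind(cl$points[2, ] - cl$points[1, ],
                   (cl$points[3:n_s, ] - cl$points[1:(n_s - 2), ]) / 2,
                   cl$points[n_s, ] - cl$points[n_s - 1, ])
  off <- vox - cl$points[nearest, , drop = FALSE]
  tg <- tangent[nearest, , drop = FALSE]
  side <- sign(tg[, 1] * off[, 2] - tg[, 2] * off[, 1])
  sdist <- dist_vox * ifelse(side == 0, 1, side)

  h <- config$half_thickness
  rim <- config$rim_thickness
  interior <- nearest > 1L & nearest < n_s  # rims only flank the band
  comp <- rep("background", nrow(vox))
  comp[dist_vox <= h] <- "tendon"
  comp[comp == "background" & interior & sdist > h & sdist <= h + rim] <- "fluid"
  comp[comp == "background" & interior & sdist < -h & sdist >= -(h + rim)] <- "bone"
  comp_m <- matrix(comp, nr, nc)

  if (!any(comp_m[1, ] == "tendon") && !any(comp_m[nr, ] == "tendon") &&
      !any(comp_m[, 1] == "tendon") && !any(comp_m[, nc] == "tendon")) {
    # band fully interior: fine
  } else {
    stop("tendon band touches the grid boundary; enlarge grid_shape or move control_points",
         call. = FALSE)
  }

  # ground-truth along-band position for tendon voxels, percent of arc length
  pos <- matrix(NA_real_, nr, nc)
  tendon_idx <- which(comp == "tendon")
  pos[tendon_idx] <- pmin(100, pmax(0, 100 * cl$arc[nearest[tendon_idx]] / cl$total))

  profile_fun <- make_profile_function(config$profile_spec)
  t2_field <- matrix(NA_real_, nr, nc)
  t2_field[tendon_idx] <- profile_fun(pos[tendon_idx])
  t2_field[comp_m == "fluid"] <- config$t2_fluid
  t2_field[comp_m == "bone"] <- config$t2_bone

  s0_field <- matrix(0, nr, nc)
  s0_field[comp_m == "tendon"] <- config$s0_tendon
  s0_field[comp_m == "fluid"] <- config$s0_fluid
  s0_field[comp_m == "bone"] <- config$s0_bone

  # seeds: tendon voxels nearest the two centerline endpoints
  seed_voxel <- function(endpoint) {
    d <- (vox[tendon_idx, 1] - endpoint[1])^2 + (vox[tendon_idx, 2] - endpoint[2])^2
    idx <- tendon_idx[which.min(d)]
    c(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
  }
  lateral_seed <- seed_voxel(cl$points[1, ])
  medial_seed <- seed_voxel(cl$points[n_s, ])

  mask <- tendon_mask(comp_m == "tendon", lateral_seed, medial_seed)

  echoes <- lapply(config$echo_train, function(te) {
    img <- s0_field * exp(-te / t2_field)
    img[is.na(img)] <- 0
    img
  })
  if (config$noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(config$seed)
    echoes <- lapply(echoes, add_rician_noise, sigma = config$noise_sigma)
  }

  image <- multi_echo_image(echoes, config$echo_train, config$voxel_spacing)
  truth <- structure(list(
    t2_field = t2_field, mask = mask, compartments = comp_m,
    position = pos, true_profile = profile_fun,
    tendon_length_mm = cl$total * config$voxel_spacing,
    config = config
  ), class = "phantom_truth")
  list(image = image, truth = truth)
}
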