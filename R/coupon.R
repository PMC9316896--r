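#' Droplet deposition parameters
#'
#' Parameters of micro-droplet deposition of an API solution onto a flat
#' stainless-steel coupon, either by a microdot printer (regular grid,
#' \code{mode = "printer"}) or by hand with a microliter syringe
#' (clustered, spatially inhomogeneous placement, \code{mode = "by-hand"}).
#' Droplet volumes are drawn uniformly from \code{volume_range} and the
#' printer pitch uniformly from \code{pitch_range}; at most
#' \code{max_droplets} droplets can be deposited. Each droplet spreads its
#' mass as a uniform disc of diameter \code{droplet_diameter}.
#'
#' The by-hand mode is a two-level process: cluster centres are placed
#' uniformly over the coupon and droplets scatter around them with Gaussian
#' spread \code{cluster_sd}. Fewer clusters and tighter scatter give a more
#' inhomogeneous surface; the defaults emulate hand deposition with
#' spot-to-spot relative standard deviation in the 27--53% band observed
#' for hand-prepared coupons.
#'
#' @param width,height Coupon dimensions, mm.
#' @param mode \code{"printer"} or \code{"by-hand"}.
#' @param pitch_range Distance between neighbouring printed droplets, mm.
#' @param volume_range Per-droplet volume range, nL.
#' @param max_droplets Maximum droplet count the printer can deposit.
#' @param droplet_diameter Diameter of the uniform disc over which one
#'   droplet's mass spreads, mm.
#' @param solution_concentration API concentration of the deposited
#'   solution, ug/nL, or \code{NULL} to solve for the concentration that
#'   meets the target density exactly.
#' @param n_droplets Droplet count for by-hand mode.
#' @param n_clusters Number of deposition clusters in by-hand mode.
#' @param cluster_sd Gaussian scatter of droplets about their cluster
#'   centre, mm (by-hand mode).
#' @return An object of class \code{deposition_profile}.
#' @export
deposition_profile <- function(width = 40, height = 40,
                               mode = c("printer", "by-hand"),
                               pitch_range = c(0.5, 1),
                               volume_range = c(4, 10),
                               max_droplets = 5200,
                               droplet_diameter = 0.4,
                               solution_concentration = NULL,
                               n_droplets = 5000,
                               n_clusters = 150,
                               cluster_sd = 8) {
  mode <- match.arg(mode)
  stopifnot(width > 0, height > 0, droplet_diameter > 0,
            length(pitch_range) == 2, pitch_range[1] <= pitch_range[2],
            pitch_range[1] > 0,
            length(volume_range) == 2, volume_range[1] <= volume_range[2],
            volume_range[1] > 0, max_droplets >= 1)
  structure(
    list(
      width = width, height = height, mode = mode,
      pitch_range = pitch_range, volume_range = volume_range,
      max_droplets = as.integer(max_droplets),
      droplet_diameter = droplet_diameter,
      solution_concentration = solution_concentration,
      n_droplets = as.integer(n_droplets),
      n_clusters = as.integer(n_clusters),
      cluster_sd = cluster_sd
    ),
    class = "deposition_profile"
  )
}

# Printer grid: randomized pitch per row/column. Each axis is tiled
# edge-to-edge into cells with widths drawn from pitch_range (rescaled to
# span the coupon exactly) and a droplet sits at each cell centre, so one
# droplet represents one equal-expected share of area -- placing droplets at
# cell boundaries instead would over-weight the coupon edges (fencepost).
grid_positions <- function(profile) {
  axis_positions <- function(extent) {
    k <- max(1L, as.integer(round(extent / mean(profile$pitch_range))))
    gaps <- stats::runif(k, profile$pitch_range[1], profile$pitch_range[2])
    gaps <- gaps * (extent / sum(gaps))
    cumsum(gaps) - gaps / 2
  }
  xs <- axis_positions(profile$width)
  ys <- axis_positions(profile$height)
  cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
}

# By-hand clustered placement; out-of-bounds scatter is redrawn (clamped
# after 20 rounds, which in practice never triggers at default spreads).
cluster_positions <- function(profile, n) {
  cx <- stats::runif(profile$n_clusters, 0, profile$width)
  cy <- stats::runif(profile$n_clusters, 0, profile$height)
  idx <- sample.int(profile$n_clusters, n, replace = TRUE)
  x <- cx[idx] + stats::rnorm(n, 0, profile$cluster_sd)
  y <- cy[idx] + stats::rnorm(n, 0, profile$cluster_sd)
  for (round in 1:20) {
    bad <- which(x < 0 | x > profile$width | y < 0 | y > profile$height)
    if (length(bad) == 0) break
    x[bad] <- cx[idx[bad]] + stats::rnorm(length(bad), 0, profile$cluster_sd)
    y[bad] <- cy[idx[bad]] + stats::rnorm(length(bad), 0, profile$cluster_sd)
  }
  x <- pmin(pmax(x, 0), profile$width)
  y <- pmin(pmax(y, 0), profile$height)
  cbind(x = x, y = y)
}

#' Generate a residue-bearing coupon
#'
#' Deposits API micro-droplets on a flat coupon so that the area-averaged
#' surface density equals \code{target_density}. Droplet volumes are drawn
#' uniformly within the profile's volume range; positions follow the
#' profile's deposition mode. When \code{solution_concentration} is
#' \code{NULL} the concentration is solved from the drawn total volume so
#' the target is met exactly; when it is given, the droplet count is chosen
#' to meet the target and an infeasibility error is raised if that count
#' exceeds \code{max_droplets}.
#'
#' @param target_density Intended area-averaged surface residue, ug/cm^2.
#' @param profile A \code{\link{deposition_profile}}.
#' @param seed Integer seed for reproducibility, or \code{NULL}.
#' @return An object of class \code{coupon_surface} with fields
#'   \code{x}, \code{y} (droplet centres, mm), \code{mass} (ug per
#'   droplet), \code{volume} (nL), \code{droplet_radius} (mm),
#'   \code{width}, \code{height}, \code{target_density},
#'   \code{concentration} (ug/nL).
#' @examples
#' cp <- generate_coupon(0.6, deposition_profile(), seed = 1)
#' coupon_mean_density(cp)
#' @export
generate_coupon <- function(target_density, profile = deposition_profile(),
                            seed = NULL) {
  if (target_density < 0) {
    stop_ftir("ftir_invalid_target", "target_density must be >= 0")
  }
  area_cm2 <- profile$width * profile$height * 0.01
  total_mass <- target_density * area_cm2
  if (total_mass == 0) {
    return(new_coupon(numeric(0), numeric(0), numeric(0), numeric(0),
                      profile, target_density, concentration = 0))
  }
  with_seed(seed, {
    pos <- switch(profile$mode,
      "printer" = grid_positions(profile),
      "by-hand" = cluster_positions(profile, profile$n_droplets)
    )
    conc <- profile$solution_concentration
    if (!is.null(conc)) {
      mean_vol <- mean(profile$volume_range)
      n_needed <- max(1L, as.integer(round(total_mass / (mean_vol * conc))))
      if (n_needed > profile$max_droplets) {
        stop_ftir(
          "ftir_infeasible_deposition",
          sprintf(
            "target density %g ug/cm^2 needs ~%d droplets at concentration %g ug/nL; printer maximum is %d",
            target_density, n_needed, conc, profile$max_droplets
          )
        )
      }
      if (n_needed > nrow(pos)) {
        pos <- pos[sample.int(nrow(pos), n_needed, replace = TRUE), , drop = FALSE]
      } else {
        pos <- pos[sample.int(nrow(pos), n_needed), , drop = FALSE]
      }
      vol <- stats::runif(n_needed, profile$volume_range[1], profile$volume_range[2])
      # rescale volumes so the drawn total hits the target exactly, clipped
      # back into the admissible range (a no-op at realistic droplet counts)
      f <- (total_mass / conc) / sum(vol)
      vol <- pmin(pmax(vol * f, profile$volume_range[1]), profile$volume_range[2])
      mass <- vol * conc
    } else {
      n <- nrow(pos)
      if (n > profile$max_droplets) {
        keep <- sample.int(n, profile$max_droplets)
        pos <- pos[keep, , drop = FALSE]
        n <- profile$max_droplets
      }
      vol <- stats::runif(n, profile$volume_range[1], profile$volume_range[2])
      conc <- total_mass / sum(vol)
      mass <- vol * conc
    }
    new_coupon(pos[, "x"], pos[, "y"], mass, vol, profile, target_density, conc)
  })
}

new_coupon <- function(x, y, mass, volume, profile, target_density, concentration) {
  structure(
    list(
      x = as.numeric(x), y = as.numeric(y),
      mass = as.numeric(mass), volume = as.numeric(volume),
      droplet_radius = profile$droplet_diameter / 2,
      width = profile$width, height = profile$height,
      target_density = target_density,
      concentration = concentration,
      mode = profile$mode
    ),
    class = "coupon_surface"
  )
}

#' @export
print.coupon_surface <- function(x, ...) {
  cat(sprintf(
    "<coupon_surface> %g x %g mm, %d droplets (%s), mean density %.4g ug/cm^2\n",
    x$width, x$height, length(x$mass), x$mode, coupon_mean_density(x)
  ))
  invisible(x)
}

#' Area-averaged surface density of a coupon
#'
#' Total deposited mass divided by coupon area.
#'
#' @param surface A \code{coupon_surface}.
#' @return Density in ug/cm^2.
#' @export
coupon_mean_density <- function(surface) {
  sum(surface$mass) / (surface$width * surface$height * 0.01)
}

# Intersection area of two discs at centre distance d (mm^2); standard
# circular-lens formula.
disc_overlap_area <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  s <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - s
}

#' Local surface density seen by one spot measurement
#'
#' Computes the residue mass inside a circular measurement footprint
#' divided by the footprint area: the quantity an FTIR spot measurement
#' responds to. Each droplet contributes its mass weighted by the fraction
#' of its disc footprint overlapping the spot. Deterministic given the
#' surface and centre.
#'
#' @param surface A \code{coupon_surface}.
#' @param center Numeric length-2, spot centre (x, y) in mm.
#' @param spot_area Spot area, mm^2 (default the 1.76 mm^2 specular
#'   reflectance interface).
#' @return Local density, ug/cm^2.
#' @examples
#' cp <- generate_coupon(0.6, deposition_profile(), seed = 1)
#' sample_spot(cp, c(20, 20))
#' @export
sample_spot <- function(surface, center, spot_area = 1.76) {
  r_spot <- sqrt(spot_area / pi)
  if (center[1] - r_spot < 0 || center[1] + r_spot > surface$width ||
      center[2] - r_spot < 0 || center[2] + r_spot > surface$height) {
    stop_ftir(
      "ftir_spot_out_of_bounds",
      sprintf("spot footprint at (%g, %g) with radius %.3g mm crosses the coupon edge",
              center[1], center[2], r_spot)
    )
  }
  if (length(surface$mass) == 0) return(0)
  r_d <- surface$droplet_radius
  d <- sqrt((surface$x - center[1])^2 + (surface$y - center[2])^2)
  near <- which(d < r_spot + r_d)
  if (length(near) == 0) return(0)
  disc_area <- pi * r_d^2
  captured <- 0
  for (i in near) {
    captured <- captured +
      surface$mass[i] * disc_overlap_area(d[i], r_spot, r_d) / disc_area
  }
  captured / (spot_area * 0.01)
}

#' Random spot centres whose footprints stay on the coupon
#'
#' @param surface A \code{coupon_surface}.
#' @param n Number of centres.
#' @param spot_area Spot area, mm^2.
#' @param seed Integer seed or \code{NULL}.
#' @return An n x 2 matrix of (x, y) centres in mm.
#' @export
random_spot_centers <- function(surface, n, spot_area = 1.76, seed = NULL) {
  r <- sqrt(spot_area / pi)
  if (2 * r >= min(surface$width, surface$height)) {
    stop_ftir("ftir_spot_out_of_bounds", "spot footprint larger than coupon")
  }
  with_seed(seed, cbind(
    x = stats::runif(n, r, surface$width - r),
    y = stats::runif(n, r, surface$height - r)
  ))
}

#' Spot-sampled densities at random locations
#'
#' Convenience wrapper: draws \code{n} uniform random spot centres (with
#' the footprint fully on the coupon) and returns the local density at
#' each, emulating "measurements taken at random locations".
#'
#' @inheritParams random_spot_centers
#' @return Numeric vector of n local densities, ug/cm^2.
#' @export
sample_spots_random <- function(surface, n, spot_area = 1.76, seed = NULL) {
  centers <- random_spot_centers(surface, n, spot_area, seed)
  vapply(seq_len(n), function(i) sample_spot(surface, centers[i, ], spot_area),
         numeric(1))
}
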