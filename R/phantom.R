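#' Raised-cosine respiratory waveform
#'
#' \code{w(t) = (1 - cos(2*pi*t)) / 2}, a standard surrogate for a tidal
#' breathing cycle: 0 at end-exhale (t = 0), 1 at peak inhale (t = 0.5).
#' Sampled at the discrete phases \code{t = p/P}, \code{p = 0..P-1}, it
#' spans exactly [0, 1] whenever P is even.
#'
#' @param t cycle fraction(s); any real, period 1.
#' @return Waveform value(s) in [0, 1].
#' @export
raised_cosine <- function(t) (1 - cos(2 * pi * t)) / 2

#' Configuration of the synthetic breathing-torso phantom
#'
#' Defines a 10-phase breathing torso with analytically known per-beam
#' motion amplitude and skin-to-tracking-structure correlation. The skin
#' radius about the body axis at polar angle theta (degrees, full circle,
#' same convention as \code{\link{beam_angles}}), slice height z and phase p
#' is
#' \deqn{rho(theta, z, p) = rho0(theta, z) + M(theta, z) \cdot
#'       w(p/P - phi(theta, z)) + noise,}
#' with \code{w} the \code{\link{raised_cosine}} waveform, \code{M >= 0} the
#' local motion amplitude (mm), \code{phi} a local phase lag (cycle
#' fraction) and Gaussian vertex noise of standard deviation
#' \code{noise_sd}.
#'
#' The default fields describe a 100-slice torso of 150 mm base radius with
#' an anterior Gaussian motion lobe peaking at 5 mm at theta = 90 deg
#' (chest/abdominal wall moving anteriorly on inhalation), no phase lag and
#' no noise; the tracking structure moves 8 mm craniocaudally, typical of a
#' lower-lung-lobe vessel.
#'
#' @param n_phases number of respiratory phase bins (default 10).
#' @param slice_zs strictly increasing axial slice heights, mm (default
#'   0..99, i.e. 1 mm slice spacing).
#' @param base_radius function \code{f(theta_deg, z) -> mm}, vectorised over
#'   theta: the motionless skin radius.
#' @param amplitude_field function \code{f(theta_deg, z) -> mm >= 0}: local
#'   peak-to-trough motion amplitude M.
#' @param lag_field function \code{f(theta_deg, z)} in [0, 1): local phase
#'   lag as a fraction of the breathing cycle.
#' @param noise_sd Gaussian vertex noise standard deviation, mm, >= 0.
#' @param ts_amplitude tracking-structure craniocaudal excursion, mm.
#' @param ts_base_z tracking-structure end-exhale z, mm.
#' @param vertex_step contour vertex sampling step, degrees; must divide
#'   360 (default 0.5, so beams cast at 1 deg resolution pass through
#'   phantom vertices exactly).
#' @param center in-plane (x, y) of the phantom axis, mm.
#' @param seed integer seed for the noise term (and only the noise term).
#' @return Object of class \code{phantom_config}.
#' @export
phantom_config <- function(n_phases = 10L,
                           slice_zs = 0:99,
                           base_radius = function(theta, z)
                             rep_len(150, length(theta)),
                           amplitude_field = function(theta, z)
                             5 * exp(-((theta - 90) / 40)^2),
                           lag_field = function(theta, z)
                             rep_len(0, length(theta)),
                           noise_sd = 0,
                           ts_amplitude = 8,
                           ts_base_z = 250,
                           vertex_step = 0.5,
                           center = c(0, 0),
                           seed = 1L) {
  if (n_phases < 3L) stop("'n_phases' must be at least 3")
  if (length(slice_zs) < 1L || any(diff(slice_zs) <= 0))
    stop("'slice_zs' must be strictly increasing")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (ts_amplitude < 0) stop("'ts_amplitude' must be non-negative")
  if (vertex_step <= 0 || abs(360 / vertex_step -
                              round(360 / vertex_step)) > 1e-9)
    stop("'vertex_step' must be a positive divisor of 360")
  stopifnot(is.function(base_radius), is.function(amplitude_field),
            is.function(lag_field), length(center) == 2L)
  structure(list(n_phases = as.integer(n_phases), slice_zs = slice_zs,
                 base_radius = base_radius,
                 amplitude_field = amplitude_field, lag_field = lag_field,
                 noise_sd = noise_sd, ts_amplitude = ts_amplitude,
                 ts_base_z = ts_base_z, vertex_step = vertex_step,
                 center = as.numeric(center), seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate the synthetic breathing torso
#'
#' Builds the multi-phase skin contour stack defined by a
#' \code{\link{phantom_config}} together with its analytic ground truth:
#' per-(slice, beam-angle) motion magnitude \code{M * (max_p w' - min_p w')}
#' for the lag-shifted waveform \code{w'_p = w(p/P - phi)}, and the exact
#' Pearson correlation of the noise-free radius series against the
#' tracking-structure trajectory over the same P discrete phases. Beams
#' with zero amplitude have an undefined (NA) correlation truth. With zero
#' lag and zero noise the radius series is a positive affine image of the
#' TS series, so the correlation truth is exactly 1 wherever M > 0;
#' anti-phase lag (phi = 0.5) gives exactly -1.
#'
#' Noise-free phantom contours are star-shaped about the slice centre (a
#' polar radius function), so every radial beam meets the skin exactly
#' once.
#'
#' @param config a \code{\link{phantom_config}}.
#' @return List with components \code{phases} (list of
#'   \code{\link{phase_contour_set}}) and \code{truth}, itself a list with
#'   \code{magnitude_truth} and \code{correlation_truth} (n_slices x 180
#'   matrices over \code{\link{beam_angles}}), and
#'   \code{ts_magnitude_truth} (mm).
#' @export
generate_torso <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  P <- config$n_phases
  set.seed(config$seed)
  thetas <- seq(0, 360 - config$vertex_step, by = config$vertex_step)
  u <- beam_direction(thetas)                 # vertex unit directions
  phases <- vector("list", P)
  slabs <- vector("list", P)
  for (p in seq_len(P) - 1L) {
    slices <- vector("list", length(config$slice_zs))
    for (s in seq_along(config$slice_zs)) {
      z <- config$slice_zs[s]
      rho0 <- config$base_radius(thetas, z)
      M <- config$amplitude_field(thetas, z)
      if (any(M < 0)) stop("amplitude field is negative at z = ", z)
      phi <- config$lag_field(thetas, z)
      rho <- rho0 + M * raised_cosine(p / P - phi)
      if (config$noise_sd > 0)
        rho <- rho + stats::rnorm(length(rho), sd = config$noise_sd)
      if (any(rho <= 0))
        stop("non-positive skin radius at z = ", z,
             " (self-intersecting torso)")
      slices[[s]] <- contour_slice(
        z, cbind(config$center[1L] + rho * u[, 1L],
                 config$center[2L] + rho * u[, 2L]))
    }
    phases[[p + 1L]] <- phase_contour_set(p, slices)
  }
  list(phases = phases, truth = phantom_truth(config))
}

# Analytic ground truth at the beam angles, from the noise-free model.
phantom_truth <- function(config) {
  P <- config$n_phases
  angles <- beam_angles()
  S <- length(config$slice_zs)
  w_ts <- raised_cosine((seq_len(P) - 1L) / P)
  ts <- config$ts_base_z + config$ts_amplitude * w_ts
  mag <- matrix(NA_real_, S, length(angles))
  corr <- matrix(NA_real_, S, length(angles))
  for (s in seq_len(S)) {
    z <- config$slice_zs[s]
    M <- config$amplitude_field(angles, z)
    phi <- config$lag_field(angles, z)
    # P x 180 lag-shifted waveform samples
    Wp <- raised_cosine(outer((seq_len(P) - 1L) / P, phi, `-`))
    span <- apply(Wp, 2L, max) - apply(Wp, 2L, min)
    mag[s, ] <- M * span
    defined <- M > 0 & span > 0 & stats::sd(ts) > 0
    if (any(defined))
      corr[s, defined] <- pmin(1, pmax(-1, suppressWarnings(
        as.vector(stats::cor(Wp[, defined, drop = FALSE], ts)))))
  }
  list(magnitude_truth = mag, correlation_truth = corr,
       ts_magnitude_truth = config$ts_amplitude * (max(w_ts) - min(w_ts)),
       z = config$slice_zs, angles = angles)
}

#' Generate the phantom tracking-structure trajectory
#'
#' The TS craniocaudal coordinate follows the same raised-cosine cycle as
#' the skin: \code{z_TS(p) = ts_base_z + ts_amplitude * w(p/P)}. The
#' craniocaudal axis is oriented so that the inhalation displacement of the
#' tracking structure is positive; a lag-free phantom skin beam is then a
#' positive affine image of the TS series (correlation +1).
#'
#' @param config a \code{\link{phantom_config}}.
#' @return A \code{\link{ts_trajectory}} of length \code{n_phases}.
#' @export
generate_ts <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  p <- seq_len(config$n_phases) - 1L
  ts_trajectory(config$ts_base_z +
                config$ts_amplitude * raised_cosine(p / config$n_phases))
}

#' Generate a synthetic L4 axial HU slice with known adipose compartments
#'
#' Builds a concentric-ellipse abdomen phantom at the level of L4: an
#' outer skin ellipse bounding the body; a subcutaneous fat ring at
#' -100 HU between the skin and the outer muscle-wall ellipse; a muscle
#' ring at +40 HU; a visceral interior at +30 HU containing seeded
#' circular fat blobs at -100 HU; air at -1000 HU outside the body. The
#' inner abdominal wall polygon (the SAT/VAT separator) and the analytic
#' compartment areas from ellipse/circle geometry are returned alongside
#' the pixel grid.
#'
#' @param config a \code{\link{phantom_config}} (supplies the seed for blob
#'   placement).
#' @param body semi-axes (a, b) of the skin ellipse, mm.
#' @param sat_inner semi-axes of the inner boundary of the subcutaneous fat
#'   ring, mm; must nest strictly inside \code{body}.
#' @param wall_inner semi-axes of the inner abdominal wall, mm; must nest
#'   strictly inside \code{sat_inner}.
#' @param n_blobs number of visceral fat blobs (0 for none).
#' @param blob_radius_range min/max blob radius, mm.
#' @param pixel_spacing pixel size (dx, dy), mm.
#' @param hu_fat,hu_muscle,hu_organ,hu_air Hounsfield values of the
#'   compartments.
#' @return List with \code{slice} (an \code{\link{hu_slice}}),
#'   \code{inner_wall} (polygon matrix, mm) and \code{truth}: analytic
#'   \code{sat_area}, \code{vat_area}, \code{tat_area}, \code{body_area}
#'   in mm^2 plus blob centres and radii.
#' @export
generate_l4_slice <- function(config = phantom_config(),
                              body = c(150, 100),
                              sat_inner = c(140, 92),
                              wall_inner = c(132, 86),
                              n_blobs = 6L,
                              blob_radius_range = c(6, 12),
                              pixel_spacing = c(1, 1),
                              hu_fat = -100, hu_muscle = 40,
                              hu_organ = 30, hu_air = -1000) {
  stopifnot(inherits(config, "phantom_config"))
  if (!(all(body > sat_inner) && all(sat_inner > wall_inner) &&
        all(wall_inner > 0)))
    stop("ellipse rings must be strictly nested: body > sat_inner > wall_inner")
  set.seed(config$seed + 104729L)  # decouple from the torso noise stream
  dx <- pixel_spacing[1L]; dy <- pixel_spacing[2L]
  margin <- 8
  x <- seq(-(body[1L] + margin), body[1L] + margin, by = dx)
  y <- seq(-(body[2L] + margin), body[2L] + margin, by = dy)
  gx <- matrix(x, nrow = length(y), ncol = length(x), byrow = TRUE)
  gy <- matrix(y, nrow = length(y), ncol = length(x))
  in_ell <- function(ab) (gx / ab[1L])^2 + (gy / ab[2L])^2 <= 1
  body_mask <- in_ell(body)
  hu <- matrix(hu_air, nrow = length(y), ncol = length(x))
  hu[body_mask] <- hu_fat                       # SAT ring (outermost layer)
  m_sat_inner <- in_ell(sat_inner)
  hu[m_sat_inner] <- hu_muscle                  # muscle wall ring
  m_wall <- in_ell(wall_inner)
  hu[m_wall] <- hu_organ                        # visceral background
  # seeded, non-overlapping visceral fat blobs fully inside the inner wall
  centers <- matrix(numeric(0), 0L, 2L)
  radii <- numeric(0)
  if (n_blobs > 0) {
    guard <- 2  # mm clearance from the wall and between blobs
    tries <- 0L
    while (length(radii) < n_blobs && tries < 10000L) {
      tries <- tries + 1L
      r <- stats::runif(1L, blob_radius_range[1L], blob_radius_range[2L])
      cx <- stats::runif(1L, -wall_inner[1L], wall_inner[1L])
      cy <- stats::runif(1L, -wall_inner[2L], wall_inner[2L])
      if ((cx / (wall_inner[1L] - r - guard))^2 +
          (cy / (wall_inner[2L] - r - guard))^2 > 1) next
      if (nrow(centers) &&
          any(sqrt((centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2) <
              radii + r + guard)) next
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
      hu[(gx - cx)^2 + (gy - cy)^2 <= r^2] <- hu_fat
    }
    if (length(radii) < n_blobs)
      stop("could not place ", n_blobs, " non-overlapping fat blobs")
  }
  wall_theta <- seq(0, 359, by = 1) * pi / 180
  inner_wall <- cbind(wall_inner[1L] * cos(wall_theta),
                      wall_inner[2L] * sin(wall_theta))
  truth <- list(
    sat_area = pi * (body[1L] * body[2L] - sat_inner[1L] * sat_inner[2L]),
    vat_area = sum(pi * radii^2),
    body_area = pi * body[1L] * body[2L],
    blob_centers = centers, blob_radii = radii)
  truth$tat_area <- truth$sat_area + truth$vat_area
  list(slice = hu_slice(hu, pixel_spacing = pixel_spacing,
                        body_mask = body_mask,
                        origin = c(x[1L], y[1L])),
       inner_wall = inner_wall, truth = truth)
}
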