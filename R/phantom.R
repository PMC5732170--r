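#' Specification of a synthetic thoracic CT phantom
#'
#' Describes the simulated scan: grid shape and spacing, the HU distribution
#' of normal lung parenchyma, and the burden of emphysema-like low
#' attenuation and subpleural fibrosis-like texture. The phantom is a
#' texture test-bed (two ellipsoidal lungs in soft tissue), not an
#' anatomical simulation.
#'
#' @param shape Integer length-3 grid size; each axis must be >= 32.
#' @param spacing Voxel spacing in mm (x, y, z), all > 0.
#' @param background_mean,background_sd Normal-lung HU distribution
#'   (defaults -850 and 40, typical aerated parenchyma).
#' @param emphysema_fraction Target fraction of lung voxels replaced by low
#'   attenuation blobs (mean about -980 HU), in \[0, 1\].
#' @param fibrosis_severity Severity of the subpleural fibrotic band in
#'   \[0, 1\]; controls the band depth (up to 8 mm at severity 1) holding
#'   ground-glass and reticular texture.
#' @param rng_seed Integer seed; all stochastic draws flow from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         background_mean = -850, background_sd = 40,
                         emphysema_fraction = 0, fibrosis_severity = 0,
                         rng_seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("shape must be three integers, each >= 32")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be positive on all axes")
  for (fr in c(emphysema_fraction, fibrosis_severity))
    if (!is.finite(fr) || fr < 0 || fr > 1)
      stop("fractions must lie in [0, 1]")
  structure(list(shape = shape, spacing = spacing,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 emphysema_fraction = emphysema_fraction,
                 fibrosis_severity = fibrosis_severity,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Generate a synthetic lung CT phantom
#'
#' Builds a soft-tissue volume containing two ellipsoidal lungs of normally
#' distributed parenchymal HU, optionally seeded with emphysema-like low
#' attenuation blobs and a subpleural fibrotic band of ground-glass and
#' reticular texture. Returns the volume with truth masks for lung,
#' emphysema and fibrosis, so downstream segmentation and parenchymal
#' scoring can be validated against known ground truth.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `lung_phantom` with elements `volume`
#'   ([ct_volume()]), `lung`, `emphysema`, `fibrosis` ([voxel_mask()]s) and
#'   the `spec`.
#' @examples
#' ph <- make_lung_phantom(phantom_spec(shape = c(32, 32, 32), rng_seed = 7))
#' mask_volume_cc(ph$lung)
#' @export
make_lung_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$rng_seed)
  d <- spec$shape; sp <- spec$spacing
  n <- prod(d)

  # soft tissue everywhere (>= 0 HU)
  vol <- array(pmax(stats::rnorm(n, 40, 15), 0), d)

  # two ellipsoidal lungs in physical coordinates
  gx <- (seq_len(d[1]) - 0.5) * sp[1]
  gy <- (seq_len(d[2]) - 0.5) * sp[2]
  gz <- (seq_len(d[3]) - 0.5) * sp[3]
  ext <- d * sp
  X <- array(rep(gx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(gy, each = d[1]), times = d[3]), d)
  Z <- array(rep(gz, each = d[1] * d[2]), d)
  ellipsoid <- function(cx, cy, cz, ax, ay, az)
    ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2 <= 1
  lung <- ellipsoid(0.30 * ext[1], 0.5 * ext[2], 0.5 * ext[3],
                    0.17 * ext[1], 0.34 * ext[2], 0.40 * ext[3]) |
          ellipsoid(0.70 * ext[1], 0.5 * ext[2], 0.5 * ext[3],
                    0.17 * ext[1], 0.34 * ext[2], 0.40 * ext[3])
  n_lung <- sum(lung)
  vol[lung] <- stats::rnorm(n_lung, spec$background_mean, spec$background_sd)

  # subpleural fibrotic band: depth grows with severity (max 8 mm)
  fibrosis <- array(FALSE, d)
  if (spec$fibrosis_severity > 0) {
    depth_mm <- 8 * spec$fibrosis_severity
    d2out <- edt_squared(!lung, sp)          # distance to nearest non-lung
    band <- lung & d2out <= depth_mm^2
    if (any(band)) {
      # inner half of the band reticular (high SD), outer half ground-glass
      inner <- band & d2out > (depth_mm / 2)^2
      outer <- band & !inner
      vol[outer] <- stats::rnorm(sum(outer), -480, 50)
      vol[inner] <- stats::rnorm(sum(inner), -500, 150)
      fibrosis <- band
    }
  }

  # emphysema: spherical low-attenuation blobs until the target voxel
  # fraction of the lung is covered
  emphysema <- array(FALSE, d)
  if (spec$emphysema_fraction > 0) {
    target <- spec$emphysema_fraction * n_lung
    host <- which(lung & !fibrosis)
    guard <- 0L
    while (sum(emphysema) < target && guard < 10000L) {
      guard <- guard + 1L
      ci <- arrayInd(sample(host, 1L), d)
      r_mm <- stats::runif(1, 1.5, 3.5)
      blob <- ((X - gx[ci[1]]) / r_mm)^2 + ((Y - gy[ci[2]]) / r_mm)^2 +
              ((Z - gz[ci[3]]) / r_mm)^2 <= 1
      emphysema <- emphysema | (blob & lung & !fibrosis)
    }
    ne <- sum(emphysema)
    vol[emphysema] <- stats::rnorm(ne, -980, 12)
  }

  structure(list(
    volume = ct_volume(vol, spacing = sp),
    lung = voxel_mask(lung, spacing = sp),
    emphysema = voxel_mask(emphysema, spacing = sp),
    fibrosis = voxel_mask(fibrosis, spacing = sp),
    spec = spec), class = "lung_phantom")
}

#' Specification of a synthetic part-solid nodule
#'
#' A spherical nodule split into an outer ground-glass compartment
#' (radiologic correlate of lepidic growth) and a solid core (invasive
#' component), in proportions set by `lepidic_fraction`.
#'
#' @param center Voxel index triple (1-based) of the nodule center.
#' @param radius_mm Nodule radius in mm (> 0).
#' @param lepidic_fraction Fraction of nodule volume given ground-glass
#'   texture, in \[0, 1\]. 1 is a pure ground-glass nodule, 0 pure solid.
#' @param solid_mean,solid_sd HU distribution of the solid core.
#' @param gg_mean,gg_sd HU distribution of the ground-glass compartment;
#'   `gg_mean` must be below `solid_mean`.
#' @return An object of class `nodule_spec`.
#' @export
nodule_spec <- function(center, radius_mm, lepidic_fraction = 0.5,
                        solid_mean = -50, solid_sd = 40,
                        gg_mean = -550, gg_sd = 60) {
  if (radius_mm <= 0) stop("radius_mm must be positive")
  if (lepidic_fraction < 0 || lepidic_fraction > 1)
    stop("lepidic_fraction must lie in [0, 1]")
  if (gg_mean >= solid_mean)
    stop("gg_mean must be below solid_mean")
  structure(list(center = as.integer(center), radius_mm = radius_mm,
                 lepidic_fraction = lepidic_fraction,
                 solid_mean = solid_mean, solid_sd = solid_sd,
                 gg_mean = gg_mean, gg_sd = gg_sd),
            class = "nodule_spec")
}

#' Implant a synthetic nodule into a phantom
#'
#' Carves an approximately spherical nodule (exact Euclidean ball on the
#' anisotropic grid) centered at `nodule$center`, assigns the outer
#' `lepidic_fraction` of its voxels ground-glass HU texture and the core
#' solid texture, and returns the modified volume plus the truth mask. The
#' mask is purely geometric: reruns with different seeds change only the HU
#' noise.
#'
#' @param volume A [ct_volume()].
#' @param lung Lung [voxel_mask()] on the same grid.
#' @param nodule A [nodule_spec()].
#' @param rng_seed Integer seed for the HU noise.
#' @return List with `volume` (new [ct_volume()]) and `mask`
#'   ([voxel_mask()] nodule truth).
#' @export
implant_nodule <- function(volume, lung, nodule, rng_seed = 1L) {
  stopifnot(inherits(volume, "ct_volume"), inherits(lung, "voxel_mask"),
            inherits(nodule, "nodule_spec"))
  check_same_geometry(volume, lung)
  d <- dim(volume$data); sp <- volume$spacing
  ctr <- check_in_bounds(nodule$center, d, "nodule center")
  if (!lung$data[ctr[1], ctr[2], ctr[3]]) stop("nodule center outside lung")
  # sphere must fit inside the grid in physical units
  ctr_mm <- (ctr - 0.5) * sp
  if (any(ctr_mm - nodule$radius_mm < 0) ||
      any(ctr_mm + nodule$radius_mm > d * sp))
    stop("nodule of radius ", nodule$radius_mm, " mm exceeds volume bounds")
  gx <- (seq_len(d[1]) - 0.5) * sp[1]
  gy <- (seq_len(d[2]) - 0.5) * sp[2]
  gz <- (seq_len(d[3]) - 0.5) * sp[3]
  D2 <- outer(outer((gx - ctr_mm[1])^2, (gy - ctr_mm[2])^2, `+`),
              (gz - ctr_mm[3])^2, `+`)
  mask <- D2 <= nodule$radius_mm^2
  if (!any(mask)) stop("nodule radius below voxel resolution")
  set.seed(as.integer(rng_seed))
  vol <- volume$data
  dist_in <- sqrt(D2[mask])
  # outer compartment = ground glass; split radius from the voxel-distance
  # quantile so the *voxel volume* fraction matches lepidic_fraction
  if (nodule$lepidic_fraction >= 1) {
    gg <- rep(TRUE, sum(mask))
  } else if (nodule$lepidic_fraction <= 0) {
    gg <- rep(FALSE, sum(mask))
  } else {
    r0 <- stats::quantile(dist_in, probs = 1 - nodule$lepidic_fraction,
                          names = FALSE)
    gg <- dist_in > r0
  }
  vals <- numeric(sum(mask))
  vals[gg] <- stats::rnorm(sum(gg), nodule$gg_mean, nodule$gg_sd)
  vals[!gg] <- stats::rnorm(sum(!gg), nodule$solid_mean, nodule$solid_sd)
  vol[mask] <- vals
  list(volume = ct_volume(vol, spacing = sp, origin = volume$origin),
       mask = voxel_mask(mask, spacing = sp, origin = volume$origin))
}
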