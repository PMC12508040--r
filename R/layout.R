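# Ground-truth emitter layouts: DNA-origami structure presets placed at
# random positions and orientations in the field of view.

LAYOUT_DESIGNS <- c("2LS", "8HB", "dimer_sensor", "single")

# Site tables in structure-local coordinates (nm), one row per site.
layout_preset_sites <- function(design, two_dyes = FALSE,
                                dimer_geometry = c(0, 260, 340, 600),
                                site_extent = 28) {
  switch(design,
    "2LS" = {
      x <- if (two_dyes) c(0, 22) else 0
      data.frame(x = x, y = 0, type = "fixed_dye", role = "dye",
                 extent = 0)
    },
    "8HB" = data.frame(x = c(-128, 128), y = 0, type = "docking",
                       role = "docking", extent = site_extent),
    "dimer_sensor" = {
      g <- dimer_geometry - mean(range(dimer_geometry))
      data.frame(x = g, y = 0, type = "docking",
                 role = c("control", "control", "control", "target"),
                 extent = site_extent)
    },
    "single" = data.frame(x = 0, y = 0, type = "docking", role = "docking",
                          extent = site_extent)
  )
}

#' Generate a ground-truth emitter layout
#'
#' Places DNA-origami structures of a given design uniformly at random (with
#' random in-plane rotation) in a rectangular field, optionally enforcing a
#' minimum separation between structure centers, and adds always-on fiducial
#' markers.
#'
#' Designs: `"2LS"` (fixed dye standard, optional second dye 22 nm away),
#' `"8HB"` (nanoruler with two docking sites 256 nm apart, 28 nm site
#' extent), `"dimer_sensor"` (collinear ~600 nm RNA sensor; three control
#' sites plus one target site whose presence is Bernoulli with probability
#' `target_occupancy`), `"single"` (one docking site per structure).
#'
#' @param design preset name.
#' @param field_size field of view, nm; scalar or length-2 `(x, y)`.
#' @param density structures per square micrometer (>= 0).
#' @param seed integer seed; identical seeds give identical layouts.
#' @param n_fiducials number of always-on fiducial markers to scatter.
#' @param min_separation_nm minimum distance between structure centers, nm.
#' @param two_dyes for `"2LS"`: include the second fixed dye 22 nm away.
#' @param target_occupancy for `"dimer_sensor"`: probability that the target
#'   site is occupied (RNA captured).
#' @param dimer_geometry for `"dimer_sensor"`: site positions along the
#'   sensor axis, nm.
#' @param site_extent docking-site extent (diameter of the region over which
#'   binding positions jitter), nm.
#' @param edge_margin_nm extra keep-out border inside the field so that no
#'   structure sits where its PSF (and fitting ROI) would be clipped.
#' @return an `emitter_layout`: a data.frame with columns `structure`,
#'   `site`, `x`, `y`, `type`, `role`, `extent` and attributes `field_size`,
#'   `design`.
#' @export
make_layout <- function(design, field_size, density, seed = NULL,
                        n_fiducials = 0, min_separation_nm = 0,
                        two_dyes = FALSE, target_occupancy = 1,
                        dimer_geometry = c(0, 260, 340, 600),
                        site_extent = 28, edge_margin_nm = 0) {
  design <- match.arg(design, LAYOUT_DESIGNS)
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  if (density < 0) stop("density must be >= 0")
  proto <- layout_preset_sites(design, two_dyes, dimer_geometry, site_extent)
  r_struct <- max(sqrt(proto$x^2 + proto$y^2) + proto$extent / 2) +
    edge_margin_nm
  area_um2 <- prod(field_size) / 1e6
  n_struct <- round(density * area_um2)
  if (n_struct > 0 && any(field_size < 2 * r_struct)) {
    stop("field too small to hold one structure of this design")
  }
  with_seed(seed, {
    # fiducials are placed first: they must not fall into one another's
    # brightest-wins candidate exclusion box nor merge at the diffraction
    # limit, and they sit away from the field border so slow stage drift
    # cannot carry them out during long acquisitions; structures are then
    # placed around them
    fxy <- matrix(numeric(0), 0, 2)
    if (n_fiducials > 0) {
      fid_fid_sep <- max(min_separation_nm, 5000)
      fid_margin <- pmin(pmax(0.05 * field_size, edge_margin_nm, 4000),
                         0.25 * field_size)
      tries <- 0
      while (nrow(fxy) < n_fiducials) {
        p <- stats::runif(2, fid_margin, field_size - fid_margin)
        ok <- nrow(fxy) == 0 ||
          min(sqrt(colSums((t(fxy) - p)^2))) >= fid_fid_sep
        if (ok) fxy <- rbind(fxy, p)
        tries <- tries + 1
        if (tries > 10000 * n_fiducials) {
          stop("could not place fiducials at the required separation")
        }
      }
    }
    # Chebyshev-safe: a structure within box_px of a fiducial would be
    # suppressed by the brightest-wins candidate exclusion
    fid_struct_sep <- max(min_separation_nm, 4300)
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < n_struct) {
      p <- stats::runif(2, min = r_struct, max = field_size - r_struct)
      ok <- (nrow(centers) == 0 || min_separation_nm <= 0 ||
               min(sqrt(colSums((t(centers) - p)^2))) >= min_separation_nm) &&
        (nrow(fxy) == 0 ||
           min(sqrt(colSums((t(fxy) - p)^2))) >= fid_struct_sep)
      if (ok) centers <- rbind(centers, p)
      tries <- tries + 1
      if (tries > 10000 * max(1, n_struct)) {
        stop("could not place structures at the requested density/separation")
      }
    }
    rows <- list()
    site_id <- 0L
    for (s in seq_len(n_struct)) {
      th <- stats::runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sites <- proto
      if (design == "dimer_sensor" &&
          stats::runif(1) > target_occupancy) {
        sites <- sites[sites$role != "target", ]
      }
      xy <- cbind(sites$x, sites$y) %*% t(rot)
      rows[[s]] <- data.frame(
        structure = s, site = site_id + seq_len(nrow(sites)),
        x = xy[, 1] + centers[s, 1], y = xy[, 2] + centers[s, 2],
        type = sites$type, role = sites$role, extent = sites$extent)
      site_id <- site_id + nrow(sites)
    }
    fid <- NULL
    if (n_fiducials > 0) {
      fid <- data.frame(structure = NA_integer_,
                        site = site_id + seq_len(n_fiducials),
                        x = fxy[, 1], y = fxy[, 2], type = "fiducial",
                        role = "fiducial", extent = 0)
    }
    out <- do.call(rbind, c(rows, list(fid)))
    if (is.null(out)) {
      out <- data.frame(structure = integer(), site = integer(),
                        x = numeric(), y = numeric(), type = character(),
                        role = character(), extent = numeric())
    }
    rownames(out) <- NULL
    structure(out, field_size = field_size, design = design,
              class = c("emitter_layout", "data.frame"))
  })
}
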