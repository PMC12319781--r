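# Optode geometry: modules, headset layouts, channel enumeration.
#
# A module is planar: 3 dual-wavelength sources on a circle (default 13.5 mm
# radius, 120 deg apart) and 6 detectors, one 37 deg on either side of each
# source, plus an optional reference detector at the module center that
# monitors the instrument response function (IRF). Headset curvature is
# handled by rigid per-module placements; the module plane itself is flat.
# Angles are measured counterclockwise from the module-local x-axis.

#' Construct a planar optical module
#'
#' @param module_id integer identifier (0-based by convention).
#' @param radius_mm radius of the circle carrying sources and detectors.
#' @param source_angles_deg angles of the source exit points.
#' @param detector_offset_deg angular offset of the detectors on either side
#'   of each source; must satisfy `0 <= offset < 60` so detector positions
#'   stay distinct for the default 120 deg source spacing.
#' @param center_irf_detector place a reference IRF detector at the center.
#' @return An object of class `optical_module`: a list with the geometry
#'   parameters and an `optodes` data frame (`id`, `kind`, `angle_deg`,
#'   `x_mm`, `y_mm`).
#' @export
optical_module <- function(module_id = 0L,
                           radius_mm = 13.5,
                           source_angles_deg = c(0, 120, 240),
                           detector_offset_deg = 37,
                           center_irf_detector = TRUE) {
  .check_num(radius_mm, "radius_mm", lower = 1e-9)
  .check_num(detector_offset_deg, "detector_offset_deg", lower = 0)
  if (detector_offset_deg >= 60)
    stop("`detector_offset_deg` must be < 60 degrees", call. = FALSE)
  if (!is.numeric(source_angles_deg) || any(!is.finite(source_angles_deg)))
    stop("`source_angles_deg` must be finite numeric", call. = FALSE)

  src <- sort(source_angles_deg %% 360)
  det <- sort(c(src - detector_offset_deg, src + detector_offset_deg) %% 360)
  ang2xy <- function(a) cbind(radius_mm * cos(a * pi / 180),
                              radius_mm * sin(a * pi / 180))
  optodes <- rbind(
    data.frame(id = sprintf("S%d", seq_along(src) - 1L), kind = "source",
               angle_deg = src, ang2xy(src)),
    data.frame(id = sprintf("D%d", seq_along(det) - 1L), kind = "detector",
               angle_deg = det, ang2xy(det))
  )
  names(optodes)[4:5] <- c("x_mm", "y_mm")
  if (center_irf_detector) {
    optodes <- rbind(optodes, data.frame(
      id = "DIRF", kind = "irf_detector", angle_deg = NA_real_,
      x_mm = 0, y_mm = 0))
  }
  structure(list(module_id = as.integer(module_id),
                 radius_mm = radius_mm,
                 source_angles_deg = src,
                 detector_offset_deg = detector_offset_deg,
                 center_irf_detector = center_irf_detector,
                 optodes = optodes),
            class = "optical_module")
}

#' @export
print.optical_module <- function(x, ...) {
  cat(sprintf("<optical_module %d> r = %.1f mm, %d sources, %d detectors%s\n",
              x$module_id, x$radius_mm,
              sum(x$optodes$kind == "source"),
              sum(x$optodes$kind == "detector"),
              if (x$center_irf_detector) " + IRF detector" else ""))
  invisible(x)
}

#' Chord distance between two points on a circle
#'
#' `2 r sin(delta/2)`; symmetric in the sign of the angle. This realizes the
#' intra-module source-detector separations of the default module geometry.
#'
#' @param radius_mm circle radius (>= 0)
#' @param delta_angle_deg angular separation in degrees
#' @return chord length in mm
#' @export
chord_distance <- function(radius_mm, delta_angle_deg) {
  .check_num(radius_mm, "radius_mm", lower = 0)
  if (!is.numeric(delta_angle_deg) || any(!is.finite(delta_angle_deg)))
    stop("`delta_angle_deg` must be finite numeric", call. = FALSE)
  2 * radius_mm * abs(sin(delta_angle_deg * pi / 360))
}

# quaternion (w, x, y, z) -> 3x3 rotation matrix
.quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Place a module in the headset frame
#'
#' @param module an [optical_module()]
#' @param position_mm 3-vector, module center in the common frame.
#' @param quaternion unit quaternion `(w, x, y, z)` rotating module-local
#'   coordinates (module plane = local xy, outward normal = local +z) into the
#'   common frame. Default: identity (module lies in the z = 0 plane).
#' @return a `module_placement` object
#' @export
module_placement <- function(module, position_mm = c(0, 0, 0),
                             quaternion = c(1, 0, 0, 0)) {
  stopifnot(inherits(module, "optical_module"),
            length(position_mm) == 3, all(is.finite(position_mm)),
            length(quaternion) == 4, all(is.finite(quaternion)))
  structure(list(module = module,
                 position_mm = as.numeric(position_mm),
                 quaternion = as.numeric(quaternion / sqrt(sum(quaternion^2)))),
            class = "module_placement")
}

#' Assemble a headset layout from placed modules
#'
#' @param placements list of [module_placement()] objects (at most 40).
#' @param surface_model free-form description of the medium surface the
#'   optodes touch (e.g. `"slab_z0"`); recorded, not interpreted.
#' @return `headset_layout` object carrying an `optodes` data frame in the
#'   common frame (`module`, `id`, `kind`, `x_mm`, `y_mm`, `z_mm`).
#' @export
headset_layout <- function(placements, surface_model = "slab_z0") {
  if (inherits(placements, "module_placement")) placements <- list(placements)
  if (inherits(placements, "optical_module"))
    placements <- list(module_placement(placements))
  placements <- lapply(placements, function(p) {
    if (inherits(p, "optical_module")) module_placement(p) else p
  })
  stopifnot(all(vapply(placements, inherits, TRUE, "module_placement")))
  if (length(placements) > 40)
    stop("a headset layout supports at most 40 modules", call. = FALSE)
  ids <- vapply(placements, function(p) p$module$module_id, integer(1))
  if (anyDuplicated(ids))
    stop("duplicate module_id in layout", call. = FALSE)

  optodes <- do.call(rbind, lapply(placements, function(p) {
    m <- p$module
    local <- rbind(t(cbind(m$optodes$x_mm, m$optodes$y_mm, 0)))
    R <- .quat_to_matrix(p$quaternion)
    world <- t(R %*% local + p$position_mm)
    data.frame(module = m$module_id, id = m$optodes$id, kind = m$optodes$kind,
               x_mm = world[, 1], y_mm = world[, 2], z_mm = world[, 3])
  }))
  structure(list(placements = placements, surface_model = surface_model,
                 optodes = optodes),
            class = "headset_layout")
}

#' Enumerate source-detector channels of a layout
#'
#' All source-detector pairs (within and across modules) with Euclidean
#' separation at most `max_sds_mm`, duplicated per wavelength; IRF detectors
#' are excluded. Dual-wavelength channels share geometry.
#'
#' @param layout a [headset_layout()] (or a bare [optical_module()], placed at
#'   the origin).
#' @param max_sds_mm separation threshold in mm.
#' @param wavelengths_nm wavelengths to enumerate (default 690 and 905 nm).
#' @return data frame with columns `source`, `detector`, `source_module`,
#'   `detector_module`, `wavelength_nm`, `sds_mm`, and the midpoint
#'   coordinates `mid_x_mm`, `mid_y_mm`, `mid_z_mm`.
#' @export
enumerate_channels <- function(layout, max_sds_mm = 50,
                               wavelengths_nm = c(690, 905)) {
  if (inherits(layout, "optical_module")) layout <- headset_layout(layout)
  stopifnot(inherits(layout, "headset_layout"))
  .check_num(max_sds_mm, "max_sds_mm", lower = 0)
  opt <- layout$optodes
  src <- opt[opt$kind == "source", , drop = FALSE]
  det <- opt[opt$kind == "detector", , drop = FALSE]
  if (nrow(src) == 0L || nrow(det) == 0L) return(.empty_channels())

  # exhaustive pairwise distances
  dx <- outer(src$x_mm, det$x_mm, "-")
  dy <- outer(src$y_mm, det$y_mm, "-")
  dz <- outer(src$z_mm, det$z_mm, "-")
  dd <- sqrt(dx^2 + dy^2 + dz^2)
  keep <- which(dd <= max_sds_mm, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(.empty_channels())
  i <- keep[, 1]; j <- keep[, 2]
  base <- data.frame(
    source = paste0(src$module[i], ":", src$id[i]),
    detector = paste0(det$module[j], ":", det$id[j]),
    source_module = src$module[i],
    detector_module = det$module[j],
    sds_mm = dd[keep],
    mid_x_mm = (src$x_mm[i] + det$x_mm[j]) / 2,
    mid_y_mm = (src$y_mm[i] + det$y_mm[j]) / 2,
    mid_z_mm = (src$z_mm[i] + det$z_mm[j]) / 2,
    src_x = src$x_mm[i], src_y = src$y_mm[i], src_z = src$z_mm[i],
    det_x = det$x_mm[j], det_y = det$y_mm[j], det_z = det$z_mm[j])
  out <- do.call(rbind, lapply(wavelengths_nm, function(w) {
    cbind(base[, 1:4], wavelength_nm = w,
          base[, 5:ncol(base)])
  }))
  out <- out[order(out$source, out$detector, out$wavelength_nm), ]
  rownames(out) <- NULL
  out
}

.empty_channels <- function() {
  data.frame(source = character(), detector = character(),
             source_module = integer(), detector_module = integer(),
             wavelength_nm = numeric(), sds_mm = numeric(),
             mid_x_mm = numeric(), mid_y_mm = numeric(), mid_z_mm = numeric())
}

#' Serialize a headset layout to JSON
#'
#' @param layout a [headset_layout()]
#' @param path file path; if `NULL`, the JSON string is returned.
#' @export
write_layout_json <- function(layout, path = NULL) {
  stopifnot(inherits(layout, "headset_layout"))
  obj <- list(
    surface_model = layout$surface_model,
    modules = lapply(layout$placements, function(p) list(
      module_id = p$module$module_id,
      radius_mm = p$module$radius_mm,
      source_angles_deg = p$module$source_angles_deg,
      detector_offset_deg = p$module$detector_offset_deg,
      center_irf_detector = p$module$center_irf_detector,
      position_mm = p$position_mm,
      quaternion = p$quaternion)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a headset layout from JSON written by [write_layout_json()]
#' @param path file path or JSON string
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  placements <- lapply(obj$modules, function(m) {
    module_placement(
      optical_module(module_id = m$module_id, radius_mm = m$radius_mm,
                     source_angles_deg = unlist(m$source_angles_deg),
                     detector_offset_deg = m$detector_offset_deg,
                     center_irf_detector = isTRUE(m$center_irf_detector)),
      position_mm = unlist(m$position_mm),
      quaternion = unlist(m$quaternion))
  })
  headset_layout(placements, surface_model = obj$surface_model)
}

#' Illustrative 40-module whole-head layout
#'
#' A demonstration layout of 40 modules tiled on a sphere of the given radius
#' by a Fibonacci-lattice rule, each module's plane tangent to the sphere.
#' Individual module placements of any physical headset are not reproduced;
#' this layout exists to exercise whole-head channel enumeration and is
#' illustrative only.
#'
#' @param n_modules number of modules (<= 40)
#' @param head_radius_mm sphere radius
#' @export
demo_headset_layout <- function(n_modules = 40, head_radius_mm = 90) {
  stopifnot(n_modules >= 1, n_modules <= 40)
  golden <- pi * (3 - sqrt(5))
  placements <- lapply(seq_len(n_modules), function(k) {
    # upper hemisphere cap, avoid the pole-adjacent crowding
    zf <- 1 - (k - 0.5) / n_modules * 0.85
    r <- sqrt(max(0, 1 - zf^2))
    th <- golden * (k - 1)
    nrm <- c(r * cos(th), r * sin(th), zf)
    pos <- head_radius_mm * nrm
    # quaternion rotating local +z onto the outward normal
    zaxis <- c(0, 0, 1)
    vcr <- c(zaxis[2] * nrm[3] - zaxis[3] * nrm[2],
             zaxis[3] * nrm[1] - zaxis[1] * nrm[3],
             zaxis[1] * nrm[2] - zaxis[2] * nrm[1])
    dt <- sum(zaxis * nrm)
    q <- if (dt > 1 - 1e-12) c(1, 0, 0, 0) else c(1 + dt, vcr)
    module_placement(optical_module(module_id = k - 1L), position_mm = pos,
                     quaternion = q / sqrt(sum(q^2)))
  })
  headset_layout(placements, surface_model = "sphere_demo")
}
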