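#' The nine femoro-tibial angle definitions
#'
#' Femoral and tibial anatomic axes each have four published construction
#' variants (`Fem1`--`Fem4`, `Tib1`--`Tib4`); nine femoral/tibial pairings of
#' these are in use for the femoro-tibial angle. `FTA_COMBINATIONS` lists
#' them in the package's canonical reporting order.
#'
#' @format character vector of 9 labels, e.g. `"Fem2+Tib1"`.
#' @export
FTA_COMBINATIONS <- c("Fem1+Tib1", "Fem1+Tib3", "Fem1+Tib4",
                      "Fem2+Tib1", "Fem2+Tib2", "Fem2+Tib3", "Fem2+Tib4",
                      "Fem3+Tib3", "Fem4+Tib4")

#' Two-point bone axis
#'
#' @param p1,p2 length-2 numeric `(x, y)` points; must differ.
#' @param label axis label, e.g. `"Fem2"`.
#' @return an object of class `bone_axis`.
#' @export
bone_axis <- function(p1, p2, label = "") {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2 || length(p2) != 2 || !all(is.finite(c(p1, p2)))) {
    stop("axis endpoints must be finite (x, y) pairs", call. = FALSE)
  }
  if (sqrt(sum((p1 - p2)^2)) < 1e-9) {
    stop("degenerate axis: endpoints coincide (", label, ")", call. = FALSE)
  }
  structure(list(p1 = p1, p2 = p2, label = label), class = "bone_axis")
}

#' Joint-line reference width of the femur or tibia
#'
#' The distal-femoral condyle width, or proximal-tibial plateau width: the
#' Euclidean distance between the most-medial and most-lateral landmarks of
#' the condyle (femur) or plateau (tibia) region. Because standard knee
#' radiographs carry no absolute calibration, this width is the pipeline's
#' internal length scale: mid-shaft measurement levels are placed at fixed
#' multiples of it (see [shaft_level_distance()]).
#'
#' @param knee a [knee_landmark_set()].
#' @param bone `"femur"` or `"tibia"`.
#' @return width in pixels (strictly positive).
#' @export
reference_width <- function(knee, bone = c("femur", "tibia")) {
  bone <- match.arg(bone)
  region <- if (bone == "femur") "fem_condyles" else "tib_plateau"
  pts <- region_points(knee, region)
  i_med <- which.max(pts[, 1])   # canonical orientation: medial = +x
  i_lat <- which.min(pts[, 1])
  w <- sqrt(sum((pts[i_med, ] - pts[i_lat, ])^2))
  if (w < 1e-6) {
    stop("degenerate ", region, " region: width is ~0", call. = FALSE)
  }
  w
}

#' Mid-shaft measurement level from the joint reference point
#'
#' Standard knee radiographs are uncalibrated, so the "approximately 10 cm
#' from the joint line" placement of the mid-shaft points is operationalised
#' as a fixed multiple of the joint-line reference width: 1.52 x condyle
#' width for the femur (measured proximally from the femoral notch) and
#' 1.42 x plateau width for the tibia (measured distally from the base of
#' the tibial spines).
#'
#' @inheritParams reference_width
#' @param ratio_femur,ratio_tibia width-to-level ratios.
#' @return level in pixels along the shaft from the joint reference point.
#' @export
shaft_level_distance <- function(knee, bone = c("femur", "tibia"),
                                 ratio_femur = 1.52, ratio_tibia = 1.42) {
  bone <- match.arg(bone)
  ratio <- if (bone == "femur") ratio_femur else ratio_tibia
  stopifnot(ratio > 0)
  ratio * reference_width(knee, bone)
}

# joint reference point from which shaft levels are measured
joint_reference_point <- function(knee, bone) {
  if (bone == "femur") {
    drop(region_points(knee, "fem_notch_apex"))
  } else {
    colMeans(region_points(knee, "tib_spine_base"))
  }
}

# intersections of the line {origin + t * dir} with a piecewise-linear
# polyline; returns data.frame(t, x, y) (possibly empty)
line_polyline_intersections <- function(origin, dir, poly) {
  n <- nrow(poly)
  out <- NULL
  for (i in seq_len(n - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    e <- b - a
    det <- dir[1] * (-e[2]) - dir[2] * (-e[1])
    if (abs(det) < 1e-12) next
    rhs <- a - origin
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / det
    s <- (dir[1] * rhs[2] - dir[2] * rhs[1]) / det
    if (s >= -1e-9 && s <= 1 + 1e-9) {
      p <- origin + t * dir
      out <- rbind(out, c(t, p))
    }
  }
  if (is.null(out)) {
    data.frame(t = numeric(), x = numeric(), y = numeric())
  } else {
    stats::setNames(as.data.frame(out), c("t", "x", "y"))
  }
}

#' Inscribed-circle mid-shaft point
#'
#' Locates the shaft center at a given level as the center of a circle
#' touching the medial and lateral cortical outlines. The shaft direction is
#' initialised from the midpoints of the first and last cortical landmark
#' pairs; at each iteration the perpendicular to the current direction,
#' placed `level` pixels from the joint reference point (femoral notch apex,
#' or tibial spine base midpoint), is intersected with both cortical
#' polylines (piecewise-linear interpolation), the circle center is the
#' midpoint of the two intersections and its radius half their gap, and the
#' direction is re-estimated from the joint reference towards the center.
#' Iteration stops when the center moves less than `tol` (fixed point), or
#' errors after `max_iter` iterations reporting the last residual.
#'
#' @inheritParams reference_width
#' @param level signed distance (pixels) of the measurement level from the
#'   joint reference point, measured along the shaft (proximally for the
#'   femur, distally for the tibia).
#' @param tol convergence tolerance on the center position, pixels.
#' @param max_iter maximum fixed-point iterations.
#' @return an object of class `shaft_circle`: `center`, `radius`, `level`,
#'   plus the iteration count.
#' @export
midshaft_point <- function(knee, bone = c("femur", "tibia"), level,
                           tol = 1e-6, max_iter = 50L) {
  bone <- match.arg(bone)
  stopifnot(is.numeric(level), length(level) == 1, level > 0)
  med <- region_points(knee, paste0(substr(bone, 1, 3), "_shaft_medial"))
  lat <- region_points(knee, paste0(substr(bone, 1, 3), "_shaft_lateral"))
  ref <- joint_reference_point(knee, bone)

  m1 <- (med[1, ] + lat[1, ]) / 2
  m2 <- (med[nrow(med), ] + lat[nrow(lat), ]) / 2
  # point away from the joint: pick the endpoint-midpoint farther from ref
  if (sum((m1 - ref)^2) > sum((m2 - ref)^2)) {
    u <- m1 - m2
  } else {
    u <- m2 - m1
  }
  u <- u / sqrt(sum(u^2))

  center <- ref + level * u
  for (it in seq_len(max_iter)) {
    q <- ref + level * u
    v <- c(-u[2], u[1])
    hit_m <- line_polyline_intersections(q, v, med)
    hit_l <- line_polyline_intersections(q, v, lat)
    if (nrow(hit_m) == 0 || nrow(hit_l) == 0) {
      stop(sprintf(
        "mid-shaft level %.1f px lies outside the landmarked %s cortical extent",
        level, bone), call. = FALSE)
    }
    pm <- unlist(hit_m[which.min(abs(hit_m$t)), c("x", "y")])
    pl <- unlist(hit_l[which.min(abs(hit_l$t)), c("x", "y")])
    new_center <- (pm + pl) / 2
    radius <- sqrt(sum((pm - pl)^2)) / 2
    shift <- sqrt(sum((new_center - center)^2))
    center <- new_center
    if (shift < tol && it > 1) {
      return(structure(list(center = unname(center), radius = radius,
                            level = level, iterations = it),
                       class = "shaft_circle"))
    }
    d <- center - ref
    u <- d / sqrt(sum(d^2))
  }
  stop(sprintf("mid-shaft circle did not converge in %d iterations (last residual %.3g px)",
               max_iter, shift), call. = FALSE)
}

#' @export
print.shaft_circle <- function(x, ...) {
  cat(sprintf("<shaft_circle> center (%.2f, %.2f), radius %.2f px, level %.1f px (%d iterations)\n",
              x$center[1], x$center[2], x$radius, x$level, x$iterations))
  invisible(x)
}

#' Construct a femoral or tibial anatomic axis under a named definition
#'
#' Resolves one of the eight axis variants to its two defining points:
#' \describe{
#'   \item{Fem1}{femoral mid-shaft at 1.52 x condyle width proximal of the
#'     notch + femoral mid-shaft at the meta-/epiphysis transition level.}
#'   \item{Fem2}{femoral mid-shaft + center of the femoral notch.}
#'   \item{Fem3}{femoral mid-shaft + base of the tibial spines.}
#'   \item{Fem4}{femoral mid-shaft + middle of the tibial plateau.}
#'   \item{Tib1}{tibial mid-shaft at 1.42 x plateau width distal of the
#'     spine base + tibial mid-shaft at the meta-/epiphysis transition.}
#'   \item{Tib2}{tibial mid-shaft + center of the femoral notch.}
#'   \item{Tib3}{tibial mid-shaft + base of the tibial spines.}
#'   \item{Tib4}{tibial mid-shaft + middle of the tibial plateau.}
#' }
#' The meta-/epiphysis transition level ("approximately 4 cm from the joint
#' line", vs 10 cm for the main mid-shaft point) is `metaphysis_fraction`
#' (default 0.4) of the main level, i.e. 0.608 x width for the femur and
#' 0.568 x width for the tibia.
#'
#' @inheritParams shaft_level_distance
#' @param definition axis label `"Fem1"`..`"Fem4"`, `"Tib1"`..`"Tib4"`.
#' @param metaphysis_fraction fraction of the main shaft level at which the
#'   meta-/epiphysis transition point is placed.
#' @return a [bone_axis()]; `p1` is the far (shaft) point, `p2` the
#'   joint-side point.
#' @export
resolve_axis <- function(knee, definition,
                         ratio_femur = 1.52, ratio_tibia = 1.42,
                         metaphysis_fraction = 0.4) {
  stopifnot(metaphysis_fraction > 0, metaphysis_fraction < 1)
  if (!grepl("^(Fem|Tib)[1-4]$", definition)) {
    stop("unknown axis definition: ", definition, call. = FALSE)
  }
  bone <- if (startsWith(definition, "Fem")) "femur" else "tibia"
  variant <- as.integer(substr(definition, 4, 4))
  level <- shaft_level_distance(knee, bone, ratio_femur, ratio_tibia)
  p1 <- midshaft_point(knee, bone, level)$center
  p2 <- switch(variant,
    midshaft_point(knee, bone, metaphysis_fraction * level)$center,
    drop(region_points(knee, "fem_notch_apex")),
    colMeans(region_points(knee, "tib_spine_base")),
    plateau_midpoint(knee))
  bone_axis(p1, p2, label = definition)
}

# middle of the tibial plateau: midpoint of the most-medial and most-lateral
# plateau margin landmarks
plateau_midpoint <- function(knee) {
  pts <- region_points(knee, "tib_plateau")
  (pts[which.max(pts[, 1]), ] + pts[which.min(pts[, 1]), ]) / 2
}

#' Signed knee-alignment angle between a femoral and a tibial axis
#'
#' Both axes are oriented distally-to-proximally (towards decreasing image
#' y); the angle is the deviation from collinearity of the two oriented
#' axes, i.e. 180 degrees minus their included angle, signed by the
#' varus/valgus convention: negative when the distal tibia deviates medially
#' relative to the femoral axis (varus, bow-legged), positive for valgus.
#' 0 degrees is a perfectly straight leg. In canonical right-knee orientation
#' (medial = +x) the sign is the plane angle from the femoral to the tibial
#' direction; inputs from unmirrored left-side images can be handled by
#' passing `side = "left"`, which flips the sign.
#'
#' @param femoral,tibial [bone_axis()] objects.
#' @param side `"right"` if the axes are in canonical (right/mirrored)
#'   orientation -- the default for everything loaded through the package
#'   readers -- `"left"` for raw left-side coordinates.
#' @return signed angle in degrees. Values beyond 45 degrees in magnitude
#'   trigger a warning (implausible anatomy).
#' @export
signed_angle <- function(femoral, tibial, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(femoral, "bone_axis"), inherits(tibial, "bone_axis"))
  df <- axis_up_direction(femoral)
  dt <- axis_up_direction(tibial)
  theta <- atan2(df[1] * dt[2] - df[2] * dt[1], sum(df * dt)) * 180 / pi
  if (side == "left") theta <- -theta
  if (is.finite(theta) && abs(theta) > 45) {
    warning(sprintf("angle %.1f deg exceeds 45 deg: implausible anatomy", theta))
  }
  theta
}

# unit direction of an axis oriented distal -> proximal (towards smaller y)
axis_up_direction <- function(axis) {
  d <- axis$p2 - axis$p1
  if (d[2] > 0 || (d[2] == 0 && d[1] < 0)) d <- -d
  d / sqrt(sum(d^2))
}

#' Measure the femoro-tibial angle under all requested definitions
#'
#' Runs the nine standard femoral/tibial axis pairings (see
#' [FTA_COMBINATIONS]) on one knee landmark set. A definition that fails
#' (e.g. a mid-shaft level outside the landmarked extent) is reported with
#' its error in the `status` column without aborting the others.
#'
#' @inheritParams resolve_axis
#' @param combinations subset of [FTA_COMBINATIONS] to measure.
#' @return data frame with columns `case_id`, `definition`, `value_deg`
#'   (varus negative), `status` (`"ok"` or the error message).
#' @export
fta_battery <- function(knee, combinations = FTA_COMBINATIONS,
                        ratio_femur = 1.52, ratio_tibia = 1.42,
                        metaphysis_fraction = 0.4) {
  stopifnot(all(combinations %in% FTA_COMBINATIONS))
  axes <- new.env(parent = emptyenv())
  get_axis <- function(label) {
    if (!exists(label, envir = axes, inherits = FALSE)) {
      assign(label,
             tryCatch(
               resolve_axis(knee, label, ratio_femur, ratio_tibia, metaphysis_fraction),
               error = function(e) e),
             envir = axes)
    }
    get(label, envir = axes, inherits = FALSE)
  }
  out <- data.frame(case_id = rep(knee$case_id, length(combinations)),
                    definition = combinations,
                    value_deg = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_along(combinations)) {
    parts <- strsplit(combinations[i], "+", fixed = TRUE)[[1]]
    fem <- get_axis(parts[1]); tib <- get_axis(parts[2])
    if (inherits(fem, "error")) {
      out$status[i] <- paste0(parts[1], ": ", conditionMessage(fem))
    } else if (inherits(tib, "error")) {
      out$status[i] <- paste0(parts[2], ": ", conditionMessage(tib))
    } else {
      val <- tryCatch(signed_angle(fem, tib), error = function(e) e)
      if (inherits(val, "error")) {
        out$status[i] <- conditionMessage(val)
      } else {
        out$value_deg[i] <- val
      }
    }
  }
  out
}

#' Gold-standard hip-knee-ankle angle from a full-limb radiograph
#'
#' The mechanical HKAA: signed angle between the femoral mechanical axis
#' (femoral head center to femoral notch center) and the tibial mechanical
#' axis (tibial spine base to ankle center), same varus-negative sign
#' convention as [signed_angle()].
#'
#' @param limb a [full_limb_set()].
#' @param side see [signed_angle()].
#' @return signed angle in degrees.
#' @export
hkaa <- function(limb, side = c("right", "left")) {
  stopifnot(inherits(limb, "full_limb_set"))
  p <- limb$points
  fem <- bone_axis(p["femoral_notch_center", ], p["femoral_head_center", ], "HKAA-femur")
  tib <- bone_axis(p["ankle_center", ], p["tibial_spine_base", ], "HKAA-tibia")
  signed_angle(fem, tib, side = side)
}
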