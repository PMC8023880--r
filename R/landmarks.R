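#' Knee landmark sets
#'
#' A `knee_landmark_set` holds the ordered 2-D landmark outline of one
#' standard AP knee radiograph (distal femur, patella, proximal tibia),
#' validated against a [knee_schema()]. Coordinates follow the image
#' convention: x increases rightward, y increases downward, units are pixels
#' (no physical calibration is assumed). Sets are stored in canonical
#' right-knee orientation, in which the anatomical medial side lies towards
#' +x; left knees are mirrored on load (see [read_landmark_file()]) so that
#' one varus/valgus sign convention holds downstream.
#'
#' @param case_id case identifier.
#' @param side `"left"` or `"right"`; recorded as metadata. The points passed
#'   to this constructor must already be in canonical orientation.
#' @param points numeric matrix (n x 2) of landmark coordinates in schema
#'   order.
#' @param schema the [knee_schema()] the points follow.
#' @return an object of class `knee_landmark_set`.
#' @export
knee_landmark_set <- function(case_id, side = c("right", "left"), points,
                              schema = default_knee_schema()) {
  side <- match.arg(side)
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must be an n x 2 matrix", call. = FALSE)
  storage.mode(points) <- "double"
  n_expected <- schema_n_points(schema)
  if (nrow(points) != n_expected) {
    stop(sprintf("schema mismatch: schema '%s' declares %d points, found %d",
                 schema$name, n_expected, nrow(points)), call. = FALSE)
  }
  if (!all(is.finite(points))) stop("all landmark coordinates must be finite", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(
    list(case_id = as.character(case_id), side = side, points = points,
         schema = schema, schema_version = schema$version),
    class = "knee_landmark_set"
  )
}

#' Extract the landmarks of a named schema region
#'
#' @param knee a `knee_landmark_set`.
#' @param region region name, e.g. `"fem_shaft_medial"`.
#' @return numeric matrix (m x 2) of the region's points, in schema order.
#' @export
region_points <- function(knee, region) {
  stopifnot(inherits(knee, "knee_landmark_set"))
  knee$points[schema_region_idx(knee$schema, region), , drop = FALSE]
}

#' @export
print.knee_landmark_set <- function(x, ...) {
  cat(sprintf("<knee_landmark_set> case %s (%s), %d points, schema %s\n",
              x$case_id, x$side, nrow(x$points), x$schema$name))
  invisible(x)
}

#' Full-limb landmark sets
#'
#' The four key points of a standing full-limb (hip-to-ankle) radiograph that
#' define the gold-standard mechanical hip-knee-ankle angle: femoral head
#' center, femoral notch center, base of the tibial spines and ankle-joint
#' center. Same image coordinate convention as [knee_landmark_set()]; the
#' femoral head must be superior (smaller y) to the notch and the ankle
#' inferior (larger y) to the spine base.
#'
#' @param case_id case identifier.
#' @param femoral_head_center,femoral_notch_center,tibial_spine_base,ankle_center
#'   length-2 numeric vectors `(x, y)`.
#' @return an object of class `full_limb_set`.
#' @export
full_limb_set <- function(case_id, femoral_head_center, femoral_notch_center,
                          tibial_spine_base, ankle_center) {
  pts <- rbind(femoral_head_center = as.numeric(femoral_head_center),
               femoral_notch_center = as.numeric(femoral_notch_center),
               tibial_spine_base = as.numeric(tibial_spine_base),
               ankle_center = as.numeric(ankle_center))
  if (ncol(pts) != 2 || !all(is.finite(pts))) {
    stop("full-limb key points must be finite (x, y) pairs", call. = FALSE)
  }
  colnames(pts) <- c("x", "y")
  if (pts["femoral_head_center", "y"] >= pts["femoral_notch_center", "y"]) {
    stop("femoral head center must be superior to the femoral notch", call. = FALSE)
  }
  if (pts["ankle_center", "y"] <= pts["tibial_spine_base", "y"]) {
    stop("ankle center must be inferior to the tibial spine base", call. = FALSE)
  }
  structure(list(case_id = as.character(case_id), points = pts),
            class = "full_limb_set")
}

#' @export
print.full_limb_set <- function(x, ...) {
  cat(sprintf("<full_limb_set> case %s\n", x$case_id))
  print(round(x$points, 2))
  invisible(x)
}

# mirror a point matrix about a vertical line; default: the centroid's x
mirror_points <- function(points, about_x = NULL) {
  if (is.null(about_x)) about_x <- mean(points[, 1])
  points[, 1] <- 2 * about_x - points[, 1]
  points
}

#' Read and write landmark point files
#'
#' The native format is the plain-text point-list dialect used by shape-model
#' tools: a `version:` line, an `n_points:` line and a brace-delimited block
#' of whitespace-separated `x y` pairs, one point per line. A two-column CSV
#' with header `x,y` is also accepted. Coordinates are written with six
#' decimal places, so reader(writer(x)) is the identity to 1e-6 px.
#'
#' Files always store the radiograph's native orientation. When
#' `side = "left"` the reader mirrors the outline about the vertical line
#' through its centroid, converting it to the canonical right-knee
#' orientation used by all geometry code.
#'
#' @param path file to read or write.
#' @param schema the expected [knee_schema()]; a point-count mismatch is an
#'   error naming expected vs found counts.
#' @param case_id case identifier to attach (default: file name stem).
#' @param side `"right"` (default) or `"left"`.
#' @return `read_landmark_file()`: a [knee_landmark_set()].
#' @export
read_landmark_file <- function(path, schema = default_knee_schema(),
                               case_id = NULL, side = c("right", "left")) {
  side <- match.arg(side)
  if (is.null(case_id)) {
    case_id <- sub("_(knee|limb)$", "", tools::file_path_sans_ext(basename(path)))
  }
  pts <- read_point_file(path)
  n_expected <- schema_n_points(schema)
  if (nrow(pts) != n_expected) {
    stop(sprintf("schema mismatch in '%s': expected %d points, found %d",
                 path, n_expected, nrow(pts)), call. = FALSE)
  }
  if (side == "left") pts <- mirror_points(pts)
  knee_landmark_set(case_id, side = side, points = pts, schema = schema)
}

#' @rdname read_landmark_file
#' @param x a `knee_landmark_set`, `full_limb_set` or n x 2 point matrix.
#'   Landmark sets of left knees are written back in canonical orientation;
#'   use `write_point_file()` on raw points to store native-orientation data.
#' @export
write_landmark_file <- function(x, path) {
  pts <- if (is.matrix(x)) x else x$points
  write_point_file(pts, path)
  invisible(path)
}

read_point_file <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^\\s*\"?x\"?\\s*,\\s*\"?y\"?\\s*$", lines[1], ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    return(parse_point_lines(paste(df$x, df$y), path, offset = 1L))
  }
  open_i <- grep("^\\s*\\{", lines)
  close_i <- grep("^\\s*\\}", lines)
  if (length(open_i) != 1 || length(close_i) != 1 || close_i <= open_i) {
    stop("malformed point file (expected one { ... } block): ", path, call. = FALSE)
  }
  n_line <- grep("^\\s*n_points\\s*:", lines, value = TRUE)
  body <- lines[(open_i + 1):(close_i - 1)]
  body_idx <- which(nzchar(trimws(body)))
  pts <- parse_point_lines(body[body_idx], path, offset = open_i + body_idx - 1L)
  if (length(n_line)) {
    n_declared <- suppressWarnings(as.integer(sub("^\\s*n_points\\s*:\\s*", "", n_line[1])))
    if (!is.na(n_declared) && n_declared != nrow(pts)) {
      stop(sprintf("point file '%s' declares n_points: %d but contains %d points",
                   path, n_declared, nrow(pts)), call. = FALSE)
    }
  }
  pts
}

parse_point_lines <- function(lines, path, offset) {
  toks <- strsplit(trimws(lines), "[,[:space:]]+")
  pts <- matrix(NA_real_, length(toks), 2)
  for (i in seq_along(toks)) {
    v <- suppressWarnings(as.numeric(toks[[i]]))
    if (length(v) != 2 || anyNA(v)) {
      stop(sprintf("parse error in '%s' at line %d: expected two numeric tokens, got '%s'",
                   path, offset[i] + 1L, paste(toks[[i]], collapse = " ")),
           call. = FALSE)
    }
    pts[i, ] <- v
  }
  pts
}

#' @rdname read_landmark_file
#' @param points n x 2 numeric matrix.
#' @param version version string recorded in the file header.
#' @export
write_point_file <- function(points, path, version = "1") {
  points <- as.matrix(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("version: %s", version),
               sprintf("n_points: %d", nrow(points)),
               "{",
               sprintf("%.6f %.6f", points[, 1], points[, 2]),
               "}"), con)
  invisible(path)
}

#' Read a full-limb key-point file
#'
#' Full-limb files use the same point-list dialect with exactly four points
#' in fixed order: femoral head center, femoral notch center, tibial spine
#' base, ankle center. Left limbs are mirrored to canonical orientation.
#'
#' @inheritParams read_landmark_file
#' @return a [full_limb_set()].
#' @export
read_limb_file <- function(path, case_id = NULL, side = c("right", "left")) {
  side <- match.arg(side)
  if (is.null(case_id)) {
    case_id <- sub("_(knee|limb)$", "", tools::file_path_sans_ext(basename(path)))
  }
  pts <- read_point_file(path)
  if (nrow(pts) != 4) {
    stop(sprintf("full-limb file '%s' must contain 4 points, found %d",
                 path, nrow(pts)), call. = FALSE)
  }
  if (side == "left") pts <- mirror_points(pts)
  full_limb_set(case_id, pts[1, ], pts[2, ], pts[3, ], pts[4, ])
}

#' Read a cohort of paired knee and full-limb landmark files
#'
#' Joins, by `case_id`, the knee landmark files (`<case_id>_knee.pts`), the
#' full-limb key-point files (`<case_id>_limb.pts`) and the metadata table
#' (CSV with header `case_id,side,sex,age,kl_grade`; `age` and `kl_grade`
#' optional). Cases that cannot be paired are reported in the returned
#' `skipped` table, never silently dropped. A case whose metadata lacks `sex`
#' is retained but flagged (`sex_missing`); sex-adjusted models downstream
#' refuse such cases.
#'
#' @param landmark_dir directory containing the landmark files.
#' @param meta_table path to the metadata CSV.
#' @param schema the [knee_schema()] of the knee files.
#' @return a list of class `knee_cohort` with elements `cases` (list of
#'   `list(knee, limb, meta)`), `meta` (data frame of retained cases) and
#'   `skipped` (data frame `case_id`, `reason`).
#' @export
read_cohort <- function(landmark_dir, meta_table, schema = default_knee_schema()) {
  if (!dir.exists(landmark_dir)) stop("landmark directory not found: ", landmark_dir, call. = FALSE)
  meta <- utils::read.csv(meta_table, stringsAsFactors = FALSE)
  need <- c("case_id", "side", "sex")
  if (!all(need %in% names(meta))) {
    stop("metadata table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  meta$case_id <- as.character(meta$case_id)
  if (anyDuplicated(meta$case_id)) {
    stop("duplicate case_id in metadata: ",
         paste(unique(meta$case_id[duplicated(meta$case_id)]), collapse = ", "),
         call. = FALSE)
  }
  cases <- list()
  skipped <- data.frame(case_id = character(), reason = character())
  kept <- logical(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$case_id[i]
    side <- match.arg(tolower(meta$side[i]), c("right", "left"))
    knee_path <- file.path(landmark_dir, paste0(id, "_knee.pts"))
    limb_path <- file.path(landmark_dir, paste0(id, "_limb.pts"))
    if (!file.exists(knee_path)) {
      skipped <- rbind(skipped, data.frame(case_id = id, reason = "missing knee landmark file"))
      next
    }
    if (!file.exists(limb_path)) {
      skipped <- rbind(skipped, data.frame(case_id = id, reason = "missing full-limb file"))
      next
    }
    knee <- read_landmark_file(knee_path, schema = schema, case_id = id, side = side)
    limb <- read_limb_file(limb_path, case_id = id, side = side)
    m <- meta[i, , drop = FALSE]
    m$sex_missing <- is.na(m$sex) | !nzchar(as.character(m$sex))
    cases[[id]] <- list(knee = knee, limb = limb, meta = m)
    kept[i] <- TRUE
  }
  unmatched <- setdiff(sub("_(knee|limb)\\.pts$", "",
                           list.files(landmark_dir, pattern = "_(knee|limb)\\.pts$")),
                       meta$case_id)
  for (id in unique(unmatched)) {
    skipped <- rbind(skipped, data.frame(case_id = id, reason = "no metadata row"))
  }
  structure(list(cases = cases, meta = meta[kept, , drop = FALSE], skipped = skipped),
            class = "knee_cohort")
}

#' @export
print.knee_cohort <- function(x, ...) {
  cat(sprintf("<knee_cohort> %d paired cases, %d skipped\n",
              length(x$cases), nrow(x$skipped)))
  if (nrow(x$skipped)) print(x$skipped)
  invisible(x)
}
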