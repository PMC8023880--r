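#' Landmark schemas
#'
#' A landmark schema declares, in order, the named anatomical regions of a
#' knee-radiograph outline and how many consecutive landmarks each region
#' occupies. All geometry code addresses landmarks exclusively through region
#' names, never through raw indices, so any point count is acceptable as long
#' as a matching schema is supplied. The package ships a 111-point default
#' schema covering the distal femur, patella and proximal tibia.
#'
#' Required regions (used by the axis constructors) are the femoral and tibial
#' shaft cortical polylines (`fem_shaft_medial`, `fem_shaft_lateral`,
#' `tib_shaft_medial`, `tib_shaft_lateral`, each ordered proximal to distal),
#' the femoral condyle arc (`fem_condyles`), the femoral notch apex
#' (`fem_notch_apex`, one point), the tibial plateau arc (`tib_plateau`) and
#' the two tibial spine base points (`tib_spine_base`).
#'
#' @param regions named integer vector (or named list) of landmarks per
#'   region, in file order.
#' @param name schema identifier.
#' @param version schema version string.
#' @return an object of class `knee_schema` with the per-region index ranges.
#' @examples
#' sch <- default_knee_schema()
#' schema_n_points(sch)
#' schema_region_idx(sch, "fem_notch_apex")
#' @export
knee_schema <- function(regions, name = "custom", version = "1.0") {
  counts <- unlist(regions)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("every region must be named", call. = FALSE)
  }
  if (anyDuplicated(names(counts))) {
    stop("duplicate region names: ",
         paste(unique(names(counts)[duplicated(names(counts))]), collapse = ", "),
         call. = FALSE)
  }
  counts <- as.integer(counts)
  names(counts) <- names(unlist(regions))
  if (any(is.na(counts)) || any(counts < 1)) {
    stop("region counts must be positive integers", call. = FALSE)
  }
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  structure(
    list(name = name, version = version,
         regions = names(counts), counts = counts,
         starts = stats::setNames(starts, names(counts)),
         ends = stats::setNames(ends, names(counts))),
    class = "knee_schema"
  )
}

#' @rdname knee_schema
#' @export
default_knee_schema <- function() {
  path <- system.file("extdata", "knee_schema_111.json", package = "kneealign")
  read_knee_schema(path)
}

#' Read a landmark schema from a JSON file
#'
#' @param path JSON file with fields `name`, `version` and `regions`
#'   (array of `{"region": ..., "n": ...}` objects in file order).
#' @return a `knee_schema`.
#' @export
read_knee_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$regions)) stop("schema file lacks a 'regions' field: ", path, call. = FALSE)
  counts <- stats::setNames(as.integer(js$regions$n), js$regions$region)
  knee_schema(counts,
              name = if (is.null(js$name)) "unnamed" else js$name,
              version = if (is.null(js$version)) "1.0" else as.character(js$version))
}

#' @rdname knee_schema
#' @param schema a `knee_schema`.
#' @export
schema_n_points <- function(schema) {
  stopifnot(inherits(schema, "knee_schema"))
  unname(schema$ends[length(schema$ends)])
}

#' @rdname knee_schema
#' @param region region name.
#' @export
schema_region_idx <- function(schema, region) {
  stopifnot(inherits(schema, "knee_schema"))
  if (!region %in% schema$regions) {
    stop("schema '", schema$name, "' has no region '", region, "'", call. = FALSE)
  }
  seq.int(schema$starts[[region]], schema$ends[[region]])
}

#' @export
print.knee_schema <- function(x, ...) {
  cat("<knee_schema>", x$name, "v", x$version, "-",
      schema_n_points(x), "points\n")
  for (r in x$regions) {
    cat(sprintf("  %-18s %3d..%3d (%d)\n", r, x$starts[[r]], x$ends[[r]], x$counts[[r]]))
  }
  invisible(x)
}
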