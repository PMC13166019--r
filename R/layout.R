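#' Construct an insole sensor layout
#'
#' An insole layout describes the fixed geometry of a pressure-sensor array:
#' per-sensor centroid coordinates, sensing areas and anatomical zone labels.
#' Coordinates use the foot-fixed convention: origin at the posterior-medial
#' corner of the insole bounding box, X increasing anteriorly (heel to toe,
#' in mm) and Y increasing laterally (in mm). Areas are in cm^2 so that
#' pressure (N cm^-2) times area gives force in N directly.
#'
#' The constructor validates the general invariants (unique positive ids,
#' positive areas, centroids inside the bounding box), which also admits
#' small toy arrays used for brute-force cross-checks. The full 16-sensor
#' anatomical contract of a production insole is enforced by
#' [validate_standard_layout()] and by [load_layout()].
#'
#' @param side "left" or "right".
#' @param size_variant free-text size label, e.g. "42-43".
#' @param length insole bounding-box length in mm (antero-posterior).
#' @param width insole bounding-box width in mm (medio-lateral).
#' @param sensors data.frame with columns `id`, `label`, `zone`, `x`, `y`
#'   (mm) and `area` (cm^2).
#' @return An object of class `insole_layout`.
#' @export
insole_layout <- function(side, size_variant, length, width, sensors) {
  side <- match.arg(side, c("left", "right"))
  stopifnot(is.numeric(length), is.numeric(width), base::length(length) == 1L,
            base::length(width) == 1L)
  if (!(length > width && width > 0)) {
    stop("insole layout requires length > width > 0 (mm)")
  }
  req <- c("id", "label", "zone", "x", "y", "area")
  if (!is.data.frame(sensors) || !all(req %in% names(sensors))) {
    stop("`sensors` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  sensors <- as.data.frame(sensors)[req]
  sensors$id <- as.integer(sensors$id)
  if (anyNA(sensors$id) || any(sensors$id < 1L)) {
    stop("sensor ids must be positive integers")
  }
  if (anyDuplicated(sensors$id)) {
    stop("duplicated sensor id: ",
         paste(unique(sensors$id[duplicated(sensors$id)]), collapse = ", "))
  }
  if (any(!is.finite(sensors$area)) || any(sensors$area <= 0)) {
    stop("all sensor areas must be positive (cm^2)")
  }
  if (any(sensors$x < 0 | sensors$x > length | sensors$y < 0 | sensors$y > width)) {
    stop("sensor centroids must lie inside the insole bounding box")
  }
  # areas are cm^2, bounding box is mm^2
  if (sum(sensors$area) * 100 > length * width) {
    stop("total sensing area exceeds the insole bounding-box area")
  }
  sensors <- sensors[order(sensors$id), , drop = FALSE]
  rownames(sensors) <- NULL
  structure(
    list(side = side, size_variant = as.character(size_variant),
         length = as.numeric(length), width = as.numeric(width),
         sensors = sensors),
    class = "insole_layout"
  )
}

#' @export
print.insole_layout <- function(x, ...) {
  cat(sprintf("<insole_layout> %s foot, size %s, %.0f x %.0f mm, %d sensors\n",
              x$side, x$size_variant, x$length, x$width, nrow(x$sensors)))
  print(x$sensors, ...)
  invisible(x)
}

#' Anatomical zone partition of the 16-sensor array
#'
#' Sensors 1-4 instrument the rearfoot, 5-8 the midfoot, 9-13 the forefoot
#' (metatarsal heads MTH1-MTH5) and 14-16 the toes.
#' @keywords internal
standard_zone_of <- function(id) {
  zone <- character(length(id))
  zone[id %in% 1:4] <- "rearfoot"
  zone[id %in% 5:8] <- "midfoot"
  zone[id %in% 9:13] <- "forefoot"
  zone[id %in% 14:16] <- "toes"
  zone
}

#' Validate the full 16-sensor anatomical contract
#'
#' Checks that a layout carries exactly the 16 sensors of the instrumented
#' insole, with ids 1-16 and the standard zone partition
#' (4 rearfoot / 4 midfoot / 5 forefoot / 3 toes).
#'
#' @param layout an `insole_layout`.
#' @return the layout, invisibly; errors on violation.
#' @export
validate_standard_layout <- function(layout) {
  stopifnot(inherits(layout, "insole_layout"))
  s <- layout$sensors
  if (nrow(s) != 16L || !setequal(s$id, 1:16)) {
    stop("standard insole layout requires exactly sensors 1-16 (got ",
         nrow(s), ")")
  }
  expected <- standard_zone_of(s$id)
  bad <- s$id[s$zone != expected]
  if (length(bad)) {
    stop("sensor(s) ", paste(bad, collapse = ", "),
         " assigned to the wrong anatomical zone")
  }
  invisible(layout)
}

#' Load an insole layout from a YAML file
#'
#' The file holds `side`, `size_variant`, `length_mm`, `width_mm` and a
#' `sensors` list with per-sensor `id`, `label`, `zone`, `x_mm`, `y_mm`,
#' `area_cm2`. The loaded layout must satisfy the full 16-sensor contract.
#'
#' @param path path to a layout YAML file.
#' @return a validated `insole_layout`.
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  doc <- yaml::read_yaml(path)
  req <- c("side", "size_variant", "length_mm", "width_mm", "sensors")
  if (!all(req %in% names(doc))) {
    stop("malformed layout file, missing field(s): ",
         paste(setdiff(req, names(doc)), collapse = ", "))
  }
  sens <- do.call(rbind, lapply(doc$sensors, function(s) {
    need <- c("id", "label", "zone", "x_mm", "y_mm", "area_cm2")
    if (!all(need %in% names(s))) stop("malformed sensor entry in layout file")
    data.frame(id = s$id, label = s$label, zone = s$zone,
               x = s$x_mm, y = s$y_mm, area = s$area_cm2)
  }))
  layout <- insole_layout(doc$side, doc$size_variant, doc$length_mm,
                          doc$width_mm, sens)
  validate_standard_layout(layout)
  layout
}

#' Default synthetic insole layout
#'
#' The bundled left-foot layout shipped with the package. The anatomical
#' zone assignment matches the instrumented insole, but the centroid
#' coordinates and areas are a synthetic, plausible stand-in (the
#' manufacturer geometry is not public), adequate for method development
#' and simulation.
#'
#' @return an `insole_layout` for a left foot.
#' @export
default_layout <- function() {
  load_layout(system.file("extdata", "layout_left_synthetic.yaml",
                          package = "insolecop", mustWork = TRUE))
}

#' Mirror a layout between left and right feet
#'
#' The right insole uses a strictly mirrored numbering convention, so a
#' right-foot layout is the medio-lateral reflection of the left one:
#' every centroid y becomes `width - y`; x, areas and ids are unchanged.
#' Mirroring twice restores the original layout bit-exactly.
#'
#' @param layout an `insole_layout`.
#' @return the mirrored `insole_layout` with `side` flipped.
#' @export
mirror_layout <- function(layout) {
  stopifnot(inherits(layout, "insole_layout"))
  layout$sensors$y <- layout$width - layout$sensors$y
  layout$side <- if (layout$side == "left") "right" else "left"
  layout
}

#' Posterior/anterior third boundaries of an insole
#'
#' The heel-to-toe roll-over criterion requires the CoP to start in the
#' posterior third of the insole and end in the anterior third; this
#' returns the two X boundaries delimiting those thirds.
#'
#' @param layout an `insole_layout`.
#' @return numeric length-2: `c(length/3, 2*length/3)` in mm.
#' @export
posterior_anterior_thirds <- function(layout) {
  stopifnot(inherits(layout, "insole_layout"))
  c(layout$length / 3, 2 * layout$length / 3)
}

#' Write a layout to a YAML file
#'
#' Inverse of [load_layout()]; round-trips losslessly.
#' @param layout an `insole_layout`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "insole_layout"))
  s <- layout$sensors
  doc <- list(
    side = layout$side, size_variant = layout$size_variant,
    length_mm = layout$length, width_mm = layout$width,
    sensors = lapply(seq_len(nrow(s)), function(i) {
      list(id = s$id[i], label = s$label[i], zone = s$zone[i],
           x_mm = s$x[i], y_mm = s$y[i], area_cm2 = s$area[i])
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
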