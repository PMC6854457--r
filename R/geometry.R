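#' Spherical head model
#'
#' A homogeneous conducting sphere standing in for the head. The sphere is
#' exact for the simulated geometry and the downstream beamformer and
#' statistics are forward-model agnostic, so no mesh-based model is needed.
#'
#' @param center Sphere centre in metres (length 3).
#' @param radius Conductor radius in metres (default 0.075, a typical adult
#'   head).
#' @return An object of class `sphere_head`.
#' @export
sphere_head <- function(center = c(0, 0, 0), radius = 0.075) {
  stopifnot(length(center) == 3, is.numeric(center))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("`radius` must be a single positive number (metres)")
  }
  structure(list(center = as.numeric(center), radius = radius),
            class = "sphere_head")
}

#' @export
print.sphere_head <- function(x, ...) {
  cat(sprintf("<sphere_head> centre (%g, %g, %g) m, radius %g m\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

new_sensor_array <- function(df, head) {
  stopifnot(all(c("name", "role", "x", "y", "z", "ox", "oy", "oz") %in% names(df)))
  out <- as_tibble(df)
  attr(out, "head") <- head
  class(out) <- c("sensor_array", class(out))
  out
}

#' Extract sensor positions or orientations as a matrix
#'
#' @param array A `sensor_array`.
#' @return An n x 3 numeric matrix.
#' @export
sensor_positions <- function(array) {
  as.matrix(array[, c("x", "y", "z")])
}

#' @rdname sensor_positions
#' @export
sensor_orientations <- function(array) {
  as.matrix(array[, c("ox", "oy", "oz")])
}

#' Build a quasi-uniform scalp magnetometer array
#'
#' Places `n_sensors` radially oriented single-axis magnetometers at a fixed
#' standoff above the sphere surface, quasi-uniformly over a spherical cap.
#' The inferior cap below `cap_zmin * radius` is excluded, mimicking the
#' coverage of a scanner-cast that leaves the neck and face free; the default
#' array covers occipital, temporal and frontal scalp bilaterally. Placement
#' uses a Fibonacci lattice whose azimuthal phase is drawn from `seed`, so a
#' given seed always yields the same array.
#'
#' @param n_sensors Number of scalp channels (1 to 256; default 21).
#' @param head A [sphere_head()].
#' @param standoff Sensor cell to scalp distance in metres (default 0.0065,
#'   typical OPM vapour-cell geometry).
#' @param cap_zmin Inferior coverage limit as a fraction of the radius
#'   (default -0.4).
#' @param seed Integer seed for the azimuthal phase.
#' @return A `sensor_array` tibble (columns name, role, x, y, z, ox, oy, oz)
#'   with the head model attached as an attribute.
#' @export
make_scalp_array <- function(n_sensors = 21, head = sphere_head(),
                             standoff = 0.0065, cap_zmin = -0.4, seed = 1) {
  if (!is.numeric(n_sensors) || length(n_sensors) != 1 ||
      n_sensors < 1 || n_sensors > 256 || n_sensors != round(n_sensors)) {
    abort("`n_sensors` must be an integer between 1 and 256")
  }
  n <- as.integer(n_sensors)
  phase <- with_seed(seed, runif(1, 0, 2 * pi))
  if (n == 1) {
    zs <- 1
    az <- phase
  } else {
    zs <- 1 - (seq_len(n) - 0.5) / n * (1 - cap_zmin)
    az <- phase + (seq_len(n) - 1) * pi * (3 - sqrt(5))
  }
  dirs <- cbind(sqrt(pmax(0, 1 - zs^2)) * cos(az),
                sqrt(pmax(0, 1 - zs^2)) * sin(az),
                zs)
  pos <- sweep(dirs * (head$radius + standoff), 2, head$center, `+`)
  new_sensor_array(tibble(
    name = sprintf("S%02d", seq_len(n)),
    role = "scalp",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    ox = dirs[, 1], oy = dirs[, 2], oz = dirs[, 3]
  ), head)
}

#' Build the reference magnetometer array
#'
#' Clusters `n_ref` sensors behind the head (the -y direction), at
#' `offset_m` from the scalp surface. The first three sensors have mutually
#' orthogonal sensitive axes (so the uniform interference field is fully
#' observed); the fourth repeats the first axis at a small spatial offset,
#' which makes the gradient component of the interference identifiable from
#' the reference signals alone.
#'
#' @param head A [sphere_head()].
#' @param offset_m Distance behind the scalp surface in metres (>= 0.05;
#'   default 0.10).
#' @param n_ref Number of reference channels (default 4).
#' @param spread Spatial extent of the cluster in metres (default 0.02).
#' @return A `sensor_array` with role `"reference"`.
#' @export
make_reference_array <- function(head = sphere_head(), offset_m = 0.10,
                                 n_ref = 4, spread = 0.02) {
  if (!is.numeric(offset_m) || length(offset_m) != 1 || offset_m < 0.05) {
    abort("`offset_m` must be at least 0.05 m")
  }
  if (!is.numeric(n_ref) || n_ref < 1 || n_ref != round(n_ref)) {
    abort("`n_ref` must be a positive integer")
  }
  n <- as.integer(n_ref)
  base <- head$center + c(0, -(head$radius + offset_m), 0)
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # small deterministic offsets keep the cluster within `spread`
  offs <- rbind(c(0, 0, 0), c(spread / 2, 0, 0), c(0, 0, spread / 2),
                c(0, -spread / 2, spread / 4))
  pos <- matrix(0, n, 3)
  ori <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    pos[i, ] <- base + offs[((i - 1) %% 4) + 1, ]
    ori[i, ] <- axes[((i - 1) %% 3) + 1, ]
  }
  new_sensor_array(tibble(
    name = sprintf("R%02d", seq_len(n)),
    role = "reference",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    ox = ori[, 1], oy = ori[, 2], oz = ori[, 3]
  ), head)
}

#' Combine scalp and reference arrays into one channel table
#'
#' @param scalp,reference `sensor_array` objects sharing a head model.
#' @return A `sensor_array` with both roles.
#' @export
bind_sensor_arrays <- function(scalp, reference) {
  head <- attr(scalp, "head")
  new_sensor_array(dplyr::bind_rows(as_tibble(scalp), as_tibble(reference)), head)
}

#' Read or write a sensor array as TSV with a JSON head-model sidecar
#'
#' The TSV holds columns name, role, x, y, z, ox, oy, oz (metres); the
#' sidecar `<path>.json` holds the sphere head model.
#'
#' @param array A `sensor_array`.
#' @param path TSV file path.
#' @return `write_sensor_array` returns `path` invisibly;
#'   `read_sensor_array` returns the `sensor_array`.
#' @export
write_sensor_array <- function(array, path) {
  utils::write.table(as.data.frame(array), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  head <- attr(array, "head")
  jsonlite::write_json(list(center = head$center, radius = head$radius),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  h <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_sensor_array(df, sphere_head(h$center, h$radius))
}
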