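#' Radial (Euclidean) displacement of a 3-vector
#'
#' @param v length-3 numeric displacement in mm.
#' @return \code{sqrt(x^2 + y^2 + z^2)}, >= 0.
#' @examples
#' radial_displacement(c(3, 4, 0))  # 5
#' @export
radial_displacement <- function(v) {
  if (length(v) != 3L || any(!is.finite(v)))
    stop_iconqa("radial_displacement() expects a finite 3-vector",
                "iconqa_validation_error")
  sqrt(sum(v^2))
}

#' Labelled fiducial point set in Leksell coordinates
#'
#' Points are expressed in the Leksell stereotactic frame (mm), whose
#' nominal centre is (100, 100, 100).  Labels must be unique; matching
#' between two sets is always by label (TG-132 anatomic-landmark method),
#' never by a point-matching search.
#'
#' @param label character vector of unique point labels.
#' @param x_mm,y_mm,z_mm coordinates in mm.
#' @return data.frame of class \code{fiducial_set}.
#' @export
fiducial_set <- function(label, x_mm, y_mm, z_mm) {
  label <- as.character(label)
  if (anyDuplicated(label))
    stop_iconqa("fiducial labels must be unique", "iconqa_validation_error")
  coords <- cbind(x_mm, y_mm, z_mm)
  if (any(!is.finite(coords)))
    stop_iconqa("fiducial coordinates must be finite", "iconqa_validation_error")
  out <- data.frame(label = label, x_mm = unname(x_mm), y_mm = unname(y_mm),
                    z_mm = unname(z_mm), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("fiducial_set", "data.frame"))
}

fiducial_coords <- function(fs) as.matrix(fs[, c("x_mm", "y_mm", "z_mm")])

#' Read / write fiducial CSV (\code{label, x_mm, y_mm, z_mm})
#'
#' @param path CSV file path.
#' @return \code{read_fiducials}: a \code{fiducial_set}.
#' @export
read_fiducials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fiducial_set(df$label, df$x_mm, df$y_mm, df$z_mm)
}

#' @rdname read_fiducials
#' @param points a \code{fiducial_set} to write.
#' @export
write_fiducials <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix, orthonormal with determinant +1.
#' @param translation length-3 translation in mm.
#' @return object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop_iconqa("rotation must be orthonormal with determinant +1",
                "iconqa_validation_error")
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop_iconqa("translation must be a finite 3-vector",
                "iconqa_validation_error")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rigid transform from clinically reported Euler angles
#'
#' Reported corrections are Euler angles in degrees with z-y-x composition
#' order: the z rotation is applied first, then y, then x, i.e.
#' \code{R = Rx \%*\% Ry \%*\% Rz}.
#'
#' @param rotation_deg length-3 \code{c(rx, ry, rz)} in degrees.
#' @param translation_mm length-3 translation in mm.
#' @return a \code{rigid_transform}.
#' @export
rigid_transform_euler <- function(rotation_deg = c(0, 0, 0),
                                  translation_mm = c(0, 0, 0)) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rigid_transform(Rx %*% Ry %*% Rz, translation_mm)
}

#' Euler angles (degrees, z-y-x order) of a rigid transform
#'
#' Inverse of [rigid_transform_euler()] away from gimbal lock
#' (\code{|ry| = 90} degrees).
#'
#' @param transform a \code{rigid_transform}.
#' @return list with \code{rotation_deg} and \code{translation_mm}.
#' @export
transform_to_euler <- function(transform) {
  R <- transform$rotation
  ry <- asin(pmin(1, pmax(-1, R[1, 3])))
  rx <- atan2(-R[2, 3], R[3, 3])
  rz <- atan2(-R[1, 2], R[1, 1])
  list(rotation_deg = c(rx, ry, rz) * 180 / pi,
       translation_mm = transform$translation)
}

#' Read / write transform JSON
#'
#' JSON schema: \code{\{"rotation_deg": [rx, ry, rz],
#' "translation_mm": [tx, ty, tz]\}} (degrees, z-y-x order).
#'
#' @param path JSON file path.
#' @return \code{read_transform_json}: a \code{rigid_transform}.
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform_euler(obj$rotation_deg, obj$translation_mm)
}

#' @rdname read_transform_json
#' @param transform a \code{rigid_transform} to write.
#' @export
write_transform_json <- function(transform, path) {
  eul <- transform_to_euler(transform)
  jsonlite::write_json(eul, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Apply a rigid transform to a fiducial set
#'
#' Rotation acts about the coordinate origin, then the translation is
#' added; labels are preserved and pairwise distances are unchanged.
#'
#' @param points a \code{fiducial_set}.
#' @param transform a \code{rigid_transform}.
#' @return transformed \code{fiducial_set}.
#' @export
apply_transform <- function(points, transform) {
  if (!inherits(transform, "rigid_transform"))
    transform <- do.call(rigid_transform, transform)
  p <- fiducial_coords(points) %*% t(transform$rotation)
  p <- sweep(p, 2, transform$translation, "+")
  fiducial_set(points$label, p[, 1], p[, 2], p[, 3])
}

#' Target registration error (TG-132 point method)
#'
#' Distances between matching labelled points after applying the
#' registration transform to the moving set.  This evaluates a registration
#' via anatomic landmarks; it does not perform image registration.
#'
#' @param fixed,moving \code{fiducial_set}s with identical label sets.
#' @param transform the registration \code{rigid_transform} mapping
#'   \code{moving} into the frame of \code{fixed} (default identity).
#' @return object of class \code{tre_result}: per-point distances (named by
#'   label), \code{mean}, \code{sd}, \code{max}, \code{n}.
#' @export
compute_tre <- function(fixed, moving, transform = rigid_transform()) {
  if (!setequal(fixed$label, moving$label) ||
      nrow(fixed) != nrow(moving))
    stop_iconqa("fixed and moving must share the same point labels",
                "iconqa_validation_error")
  moving <- moving[match(fixed$label, moving$label), , drop = FALSE]
  mt <- apply_transform(moving, transform)
  d <- sqrt(rowSums((fiducial_coords(fixed) - fiducial_coords(mt))^2))
  names(d) <- fixed$label
  structure(list(distances = d,
                 mean = mean(d),
                 sd = if (length(d) > 1L) stats::sd(d) else 0,
                 max = max(d),
                 n = length(d)),
            class = "tre_result")
}

#' @export
print.tre_result <- function(x, ...) {
  cat(sprintf("TRE over %d points: mean %.3f mm, SD %.3f mm, max %.3f mm\n",
              x$n, x$mean, x$sd, x$max))
  invisible(x)
}

#' Known-offset registration residual
#'
#' For image-guidance QA the phantom is shifted by a known offset and the
#' software's recommended correction is compared against it: the residual is
#' the signed per-axis difference \code{correction - offset} (a perfect
#' system yields zero).
#'
#' @param known_offset_mm applied offset, length-3 mm.
#' @param recommended_correction_mm software-recommended correction,
#'   length-3 mm.
#' @return signed 3-vector residual in mm.
#' @export
registration_residual <- function(known_offset_mm, recommended_correction_mm) {
  if (length(known_offset_mm) != 3L || length(recommended_correction_mm) != 3L ||
      any(!is.finite(c(known_offset_mm, recommended_correction_mm))))
    stop_iconqa("offset and correction must be finite 3-vectors",
                "iconqa_validation_error")
  as.numeric(recommended_correction_mm) - as.numeric(known_offset_mm)
}

#' Motion-camera readout accuracy
#'
#' Summarises micrometer-phantom tests of the HDMM camera: a known
#' sub-threshold move is applied on each axis and the camera readout is
#' recorded.  Per-axis signed errors (readout - applied) are summarised as
#' mean +/- SD, and the per-measurement error-vector norms as the vector
#' mean +/- SD, packaged as a systematic Type A component row.
#'
#' @param applied_moves n x 3 matrix (or data.frame) of applied moves, mm.
#' @param readouts n x 3 matrix of camera readouts, mm.
#' @param name component label.
#' @return one-row \code{component_table}.
#' @export
readout_accuracy <- function(applied_moves, readouts, name = "HDMM Accuracy") {
  a <- as.matrix(applied_moves)
  r <- as.matrix(readouts)
  if (!all(dim(a) == dim(r)) || ncol(a) != 3L)
    stop_iconqa("applied_moves and readouts must be equal-size n x 3 matrices",
                "iconqa_validation_error")
  e <- r - a
  vm <- vector_mean(e)
  uncertainty_component(
    name = name,
    axis_mean = colMeans(e),
    axis_sd = apply(e, 2, function(col) if (nrow(e) > 1L) stats::sd(col) else 0),
    vec_mean = vm$mean, vec_sd = vm$sd, n = nrow(e),
    error_type = "systematic", class = "A")
}
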