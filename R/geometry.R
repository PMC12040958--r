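# Heart localization and orientation from cardiac MRI plane metadata.
#
# A standard cine acquisition provides a short-axis (SAX) stack plus 2-chamber
# and 4-chamber long-axis views. Each view defines a plane n.(X - P) = 0; the
# heart center is the intersection of the mid-SAX, 2CH and 4CH planes, and a
# heart-local orthonormal frame (eX, eY, eZ) is built from the SAX and 4CH
# normals. Electrode coordinates can then be expressed relative to the heart.

#' Construct an imaging plane
#'
#' A plane in 3D given by a normal direction and a point on the plane
#' (as extracted from DICOM-style orientation/position metadata). The normal is
#' re-normalized to unit length on ingestion.
#'
#' @param normal numeric length-3 direction (need not be unit length)
#' @param point numeric length-3 point on the plane, in mm
#' @return an object of class `plane3d` with unit `normal` and `point`
#' @examples
#' plane3d(c(0, 0, 2), c(0, 0, 5))
#' @export
plane3d <- function(normal, point) {
  stopifnot(is_num_vec(normal, 3), is_num_vec(point, 3))
  structure(list(normal = normalize(as.numeric(normal)),
                 point = as.numeric(point)),
            class = "plane3d")
}

#' @export
print.plane3d <- function(x, ...) {
  cat(sprintf("<plane3d> n = (%.4f, %.4f, %.4f), P = (%.1f, %.1f, %.1f) mm\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$point[1], x$point[2], x$point[3]))
  invisible(x)
}

#' Heart center position from three imaging planes
#'
#' Solves the 3x3 linear system n_i . X = n_i . P_i stacking the mid short-axis,
#' 2-chamber and 4-chamber plane equations; the unique solution is the heart
#' center. Near-coplanar normals (parallel or duplicated views) make the system
#' ill-posed and raise a `ecgvae_degenerate_geometry` error.
#'
#' @param sax,lax2ch,lax4ch `plane3d` objects for the SAX, 2CH and 4CH views
#' @param cond_tol condition-number threshold above which the plane triple is
#'   declared degenerate (default 1e8; mm-scale coordinates in double precision)
#' @return numeric length-3 heart position in mm
#' @export
heart_position <- function(sax, lax2ch, lax4ch, cond_tol = 1e8) {
  stopifnot(inherits(sax, "plane3d"), inherits(lax2ch, "plane3d"),
            inherits(lax4ch, "plane3d"))
  A <- rbind(sax$normal, lax2ch$normal, lax4ch$normal)
  d <- svd(A, nu = 0, nv = 0)$d
  if (d[3] <= 0 || d[1] / d[3] > cond_tol) {
    abort_ecgvae("imaging-plane normals are (near-)coplanar; cannot intersect",
                 "degenerate_geometry")
  }
  b <- c(sum(sax$normal * sax$point),
         sum(lax2ch$normal * lax2ch$point),
         sum(lax4ch$normal * lax4ch$point))
  as.numeric(solve(A, b))
}

#' Heart-local orthonormal frame from the SAX and 4CH planes
#'
#' The local X axis is the (normalized) direction of the SAX/4CH intersection
#' line, eX = (nSAX x n4CH)/|.|; the local Z axis is the 4CH normal with any
#' eX-parallel component projected out; eY completes a right-handed frame
#' (eY = eZ x eX, so that det[eX eY eZ] = +1).
#'
#' @param sax,lax4ch `plane3d` objects
#' @return list with unit vectors `eX`, `eY`, `eZ`
#' @export
heart_frame <- function(sax, lax4ch) {
  stopifnot(inherits(sax, "plane3d"), inherits(lax4ch, "plane3d"))
  L <- cross3(sax$normal, lax4ch$normal)
  if (vnorm(L) < 1e-10) {
    abort_ecgvae("SAX and 4CH normals are (near-)parallel", "degenerate_geometry")
  }
  eX <- L / vnorm(L)
  n4 <- lax4ch$normal
  eZ <- normalize(n4 - sum(n4 * eX) * eX)
  eY <- cross3(eZ, eX)
  list(eX = eX, eY = eY, eZ = eZ)
}

#' Euler angles between a heart frame and the anatomical axes
#'
#' Three projection angles, in degrees: `alpha = acos(eX . x)`,
#' `beta = -acos(eZ . z)`, `gamma = -acos(eX . N)` where `N` is the normal of
#' the anatomical XOY plane (the z axis). These are independent arccos
#' projections, not a rotation decomposition; dot products are clamped to
#' [-1, 1] to absorb rounding.
#'
#' @param frame list with unit vectors `eX`, `eY`, `eZ` (as from [heart_frame()])
#' @param axes 3x3 matrix whose columns are the anatomical x, y, z axes
#'   (default identity)
#' @return named numeric vector `(alpha, beta, gamma)` in degrees
#' @export
euler_angles <- function(frame, axes = diag(3)) {
  stopifnot(is_num_vec(frame$eX, 3), is_num_vec(frame$eZ, 3))
  xhat <- axes[, 1]; zhat <- axes[, 3]
  Nhat <- zhat  # normal of the anatomical XOY plane
  r2d <- 180 / pi
  c(alpha = acos(clamp(sum(frame$eX * xhat) / (vnorm(frame$eX) * vnorm(xhat)))) * r2d,
    beta  = -acos(clamp(sum(frame$eZ * zhat) / (vnorm(frame$eZ) * vnorm(zhat)))) * r2d,
    gamma = -acos(clamp(sum(frame$eX * Nhat) / (vnorm(frame$eX) * vnorm(Nhat)))) * r2d)
}

#' Construct a heart pose
#'
#' Bundles heart position (mm), the heart-local orthonormal frame and its Euler
#' angles. Orthonormality and right-handedness are validated to 1e-9.
#'
#' @param position numeric length-3, mm
#' @param frame list with `eX`, `eY`, `eZ` unit vectors
#' @param euler optional precomputed angles; recomputed from the frame if NULL
#' @return object of class `heart_pose`
#' @export
heart_pose <- function(position, frame, euler = NULL) {
  stopifnot(is_num_vec(position, 3))
  R <- cbind(frame$eX, frame$eY, frame$eZ)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    abort_ecgvae("heart frame is not orthonormal", "degenerate_geometry")
  }
  if (abs(det(R) - 1) > 1e-9) {
    abort_ecgvae("heart frame is not right-handed", "degenerate_geometry")
  }
  if (is.null(euler)) euler <- euler_angles(frame)
  structure(list(position = as.numeric(position),
                 eX = frame$eX, eY = frame$eY, eZ = frame$eZ,
                 euler = euler),
            class = "heart_pose")
}

#' @export
print.heart_pose <- function(x, ...) {
  cat(sprintf("<heart_pose> position (%.1f, %.1f, %.1f) mm; euler (%.1f, %.1f, %.1f) deg\n",
              x$position[1], x$position[2], x$position[3],
              x$euler[1], x$euler[2], x$euler[3]))
  invisible(x)
}

#' Compute a heart pose from the three imaging planes
#'
#' Convenience wrapper: position from [heart_position()], frame from
#' [heart_frame()], angles from [euler_angles()].
#'
#' @inheritParams heart_position
#' @return `heart_pose`
#' @export
pose_from_planes <- function(sax, lax2ch, lax4ch, cond_tol = 1e8) {
  pos <- heart_position(sax, lax2ch, lax4ch, cond_tol = cond_tol)
  fr <- heart_frame(sax, lax4ch)
  heart_pose(pos, fr)
}

rotation_of <- function(pose) cbind(pose$eX, pose$eY, pose$eZ)

#' Construct an electrode layout
#'
#' Ten named electrode coordinates (RA, LA, RL, LL, V1..V6) tagged with the
#' coordinate frame they live in. When flattened to a 30-vector the canonical
#' ordering of [electrode_names()] is used.
#'
#' @param coords 10x3 numeric matrix with rownames among the electrode names,
#'   in mm
#' @param frame either "anatomical" or "heart"
#' @return object of class `electrode_layout`
#' @export
electrode_layout <- function(coords, frame = c("anatomical", "heart")) {
  frame <- match.arg(frame)
  coords <- as.matrix(coords)
  if (!all(electrode_names() %in% rownames(coords)) || nrow(coords) != 10 ||
      ncol(coords) != 3 || !all(is.finite(coords))) {
    abort_ecgvae("layout must contain exactly the 10 named electrodes with finite 3D coordinates",
                 "bad_layout")
  }
  coords <- coords[electrode_names(), , drop = FALSE]
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, frame = frame), class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> frame = %s\n", x$frame))
  print(round(x$coords, 2))
  invisible(x)
}

#' Flatten an electrode layout to a 30-vector
#'
#' Canonical order RA, LA, RL, LL, V1..V6, each contributing (x, y, z).
#'
#' @param layout `electrode_layout`
#' @return numeric length-30 vector
#' @export
flatten_layout <- function(layout) {
  stopifnot(inherits(layout, "electrode_layout"))
  as.numeric(t(layout$coords))
}

#' Transform electrode coordinates into the heart frame
#'
#' Maps each anatomical coordinate p to
#' ((p - position).eX, (p - position).eY, (p - position).eZ), i.e. a rigid
#' transform placing the heart center at the origin with axes (eX, eY, eZ).
#'
#' @param layout `electrode_layout` in the anatomical frame
#' @param pose `heart_pose`
#' @return `electrode_layout` in the heart frame
#' @export
to_heart_frame <- function(layout, pose) {
  stopifnot(inherits(layout, "electrode_layout"), inherits(pose, "heart_pose"))
  if (layout$frame != "anatomical") {
    abort_ecgvae("layout is already in the heart frame", "frame_mismatch")
  }
  R <- rotation_of(pose)
  shifted <- sweep(layout$coords, 2, pose$position)
  electrode_layout(shifted %*% R, frame = "heart")
}

#' Transform electrode coordinates back to the anatomical frame
#'
#' Inverse of [to_heart_frame()].
#'
#' @param layout `electrode_layout` in the heart frame
#' @param pose `heart_pose`
#' @return `electrode_layout` in the anatomical frame
#' @export
to_anatomical_frame <- function(layout, pose) {
  stopifnot(inherits(layout, "electrode_layout"), inherits(pose, "heart_pose"))
  if (layout$frame != "heart") {
    abort_ecgvae("layout is not in the heart frame", "frame_mismatch")
  }
  R <- rotation_of(pose)
  back <- sweep(layout$coords %*% t(R), 2, pose$position, `+`)
  electrode_layout(back, frame = "anatomical")
}

#' Read imaging-plane metadata from CSV
#'
#' Expected columns: subject_id, plane (SAX, 2CH or 4CH), normal_x, normal_y,
#' normal_z, point_x, point_y, point_z.
#'
#' @param path CSV file
#' @return named list (by subject) of lists of `plane3d` keyed by plane label
#' @export
read_planes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "plane", "normal_x", "normal_y", "normal_z",
            "point_x", "point_y", "point_z")
  if (!all(need %in% names(df))) abort_ecgvae("planes CSV is missing columns", "bad_input")
  out <- list()
  for (i in seq_len(nrow(df))) {
    sid <- as.character(df$subject_id[i])
    pl <- plane3d(c(df$normal_x[i], df$normal_y[i], df$normal_z[i]),
                  c(df$point_x[i], df$point_y[i], df$point_z[i]))
    if (is.null(out[[sid]])) out[[sid]] <- list()
    out[[sid]][[df$plane[i]]] <- pl
  }
  out
}

#' Write imaging-plane metadata to CSV
#'
#' @param planes structure as returned by [read_planes_csv()]
#' @param path output CSV file
#' @return `path`, invisibly
#' @export
write_planes_csv <- function(planes, path) {
  rows <- list()
  for (sid in names(planes)) {
    for (lab in names(planes[[sid]])) {
      p <- planes[[sid]][[lab]]
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sid, plane = lab,
        normal_x = p$normal[1], normal_y = p$normal[2], normal_z = p$normal[3],
        point_x = p$point[1], point_y = p$point[2], point_z = p$point[3])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read electrode layouts from CSV
#'
#' Expected columns: subject_id, electrode, x, y, z, frame.
#'
#' @param path CSV file
#' @return named list of `electrode_layout` by subject id
#' @export
read_electrodes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "electrode", "x", "y", "z", "frame")
  if (!all(need %in% names(df))) abort_ecgvae("electrode CSV is missing columns", "bad_input")
  out <- list()
  for (sid in unique(as.character(df$subject_id))) {
    sub <- df[as.character(df$subject_id) == sid, ]
    m <- as.matrix(sub[, c("x", "y", "z")])
    rownames(m) <- sub$electrode
    out[[sid]] <- electrode_layout(m, frame = unique(sub$frame)[1])
  }
  out
}

#' Write electrode layouts to CSV
#'
#' @param layouts named list of `electrode_layout` by subject id
#' @param path output CSV file
#' @return `path`, invisibly
#' @export
write_electrodes_csv <- function(layouts, path) {
  rows <- lapply(names(layouts), function(sid) {
    lay <- layouts[[sid]]
    data.frame(subject_id = sid, electrode = rownames(lay$coords),
               x = lay$coords[, 1], y = lay$coords[, 2], z = lay$coords[, 3],
               frame = lay$frame, row.names = NULL)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
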