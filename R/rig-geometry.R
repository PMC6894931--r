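#' Fit a proper rigid transform between two point sets (Kabsch)
#'
#' Least-squares orthogonal Procrustes with translation, constrained to a
#' proper rotation (reflections excluded by the usual sign correction on the
#' smallest singular vector). Maps manipulator-frame points onto
#' microscope/stage-frame points. Coordinates are um, right-handed, z up.
#'
#' @param manip_points n x 3 matrix of manipulator-frame points (n >= 3).
#' @param scope_points n x 3 matrix of the same points in the microscope frame.
#' @return a \linkS4class{RigidTransform} with the residual RMS (um).
#' @examples
#' P <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))
#' Rz <- rbind(c(0,-1,0), c(1,0,0), c(0,0,1))
#' Q <- t(Rz %*% t(P)) + rep(c(10, 20, 30), each = 4)
#' fitRigidTransform(P, Q)
#' @export
fitRigidTransform <- function(manip_points, scope_points) {
  P <- as.matrix(manip_points); Q <- as.matrix(scope_points)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("point sets must be equal-sized n x 3 matrices", call. = FALSE)
  if (nrow(P) < 3L)
    stop("at least 3 point correspondences are required", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  if (qr(Pc)$rank < 2L)
    stop("degenerate geometry: points are collinear or coincident",
         call. = FALSE)
  H <- crossprod(Pc, Qc)             # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cq - as.vector(R %*% cp)
  resid <- Qc - Pc %*% t(R)
  rms <- sqrt(mean(rowSums(resid^2)))
  new("RigidTransform", rotation = R, translation = t_vec, rms = rms)
}

#' Apply / invert a rigid transform
#'
#' \code{toScope} maps manipulator coordinates into the microscope frame
#' (R p + t); \code{toManip} is its exact inverse.
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param p a length-3 vector or n x 3 matrix of points (um).
#' @return points in the target frame, same shape as \code{p}.
#' @export
toScope <- function(transform, p) {
  stopifnot(is(transform, "RigidTransform"))
  .applyRT(transform@rotation, transform@translation, p)
}

#' @rdname toScope
#' @export
toManip <- function(transform, p) {
  stopifnot(is(transform, "RigidTransform"))
  R <- transform@rotation
  .applyRT(t(R), -as.vector(t(R) %*% transform@translation), p)
}

.applyRT <- function(R, t_vec, p) {
  if (is.matrix(p)) sweep(p %*% t(R), 2L, -t_vec)
  else as.vector(R %*% p) + t_vec
}

#' Pipette poses around the recording chamber
#'
#' @param id pipette indices (1..10).
#' @param azimuth_deg bearing of each pipette's home position as seen from
#'   the chamber centre (degrees, pairwise distinct).
#' @param approach_deg angle of the pipette's longitudinal axis above the
#'   horizontal; 27 degrees is steep enough to reach into the slice while
#'   clearing the chamber wall.
#' @param tip optional n x 3 matrix of current tip positions (um).
#' @return data.frame of poses.
#' @export
pipettePoses <- function(id, azimuth_deg, approach_deg = 27, tip = NULL) {
  if (any(duplicated(azimuth_deg)))
    stop("invalid-pose: azimuths must be pairwise distinct", call. = FALSE)
  if (any(approach_deg <= 0 | approach_deg >= 90))
    stop("approach angle must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  n <- length(id)
  if (is.null(tip)) tip <- matrix(NA_real_, n, 3L)
  data.frame(id = as.integer(id), azimuth_deg = azimuth_deg,
             approach_deg = rep_len(approach_deg, n),
             tip_x = tip[, 1L], tip_y = tip[, 2L], tip_z = tip[, 3L])
}

#' Plan staging targets above a region of interest
#'
#' Each pipette is assigned a target on a circle of radius
#' \code{spread_radius} around the ROI centre, at \code{stage_height} above
#' the slice surface, in the angular sector nearest its home azimuth (ties
#' broken by pipette id). A collision flag is raised when any pair of
#' targets is closer than \code{clearance}.
#'
#' @param poses data.frame from \code{\link{pipettePoses}}.
#' @param roi_center length-3 ROI centre (um; z = slice surface).
#' @param spread_radius circle radius (um).
#' @param stage_height staging height above the slice surface (um,
#'   default 200).
#' @param clearance minimum allowed pairwise tip distance (um).
#' @return data.frame of targets (id, x, y, z, azimuth_deg) with attributes
#'   \code{collision} (logical) and \code{min_pair_distance} (um).
#' @export
planTargets <- function(poses, roi_center, spread_radius, stage_height = 200,
                        clearance = 20) {
  if (any(duplicated(poses$azimuth_deg)))
    stop("invalid-pose: azimuths must be pairwise distinct", call. = FALSE)
  stopifnot(spread_radius >= 0, stage_height >= 0)
  ord <- order(poses$azimuth_deg, poses$id)
  poses <- poses[ord, , drop = FALSE]
  az <- poses$azimuth_deg * pi / 180
  x <- roi_center[1L] + spread_radius * cos(az)
  y <- roi_center[2L] + spread_radius * sin(az)
  z <- rep(roi_center[3L] + stage_height, nrow(poses))
  out <- data.frame(id = poses$id, x_um = x, y_um = y, z_um = z,
                    azimuth_deg = poses$azimuth_deg)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) >= 2L) {
    dmin <- min(stats::dist(cbind(out$x_um, out$y_um, out$z_um)))
  } else dmin <- Inf
  attr(out, "min_pair_distance") <- dmin
  attr(out, "collision") <- is.finite(dmin) && dmin < clearance
  out
}

#' Axis-aligned approach path to a target
#'
#' The final segment approaches the target along the pipette's longitudinal
#' axis (determined by azimuth and approach angle), so the tip moves through
#' the tissue only along its own axis. Preceding free-space segments bring
#' the tip onto that axis above the slice.
#'
#' @param pose single-row data.frame from \code{\link{pipettePoses}}, with
#'   tip coordinates set.
#' @param target length-3 target (um), below the current tip.
#' @param standoff distance along the axis from which the final axial
#'   segment starts (um).
#' @return data.frame of waypoints (x, y, z, segment type); the last segment
#'   is \code{"axial"}.
#' @export
approachPath <- function(pose, target, standoff = 100) {
  tip <- c(pose$tip_x, pose$tip_y, pose$tip_z)
  if (any(!is.finite(tip))) stop("pose has no tip position", call. = FALSE)
  if (target[3L] >= tip[3L])
    stop("path-infeasible: target must lie below the current tip",
         call. = FALSE)
  ax <- .pipetteAxis(pose$azimuth_deg, pose$approach_deg)
  entry <- target - standoff * ax          # ax points downward along travel
  if (entry[3L] > tip[3L])
    stop("path-infeasible: axial entry point lies above the tip; retract first",
         call. = FALSE)
  wps <- rbind(tip,
               c(entry[1L], entry[2L], tip[3L]),  # lateral, free space
               entry,                              # descend to entry point
               target)                             # axial segment
  out <- data.frame(x_um = wps[, 1L], y_um = wps[, 2L], z_um = wps[, 3L],
                    segment = c("start", "lateral", "descend", "axial"))
  rownames(out) <- NULL
  out
}

# Unit vector of tip travel: horizontal heading toward the chamber centre
# (opposite the azimuth bearing), descending at the approach angle.
.pipetteAxis <- function(azimuth_deg, approach_deg) {
  az <- azimuth_deg * pi / 180; al <- approach_deg * pi / 180
  c(-cos(az) * cos(al), -sin(az) * cos(al), -sin(al))
}

#' Can a pipette reach a target inside the walled recording well?
#'
#' A straight approach at the pose's angle clears the wall top iff the
#' horizontal distance from the wall crossing to the target is at least
#' wall_height / tan(approach_angle).
#'
#' @param pose single-row pose (for the approach angle and azimuth).
#' @param well list with \code{inner_radius} and \code{wall_height} (um,
#'   wall height above the target plane).
#' @param target length-3 target inside the inner well (um, chamber-centred
#'   xy).
#' @return list: \code{reachable} (logical), \code{limit} (name of the
#'   binding constraint or NA), \code{standoff_required},
#'   \code{standoff_available} (um).
#' @examples
#' pose <- pipettePoses(1, azimuth_deg = 0, approach_deg = 27)
#' wellGeometry <- list(inner_radius = 13000, wall_height = 2000)
#' reachability(pose, wellGeometry, target = c(8500, 0, 0))
#' @export
reachability <- function(pose, well, target) {
  r_t <- sqrt(target[1L]^2 + target[2L]^2)
  if (r_t > well$inner_radius)
    stop("target must lie inside the inner well", call. = FALSE)
  h <- .pipetteAxis(pose$azimuth_deg, pose$approach_deg)[1:2]
  h <- h / sqrt(sum(h^2))
  # distance s > 0 such that target - s*h lies on the wall circle
  txy <- target[1:2]
  b <- -2 * sum(txy * h)
  cc <- sum(txy^2) - well$inner_radius^2
  s_in <- (-b + sqrt(b^2 - 4 * cc)) / 2   # entry distance inside the wall
  need <- well$wall_height / tan(pose$approach_deg * pi / 180)
  ok <- s_in >= need
  list(reachable = ok,
       limit = if (ok) NA_character_ else "wall_clearance",
       standoff_required = need, standoff_available = s_in)
}

#' Read / write pose and target tables
#'
#' CSV with columns id, x_um, y_um, z_um, azimuth_deg, approach_deg.
#'
#' @param path file path.
#' @param poses pose data.frame.
#' @return \code{readPoses} returns a data.frame.
#' @export
readPoses <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readPoses
#' @export
writePoses <- function(poses, path) {
  utils::write.csv(poses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
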