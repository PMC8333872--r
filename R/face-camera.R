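# Camera coordinate convention used throughout the simulator:
#   origin at the camera pinhole, x rightward in the image, y downward,
#   z along the principal axis toward the subject (right-handed).
# "left"/"right" in landmark names refer to image left/right at the
# identity head pose.

#' Raw landmark names emitted by the simulator
#'
#' Thirteen tracked points per frame: four pupil-rim corners per eye, the
#' lateral and medial corner of each eye, and one point between the upper lip
#' and the philtrum. The seven regressor landmarks (pupil centres replacing
#' the rim corners) are derived downstream by [assemble_features()].
#'
#' @return Character vector of 13 landmark names, in column order.
#' @export
raw_landmark_names <- function() {
  c("left_lateral", paste0("left_pupil_c", 1:4), "left_medial",
    "right_medial", paste0("right_pupil_c", 1:4), "right_lateral",
    "lip_philtrum")
}

#' Derived landmark names used as regressor features
#'
#' The fixed order of the seven landmarks whose (x, y) coordinates form the
#' 14-element feature vector.
#'
#' @return Character vector of 7 landmark names.
#' @export
feature_landmark_names <- function() {
  c("left_lateral", "left_pupil", "left_medial",
    "right_medial", "right_pupil", "right_lateral", "lip_philtrum")
}

#' Head pose
#'
#' Rigid placement of the head in camera coordinates. Rotations are applied
#' in the order yaw (about the vertical y axis), then pitch (about x), then
#' roll (about z): `R = Rz(roll) Rx(pitch) Ry(yaw)`.
#'
#' @param position Numeric length-3 head-centre position in mm (camera
#'   coordinates); must have positive depth (z > 0). The default places the
#'   eyes at camera height, 500 mm from the screen plane.
#' @param yaw,pitch,roll Rotation angles in degrees.
#' @return An object of class `head_pose`.
#' @export
head_pose <- function(position = c(0, 0, 500), yaw = 0, pitch = 0, roll = 0) {
  stopifnot(length(position) == 3, all(is.finite(position)),
            is.finite(yaw), is.finite(pitch), is.finite(roll))
  if (position[3] <= 0) stop("head must be in front of the camera (z > 0)")
  structure(list(position = as.numeric(position),
                 yaw = yaw, pitch = pitch, roll = roll),
            class = "head_pose")
}

rotation_matrix <- function(pose) {
  y <- pose$yaw * pi / 180; p <- pose$pitch * pi / 180; r <- pose$roll * pi / 180
  Ry <- matrix(c(cos(y), 0, -sin(y), 0, 1, 0, sin(y), 0, cos(y)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(p), sin(p), 0, -sin(p), cos(p)), 3, 3)
  Rz <- matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
  Rz %*% Rx %*% Ry
}

#' Geometric face model
#'
#' Head-local landmark anchors in millimetres (x toward image-right at the
#' identity pose, y downward, z away from the camera; the facial surface lies
#' at small negative z). The default face is bilaterally symmetric with an
#' interpupillary distance of 63 mm and 12-mm eyeballs -- conventional adult
#' anthropometric values, not fitted to any dataset.
#'
#' Pupil-rim corners are constructed at runtime on a ring of radius
#' `iris_ring_radius_mm` centred on the pupil point (the intersection of the
#' gaze axis with the eyeball sphere), so their centroid equals the pupil
#' point by construction.
#'
#' @param interpupillary_mm Distance between eyeball centres.
#' @param eyeball_radius_mm Eyeball radius.
#' @param iris_ring_radius_mm Radius of the pupil-corner ring.
#' @return An object of class `face_model`.
#' @export
face_model <- function(interpupillary_mm = 63, eyeball_radius_mm = 12,
                       iris_ring_radius_mm = 2) {
  stopifnot(interpupillary_mm > 0, eyeball_radius_mm > 0,
            iris_ring_radius_mm > 0)
  half <- interpupillary_mm / 2
  structure(list(
    rigid = rbind(
      left_lateral  = c(-half - 13.5, 0, -8),
      left_medial   = c(-half + 13.5, 0, -10),
      right_medial  = c( half - 13.5, 0, -10),
      right_lateral = c( half + 13.5, 0, -8),
      lip_philtrum  = c(0, 52, -12)
    ),
    eye_centers = rbind(left = c(-half, 0, 0), right = c(half, 0, 0)),
    eyeball_radius_mm = eyeball_radius_mm,
    iris_ring_radius_mm = iris_ring_radius_mm
  ), class = "face_model")
}

#' Pinhole camera model with an attached screen plane
#'
#' The camera sits at the top bezel of the screen, looking at the subject.
#' The screen plane lies at z = 0 in camera coordinates, its top edge
#' `screen_offset_mm` below the camera centre; screen pixel x increases
#' toward the camera's -x (the subject faces the camera, so the image is
#' mirrored).
#'
#' @param geom A [screen_geometry()]; defines the screen plane placement.
#' @param focal_length_px Pinhole focal length in pixels. The default 1360
#'   corresponds to a consumer webcam with a ~70 degree horizontal field of
#'   view at 1920-px width, of which the frame is a face crop.
#' @param frame_width_px,frame_height_px Camera frame size (default 600 x 500).
#' @param principal_point Image point (px) of the principal axis; defaults to
#'   the frame centre.
#' @param screen_offset_mm Vertical distance from the camera centre to the
#'   screen top edge.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(geom = screen_geometry(), focal_length_px = 1360,
                         frame_width_px = 600, frame_height_px = 500,
                         principal_point = NULL, screen_offset_mm = 50) {
  assert_geometry(geom)
  stopifnot(focal_length_px > 0, frame_width_px > 0, frame_height_px > 0)
  if (is.null(principal_point)) {
    principal_point <- c(frame_width_px / 2, frame_height_px / 2)
  }
  structure(list(
    focal_length_px = focal_length_px,
    principal_point = as.numeric(principal_point),
    frame_width_px = frame_width_px,
    frame_height_px = frame_height_px,
    screen_origin = c(geom$width_mm / 2, screen_offset_mm, 0),
    screen_x_axis = c(-1, 0, 0),
    screen_y_axis = c(0, 1, 0),
    mm_per_px = c(geom$width_mm / geom$width_px, geom$height_mm / geom$height_px)
  ), class = "camera_model")
}

#' Map screen pixel coordinates to 3D camera coordinates
#'
#' @param cam A [camera_model()].
#' @param xy_px Length-2 vector or n x 2 matrix of screen coordinates (px).
#' @return An n x 3 matrix of points on the screen plane, in mm.
#' @export
screen_to_camera <- function(cam, xy_px) {
  stopifnot(inherits(cam, "camera_model"))
  xy <- matrix(as.numeric(xy_px), ncol = 2)
  mm <- cbind(xy[, 1] * cam$mm_per_px[1], xy[, 2] * cam$mm_per_px[2])
  t(cam$screen_origin +
      outer(cam$screen_x_axis, mm[, 1]) + outer(cam$screen_y_axis, mm[, 2]))
}

#' Project 3D camera-frame points through the pinhole model
#'
#' @param cam A [camera_model()].
#' @param points n x 3 matrix of camera-coordinate points (mm).
#' @return n x 2 matrix of frame pixel coordinates; rows with non-positive
#'   depth are `NA` (behind the camera).
#' @export
project_points <- function(cam, points) {
  stopifnot(inherits(cam, "camera_model"))
  pts <- matrix(as.numeric(points), ncol = 3)
  z <- pts[, 3]
  uv <- cbind(cam$focal_length_px * pts[, 1] / z + cam$principal_point[1],
              cam$focal_length_px * pts[, 2] / z + cam$principal_point[2])
  uv[z <= 0, ] <- NA_real_
  uv
}

#' Unit gaze direction from an eyeball centre to a fixated point
#'
#' @param eyeball_center,target Length-3 points in mm (camera coordinates).
#' @return Unit length-3 vector pointing from the eyeball centre to the
#'   target.
#' @export
gaze_direction <- function(eyeball_center, target) {
  stopifnot(length(eyeball_center) == 3, length(target) == 3,
            all(is.finite(eyeball_center)), all(is.finite(target)))
  v <- as.numeric(target) - as.numeric(eyeball_center)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("target coincides with the eyeball centre")
  v / nv
}

# Orthonormal basis perpendicular to a unit vector g.
orthobasis <- function(g) {
  ref <- if (abs(g[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * g) * g
  u <- u / sqrt(sum(u^2))
  v <- c(g[2] * u[3] - g[3] * u[2],
         g[3] * u[1] - g[1] * u[3],
         g[1] * u[2] - g[2] * u[1])
  rbind(u, v)
}
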