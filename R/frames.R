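# Frame and rotation conventions, shared by the generator and the
# preprocessing chain.
#
# Tag/bird frame: x = forward (surge), y = right (sway), z = up (heave).
# Navigation frame: x = north, y = east, z = up.
# Heading psi is measured clockwise from magnetic north viewed from above, so
# the tag-to-nav attitude is R = Rz(psi) Ry(-pitch) Rx(roll), with pitch
# positive nose-up and roll positive raising the right (sway) axis above
# the horizon. At rest the
# accelerometer reads the specific force (0, 0, 1) g rotated into the tag
# frame: (sin pitch, sin roll cos pitch, cos roll cos pitch).

rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

rot_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, 360) degrees
#' @param x angles in degrees.
#' @return angles wrapped to [0, 360).
#' @keywords internal
wrap360 <- function(x) ((x %% 360) + 360) %% 360

# Rotate a navigation-frame vector field into the tag frame for a series of
# attitudes. nav is length-3; psi/pitch/roll are radian vectors of equal
# length. Returns an n x 3 matrix. Vectorized composition of
# Rx(-roll) Ry(pitch) Rz(-psi) applied to `nav`.
nav_to_tag <- function(nav, psi, pitch, roll) {
  v0x <- nav[1] * cos(psi) + nav[2] * sin(psi)
  v0y <- -nav[1] * sin(psi) + nav[2] * cos(psi)
  v0z <- rep(nav[3], length(psi))
  v1x <- v0x * cos(pitch) + v0z * sin(pitch)
  v1y <- v0y
  v1z <- -v0x * sin(pitch) + v0z * cos(pitch)
  cbind(
    v1x,
    v1y * cos(roll) + v1z * sin(roll),
    -v1y * sin(roll) + v1z * cos(roll),
    deparse.level = 0
  )
}

# Undo pitch and roll on tag-frame magnetometer samples so heading can be
# read in the horizontal plane: m_level = Ry(-pitch) Rx(roll) m_tag.
tag_to_level <- function(m, pitch, roll) {
  v1x <- m[, 1]
  v1y <- m[, 2] * cos(roll) - m[, 3] * sin(roll)
  v1z <- m[, 2] * sin(roll) + m[, 3] * cos(roll)
  cbind(
    v1x * cos(pitch) - v1z * sin(pitch),
    v1y,
    v1x * sin(pitch) + v1z * cos(pitch),
    deparse.level = 0
  )
}
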