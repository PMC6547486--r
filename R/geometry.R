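# Local coordinate frames and the five distance-dependent angles.
#
# Every heavy atom gets a right-handed orthonormal frame from itself and its
# two frame-defining bonded neighbours (u = n1 - atom, v = n2 - atom):
#   Vx = unit(u), Vz = unit(u x v), Vy = Vz x Vx.
# For an ordered pair (a, b) at distance r < 15 A the descriptors are the
# polar/azimuth angles of r_ab in frame a (theta_a, phi_a), of r_ba in frame b
# (theta_b, phi_b), and the dihedral chi between plane (r_ab, Vz(a)) and
# plane (Vz(b), r_ba) about the pair axis. All angles are kept in degrees.

DIST_MAX <- 15.0
N_DIST_BINS <- 29L
N_ANGLE_BINS <- 12L
N_TYPES <- 167L
N_KINDS <- 5L  # theta_a, theta_b, phi_a, phi_b, chi

#' Distance-bin edges of the pair potential
#'
#' 29 half-open bins on `[0, 15)` A: one wide bin `[0, 2.2)`, 0.4 A bins up
#' to 7.0 A, then 0.5 A bins up to 15.0 A.
#'
#' @return Numeric vector of 30 bin edges.
#' @export
distance_bin_edges <- function() {
  round(c(0, 2.2, 2.2 + 0.4 * (1:12), 7.0 + 0.5 * (1:16)), 10)
}

#' Distance bin index
#'
#' @param r Distances in Angstrom, `0 <= r < 15`.
#' @return Integer bin indices in `1..29` (vectorised).
#' @export
#' @examples
#' distance_bin(c(1.0, 2.2, 7.0, 14.99))
distance_bin <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= DIST_MAX))
    stop(andis_error("range", "distance out of [0, 15) A"))
  findInterval(r, distance_bin_edges())
}

bin_widths <- function() diff(distance_bin_edges())
bin_midpoints <- function() {
  e <- distance_bin_edges()
  (e[-1] + e[-length(e)]) / 2
}

#' Angle bin index
#'
#' Polar angles (`[0, 180]`, 15 degree bins) and azimuth/dihedral angles
#' (`[0, 360)`, 30 degree bins) are split into 12 equal bins; the closed
#' upper polar boundary (180) maps to bin 12.
#'
#' @param angle Angles in degrees.
#' @param kind `"polar"` or `"azimuth"` (azimuth covers dihedrals too).
#' @return Integer bin indices in `1..12` (vectorised).
#' @export
angle_bin <- function(angle, kind = c("polar", "azimuth")) {
  kind <- match.arg(kind)
  if (kind == "polar") {
    if (any(angle < 0 | angle > 180))
      stop(andis_error("range", "polar angle out of [0, 180]"))
    width <- 15
  } else {
    if (any(angle < 0 | angle >= 360))
      stop(andis_error("range", "azimuth/dihedral angle out of [0, 360)"))
    width <- 30
  }
  pmin(as.integer(angle / width) + 1L, N_ANGLE_BINS)
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

dot_rows <- function(a, b) rowSums(a * b)

# Frames for every atom of a chain. Returns origin/Vx/Vy/Vz as n x 3 matrices
# plus `ok`; atoms whose neighbours are missing or collinear get ok = FALSE.
chain_frames <- function(chain) {
  a <- chain$atoms
  n <- nrow(a)
  key <- paste(a$residue_index, a$atom_name)
  tab <- atom_type_table()
  row <- match(paste(a$residue_name, a$atom_name), paste(tab$residue, tab$atom))
  nb1 <- tab$neighbor1[row]
  nb2 <- tab$neighbor2[row]

  resolve <- function(nb) {
    res <- a$residue_index + ifelse(substr(nb, 1, 1) == "-", -1L,
                            ifelse(substr(nb, 1, 1) == "+", 1L, 0L))
    nm <- sub("^[-+]", "", nb)
    match(paste(res, nm), key)
  }
  i1 <- resolve(nb1)
  i2 <- resolve(nb2)
  # terminal fallbacks: N of residue 1 -> (CA, C); C of last residue -> (CA, O)
  fallback <- is.na(i1) & a$atom_name == "N"
  i1[fallback] <- resolve(rep("CA", n))[fallback]
  i2[fallback] <- resolve(rep("C", n))[fallback]
  fallback_c <- is.na(i2) & a$atom_name == "C"
  i2[fallback_c] <- resolve(rep("O", n))[fallback_c]

  xyz <- coords(chain)
  ok <- !is.na(i1) & !is.na(i2)
  i1[!ok] <- 1L; i2[!ok] <- 1L
  u <- xyz[i1, , drop = FALSE] - xyz
  v <- xyz[i2, , drop = FALSE] - xyz
  w <- cross_rows(u, v)
  nu <- sqrt(rowSums(u^2))
  nw <- sqrt(rowSums(w^2))
  ok <- ok & nu > 1e-6 & nw > 1e-6
  nu[nu == 0] <- 1; nw[nw == 0] <- 1
  Vx <- u / nu
  Vz <- w / nw
  Vy <- cross_rows(Vz, Vx)
  list(origin = xyz, Vx = Vx, Vy = Vy, Vz = Vz, ok = ok)
}

#' Local coordinate frame of one atom
#'
#' @param chain A `protein_chain`.
#' @param atom_index Row index into `chain$atoms`.
#' @return List with `origin`, `Vx`, `Vy`, `Vz` (unit 3-vectors), or `NULL`
#'   when the frame is unavailable (missing or collinear neighbours).
#' @export
build_local_frame <- function(chain, atom_index) {
  fr <- chain_frames(chain)
  if (!fr$ok[atom_index]) return(NULL)
  list(origin = unname(fr$origin[atom_index, ]),
       Vx = unname(fr$Vx[atom_index, ]),
       Vy = unname(fr$Vy[atom_index, ]),
       Vz = unname(fr$Vz[atom_index, ]))
}

rad2deg <- function(x) x * (180 / pi)

# Vectorised geometry for ordered pairs (i -> j) given precomputed frames.
# chi is symmetric under the direction swap with this plane convention
# (both plane normals flip sign and so does the axis), so one value serves
# both directions.
pair_geometry_many <- function(frames, i, j) {
  d <- frames$origin[j, , drop = FALSE] - frames$origin[i, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) stop(andis_error("range", "zero-distance atom pair"))
  u <- d / r
  clamp <- function(x) pmin(1, pmax(-1, x))
  Vxi <- frames$Vx[i, , drop = FALSE]; Vyi <- frames$Vy[i, , drop = FALSE]
  Vzi <- frames$Vz[i, , drop = FALSE]
  Vxj <- frames$Vx[j, , drop = FALSE]; Vyj <- frames$Vy[j, , drop = FALSE]
  Vzj <- frames$Vz[j, , drop = FALSE]
  theta_a <- rad2deg(acos(clamp(dot_rows(u, Vzi))))
  theta_b <- rad2deg(acos(clamp(dot_rows(-u, Vzj))))
  phi_a <- rad2deg(atan2(dot_rows(u, Vyi), dot_rows(u, Vxi))) %% 360
  phi_b <- rad2deg(atan2(dot_rows(-u, Vyj), dot_rows(-u, Vxj))) %% 360
  # normals of plane (r_ab, Vz(a)) and plane (Vz(b), r_ba)
  n1 <- cross_rows(u, Vzi)
  n2 <- cross_rows(u, Vzj)  # = Vz(b) x r_ba up to the shared normalisation
  chi <- rad2deg(atan2(dot_rows(u, cross_rows(n1, n2)), dot_rows(n1, n2))) %% 360
  degen <- sqrt(rowSums(n1^2)) < 1e-9 | sqrt(rowSums(n2^2)) < 1e-9
  chi[degen] <- 0  # polar axis aligned with the pair axis: dihedral undefined
  phi_a[phi_a >= 360] <- 0
  phi_b[phi_b >= 360] <- 0
  chi[chi >= 360] <- 0
  data.frame(r = r, theta_a = theta_a, theta_b = theta_b,
             phi_a = phi_a, phi_b = phi_b, chi = chi)
}

#' Distance, angles and bin indices for one ordered atom pair
#'
#' @param frame_a,frame_b Local frames as returned by [build_local_frame()].
#' @return List with `r`, `theta_a`, `theta_b`, `phi_a`, `phi_b`, `chi`
#'   (degrees), `dist_bin` (1..29) and `angle_bins` (five indices, 1..12, in
#'   the order theta_a, theta_b, phi_a, phi_b, chi).
#' @export
pair_geometry <- function(frame_a, frame_b) {
  frames <- list(origin = rbind(frame_a$origin, frame_b$origin),
                 Vx = rbind(frame_a$Vx, frame_b$Vx),
                 Vy = rbind(frame_a$Vy, frame_b$Vy),
                 Vz = rbind(frame_a$Vz, frame_b$Vz))
  g <- pair_geometry_many(frames, 1L, 2L)
  if (g$r >= DIST_MAX)
    stop(andis_error("range", "pair distance beyond 15 A"))
  list(r = g$r, theta_a = g$theta_a, theta_b = g$theta_b,
       phi_a = g$phi_a, phi_b = g$phi_b, chi = g$chi,
       dist_bin = distance_bin(g$r),
       angle_bins = c(angle_bin(g$theta_a, "polar"),
                      angle_bin(g$theta_b, "polar"),
                      angle_bin(g$phi_a, "azimuth"),
                      angle_bin(g$phi_b, "azimuth"),
                      angle_bin(g$chi, "azimuth")))
}
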