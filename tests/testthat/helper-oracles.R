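# Independent oracles used across test files.

# Change-of-basis oracle for the five pair angles: express the pair vector in
# each frame's basis explicitly, then read polar/azimuth angles off spherical
# coordinates; the dihedral from the classic four-point atan2 formula applied
# to the two plane normals.
oracle_pair_angles <- function(frame_a, frame_b) {
  rad2deg <- function(x) x * 180 / pi
  rab <- frame_b$origin - frame_a$origin
  rba <- -rab
  to_basis <- function(v, fr) {
    c(sum(v * fr$Vx), sum(v * fr$Vy), sum(v * fr$Vz))
  }
  sph <- function(v) {
    r <- sqrt(sum(v^2))
    theta <- rad2deg(acos(max(-1, min(1, v[3] / r))))
    phi <- rad2deg(atan2(v[2], v[1])) %% 360
    c(theta = theta, phi = phi)
  }
  sa <- sph(to_basis(rab, frame_a))
  sb <- sph(to_basis(rba, frame_b))
  n1 <- pracma_cross(rab, frame_a$Vz)
  n2 <- pracma_cross(frame_b$Vz, rba)
  axis <- rab / sqrt(sum(rab^2))
  chi <- rad2deg(atan2(sum(axis * pracma_cross(n1, n2)), sum(n1 * n2))) %% 360
  list(r = sqrt(sum(rab^2)),
       theta_a = sa["theta"], phi_a = sa["phi"],
       theta_b = sb["theta"], phi_b = sb["phi"], chi = chi)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_frame <- function() {
  repeat {
    m <- matrix(rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    if (abs(det(q) - 1) < 1e-9) break
  }
  list(origin = rnorm(3, sd = 4), Vx = q[, 1], Vy = q[, 2], Vz = q[, 3])
}

# Brute-force O(N^3)-style shielding oracle straight from coordinates.
oracle_shielding_weight <- function(chain, i, j) {
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  res <- chain$atoms$residue_index
  w <- 1
  for (x in seq_len(nrow(xyz))) {
    if (x == i || x == j) next
    da <- sqrt(sum((xyz[x, ] - xyz[i, ])^2))
    db <- sqrt(sum((xyz[x, ] - xyz[j, ])^2))
    if (da >= 7 || db >= 7) next
    sa <- abs(res[x] - res[i]); sb <- abs(res[x] - res[j])
    if (sa < 2 || sb < 2 || max(sa, sb) < 7) next
    va <- xyz[i, ] - xyz[x, ]; vb <- xyz[j, ] - xyz[x, ]
    cosa <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
    alpha <- acos(max(-1, min(1, cosa))) * 180 / pi
    if (alpha > 60) w <- w * (180 - alpha) / 180
  }
  w
}

# Small helper: a valid 30-residue training chain, cached per test run.
cached_corpus <- local({
  cache <- NULL
  function(n = 3, seed = 42) {
    key <- paste(n, seed)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      cache <<- make_training_corpus(n, seed = seed)
      attr(cache, "key") <<- key
    }
    cache
  }
})
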