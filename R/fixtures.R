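# Deterministic synthetic structures: ideal-geometry chains built from
# internal coordinates, noise-perturbed decoy ensembles with pseudo-quality
# scores, and training corpora (optionally with a planted angular bias) so
# derivation, scoring and evaluation are testable without external data.

deg2rad <- function(x) x * (pi / 180)

# NeRF placement: position X bonded to p1 with bond length `bond`, angle
# p2-p1-X `angle` and torsion p3-p2-p1-X `torsion` (degrees).
place_atom <- function(p3, p2, p1, bond, angle, torsion) {
  th <- deg2rad(angle); ta <- deg2rad(torsion)
  bc <- p1 - p2; bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p3
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(th), bond * sin(th) * cos(ta), bond * sin(th) * sin(ta))
  p1 + d[1] * bc + d[2] * m + d[3] * n
}

# Side-chain internal coordinates: atom, p1, p2, p3, bond (A), angle, torsion
# (degrees). References are atoms of the same residue placed earlier.
sc_entry <- function(atom, p1, p2, p3, bond, angle, torsion)
  list(atom = atom, p1 = p1, p2 = p2, p3 = p3,
       bond = bond, angle = angle, torsion = torsion)

side_chain_zmat <- function() {
  cb <- sc_entry("CB", "CA", "N", "C", 1.53, 110.5, 122.5)
  list(
    ALA = list(cb),
    ARG = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.52, 114, -65),
      sc_entry("CD", "CG", "CB", "CA", 1.52, 111, 180),
      sc_entry("NE", "CD", "CG", "CB", 1.46, 112, 180),
      sc_entry("CZ", "NE", "CD", "CG", 1.33, 124, 180),
      sc_entry("NH1", "CZ", "NE", "CD", 1.33, 120, 0),
      sc_entry("NH2", "CZ", "NE", "CD", 1.33, 120, 180)),
    ASN = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.52, 113, -65),
      sc_entry("OD1", "CG", "CB", "CA", 1.23, 121, -60),
      sc_entry("ND2", "CG", "CB", "CA", 1.33, 117, 120)),
    ASP = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.52, 113, -65),
      sc_entry("OD1", "CG", "CB", "CA", 1.25, 119, -60),
      sc_entry("OD2", "CG", "CB", "CA", 1.25, 119, 120)),
    CYS = list(cb, sc_entry("SG", "CB", "CA", "N", 1.81, 114, -65)),
    GLN = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.52, 114, -65),
      sc_entry("CD", "CG", "CB", "CA", 1.52, 112, 180),
      sc_entry("OE1", "CD", "CG", "CB", 1.23, 121, -60),
      sc_entry("NE2", "CD", "CG", "CB", 1.33, 117, 120)),
    GLU = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.52, 114, -65),
      sc_entry("CD", "CG", "CB", "CA", 1.52, 112, 180),
      sc_entry("OE1", "CD", "CG", "CB", 1.25, 119, -60),
      sc_entry("OE2", "CD", "CG", "CB", 1.25, 119, 120)),
    GLY = list(),
    HIS = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.50, 114, -65),
      sc_entry("ND1", "CG", "CB", "CA", 1.38, 122, -75),
      sc_entry("CD2", "CG", "CB", "CA", 1.36, 130, 105),
      sc_entry("CE1", "ND1", "CG", "CB", 1.32, 108, 180),
      sc_entry("NE2", "CD2", "CG", "CB", 1.37, 107, 180)),
    ILE = list(cb,
      sc_entry("CG1", "CB", "CA", "N", 1.53, 110.5, -60),
      sc_entry("CG2", "CB", "CA", "N", 1.53, 110.5, 60),
      sc_entry("CD1", "CG1", "CB", "CA", 1.53, 113, 170)),
    LEU = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.53, 116, -60),
      sc_entry("CD1", "CG", "CB", "CA", 1.53, 110, 180),
      sc_entry("CD2", "CG", "CB", "CA", 1.53, 110, 60)),
    LYS = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.52, 114, -65),
      sc_entry("CD", "CG", "CB", "CA", 1.52, 111, 180),
      sc_entry("CE", "CD", "CG", "CB", 1.52, 111, 180),
      sc_entry("NZ", "CE", "CD", "CG", 1.49, 112, 180)),
    MET = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.52, 114, -65),
      sc_entry("SD", "CG", "CB", "CA", 1.81, 112, 180),
      sc_entry("CE", "SD", "CG", "CB", 1.79, 100, 180)),
    PHE = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.50, 114, -65),
      sc_entry("CD1", "CG", "CB", "CA", 1.39, 120, 85),
      sc_entry("CD2", "CG", "CB", "CA", 1.39, 120, -95),
      sc_entry("CE1", "CD1", "CG", "CB", 1.39, 120, 180),
      sc_entry("CE2", "CD2", "CG", "CB", 1.39, 120, 180),
      sc_entry("CZ", "CE1", "CD1", "CG", 1.39, 120, 0)),
    PRO = list(sc_entry("CB", "CA", "N", "C", 1.53, 103, 115),
      sc_entry("CG", "CB", "CA", "N", 1.49, 104, 30),
      sc_entry("CD", "CG", "CB", "CA", 1.50, 105, -35)),
    SER = list(cb, sc_entry("OG", "CB", "CA", "N", 1.42, 111, -65)),
    THR = list(cb,
      sc_entry("OG1", "CB", "CA", "N", 1.43, 109, -60),
      sc_entry("CG2", "CB", "CA", "N", 1.53, 111, 60)),
    TRP = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.50, 114, -65),
      sc_entry("CD1", "CG", "CB", "CA", 1.37, 127, 90),
      sc_entry("CD2", "CG", "CB", "CA", 1.43, 127, -90),
      sc_entry("NE1", "CD1", "CG", "CB", 1.38, 110, 180),
      sc_entry("CE2", "CD2", "CG", "CB", 1.41, 107, 180),
      sc_entry("CE3", "CD2", "CG", "CB", 1.40, 133, 0),
      sc_entry("CZ2", "CE2", "CD2", "CG", 1.40, 122, 180),
      sc_entry("CZ3", "CE3", "CD2", "CG", 1.39, 118, 180),
      sc_entry("CH2", "CZ2", "CE2", "CD2", 1.37, 117, 0)),
    TYR = list(cb,
      sc_entry("CG", "CB", "CA", "N", 1.50, 114, -65),
      sc_entry("CD1", "CG", "CB", "CA", 1.39, 120, 85),
      sc_entry("CD2", "CG", "CB", "CA", 1.39, 120, -95),
      sc_entry("CE1", "CD1", "CG", "CB", 1.39, 120, 180),
      sc_entry("CE2", "CD2", "CG", "CB", 1.39, 120, 180),
      sc_entry("CZ", "CE1", "CD1", "CG", 1.39, 120, 0),
      sc_entry("OH", "CZ", "CE1", "CD1", 1.38, 120, 180)),
    VAL = list(cb,
      sc_entry("CG1", "CB", "CA", "N", 1.53, 110.5, -60),
      sc_entry("CG2", "CB", "CA", "N", 1.53, 110.5, 60)))
}

aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

parse_sequence <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1 && nchar(sequence) != 3) {
    letters1 <- strsplit(sequence, "")[[1]]
    res <- unname(aa1to3[letters1])
    if (anyNA(res))
      stop(andis_error("fixture", paste("unknown residue letter(s):",
        paste(unique(letters1[is.na(res)]), collapse = ", "))))
    return(res)
  }
  sequence <- toupper(sequence)
  if (all(nchar(sequence) == 1)) {
    res <- unname(aa1to3[sequence])
    if (anyNA(res)) stop(andis_error("fixture", "unknown residue letter"))
    return(res)
  }
  if (!all(sequence %in% standard_residues()))
    stop(andis_error("fixture", "unknown residue code"))
  sequence
}

#' Build an ideal-geometry protein chain
#'
#' Constructs all heavy atoms of a chain from standard internal coordinates
#' (bond lengths, angles, side-chain torsions); the backbone follows either
#' ideal alpha-helix dihedrals (phi/psi = -57/-47 degrees) or an extended
#' conformation (-139/135).
#'
#' @param sequence One-letter string (e.g. `"AAAG"`), or vector of one- or
#'   three-letter residue codes.
#' @param backbone `"helix"` or `"extended"`.
#' @param chain_id Chain identifier.
#' @return A `protein_chain` with every residue complete.
#' @export
#' @examples
#' ch <- build_chain(strrep("A", 10))
#' ch$length           # 10
#' nrow(ch$atoms)      # 50 heavy atoms (5 per alanine)
build_chain <- function(sequence, backbone = c("helix", "extended"),
                        chain_id = "A") {
  backbone <- match.arg(backbone)
  seq3 <- parse_sequence(sequence)
  n <- length(seq3)
  phi <- if (backbone == "helix") -57 else -139
  psi <- if (backbone == "helix") -47 else 135
  zmat <- side_chain_zmat()

  rows <- vector("list", n)
  prev <- NULL  # list(N, CA, C) of previous residue
  for (i in seq_len(n)) {
    pos <- list()
    if (i == 1L) {
      pos$N <- c(0, 0, 0)
      pos$CA <- c(1.458, 0, 0)
      pos$C <- place_atom(c(0, 1, 0), pos$N, pos$CA, 1.525, 111.2, 33)
    } else {
      pos$N <- place_atom(prev$N, prev$CA, prev$C, 1.329, 116.2, psi)
      pos$CA <- place_atom(prev$CA, prev$C, pos$N, 1.458, 121.7, 180)
      pos$C <- place_atom(prev$C, pos$N, pos$CA, 1.525, 111.2, phi)
    }
    pos$O <- place_atom(pos$N, pos$CA, pos$C, 1.231, 120.5, psi + 180)
    for (e in zmat[[seq3[i]]])
      pos[[e$atom]] <- place_atom(pos[[e$p3]], pos[[e$p2]], pos[[e$p1]],
                                  e$bond, e$angle, e$torsion)
    nm <- residue_atoms(seq3[i])
    xyz <- do.call(rbind, pos[nm])
    rows[[i]] <- data.frame(
      residue_name = seq3[i], atom_name = nm, residue_index = i,
      type_index = atom_type(rep(seq3[i], length(nm)), nm),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
    prev <- pos[c("N", "CA", "C")]
  }
  new_protein_chain(do.call(rbind, rows), chain_id)
}

random_rotation <- function() {
  # uniform random rotation from a QR decomposition with sign fix
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_chain <- function(chain, rotation = diag(3), translation = c(0, 0, 0),
                            residues = NULL) {
  a <- chain$atoms
  sel <- if (is.null(residues)) rep(TRUE, nrow(a)) else
    a$residue_index %in% residues
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr) %*% t(rotation)
  xyz <- sweep(xyz, 2, ctr + translation, "+")
  a[sel, c("x", "y", "z")] <- xyz
  new_protein_chain(a, chain$chain_id)
}

rmsd_to <- function(a, b) sqrt(mean(rowSums((coords(a) - coords(b))^2)))

#' Generate noise-perturbed decoys with pseudo-quality scores
#'
#' Adds i.i.d. Gaussian noise to every coordinate of the native; the sidecar
#' pseudo-quality score is `exp(-RMSD/3)` against the unperturbed native
#' (direct coordinate RMSD, no superposition), a monotone stand-in for
#' TM-score in tests.
#'
#' @param native A `protein_chain`.
#' @param noise_sds Noise levels (A), one group of decoys per level.
#' @param n_per_level Decoys per noise level.
#' @param seed Integer seed; fully determines the ensemble.
#' @param dir Optional output directory: writes `native.pdb`,
#'   `decoy_###.pdb` and `scores.tsv` (model-id, score).
#' @return List with `decoys` (named list of chains), `quality` (data frame
#'   `model`, `score`, `noise_sd`) and `dir`.
#' @export
make_decoys <- function(native, noise_sds = c(0.25, 0.5, 1, 2), n_per_level = 5,
                        seed = 1, dir = NULL) {
  withr_seed(seed)
  decoys <- list()
  rows <- list()
  idx <- 0L
  for (sd_ in noise_sds) {
    for (rep_ in seq_len(n_per_level)) {
      idx <- idx + 1L
      id <- sprintf("decoy_%03d", idx)
      a <- native$atoms
      a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(a), sd = sd_), ncol = 3)
      dec <- new_protein_chain(a, native$chain_id)
      decoys[[id]] <- dec
      rows[[idx]] <- data.frame(model = id,
                                score = exp(-rmsd_to(dec, native) / 3),
                                noise_sd = sd_, stringsAsFactors = FALSE)
    }
  }
  quality <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_pdb(native, file.path(dir, "native.pdb"))
    for (id in names(decoys))
      write_pdb(decoys[[id]], file.path(dir, paste0(id, ".pdb")))
    utils::write.table(quality[, c("model", "score")],
                       file.path(dir, "scores.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(list(decoys = decoys, quality = quality, dir = dir))
}

withr_seed <- function(seed) set.seed(as.integer(seed) %% .Machine$integer.max)

corpus_sequence <- function(n, exclude = character(0)) {
  # alanine-rich background: concentrates pair statistics on few atom types,
  # the desk-scale stand-in for a large training set's statistical depth
  pool <- c("A", "A", "A", "A", "A", "A", "A", "A", "G", "S")
  pool <- pool[!aa1to3[pool] %in% exclude]
  sample(pool, n, replace = TRUE)
}

rotation_about <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * K %*% K
}

# A compact "hairpin": two ideal helical segments, the second rigidly
# re-posed.
#   pose "packed": stereotyped antiparallel helix pair (interaxial offset
#     ~9 A, ~10 degree orientation scatter) — contact-rich, with the
#     reproducible packing geometry the potential is meant to learn
#   pose "random": uniform random orientation, centroid 6-14 A away —
#     cross-segment angle distributions close to the uniform reference
two_segment_chain <- function(seq1, rest, pose, jitter_sd = 0.08) {
  n <- length(seq1) + length(rest)
  ch <- build_chain(c(seq1, rest), backbone = "helix")
  seg_b <- (length(seq1) + 1L):n
  a_ctr <- colMeans(coords(ch)[ch$atoms$residue_index <= length(seq1), ])
  b_ctr <- colMeans(coords(ch)[ch$atoms$residue_index > length(seq1), ])
  if (pose == "packed") {
    ax <- stats::rnorm(3)
    rot <- rotation_about(ax, stats::rnorm(1, 0, 10 * pi / 180)) %*%
      rotation_about(c(1, 0, 0), pi)
    target <- a_ctr + c(0, 9, 0) + stats::rnorm(3, 0, 0.4)
  } else {
    rot <- random_rotation()
    dirn <- stats::rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
    target <- a_ctr + dirn * stats::runif(1, 6, 14)
  }
  ch <- transform_chain(ch, rot, target - b_ctr, residues = seg_b)
  a <- ch$atoms
  a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * nrow(a), sd = jitter_sd), ncol = 3)
  new_protein_chain(a, ch$chain_id)
}

#' Generate a synthetic training corpus
#'
#' Chains of two ideal-helix segments whose relative pose is randomised:
#' `"packed"` poses put the segments in contact (a crude tertiary fold, rich
#' in short-range cross pairs), `"random"` poses sample the relative
#' orientation uniformly so cross-segment angle distributions are close to
#' the uniform reference.
#'
#' A planted angular bias re-poses the second segment so that the polar
#' angle `theta_a` of one designated atom pair falls inside a chosen hot bin
#' with probability `prob`: `planted_bias = list(res_a, atom_a, res_b,
#' atom_b, dist_bin, hot_bin, prob)`. The marker residues are inserted at
#' positions 3 and `length - 2` and excluded from the background alphabet so
#' the biased (type pair, distance bin) slice receives no background counts.
#'
#' @param n_chains Number of chains.
#' @param seed Integer seed; fully determines the corpus.
#' @param n_residues Residues per chain (>= 30 to pass training validation).
#' @param pose `"packed"` or `"random"`.
#' @param planted_bias Optional bias description (see above).
#' @return List of `protein_chain` objects.
#' @export
make_training_corpus <- function(n_chains, seed = 1, n_residues = 30,
                                 pose = c("packed", "random"),
                                 planted_bias = NULL) {
  pose <- match.arg(pose)
  stopifnot(n_chains >= 1, n_residues >= 30)
  withr_seed(seed)
  half <- n_residues %/% 2L
  lapply(seq_len(n_chains), function(ic) {
    if (is.null(planted_bias)) {
      s1 <- corpus_sequence(half)
      s2 <- corpus_sequence(n_residues - half)
      return(two_segment_chain(s1, s2, pose))
    }
    pb <- planted_bias
    exclude <- c(pb$res_a, pb$res_b)
    s1 <- corpus_sequence(half, exclude)
    s2 <- corpus_sequence(n_residues - half, exclude)
    s1[3] <- names(aa1to3)[aa1to3 == pb$res_a]
    s2[length(s2) - 2L] <- names(aa1to3)[aa1to3 == pb$res_b]
    ch <- two_segment_chain(s1, s2, "random")
    # re-pose segment B so theta_a of the marker pair lands in the hot bin
    frames <- chain_frames(ch)
    a <- ch$atoms
    m <- which(a$residue_index == 3 & a$atom_name == pb$atom_a)
    nn <- which(a$residue_index == n_residues - 2L & a$atom_name == pb$atom_b)
    stopifnot(length(m) == 1L, length(nn) == 1L, frames$ok[m])
    theta <- if (stats::runif(1) < pb$prob)
      stats::runif(1, (pb$hot_bin - 1) * 15, pb$hot_bin * 15)
    else stats::runif(1, 0, 180)
    phi <- stats::runif(1, 0, 360)
    edges <- distance_bin_edges()
    r <- stats::runif(1, edges[pb$dist_bin], edges[pb$dist_bin + 1])
    dirn <- sin(deg2rad(theta)) * (cos(deg2rad(phi)) * frames$Vx[m, ] +
                                   sin(deg2rad(phi)) * frames$Vy[m, ]) +
            cos(deg2rad(theta)) * frames$Vz[m, ]
    target <- frames$origin[m, ] + r * dirn
    shift <- target - unlist(a[nn, c("x", "y", "z")])
    seg_b <- a$residue_index > half
    a[seg_b, c("x", "y", "z")] <-
      sweep(a[seg_b, c("x", "y", "z")], 2, shift, "+")
    new_protein_chain(a, ch$chain_id)
  })
}

#' Sample pair distances from the random-walk reference
#'
#' Draws distances whose bin distribution follows
#' [rw_reference_weights()] (uniform within each bin), for self-consistency
#' experiments on the random-walk potential.
#'
#' @param n Number of distances.
#' @param length Nominal chain length of the reference.
#' @param kohn_length Rigid step length (A).
#' @param seed Integer seed.
#' @return Numeric vector of `n` distances in `[0, 15)`.
#' @export
sample_rw_reference <- function(n, length = 100, kohn_length = 3.8, seed = 1) {
  withr_seed(seed)
  w <- rw_reference_weights(length, kohn_length)
  bins <- sample.int(29L, n, replace = TRUE, prob = w)
  edges <- distance_bin_edges()
  stats::runif(n, edges[bins], edges[bins + 1])
}
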