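# Pair enumeration and the shielding ("effective atomic interaction") weight.
#
# Only atom pairs at least 7 residues apart in sequence and closer than the
# distance cutoff interact. A pair can be shielded by a third heavy atom x
# lying within 7 A of both endpoints: whenever the angle alpha = a-x-b
# exceeds 60 degrees (and x is at least 2 residues from both endpoints and
# at least 7 from one of them) the pair energy is damped by a factor
# (180 - alpha)/180 per shielder; a pair with no such shielder is fully
# effective (weight 1).

SHIELD_RADIUS <- 7.0
SHIELD_ALPHA <- 60.0

#' Enumerate interacting atom pairs of a chain
#'
#' Yields every unordered heavy-atom pair (`i < j` in atom order) with residue
#' separation `>= 7` and distance `< r_max`, together with its five-angle
#' geometry and all bin indices. Pairs involving atoms whose local frame is
#' unavailable (missing or collinear neighbours, e.g. in trimmed decoys) are
#' skipped; their count is returned as attribute `n_skipped`.
#'
#' @param chain A `protein_chain`.
#' @param r_max Maximum pair distance in Angstrom (default 15).
#' @param frames Optional precomputed [chain_frames] result (internal reuse).
#' @return Data frame with columns `i`, `j`, `type_a`, `type_b`, `sep`, `r`,
#'   `dist_bin`, `theta_a`, `theta_b`, `phi_a`, `phi_b`, `chi`, `s_theta_a`,
#'   `s_theta_b`, `s_phi_a`, `s_phi_b`, `s_chi`.
#' @export
enumerate_pairs <- function(chain, r_max = DIST_MAX, frames = NULL) {
  if (is.null(frames)) frames <- chain_frames(chain)
  a <- chain$atoms
  n <- nrow(a)
  xyz <- coords(chain)
  res <- a$residue_index
  # candidate pairs: block over i to keep memory bounded on long chains
  block <- 2000L
  out <- vector("list", 0L)
  n_skipped <- 0L
  for (start in seq(1L, n, by = block)) {
    end <- min(start + block - 1L, n)
    ii <- start:end
    # sep >= 7 mask via outer on residue indices
    sep <- abs(outer(res[ii], res, "-"))
    cand <- which(sep >= 7L & outer(ii, seq_len(n), "<"), arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    pi <- ii[cand[, 1]]
    pj <- cand[, 2]
    d2 <- rowSums((xyz[pi, , drop = FALSE] - xyz[pj, , drop = FALSE])^2)
    near <- d2 < r_max^2 & d2 > 0
    pi <- pi[near]; pj <- pj[near]
    if (length(pi) == 0L) next
    okp <- frames$ok[pi] & frames$ok[pj]
    n_skipped <- n_skipped + sum(!okp)
    pi <- pi[okp]; pj <- pj[okp]
    if (length(pi) == 0L) next
    g <- pair_geometry_many(frames, pi, pj)
    out[[length(out) + 1L]] <- data.frame(
      i = pi, j = pj,
      type_a = a$type_index[pi], type_b = a$type_index[pj],
      sep = abs(res[pi] - res[pj]),
      r = g$r, dist_bin = distance_bin(g$r),
      theta_a = g$theta_a, theta_b = g$theta_b,
      phi_a = g$phi_a, phi_b = g$phi_b, chi = g$chi,
      s_theta_a = angle_bin(g$theta_a, "polar"),
      s_theta_b = angle_bin(g$theta_b, "polar"),
      s_phi_a = angle_bin(g$phi_a, "azimuth"),
      s_phi_b = angle_bin(g$phi_b, "azimuth"),
      s_chi = angle_bin(g$chi, "azimuth"))
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(), j = integer(), type_a = integer(),
               type_b = integer(), sep = integer(), r = numeric(),
               dist_bin = integer(), theta_a = numeric(), theta_b = numeric(),
               phi_a = numeric(), phi_b = numeric(), chi = numeric(),
               s_theta_a = integer(), s_theta_b = integer(),
               s_phi_a = integer(), s_phi_b = integer(), s_chi = integer())
  attr(pairs, "n_skipped") <- n_skipped
  pairs
}

# Vectorised weights for a whole pair table. The shielder angle alpha at x
# needs only the three pair distances (law of cosines), so a cached distance
# matrix serves every pair; chains too large for the dense matrix fall back
# to per-pair column computation.
shielding_weights <- function(chain, pairs) {
  n_pairs <- nrow(pairs)
  if (n_pairs == 0L) return(numeric(0))
  xyz <- coords(chain)
  n <- nrow(xyz)
  res <- chain$atoms$residue_index
  D <- if (n <= 4000L) as.matrix(stats::dist(xyz)) else NULL
  col_dist <- function(i) {
    if (!is.null(D)) D[, i]
    else sqrt(.rowSums((xyz - rep(xyz[i, ], each = n))^2, n, 3L))
  }
  w <- rep(1, n_pairs)
  for (p in seq_len(n_pairs)) {
    i <- pairs$i[p]; j <- pairs$j[p]
    da <- col_dist(i)
    db <- col_dist(j)
    sep_a <- abs(res - res[i])
    sep_b <- abs(res - res[j])
    cand <- which(da < SHIELD_RADIUS & db < SHIELD_RADIUS & da > 0 & db > 0 &
                  sep_a >= 2L & sep_b >= 2L & pmax(sep_a, sep_b) >= 7L)
    if (length(cand) == 0L) next
    dab <- pairs$r[p]
    cosa <- (da[cand]^2 + db[cand]^2 - dab^2) / (2 * da[cand] * db[cand])
    alpha <- rad2deg(acos(pmin(1, pmax(-1, cosa))))
    shield <- alpha > SHIELD_ALPHA
    if (any(shield)) w[p] <- prod((180 - alpha[shield]) / 180)
  }
  w
}

#' Shielding weight of one atom pair
#'
#' @param chain A `protein_chain`.
#' @param i,j Atom row indices of the pair endpoints.
#' @return Weight in `(0, 1]`; 1 when no heavy atom shields the pair.
#' @export
#' @examples
#' # a lone pair with no third atom nearby is fully effective (weight 1)
shielding_weight <- function(chain, i, j) {
  xyz <- coords(chain)
  r <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  shielding_weights(chain, data.frame(i = i, j = j, r = r))
}
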