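# Derivation of the two score matrices:
#   * angle potential: E = -ln(p_obs/p_ref) per angle kind, conditioned on the
#     distance bin, with p_ref the mean of p_obs over the 12 angle bins
#     (i.e. E = -ln(12 p_obs)); bins start from a 0.1 pseudocount and slices
#     observed fewer than 20 times are zeroed.
#   * random-walk pair potential: distance-only energies against an ideal
#     freely-jointed chain reference with rigid (Kohn) step length.
#
# Count tensors are dense: [12 angle bins, 29 distance bins, 167, 167, 5].

OCC_THRESHOLD <- 20L
RW_CAP <- 10
PSEUDOCOUNT <- 0.1

counts_index <- function(s, d, a, b, k) {
  s + 12 * ((d - 1) + 29 * ((a - 1) + 167 * ((b - 1) + 167 * (k - 1))))
}

occ_index <- function(d, a, b, k) {
  d + 29 * ((a - 1) + 167 * ((b - 1) + 167 * (k - 1)))
}

rw_index <- function(d, a, b) d + 29 * ((a - 1) + 167 * (b - 1))

empty_tensors <- function(mode) {
  list(counts = array(PSEUDOCOUNT, dim = c(12, 29, 167, 167, 5)),
       occ = array(0L, dim = c(29, 167, 167, 5)),
       rw = list(N_obs = array(0, dim = c(29, 167, 167)),
                 proteins = list(), r_cut_ref = DIST_MAX),
       mode = mode,
       n_chains = 0L)
}

# Per-chain observations: linear indices + weights for both pair directions.
chain_observations <- function(chain, mode) {
  pairs <- enumerate_pairs(chain, DIST_MAX)
  w <- if (mode == "weighted" && nrow(pairs) > 0)
    shielding_weights(chain, pairs) else rep(1, nrow(pairs))
  a <- pairs$type_a; b <- pairs$type_b; d <- pairs$dist_bin
  s_dir1 <- cbind(pairs$s_theta_a, pairs$s_theta_b, pairs$s_phi_a,
                  pairs$s_phi_b, pairs$s_chi)
  s_dir2 <- s_dir1[, c(2, 1, 4, 3, 5), drop = FALSE]
  li <- c(vapply(1:5, function(k) counts_index(s_dir1[, k], d, a, b, k),
                 numeric(nrow(pairs))),
          vapply(1:5, function(k) counts_index(s_dir2[, k], d, b, a, k),
                 numeric(nrow(pairs))))
  oi <- c(vapply(1:5, function(k) occ_index(d, a, b, k),
                 numeric(nrow(pairs))),
          vapply(1:5, function(k) occ_index(d, b, a, k),
                 numeric(nrow(pairs))))
  ab <- a + 167 * (b - 1)
  ba <- b + 167 * (a - 1)
  list(li = li, w = rep(w, 10L),
       oi = oi,
       rw_li = c(rw_index(d, a, b), rw_index(d, b, a)),
       ab = c(ab, ba),
       length = chain$length)
}

#' Accumulate pair observations from training chains
#'
#' Adds every qualifying pair (residue separation `>= 7`, distance `< 15` A)
#' of each chain to the angle count tensor and the random-walk statistics.
#' Each unordered pair is accumulated in both directions (types and angle
#' roles swapped), so the count tensor is mirror-symmetric by construction.
#' In `"weighted"` mode the shielding weight multiplies the angle counts
#' (raw occurrences and random-walk counts stay unweighted).
#'
#' @param chains A `protein_chain` or list of them; each must pass
#'   [validate_training_chain()].
#' @param tensors Result of a previous `accumulate()` call to extend, or
#'   `NULL` to start fresh.
#' @param mode `"weighted"` (default) or `"unweighted"`.
#' @return A count-tensor object (list with `counts`, `occ`, `rw`, `mode`,
#'   `n_chains`).
#' @export
accumulate <- function(chains, tensors = NULL,
                       mode = c("weighted", "unweighted")) {
  if (inherits(chains, "protein_chain")) chains <- list(chains)
  if (is.null(tensors)) {
    mode <- match.arg(mode)
    tensors <- empty_tensors(mode)
  } else {
    mode <- tensors$mode
  }
  obs <- lapply(chains, function(ch) {
    v <- validate_training_chain(ch)
    if (!v$ok)
      stop(andis_error("validate",
                       paste("chain rejected for training:", v$reason)))
    chain_observations(ch, mode)
  })
  li <- unlist(lapply(obs, `[[`, "li"))
  w <- unlist(lapply(obs, `[[`, "w"))
  if (length(li)) {
    agg <- rowsum(w, group = li)
    ids <- as.numeric(rownames(agg))
    tensors$counts[ids] <- tensors$counts[ids] + agg[, 1]
    oi <- unlist(lapply(obs, `[[`, "oi"))
    oagg <- rowsum(rep(1L, length(oi)), group = oi)
    oids <- as.numeric(rownames(oagg))
    tensors$occ[oids] <- tensors$occ[oids] + oagg[, 1]
    rwli <- unlist(lapply(obs, `[[`, "rw_li"))
    ragg <- rowsum(rep(1, length(rwli)), group = rwli)
    rids <- as.numeric(rownames(ragg))
    tensors$rw$N_obs[rids] <- tensors$rw$N_obs[rids] + ragg[, 1]
  }
  tensors$rw$proteins <- c(tensors$rw$proteins, lapply(obs, function(o) {
    if (length(o$ab)) {
      t_ab <- rowsum(rep(1, length(o$ab)), group = o$ab)
      list(ab = as.numeric(rownames(t_ab)), count = t_ab[, 1],
           length = o$length)
    } else list(ab = numeric(0), count = numeric(0), length = o$length)
  }))
  tensors$n_chains <- tensors$n_chains + length(chains)
  tensors
}

#' Derive the angle potential from accumulated counts
#'
#' Per (angle kind, type pair, distance bin) slice: `p_obs(s)` is the
#' pseudocounted, normalised bin probability and the reference is its mean
#' over the 12 bins, so `E(s) = -ln(12 p_obs(s))` (kB*T = 1). Slices whose
#' raw occurrence is below 20 are set identically to 0.
#'
#' @param tensors Result of [accumulate()].
#' @return An `angle_potential`: 5-dimensional array
#'   `[12, 29, 167, 167, 5]` of dimensionless energies.
#' @export
derive_angle_potential <- function(tensors) {
  E <- array(0, dim = c(12, 29, 167, 167, 5))
  # slices below the occurrence threshold stay 0; untouched slices are
  # uniform (pure pseudocount) and would be 0 anyway, so only populated
  # slices above threshold need the log transform
  hi <- which(as.vector(tensors$occ) >= OCC_THRESHOLD)
  if (length(hi)) {
    cells <- rep((hi - 1) * 12, each = 12L) + seq_len(12L)
    sub <- matrix(tensors$counts[cells], nrow = 12L)
    p <- sub / rep(.colSums(sub, 12L, ncol(sub)), each = 12L)
    E[cells] <- -log(12 * p)
  }
  class(E) <- c("angle_potential", class(E))
  E
}

# Per-bin reference weights of the random-walk chain for one protein length:
# density shape (r/r_cut)^2 * S(r)/S(r_cut) with
# S(r) = sum_{n=1}^{L} exp(-3 r^2 / (2 n l^2)) / n^{3/2},
# evaluated at bin midpoints, multiplied by bin width, normalised to sum 1
# so expected counts conserve each protein's observed total.

#' Random-walk reference distribution over the distance bins
#'
#' @param length Protein chain length (number of residues).
#' @param kohn_length Rigid step (Kohn) length in Angstrom.
#' @param r_cut Reference cutoff in Angstrom (default 15).
#' @return Numeric vector of 29 probabilities summing to 1.
#' @export
rw_reference_weights <- function(length, kohn_length = 3.8, r_cut = DIST_MAX) {
  n <- seq_len(length)
  S <- function(r) sum(exp(-3 * r^2 / (2 * n * kohn_length^2)) / n^1.5)
  mids <- bin_midpoints()
  h <- vapply(mids, function(r) (r / r_cut)^2 * S(r) / S(r_cut), numeric(1))
  w <- h * bin_widths()
  w / sum(w)
}

#' Construct random-walk statistics from a plain distance sample
#'
#' Convenience constructor for calibration and self-consistency experiments:
#' treats `distances` as the observed pair distances of a single atom-type
#' pair in one protein.
#'
#' @param distances Pair distances in `[0, 15)` A.
#' @param length Chain length of the (nominal) source protein.
#' @param type_a,type_b Atom type indices (default 1, 1).
#' @return A random-walk statistics object usable by [derive_rw_potential()].
#' @export
rw_statistics <- function(distances, length, type_a = 1L, type_b = 1L) {
  N_obs <- array(0, dim = c(29, 167, 167))
  d <- distance_bin(distances)
  cnt <- tabulate(d, nbins = 29L)
  N_obs[cbind(1:29, type_a, type_b)] <- cnt
  if (type_a != type_b) N_obs[cbind(1:29, type_b, type_a)] <- cnt
  ab <- unique(c(type_a + 167 * (type_b - 1), type_b + 167 * (type_a - 1)))
  list(N_obs = N_obs,
       proteins = list(list(ab = ab,
                            count = rep(sum(cnt), length(ab)),
                            length = length)),
       r_cut_ref = DIST_MAX)
}

#' Derive the random-walk pair potential
#'
#' `E_rw(a, b, d) = -ln(N_obs / N_exp)` where the expected counts follow the
#' random-walk chain reference shape of each training protein (evaluated at
#' the distance-bin midpoints and scaled to that protein's observed pair
#' total within the reference cutoff). Cells with zero observed counts are
#' capped at `+10`; cells never expected are 0.
#'
#' @param x Result of [accumulate()] or an [rw_statistics()] object.
#' @param kohn_length Rigid step length of the reference chain, Angstrom.
#' @param cap Upper bound applied to the energies.
#' @return An `rw_potential`: array `[29, 167, 167]` of dimensionless
#'   energies indexed by (distance bin, type a, type b).
#' @export
derive_rw_potential <- function(x, kohn_length = 3.8, cap = RW_CAP) {
  rw <- if (!is.null(x$rw)) x$rw else x
  protos <- rw$proteins
  if (length(protos) == 0L)
    stop(andis_error("derive", "no accumulated random-walk statistics"))
  expected <- matrix(0, nrow = 167 * 167, ncol = 29)
  lens <- vapply(protos, `[[`, numeric(1), "length")
  for (L in unique(lens)) {
    wts <- rw_reference_weights(L, kohn_length, rw$r_cut_ref)
    for (p in protos[lens == L]) {
      if (length(p$ab))
        expected[p$ab, ] <- expected[p$ab, , drop = FALSE] +
          outer(p$count, wts)
    }
  }
  obs <- t(matrix(rw$N_obs, nrow = 29))  # [ab, d]
  E <- matrix(0, nrow = 167 * 167, ncol = 29)
  pos <- expected > 0
  E[pos] <- -log(obs[pos] / expected[pos])
  E[pos & obs == 0] <- cap
  E <- pmin(E, cap)
  out <- array(t(E), dim = c(29, 167, 167))
  class(out) <- c("rw_potential", class(out))
  out
}

#' Derive the full potential from training chains
#'
#' Runs [accumulate()], [derive_angle_potential()] and
#' [derive_rw_potential()] and bundles the matrices with a metadata header.
#'
#' @param chains List of `protein_chain` objects passing
#'   [validate_training_chain()].
#' @param mode `"weighted"` (shielding weights applied to angle counts,
#'   the default) or `"unweighted"`.
#' @param kohn_length Rigid step length for the random-walk reference (A).
#' @return An `andis_potential`: list with `ag` (angle potential), `rw`
#'   (random-walk potential) and `header`.
#' @export
derive_potential <- function(chains, mode = c("weighted", "unweighted"),
                             kohn_length = 3.8) {
  mode <- match.arg(mode)
  tensors <- accumulate(chains, mode = mode)
  ag <- derive_angle_potential(tensors)
  rw <- derive_rw_potential(tensors, kohn_length = kohn_length)
  structure(list(
    ag = ag, rw = rw,
    header = list(format = "andis-matrix/1",
                  mode = mode,
                  kohn_length = kohn_length,
                  r_cut_ref = DIST_MAX,
                  occ_threshold = OCC_THRESHOLD,
                  rw_cap = RW_CAP,
                  n_chains = tensors$n_chains)),
    class = "andis_potential")
}

#' @export
print.andis_potential <- function(x, ...) {
  cat(sprintf("<andis_potential: %s mode, %d training chains, l = %.2f A>\n",
              x$header$mode, x$header$n_chains, x$header$kohn_length))
  invisible(x)
}

#' Save / load a derived potential
#'
#' The container holds a one-line JSON header (readable without loading the
#' tensors) followed by the serialized matrices; simple sum checksums guard
#' against truncation and corruption.
#'
#' @param potential An `andis_potential`.
#' @param path File path.
#' @return `save_potential()` returns `path` invisibly; `load_potential()`
#'   the restored `andis_potential`.
#' @export
save_potential <- function(potential, path) {
  stopifnot(inherits(potential, "andis_potential"))
  header <- potential$header
  header$checksum_ag <- sum(potential$ag)
  header$checksum_rw <- sum(potential$rw)
  con <- file(path, "wb")
  on.exit(close(con))
  json <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  writeChar(paste0(json, "\n"), con, eos = NULL)
  serialize(list(ag = unclass(potential$ag), rw = unclass(potential$rw)), con)
  invisible(path)
}

#' @rdname save_potential
#' @export
load_potential <- function(path) {
  header <- read_potential_header(path)
  con <- file(path, "rb")
  on.exit(close(con))
  readLines(con, n = 1L, warn = FALSE)
  tensors <- tryCatch(unserialize(con), error = function(e)
    stop(andis_error("matrix", paste("corrupt potential file:",
                                     conditionMessage(e)))))
  ok <- isTRUE(all.equal(sum(tensors$ag), header$checksum_ag,
                         tolerance = 1e-8)) &&
    isTRUE(all.equal(sum(tensors$rw), header$checksum_rw, tolerance = 1e-8))
  if (!ok)
    stop(andis_error("matrix", "checksum mismatch in potential file"))
  header$checksum_ag <- NULL
  header$checksum_rw <- NULL
  ag <- tensors$ag
  class(ag) <- c("angle_potential", class(ag))
  rw <- tensors$rw
  class(rw) <- c("rw_potential", class(rw))
  structure(list(ag = ag, rw = rw, header = header),
            class = "andis_potential")
}

#' @rdname save_potential
#' @export
read_potential_header <- function(path) {
  if (!file.exists(path))
    stop(andis_error("matrix", paste("file not found:", path)))
  con <- file(path, "rb")
  on.exit(close(con))
  line <- readLines(con, n = 1L, warn = FALSE)
  header <- tryCatch(jsonlite::fromJSON(line), error = function(e)
    stop(andis_error("matrix", "missing or corrupt potential header")))
  if (!identical(header$format, "andis-matrix/1"))
    stop(andis_error("matrix",
                     paste("unsupported matrix format:", header$format)))
  header
}
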