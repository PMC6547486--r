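# Cutoff-switched scoring: mode logic, oracle totals, additivity, invariance.

make_test_potential <- function(seed = 55) {
  chains <- cached_corpus(3, seed = 21)
  pot <- derive_potential(chains, mode = "unweighted")
  pot
}

test_that("the scoring mode is a pure function of the cutoff", {
  for (rc in seq(7, 9, by = 0.5))
    expect_equal(scoring_mode(rc), "weighted_angle")
  expect_equal(scoring_mode(9.5), "angle")
  for (rc in seq(10, 15, by = 0.5))
    expect_equal(scoring_mode(rc), "combined")
  expect_error(scoring_mode(9.25), class = "andis_config_error")
  expect_error(scoring_mode(16), class = "andis_config_error")
})

test_that("hand-summed pair energies match score_structure exactly", {
  pot <- make_test_potential()
  ch <- cached_corpus(3, seed = 21)[[2]]
  for (rc in c(7.0, 9.5, 15.0)) {
    res <- score_structure(ch, pot, r_cut = rc, per_pair = TRUE)
    p <- enumerate_pairs(ch, r_max = rc)
    # oracle: explicit per-pair loop with 5-d array subscripts
    e_ag <- numeric(nrow(p))
    s_mat <- cbind(p$s_theta_a, p$s_theta_b, p$s_phi_a, p$s_phi_b, p$s_chi)
    for (q in seq_len(nrow(p)))
      for (k in 1:5)
        e_ag[q] <- e_ag[q] + pot$ag[s_mat[q, k], p$dist_bin[q],
                                    p$type_a[q], p$type_b[q], k]
    expected <- if (rc <= 9.0) {
      sum(andis:::shielding_weights(ch, p) * e_ag)
    } else if (rc == 9.5) {
      sum(e_ag)
    } else {
      e_rw <- numeric(nrow(p))
      for (q in seq_len(nrow(p)))
        e_rw[q] <- pot$rw[p$dist_bin[q], p$type_a[q], p$type_b[q]]
      sum(0.5 * e_ag + e_rw)
    }
    expect_equal(res$energy, expected, tolerance = 1e-12)
    expect_equal(res$n_pairs, nrow(p))
  }
})

test_that("weights are identically 1 at the 9.5 A cutoff", {
  pot <- make_test_potential()
  ch <- cached_corpus(3, seed = 21)[[1]]
  res <- score_structure(ch, pot, r_cut = 9.5, per_pair = TRUE)
  p <- res$breakdown
  e_manual <- andis:::angle_energy_lookup(pot$ag, p)
  expect_equal(p$energy, e_manual)  # no weighting applied
})

test_that("energy is additive across nested cutoffs within one mode", {
  pot <- make_test_potential()
  ch <- cached_corpus(3, seed = 21)[[1]]
  e15 <- score_structure(ch, pot, 15, per_pair = TRUE)
  e145 <- score_structure(ch, pot, 14.5)
  shell <- e15$breakdown[e15$breakdown$r >= 14.5, ]
  expect_equal(e15$energy, e145$energy + sum(shell$energy), tolerance = 1e-9)
})

test_that("cutoff sweep equals independent per-cutoff scoring exactly", {
  pot <- make_test_potential()
  chains <- cached_corpus(2, seed = 31)
  grid <- c(7, 8.5, 9.5, 10, 13, 15)
  sw <- cutoff_sweep(chains, pot, grid)
  for (ix in seq_len(nrow(sw))) {
    ch <- chains[[which(sw$structure[ix] == sprintf("structure_%d",
                                                    seq_along(chains)))]]
    ref <- score_structure(ch, pot, sw$r_cut[ix])
    expect_equal(sw$energy[ix], ref$energy, tolerance = 1e-12)
    expect_equal(sw$n_pairs[ix], ref$n_pairs)
  }
  # pair counts are non-decreasing in the cutoff
  for (nm in unique(sw$structure))
    expect_true(all(diff(sw$n_pairs[sw$structure == nm]) >= 0))
})

test_that("total energy is invariant under rigid-body motion", {
  pot <- make_test_potential()
  ch <- cached_corpus(2, seed = 31)[[1]]
  set.seed(8)
  moved <- andis:::transform_chain(ch, andis:::random_rotation(), c(5, 17, -9))
  for (rc in c(7.0, 9.5, 15.0)) {
    e0 <- score_structure(ch, pot, rc)$energy
    e1 <- score_structure(moved, pot, rc)$energy
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("an all-zero potential scores any structure to zero", {
  pot <- structure(list(
    ag = array(0, dim = c(12, 29, 167, 167, 5)),
    rw = array(0, dim = c(29, 167, 167)),
    header = list(mode = "unweighted")), class = "andis_potential")
  ch <- cached_corpus(2, seed = 31)[[2]]
  expect_equal(score_structure(ch, pot, 7)$energy, 0)
  expect_equal(score_structure(ch, pot, 15)$energy, 0)
})

test_that("structures with no interacting pairs warn and score zero", {
  pot <- make_test_potential()
  tiny <- build_chain("AAAA")
  expect_warning(res <- score_structure(tiny, pot, 7), "no interacting pairs")
  expect_equal(res$energy, 0)
  expect_equal(res$n_pairs, 0L)
})

test_that("decoys with missing atoms are scored over present atoms only", {
  pot <- make_test_potential()
  ch <- cached_corpus(2, seed = 31)[[1]]
  keep <- !(ch$atoms$residue_index == 10 & ch$atoms$atom_name %in%
              c("CB", "O"))
  trimmed <- andis:::new_protein_chain(ch$atoms[keep, ], "A")
  res <- score_structure(trimmed, pot, 15)
  expect_lt(res$coverage, 1)
  expect_gt(res$n_pairs, 0)
})
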