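# Count accumulation, Boltzmann inversion of the angle statistics, the
# random-walk pair potential and matrix serialization.

test_that("count tensors start from the 0.1 pseudocount and have full shape", {
  tens <- andis:::empty_tensors("unweighted")
  expect_equal(dim(tens$counts), c(12L, 29L, 167L, 167L, 5L))
  expect_equal(dim(tens$occ), c(29L, 167L, 167L, 5L))
  expect_true(all(tens$counts == 0.1))
  expect_true(all(tens$occ == 0L))
})

test_that("accumulation is mirror-symmetric and conserves totals", {
  ch <- cached_corpus(1, seed = 13)[[1]]
  tens <- accumulate(ch, mode = "unweighted")
  n_pairs <- nrow(enumerate_pairs(ch))
  # 2 directions x 5 angle kinds, one unit each
  expect_equal(sum(tens$counts - 0.1), 10 * n_pairs, tolerance = 1e-6)
  expect_equal(sum(tens$occ), 10L * n_pairs)
  # theta_a counts of (a, b) equal theta_b counts of (b, a), etc.
  ab <- unique(cbind(ch$atoms$type_index[enumerate_pairs(ch)$i],
                     ch$atoms$type_index[enumerate_pairs(ch)$j]))
  for (k in seq_len(min(5, nrow(ab)))) {
    a <- ab[k, 1]; b <- ab[k, 2]
    expect_equal(tens$counts[, , a, b, 1], tens$counts[, , b, a, 2])
    expect_equal(tens$counts[, , a, b, 3], tens$counts[, , b, a, 4])
    expect_equal(tens$counts[, , a, b, 5], tens$counts[, , b, a, 5])
  }
})

test_that("weighted accumulation weights counts but not raw occurrences", {
  ch <- cached_corpus(1, seed = 13)[[1]]
  tw <- accumulate(ch, mode = "weighted")
  tu <- accumulate(ch, mode = "unweighted")
  expect_equal(sum(tw$occ), sum(tu$occ))
  expect_lte(sum(tw$counts), sum(tu$counts))
  p <- enumerate_pairs(ch)
  w <- andis:::shielding_weights(ch, p)
  expect_equal(sum(tw$counts - 0.1), 10 * sum(w), tolerance = 1e-6)
})

test_that("chains failing training validation are rejected", {
  expect_error(accumulate(build_chain(strrep("A", 10))),
               class = "andis_validate_error")
})

test_that("energies follow -ln(12 p) with the occurrence-20 rule", {
  tens <- andis:::empty_tensors("unweighted")
  # uniform slice above threshold -> identically 0
  tens$counts[, 5, 1, 2, 1] <- 10.1
  tens$occ[5, 1, 2, 1] <- 120L
  # hot-bin slice: one bin holds all the mass
  tens$counts[, 8, 3, 4, 2] <- 0.1
  tens$counts[6, 8, 3, 4, 2] <- 100.1
  tens$occ[8, 3, 4, 2] <- 100L
  # populated but below threshold -> zeroed
  tens$counts[2, 9, 5, 6, 3] <- 19.1
  tens$occ[9, 5, 6, 3] <- 19L
  E <- derive_angle_potential(tens)
  expect_equal(E[, 5, 1, 2, 1], rep(0, 12))
  # slice total: 100.1 in the hot bin plus 11 x 0.1 pseudocounts = 101.2
  expect_equal(E[6, 8, 3, 4, 2], -log(12 * 100.1 / 101.2), tolerance = 1e-12)
  expect_equal(E[1, 8, 3, 4, 2], -log(12 * 0.1 / 101.2), tolerance = 1e-12)
  expect_equal(round(E[6, 8, 3, 4, 2], 3), -2.474)
  expect_equal(round(E[1, 8, 3, 4, 2], 3), 4.435)
  expect_equal(E[, 9, 5, 6, 3], rep(0, 12))
})

test_that("populated slices are normalised probabilities with unit mean Boltzmann factor", {
  chains <- cached_corpus(3, seed = 21)
  tens <- accumulate(chains, mode = "unweighted")
  E <- derive_angle_potential(tens)
  hi <- which(tens$occ >= 20)
  idx <- arrayInd(hi[seq_len(min(200, length(hi)))], dim(tens$occ))
  for (r in seq_len(nrow(idx))) {
    cnt <- tens$counts[, idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4]]
    p <- cnt / sum(cnt)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    e <- E[, idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4]]
    expect_equal(mean(exp(-e)), 1, tolerance = 1e-9)
    expect_equal(e, -log(12 * p), tolerance = 1e-12)
  }
})

test_that("a planted angular bias is recovered as the energy minimum", {
  bias <- list(res_a = "TRP", atom_a = "CH2", res_b = "MET", atom_b = "SD",
               dist_bin = 17L, hot_bin = 4L, prob = 0.8)
  corpus <- make_training_corpus(40, seed = 77, planted_bias = bias)
  tens <- accumulate(corpus, mode = "unweighted")
  a <- atom_type("TRP", "CH2"); b <- atom_type("MET", "SD")
  expect_gte(tens$occ[17, a, b, 1], 20L)
  E <- derive_angle_potential(tens)
  expect_equal(which.min(E[, 17, a, b, 1]), 4L)
})

test_that("random-walk reference weights are a proper distribution", {
  w <- rw_reference_weights(100)
  expect_equal(length(w), 29L)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
})

test_that("a corpus sampled from the reference yields near-zero RW energies", {
  d <- sample_rw_reference(2e5, length = 100, seed = 4)
  stats <- rw_statistics(d, length = 100)
  E <- derive_rw_potential(stats)
  w <- rw_reference_weights(100)
  populated <- which(2e5 * w >= 1e3)
  expect_gt(length(populated), 10)
  expect_lt(max(abs(E[cbind(populated, 1, 1)])), 0.1)
})

test_that("single-bin observations give a negative well and capped elsewhere", {
  d <- runif(500, 8.0, 8.4)  # all in one bin
  b <- distance_bin(8.2)
  stats <- rw_statistics(d, length = 80)
  E <- derive_rw_potential(stats)
  expect_lt(E[b, 1, 1], 0)
  others <- setdiff(1:29, b)
  expect_true(all(E[cbind(others, 1, 1)] == andis:::RW_CAP))
})

test_that("potential files round-trip losslessly with a readable header", {
  chains <- cached_corpus(3, seed = 21)
  pot <- derive_potential(chains, mode = "unweighted")
  path <- tempfile(fileext = ".andis")
  save_potential(pot, path)
  header <- read_potential_header(path)
  expect_equal(header$mode, "unweighted")
  expect_equal(header$format, "andis-matrix/1")
  back <- load_potential(path)
  expect_identical(unclass(back$ag), unclass(pot$ag))
  expect_identical(unclass(back$rw), unclass(pot$rw))
  # truncation is caught
  raw <- readBin(path, "raw", file.size(path))
  trunc_path <- tempfile()
  writeBin(raw[seq_len(length(raw) %/% 2)], trunc_path)
  expect_error(load_potential(trunc_path), class = "andis_matrix_error")
})
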