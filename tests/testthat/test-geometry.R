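# Distance/angle binning, local frames and the five-angle pair geometry.

test_that("distance binning partitions [0, 15) into exactly 29 half-open bins", {
  edges <- distance_bin_edges()
  expect_equal(length(edges), 30L)
  expect_equal(edges[c(1, 2, 14, 30)], c(0, 2.2, 7.0, 15.0))
  expect_equal(distance_bin(1.0), 1L)     # wide first bin
  expect_equal(distance_bin(2.2), 2L)     # half-open edges
  expect_equal(distance_bin(7.0), 14L)    # 0.4 A bins end at 7.0
  expect_equal(distance_bin(5.0), 9L)     # 2.2 + 7 * 0.4
  expect_equal(distance_bin(14.99), 29L)
  # every r maps to exactly one bin, edges shared by no two bins
  r <- seq(0, 14.999, by = 0.0007)
  b <- distance_bin(r)
  expect_true(all(b >= 1 & b <= 29))
  expect_true(all(r >= edges[b] & r < edges[b + 1]))
  expect_error(distance_bin(15.0), class = "andis_range_error")
  expect_error(distance_bin(-0.1), class = "andis_range_error")
})

test_that("angle binning is 15-degree polar / 30-degree azimuth with closed top", {
  expect_equal(angle_bin(0, "polar"), 1L)
  expect_equal(angle_bin(180, "polar"), 12L)
  expect_equal(angle_bin(359.9, "azimuth"), 12L)
  expect_error(angle_bin(360, "azimuth"), class = "andis_range_error")
  # uniform sweep: 1200 equally spaced polar angles put 100 in each bin
  sweep_angles <- (0:1199) * 180 / 1200
  expect_equal(unname(table(angle_bin(sweep_angles, "polar"))),
               rep(100L, 12), ignore_attr = TRUE)
})

test_that("axis-aligned neighbours give the canonical frame", {
  golden <- system.file("extdata", "golden_dipeptide.pdb", package = "andis")
  ch <- read_pdb(golden)
  # CA of GLY1: neighbours N at (0,0,0) and C at (1.5,1.5,0); CA (1.5,0,0)
  fr <- build_local_frame(ch, which(ch$atoms$atom_name == "CA" &
                                      ch$atoms$residue_index == 1))
  expect_equal(fr$Vx, c(-1, 0, 0))
  expect_equal(fr$Vz, c(0, 0, -1))
  expect_equal(fr$Vy, c(0, 1, 0))
})

test_that("frames are orthonormal and right-handed across a full chain", {
  ch <- build_chain(paste(rep(names(andis:::aa1to3), 2), collapse = ""))
  fr <- andis:::chain_frames(ch)
  expect_true(all(fr$ok))
  expect_lt(max(abs(rowSums(fr$Vx^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fr$Vx * fr$Vz))), 1e-9)
  handed <- andis:::cross_rows(fr$Vx, fr$Vy) - fr$Vz
  expect_lt(max(abs(handed)), 1e-9)
})

test_that("collinear neighbours yield a frame-unavailable signal", {
  ch <- build_chain("GG")
  a <- ch$atoms
  # make N, CA, C of residue 1 collinear: CA frame (N, C) degenerates
  a[a$residue_index == 1 & a$atom_name == "N", c("x", "y", "z")] <- c(0, 0, 0)
  a[a$residue_index == 1 & a$atom_name == "CA", c("x", "y", "z")] <- c(1.5, 0, 0)
  a[a$residue_index == 1 & a$atom_name == "C", c("x", "y", "z")] <- c(3.0, 0, 0)
  broken <- andis:::new_protein_chain(a, "A")
  expect_null(build_local_frame(broken,
    which(a$residue_index == 1 & a$atom_name == "CA")))
})

test_that("pair angles match the change-of-basis oracle", {
  set.seed(1)
  for (k in 1:500) {
    fa <- random_frame(); fb <- random_frame()
    if (sqrt(sum((fa$origin - fb$origin)^2)) >= 15) next
    g <- pair_geometry(fa, fb)
    o <- oracle_pair_angles(fa, fb)
    expect_equal(g$theta_a, unname(o$theta_a), tolerance = 1e-9)
    expect_equal(g$theta_b, unname(o$theta_b), tolerance = 1e-9)
    expect_lt(min(abs(g$phi_a - o$phi_a), 360 - abs(g$phi_a - o$phi_a)), 1e-6)
    expect_lt(min(abs(g$phi_b - o$phi_b), 360 - abs(g$phi_b - o$phi_b)), 1e-6)
    expect_lt(min(abs(g$chi - o$chi), 360 - abs(g$chi - o$chi)), 1e-6)
  }
})

test_that("polar axis and azimuth origin conventions hold", {
  fa <- list(origin = c(0, 0, 0), Vx = c(1, 0, 0), Vy = c(0, 1, 0),
             Vz = c(0, 0, 1))
  fb <- list(origin = c(0, 0, 5), Vx = c(0, 1, 0), Vy = c(1, 0, 0),
             Vz = c(0, 0, -1))
  g <- pair_geometry(fa, fb)
  expect_equal(g$theta_a, 0)            # r_ab along Vz(a)
  fb2 <- fb; fb2$origin <- c(3, 0, 4)   # in the Vx-Vz plane, +x component
  g2 <- pair_geometry(fa, fb2)
  expect_equal(g2$phi_a, 0)
})

test_that("swapping the pair direction swaps angle roles and keeps r and chi", {
  set.seed(7)
  for (k in 1:50) {
    fa <- random_frame(); fb <- random_frame()
    if (sqrt(sum((fa$origin - fb$origin)^2)) >= 15) next
    g1 <- pair_geometry(fa, fb)
    g2 <- pair_geometry(fb, fa)
    expect_equal(g1$r, g2$r)
    expect_equal(g1$theta_a, g2$theta_b)
    expect_equal(g1$phi_a, g2$phi_b)
    expect_equal(g1$chi, g2$chi, tolerance = 1e-9)
  }
})

test_that("pair geometry is invariant under rigid-body motion", {
  ch <- cached_corpus(1, seed = 5)[[1]]
  p0 <- enumerate_pairs(ch)
  set.seed(3)
  rot <- andis:::random_rotation()
  moved <- andis:::transform_chain(ch, rot, c(11, -4, 2))
  p1 <- enumerate_pairs(moved)
  expect_equal(nrow(p0), nrow(p1))
  for (col in c("r", "theta_a", "theta_b", "phi_a", "phi_b", "chi"))
    expect_equal(p1[[col]], p0[[col]], tolerance = 1e-6)
})

test_that("zero-distance pairs raise a degenerate-pair error", {
  fa <- random_frame()
  fb <- random_frame()
  fb$origin <- fa$origin
  expect_error(pair_geometry(fa, fb), class = "andis_range_error")
})
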