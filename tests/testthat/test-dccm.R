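# small hand-built trajectory: n atoms, displacement list per frame
make_disp_traj <- function(disp_frames, resids) {
  n_at <- length(resids)
  purrr::imap_dfr(disp_frames, function(d, f) {
    tibble::tibble(run = 1L, frame = f, time_ns = f - 1,
                   atom_id = seq_len(n_at), atom_name = "CA",
                   resid = as.integer(resids), resname = "GLY", chain = "A",
                   element = "C",
                   x = 10 * seq_len(n_at) + d, y = 0, z = 0)
  }) |> as_trajectory()
}

test_that("DCCM normalisation, symmetry and bounds hold", {
  traj <- simulate_correlated_fluctuations(diag(8), 500, seed = 2)
  d <- compute_dccm(traj)
  expect_equal(unname(diag(d$cor)), rep(1, 8))
  expect_lt(max(abs(d$cor - t(d$cor))), 1e-12)
  expect_true(all(d$cor >= -1 & d$cor <= 1))
  expect_named(d$per_run, "run_1")
})

test_that("identical and mirrored displacements give correlation +/-1", {
  # atom 2 copies atom 1's displacements, atom 3 mirrors them
  disp <- list(c(1, 1, -1), c(-0.5, -0.5, 0.5), c(2, 2, -2), c(0, 0, 0))
  traj <- make_disp_traj(disp, resids = 1001:1003)
  d <- compute_dccm(traj)
  expect_equal(d$cor[1, 2], 1)
  expect_equal(d$cor[1, 3], -1)
  expect_equal(d$cor[2, 3], -1)
})

test_that("block-correlated fluctuations are recovered within sampling error", {
  cmat <- block_correlation(c(10, 10), within = 0.8, between = -0.5)
  traj <- simulate_correlated_fluctuations(
    cmat, n_frames = 20000, resids = c(1095:1104, 1141:1150), seed = 7)
  d <- compute_dccm(traj)
  within_1 <- d$cor[1:10, 1:10][upper.tri(diag(10))]
  within_2 <- d$cor[11:20, 11:20][upper.tri(diag(10))]
  between <- d$cor[1:10, 11:20]
  expect_lt(max(abs(within_1 - 0.8)), 0.05)
  expect_lt(max(abs(within_2 - 0.8)), 0.05)
  expect_lt(max(abs(between + 0.5)), 0.05)
})

test_that("zeroing rule is boundary-inclusive, diagonal-preserving, idempotent", {
  traj <- simulate_correlated_fluctuations(diag(4), 50, seed = 3)
  d <- compute_dccm(traj)
  d$cor[1, 2] <- d$cor[2, 1] <- 0.25
  d$cor[1, 3] <- d$cor[3, 1] <- 0.30
  d$cor[1, 4] <- d$cor[4, 1] <- -0.50
  d$cor[2, 3] <- d$cor[3, 2] <- -0.30
  d$cor[2, 4] <- d$cor[4, 2] <- 0.31
  thr <- threshold_dccm(d)
  expect_equal(thr$thresholded[1, 2], 0)      # inside band
  expect_equal(thr$thresholded[1, 3], 0)      # boundary inclusive
  expect_equal(thr$thresholded[2, 3], 0)      # negative boundary
  expect_equal(thr$thresholded[1, 4], -0.50)  # outside band untouched
  expect_equal(thr$thresholded[2, 4], 0.31)
  expect_equal(unname(diag(thr$thresholded)), rep(1, 4))
  expect_equal(thr$cor[1, 2], 0.25)           # original retained
  d2 <- thr
  d2$cor <- thr$thresholded
  expect_equal(threshold_dccm(d2)$thresholded, thr$thresholded)
})

test_that("zero-fluctuation residues are flagged, not silently zeroed", {
  traj <- simulate_correlated_fluctuations(diag(3), 50, sds = c(1, 1, 0),
                                           seed = 4)
  expect_warning(d <- compute_dccm(traj), "zero fluctuation")
  expect_equal(d$undefined_residues, 1003)
  expect_true(all(is.na(d$cor[3, ])))
  expect_true(all(is.na(d$cor[, 3])))
  expect_equal(d$cor[1, 1], 1)
})

test_that("white-noise off-diagonals vanish at large frame counts", {
  traj <- simulate_correlated_fluctuations(diag(10), n_frames = 50000,
                                           seed = 11)
  d <- compute_dccm(traj)
  off <- d$cor[upper.tri(d$cor)]
  expect_lt(max(abs(off)), 0.1)
})

test_that("DCCM is invariant under a global rigid motion after refitting", {
  traj <- simulate_correlated_fluctuations(
    block_correlation(c(4, 4), 0.6, -0.3), 400, sds = 0.5, seed = 6)
  d1 <- compute_dccm(superpose(traj))
  moved <- apply_rigid(traj, random_rotation(8), shift = c(12, -3, 7))
  d2 <- compute_dccm(superpose(moved))
  expect_lt(max(abs(d1$cor - d2$cor)), 1e-6)
})

test_that("DCCM agrees with the bio3d implementation on a shared ensemble", {
  traj <- simulate_correlated_fluctuations(
    block_correlation(c(5, 5), 0.7, -0.4), 2000, seed = 12)
  d <- compute_dccm(traj)
  co <- traj_coords(dplyr::filter(traj, atom_name == "CA"))
  xyz <- matrix(NA_real_, nrow(co$frames), 3 * ncol(co$x))
  xyz[, seq(1, ncol(xyz), 3)] <- co$x
  xyz[, seq(2, ncol(xyz), 3)] <- co$y
  xyz[, seq(3, ncol(xyz), 3)] <- co$z
  oracle <- bio3d::dccm.xyz(xyz)
  expect_lt(max(abs(unname(d$cor) - unname(oracle))), 1e-10)
})

test_that("region coupling summarises cross-blocks and flags anticorrelation", {
  cmat <- block_correlation(c(10, 10), within = 0.8, between = -0.5)
  traj <- simulate_correlated_fluctuations(
    cmat, n_frames = 20000, resids = c(1095:1104, 1141:1150), seed = 7)
  d <- threshold_dccm(compute_dccm(traj))
  rc <- region_coupling(d, region_set()[1:2, ])
  r12 <- dplyr::filter(rc, region_a == "R1", region_b == "R2")
  expect_equal(r12$n_entries, 100)
  expect_gt(r12$frac_anticorrelated, 0.95)
  expect_true(r12$anticorrelated_call)
  expect_error(region_coupling(d, region_set()), "R3")
})

test_that("self-region coupling excludes the diagonal (3-residue enumeration)", {
  traj <- simulate_correlated_fluctuations(diag(3), 100,
                                           resids = 1095:1097, seed = 5)
  d <- compute_dccm(traj)
  rc <- region_coupling(d, region_set()[1, ])
  # by hand: 3x3 block minus diagonal = 6 entries, mean of the off-diagonals
  off <- d$cor[row(d$cor) != col(d$cor)]
  expect_equal(rc$n_entries, 6)
  expect_equal(rc$mean_correlation, mean(off))
})

test_that("all-zero off-diagonal matrix yields zero fractions and means", {
  traj <- simulate_correlated_fluctuations(diag(6), 100,
                                           resids = 1095:1100, seed = 5)
  d <- compute_dccm(traj)
  d$cor[row(d$cor) != col(d$cor)] <- 0
  rc <- region_coupling(d, region_set()[1, ])
  expect_equal(rc$mean_correlation, 0)
  expect_equal(rc$frac_anticorrelated, 0)
  expect_equal(rc$frac_correlated, 0)
})

test_that("contact occupancy counts frames below the heavy-atom cutoff", {
  held_close <- make_pair_traj(rep(3, 10))
  cm <- compute_contact_map(held_close)
  expect_equal(cm$occupancy["1102", "1184"], 1)
  held_far <- make_pair_traj(rep(20, 10))
  expect_equal(compute_contact_map(held_far)$occupancy["1102", "1184"], 0)
  toggling <- make_pair_traj(c(rep(3, 3), rep(20, 7)))
  expect_equal(compute_contact_map(toggling)$occupancy["1102", "1184"], 0.30)
  expect_equal(unname(diag(cm$occupancy)), rep(1, 2))
})
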