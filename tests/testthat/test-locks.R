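test_that("lock engagement is boundary-inclusive on the distance cutoff", {
  traj <- make_pair_traj(c(4, 6, 5.0, 4.9, 20))
  series <- evaluate_locks(traj, lock_definitions()[1, ], engage_cutoff = 5.0)
  expect_equal(series$states$engaged, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(series$states$distance, c(4, 6, 5.0, 4.9, 20))
  # trivial near/far calls
  expect_true(evaluate_locks(make_pair_traj(3.8),
                             lock_definitions()[1, ])$states$engaged)
  expect_false(evaluate_locks(make_pair_traj(12),
                              lock_definitions()[1, ])$states$engaged)
})

test_that("lock distances use minimum side-chain distance, not backbone", {
  # side chains 8 A apart but a backbone CA sits 2 A away: sidechain scope
  # must report 8, heavy scope the backbone-inclusive minimum of 2
  traj <- make_pair_traj(rep(8, 3))
  traj$x[traj$atom_name == "CA" & traj$resid == 1184] <- 2
  traj$z[traj$atom_name == "CA" & traj$resid == 1184] <- 0
  side <- evaluate_locks(traj, lock_definitions()[1, ],
                         atom_scope = "sidechain")
  heavy <- evaluate_locks(traj, lock_definitions()[1, ],
                          atom_scope = "heavy")
  expect_equal(unique(side$states$distance), 8)
  expect_equal(unique(heavy$states$distance), 2)
})

test_that("missing side-chain atoms produce a named error", {
  traj <- make_pair_traj(rep(4, 2))
  bad_locks <- tibble::tibble(lock_id = "D1", resid_a = 1184L,
                              resid_b = 1121L)
  expect_error(evaluate_locks(traj, bad_locks), "1121")
})

test_that("open requires all four locks released", {
  all_released <- make_lock_traj(matrix(9, nrow = 4, ncol = 4,
                                        dimnames = list(NULL, paste0("D", 1:4))))
  s <- evaluate_locks(all_released)
  expect_equal(dplyr::filter(open_fraction(s), scope == "pooled")$open_fraction,
               1)
  # one lock permanently engaged closes every frame whatever the others do
  dm <- matrix(9, nrow = 8, ncol = 4, dimnames = list(NULL, paste0("D", 1:4)))
  dm[, "D3"] <- 4
  dm[1:4, "D1"] <- 4.5
  s2 <- evaluate_locks(make_lock_traj(dm))
  expect_equal(dplyr::filter(open_fraction(s2),
                             scope == "pooled")$open_fraction, 0)
})

test_that("markov-gated open fraction is recovered within 3 SE of truth", {
  pi_open <- 0.10
  p_oc <- 0.1
  p_co <- p_oc * pi_open / (1 - pi_open)
  sim <- simulate_gated_trajectory(gating_model(p_co = p_co, p_oc = p_oc),
                                   n_frames = 20000, seed = 404)
  s <- evaluate_locks(sim$trajectory)
  est <- dplyr::filter(open_fraction(s), scope == "pooled")$open_fraction
  se <- markov_se(pi_open, p_co, p_oc, 20000)
  expect_lt(abs(est - pi_open), 3 * se)
  # classification agrees with generator labels near-perfectly
  agree <- mean(classify_open(s)$open == sim$truth$open)
  expect_gte(agree, 0.999)
})

test_that("per-lock engaged fractions match direct enumeration and truth", {
  dm <- matrix(9, nrow = 4, ncol = 4, dimnames = list(NULL, paste0("D", 1:4)))
  dm[1:3, "D4"] <- 4  # engaged in 3 of 4 frames
  freq <- per_lock_frequency(evaluate_locks(make_lock_traj(dm)))
  expect_equal(dplyr::filter(freq, lock_id == "D4")$engaged_fraction, 0.75)

  probs <- c(0.9, 0.8, 0.7, 0.6)
  sim <- simulate_gated_trajectory(
    gating_model(lock_mode = "independent", engage_probs = probs),
    n_frames = 50000, seed = 71)
  freq2 <- per_lock_frequency(evaluate_locks(sim$trajectory))
  expect_lt(max(abs(freq2$engaged_fraction - probs)), 0.01)
})

test_that("lock-state entropy matches hand-computed histograms", {
  expect_equal(shannon_entropy(rep(5, 16)), 4)
  expect_equal(shannon_entropy(c(10, rep(0, 15))), 0)
  expect_equal(shannon_entropy(c(8, 4, 2, 2)), 1.75)
  # via a constructed lock series: 8 frames of one state, 4+2+2 of others
  states <- c(rep("1111", 8), rep("0000", 4), rep("1010", 2), rep("0101", 2))
  flags <- purrr::imap_dfr(states, function(s, f) {
    tibble::tibble(run = 1L, frame = f, lock_id = paste0("D", 1:4),
                   engaged = strsplit(s, "")[[1]] == "1")
  })
  ent <- lock_state_entropy(lock_series_from_flags(flags))
  expect_equal(ent$entropy_bits, 1.75)
  expect_equal(ent$normalized, 1.75 / 4)
  expect_equal(sum(ent$states$count), 16)
  expect_equal(nrow(ent$states), 16)
})

test_that("entropy is label-permutation invariant and maximal iff uniform", {
  counts <- c(12, 5, 3, 1, rep(0, 12))
  expect_equal(shannon_entropy(counts), shannon_entropy(rev(counts)))
  expect_equal(shannon_entropy(counts), shannon_entropy(sample(counts)))
  expect_lt(shannon_entropy(counts), 4)
  expect_equal(shannon_entropy(rep(3, 16)), 4)
})

test_that("open-state report is consistent with its component statistics", {
  sim1 <- simulate_gated_trajectory(
    gating_model(p_co = 0.001, p_oc = 0.099),  # pi = 0.01
    n_frames = 8000, seed = 21)
  sim2 <- simulate_gated_trajectory(
    gating_model(p_co = 0.1 * 0.19 / 0.81, p_oc = 0.1),   # pi = 0.19
    n_frames = 8000, seed = 22)
  s1 <- evaluate_locks(sim1$trajectory, condition = "low")
  s2 <- evaluate_locks(sim2$trajectory, condition = "high")
  rep <- open_state_report(list(low = s1, high = s2))
  expect_equal(rep$open_pct[1],
               100 * dplyr::filter(open_fraction(s1),
                                   scope == "pooled")$open_fraction)
  expect_equal(rep$D4_engaged_pct[2],
               100 * dplyr::filter(per_lock_frequency(s2),
                                   lock_id == "D4")$engaged_fraction)
  expect_lt(rep$open_pct[1], rep$open_pct[2])  # ordering preserved
  expect_equal(rep$entropy_bits[1], lock_state_entropy(s1)$entropy_bits)
})

test_that("open fraction is monotone in the engagement cutoff with correct limits", {
  sim <- simulate_gated_trajectory(gating_model(p_co = 0.05, p_oc = 0.1),
                                   n_frames = 2000, seed = 33)
  sweep <- cutoff_sweep(sim$trajectory, cutoffs = c(0.5, 4, 4.5, 5, 5.5, 6, 50))
  expect_true(all(diff(sweep$open_fraction) <= 0))
  expect_equal(sweep$open_fraction[1], 1)   # cutoff below all distances
  expect_equal(sweep$open_fraction[nrow(sweep)], 0)  # cutoff above all
})

test_that("open count never exceeds any single lock's released count", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_gated_trajectory(
      gating_model(p_co = 0.03, p_oc = 0.07,
                   lock_mode = if (seed == 2) "independent" else "state",
                   engage_probs = if (seed == 2) c(0.5, 0.6, 0.7, 0.8)),
      n_frames = 3000, seed = seed)
    s <- evaluate_locks(sim$trajectory)
    expect_true(check_gating_invariant(s))
    n_open <- dplyr::filter(open_fraction(s), scope == "pooled")$n_open
    freq <- per_lock_frequency(s)
    expect_true(all(n_open <= freq$n_frames - freq$n_engaged))
  }
})

test_that("open fraction is invariant under frame permutation and run order", {
  sim <- simulate_gated_trajectory(gating_model(p_co = 0.05, p_oc = 0.1),
                                   n_frames = 500, n_runs = 2, seed = 13)
  s <- evaluate_locks(sim$trajectory)
  base <- dplyr::filter(open_fraction(s), scope == "pooled")$open_fraction
  swapped <- sim$trajectory |>
    dplyr::mutate(run = ifelse(run == 1L, 2L, 1L)) |>
    as_trajectory()
  s2 <- evaluate_locks(swapped)
  expect_equal(dplyr::filter(open_fraction(s2),
                             scope == "pooled")$open_fraction, base)
  shuffled <- sim$truth[sample(nrow(sim$truth)), ]
  expect_equal(mean(shuffled$open), mean(sim$truth$open))
})
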