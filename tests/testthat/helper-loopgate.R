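# Fixture builders shared across the suite. All synthetic, built in code.

# Two-residue toy: residue pair with one fixed and one mobile side-chain
# heavy atom realising the given per-frame distances exactly.
make_pair_traj <- function(distances,
                           res_a = list(resid = 1184L, resname = "LEU",
                                        sc = "CD1"),
                           res_b = list(resid = 1102L, resname = "CYS",
                                        sc = "SG"),
                           extra_backbone = TRUE) {
  n <- length(distances)
  atoms <- list(
    list(atom_name = res_b$sc, resid = res_b$resid, resname = res_b$resname,
         x = rep(0, n), y = 0, z = 0),
    list(atom_name = res_a$sc, resid = res_a$resid, resname = res_a$resname,
         x = distances, y = 0, z = 0)
  )
  if (extra_backbone) {
    atoms <- c(atoms, list(
      list(atom_name = "CA", resid = res_b$resid, resname = res_b$resname,
           x = rep(-3, n), y = 0, z = 0),
      list(atom_name = "CA", resid = res_a$resid, resname = res_a$resname,
           x = distances + 3, y = 0, z = 1)
    ))
  }
  rows <- purrr::imap_dfr(atoms, function(a, i) {
    tibble::tibble(
      run = 1L, frame = seq_len(n), time_ns = as.numeric(seq_len(n) - 1),
      atom_id = as.integer(i), atom_name = a$atom_name, resid = a$resid,
      resname = a$resname, chain = "A",
      element = substr(a$atom_name, 1, 1),
      x = rep(a$x, length.out = n), y = rep(a$y, length.out = n),
      z = rep(a$z, length.out = n))
  })
  as_trajectory(rows)
}

# Minimal lock toy: all four lock pairs, each with its own per-frame
# distance matrix (n_frames x 4, columns D1..D4), realised exactly.
make_lock_traj <- function(dist_matrix) {
  n <- nrow(dist_matrix)
  zone <- c(D1 = 0, D2 = 100, D3 = 200, D4 = 300)
  spec <- list(
    list(atom_name = "SG", resid = 1102L, resname = "CYS", zone = "D1", x = 0),
    list(atom_name = "CB", resid = 1102L, resname = "CYS", zone = "D2", x = 0),
    list(atom_name = "OG1", resid = 1121L, resname = "THR", zone = "D3", x = 0),
    list(atom_name = "CG2", resid = 1121L, resname = "THR", zone = "D4", x = 0),
    list(atom_name = "CD1", resid = 1184L, resname = "LEU", zone = "D1",
         x = dist_matrix[, "D1"]),
    list(atom_name = "SG", resid = 1183L, resname = "CYS", zone = "D2",
         x = dist_matrix[, "D2"]),
    list(atom_name = "CB", resid = 1183L, resname = "CYS", zone = "D3",
         x = dist_matrix[, "D3"]),
    list(atom_name = "CD1", resid = 1181L, resname = "LEU", zone = "D4",
         x = dist_matrix[, "D4"])
  )
  rows <- purrr::imap_dfr(spec, function(a, i) {
    tibble::tibble(
      run = 1L, frame = seq_len(n), time_ns = as.numeric(seq_len(n) - 1),
      atom_id = as.integer(i), atom_name = a$atom_name, resid = a$resid,
      resname = a$resname, chain = "A",
      element = substr(a$atom_name, 1, 1),
      x = rep(a$x, length.out = n), y = zone[[a$zone]], z = 0)
  })
  as_trajectory(rows)
}

# standard error of the occupancy estimate of a stationary two-state chain,
# inflated for autocorrelation: var = pi(1-pi)/n * (1+lambda)/(1-lambda)
markov_se <- function(pi_open, p_co, p_oc, n) {
  lambda <- 1 - p_co - p_oc
  sqrt(pi_open * (1 - pi_open) / n * (1 + lambda) / (1 - lambda))
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

apply_rigid <- function(traj, rot, shift = c(0, 0, 0)) {
  xyz <- as.matrix(traj[, c("x", "y", "z")]) %*% rot
  traj$x <- xyz[, 1] + shift[1]
  traj$y <- xyz[, 2] + shift[2]
  traj$z <- xyz[, 3] + shift[3]
  traj
}
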