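#' Trajectory tibbles
#'
#' A trajectory is stored as a long tibble with one row per atom per frame and
#' columns `run`, `frame`, `time_ns`, `atom_id`, `atom_name`, `resid`,
#' `resname`, `chain`, `element`, `x`, `y`, `z` (coordinates in Angstrom,
#' times in nanoseconds). All runs share one topology; frame times are
#' strictly increasing within a run. `as_trajectory()` validates a data frame
#' against this contract and is called by every reader and generator.
#'
#' @param data A data frame with the columns listed above.
#' @return A validated trajectory tibble.
#' @export
as_trajectory <- function(data) {
  required <- c("run", "frame", "time_ns", "atom_id", "atom_name", "resid",
                "resname", "chain", "element", "x", "y", "z")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("trajectory is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  traj <- as_tibble(data) |>
    arrange(.data$run, .data$frame, .data$atom_id)
  if (nrow(traj) == 0) {
    abort("trajectory has zero frames")
  }
  if (!all(is.finite(traj$x) & is.finite(traj$y) & is.finite(traj$z))) {
    abort("trajectory coordinates must be finite")
  }
  # one shared topology: every (run, frame) carries the identical atom set
  topo <- traj |>
    filter(.data$run == traj$run[1], .data$frame == traj$frame[1]) |>
    select("atom_id", "atom_name", "resid", "resname", "chain", "element")
  if (anyDuplicated(topo$atom_id) > 0) {
    abort("atom_ids must be unique within a frame")
  }
  n_atoms <- nrow(topo)
  frames <- traj |> count(.data$run, .data$frame, name = "n_atoms")
  if (any(frames$n_atoms != n_atoms)) {
    abort("all frames must contain the same atoms as the topology")
  }
  times <- traj |> distinct(.data$run, .data$frame, .data$time_ns)
  bad <- times |>
    group_by(.data$run) |>
    summarise(ok = all(diff(.data$time_ns) > 0) || n() == 1) |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("frame times must be strictly increasing within run ",
                 paste(bad$run, collapse = ", ")))
  }
  traj
}

#' Extract the topology of a trajectory
#'
#' @param traj A trajectory tibble (see [as_trajectory()]).
#' @return A tibble with one row per atom: `atom_id`, `atom_name`, `resid`,
#'   `resname`, `chain`, `element`.
#' @export
trajectory_topology <- function(traj) {
  traj |>
    filter(.data$run == traj$run[1], .data$frame == traj$frame[1]) |>
    select("atom_id", "atom_name", "resid", "resname", "chain", "element") |>
    arrange(.data$atom_id)
}

# frame index (run, frame, time_ns), one row per retained frame, sorted
traj_frames <- function(traj) {
  traj |>
    distinct(.data$run, .data$frame, .data$time_ns) |>
    arrange(.data$run, .data$frame)
}

# Dense coordinate view: x/y/z matrices of n_frames_total x n_atoms, plus the
# topology (column order) and frame index (row order). Single allocation;
# every numerical routine works from this.
traj_coords <- function(traj) {
  traj <- arrange(traj, .data$run, .data$frame, .data$atom_id)
  topo <- trajectory_topology(traj)
  frames <- traj_frames(traj)
  n_atoms <- nrow(topo)
  n_frames <- nrow(frames)
  list(
    topology = topo,
    frames = frames,
    x = matrix(traj$x, nrow = n_frames, ncol = n_atoms, byrow = TRUE),
    y = matrix(traj$y, nrow = n_frames, ncol = n_atoms, byrow = TRUE),
    z = matrix(traj$z, nrow = n_frames, ncol = n_atoms, byrow = TRUE)
  )
}

# inverse of traj_coords: rebuild the long tibble from a dense view
coords_to_traj <- function(co) {
  n_atoms <- nrow(co$topology)
  n_frames <- nrow(co$frames)
  frame_rep <- co$frames[rep(seq_len(n_frames), each = n_atoms), ]
  topo_rep <- co$topology[rep(seq_len(n_atoms), times = n_frames), ]
  tibble(
    run = frame_rep$run,
    frame = frame_rep$frame,
    time_ns = frame_rep$time_ns,
    atom_id = topo_rep$atom_id,
    atom_name = topo_rep$atom_name,
    resid = topo_rep$resid,
    resname = topo_rep$resname,
    chain = topo_rep$chain,
    element = topo_rep$element,
    x = as.vector(t(co$x)),
    y = as.vector(t(co$y)),
    z = as.vector(t(co$z))
  )
}

infer_element <- function(atom_name) {
  first <- sub("^[0-9]*", "", atom_name)
  substr(first, 1, 1)
}

#' Read a trajectory from PDB (and optional DCD) files
#'
#' Loads a topology from a PDB file (single- or multi-model) and, optionally,
#' per-run coordinate files. Each trajectory file becomes one run; with no
#' trajectory files the models of the topology PDB form a single run. PDB
#' files carry no time axis, so frame times are assigned uniformly as
#' `t0_ns + dt_ns * (0, 1, 2, ...)` per run.
#'
#' @param topology_path Path to a PDB file.
#' @param trajectory_paths Optional character vector of per-run coordinate
#'   files (multi-model PDB or DCD; format chosen by extension).
#' @param dt_ns Frame spacing in ns used when files carry no times.
#' @param t0_ns Time of the first frame in ns.
#' @return A trajectory tibble.
#' @export
read_trajectory <- function(topology_path, trajectory_paths = NULL,
                            dt_ns = 1, t0_ns = 0) {
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  topo <- tibble(
    atom_id = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    resid = as.integer(at$resno),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    element = ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
                     infer_element(trimws(at$elety)), trimws(at$elesy))
  )
  n_atoms <- nrow(topo)

  run_xyz <- list()
  if (is.null(trajectory_paths)) {
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    run_xyz[[1]] <- xyz
  } else {
    for (i in seq_along(trajectory_paths)) {
      path <- trajectory_paths[[i]]
      if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
        xyz <- bio3d::read.dcd(path, verbose = FALSE)
      } else {
        tp <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
        xyz <- tp$xyz
      }
      if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
      if (ncol(xyz) != 3 * n_atoms) {
        abort(sprintf(
          "atom count mismatch: topology has %d atoms but '%s' has %d",
          n_atoms, path, ncol(xyz) / 3))
      }
      run_xyz[[i]] <- xyz
    }
  }
  if (sum(vapply(run_xyz, nrow, integer(1))) == 0) {
    abort("no frames found in input files")
  }

  runs <- purrr::imap(run_xyz, function(xyz, i) {
    n_frames <- nrow(xyz)
    idx <- rep(seq_len(n_frames), each = n_atoms)
    tibble(
      run = as.integer(i),
      frame = idx,
      time_ns = t0_ns + dt_ns * (idx - 1),
      atom_id = rep(topo$atom_id, times = n_frames),
      atom_name = rep(topo$atom_name, times = n_frames),
      resid = rep(topo$resid, times = n_frames),
      resname = rep(topo$resname, times = n_frames),
      chain = rep(topo$chain, times = n_frames),
      element = rep(topo$element, times = n_frames),
      x = as.vector(t(xyz[, seq(1, 3 * n_atoms, 3), drop = FALSE])),
      y = as.vector(t(xyz[, seq(2, 3 * n_atoms, 3), drop = FALSE])),
      z = as.vector(t(xyz[, seq(3, 3 * n_atoms, 3), drop = FALSE]))
    )
  })
  as_trajectory(bind_rows(runs))
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, runs concatenated in order. Coordinates
#' are written at PDB precision (0.001 Angstrom).
#'
#' @param traj A trajectory tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  co <- traj_coords(traj)
  topo <- co$topology
  n_frames <- nrow(co$frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      topo$atom_id,
      ifelse(nchar(topo$atom_name) < 4, paste0(" ", topo$atom_name),
             topo$atom_name),
      topo$resname, topo$chain, topo$resid,
      co$x[f, ], co$y[f, ], co$z[f, ], topo$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Restrict a trajectory to an analysis window
#'
#' Removes equilibration frames (times below `discard_initial_ns`) from each
#' run and then keeps every `stride`-th surviving frame. The default discards
#' the first 100 ns, the convention of analysing the last 400 ns of 500-ns
#' production runs.
#'
#' @param traj A trajectory tibble.
#' @param discard_initial_ns Initial simulated time to drop, in ns (>= 0).
#' @param stride Keep every `stride`-th frame of the remainder (>= 1).
#' @return The windowed trajectory tibble.
#' @export
apply_window <- function(traj, discard_initial_ns = 100, stride = 1) {
  if (discard_initial_ns < 0) abort("discard_initial_ns must be >= 0")
  if (stride < 1) abort("stride must be >= 1")
  stride <- as.integer(stride)
  frames <- traj_frames(traj)
  kept <- frames |>
    filter(.data$time_ns >= discard_initial_ns) |>
    group_by(.data$run) |>
    filter((dplyr::row_number() - 1L) %% stride == 0L) |>
    ungroup()
  empty <- setdiff(unique(frames$run), unique(kept$run))
  if (length(empty) > 0) {
    abort(paste0("analysis window leaves no frames in run ",
                 paste(empty, collapse = ", ")))
  }
  out <- dplyr::semi_join(traj, kept, by = c("run", "frame"))
  attr(out, "window") <- list(discard_initial_ns = discard_initial_ns,
                              stride = stride)
  out
}

# Kabsch rotation: 3x3 matrix R minimizing ||Pc %*% R - Qc|| for centred
# row-coordinate matrices
kabsch_rotation <- function(pc, qc) {
  h <- crossprod(pc, qc)
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Rigid-body superposition onto a mean reference
#'
#' Least-squares fits every frame (optimal rotation plus translation) onto a
#' reference structure using the fit atoms, by default the C-alpha atoms of
#' all residues. The reference is the ensemble mean, refined iteratively:
#' frames are fitted to the current mean fit-atom structure, the mean is
#' recomputed, and the cycle repeats until the mean stabilises. Starting from
#' the raw ensemble mean (with a first-frame fallback if that mean is
#' geometrically degenerate) makes the operation exactly idempotent: an
#' already-fitted ensemble is left untouched. Superposition is required
#' before fluctuation (DCCM) analysis so that internal motions are not
#' confounded with rigid-body drift.
#'
#' @param traj A trajectory tibble.
#' @param fit_resids Residue numbers used for fitting (default: all).
#' @param fit_atom_name Atom name selecting one fit atom per residue
#'   (default `"CA"`).
#' @param max_iter,tol Convergence controls for the mean-reference iteration.
#' @return The superposed trajectory tibble.
#' @export
superpose <- function(traj, fit_resids = NULL, fit_atom_name = "CA",
                      max_iter = 20, tol = 1e-9) {
  co <- traj_coords(traj)
  topo <- co$topology
  sel <- topo$atom_name == fit_atom_name
  if (!is.null(fit_resids)) sel <- sel & topo$resid %in% fit_resids
  if (sum(sel) < 3) {
    abort(sprintf(
      "degenerate fit: need at least 3 fit atoms, found %d (atom '%s')",
      sum(sel), fit_atom_name))
  }
  fit_to_reference <- function(co, ref) {
    n_frames <- nrow(co$frames)
    qbar <- colMeans(ref)
    qc <- sweep(ref, 2, qbar)
    for (f in seq_len(n_frames)) {
      p <- cbind(co$x[f, ], co$y[f, ], co$z[f, ])
      pbar <- colMeans(p[sel, , drop = FALSE])
      r <- kabsch_rotation(sweep(p[sel, , drop = FALSE], 2, pbar), qc)
      new <- sweep(sweep(p, 2, pbar) %*% r, 2, qbar, `+`)
      co$x[f, ] <- new[, 1]; co$y[f, ] <- new[, 2]; co$z[f, ] <- new[, 3]
    }
    co
  }
  fit_mean <- function(co) {
    cbind(colMeans(co$x[, sel, drop = FALSE]),
          colMeans(co$y[, sel, drop = FALSE]),
          colMeans(co$z[, sel, drop = FALSE]))
  }
  ref <- fit_mean(co)
  svals <- svd(sweep(ref, 2, colMeans(ref)))$d
  if (svals[1] == 0 || svals[3] / svals[1] < 1e-8) {
    ref <- cbind(co$x[1, sel], co$y[1, sel], co$z[1, sel])
  }
  for (i in seq_len(max_iter)) {
    co <- fit_to_reference(co, ref)
    new_ref <- fit_mean(co)
    delta <- max(abs(new_ref - ref))
    ref <- new_ref
    if (delta < tol) break
  }
  coords_to_traj(co)
}
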