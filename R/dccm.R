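#' Dynamic cross-correlation map of residue fluctuations
#'
#' Computes the residue-wise dynamic cross-correlation matrix
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}}}
#' where \eqn{\Delta r_i} is the displacement of residue *i*'s selected atom
#' (default C-alpha) from its mean position. Mean positions are removed per
#' run (so slow inter-run drift does not inflate correlations) and the
#' scalar-product averages are pooled over all retained frames of all runs.
#' Per-run matrices are retained alongside the pooled one. The ensemble must
#' be superposed first (see [superpose()]); the function cannot verify this.
#'
#' Residues whose selected atom shows zero total fluctuation have no defined
#' correlation; their rows and columns are set to `NA` and reported in a
#' warning and in the `undefined_residues` field, never silently zeroed.
#'
#' @param traj A superposed trajectory tibble.
#' @param atom_name Atom used to represent each residue (default `"CA"`).
#' @return An object of class `loopgate_dccm` with fields `cor` (pooled
#'   matrix), `per_run` (list of per-run matrices), `residues`,
#'   `undefined_residues`, and (after [threshold_dccm()]) `thresholded` and
#'   `threshold`.
#' @export
compute_dccm <- function(traj, atom_name = "CA") {
  sub <- filter(traj, .data$atom_name == !!atom_name)
  if (nrow(sub) == 0) {
    abort(sprintf("no atoms named '%s' in trajectory", atom_name))
  }
  co <- traj_coords(sub)
  if (nrow(co$frames) < 2) abort("DCCM requires at least 2 frames")
  residues <- co$topology$resid
  runs <- unique(co$frames$run)

  run_sums <- purrr::map(runs, function(r) {
    idx <- co$frames$run == r
    dx <- scale(co$x[idx, , drop = FALSE], scale = FALSE)
    dy <- scale(co$y[idx, , drop = FALSE], scale = FALSE)
    dz <- scale(co$z[idx, , drop = FALSE], scale = FALSE)
    list(s = crossprod(dx) + crossprod(dy) + crossprod(dz), n = sum(idx))
  })
  normalise <- function(s) {
    v <- diag(s)
    denom <- sqrt(outer(v, v))
    c_mat <- s / denom
    c_mat[v == 0, ] <- NA_real_
    c_mat[, v == 0] <- NA_real_
    c_mat <- pmin(pmax(c_mat, -1), 1)
    diag(c_mat)[v > 0] <- 1
    dimnames(c_mat) <- list(residues, residues)
    c_mat
  }
  pooled_s <- Reduce(`+`, purrr::map(run_sums, "s"))
  pooled <- normalise(pooled_s)
  undefined <- residues[diag(pooled_s) == 0]
  if (length(undefined) > 0) {
    warn(paste0("residues with zero fluctuation (correlation undefined): ",
                paste(undefined, collapse = ", ")))
  }
  per_run <- setNames(purrr::map(run_sums, function(rs) normalise(rs$s)),
                      paste0("run_", runs))
  structure(
    list(cor = pooled, per_run = per_run, residues = residues,
         undefined_residues = undefined, atom_name = atom_name,
         threshold = NULL, thresholded = NULL),
    class = "loopgate_dccm")
}

#' Apply the display-threshold (zeroing) rule to a correlation matrix
#'
#' Correlation coefficients with magnitude at or below `threshold` (default
#' 0.3, the conventional band for visualising only significant couplings)
#' are set to zero; the boundary is inclusive. The diagonal and the original
#' matrix are preserved.
#'
#' @param dccm A `loopgate_dccm` object.
#' @param threshold Magnitude below (or at) which entries display as zero.
#' @return The `loopgate_dccm` with `thresholded` and `threshold` filled in.
#' @export
threshold_dccm <- function(dccm, threshold = 0.3) {
  stopifnot(inherits(dccm, "loopgate_dccm"))
  m <- dccm$cor
  zero <- !is.na(m) & abs(m) <= threshold
  diag(zero) <- FALSE
  m[zero] <- 0
  dccm$thresholded <- m
  dccm$threshold <- threshold
  dccm
}

#' @export
print.loopgate_dccm <- function(x, ...) {
  cat(sprintf("<loopgate_dccm> %d residues (%s), %d run(s)%s\n",
              length(x$residues), x$atom_name, length(x$per_run),
              if (!is.null(x$threshold))
                sprintf(", thresholded at |c| <= %.2f", x$threshold)
              else ""))
  if (length(x$undefined_residues) > 0) {
    cat("  undefined (zero-fluctuation) residues:",
        paste(x$undefined_residues, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.loopgate_dccm <- function(x, ...) {
  m <- x$cor
  out <- tibble(
    resid_i = rep(x$residues, times = length(x$residues)),
    resid_j = rep(x$residues, each = length(x$residues)),
    correlation = as.vector(m)
  )
  if (!is.null(x$thresholded)) {
    out$thresholded <- as.vector(x$thresholded)
  }
  out
}

#' Named residue regions of the SET domain
#'
#' Default regions used to summarise coupled motions: R1 (1095-1130, the
#' H3V35/H3P38-binding patch side), R2 (1140-1150, containing T1150) and R3
#' (1177-1203, the post-SET loop carrying the autoinhibitory loop).
#'
#' @param ... Named integer vectors overriding or extending the defaults,
#'   e.g. `region_set(R4 = 1210:1220)`.
#' @return A tibble with columns `region`, `from`, `to`.
#' @export
region_set <- function(...) {
  defaults <- list(R1 = c(1095L, 1130L), R2 = c(1140L, 1150L),
                   R3 = c(1177L, 1203L))
  extra <- list(...)
  extra <- purrr::map(extra, function(v) c(min(v), max(v)))
  regions <- modifyList(defaults, extra)
  tibble(
    region = names(regions),
    from = purrr::map_int(regions, function(v) as.integer(v[1])),
    to = purrr::map_int(regions, function(v) as.integer(v[2]))
  )
}

#' Summarise correlation coupling between residue regions
#'
#' For every ordered pair of regions, summarises the cross-block correlation
#' entries: the mean coefficient and the fractions of entries at or beyond
#' the +/- threshold. A region pair is called anti-correlated when the
#' fraction of entries \eqn{c \le -\mathrm{threshold}} exceeds
#' `call_threshold`. For a region paired with itself the diagonal is
#' excluded.
#'
#' @param dccm A `loopgate_dccm` object.
#' @param regions A region tibble from [region_set()].
#' @param threshold Correlation magnitude defining "significant" coupling
#'   (defaults to the matrix's stored display threshold, else 0.3).
#' @param call_threshold Minimum anti-correlated fraction for the
#'   qualitative anti-correlation call.
#' @return A tibble with one row per ordered region pair.
#' @export
region_coupling <- function(dccm, regions = region_set(), threshold = NULL,
                            call_threshold = 0.10) {
  stopifnot(inherits(dccm, "loopgate_dccm"))
  threshold <- threshold %||% dccm$threshold %||% 0.3
  res <- dccm$residues
  members <- purrr::map(seq_len(nrow(regions)), function(i) {
    which(res >= regions$from[i] & res <= regions$to[i])
  })
  names(members) <- regions$region
  empty <- regions$region[purrr::map_int(members, length) == 0]
  if (length(empty) > 0) {
    abort(paste0("region(s) with no residues in the matrix: ",
                 paste(empty, collapse = ", ")))
  }
  pairs <- tidyr::expand_grid(region_a = regions$region,
                              region_b = regions$region)
  purrr::pmap_dfr(pairs, function(region_a, region_b) {
    ia <- members[[region_a]]
    ib <- members[[region_b]]
    block <- dccm$cor[ia, ib, drop = FALSE]
    if (region_a == region_b) {
      keep <- row(block) != col(block)
      vals <- block[keep]
    } else {
      vals <- as.vector(block)
    }
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
      return(tibble(region_a, region_b, n_entries = 0L,
                    mean_correlation = NA_real_, frac_anticorrelated = NA_real_,
                    frac_correlated = NA_real_, anticorrelated_call = NA))
    }
    frac_anti <- mean(vals <= -threshold)
    tibble(
      region_a, region_b,
      n_entries = length(vals),
      mean_correlation = mean(vals),
      frac_anticorrelated = frac_anti,
      frac_correlated = mean(vals >= threshold),
      anticorrelated_call = frac_anti > call_threshold
    )
  })
}

#' Residue-residue contact occupancy map
#'
#' Occupancy of residue pair (i, j) is the fraction of frames in which the
#' minimum heavy-atom distance between the residues is at or below
#' `distance_cutoff` (default 4.5 Angstrom). Used to check that local
#' packing is maintained along a trajectory.
#'
#' @param traj A trajectory tibble.
#' @param distance_cutoff Contact distance in Angstrom.
#' @return An object of class `loopgate_contact_map` with fields `occupancy`
#'   (symmetric matrix with unit diagonal), `residues` and `distance_cutoff`.
#' @export
compute_contact_map <- function(traj, distance_cutoff = 4.5) {
  heavy <- filter(traj, toupper(.data$element) != "H")
  if (nrow(heavy) == 0) abort("no heavy atoms present")
  co <- traj_coords(heavy)
  residues <- sort(unique(co$topology$resid))
  n_res <- length(residues)
  n_frames <- nrow(co$frames)
  occ <- diag(1, n_res)
  dimnames(occ) <- list(residues, residues)
  atom_idx <- purrr::map(residues, function(r) which(co$topology$resid == r))
  for (i in seq_len(n_res - 1)) {
    for (j in seq((i + 1), n_res)) {
      dmin <- rep(Inf, n_frames)
      for (a in atom_idx[[i]]) {
        for (b in atom_idx[[j]]) {
          d2 <- (co$x[, a] - co$x[, b])^2 + (co$y[, a] - co$y[, b])^2 +
            (co$z[, a] - co$z[, b])^2
          dmin <- pmin(dmin, d2)
        }
      }
      occ[i, j] <- occ[j, i] <- mean(sqrt(dmin) <= distance_cutoff)
    }
  }
  structure(
    list(occupancy = occ, residues = residues,
         distance_cutoff = distance_cutoff),
    class = "loopgate_contact_map")
}

#' @export
print.loopgate_contact_map <- function(x, ...) {
  cat(sprintf("<loopgate_contact_map> %d residues, cutoff %.2f A\n",
              length(x$residues), x$distance_cutoff))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.loopgate_contact_map <- function(x, ...) {
  tibble(
    resid_i = rep(x$residues, times = length(x$residues)),
    resid_j = rep(x$residues, each = length(x$residues)),
    occupancy = as.vector(x$occupancy)
  )
}
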