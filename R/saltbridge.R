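#' Default salt-bridge pairs around the autoinhibitory loop
#'
#' The charged cluster surrounding the autoinhibitory loop forms a network
#' of salt bridges (D1098, E1099/K1099, D1123, K1124, D1125, R1126, K1152,
#' D1158, D1182). The defaults cover the bridges named in the text: the
#' D1123-K1152 bridge that conditions loop opening, E1099-K1124,
#' D1182-K1152, and the K1099-D1125 bridge formed by the E1099K mutant.
#' Pairs whose residues are absent from a topology must be dropped by the
#' caller; [detect_salt_bridges()] validates chemistry.
#'
#' @return A tibble with columns `acidic_resid`, `basic_resid`.
#' @export
salt_bridge_pairs <- function() {
  tibble(
    acidic_resid = c(1123L, 1099L, 1182L, 1125L),
    basic_resid = c(1152L, 1124L, 1152L, 1099L)
  )
}

.acidic_oxygens <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basic_nitrogens <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                         HIS = c("ND1", "NE2"))

#' Detect salt bridges along a trajectory
#'
#' A bridge is present in a frame when the minimum distance between any
#' side-chain carboxylate oxygen of the acidic residue (ASP OD1/OD2,
#' GLU OE1/OE2) and any charged side-chain nitrogen of the basic residue
#' (LYS NZ, ARG NE/NH1/NH2) is at or below `contact_cutoff` (default 4.0
#' Angstrom). Histidine is accepted as the basic partner only with
#' `include_his = TRUE`, since its protonation state is not modelled.
#'
#' @param traj A trajectory tibble.
#' @param pairs Tibble of `acidic_resid`, `basic_resid`
#'   (default [salt_bridge_pairs()]).
#' @param contact_cutoff Contact distance in Angstrom.
#' @param include_his Allow HIS as the basic residue.
#' @return An object of class `bridge_series`: list with `states` (tibble of
#'   `run`, `frame`, `time_ns`, `pair`, `distance`, `present`), `pairs` and
#'   `contact_cutoff`.
#' @export
detect_salt_bridges <- function(traj, pairs = salt_bridge_pairs(),
                                contact_cutoff = 4, include_his = FALSE) {
  co <- traj_coords(traj)
  topo <- co$topology
  res_name <- function(resid) {
    nm <- unique(topo$resname[topo$resid == resid])
    if (length(nm) == 0) abort(sprintf("residue %d not in topology", resid))
    nm[1]
  }
  basic_ok <- c("LYS", "ARG", if (include_his) "HIS")
  states <- purrr::pmap_dfr(pairs, function(acidic_resid, basic_resid) {
    a_name <- res_name(acidic_resid)
    b_name <- res_name(basic_resid)
    if (!a_name %in% names(.acidic_oxygens)) {
      abort(sprintf(
        "salt-bridge definition error: residue %d (%s) is not acidic (ASP/GLU)",
        acidic_resid, a_name))
    }
    if (!b_name %in% basic_ok) {
      abort(sprintf(
        "salt-bridge definition error: residue %d (%s) is not basic (%s)",
        basic_resid, b_name, paste(basic_ok, collapse = "/")))
    }
    ia <- which(topo$resid == acidic_resid &
                  topo$atom_name %in% .acidic_oxygens[[a_name]])
    ib <- which(topo$resid == basic_resid &
                  topo$atom_name %in% .basic_nitrogens[[b_name]])
    if (length(ia) == 0 || length(ib) == 0) {
      abort(sprintf(
        "missing charged-group atoms for pair %d-%d (need %s / %s)",
        acidic_resid, basic_resid,
        paste(.acidic_oxygens[[a_name]], collapse = ","),
        paste(.basic_nitrogens[[b_name]], collapse = ",")))
    }
    dmin <- rep(Inf, nrow(co$frames))
    for (a in ia) {
      for (b in ib) {
        d2 <- (co$x[, a] - co$x[, b])^2 + (co$y[, a] - co$y[, b])^2 +
          (co$z[, a] - co$z[, b])^2
        dmin <- pmin(dmin, d2)
      }
    }
    d <- sqrt(dmin)
    tibble(run = co$frames$run, frame = co$frames$frame,
           time_ns = co$frames$time_ns,
           pair = sprintf("%s%d-%s%d", bio3d::aa321(a_name), acidic_resid,
                          bio3d::aa321(b_name), basic_resid),
           distance = d, present = d <= contact_cutoff)
  })
  structure(
    list(states = states, pairs = pairs, contact_cutoff = contact_cutoff),
    class = "bridge_series")
}

#' @export
print.bridge_series <- function(x, ...) {
  occ <- bridge_occupancy(x)
  cat(sprintf("<bridge_series> %d pair(s), cutoff %.2f A\n",
              nrow(occ), x$contact_cutoff))
  print(occ)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bridge_series <- function(x, ...) x$states

#' Per-pair salt-bridge occupancy
#'
#' @param bridges A `bridge_series`.
#' @return A tibble: `pair`, `n_frames`, `n_present`, `occupancy`.
#' @export
bridge_occupancy <- function(bridges) {
  stopifnot(inherits(bridges, "bridge_series"))
  bridges$states |>
    group_by(.data$pair) |>
    summarise(n_frames = n(), n_present = sum(.data$present),
              .groups = "drop") |>
    mutate(occupancy = .data$n_present / .data$n_frames)
}

#' Loop-opening probability conditioned on a salt bridge
#'
#' Crosses the per-frame open/closed classification with the presence of one
#' salt bridge and reports P(open | bridge present), P(open | bridge
#' broken), and the odds ratio odds(open | broken) / odds(open | present)
#' (> 1 means the loop favours the open state when the bridge is broken).
#' The odds ratio uses the Haldane-Anscombe 0.5 correction when any cell of
#' the 2x2 table is zero. A conditioning set with no frames (e.g. a bridge
#' that is always present) yields `NA` for that conditional and
#' `estimable = FALSE`, never a silent NaN.
#'
#' @param bridges A `bridge_series`.
#' @param open_flags Per-frame open flags from [classify_open()].
#' @param pair Pair label to condition on (required when `bridges` holds
#'   more than one pair).
#' @return A one-row tibble with the 2x2 counts (`n_open_present`,
#'   `n_closed_present`, `n_open_broken`, `n_closed_broken`), the two
#'   conditional probabilities, `odds_ratio` and `estimable`.
#' @export
conditional_open_probability <- function(bridges, open_flags, pair = NULL) {
  stopifnot(inherits(bridges, "bridge_series"))
  pairs_avail <- unique(bridges$states$pair)
  if (is.null(pair)) {
    if (length(pairs_avail) != 1) {
      abort(paste0("specify `pair`; available: ",
                   paste(pairs_avail, collapse = ", ")))
    }
    pair <- pairs_avail
  }
  b <- filter(bridges$states, .data$pair == !!pair)
  if (nrow(b) == 0) abort(sprintf("pair '%s' not in bridge series", pair))
  joined <- dplyr::inner_join(
    select(b, "run", "frame", "present"),
    select(open_flags, "run", "frame", "open"),
    by = c("run", "frame"))
  if (nrow(joined) != nrow(b) || nrow(joined) != nrow(open_flags)) {
    abort("frame mismatch between bridge series and open flags")
  }
  n_op <- sum(joined$present & joined$open)
  n_cp <- sum(joined$present & !joined$open)
  n_ob <- sum(!joined$present & joined$open)
  n_cb <- sum(!joined$present & !joined$open)
  p_present <- (n_op + n_cp)
  p_broken <- (n_ob + n_cb)
  p_open_present <- if (p_present > 0) n_op / p_present else NA_real_
  p_open_broken <- if (p_broken > 0) n_ob / p_broken else NA_real_
  estimable <- p_present > 0 && p_broken > 0
  if (!estimable) {
    inform(sprintf(
      "pair %s: bridge %s in every frame; conditional not estimable",
      pair, if (p_present > 0) "present" else "broken"))
  }
  cells <- c(n_op, n_cp, n_ob, n_cb)
  if (estimable) {
    if (any(cells == 0)) cells <- cells + 0.5
    odds_ratio <- (cells[3] / cells[4]) / (cells[1] / cells[2])
  } else {
    odds_ratio <- NA_real_
  }
  tibble(
    pair = pair,
    n_open_present = n_op, n_closed_present = n_cp,
    n_open_broken = n_ob, n_closed_broken = n_cb,
    p_open_given_present = p_open_present,
    p_open_given_broken = p_open_broken,
    odds_ratio = odds_ratio,
    estimable = estimable
  )
}
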