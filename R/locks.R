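#' The four distance locks of the autoinhibitory loop
#'
#' Residue-pair distance measures encoding the hydrophobic contacts that hold
#' the NSD2 autoinhibitory loop closed over the H3V35-binding patch:
#' D1 L1184-C1102, D2 C1183-C1102, D3 C1183-T1121, D4 L1181-T1121. A lock is
#' "engaged" when the residues are in contact and "released" otherwise; the
#' loop is "open" in a frame only when all four locks are simultaneously
#' released. An optional fifth distance series (D5 L1181-T1150, off by
#' default) tracks the additional threonine contact of L1181.
#'
#' @param include_d5 Also track the L1181-T1150 distance.
#' @return A tibble with columns `lock_id`, `resid_a`, `resid_b`.
#' @export
lock_definitions <- function(include_d5 = FALSE) {
  locks <- tibble(
    lock_id = c("D1", "D2", "D3", "D4"),
    resid_a = c(1184L, 1183L, 1183L, 1181L),
    resid_b = c(1102L, 1102L, 1121L, 1121L)
  )
  if (include_d5) {
    locks <- bind_rows(locks, tibble(lock_id = "D5", resid_a = 1181L,
                                     resid_b = 1150L))
  }
  locks
}

# backbone atom names; side-chain scope excludes these (and hydrogens)
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

# per-frame minimum distance between two residues' atoms within scope
residue_pair_min_dist <- function(co, resid_a, resid_b, scope) {
  topo <- co$topology
  in_scope <- toupper(topo$element) != "H"
  if (scope == "sidechain") {
    in_scope <- in_scope & !(topo$atom_name %in% .backbone_atoms)
  }
  ia <- which(topo$resid == resid_a & in_scope)
  ib <- which(topo$resid == resid_b & in_scope)
  if (length(ia) == 0 || length(ib) == 0) {
    missing <- c(if (length(ia) == 0) resid_a, if (length(ib) == 0) resid_b)
    abort(sprintf("no %s heavy atoms found for residue(s) %s",
                  if (scope == "sidechain") "side-chain" else "",
                  paste(missing, collapse = ", ")))
  }
  dmin <- rep(Inf, nrow(co$frames))
  for (a in ia) {
    for (b in ib) {
      d2 <- (co$x[, a] - co$x[, b])^2 + (co$y[, a] - co$y[, b])^2 +
        (co$z[, a] - co$z[, b])^2
      dmin <- pmin(dmin, d2)
    }
  }
  sqrt(dmin)
}

#' Evaluate the distance locks frame by frame
#'
#' For each frame and lock, the lock distance is the minimum pairwise
#' distance between the two residues' atoms within `atom_scope` (side-chain
#' heavy atoms by default, since the locks encode side-chain hydrophobic
#' contacts). A lock is engaged when its distance is at or below
#' `engage_cutoff` (boundary inclusive; default 5.0 Angstrom). The raw
#' distance series is retained for plotting.
#'
#' @param traj A trajectory tibble.
#' @param locks Lock definitions, see [lock_definitions()].
#' @param engage_cutoff Engagement distance in Angstrom.
#' @param atom_scope `"sidechain"` (side-chain heavy atoms) or `"heavy"`
#'   (all heavy atoms).
#' @param condition Optional condition label carried into reports.
#' @return An object of class `lock_series`: a list with `states` (tibble of
#'   `run`, `frame`, `time_ns`, `lock_id`, `distance`, `engaged`), `locks`,
#'   `engage_cutoff`, `atom_scope` and `condition`.
#' @export
evaluate_locks <- function(traj, locks = lock_definitions(),
                           engage_cutoff = 5,
                           atom_scope = c("sidechain", "heavy"),
                           condition = NA_character_) {
  atom_scope <- match.arg(atom_scope)
  co <- traj_coords(traj)
  frames <- co$frames
  if (nrow(frames) < 1) abort("need at least one frame")
  states <- purrr::pmap_dfr(locks, function(lock_id, resid_a, resid_b) {
    d <- residue_pair_min_dist(co, resid_a, resid_b, atom_scope)
    tibble(run = frames$run, frame = frames$frame, time_ns = frames$time_ns,
           lock_id = lock_id, distance = d, engaged = d <= engage_cutoff)
  })
  structure(
    list(states = arrange(states, .data$run, .data$frame, .data$lock_id),
         locks = locks, engage_cutoff = engage_cutoff,
         atom_scope = atom_scope, condition = condition),
    class = "lock_series")
}

#' Build a lock_series directly from engagement flags
#'
#' Used when lock states come from a source other than distances (e.g.
#' generator ground truth): `flags` is a tibble with `run`, `frame`,
#' `lock_id`, `engaged` and optionally `time_ns` and `distance`.
#'
#' @param flags Tibble of per-frame, per-lock engagement flags.
#' @param engage_cutoff,atom_scope,condition Metadata carried along.
#' @return A `lock_series` object.
#' @export
lock_series_from_flags <- function(flags, engage_cutoff = NA_real_,
                                   atom_scope = NA_character_,
                                   condition = NA_character_) {
  if (!all(c("run", "frame", "lock_id", "engaged") %in% names(flags))) {
    abort("flags must have columns run, frame, lock_id, engaged")
  }
  if (!"time_ns" %in% names(flags)) flags$time_ns <- flags$frame
  if (!"distance" %in% names(flags)) flags$distance <- NA_real_
  locks <- tibble(lock_id = sort(unique(flags$lock_id)),
                  resid_a = NA_integer_, resid_b = NA_integer_)
  structure(
    list(states = arrange(as_tibble(flags), .data$run, .data$frame,
                          .data$lock_id),
         locks = locks, engage_cutoff = engage_cutoff,
         atom_scope = atom_scope, condition = condition),
    class = "lock_series")
}

#' @export
print.lock_series <- function(x, ...) {
  nf <- nrow(distinct(x$states, .data$run, .data$frame))
  cat(sprintf(
    "<lock_series> %d frames x %d locks, cutoff %s A (%s scope)%s\n",
    nf, nrow(x$locks), format(x$engage_cutoff), x$atom_scope,
    if (!is.na(x$condition)) paste0(", condition ", x$condition) else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lock_series <- function(x, ...) x$states

# per-frame wide view: one row per (run, frame) with open flag and state id
# (state = lock engagement bits in lock_id order, e.g. "1010")
lock_frame_states <- function(series, lock_ids = NULL) {
  lock_ids <- lock_ids %||% intersect(c("D1", "D2", "D3", "D4"),
                                      unique(series$states$lock_id))
  lock_ids <- sort(lock_ids)
  wide <- series$states |>
    filter(.data$lock_id %in% lock_ids) |>
    tidyr::pivot_wider(id_cols = c("run", "frame", "time_ns"),
                       names_from = "lock_id", values_from = "engaged")
  eng <- as.matrix(wide[, lock_ids, drop = FALSE])
  tibble(
    run = wide$run, frame = wide$frame, time_ns = wide$time_ns,
    open = rowSums(eng) == 0,
    state = do.call(paste0, as.data.frame(1L * eng))
  )
}

#' Classify frames as loop-open or loop-closed
#'
#' A frame is open if and only if all four locks are released; any engaged
#' lock closes the loop.
#'
#' @param series A `lock_series`.
#' @return A tibble with one row per frame: `run`, `frame`, `time_ns`,
#'   `open`.
#' @export
classify_open <- function(series) {
  stopifnot(inherits(series, "lock_series"))
  lock_frame_states(series) |> select("run", "frame", "time_ns", "open")
}

#' Open-state occupancy, pooled and per run
#'
#' @param series A `lock_series`.
#' @return A tibble with a `"pooled"` row and one row per run: `scope`,
#'   `n_frames`, `n_open`, `open_fraction`.
#' @export
open_fraction <- function(series) {
  fl <- classify_open(series)
  per_run <- fl |>
    group_by(scope = paste0("run_", .data$run)) |>
    summarise(n_frames = n(), n_open = sum(.data$open), .groups = "drop")
  pooled <- tibble(scope = "pooled", n_frames = nrow(fl),
                   n_open = sum(fl$open))
  bind_rows(pooled, per_run) |>
    mutate(open_fraction = .data$n_open / .data$n_frames)
}

#' Engaged fraction of each lock
#'
#' @param series A `lock_series`.
#' @param per_run Also return per-run rows (default pooled only).
#' @return A tibble: `lock_id`, `scope`, `n_frames`, `n_engaged`,
#'   `engaged_fraction`.
#' @export
per_lock_frequency <- function(series, per_run = FALSE) {
  stopifnot(inherits(series, "lock_series"))
  pooled <- series$states |>
    group_by(.data$lock_id) |>
    summarise(scope = "pooled", n_frames = n(),
              n_engaged = sum(.data$engaged), .groups = "drop")
  out <- pooled
  if (per_run) {
    by_run <- series$states |>
      group_by(.data$lock_id, scope = paste0("run_", .data$run)) |>
      summarise(n_frames = n(), n_engaged = sum(.data$engaged),
                .groups = "drop")
    out <- bind_rows(pooled, by_run)
  }
  mutate(out, engaged_fraction = .data$n_engaged / .data$n_frames)
}

#' Shannon entropy of a discrete state histogram
#'
#' \eqn{H = -\sum_s p_s \log_2 p_s} in bits; zero-count states contribute
#' zero.
#'
#' @param counts Non-negative state counts (zero counts allowed).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) abort("empty histogram")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Entropy of the 16 lock-state combinations
#'
#' Tabulates the \eqn{2^4 = 16} joint engaged/released combinations of the
#' four locks over all retained frames and computes the Shannon entropy of
#' the histogram in bits (maximum 4 bits at a uniform distribution). A more
#' even distribution indicates that the loop switches its contacts more
#' freely.
#'
#' @param series A `lock_series`.
#' @return An object of class `lock_entropy`: list with `states` (tibble of
#'   the 16 combinations with counts and probabilities), `entropy_bits`,
#'   `normalized` (entropy divided by 4) and `condition`.
#' @export
lock_state_entropy <- function(series) {
  stopifnot(inherits(series, "lock_series"))
  lock_ids <- intersect(c("D1", "D2", "D3", "D4"),
                        unique(series$states$lock_id))
  st <- lock_frame_states(series, lock_ids)
  all_states <- apply(expand.grid(rep(list(c("0", "1")), length(lock_ids))),
                      1, paste, collapse = "")
  counts <- table(factor(st$state, levels = sort(all_states)))
  states <- tibble(state = names(counts), count = as.integer(counts)) |>
    mutate(probability = .data$count / sum(.data$count))
  h <- shannon_entropy(states$count)
  structure(
    list(states = states, entropy_bits = h,
         normalized = h / length(lock_ids), condition = series$condition),
    class = "lock_entropy")
}

#' @export
print.lock_entropy <- function(x, ...) {
  cat(sprintf("<lock_entropy> H = %.4f bits (normalized %.4f)%s\n",
              x$entropy_bits, x$normalized,
              if (!is.na(x$condition)) paste0(", condition ", x$condition)
              else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lock_entropy <- function(x, ...) x$states

#' Condition comparison table of loop gating statistics
#'
#' One row per condition with the pooled open percentage, per-lock engaged
#' percentages and lock-state entropy; per-run open fractions give the
#' between-run spread.
#'
#' @param series_list Named list of `lock_series`, one per condition
#'   (names override each series' own `condition` label).
#' @return A tibble with one row per condition.
#' @export
open_state_report <- function(series_list) {
  if (length(series_list) == 0) abort("need at least one condition")
  if (is.null(names(series_list)) || any(names(series_list) == "")) {
    names(series_list) <- purrr::map_chr(
      series_list, function(s) s$condition %||% NA_character_)
  }
  purrr::imap_dfr(series_list, function(series, cond) {
    of <- open_fraction(series)
    pooled <- filter(of, .data$scope == "pooled")
    runs <- filter(of, .data$scope != "pooled")
    freq <- per_lock_frequency(series)
    ent <- lock_state_entropy(series)
    row <- tibble(
      condition = cond,
      n_frames = pooled$n_frames,
      open_pct = 100 * pooled$open_fraction,
      open_pct_run_sd = if (nrow(runs) > 1) 100 * sd(runs$open_fraction)
                        else NA_real_,
      entropy_bits = ent$entropy_bits
    )
    for (k in seq_len(nrow(freq))) {
      row[[paste0(freq$lock_id[k], "_engaged_pct")]] <-
        100 * freq$engaged_fraction[k]
    }
    row
  })
}

#' Sensitivity of gating statistics to the engagement cutoff
#'
#' Re-evaluates the locks over a grid of engagement cutoffs and reports the
#' open fraction and per-lock engaged fractions at each. Published open
#' percentages depend on the (unstated) cutoff convention, so reports should
#' carry this sweep.
#'
#' @param traj A trajectory tibble.
#' @param locks Lock definitions.
#' @param cutoffs Numeric vector of cutoffs in Angstrom.
#' @param atom_scope As in [evaluate_locks()].
#' @return A tibble: `engage_cutoff`, `open_fraction`, then one
#'   `<lock>_engaged_fraction` column per lock.
#' @export
cutoff_sweep <- function(traj, locks = lock_definitions(),
                         cutoffs = seq(4, 6, by = 0.25),
                         atom_scope = c("sidechain", "heavy")) {
  atom_scope <- match.arg(atom_scope)
  base <- evaluate_locks(traj, locks, engage_cutoff = max(cutoffs),
                         atom_scope = atom_scope)
  purrr::map_dfr(cutoffs, function(cut) {
    s <- base
    s$states$engaged <- s$states$distance <= cut
    s$engage_cutoff <- cut
    freq <- per_lock_frequency(s)
    row <- tibble(engage_cutoff = cut,
                  open_fraction = filter(open_fraction(s),
                                         .data$scope == "pooled")$open_fraction)
    for (k in seq_len(nrow(freq))) {
      row[[paste0(freq$lock_id[k], "_engaged_fraction")]] <-
        freq$engaged_fraction[k]
    }
    row
  })
}
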