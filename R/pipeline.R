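#' Assert the gating count invariant on a lock series
#'
#' Openness requires all locks released, so on raw counts the number of open
#' frames can never exceed the released count of any single lock. Violations
#' indicate a corrupted state series.
#'
#' @param series A `lock_series`.
#' @return `TRUE` invisibly; aborts on violation.
#' @export
check_gating_invariant <- function(series) {
  of <- filter(open_fraction(series), .data$scope == "pooled")
  freq <- per_lock_frequency(series)
  released <- freq$n_frames - freq$n_engaged
  if (any(of$n_open > released)) {
    abort(sprintf(
      "gating invariant violated: %d open frames exceed released count of lock %s",
      of$n_open, freq$lock_id[which.min(released)]))
  }
  invisible(TRUE)
}

#' Default pipeline configuration
#'
#' Materialises every analysis default into one explicit list: the
#' equilibration discard (100 ns), the +/-0.3 correlation display band, the
#' 5.0 Angstrom lock engagement cutoff, the 4.0 Angstrom salt-bridge cutoff
#' and the 4.5 Angstrom contact cutoff, so that every threshold appearing in
#' a report is visible in the configuration that produced it.
#'
#' @param conditions Named list of condition inputs; each entry is either
#'   `list(preset = "gating", pi_open = ..., n_frames = ..., seed = ...,
#'   bridge = TRUE/FALSE)` or `list(topology = path, trajectories = paths)`.
#' @param seed Base seed for simulated conditions without their own.
#' @return A config list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(conditions = list(), seed = 1L) {
  list(
    conditions = conditions,
    window = list(discard_initial_ns = 100, stride = 1),
    dt_ns = 1,
    dccm = list(atom_name = "CA", threshold = 0.3),
    locks = list(engage_cutoff = 5, atom_scope = "sidechain"),
    saltbridges = list(contact_cutoff = 4, enabled = TRUE),
    kinetics = NULL,
    seed = seed
  )
}

validate_config <- function(config) {
  allowed <- c("conditions", "window", "dt_ns", "dccm", "locks",
               "saltbridges", "kinetics", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(config$conditions) == 0) {
    abort("config error: empty condition list")
  }
  if (is.null(names(config$conditions)) ||
      any(names(config$conditions) == "")) {
    abort("config error: conditions must be named")
  }
  sub_allowed <- list(
    window = c("discard_initial_ns", "stride"),
    dccm = c("atom_name", "threshold"),
    locks = c("engage_cutoff", "atom_scope"),
    saltbridges = c("contact_cutoff", "enabled"))
  for (section in names(sub_allowed)) {
    unknown <- setdiff(names(config[[section]]), sub_allowed[[section]])
    if (length(unknown) > 0) {
      abort(paste0("unknown config key(s) in ", section, ": ",
                   paste(unknown, collapse = ", ")))
    }
  }
  invisible(config)
}

load_condition <- function(spec, cond, config) {
  if (!is.null(spec$preset)) {
    if (!identical(spec$preset, "gating")) {
      abort(sprintf("condition %s: unknown preset '%s'", cond, spec$preset))
    }
    pi_open <- spec$pi_open %||% 0.1
    p_oc <- spec$p_oc %||% 0.1
    bridge <- if (isTRUE(spec$bridge)) bridge_model() else NULL
    model <- gating_model(p_co = p_oc * pi_open / (1 - pi_open), p_oc = p_oc,
                          bridge = bridge,
                          engage_cutoff = config$locks$engage_cutoff)
    sim <- simulate_gated_trajectory(
      model, n_frames = spec$n_frames %||% 5000,
      n_runs = spec$n_runs %||% 1, dt_ns = config$dt_ns,
      seed = spec$seed %||% config$seed)
    sim$trajectory
  } else if (!is.null(spec$topology)) {
    if (!file.exists(spec$topology)) {
      abort(sprintf("condition %s: topology file not found: %s", cond,
                    spec$topology))
    }
    read_trajectory(spec$topology, spec$trajectories, dt_ns = config$dt_ns)
  } else {
    abort(sprintf("condition %s: need either a preset or a topology path",
                  cond))
  }
}

run_stage <- function(name, output_dir, force, compute) {
  cache <- file.path(output_dir, paste0(name, ".json"))
  if (!force && file.exists(cache)) {
    message("stage ", name, ": cache hit")
    return(jsonlite::fromJSON(cache, simplifyVector = TRUE))
  }
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(compute(), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  jsonlite::write_json(out, cache, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  message(sprintf("stage %s: %.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  jsonlite::fromJSON(cache, simplifyVector = TRUE)
}

#' Run the end-to-end loop-gating analysis pipeline
#'
#' For every configured condition: analysis window, superposition, DCCM with
#' display thresholding and region coupling, lock evaluation with open-state
#' statistics and entropy, and (when bridge residues are present and
#' enabled) salt-bridge occupancy with loop-state conditioning; plus a
#' kinetics stage when plate data or a simulation request is configured.
#' Stage outputs are cached as JSON under `output_dir`; re-running with the
#' same config skips completed stages unless `force = TRUE`. The report is
#' deterministic for a fixed config (timestamps are confined to log
#' messages).
#'
#' @param config A config list from [pipeline_config()] (or a path to a
#'   JSON file containing one).
#' @param output_dir Directory for cached stage outputs and the report.
#' @param force Recompute all stages, ignoring caches.
#' @return The report, invisibly also written to
#'   `file.path(output_dir, "report.json")`.
#' @export
run_pipeline <- function(config, output_dir = tempfile("loopgate_"),
                         force = FALSE) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  validate_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  condition_results <- purrr::imap(config$conditions, function(spec, cond) {
    run_stage(paste0("condition_", cond), output_dir, force, function() {
      traj <- load_condition(spec, cond, config)
      traj <- apply_window(traj,
                           discard_initial_ns = config$window$discard_initial_ns,
                           stride = config$window$stride)
      series <- evaluate_locks(
        traj, engage_cutoff = config$locks$engage_cutoff,
        atom_scope = config$locks$atom_scope, condition = cond)
      check_gating_invariant(series)
      of <- open_fraction(series)
      freq <- per_lock_frequency(series)
      ent <- lock_state_entropy(series)

      fitted <- superpose(traj, fit_atom_name = config$dccm$atom_name)
      dccm <- threshold_dccm(compute_dccm(fitted, config$dccm$atom_name),
                             threshold = config$dccm$threshold)
      regions_present <- region_set() |>
        filter(purrr::map2_lgl(.data$from, .data$to, function(a, b) {
          any(dccm$residues >= a & dccm$residues <= b)
        }))
      coupling <- if (nrow(regions_present) > 0) {
        region_coupling(dccm, regions_present)
      } else NULL

      topo <- trajectory_topology(traj)
      bridges <- NULL
      if (isTRUE(config$saltbridges$enabled)) {
        pairs <- salt_bridge_pairs() |>
          filter(.data$acidic_resid %in% topo$resid,
                 .data$basic_resid %in% topo$resid)
        if (nrow(pairs) > 0) {
          bs <- detect_salt_bridges(
            traj, pairs, contact_cutoff = config$saltbridges$contact_cutoff)
          flags <- classify_open(series)
          bridges <- list(
            occupancy = bridge_occupancy(bs),
            conditionals = purrr::map_dfr(
              unique(bs$states$pair), function(p) {
                conditional_open_probability(bs, flags, pair = p)
              }))
        }
      }
      list(
        condition = cond,
        n_frames = filter(of, .data$scope == "pooled")$n_frames,
        open = of,
        per_lock = freq,
        entropy_bits = ent$entropy_bits,
        state_histogram = ent$states,
        region_coupling = coupling,
        salt_bridges = bridges,
        thresholds = list(
          engage_cutoff = config$locks$engage_cutoff,
          atom_scope = config$locks$atom_scope,
          dccm_threshold = config$dccm$threshold,
          bridge_cutoff = config$saltbridges$contact_cutoff,
          discard_initial_ns = config$window$discard_initial_ns,
          stride = config$window$stride)
      )
    })
  })

  kinetics_result <- NULL
  if (!is.null(config$kinetics)) {
    kinetics_result <- run_stage("kinetics", output_dir, force, function() {
      kc <- config$kinetics
      if (identical(kc$source, "simulate")) {
        sim <- simulate_kinetics(seed = kc$seed %||% config$seed)
        data <- sim$data
        calibration <- sim$calibration
        enzyme <- setNames(sim$truth$enzyme_nM, sim$truth$condition)
      } else {
        data <- dplyr::as_tibble(utils::read.csv(kc$data_csv))
        calibration <- dplyr::as_tibble(utils::read.csv(kc$calibration_csv))
        enzyme <- unlist(kc$enzyme_nM)
      }
      sc <- fit_standard_curve(calibration)
      rates <- initial_rates(data, standard_curve = sc)
      fits <- fit_mm_panel(rates, enzyme)
      reference <- kc$reference %||% names(fits)[1]
      list(
        standard_curve = list(slope = sc$slope, intercept = sc$intercept,
                              r_squared = sc$r_squared),
        fits = purrr::map_dfr(fits, glance),
        fold_changes = compare_conditions(fits, reference)
      )
    })
  }

  open_table <- purrr::map_dfr(condition_results, function(res) {
    open_df <- as_tibble(res$open)
    pooled <- open_df[open_df$scope == "pooled", ]
    per_lock <- as_tibble(res$per_lock)
    row <- tibble(condition = res$condition,
                  n_frames = pooled$n_frames,
                  open_pct = 100 * pooled$open_fraction,
                  entropy_bits = res$entropy_bits)
    for (k in seq_len(nrow(per_lock))) {
      row[[paste0(per_lock$lock_id[k], "_engaged_pct")]] <-
        100 * per_lock$engaged_fraction[k]
    }
    row
  })

  report <- list(
    open_state_table = open_table,
    conditions = condition_results,
    kinetics = kinetics_result,
    provenance = list(
      package = "loopgate",
      version = as.character(utils::packageVersion("loopgate")),
      seed = config$seed,
      config = config
    )
  )
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}
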