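# ---------------------------------------------------------------------------
# Experiment emulator: named presets of the in vivo lineage-tracing
# protocols, a response model translating exposure schedules into
# genotype-specific fate schedules, and the observation model (per-animal
# replicates, microscopy field sampling).
#
# Timeline convention: t = 0 at clone induction; exposures start after a
# 7-day lead (168 h). Output clone tables report time_h relative to the
# last exposure (or the matched sham time for unexposed scenarios), which
# is how lineage-tracing experiments are reported.
# ---------------------------------------------------------------------------

INDUCTION_LEAD_H <- 168

#' Default model parameters of the experiment emulator
#'
#' Baseline progenitor behaviour plus the perturbation-response knobs.
#' The baseline (`r`, `lambda`, `gamma`, `mu`) keeps an unperturbed
#' tissue stationary; `rho_wave`/`wave_h` define the induced
#' differentiation wave that follows each exposure in responsive cells;
#' `nac_delta`/`nac_window_h` define the fate tilt imposed on mutant
#' cells when an exposure occurs under antioxidant cover. These defaults
#' are documented calibration choices, not measured constants.
#'
#' @return A named list of parameters.
#' @export
scenario_defaults <- function() {
  list(
    r = 0.1,            # symmetric-division probability
    lambda = 2 / 7,     # divisions per progenitor per day
    gamma = 0.5,        # stratifications per basal differentiating cell/day
    mu = 0.5,           # sheddings per suprabasal cell per day
    rho_wave = 0.5,     # induced differentiation rate during a wave (/day)
    wave_h = 24,        # duration of the post-exposure wave
    nac_delta = -0.3,   # mutant fate tilt during the antioxidant window
    nac_window_h = 72,  # duration of that window after each exposure
    nac_rho = 0.25,     # induced differentiation rate of mutant cells
                        # during a wave under antioxidant cover (/day)
    tau_s_h = 8,        # S-phase duration for EdU labelling
    k_fb = 6,           # density-feedback gain on the fate tilt
    delta_max = 0.8,    # cap on the feedback tilt
    update_h = 6,       # feedback update interval
    k_lambda = 12,      # division-rate compensation gain
    lambda_mult_max = 4 # cap on the division-rate multiplier
  )
}

preset_table <- function() {
  tibble::tribble(
    ~name,          ~n_exposures, ~dose_mGy, ~spacing_h, ~nac,  ~edu,
    "ctrl",          0L,           0,         NA,         FALSE, FALSE,
    "ldir50x1",      1L,           50,        NA,         FALSE, TRUE,
    "ldir50x5",      5L,           50,        168,        FALSE, TRUE,
    "ldir50x10",    10L,           50,        72,         FALSE, FALSE,
    "ldir500x1",     1L,           500,       NA,         FALSE, FALSE,
    "nac_only",      0L,           0,         NA,         TRUE,  FALSE,
    "nac_ldir50x5",  5L,           50,        168,        TRUE,  TRUE
  )
}

#' List the built-in experiment presets
#'
#' Presets mirror the study protocols: unexposed control, a single
#' 50 mGy exposure read out at 24/48 h and 10 d, a course of five 50 mGy
#' doses over 30 days (>= 3 day spacing), ten 50 mGy doses versus a
#' single 500 mGy dose (equal total dose, read out at 30 d), antioxidant
#' alone, and antioxidant combined with the five-dose course. An EdU
#' pulse, when scheduled, falls 1 h before the final exposure.
#'
#' @return A tibble with one row per preset: exposure count, dose per
#'   exposure, spacing, antioxidant and EdU flags, and total dose.
#' @export
#' @examples
#' list_presets()
list_presets <- function() {
  dplyr::mutate(preset_table(),
                total_dose_mGy = .data$n_exposures * .data$dose_mGy)
}

#' Build a scenario from a preset
#'
#' A scenario fully specifies one emulated experiment: exposure times,
#' genotype mix, antioxidant flag, EdU pulse, sample times, observation
#' geometry and the root seed. All randomness downstream is governed by
#' `seed`; regenerating with the same scenario reproduces the table
#' bit-identically.
#'
#' Default cohort sizes follow the in vivo designs: 4 animals per
#' condition, around 2000 induced clones per condition in a 85:15
#' wild-type:mutant mix (mutant alleles are induced in scattered single
#' cells, so they start as a minority of labelled clones).
#'
#' @param name A preset name from [list_presets()].
#' @param seed Root seed of the scenario.
#' @param ... Overrides for any scenario field (e.g. `n_wt`, `n_animals`,
#'   `sample_times_h`).
#' @return An object of class `scenario`.
#' @export
#' @examples
#' preset_scenario("ldir50x5", seed = 1)
preset_scenario <- function(name, seed = 1, ...) {
  tab <- preset_table()
  if (!name %in% tab$name) {
    abort(sprintf("unknown preset '%s'; see list_presets()", name),
          class = "spclone_config_error")
  }
  row <- tab[tab$name == name, ]
  first <- INDUCTION_LEAD_H
  exposures_h <- if (row$n_exposures == 0) numeric(0)
    else if (row$n_exposures == 1) first
    else first + row$spacing_h * (seq_len(row$n_exposures) - 1)
  last <- if (length(exposures_h)) max(exposures_h) else first  # sham anchor
  sample_offsets_h <- switch(
    name,
    ctrl = c(24, 48, 240, 720),
    ldir50x1 = c(24, 48, 240),
    ldir50x5 = 48,
    ldir50x10 = 72,       # 30 d after the first exposure
    ldir500x1 = 720,      # 30 d
    nac_only = 720,
    nac_ldir50x5 = 48
  )
  sc <- list(
    name = name,
    exposures_h = exposures_h,
    dose_mGy = row$dose_mGy,
    nac = row$nac,
    edu = row$edu,
    edu_pulse_h = if (row$edu && length(exposures_h)) last - 1 else NULL,
    sample_times_h = last + sample_offsets_h,
    anchor_h = last,
    n_wt = 1700L, n_mut = 300L, n_animals = 4L,
    fields_per_animal = 8L, cells_per_field = 300,
    seed = seed,
    params = scenario_defaults()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(sc))
  if (length(unknown)) {
    abort(paste0("unknown scenario fields: ", paste(unknown, collapse = ", ")),
          class = "spclone_config_error")
  }
  sc[names(over)] <- over
  validate_scenario(structure(sc, class = "scenario"))
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  if (!length(sc$exposures_h) %in% c(0L, 1L, 5L, 10L)) {
    abort("exposure count must be one of 0, 1, 5, 10",
          class = "spclone_config_error")
  }
  if (!is.null(sc$edu_pulse_h) && length(sc$exposures_h) == 0) {
    abort("EdU pulse is anchored to an exposure; scenario has none",
          class = "spclone_config_error")
  }
  if (length(sc$exposures_h) > 1 && min(diff(sort(sc$exposures_h))) < 72) {
    abort("exposures must be separated by at least 72 h",
          class = "spclone_config_error")
  }
  if (sc$n_wt + sc$n_mut < 1 || sc$n_animals < 1) {
    abort("scenario needs at least one clone and one animal",
          class = "spclone_config_error")
  }
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s'> %d exposure(s) of %g mGy%s%s\n", x$name,
              length(x$exposures_h), x$dose_mGy,
              if (x$nac) " + NAC" else "",
              if (isTRUE(x$edu)) " + EdU pulse" else ""))
  cat(sprintf("  %d animals x (%d WT + %d mutant) clones; sample at %s h post-exposure\n",
              x$n_animals, x$n_wt, x$n_mut,
              paste(x$sample_times_h - x$anchor_h, collapse = "/")))
  invisible(x)
}

# ---- response model -------------------------------------------------------

# Wild-type cells respond to each exposure with a transient induced-
# differentiation wave (rho > 0 for wave_h hours); recovery is driven by
# the shared density feedback rather than a scheduled proliferation term,
# consistent with unchanged proliferation markers at 24 h and a rise by
# 48 h. Antioxidant cover suppresses the wild-type wave. Mutant cells are
# resistant to the wave; under antioxidant cover an exposure instead
# triggers the wave in the mutant plus a negative fate tilt for
# nac_window_h, the redox-reversal phenotype.
build_response_schedules <- function(sc, t_end_h) {
  p <- sc$params
  base <- balanced_fate_params(r = p$r, lambda = p$lambda,
                               gamma = p$gamma, mu = p$mu)
  wt <- constant_schedule(base, t_end_h = t_end_h)
  mut <- constant_schedule(base, t_end_h = t_end_h)
  add_wave <- function(sch, t_exp, rho = p$rho_wave) {
    schedule_modify(sch, t_exp, min(t_exp + p$wave_h, t_end_h),
                    function(row) { row$rho <- rho; row })
  }
  add_nac_tilt <- function(sch, t_exp) {
    to <- min(t_exp + p$nac_window_h, t_end_h)
    schedule_modify(sch, t_exp, to, function(row) {
      pr <- shift_symmetric_probs(row$p_pp, row$p_dd, p$nac_delta)
      row$p_pp <- pr$p_pp; row$p_dd <- pr$p_dd
      row
    })
  }
  for (t_exp in sc$exposures_h) {
    if (t_exp >= t_end_h) next
    if (!sc$nac) {
      wt <- add_wave(wt, t_exp)            # wild type differentiates
    } else {
      # reversal: the protected wild type no longer differentiates while
      # the mutant becomes partially sensitive to the exposure
      mut <- add_wave(mut, t_exp, rho = p$nac_rho)
      mut <- add_nac_tilt(mut, t_exp)
    }
  }
  list(WT = wt, mut = mut)
}

#' Generate a simulated lineage-tracing experiment
#'
#' Turns a [preset_scenario()] into a clone table with the study's
#' observation model. Animals are independent replicates sharing the
#' scenario's root seed stream; each animal is one [simulate_tissue()]
#' run in which all of its clones share the density-feedback pool. The
#' EdU pulse, when scheduled, is applied 1 h before the final exposure.
#' Fully shed clones are dropped from the observed table (they are
#' invisible to microscopy) but kept in `clones_all`.
#'
#' @param scenario A `scenario` object, or a preset name.
#' @param seed Optional override of the scenario seed.
#' @return An object of class `clone_experiment`: list with `clones`
#'   (observed clone table), `clones_all` (including unobservable),
#'   `density` (per-animal relative basal-density trajectories, time in
#'   hours post-exposure), `scenario`, and `metadata` (every parameter
#'   needed to regenerate the table bit-identically).
#' @export
#' @examples
#' expt <- generate_experiment(preset_scenario("ctrl", seed = 1,
#'   n_wt = 40, n_mut = 10, n_animals = 2))
#' head(expt$clones)
generate_experiment <- function(scenario, seed = NULL) {
  if (is.character(scenario)) scenario <- preset_scenario(scenario)
  sc <- validate_scenario(scenario)
  if (!is.null(seed)) sc$seed <- seed
  p <- sc$params
  t_end_h <- max(sc$sample_times_h)
  schedules <- build_response_schedules(sc, t_end_h)
  fb <- feedback_rule(k_fb = p$k_fb, delta_max = p$delta_max,
                      update_h = p$update_h, k_lambda = p$k_lambda,
                      lambda_mult_max = p$lambda_mult_max)
  run_animal <- function(a) {
    sim <- simulate_tissue(
      n_wt = sc$n_wt, n_mut = sc$n_mut,
      schedule_wt = schedules$WT, schedule_mut = schedules$mut,
      t_end_h = t_end_h, sample_times_h = sc$sample_times_h,
      feedback = fb, edu_pulse_h = sc$edu_pulse_h, tau_s_h = p$tau_s_h
    )
    sim$clones$animal_id <- a
    sim$density$animal_id <- a
    sim
  }
  sims <- withr::with_seed(sc$seed, lapply(seq_len(sc$n_animals), run_animal))
  clones <- dplyr::bind_rows(lapply(sims, `[[`, "clones"))
  density <- dplyr::bind_rows(lapply(sims, `[[`, "density"))
  clones <- dplyr::mutate(
    clones,
    condition = sc$name,
    time_h = .data$time_h - sc$anchor_h,
    clone_id = paste0("a", .data$animal_id, "_c", .data$clone_id)
  )
  clones <- dplyr::select(clones, "clone_id", "animal_id", "condition",
                          "genotype", "time_h", dplyr::everything())
  density$time_h <- density$time_h - sc$anchor_h
  structure(list(
    clones = dplyr::filter(clones, .data$observable),
    clones_all = clones,
    density = density,
    scenario = sc,
    metadata = list(package_version = as.character(utils::packageVersion("spclone")),
                    seed = sc$seed, scenario = unclass(sc),
                    t_end_h = t_end_h)
  ), class = "clone_experiment")
}

#' @export
print.clone_experiment <- function(x, ...) {
  cat(sprintf("<clone_experiment '%s'> %d observed clone records (%d total), %d animals\n",
              x$scenario$name, nrow(x$clones), nrow(x$clones_all),
              x$scenario$n_animals))
  invisible(x)
}

#' Sample basal cells into microscopy fields
#'
#' Emulates counting DAPI+ basal cells per field in random images: each
#' field count is Poisson with mean `cells_per_field` scaled by the true
#' relative density, so the field mean estimates relative density.
#'
#' @param rel_density True basal density relative to homeostasis.
#' @param n_fields Number of fields (>= 1).
#' @param cells_per_field Expected basal cells per field at homeostatic
#'   density.
#' @param seed Optional integer seed.
#' @return Integer vector of per-field counts.
#' @export
sample_density_fields <- function(rel_density, n_fields,
                                  cells_per_field = 300, seed = NULL) {
  if (n_fields < 1) abort("need at least one field",
                          class = "spclone_config_error")
  run <- function() rpois(n_fields, cells_per_field * rel_density)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Per-animal field counts from an experiment
#'
#' Applies [sample_density_fields()] to each animal's relative basal
#' density at the requested time, using the scenario's field geometry.
#'
#' @param experiment A `clone_experiment`.
#' @param time_h Time (hours post-exposure) at which density is read.
#' @param seed Optional integer seed.
#' @return A tibble with `animal_id`, `field` and `count`.
#' @export
experiment_density_fields <- function(experiment, time_h, seed = NULL) {
  stopifnot(inherits(experiment, "clone_experiment"))
  sc <- experiment$scenario
  dens <- experiment$density
  run <- function() {
    purrr::map(sort(unique(dens$animal_id)), function(a) {
      da <- dens[dens$animal_id == a, ]
      i <- which.min(abs(da$time_h - time_h))
      tibble(animal_id = a, field = seq_len(sc$fields_per_animal),
             count = sample_density_fields(da$rel_density[i],
                                           sc$fields_per_animal,
                                           sc$cells_per_field))
    }) |> dplyr::bind_rows()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
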