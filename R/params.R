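#' Model parameters
#'
#' Builds the full parameter set of the lattice model of Teff/Treg
#' cross-regulation. Defaults reproduce the published configuration: a 51x51
#' patch grid of white matter, a 2.4 h time step (3650 steps per simulated
#' year, 18250 steps = 5 years), 100 myelin units per patch, and stochastic
#' pulse-train introduction of resting Teff, resting Treg and virus particles
#' at an expected 100 impulses per species per year.
#'
#' Three constants of the model are calibration choices rather than published
#' values and are deliberately exposed: `rec_mye` (myelin regrowth per patch
#' per step), `virus_radius` (contact radius for virus-driven activation,
#' mirroring `treg_radius`) and `mean_Tregs` (half-saturation constant of the
#' Treg inhibition term). See the package vignette for the rationale behind
#' their defaults.
#'
#' @param grid_size Lattice side length in patches. The lattice is toroidal.
#' @param dt_hours Hours of simulated time per step.
#' @param steps_per_year Steps making up one simulated year.
#' @param init_mye Initial myelin per patch (arbitrary units).
#' @param eat_mye Myelin destroyed by one Teff attack.
#' @param rec_mye Myelin recovered per damaged (non-zero) patch per step.
#' @param eff_dup Maximum Teff duplication probability per eligible event.
#' @param p_t Maximum Treg duplication probability per eligible event
#'   (0.1 in the healthy scenario, 0.025 in the impaired "hill" scenario).
#' @param treg_radius Radius (patch units, Euclidean, inclusive) within which
#'   active Tregs are visible — both for Teff down-regulation and for Treg
#'   target search.
#' @param virus_radius Radius within which a resting T cell encounters a virus.
#' @param mean_Tregs Half-saturation constant (cells) of the Treg inhibition
#'   factor in the Teff duplication law.
#' @param patch_density Maximum number of agents on a patch for a duplication
#'   to proceed there.
#' @param hlife Mean half-life of agents, in steps; initial life counters are
#'   drawn uniformly from 1..2*hlife.
#' @param pulse_prob Success probability of each per-species Bernoulli pulse
#'   trial.
#' @param pulse_mode `"per_step"` (default) performs the three per-species
#'   Bernoulli trials on every time step — the model's literal introduction
#'   rule, and the mode under which the healthy/hill separation emerges;
#'   `"per_day"` performs them once per simulated day (every
#'   `round(24/dt_hours)` steps), which instead calibrates the expected rate
#'   to the nominal 100 impulses per species per year.
#' @param agents_per_pulse Agents introduced per successful pulse trial.
#'
#' @return A validated named list of class `rrmsim_params`.
#' @examples
#' p <- sim_params()
#' p$eff_dup
#' hill <- sim_params(p_t = 0.025)
#' @export
sim_params <- function(grid_size = 51,
                       dt_hours = 2.4,
                       steps_per_year = 3650,
                       init_mye = 100,
                       eat_mye = 5,
                       rec_mye = 1,
                       eff_dup = 0.1,
                       p_t = 0.1,
                       treg_radius = 3,
                       virus_radius = 3,
                       mean_Tregs = 10,
                       patch_density = 3,
                       hlife = 60,
                       pulse_prob = 100 / 365,
                       pulse_mode = c("per_step", "per_day"),
                       agents_per_pulse = 1) {
  pulse_mode <- match.arg(pulse_mode)
  p <- list(
    grid_size = as.integer(grid_size), dt_hours = dt_hours,
    steps_per_year = as.integer(steps_per_year),
    init_mye = as.numeric(init_mye), eat_mye = as.numeric(eat_mye),
    rec_mye = as.numeric(rec_mye),
    eff_dup = as.numeric(eff_dup), p_t = as.numeric(p_t),
    treg_radius = as.numeric(treg_radius),
    virus_radius = as.numeric(virus_radius),
    mean_Tregs = as.numeric(mean_Tregs),
    patch_density = as.integer(patch_density), hlife = as.integer(hlife),
    pulse_prob = as.numeric(pulse_prob), pulse_mode = pulse_mode,
    agents_per_pulse = as.integer(agents_per_pulse)
  )
  validate_params(p)
}

validate_params <- function(p) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  num1 <- function(x) length(x) == 1 && is.finite(x)
  for (f in names(sim_param_defaults())) {
    stop_if(is.null(p[[f]]), paste0("missing parameter: ", f))
    if (f != "pulse_mode") stop_if(!num1(p[[f]]), paste0(f, " must be a single finite number"))
  }
  for (f in c("eff_dup", "p_t", "pulse_prob")) {
    stop_if(p[[f]] < 0 || p[[f]] > 1, paste0(f, " is a probability and must lie in [0, 1]"))
  }
  stop_if(p$grid_size < 3, "grid_size must be >= 3")
  stop_if(p$dt_hours <= 0, "dt_hours must be > 0")
  stop_if(p$steps_per_year < 1, "steps_per_year must be >= 1")
  stop_if(p$init_mye <= 0, "init_mye must be > 0")
  stop_if(p$eat_mye < 0, "eat_mye must be >= 0")
  stop_if(p$eat_mye > p$init_mye, "eat_mye must not exceed init_mye")
  stop_if(p$rec_mye < 0, "rec_mye must be >= 0")
  stop_if(p$treg_radius < 0 || p$virus_radius < 0, "radii must be >= 0")
  stop_if(p$mean_Tregs <= 0, "mean_Tregs must be > 0")
  stop_if(p$patch_density < 1, "patch_density must be >= 1")
  stop_if(p$hlife < 1, "hlife must be >= 1")
  stop_if(!p$pulse_mode %in% c("per_day", "per_step"),
          "pulse_mode must be 'per_day' or 'per_step'")
  stop_if(p$agents_per_pulse < 1, "agents_per_pulse must be >= 1")
  structure(p, class = "rrmsim_params")
}

sim_param_defaults <- function() {
  list(
    grid_size = 51L, dt_hours = 2.4, steps_per_year = 3650L,
    init_mye = 100, eat_mye = 5, rec_mye = 1,
    eff_dup = 0.1, p_t = 0.1, treg_radius = 3, virus_radius = 3,
    mean_Tregs = 10, patch_density = 3L, hlife = 60L,
    pulse_prob = 100 / 365, pulse_mode = "per_step", agents_per_pulse = 1L
  )
}

#' Scenario presets: healthy vs impaired cross-regulation
#'
#' The two virtual-patient arms differ only in the maximum Treg duplication
#' probability: in the healthy arm Tregs duplicate as readily as Teffs
#' (`p_t = eff_dup = 0.1`); in the "hill" (impaired) arm the Treg maximum
#' duplication rate is reduced to 0.025, breaking the Teff-Treg balance.
#'
#' @param scenario `"healthy"` or `"hill"`.
#' @param params Base parameter set to modify.
#' @return A `rrmsim_params` object with the scenario's `eff_dup`/`p_t`.
#' @examples
#' scenario_params("hill")$p_t
#' @export
scenario_params <- function(scenario = c("healthy", "hill"),
                            params = sim_params()) {
  scenario <- match.arg(scenario)
  params$eff_dup <- 0.1
  params$p_t <- if (scenario == "healthy") 0.1 else 0.025
  out <- validate_params(params)
  attr(out, "scenario") <- scenario
  out
}

#' @export
print.rrmsim_params <- function(x, ...) {
  cat("<rrmsim_params>\n")
  sc <- attr(x, "scenario")
  if (!is.null(sc)) cat("  scenario:", sc, "\n")
  for (f in names(x)) cat(sprintf("  %-17s %s\n", f, format(x[[f]])))
  invisible(x)
}
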