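#' @useDynLib rrmsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Re-attach the S3 class after a round trip through the C++ engine.
rewrap <- function(w) {
  out <- structure(w[c("params", "myelin", "agents", "step")],
                   class = "rrmsim_world")
  extra <- setdiff(names(w), c("params", "myelin", "agents", "step"))
  for (f in extra) attr(out, f) <- w[[f]]
  out
}

rule_result <- function(w, field) {
  out <- rewrap(w)
  list(world = out, outcome = attr(out, field))
}

#' Stochastic pulse injection for the current step
#'
#' New agents enter the tissue as stochastic pulse trains rather than
#' continuous noise: one Bernoulli trial per species (Teff, then Treg, then
#' virus) with success probability `pulse_prob`. In the default `per_step`
#' mode the trials run on every time step; in `per_day` mode they run only on
#' steps that begin a new simulated day (every `round(24/dt_hours)` steps,
#' i.e. every 10 steps at the default 2.4 h step), which calibrates the
#' expected rate to 100 impulses per species per year. Each success places
#' `agents_per_pulse` agents on uniformly random patches — T cells resting,
#' with a fresh [draw_initial_life()] counter.
#'
#' @param world A `rrmsim_world`.
#' @return A list: `world` (updated) and `events`, a tibble with one row per
#'   species that pulsed this step (`species`, `count`).
#' @examples
#' set.seed(1)
#' pulse_events(new_world(sim_params(grid_size = 11)))$events
#' @export
pulse_events <- function(world) {
  check_world(world)
  w <- cpp_pulse_events(world)
  ev <- w$events
  events <- tibble::tibble(
    species = factor(SPECIES_LEVELS[ev$species], levels = SPECIES_LEVELS),
    count = as.integer(ev$count)
  )
  list(world = rewrap(w), events = events)
}

#' Move an agent to a random Von Neumann neighbour
#'
#' @param world A `rrmsim_world`.
#' @param i Agent index (1-based, into `world_agents(world)` rows).
#' @return The updated world.
#' @export
move_agent <- function(world, i) {
  check_world(world)
  rewrap(cpp_move_agent(world, as.integer(i)))
}

#' Virus-driven activation of a resting T cell
#'
#' If at least one virus lies within `virus_radius` (toroidal Euclidean,
#' inclusive) of a resting Teff or Treg, the nearest virus (ties broken
#' uniformly at random) is consumed and the cell switches to the active
#' state — the model's rendering of activation through molecular mimicry of
#' viral epitopes.
#'
#' @param world A `rrmsim_world`.
#' @param i Index of a resting T cell.
#' @return A list: `world` (updated) and `outcome` (`TRUE` if activation
#'   occurred).
#' @export
activate_by_virus <- function(world, i) {
  check_world(world)
  rule_result(cpp_activate_by_virus(world, as.integer(i)), "activated")
}

#' Myelin attack by an active Teff
#'
#' An active Teff on a patch with non-zero myelin destroys `eat_mye` units
#' (floored at zero) and becomes eligible to duplicate. On a fully
#' demyelinated patch nothing happens and the cell is not eligible.
#'
#' @param world A `rrmsim_world`.
#' @param i Index of an active Teff.
#' @return A list: `world` (updated) and `outcome` (`TRUE` if an attack took
#'   place, i.e. the cell may attempt duplication).
#' @export
teff_attack <- function(world, i) {
  check_world(world)
  rule_result(cpp_teff_attack(world, as.integer(i)), "attacked")
}

#' Teff duplication probability
#'
#' The per-event duplication probability of an attack-eligible Teff:
#' \deqn{p_e = \mathrm{eff\_dup}\cdot\frac{\mathrm{myelin}^2}{\mathrm{init\_mye}^2}
#'   \cdot\frac{\mathrm{mean\_Tregs}}{\mathrm{Treg\_here}+\mathrm{mean\_Tregs}}}
#' Duplication is favoured on well-myelinated patches (quadratic in local
#' myelin) and suppressed by nearby active Tregs through a saturating
#' inhibition term with half-saturation constant `mean_Tregs`. `p_e` never
#' exceeds `eff_dup`.
#'
#' @param myelin Myelin on the Teff's patch, in `[0, init_mye]`. Vectorised.
#' @param params A [sim_params()] object.
#' @param treg_here Number of active Tregs within `treg_radius` (>= 0).
#' @return The probability `p_e`.
#' @examples
#' p <- sim_params()
#' teff_duplication_probability(100, p, 0)   # 0.1
#' teff_duplication_probability(50, p, 10)   # 0.1 * 0.25 * 0.5
#' @export
teff_duplication_probability <- function(myelin, params, treg_here = 0) {
  params <- validate_params(params)
  if (any(myelin < 0 | myelin > params$init_mye))
    stop("myelin must lie in [0, init_mye]", call. = FALSE)
  if (any(treg_here < 0)) stop("treg_here must be >= 0", call. = FALSE)
  params$eff_dup * (myelin / params$init_mye)^2 *
    params$mean_Tregs / (treg_here + params$mean_Tregs)
}

#' Count active Tregs within a radius
#'
#' Only active Tregs count: in the model only activated Tregs release the
#' inhibitory signals that down-regulate Teff duplication. Distance is
#' toroidal Euclidean and the boundary is inclusive.
#'
#' @param world A `rrmsim_world`.
#' @param position `c(row, col)`, 0-based.
#' @param radius Radius in patch units (defaults to the world's `treg_radius`).
#' @return Integer count.
#' @export
count_tregs_in_radius <- function(world, position,
                                  radius = world$params$treg_radius) {
  check_world(world)
  cpp_count_tregs_in_radius(world, as.integer(position[1]),
                            as.integer(position[2]), radius)
}

#' Attempt a duplication event
#'
#' A Bernoulli trial with probability `prob`; on success the parent's patch
#' must hold fewer than `patch_density` agents (all species counted) for the
#' newborn to appear. If the density gate fails, the parent relocates to a
#' random Von Neumann neighbour and exactly one retry is made with a freshly
#' recomputed probability (the Teff law at the new patch, or `p_t` again for a
#' Treg). A newborn is born active on a random Von Neumann neighbour with a
#' fresh life draw; the parent's life counter is halved (floored, minimum 1).
#'
#' @param world A `rrmsim_world`.
#' @param i Index of an active T cell.
#' @param prob Duplication probability in `[0, 1]` (e.g. from
#'   [teff_duplication_probability()] or `p_t`).
#' @return A list: `world` (updated) and `outcome` (`TRUE` if a newborn was
#'   created).
#' @export
attempt_duplication <- function(world, i, prob) {
  check_world(world)
  rule_result(cpp_attempt_duplication(world, as.integer(i), prob), "duplicated")
}

#' Suppression of an active Teff by an active Treg
#'
#' If any active Teff lies within `treg_radius` of an active Treg, the nearest
#' one (ties broken uniformly) is removed from the simulation and the Treg
#' moves onto its patch; the Treg is then eligible to duplicate (the positive
#' feedback of the cross-regulation loop).
#'
#' @param world A `rrmsim_world`.
#' @param i Index of an active Treg.
#' @return A list: `world` (updated) and `outcome` (`TRUE` if a Teff was
#'   suppressed).
#' @export
treg_suppress <- function(world, i) {
  check_world(world)
  rule_result(cpp_treg_suppress(world, as.integer(i)), "suppressed")
}

#' Myelin recovery step
#'
#' Every patch still holding some myelin regrows `rec_mye` units, capped at
#' `init_mye` (remyelination by resident oligodendrocytes). A patch at zero is
#' a permanent lesion and never recovers.
#'
#' @param world A `rrmsim_world`.
#' @return A list: `world` (updated) and `recovered`, the total units
#'   restored across the lattice.
#' @export
recover_myelin <- function(world) {
  check_world(world)
  w <- cpp_recover_myelin(world)
  out <- rewrap(w)
  list(world = out, recovered = attr(out, "recovered"))
}

#' Life decrement and death
#'
#' Every agent's life counter drops by one; agents reaching zero are removed.
#'
#' @param world A `rrmsim_world`.
#' @return A list: `world` (updated) and `removed`, the number of agents that
#'   died this step.
#' @export
decrement_life_and_reap <- function(world) {
  check_world(world)
  w <- cpp_decrement_life_and_reap(world)
  out <- rewrap(w)
  list(world = out, removed = attr(out, "removed"))
}
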