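#' Create a fresh simulation world
#'
#' A world is the full model state: the parameter set, the toroidal myelin
#' lattice (every patch starts at `init_mye`), the agent population and the
#' step counter. A fresh world contains no agents; every agent enters later
#' through a stochastic pulse.
#'
#' Together with a seed (set via [run_simulation()] or `set.seed()`), a world
#' determines the whole trajectory: two worlds built from equal parameters and
#' stepped under equal seeds coincide in every observable.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `rrmsim_world` with elements `params`, `myelin`
#'   (grid_size x grid_size numeric matrix), `agents` (parallel integer
#'   vectors `species`, `state`, `life`, `row`, `col`) and `step`.
#' @examples
#' w <- new_world(sim_params(grid_size = 11))
#' w$step
#' @export
new_world <- function(params = sim_params()) {
  params <- validate_params(params)
  g <- params$grid_size
  structure(
    list(
      params = params,
      myelin = matrix(params$init_mye, nrow = g, ncol = g),
      agents = list(species = integer(0), state = integer(0),
                    life = integer(0), row = integer(0), col = integer(0)),
      step = 0L
    ),
    class = "rrmsim_world"
  )
}

SPECIES_LEVELS <- c("teff", "treg", "virus")
STATE_LEVELS <- c("resting", "active")

species_code <- function(species) {
  m <- match(species, SPECIES_LEVELS)
  if (anyNA(m)) stop("species must be one of: ", paste(SPECIES_LEVELS, collapse = ", "),
                     call. = FALSE)
  as.integer(m)
}

state_code <- function(state) {
  m <- match(state, STATE_LEVELS)
  if (anyNA(m)) stop("state must be 'resting' or 'active'", call. = FALSE)
  as.integer(m) - 1L
}

#' Add an agent to a world
#'
#' Mainly a scaffolding tool for building specific configurations (tests,
#' worked examples); during a simulation agents enter via pulses and
#' duplication.
#'
#' @param world A `rrmsim_world`.
#' @param species `"teff"`, `"treg"` or `"virus"`.
#' @param state `"resting"` or `"active"`; ignored for viruses, which carry no
#'   internal state.
#' @param life Life counter in steps (>= 1); `NULL` draws it uniformly from
#'   1..2*hlife as at introduction.
#' @param row,col 0-based lattice position.
#' @return The updated world.
#' @examples
#' w <- new_world(sim_params(grid_size = 11))
#' w <- add_agent(w, "teff", "active", life = 50, row = 5, col = 5)
#' @export
add_agent <- function(world, species, state = "resting", life = NULL,
                      row = 0L, col = 0L) {
  check_world(world)
  g <- world$params$grid_size
  if (row < 0 || row >= g || col < 0 || col >= g)
    stop("position must lie on the lattice (0-based)", call. = FALSE)
  sp <- species_code(species)
  st <- if (sp == 3L) 0L else state_code(state)
  if (is.null(life)) life <- draw_initial_life(world$params$hlife)
  if (life < 1) stop("life must be >= 1", call. = FALSE)
  a <- world$agents
  a$species <- c(a$species, sp)
  a$state <- c(a$state, st)
  a$life <- c(a$life, as.integer(life))
  a$row <- c(a$row, as.integer(row))
  a$col <- c(a$col, as.integer(col))
  world$agents <- a
  world
}

#' Agents of a world as a tibble
#'
#' @param world A `rrmsim_world`.
#' @return A tibble with one row per agent: `species`, `state` (factors),
#'   `life`, `row`, `col`.
#' @examples
#' world_agents(new_world(sim_params(grid_size = 5)))
#' @export
world_agents <- function(world) {
  check_world(world)
  a <- world$agents
  tibble::tibble(
    species = factor(SPECIES_LEVELS[a$species], levels = SPECIES_LEVELS),
    state = factor(ifelse(a$species == 3L, NA_character_,
                          STATE_LEVELS[a$state + 1L]), levels = STATE_LEVELS),
    life = a$life, row = a$row, col = a$col
  )
}

check_world <- function(world) {
  if (!inherits(world, "rrmsim_world")) stop("not a rrmsim_world", call. = FALSE)
  invisible(world)
}

#' @export
print.rrmsim_world <- function(x, ...) {
  cnt <- table(factor(SPECIES_LEVELS[x$agents$species], levels = SPECIES_LEVELS))
  cat(sprintf("<rrmsim_world> %dx%d lattice, step %d\n",
              x$params$grid_size, x$params$grid_size, x$step))
  cat(sprintf("  agents: %d teff, %d treg, %d virus\n",
              cnt[["teff"]], cnt[["treg"]], cnt[["virus"]]))
  d <- compute_damage(x)
  cat(sprintf("  damage: %.0f recoverable + %.0f unrecoverable = %.0f units\n",
              d$recoverable, d$unrecoverable, d$total))
  invisible(x)
}

#' Toroidal Euclidean distance between lattice positions
#'
#' Distances wrap around both axes (minimum-image convention), so opposite
#' edges of the lattice are adjacent. Vectorised over positions.
#'
#' @param a,b Positions as length-2 vectors `c(row, col)` (0-based), or
#'   two-column matrices of positions.
#' @param grid_size Lattice side length.
#' @return Euclidean distance(s) in patch units.
#' @examples
#' torus_distance(c(0, 0), c(0, 50), 51) # wraps: distance 1
#' torus_distance(c(0, 0), c(3, 4), 51)  # 5
#' @export
torus_distance <- function(a, b, grid_size) {
  a <- matrix(a, ncol = 2)
  b <- matrix(b, ncol = 2)
  d <- abs(a - b) %% grid_size
  d <- pmin(d, grid_size - d)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

#' Von Neumann neighbourhood of a lattice position
#'
#' The four orthogonally adjacent patches, wrapped toroidally.
#'
#' @param p Position `c(row, col)`, 0-based.
#' @param grid_size Lattice side length (>= 3).
#' @return A 4x2 integer matrix of `(row, col)` neighbours.
#' @examples
#' von_neumann_neighbors(c(0, 0), 51)
#' @export
von_neumann_neighbors <- function(p, grid_size) {
  if (grid_size < 3) stop("grid_size must be >= 3", call. = FALSE)
  off <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  out <- sweep(off, 2, as.integer(p), `+`) %% as.integer(grid_size)
  colnames(out) <- c("row", "col")
  out
}

#' Draw an initial life counter
#'
#' Agents enter the simulation with a life counter drawn uniformly from the
#' integers 1..2*hlife, so the mean residual life equals roughly the mean
#' half-life `hlife`.
#'
#' @param hlife Mean half-life in steps (>= 1).
#' @return A single integer in `[1, 2*hlife]`.
#' @examples
#' set.seed(1)
#' draw_initial_life(60)
#' @export
draw_initial_life <- function(hlife) {
  if (!is.numeric(hlife) || length(hlife) != 1 || hlife < 1)
    stop("hlife must be a single number >= 1", call. = FALSE)
  cpp_draw_initial_life(as.integer(hlife))
}
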