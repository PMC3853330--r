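#' Advance a world by one or more steps
#'
#' One step applies, in fixed order: (1) pulse injection; (2) one turn per
#' agent, the turn order freshly shuffled each step (resting T cells attempt
#' virus-driven activation; active Teffs attack the local myelin and, if
#' eligible, attempt duplication under the [teff_duplication_probability()]
#' law; active Tregs attempt suppression and, on success, duplication with
#' probability `p_t`; every surviving agent then takes one random Von Neumann
#' move); (3) myelin recovery; (4) life decrement and death. The shuffling
#' emulates NetLogo-style randomised `ask` scheduling while keeping the
#' consumption order of the single random stream reproducible.
#'
#' @param world A `rrmsim_world`.
#' @param n Number of steps to advance.
#' @return The world at `step + n`.
#' @examples
#' set.seed(1)
#' w <- world_step(new_world(sim_params(grid_size = 11)), 10)
#' w$step
#' @export
world_step <- function(world, n = 1) {
  check_world(world)
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n == 0) return(world)
  rewrap(cpp_step(world, as.integer(n)))
}

ts_colnames <- c("step", "teff_resting", "teff_active", "treg_resting",
                 "treg_active", "virus", "recoverable", "unrecoverable",
                 "total")

#' Run one virtual patient
#'
#' Seeds the random stream (the seed is the virtual patient's identity: each
#' seed yields a different, fully reproducible disease course), builds a
#' fresh agent-free world and iterates [world_step()], recording population
#' counts and damage after every step.
#'
#' @param params A [sim_params()] object (see [scenario_params()] for the
#'   healthy / hill presets).
#' @param seed Integer seed identifying the virtual patient.
#' @param steps Number of steps; the published runs use 18250 (5 years at
#'   2.4 h per step).
#' @return An object of class `rrmsim_run`: a list with `timeseries` (a
#'   tibble of `steps + 1` rows: step, the five population counts, and
#'   recoverable / unrecoverable / total damage in myelin units), `world`
#'   (the final state), `params`, `seed` and `steps`.
#' @examples
#' run <- run_simulation(sim_params(grid_size = 21), seed = 1, steps = 200)
#' tail(run$timeseries, 3)
#' @export
run_simulation <- function(params = sim_params(), seed = 1L, steps = 18250L) {
  params <- validate_params(params)
  if (steps < 0) stop("steps must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  res <- cpp_run(new_world(params), as.integer(steps))
  ts <- res$ts
  colnames(ts) <- ts_colnames
  ts <- tibble::as_tibble(ts)
  ts$step <- as.integer(ts$step)
  structure(
    list(timeseries = ts, world = rewrap(res$world), params = params,
         seed = as.integer(seed), steps = as.integer(steps)),
    class = "rrmsim_run"
  )
}

#' @export
print.rrmsim_run <- function(x, ...) {
  final <- x$timeseries[nrow(x$timeseries), ]
  cat(sprintf("<rrmsim_run> seed %d, %d steps (%.2f simulated years)\n",
              x$seed, x$steps, x$steps / x$params$steps_per_year))
  cat(sprintf("  final damage: %.0f recoverable + %.0f unrecoverable = %.0f units\n",
              final$recoverable, final$unrecoverable, final$total))
  invisible(x)
}

#' Damage accounting for a world
#'
#' Damage is expressed in myelin units. Patches still holding myelin
#' contribute their deficit `init_mye - myelin` as recoverable damage;
#' fully demyelinated patches are permanent lesions and contribute `init_mye`
#' each as unrecoverable damage. The ceiling is therefore
#' `grid_size^2 * init_mye` (260100 units at defaults).
#'
#' @param world A `rrmsim_world`.
#' @return A one-row tibble: `recoverable`, `unrecoverable`, `total`.
#' @examples
#' compute_damage(new_world(sim_params(grid_size = 5)))
#' @export
compute_damage <- function(world) {
  check_world(world)
  m <- world$myelin
  init <- world$params$init_mye
  zero <- m <= 0
  tibble::tibble(
    recoverable = sum(init - m[!zero]),
    unrecoverable = init * sum(zero),
    total = recoverable + unrecoverable
  )
}

#' Spatial damage snapshot
#'
#' Classifies every patch as intact, recoverable damage (some myelin lost but
#' non-zero) or unrecoverable (a permanent lesion, the "black patch" of the
#' spatial plots).
#'
#' @param world A `rrmsim_world`.
#' @return An object of class `rrmsim_snapshot`: a tibble with one row per
#'   patch (`row`, `col`, `myelin`, `category`), carrying the raw myelin
#'   matrix in the `"myelin_matrix"` attribute.
#' @examples
#' snap <- snapshot(new_world(sim_params(grid_size = 5)))
#' table(snap$category)
#' @export
snapshot <- function(world) {
  check_world(world)
  m <- world$myelin
  g <- world$params$grid_size
  grid <- expand.grid(col = 0:(g - 1), row = 0:(g - 1))[, c("row", "col")]
  myel <- as.vector(t(m))  # row-major to match (row, col) ordering
  category <- factor(
    ifelse(myel <= 0, "unrecoverable",
           ifelse(myel < world$params$init_mye, "recoverable", "intact")),
    levels = c("intact", "recoverable", "unrecoverable")
  )
  out <- tibble::tibble(row = grid$row, col = grid$col,
                        myelin = myel, category = category)
  attr(out, "myelin_matrix") <- m
  attr(out, "init_mye") <- world$params$init_mye
  class(out) <- c("rrmsim_snapshot", class(out))
  out
}

#' Write a run's time series to CSV
#'
#' Columns: `step, teff_resting, teff_active, treg_resting, treg_active,
#' virus, recoverable, unrecoverable, total`.
#'
#' @param run A `rrmsim_run` (or its `timeseries` tibble).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(run, path) {
  ts <- if (inherits(run, "rrmsim_run")) run$timeseries else run
  if (!all(ts_colnames %in% names(ts)))
    stop("not a simulation time series", call. = FALSE)
  utils::write.csv(ts[ts_colnames], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a snapshot's myelin matrix to CSV
#'
#' @param snap A `rrmsim_snapshot` or `rrmsim_world`.
#' @param path Output file; a headerless grid_size x grid_size CSV matrix of
#'   myelin values.
#' @return `path`, invisibly.
#' @export
write_snapshot_csv <- function(snap, path) {
  m <- snapshot_matrix(snap)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a snapshot as a PNG image
#'
#' One pixel per patch, lossless: white for intact patches, grey shades for
#' recoverable damage (darker = more myelin lost), black for permanent
#' lesions — mirroring the model's light-grey / dark-grey / black patch
#' colouring.
#'
#' @param snap A `rrmsim_snapshot` or `rrmsim_world`.
#' @param path Output PNG file.
#' @return `path`, invisibly.
#' @export
write_snapshot_image <- function(snap, path) {
  m <- snapshot_matrix(snap)
  init <- attr(m, "init_mye")
  grey <- m / init                 # 1 = intact (white), 0 = lesion (black)
  grey[m > 0] <- 0.25 + 0.75 * grey[m > 0]  # keep lesions visually distinct
  png::writePNG(grey, path)
  invisible(path)
}

snapshot_matrix <- function(snap) {
  if (inherits(snap, "rrmsim_world")) snap <- snapshot(snap)
  if (!inherits(snap, "rrmsim_snapshot")) stop("not a snapshot", call. = FALSE)
  m <- attr(snap, "myelin_matrix")
  attr(m, "init_mye") <- attr(snap, "init_mye")
  m
}
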