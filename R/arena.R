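#' Simulate one foraging trial of a clonal swarm
#'
#' Runs the embodied simulation for \code{n_steps} synchronous ticks from a
#' seeded random initial placement.  Each tick performs per-robot motion
#' (searching random walk, homing while depositing, or trail following),
#' robot-robot collision detection with Stay/Leave resolution and
#' interpenetration removal, one pheromone field update (deposit,
#' evaporation, 4-neighbour diffusion), and the behavioral state
#' transitions.  Fitness is the number of completed foraging bouts
#' (food-to-nest deliveries).
#'
#' The same (genotype, config, seed) triple always yields a bit-identical
#' result: all randomness comes from per-robot counter-seeded streams
#' internal to the simulator, so the trial is independent of R's RNG state.
#'
#' @param genotype anything accepted by \code{\link{as_genotype}}.
#' @param config a \code{\link{sim_config}}.
#' @param seed non-negative number fixing all randomness of the trial.
#' @param log_events if \code{TRUE} the result carries an event log
#'   (data.frame of bout and collision events) for fine-grained comparisons.
#' @return A list of class \code{trial_result} with elements \code{bouts},
#'   \code{collisions}, \code{time_budget} (steps spent in S1/S2/S3, summing
#'   to \code{n_robots * n_steps}), \code{n_steps}, \code{genotype},
#'   \code{seed} and optionally \code{events}.
#' @examples
#' cfg <- reduced_arena_config(n_steps = 200)
#' simulate_trial("{1,0,0;0}", cfg, seed = 1)
#' @export
simulate_trial <- function(genotype, config = sim_config(), seed,
                           log_events = FALSE) {
  g <- as_genotype(genotype)
  config <- validate_sim_config(unclass(config))
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed), seed >= 0)
  res <- cpp_simulate_trial(config, as.integer(g), as.numeric(seed), log_events)
  res$genotype <- format(g)
  res$seed <- as.numeric(seed)
  class(res) <- "trial_result"
  res
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial %s seed=%g> bouts=%d collisions=%d  S1/S2/S3 = %d/%d/%d steps\n",
              x$genotype, x$seed, as.integer(x$bouts), as.integer(x$collisions),
              as.integer(x$time_budget[1]), as.integer(x$time_budget[2]),
              as.integer(x$time_budget[3])))
  invisible(x)
}

#' One-row data frame summary of a trial
#' @param x a \code{trial_result}.
#' @param row.names,optional,... standard \code{as.data.frame} arguments (unused).
#' @export
as.data.frame.trial_result <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(genotype = x$genotype, seed = x$seed,
             bouts = as.integer(x$bouts), collisions = as.integer(x$collisions),
             steps_S1 = as.integer(x$time_budget[1]),
             steps_S2 = as.integer(x$time_budget[2]),
             steps_S3 = as.integer(x$time_budget[3]),
             stringsAsFactors = FALSE)
}

#' Create an initial world state
#'
#' Robots are placed uniformly at random (bodies inside the walls, without
#' overlap), all in the searching state with an empty pheromone field.  The
#' returned list can be advanced tick by tick with \code{\link{step_world}}
#' and its fields edited directly to construct specific scenarios.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed seed for placement and all subsequent per-robot randomness.
#' @return A list with per-robot vectors (\code{x}, \code{y}, \code{heading},
#'   \code{state}, \code{stay_timer}, \code{leave_remaining},
#'   \code{trail_lost}), the \code{pheromone} matrix, the \code{contact} map,
#'   counters and the serialized RNG state.
#' @export
make_world <- function(config = sim_config(), seed) {
  config <- validate_sim_config(unclass(config))
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed), seed >= 0)
  cpp_make_world(config, as.numeric(seed))
}

#' Advance the world by one synchronous tick
#'
#' @param world a world list from \code{\link{make_world}} (possibly edited).
#' @param genotype shared genotype of the clonal swarm.
#' @param config the same \code{\link{sim_config}} used to build the world.
#' @return The updated world list.
#' @export
step_world <- function(world, genotype, config = sim_config()) {
  g <- as_genotype(genotype)
  config <- validate_sim_config(unclass(config))
  cpp_step_world(world, as.integer(g), config)
}

#' Behavioral state transition for a single robot
#'
#' Applies the S1/S2/S3 state machine to one robot given a snapshot of its
#' local percepts.  Deterministic: S1 -> S2 on reaching food; S2 -> S1 (one
#' bout counted; or S3 when p = 1 and standing on a detectable trail) on
#' reaching the nest; S1 -> S3 when p = 1 and the local concentration is at
#' or above threshold; S3 -> S2 on reaching food; S3 -> S1 on trail loss.
#'
#' @param robot a list with at least \code{state} (1, 2 or 3).
#' @param percepts a list with logical \code{at_food}, \code{at_nest},
#'   numeric \code{pheromone} (local concentration) and logical
#'   \code{trail_lost} (the trail-loss counter has expired).
#' @param genotype the swarm genotype; only \code{p} is consulted here.
#' @param config a \code{\link{sim_config}} (for the detection threshold).
#' @return The robot list with updated \code{state}, plus a logical
#'   attribute-free field \code{bout} that is \code{TRUE} when this
#'   transition completed a delivery.
#' @export
transition_state <- function(robot, percepts, genotype, config = sim_config()) {
  g <- as_genotype(genotype)
  st <- robot$state
  if (!is.numeric(st) || length(st) != 1L || !(st %in% 1:3))
    stop("unknown behavior_state '", st, "'; must be 1, 2 or 3", call. = FALSE)
  thr <- config$detection_threshold
  on_trail <- g[["p"]] == 1L && isTRUE(percepts$pheromone >= thr)
  bout <- FALSE
  if (st == 1) {
    if (isTRUE(percepts$at_food)) st <- 2
    else if (on_trail) st <- 3
  } else if (st == 2) {
    if (isTRUE(percepts$at_nest)) {
      bout <- TRUE
      st <- if (on_trail) 3 else 1
    }
  } else {
    if (isTRUE(percepts$at_food)) st <- 2
    else if (isTRUE(percepts$trail_lost)) st <- 1
  }
  robot$state <- as.integer(st)
  robot$bout <- bout
  robot
}

#' Resolve a robot-robot collision
#'
#' Each colliding robot takes the reaction written at the locus matching its
#' own current behavioral state: allele 0 = Stay (halt for the configured
#' time), allele 1 = Leave (back up the configured distance).
#'
#' @param robot_a,robot_b lists with \code{position} (length-2, mm) and
#'   \code{state} (1, 2 or 3).
#' @param genotype the shared swarm genotype.
#' @param config a \code{\link{sim_config}}; supplies the contact distance
#'   and the Stay/Leave magnitudes.
#' @return A list with \code{reactions} (character, \code{"Stay"} or
#'   \code{"Leave"} for a then b) and the two robots with \code{stay_timer} /
#'   \code{leave_remaining} set.
#' @export
resolve_collision <- function(robot_a, robot_b, genotype, config = sim_config()) {
  g <- as_genotype(genotype)
  d <- sqrt(sum((robot_a$position - robot_b$position)^2))
  if (d > config$robot_diameter_mm + 1e-9)
    stop("robots are not in contact (centre distance ", round(d, 3),
         " mm > diameter ", config$robot_diameter_mm, " mm)", call. = FALSE)
  one <- function(r) {
    st <- r$state
    if (!(st %in% 1:3)) stop("unknown behavior_state '", st, "'", call. = FALSE)
    allele <- g[[st]]
    if (allele == 0L) {
      r$stay_timer <- as.integer(round(config$stay_duration_s / config$dt_s))
      r$leave_remaining <- 0
      list(robot = r, reaction = "Stay")
    } else {
      r$leave_remaining <- config$leave_distance_mm
      r$stay_timer <- 0L
      list(robot = r, reaction = "Leave")
    }
  }
  a <- one(robot_a); b <- one(robot_b)
  list(reactions = c(a$reaction, b$reaction), robot_a = a$robot, robot_b = b$robot)
}

#' One pheromone field update
#'
#' Adds point deposits into their containing grid cells, then applies
#' multiplicative evaporation and one step of mass-conserving 4-neighbour
#' diffusion (no-flux walls).
#'
#' @param field concentration matrix (rows = cells along the field length,
#'   columns = across the width), as produced by \code{\link{make_world}}.
#' @param deposits a 3-column matrix or data.frame (x mm, y mm, amount);
#'   zero rows allowed.
#' @param config a \code{\link{sim_config}}.
#' @return The updated concentration matrix.
#' @export
update_pheromone <- function(field, deposits = NULL, config = sim_config()) {
  config <- validate_sim_config(unclass(config))
  if (is.null(deposits) || NROW(deposits) == 0L) {
    deposits <- matrix(numeric(0), ncol = 3)
  } else {
    deposits <- as.matrix(deposits)
    if (ncol(deposits) != 3) stop("deposits must have columns x, y, amount", call. = FALSE)
  }
  if (any(field < 0)) stop("field must be non-negative everywhere", call. = FALSE)
  cpp_update_pheromone(field, deposits, config)
}

#' Deterministic sub-seed derivation
#'
#' Expands one master seed into a stream of sub-seeds (one per trial, run or
#' stage) through a counter-based generator, so adding trials never perturbs
#' the seeds of existing ones.
#'
#' @param seed master seed (non-negative number).
#' @param n how many sub-seeds.
#' @return Numeric vector of \code{n} integers below 2^53.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, n >= 0)
  cpp_derive_seeds(as.numeric(seed), as.integer(n))
}
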