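#' Simulation configuration
#'
#' Builds and validates the full configuration of one foraging trial: arena
#' geometry, pheromone-field numerics and the behavioral controller.  The
#' defaults are the full-scale study conditions: a 900 x 9000 mm walled field
#' with the nest zone (diameter 1000 mm) centred on one end wall and the food
#' disk (diameter 300 mm) on the opposite end, 30 robots of diameter 150 mm
#' moving at up to 100 mm/s, and 12,000 time steps of 0.1 s (20 simulated
#' minutes).
#'
#' @param field_width_mm,field_length_mm arena dimensions (mm).
#' @param food_diameter_mm diameter of the food disk at the far end (mm).
#' @param nest_diameter_mm diameter of the nest delivery zone (mm).  May
#'   exceed the field width (it does at full scale); the zone is then clipped
#'   by the walls.
#' @param food_light_radius_mm radius within which robots sense the food
#'   light and home on it (mm).
#' @param robot_diameter_mm rigid-disk robot body diameter (mm).
#' @param robot_max_speed_mm_s maximum speed (mm/s).
#' @param n_robots robots per swarm.
#' @param n_steps trial length in time steps.
#' @param dt_s seconds of simulated time per step.
#' @param grid_cell_mm pheromone grid cell edge (mm).
#' @param deposit_amount_per_step pheromone laid into the robot's cell per
#'   step while carrying food.
#' @param evaporation_coeff fraction of pheromone retained per step
#'   (multiplicative decay), in (0, 1].
#' @param diffusion_coeff 4-neighbour diffusion coefficient per step, in
#'   [0, 0.25] for stability; mass-conserving with no-flux walls.
#' @param detection_threshold concentration at or above which a robot with
#'   p = 1 perceives the trail and is recruited.
#' @param follow_threshold concentration down to which a robot already
#'   committed to the trail keeps tracking it (sensory hysteresis; at or
#'   below \code{detection_threshold}).  A follower whose sensors all read
#'   below this for \code{trail_lost_steps} consecutive steps gives up.
#' @param heading_noise_sd per-step Gaussian heading perturbation (radians)
#'   of the searching random walk.
#' @param steer_noise_sd per-step Gaussian heading noise (radians) of the
#'   homing and trail-following controllers; lets inbound and outbound
#'   streams spread laterally instead of sharing one exact lane.
#' @param stay_duration_s how long the Stay reaction halts the robot (s).
#' @param leave_distance_mm how far the Leave reaction backs the robot up (mm).
#' @param trail_lost_steps consecutive below-threshold sensor readings after
#'   which a trail-following robot gives up and resumes searching.
#' @param sensor_ahead_mm,sensor_side_mm forward and lateral offsets of the
#'   two virtual trail sensors (mm).
#' @param turn_rate_rad maximum steering turn per step (radians).
#' @return A validated list of class \code{sim_config}.
#' @examples
#' cfg <- sim_config()
#' small <- reduced_arena_config()
#' @export
sim_config <- function(field_width_mm = 900,
                       field_length_mm = 9000,
                       food_diameter_mm = 300,
                       nest_diameter_mm = 1000,
                       food_light_radius_mm = 600,
                       robot_diameter_mm = 150,
                       robot_max_speed_mm_s = 100,
                       n_robots = 30,
                       n_steps = 12000,
                       dt_s = 0.1,
                       grid_cell_mm = 30,
                       deposit_amount_per_step = 3,
                       evaporation_coeff = 0.997,
                       diffusion_coeff = 0.05,
                       detection_threshold = 0.05,
                       follow_threshold = 0.01,
                       heading_noise_sd = 0.4,
                       steer_noise_sd = 0.1,
                       stay_duration_s = 1.5,
                       leave_distance_mm = 150,
                       trail_lost_steps = 10,
                       sensor_ahead_mm = 75,
                       sensor_side_mm = 45,
                       turn_rate_rad = 0.3) {
  cfg <- list(
    field_width_mm = field_width_mm,
    field_length_mm = field_length_mm,
    food_diameter_mm = food_diameter_mm,
    nest_diameter_mm = nest_diameter_mm,
    food_light_radius_mm = food_light_radius_mm,
    robot_diameter_mm = robot_diameter_mm,
    robot_max_speed_mm_s = robot_max_speed_mm_s,
    n_robots = n_robots,
    n_steps = n_steps,
    dt_s = dt_s,
    grid_cell_mm = grid_cell_mm,
    deposit_amount_per_step = deposit_amount_per_step,
    evaporation_coeff = evaporation_coeff,
    diffusion_coeff = diffusion_coeff,
    detection_threshold = detection_threshold,
    follow_threshold = follow_threshold,
    heading_noise_sd = heading_noise_sd,
    steer_noise_sd = steer_noise_sd,
    stay_duration_s = stay_duration_s,
    leave_distance_mm = leave_distance_mm,
    trail_lost_steps = trail_lost_steps,
    sensor_ahead_mm = sensor_ahead_mm,
    sensor_side_mm = sensor_side_mm,
    turn_rate_rad = turn_rate_rad)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  num1 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("config key '", key, "' must be a single number", call. = FALSE)
    as.numeric(v)
  }
  pos <- function(key) {
    v <- num1(key)
    if (v <= 0) stop("config key '", key, "' must be strictly positive (got ", v, ")",
                     call. = FALSE)
    v
  }
  nonneg <- function(key) {
    v <- num1(key)
    if (v < 0) stop("config key '", key, "' must be non-negative (got ", v, ")",
                    call. = FALSE)
    v
  }
  for (k in c("field_width_mm", "field_length_mm", "food_diameter_mm",
              "nest_diameter_mm", "food_light_radius_mm", "robot_diameter_mm",
              "robot_max_speed_mm_s", "n_robots", "dt_s", "grid_cell_mm",
              "stay_duration_s", "turn_rate_rad"))
    pos(k)
  for (k in c("n_steps", "deposit_amount_per_step", "detection_threshold",
              "follow_threshold", "heading_noise_sd", "steer_noise_sd",
              "leave_distance_mm", "diffusion_coeff"))
    nonneg(k)
  if (num1("evaporation_coeff") <= 0 || num1("evaporation_coeff") > 1)
    stop("config key 'evaporation_coeff' must lie in (0, 1]", call. = FALSE)
  if (num1("diffusion_coeff") > 0.25)
    stop("config key 'diffusion_coeff' must be <= 0.25 for a stable 4-neighbour update",
         call. = FALSE)
  if (num1("robot_diameter_mm") >= num1("field_width_mm"))
    stop("config key 'robot_diameter_mm' must be smaller than 'field_width_mm'",
         call. = FALSE)
  if (num1("food_diameter_mm") > num1("field_width_mm"))
    stop("config key 'food_diameter_mm': food disk does not fit across the field",
         call. = FALSE)
  # food at y = L, nest zone at y = 0: the two zones must not meet
  if (num1("nest_diameter_mm") / 2 + num1("food_diameter_mm") / 2 >=
      num1("field_length_mm"))
    stop("config: nest and food zones overlap; increase 'field_length_mm'",
         call. = FALSE)
  if (num1("follow_threshold") > num1("detection_threshold"))
    stop("config key 'follow_threshold' must not exceed 'detection_threshold'",
         call. = FALSE)
  if (num1("trail_lost_steps") < 1)
    stop("config key 'trail_lost_steps' must be >= 1", call. = FALSE)
  cfg$n_robots <- as.integer(cfg$n_robots)
  cfg$n_steps <- as.integer(cfg$n_steps)
  cfg$trail_lost_steps <- as.integer(cfg$trail_lost_steps)
  structure(cfg, class = "sim_config")
}

#' Desk-scale arena configuration
#'
#' The reduced study condition used for landscape mapping and the surrogate
#' fitness distributions: the full-scale arena shortened to 6000 mm and
#' trials shortened to 6000 steps (10 simulated minutes), all other
#' parameters unchanged.  At this scale the swarm density (9.8% of the arena
#' area) stays close to the full-scale 6.5%, which keeps the collision regime
#' comparable while trials run an order of magnitude faster.
#'
#' @param ... overrides passed on to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
reduced_arena_config <- function(...) {
  args <- modifyList(list(field_length_mm = 6000, n_steps = 6000), list(...))
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  arena: %g x %g mm, food d=%g mm @ far end, nest d=%g mm @ near end\n",
              x$field_width_mm, x$field_length_mm, x$food_diameter_mm,
              x$nest_diameter_mm))
  cat(sprintf("  robots: n=%d, d=%g mm, %g mm/s, %d steps x %g s\n",
              x$n_robots, x$robot_diameter_mm, x$robot_max_speed_mm_s,
              x$n_steps, x$dt_s))
  cat(sprintf("  pheromone: cell %g mm, deposit %g, retain %g, diffuse %g, threshold %g\n",
              x$grid_cell_mm, x$deposit_amount_per_step, x$evaporation_coeff,
              x$diffusion_coeff, x$detection_threshold))
  invisible(x)
}

# config fingerprint used to tie fitness samples to their generating config
config_fingerprint <- function(cfg) {
  paste(vapply(cfg[sort(names(cfg))],
               function(v) format(v, digits = 15), character(1)),
        collapse = "|")
}
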