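test_that("state machine follows the three-state transition diagram", {
  cfg <- tiny_config()
  rob <- list(state = 1L)
  # searching robot reaching food starts carrying
  out <- transition_state(rob, list(at_food = TRUE, at_nest = FALSE,
                                    pheromone = 0, trail_lost = FALSE),
                          "{1,0,1;1}", cfg)
  expect_equal(out$state, 2L)
  # pheromone-blind robot ignores even a strong trail
  out <- transition_state(rob, list(at_food = FALSE, at_nest = FALSE,
                                    pheromone = 10, trail_lost = FALSE),
                          "{1,0,1;0}", cfg)
  expect_equal(out$state, 1L)
  # pheromone-sensitive robot on a detectable trail is recruited
  out <- transition_state(rob, list(at_food = FALSE, at_nest = FALSE,
                                    pheromone = cfg$detection_threshold,
                                    trail_lost = FALSE),
                          "{1,0,1;1}", cfg)
  expect_equal(out$state, 3L)
  # carrier reaching the nest scores a bout and resumes searching
  out <- transition_state(list(state = 2L),
                          list(at_food = FALSE, at_nest = TRUE,
                               pheromone = 0, trail_lost = FALSE),
                          "{1,0,1;1}", cfg)
  expect_equal(out$state, 1L)
  expect_true(out$bout)
  # ... or rejoins its own trail immediately when it can sense it
  out <- transition_state(list(state = 2L),
                          list(at_food = FALSE, at_nest = TRUE,
                               pheromone = 1, trail_lost = FALSE),
                          "{1,0,1;1}", cfg)
  expect_equal(out$state, 3L)
  expect_true(out$bout)
  # recruited robot loses the trail and resumes searching
  out <- transition_state(list(state = 3L),
                          list(at_food = FALSE, at_nest = FALSE,
                               pheromone = 0, trail_lost = TRUE),
                          "{1,0,1;1}", cfg)
  expect_equal(out$state, 1L)
  # unknown state is a contract violation
  expect_error(transition_state(list(state = 5L), list(), "{0,0,0;0}", cfg),
               "behavior_state")
})

test_that("collision reactions come from the locus of each robot's own state", {
  cfg <- tiny_config()
  mk <- function(state, x) list(position = c(x, 100), state = state)
  touching <- cfg$robot_diameter_mm
  # inbound (S2, b2=0 Stay) has priority over outbound (S3, b3=1 Leave)
  res <- resolve_collision(mk(2L, 0), mk(3L, touching), "{1,0,1;1}", cfg)
  expect_equal(res$reactions, c("Stay", "Leave"))
  expect_gt(res$robot_a$stay_timer, 0)
  expect_equal(res$robot_b$leave_remaining, cfg$leave_distance_mm)
  # all-Stay genome
  res <- resolve_collision(mk(1L, 0), mk(1L, touching), "{0,0,0;0}", cfg)
  expect_equal(res$reactions, c("Stay", "Stay"))
  # searching robots Leave when b1 = 1
  res <- resolve_collision(mk(1L, 0), mk(2L, touching), "{1,0,0;0}", cfg)
  expect_equal(res$reactions, c("Leave", "Stay"))
  # non-contacting pair is a contract violation
  expect_error(resolve_collision(mk(1L, 0), mk(1L, 2 * touching),
                                 "{0,0,0;0}", cfg),
               "not in contact")
})

test_that("pheromone update: fixed point, decay, and diffusion kernel oracle", {
  cfg <- tiny_config(diffusion_coeff = 0.1, evaporation_coeff = 0.99)
  w <- make_world(cfg, seed = 1)
  zero <- w$pheromone
  # all-zero field with no deposits is a fixed point
  expect_identical(update_pheromone(zero, NULL, cfg), zero)
  # total mass strictly decreases absent deposits
  f <- zero; f[10, 10] <- 5; f[3, 7] <- 2
  f1 <- update_pheromone(f, NULL, cfg)
  expect_lt(sum(f1), sum(f))
  expect_true(all(f1 >= 0))
  # unit impulse after k steps matches an independent convolution oracle
  k <- 6
  imp <- zero; imp[8, 8] <- 1
  got <- imp
  for (i in seq_len(k)) got <- update_pheromone(got, NULL, cfg)
  # oracle: explicit 4-neighbour update with no-flux walls, written directly
  D <- cfg$diffusion_coeff; E <- cfg$evaporation_coeff
  ref <- imp
  for (i in seq_len(k)) {
    nr <- nrow(ref); nc <- ncol(ref)
    up <- rbind(ref[1, ], ref[-nr, ]); dn <- rbind(ref[-1, ], ref[nr, ])
    lf <- cbind(ref[, 1], ref[, -nc]); rt <- cbind(ref[, -1], ref[, nc])
    ref <- E * (ref + D * (up + dn + lf + rt - 4 * ref))
  }
  expect_equal(got, ref, tolerance = 1e-12)
  # deposits outside the field are rejected with the position named
  expect_error(update_pheromone(zero, cbind(1e6, 10, 1), cfg), "outside")
})

test_that("a staying robot does not move during a tick", {
  cfg <- tiny_config()
  w <- make_world(cfg, seed = 2)
  w <- place_robot(w, 1, x = 450, y = 700, state = 1, stay = 5)
  w2 <- step_world(w, "{0,0,0;0}", cfg)
  expect_equal(w2$x[1], w$x[1])
  expect_equal(w2$y[1], w$y[1])
  expect_equal(w2$stay_timer[1], 4L)
})

test_that("a carrier adjacent to the nest scores exactly one bout", {
  cfg <- tiny_config(n_robots = 1)
  w <- make_world(cfg, seed = 3)
  # just outside the nest zone, heading straight at it
  w <- place_robot(w, 1, x = cfg$field_width_mm / 2,
                   y = cfg$nest_diameter_mm / 2 + 5,
                   heading = -pi / 2, state = 2)
  w2 <- step_world(w, "{1,0,0;0}", cfg)
  expect_equal(w2$bouts, 1)
  expect_equal(w2$state[1], 1L)
})

test_that("per-state time budgets count every robot every tick", {
  cfg <- tiny_config(n_steps = 50)
  w <- make_world(cfg, seed = 4)
  for (i in 1:10) w <- step_world(w, "{1,0,1;1}", cfg)
  expect_equal(sum(w$time_budget), cfg$n_robots * 10)
  r <- simulate_trial("{1,0,1;1}", cfg, seed = 4)
  expect_equal(sum(r$time_budget), cfg$n_robots * cfg$n_steps)
})

test_that("trials are deterministic, seed-sensitive and event-log identical", {
  cfg <- tiny_config()
  a <- simulate_trial("{1,0,0;1}", cfg, seed = 11, log_events = TRUE)
  b <- simulate_trial("{1,0,0;1}", cfg, seed = 11, log_events = TRUE)
  expect_identical(a$events, b$events)
  expect_identical(a$bouts, b$bouts)
  expect_identical(a$collisions, b$collisions)
  c <- simulate_trial("{1,0,0;1}", cfg, seed = 12, log_events = TRUE)
  expect_false(identical(a$events, c$events))
})

test_that("an empty trial returns zero bouts and collisions", {
  cfg <- tiny_config(n_steps = 0)
  r <- simulate_trial("{1,0,1;1}", cfg, seed = 1)
  expect_equal(r$bouts, 0)
  expect_equal(r$collisions, 0)
})

test_that("a lone robot at the food boundary facing the nest completes a bout in bounded time", {
  # straight-line kinematics oracle: distance from the food edge to the nest
  # zone divided by the per-step displacement, plus slack for the turn
  cfg <- tiny_config(n_robots = 1, n_steps = 400)
  w <- make_world(cfg, seed = 5)
  start_y <- cfg$field_length_mm - cfg$food_diameter_mm / 2 -
    cfg$robot_diameter_mm / 2
  w <- place_robot(w, 1, x = cfg$field_width_mm / 2, y = start_y,
                   heading = -pi / 2, state = 1)
  travel <- start_y - cfg$nest_diameter_mm / 2
  step_mm <- cfg$robot_max_speed_mm_s * cfg$dt_s
  bound <- ceiling(travel / step_mm) + 50
  for (i in seq_len(bound)) w <- step_world(w, "{0,0,0;0}", cfg)
  expect_gte(w$bouts, 1)
})

test_that("bouts are monotone in trial length under a prefix-stable stream", {
  cfg_short <- tiny_config(n_steps = 250)
  cfg_long <- tiny_config(n_steps = 500)
  for (s in 1:5) {
    b1 <- simulate_trial("{1,0,0;0}", cfg_short, seed = s)$bouts
    b2 <- simulate_trial("{1,0,0;0}", cfg_long, seed = s)$bouts
    expect_lte(b1, b2)
  }
})

test_that("robot bodies never interpenetrate after a tick resolves", {
  cfg <- tiny_config(n_robots = 12, field_length_mm = 1200)
  w <- make_world(cfg, seed = 6)
  for (i in 1:60) {
    w <- step_world(w, "{0,0,0;0}", cfg)
    d <- as.matrix(dist(cbind(w$x, w$y)))
    diag(d) <- Inf
    expect_gte(min(d), cfg$robot_diameter_mm - 1e-6)
  }
})

test_that("flipping b3 leaves trials bit-identical whenever p = 0", {
  cfg <- tiny_config(n_steps = 300)
  pairs <- list(c("{0,0,0;0}", "{0,0,1;0}"), c("{1,0,0;0}", "{1,0,1;0}"),
                c("{0,1,0;0}", "{0,1,1;0}"), c("{1,1,0;0}", "{1,1,1;0}"))
  for (pair in pairs) {
    for (s in 1:3) {
      a <- simulate_trial(pair[1], cfg, seed = s, log_events = TRUE)
      b <- simulate_trial(pair[2], cfg, seed = s, log_events = TRUE)
      expect_identical(a$events, b$events)
      expect_identical(a$bouts, b$bouts)
      expect_identical(a$time_budget, b$time_budget)
    }
  }
})

test_that("pheromone stays non-negative and robot count constant through a trial", {
  cfg <- tiny_config(n_steps = 120)
  w <- make_world(cfg, seed = 9)
  for (i in 1:120) {
    w <- step_world(w, "{1,0,1;1}", cfg)
    expect_length(w$x, cfg$n_robots)
    expect_gte(min(w$pheromone), 0)
  }
})
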