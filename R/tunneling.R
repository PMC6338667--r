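#' Parameters of the two-step valley-crossing model
#'
#' Three genotype classes: the resident (relative fitness 1), an
#' intermediate with relative fitness \code{r_x} (the neutral intermediate
#' has \code{r_x} near 1, the inferior one \code{r_x < 1}) and the final
#' genotype with relative fitness \code{a}.  Mutation converts resident to
#' intermediate, and intermediate to final, each with probability \code{mu}
#' per offspring.
#'
#' @param N population size.
#' @param mu per-step mutation probability.
#' @param r_x relative fitness of the intermediate (> 0).
#' @param a relative fitness of the final genotype (> 0).
#' @return A validated list of class \code{tunneling_params}.
#' @export
tunneling_params <- function(N, mu, r_x, a) {
  if (!is.numeric(N) || length(N) != 1L || N < 2)
    stop("N must be >= 2", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0 || mu >= 1)
    stop("mu must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(r_x) || length(r_x) != 1L || r_x <= 0)
    stop("r_x must be > 0", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || a <= 0)
    stop("a must be > 0", call. = FALSE)
  structure(list(N = as.integer(N), mu = as.numeric(mu),
                 r_x = as.numeric(r_x), a = as.numeric(a)),
            class = "tunneling_params")
}

#' Fixation probability of a single mutant in a Wright-Fisher population
#'
#' Exact fixation probability of one copy of a mutant with relative fitness
#' \code{r} among \code{N} haploid Wright-Fisher reproducers, computed by
#' solving the absorbing Markov chain (the mutant count follows a binomial
#' update with success probability \code{i r / (i r + N - i)}).  The neutral
#' case is the martingale value \code{1/N} exactly.
#'
#' @param r relative fitness (> 0); vectorized.
#' @param N population size (>= 2).
#' @return Fixation probability in [0, 1] for each element of \code{r}.
#' @export
fixation_probability <- function(r, N) {
  if (!is.numeric(r) || any(is.na(r)) || any(r <= 0))
    stop("r must be > 0", call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || N < 2)
    stop("N must be >= 2", call. = FALSE)
  N <- as.integer(N)
  vapply(r, function(ri) {
    if (ri == 1) return(1 / N)
    wf_fixation_exact(ri, N)
  }, numeric(1))
}

# exact single-mutant WF fixation probability by linear solve
wf_fixation_exact <- function(r, N) {
  i <- 1:(N - 1)
  p <- i * r / (i * r + (N - i))
  # P[i, j] = P(j mutants | i mutants), transient states only
  P <- outer(p, 0:N, function(pi, j) stats::dbinom(j, N, pi))
  Q <- P[, 2:N, drop = FALSE]           # to transient states 1..N-1
  b <- P[, N + 1]                       # straight to fixation
  u <- solve(diag(N - 1) - Q, b)
  min(max(u[1], 0), 1)
}

# establishment-and-fixation probability used inside the branching process:
# one copy of the final genotype (fitness a) among residents
rho_final <- function(a, N) fixation_probability(a, N)

# Exact finite-N tunnel chain.  State: k = number of intermediate swarms
# (fitness r) among N; the rest are residents (fitness 1).  Each offspring
# picks an intermediate parent with probability p_k = k r / (k r + N - k)
# and then launches an ultimately-fixing final lineage with probability
# mu * rho.  Absorbing outcomes from one intermediate copy:
#   sigma1 - a successful final lineage is launched before the intermediate
#            class is lost or fixes (the tunneling route),
#   u1     - the intermediate fixes with no success en route (the
#            sequential route then waits for the secondary mutation).
# Solved exactly by one dense linear solve; replaces the infinite-population
# branching approximation, whose bias is large at small N (a conditionally
# surviving lineage grows to a size comparable with N).
exact_tunnel_chain <- function(N, mu, r, rho) {
  N <- as.integer(N)
  k <- 1:(N - 1)
  p <- k * r / (k * r + (N - k))
  s <- p * mu * rho                 # per-offspring success hazard
  no_succ <- (1 - s)^N              # no success launched this generation
  q <- p * (1 - mu) / (1 - s)       # intermediate fraction given no success
  M <- matrix(0, N - 1, N - 1)
  to_ext <- numeric(N - 1)
  to_fix <- numeric(N - 1)
  for (i in seq_along(k)) {
    pj <- stats::dbinom(0:N, N, q[i]) * no_succ[i]
    M[i, ] <- pj[2:N]
    to_ext[i] <- pj[1]
    to_fix[i] <- pj[N + 1]
  }
  A <- diag(N - 1) - M
  sol <- solve(A, cbind(fix = to_fix, succ = (1 - no_succ)))
  list(sigma1 = min(max(sol[1, "succ"], 0), 1),
       u1 = min(max(sol[1, "fix"], 0), 1))
}

#' Probability that a single intermediate swarm fails to seed the final genotype
#'
#' \code{v1} is the probability of non-appearance or extinction of the
#' final-genotype lineage arising from one swarm of the intermediate
#' genotype, conditional on that intermediate lineage not sweeping to
#' fixation itself.  It is computed from the exact finite-N absorbing chain
#' of the intermediate copy number, in which every offspring of an
#' intermediate launches an ultimately-fixing final lineage with
#' probability \code{mu * U(a)}; with sigma1 the probability of such a
#' launch and u1 the probability of intermediate fixation without one,
#' \code{v1 = 1 - sigma1 / (1 - u1)}.
#'
#' @param params a \code{\link{tunneling_params}}.
#' @return \code{v1} in [0, 1] (1 when \code{mu = 0}: the final genotype can
#'   never appear).
#' @export
solve_v1 <- function(params) {
  stopifnot(inherits(params, "tunneling_params"))
  ch <- exact_tunnel_chain(params$N, params$mu, params$r_x,
                           rho_final(params$a, params$N))
  1 - ch$sigma1 / (1 - ch$u1)
}

#' Stochastic tunneling rate
#'
#' Per-generation rate at which the population launches an
#' ultimately-successful tunnel straight from the resident to the final
#' genotype: \code{T = N mu (1 - U(r_x)) (1 - v1)}, where \code{U} is the
#' probability that the intermediate itself sweeps and \code{v1} the
#' conditional failure probability of \code{\link{solve_v1}}; with the
#' exact-chain components this equals \code{N mu sigma1}.
#'
#' @param params a \code{\link{tunneling_params}}.
#' @return The rate \code{T >= 0}.
#' @export
tunneling_rate <- function(params) {
  stopifnot(inherits(params, "tunneling_params"))
  ch <- exact_tunnel_chain(params$N, params$mu, params$r_x,
                           rho_final(params$a, params$N))
  params$N * params$mu * ch$sigma1
}

#' Fixation rates of the primary and secondary mutation
#'
#' \code{S1 = N mu u1} is the per-generation rate at which the intermediate
#' genotype arises and sweeps to fixation (without having launched a
#' successful final lineage on the way, which would be a tunnel);
#' \code{S2 = N mu U(a / r_x)} the rate at which, once the intermediate is
#' resident, the final genotype arises and fixes (fitness relative to the
#' new resident).
#'
#' @param params a \code{\link{tunneling_params}}.
#' @return Named numeric vector \code{c(S1, S2)}.
#' @export
sequential_rates <- function(params) {
  stopifnot(inherits(params, "tunneling_params"))
  ch <- exact_tunnel_chain(params$N, params$mu, params$r_x,
                           rho_final(params$a, params$N))
  c(S1 = params$N * params$mu * ch$u1,
    S2 = params$N * params$mu * fixation_probability(params$a / params$r_x,
                                                     params$N))
}

#' Expected waiting time to fixation of the final genotype
#'
#' Evaluates
#' \deqn{E[t] = \frac{T}{(T+S_1)^2} + \frac{S_1 (S_1+S_2+T)}{S_2 (T+S_1)^2}}
#' in generations, where the first term is the contribution of tunneling
#' paths (resident to final without the intermediate ever fixing) and the
#' second that of sequential paths (intermediate fixes, then the final).
#' At \code{T = 0} the expression reduces algebraically to
#' \code{1/S1 + 1/S2}.
#'
#' @param params a \code{\link{tunneling_params}}.
#' @return \code{E[t]} in generations (> 0).  \code{mu = 0} is degenerate
#'   (no rates) and raises an error rather than returning NaN.
#' @export
expected_fixation_time <- function(params) {
  res <- tunneling_result(params)
  res$expected_time
}

#' Full analytic solution for one parameter set
#'
#' @param params a \code{\link{tunneling_params}}.
#' @return A list of class \code{tunneling_result} with \code{U_rx},
#'   \code{v1}, \code{T}, \code{rate_S1}, \code{rate_S2} and
#'   \code{expected_time}.
#' @export
tunneling_result <- function(params) {
  stopifnot(inherits(params, "tunneling_params"))
  if (params$mu == 0)
    stop("mu = 0: neither mutation can occur, the expected fixation time is undefined",
         call. = FALSE)
  ch <- exact_tunnel_chain(params$N, params$mu, params$r_x,
                           rho_final(params$a, params$N))
  U <- ch$u1
  v1 <- 1 - ch$sigma1 / (1 - ch$u1)
  Tt <- params$N * params$mu * ch$sigma1
  S1 <- params$N * params$mu * ch$u1
  S2 <- params$N * params$mu * fixation_probability(params$a / params$r_x,
                                                    params$N)
  Et <- Tt / (Tt + S1)^2 + S1 * (S1 + S2 + Tt) / (S2 * (Tt + S1)^2)
  structure(list(U_rx = U, v1 = v1, T = Tt,
                 rate_S1 = S1, rate_S2 = S2,
                 expected_time = Et, params = params),
            class = "tunneling_result")
}

#' @export
print.tunneling_result <- function(x, ...) {
  cat(sprintf("<tunneling N=%d mu=%g r_x=%g a=%g>\n", x$params$N, x$params$mu,
              x$params$r_x, x$params$a))
  cat(sprintf("  U(r_x)=%.4g  v1=%.4g  T=%.4g  S1=%.4g  S2=%.4g\n",
              x$U_rx, x$v1, x$T, x$rate_S1, x$rate_S2))
  cat(sprintf("  E[t] = %.2f generations\n", x$expected_time))
  invisible(x)
}

#' Brute-force two-step Wright-Fisher simulation
#'
#' Direct stochastic simulation of the valley-crossing process the analytic
#' model describes: resident (fitness 1) to intermediate (fitness \code{r})
#' to final (fitness \code{a}), one-directional mutation with probability
#' \code{mu} at each step, fitness-proportional Wright-Fisher resampling.
#' Used as the independent oracle for
#' \code{\link{expected_fixation_time}}.
#'
#' @param N population size.
#' @param mu mutation probability.
#' @param r,a intermediate and final relative fitness.
#' @param n_rep replicates.
#' @param max_generations per-replicate guard.
#' @param seed RNG seed (internal deterministic stream).
#' @return A data.frame with one row per replicate: \code{fixation} (the
#'   generation at which the final type fixed) and \code{seeding} (the
#'   generation at which the ultimately fixing intermediate lineage was
#'   seeded by mutation).  NA where the guard hit.  The analytic rates
#'   \code{T} and \code{S1} clock successful seedings, so
#'   \code{\link{expected_fixation_time}} is compared against
#'   \code{seeding}; the gap to \code{fixation} is the maturation and sweep
#'   time the rate description leaves out.
#' @export
simulate_two_step <- function(N, mu, r, a, n_rep = 1000,
                              max_generations = 1e7, seed = 1) {
  res <- cpp_wf_two_step(as.integer(N), mu, r, a, as.integer(n_rep),
                         as.numeric(max_generations), as.numeric(seed))
  data.frame(fixation = res$fixation, seeding = res$seeding)
}

# fast interpolated U(r): exact values on a log-spaced grid, monotone spline
fixation_interpolator <- function(N, r_min, r_max, n_grid = 257) {
  r_min <- max(r_min * 0.999, 1e-8)
  r_max <- r_max * 1.001
  grid <- exp(seq(log(r_min), log(r_max), length.out = n_grid))
  u <- fixation_probability(grid, N)
  f <- stats::splinefun(log(grid), u, method = "hyman")
  function(r) pmin(pmax(f(log(r)), 0), 1)
}

# bilinear interpolation on a (x, y) grid
interp2 <- function(xg, yg, Z, x, y) {
  ix <- pmin(pmax(findInterval(x, xg), 1L), length(xg) - 1L)
  iy <- pmin(pmax(findInterval(y, yg), 1L), length(yg) - 1L)
  wx <- (x - xg[ix]) / (xg[ix + 1L] - xg[ix])
  wy <- (y - yg[iy]) / (yg[iy + 1L] - yg[iy])
  wx <- pmin(pmax(wx, 0), 1); wy <- pmin(pmax(wy, 0), 1)
  Z[cbind(ix, iy)] * (1 - wx) * (1 - wy) +
    Z[cbind(ix + 1L, iy)] * wx * (1 - wy) +
    Z[cbind(ix, iy + 1L)] * (1 - wx) * wy +
    Z[cbind(ix + 1L, iy + 1L)] * wx * wy
}

# vectorized E[t] over draws of (r_x, a) with shared N and mu.  The exact
# tunnel-chain quantities sigma1(r, rho) and u1(r, rho) are evaluated on a
# (log r, rho) grid and interpolated bilinearly; with few distinct draws
# (point masses) every pair is solved exactly instead.
expected_time_vec <- function(r_x, a, N, mu, Ufun) {
  rho <- Ufun(a)
  key <- paste(signif(r_x, 12), signif(rho, 12))
  uk <- !duplicated(key)
  if (sum(uk) <= 64) {
    sig <- u1 <- setNames(numeric(sum(uk)), key[uk])
    for (i in which(uk)) {
      ch <- exact_tunnel_chain(N, mu, r_x[i], rho[i])
      sig[key[i]] <- ch$sigma1
      u1[key[i]] <- ch$u1
    }
    sigma1 <- unname(sig[key])
    uu <- unname(u1[key])
  } else {
    lr <- log(r_x)
    xg <- seq(min(lr), max(lr), length.out = 41)
    yg <- seq(min(rho), max(rho), length.out = 17)
    if (diff(range(xg)) == 0) xg <- xg[1] + c(-1e-6, 1e-6, seq_len(39) * 0)[1:41] * 0 + seq(-1e-6, 1e-6, length.out = 41)
    if (diff(range(yg)) == 0) yg <- yg[1] + seq(-1e-9, 1e-9, length.out = 17)
    Zs <- matrix(0, 41, 17)
    Zu <- matrix(0, 41, 17)
    for (i in 1:41) for (j in 1:17) {
      ch <- exact_tunnel_chain(N, mu, exp(xg[i]), min(max(yg[j], 0), 1))
      Zs[i, j] <- ch$sigma1
      Zu[i, j] <- ch$u1
    }
    sigma1 <- interp2(xg, yg, Zs, lr, rho)
    uu <- interp2(xg, yg, Zu, lr, rho)
  }
  Tt <- N * mu * sigma1
  S1 <- N * mu * uu
  S2 <- N * mu * Ufun(a / r_x)
  Tt / (Tt + S1)^2 + S1 * (S1 + S2 + Tt) / (S2 * (Tt + S1)^2)
}

#' Predicted distribution of path choice and waiting time over outcome sets
#'
#' The hybrid analysis: for every predicted evolutionary outcome, one triple
#' (r0, r-, a) is drawn from the resampled relative-fitness distributions,
#' the expected fixation time is computed for the two candidate tunneling
#' paths (via the neutral intermediate at \code{r0} and via the inferior
#' intermediate at \code{r-}), and the path with the strictly shorter
#' waiting time is recorded together with that time (exact ties go to the
#' neutral intermediate and are counted).  Outcomes are grouped into sets
#' and summarized across sets by 2.5th/97.5th percentiles.
#'
#' @param r0_samples,rminus_samples,a_samples
#'   \code{\link{relative_fitness}} results (or bare numeric vectors) for
#'   the neutral intermediate, the inferior intermediate and the final
#'   genotype, all relative to the resident.
#' @param n_sets number of outcome sets.
#' @param set_size outcomes per set.
#' @param N,mu population size and per-locus mutation rate of the modeled
#'   population.
#' @param seed RNG seed for the draws.
#' @return A list of class \code{outcome_set_prediction}:
#'   \code{neutral_counts} (per set, how many outcomes chose the
#'   neutral-intermediate path), \code{mean_wait} (per-set mean E[t] of the
#'   chosen paths), \code{count_interval} and \code{wait_interval}
#'   (2.5th/97.5th percentiles across sets), \code{n_redrawn} (non-positive
#'   fitness draws rejected and redrawn) and \code{n_ties}.
#' @export
predict_outcome_sets <- function(r0_samples, rminus_samples, a_samples,
                                 n_sets = 1000, set_size = 50,
                                 N = 200, mu = 0.001, seed = 1) {
  take <- function(x) {
    if (inherits(x, "relative_fitness_samples")) x$samples
    else as.numeric(x)
  }
  r0 <- take(r0_samples); rm_ <- take(rminus_samples); av <- take(a_samples)
  if (length(r0) == 0L || length(rm_) == 0L || length(av) == 0L)
    stop("sample vectors must be non-empty", call. = FALSE)
  if (n_sets < 1 || set_size < 1)
    stop("n_sets and set_size must be >= 1", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  total <- n_sets * set_size
  draw_pos <- function(pool, n) {
    out <- pool[sample.int(length(pool), n, replace = TRUE)]
    bad <- which(out <= 0)
    redrawn <- 0L
    while (length(bad) > 0L) {
      if (all(pool <= 0))
        stop("all samples are non-positive; cannot draw a valid relative fitness",
             call. = FALSE)
      out[bad] <- pool[sample.int(length(pool), length(bad), replace = TRUE)]
      redrawn <- redrawn + length(bad)
      bad <- bad[out[bad] <= 0]
    }
    list(x = out, redrawn = redrawn)
  }
  d0 <- draw_pos(r0, total); dm <- draw_pos(rm_, total); da <- draw_pos(av, total)
  allr <- c(d0$x, dm$x, da$x, da$x / d0$x, da$x / dm$x)
  Ufun <- fixation_interpolator(N, min(allr), max(allr))
  Et0 <- expected_time_vec(d0$x, da$x, N, mu, Ufun)
  Etm <- expected_time_vec(dm$x, da$x, N, mu, Ufun)
  neutral <- Et0 <= Etm
  n_ties <- sum(Et0 == Etm)
  chosen <- ifelse(neutral, Et0, Etm)
  set_id <- rep(seq_len(n_sets), each = set_size)
  neutral_counts <- as.integer(tapply(neutral, set_id, sum))
  mean_wait <- as.numeric(tapply(chosen, set_id, mean))
  structure(list(
    neutral_counts = neutral_counts,
    mean_wait = mean_wait,
    count_interval = stats::quantile(neutral_counts, c(0.025, 0.975)),
    wait_interval = stats::quantile(mean_wait, c(0.025, 0.975)),
    n_redrawn = d0$redrawn + dm$redrawn + da$redrawn,
    n_ties = n_ties, n_sets = n_sets, set_size = set_size,
    N = N, mu = mu),
    class = "outcome_set_prediction")
}

#' @export
print.outcome_set_prediction <- function(x, ...) {
  cat(sprintf("<outcome_set_prediction %d sets x %d outcomes (N=%d, mu=%g)>\n",
              x$n_sets, x$set_size, x$N, x$mu))
  cat(sprintf("  neutral-intermediate path: median %d/%d per set, 95%% interval [%g, %g]\n",
              as.integer(stats::median(x$neutral_counts)), x$set_size,
              x$count_interval[1], x$count_interval[2]))
  cat(sprintf("  mean waiting time per set: median %.1f generations, 95%% interval [%.1f, %.1f]\n",
              stats::median(x$mean_wait), x$wait_interval[1], x$wait_interval[2]))
  if (x$n_redrawn > 0) cat(sprintf("  %d non-positive draws redrawn\n", x$n_redrawn))
  if (x$n_ties > 0) cat(sprintf("  %d exact ties assigned to the neutral path\n", x$n_ties))
  invisible(x)
}

#' Is an observed per-set count inside the predicted 95 percent interval?
#'
#' @param prediction an \code{\link{predict_outcome_sets}} result.
#' @param observed_count observed number of neutral-intermediate outcomes in
#'   a set of \code{set_size}.
#' @return TRUE when \code{observed_count} lies within the inclusive
#'   [2.5th, 97.5th] percentile interval of the per-set counts.
#' @export
within_predicted_interval <- function(prediction, observed_count) {
  stopifnot(inherits(prediction, "outcome_set_prediction"))
  observed_count >= prediction$count_interval[1] &&
    observed_count <= prediction$count_interval[2]
}
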