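#' Empirical fitness distribution of one genotype
#'
#' Runs \code{n_trials} independent foraging trials (per-trial seeds derived
#' from \code{seed} by index, so the same call always reproduces the same
#' sample vector and trials may be computed in any order) and keeps every
#' per-trial bout count, not just the mean.
#'
#' @param genotype anything accepted by \code{\link{as_genotype}}.
#' @param n_trials number of trials (>= 1).
#' @param config a \code{\link{sim_config}}.
#' @param seed base seed; trial i uses the i-th derived sub-seed.
#' @return A list of class \code{fitness_distribution}: \code{genotype},
#'   \code{samples} (bout counts), \code{collisions} (per-trial collision
#'   counts), \code{n_trials}, \code{seed}, \code{fingerprint} (ties the
#'   samples to the generating config) and \code{config}.
#' @export
estimate_fitness_samples <- function(genotype, n_trials, config = sim_config(),
                                     seed = 1) {
  g <- as_genotype(genotype)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("n_trials must be >= 1", call. = FALSE)
  n_trials <- as.integer(n_trials)
  config <- validate_sim_config(unclass(config))
  seeds <- derive_seeds(seed, n_trials)
  bouts <- integer(n_trials)
  colls <- integer(n_trials)
  gi <- as.integer(g)
  for (i in seq_len(n_trials)) {
    r <- cpp_simulate_trial(config, gi, seeds[i], FALSE)
    bouts[i] <- as.integer(r$bouts)
    colls[i] <- as.integer(r$collisions)
  }
  structure(list(genotype = format(g), samples = bouts, collisions = colls,
                 n_trials = n_trials, seed = as.numeric(seed),
                 fingerprint = config_fingerprint(config), config = config),
            class = "fitness_distribution")
}

#' @export
print.fitness_distribution <- function(x, ...) {
  cat(sprintf("<fitness_distribution %s> n=%d trials, mean bouts %.3f (sd %.3f), mean collisions %.1f\n",
              x$genotype, x$n_trials, mean(x$samples), stats::sd(x$samples),
              mean(x$collisions)))
  invisible(x)
}

#' Map the 16-genotype fitness landscape
#'
#' @param n_trials trials per genotype.
#' @param config a \code{\link{sim_config}}.
#' @param seed base seed.  Every genotype uses the same per-trial seed
#'   stream, so sample vectors do not depend on which genotypes are
#'   requested and genotypes whose differing loci are unexpressed (b3 under
#'   p = 0) get bit-identical samples.
#' @param genotypes character vector of genotype labels (default all 16).
#' @return A list of class \code{fitness_landscape}: \code{distributions}
#'   (named list of \code{\link{estimate_fitness_samples}} results) and
#'   \code{summary} (data.frame with per-genotype mean/var of bouts and mean
#'   collisions).
#' @export
fitness_landscape <- function(n_trials, config = sim_config(), seed = 1,
                              genotypes = all_genotypes()) {
  dists <- lapply(genotypes, function(lab) {
    estimate_fitness_samples(lab, n_trials, config, seed = seed)
  })
  names(dists) <- genotypes
  summ <- data.frame(
    genotype = genotypes,
    mean_bouts = vapply(dists, function(d) mean(d$samples), numeric(1)),
    var_bouts = vapply(dists, function(d) stats::var(d$samples), numeric(1)),
    mean_collisions = vapply(dists, function(d) mean(d$collisions), numeric(1)),
    n = n_trials,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(distributions = dists, summary = summ, seed = seed,
                 fingerprint = config_fingerprint(config)),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat("<fitness_landscape>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Bootstrap relative-fitness samples
#'
#' Resamples both distributions with replacement and returns \code{n_boot}
#' replicates of (mean of resampled numerator) / (mean of resampled
#' baseline) -- the relative mean swarm fitness of the numerator genotype
#' against the baseline (by default the pre-tunneling resident
#' \verb{{1,0,0;0}}).
#'
#' @param dist a \code{fitness_distribution} (numerator genotype).
#' @param baseline a \code{fitness_distribution} generated under the same
#'   config (checked through the config fingerprint).
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @return A list of class \code{relative_fitness_samples}: \code{genotype},
#'   \code{baseline}, \code{samples} (the ratio replicates) and
#'   \code{n_boot}.
#' @export
relative_fitness <- function(dist, baseline, n_boot = 10000, seed = 1) {
  stopifnot(inherits(dist, "fitness_distribution"),
            inherits(baseline, "fitness_distribution"))
  if (!identical(dist$fingerprint, baseline$fingerprint))
    stop("fitness distributions were generated under different configs",
         call. = FALSE)
  if (mean(baseline$samples) == 0)
    stop("baseline mean fitness is zero; relative fitness undefined",
         call. = FALSE)
  n_boot <- as.integer(n_boot)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  nx <- length(dist$samples)
  nb <- length(baseline$samples)
  ratios <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    num <- mean(dist$samples[sample.int(nx, nx, replace = TRUE)])
    den <- mean(baseline$samples[sample.int(nb, nb, replace = TRUE)])
    # a zero-resample of the baseline is possible for very sparse fitness;
    # redraw rather than divide by zero
    while (den == 0)
      den <- mean(baseline$samples[sample.int(nb, nb, replace = TRUE)])
    ratios[i] <- num / den
  }
  structure(list(genotype = dist$genotype, baseline = baseline$genotype,
                 samples = ratios, n_boot = n_boot),
            class = "relative_fitness_samples")
}

#' @export
print.relative_fitness_samples <- function(x, ...) {
  q <- stats::quantile(x$samples, c(0.025, 0.5, 0.975))
  cat(sprintf("<relative_fitness %s vs %s> median %.3f [%.3f, %.3f] (n_boot=%d)\n",
              x$genotype, x$baseline, q[2], q[1], q[3], x$n_boot))
  invisible(x)
}

# save and restore R's RNG state so seeded helpers do not disturb callers
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
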