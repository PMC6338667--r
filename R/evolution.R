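#' Configuration of a Wright-Fisher evolution run
#'
#' The evolving population holds \code{N} non-interacting clonal swarms with
#' constant size and non-overlapping generations.  Each generation every
#' offspring swarm picks a parent in proportion to the parent's realized
#' fitness, inherits its genotype, and then every locus flips independently
#' with probability \code{mu}.  Every swarm's fitness is redrawn from the
#' fitness provider each generation, so selection acts on noisy per-trial
#' foraging performance, not on genotype means.
#'
#' @param fitness_provider a function taking an N x 4 genotype matrix and
#'   returning one realized fitness value per swarm.  See
#'   \code{\link{fitness_provider_surrogate}} and
#'   \code{\link{fitness_provider_live}}.
#' @param N population size in swarms.
#' @param mu per-locus mutation probability per offspring swarm.
#' @param initial_genotype genotype of the founding population.
#' @param stop_genotype run ends when this genotype is fixed.
#' @param max_generations guard: a run that has not fixed by then is
#'   returned flagged unfixed.
#' @return A list of class \code{evolution_config}.
#' @export
evolution_config <- function(fitness_provider,
                             N = 200, mu = 0.001,
                             initial_genotype = "{0,0,0;0}",
                             stop_genotype = "{1,0,1;1}",
                             max_generations = 5000) {
  if (!is.function(fitness_provider))
    stop("fitness_provider must be a function(genotype matrix) -> numeric",
         call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || N < 2)
    stop("N must be >= 2", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0 || mu > 1)
    stop("mu must lie in [0, 1]", call. = FALSE)
  structure(list(fitness_provider = fitness_provider,
                 N = as.integer(N), mu = as.numeric(mu),
                 initial_genotype = as_genotype(initial_genotype),
                 stop_genotype = as_genotype(stop_genotype),
                 max_generations = as.integer(max_generations)),
            class = "evolution_config")
}

#' Surrogate fitness provider backed by stored landscape samples
#'
#' Draws each swarm's realized fitness uniformly from the per-trial bout
#' counts estimated for its genotype, so the evolutionary layer sees the
#' same fitness noise the foraging simulator produces, at negligible cost.
#'
#' @param landscape a \code{\link{fitness_landscape}} covering every
#'   genotype the run can reach (all 16 under nonzero mutation).
#' @return A provider function for \code{\link{evolution_config}}.
#' @export
fitness_provider_surrogate <- function(landscape) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  pools <- vector("list", 16L)
  for (lab in names(landscape$distributions))
    pools[[genotype_index(lab)]] <- landscape$distributions[[lab]]$samples
  function(G) {
    ids <- as.integer(G %*% c(8L, 4L, 2L, 1L)) + 1L
    out <- numeric(length(ids))
    for (id in unique(ids)) {
      pool <- pools[[id]]
      if (is.null(pool))
        stop("surrogate landscape has no samples for genotype index ", id,
             call. = FALSE)
      sel <- ids == id
      out[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
    }
    out
  }
}

#' Live fitness provider running one foraging trial per swarm
#'
#' Every call runs one full agent-based trial per swarm with a fresh
#' deterministic sub-seed.  Orders of magnitude slower than the surrogate;
#' intended for small validation runs.
#'
#' @param config a \code{\link{sim_config}} for the trials.
#' @param seed base seed of the trial-seed stream.
#' @return A provider function for \code{\link{evolution_config}}.
#' @export
fitness_provider_live <- function(config = reduced_arena_config(), seed = 1) {
  config <- validate_sim_config(unclass(config))
  counter <- new.env(parent = emptyenv())
  counter$i <- 0
  function(G) {
    n <- nrow(G)
    seeds <- derive_seeds(seed, counter$i + n)[(counter$i + 1):(counter$i + n)]
    counter$i <- counter$i + n
    vapply(seq_len(n), function(k) {
      as.numeric(cpp_simulate_trial(config, as.integer(G[k, ]), seeds[k], FALSE)$bouts)
    }, numeric(1))
  }
}

#' Mutate one genotype
#'
#' Each of the four loci independently flips to the other allele with
#' probability \code{mu} (applied once per offspring swarm; the clonal swarm
#' shares one genome).  Uses R's RNG.
#'
#' @param g anything accepted by \code{\link{as_genotype}}.
#' @param mu per-locus flip probability.
#' @return The (possibly) mutated \code{swarm_genotype}.
#' @export
mutate_genotype <- function(g, mu) {
  g <- as_genotype(g)
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0 || mu > 1)
    stop("mu must lie in [0, 1]", call. = FALSE)
  flip <- runif(4L) < mu
  v <- as.integer(g)
  v[flip] <- 1L - v[flip]
  genotype(v[1], v[2], v[3], v[4])
}

# vectorized mutation of an N x 4 genotype matrix; returns the matrix plus
# the flip positions
mutate_rows <- function(G, mu) {
  flips <- matrix(runif(length(G)) < mu, nrow = nrow(G))
  G[flips] <- 1L - G[flips]
  list(G = G, flips = flips)
}

#' One Wright-Fisher generation
#'
#' Fitness-proportional parent choice with replacement (inverse-CDF sampling,
#' one uniform draw per offspring), per-locus mutation of each offspring
#' swarm, and a fresh fitness draw for every offspring.  If every parent has
#' zero realized fitness, parents are chosen uniformly (proportionality is
#' undefined) and the fallback is flagged.
#'
#' @param pop a list with \code{generation}, \code{genotypes} (N x 4 integer
#'   matrix) and \code{fitness} (numeric N), as produced by this function or
#'   assembled by hand.
#' @param config an \code{\link{evolution_config}}.
#' @return A list with the new \code{pop}, the \code{parents} index vector
#'   (offspring i descends from \code{parents[i]}), a data.frame of
#'   \code{mutation_events} (offspring, locus, from, to) and the logical
#'   \code{uniform_fallback}.
#' @export
next_generation <- function(pop, config) {
  stopifnot(inherits(config, "evolution_config"))
  N <- config$N
  if (nrow(pop$genotypes) != N)
    stop("population has ", nrow(pop$genotypes), " swarms, config expects ", N,
         call. = FALSE)
  fit <- pop$fitness
  if (any(fit < 0)) stop("fitness values must be >= 0", call. = FALSE)
  fallback <- FALSE
  if (sum(fit) == 0) {
    fallback <- TRUE
    fit <- rep(1, N)
  }
  cum <- cumsum(fit) / sum(fit)
  parents <- findInterval(runif(N), cum) + 1L
  parents[parents > N] <- N  # guard against u == 1 rounding
  G <- pop$genotypes[parents, , drop = FALSE]
  mut <- mutate_rows(G, config$mu)
  ev <- which(mut$flips, arr.ind = TRUE)
  events <- data.frame(
    offspring = as.integer(ev[, 1]),
    locus = c("b1", "b2", "b3", "p")[ev[, 2]],
    from = 1L - mut$G[ev], to = mut$G[ev],
    stringsAsFactors = FALSE)
  newpop <- list(generation = pop$generation + 1L,
                 genotypes = mut$G,
                 fitness = config$fitness_provider(mut$G))
  list(pop = newpop, parents = parents, mutation_events = events,
       uniform_fallback = fallback)
}

#' Run Wright-Fisher evolution to fixation of the target genotype
#'
#' Starts from a population fixed for the initial genotype and iterates
#' \code{\link{next_generation}} until the stop genotype is fixed or the
#' generation guard is reached.  The full per-generation parent map and
#' genotype table are kept so any genealogy can be reconstructed.
#'
#' @param config an \code{\link{evolution_config}}.
#' @param seed seed for all randomness of the run (parent choice, mutation,
#'   surrogate fitness draws).
#' @param initial_genotypes optional N x 4 integer matrix overriding the
#'   uniform initial population (used e.g. to start from a mixed stand when
#'   checking drift expectations).
#' @return A list of class \code{evolution_run}: \code{freq} (generations x
#'   16 genotype-frequency matrix, rows summing to 1), \code{genotype_ids}
#'   ((generations+1) x N matrix of canonical genotype indices; row g+1 is
#'   generation g), \code{parents} (generations x N parent-index matrix),
#'   \code{events} (generation, offspring, locus, from, to),
#'   \code{fixed}, \code{fixation_generation}, \code{zero_fitness_generations}
#'   and the run parameters.
#' @export
run_evolution <- function(config, seed = 1, initial_genotypes = NULL) {
  stopifnot(inherits(config, "evolution_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  N <- config$N
  gmax <- config$max_generations
  stop_id <- genotype_index(config$stop_genotype)
  if (is.null(initial_genotypes)) {
    G0 <- matrix(rep(as.integer(config$initial_genotype), each = N), nrow = N)
  } else {
    G0 <- initial_genotypes
    storage.mode(G0) <- "integer"
    if (!is.matrix(G0) || nrow(G0) != N || ncol(G0) != 4L)
      stop("initial_genotypes must be an N x 4 matrix", call. = FALSE)
  }
  pop <- list(generation = 0L, genotypes = G0,
              fitness = config$fitness_provider(G0))
  ids <- matrix(NA_integer_, nrow = gmax + 1L, ncol = N)
  parents <- matrix(NA_integer_, nrow = gmax, ncol = N)
  events <- vector("list", gmax)
  id_of <- function(G) as.integer(G %*% c(8L, 4L, 2L, 1L)) + 1L
  ids[1L, ] <- id_of(pop$genotypes)
  zero_fallbacks <- 0L
  fixed <- all(ids[1L, ] == stop_id)
  gen <- 0L
  while (!fixed && gen < gmax) {
    stepped <- next_generation(pop, config)
    gen <- gen + 1L
    pop <- stepped$pop
    parents[gen, ] <- stepped$parents
    ids[gen + 1L, ] <- id_of(pop$genotypes)
    if (nrow(stepped$mutation_events) > 0) {
      e <- stepped$mutation_events
      e$generation <- gen
      events[[gen]] <- e
    }
    if (stepped$uniform_fallback) zero_fallbacks <- zero_fallbacks + 1L
    fixed <- all(ids[gen + 1L, ] == stop_id)
  }
  n_gen <- gen
  ids <- ids[seq_len(n_gen + 1L), , drop = FALSE]
  parents <- parents[seq_len(n_gen), , drop = FALSE]
  events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(offspring = integer(0), locus = character(0),
                         from = integer(0), to = integer(0),
                         generation = integer(0), stringsAsFactors = FALSE)
  freq <- t(apply(ids, 1L, function(row) tabulate(row, nbins = 16L))) / N
  colnames(freq) <- all_genotypes()
  rownames(freq) <- 0:n_gen
  structure(list(freq = freq, genotype_ids = ids, parents = parents,
                 events = events[, c("generation", "offspring", "locus",
                                     "from", "to")],
                 fixed = fixed,
                 fixation_generation = if (fixed) n_gen else NA_integer_,
                 zero_fitness_generations = zero_fallbacks,
                 N = N, mu = config$mu,
                 initial_genotype = format(config$initial_genotype),
                 stop_genotype = format(config$stop_genotype),
                 seed = seed),
            class = "evolution_run")
}

#' @export
print.evolution_run <- function(x, ...) {
  if (x$fixed)
    cat(sprintf("<evolution_run N=%d mu=%g> fixed %s at generation %d\n",
                x$N, x$mu, x$stop_genotype, x$fixation_generation))
  else
    cat(sprintf("<evolution_run N=%d mu=%g> UNFIXED after %d generations\n",
                x$N, x$mu, nrow(x$freq) - 1L))
  invisible(x)
}

#' Classify the mutation order along a genotype-label lineage
#'
#' Given the genotype labels along one genealogy (generation 0 first), finds
#' the first generation at which the lineage carries the pre-tunneling
#' resident \verb{{1,0,0;0}} and classifies what happens afterwards:
#' \code{b3_first} if the first 0->1 mutation at locus b3 strictly precedes
#' the first 0->1 mutation at locus p and the lineage only visits
#' shortest-path genotypes (\verb{{1,0,0;0}}, \verb{{1,0,1;0}},
#' \verb{{1,0,1;1}}); \code{p_first} symmetrically; anything else
#' \code{irregular}.
#'
#' @param labels character vector of genotype labels along the lineage.
#' @return A list with \code{class}, \code{anchor_generation} (0-based),
#'   \code{b3_generation}, \code{p_generation} (first 0->1 events anywhere on
#'   the lineage, 0-based generation of the offspring carrying the new
#'   allele) and \code{precedence} ("b3", "p" or NA).
#' @export
classify_lineage <- function(labels) {
  G <- t(vapply(labels, function(l) as.integer(as_genotype(l)), integer(4)))
  n <- nrow(G)
  first_rise <- function(col) {
    ix <- which(diff(G[, col]) == 1L)
    if (length(ix) == 0L) NA_integer_ else ix[1]  # offspring generation (0-based)
  }
  b3_gen <- first_rise(3L)
  p_gen <- first_rise(4L)
  precedence <- if (is.na(b3_gen) || is.na(p_gen)) NA_character_
                else if (b3_gen < p_gen) "b3"
                else if (p_gen < b3_gen) "p" else NA_character_
  ids <- as.integer(G %*% c(8L, 4L, 2L, 1L)) + 1L
  anchor <- which(ids == 9L)[1]  # {1,0,0;0}
  cls <- "irregular"
  if (!is.na(anchor)) {
    after <- ids[anchor:n]
    rise_after <- function(col) {
      ix <- which(diff(G[anchor:n, col]) == 1L)
      if (length(ix) == 0L) NA_integer_ else (anchor - 1L) + ix[1]
    }
    b3a <- rise_after(3L)
    pa <- rise_after(4L)
    if (!is.na(b3a) && !is.na(pa)) {
      if (b3a < pa && all(after %in% c(9L, 11L, 12L))) cls <- "b3_first"
      else if (pa < b3a && all(after %in% c(9L, 10L, 12L))) cls <- "p_first"
    }
  }
  list(class = cls,
       anchor_generation = if (is.na(anchor)) NA_integer_ else anchor - 1L,
       b3_generation = b3_gen, p_generation = p_gen,
       precedence = precedence)
}

# trace the focal genealogy of a fixed run: lowest-index swarm of the first
# all-fixed generation, followed back to generation 0
trace_focal_lineage <- function(run) {
  if (!run$fixed) stop("run did not reach fixation; no genealogy to trace",
                       call. = FALSE)
  fg <- run$fixation_generation
  idx <- 1L
  path <- integer(fg + 1L)
  path[fg + 1L] <- idx
  g <- fg
  while (g > 0L) {
    idx <- run$parents[g, idx]
    path[g] <- idx
    g <- g - 1L
  }
  labels <- all_genotypes()[run$genotype_ids[cbind(seq_len(fg + 1L), path)]]
  list(swarm_index = path, labels = labels)
}

#' Classify the genealogy of a fixed evolution run
#'
#' Traces the lineage of the lowest-index swarm in the first generation
#' where the stop genotype is fixed back to generation 0, then applies
#' \code{\link{classify_lineage}}.
#'
#' @param run a fixed \code{\link{run_evolution}} result.
#' @return A list of class \code{genealogy_classification}: the fields of
#'   \code{\link{classify_lineage}} plus \code{lineage_labels} and
#'   \code{swarm_index}.
#' @export
classify_genealogy <- function(run) {
  stopifnot(inherits(run, "evolution_run"))
  lin <- trace_focal_lineage(run)
  out <- classify_lineage(lin$labels)
  out$lineage_labels <- lin$labels
  out$swarm_index <- lin$swarm_index
  class(out) <- "genealogy_classification"
  out
}

#' @export
print.genealogy_classification <- function(x, ...) {
  cat(sprintf("<genealogy %s> b3 0->1 at gen %s, p 0->1 at gen %s (anchor %s)\n",
              x$class, x$b3_generation, x$p_generation, x$anchor_generation))
  invisible(x)
}

#' Peak frequency of the pre-tunneling resident before the focal mutations
#'
#' The maximum population frequency attained by \verb{{1,0,0;0}} in the
#' generations strictly before the first 0->1 mutation at locus b3 or p on
#' the focal genealogy -- how completely the resident took over before the
#' lineage of the final genotype started crossing the valley.
#'
#' @param run a fixed \code{\link{run_evolution}} result.
#' @param classification optionally, a precomputed
#'   \code{\link{classify_genealogy}} result for \code{run}.
#' @return The peak frequency (0 if the first focal mutation predates any
#'   resident presence).
#' @export
origin_peak_frequency <- function(run, classification = NULL) {
  stopifnot(inherits(run, "evolution_run"))
  if (is.null(classification)) classification <- classify_genealogy(run)
  gstar <- min(classification$b3_generation, classification$p_generation,
               na.rm = TRUE)
  rows <- seq_len(gstar)  # generations 0 .. gstar-1
  max(run$freq[rows, "{1,0,0;0}"])
}
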