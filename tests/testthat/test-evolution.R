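# surrogate landscape built from synthetic per-genotype pools: cheap,
# controlled fitness values for exercising the Wright-Fisher layer
fake_landscape <- function(means, noise = 0L) {
  dists <- lapply(names(means), function(lab) {
    structure(list(genotype = lab,
                   samples = pmax(0L, means[[lab]] + seq(-noise, noise)),
                   collisions = integer(0), n_trials = 2 * noise + 1,
                   seed = 0, fingerprint = "fake", config = NULL),
              class = "fitness_distribution")
  })
  names(dists) <- names(means)
  structure(list(distributions = dists, summary = NULL, seed = 0,
                 fingerprint = "fake"),
            class = "fitness_landscape")
}

all16 <- function(base = 1L, overrides = list()) {
  means <- setNames(as.list(rep(base, 16)), all_genotypes())
  for (nm in names(overrides)) means[[nm]] <- overrides[[nm]]
  means
}

test_that("mutation flips each locus independently at the requested rate", {
  set.seed(1)
  expect_identical(as.integer(mutate_genotype("{1,0,1;1}", 0)), c(1L, 0L, 1L, 1L))
  expect_identical(as.integer(mutate_genotype("{1,0,1;1}", 1)), c(0L, 1L, 0L, 0L))
  # binomial oracle on the vectorized path used by next_generation
  set.seed(42)
  n <- 200000L
  G <- matrix(0L, n, 4)
  flips <- mutate_rows(G, 0.001)$flips
  rate <- colMeans(flips)
  ci <- qbinom(c(0.005, 0.995), n, 0.001) / n
  expect_true(all(rate >= ci[1] & rate <= ci[2]))
})

test_that("next_generation keeps size, records parents and mutation events", {
  land <- fake_landscape(all16(5L))
  config <- evolution_config(fitness_provider_surrogate(land), N = 40, mu = 0.05)
  set.seed(9)
  G <- matrix(rep(c(0L, 0L, 0L, 0L), each = 40), nrow = 40)
  pop <- list(generation = 0L, genotypes = G, fitness = rep(1, 40))
  out <- next_generation(pop, config)
  expect_equal(nrow(out$pop$genotypes), 40L)
  expect_true(all(out$parents >= 1 & out$parents <= 40))
  # recorded events match the offspring-parent genotype differences exactly
  diffs <- out$pop$genotypes != G[out$parents, , drop = FALSE]
  expect_equal(nrow(out$mutation_events), sum(diffs))
  for (k in seq_len(nrow(out$mutation_events))) {
    ev <- out$mutation_events[k, ]
    loc <- match(ev$locus, c("b1", "b2", "b3", "p"))
    expect_true(diffs[ev$offspring, loc])
    expect_equal(out$pop$genotypes[ev$offspring, loc], ev$to)
  }
})

test_that("fitness-proportional selection reproduces multinomial expectations", {
  land <- fake_landscape(all16(1L))
  config <- evolution_config(fitness_provider_surrogate(land), N = 60, mu = 0)
  set.seed(4)
  G <- matrix(rep(c(0L, 0L, 0L, 0L), each = 60), nrow = 60)
  G[1:30, 1] <- 1L  # half the population carries b1
  # fitness ratio 2:1 between the two classes
  pop <- list(generation = 0L, genotypes = G,
              fitness = c(rep(2, 30), rep(1, 30)))
  share <- replicate(300, {
    out <- next_generation(pop, config)
    mean(out$pop$genotypes[, 1])
  })
  # expected offspring share of the fit class is 2/3
  se <- sqrt(2 / 9 / (60 * 300))  # binomial-ish Monte Carlo error
  expect_lt(abs(mean(share) - 2 / 3), 5 * max(se, 0.005))
})

test_that("zero total fitness falls back to uniform parent choice", {
  land <- fake_landscape(all16(0L))
  config <- evolution_config(fitness_provider_surrogate(land), N = 10, mu = 0)
  set.seed(2)
  G <- matrix(0L, 10, 4)
  pop <- list(generation = 0L, genotypes = G, fitness = rep(0, 10))
  out <- next_generation(pop, config)
  expect_true(out$uniform_fallback)
  expect_equal(nrow(out$pop$genotypes), 10L)
})

test_that("run_evolution fixes a dominant genotype quickly and records structure", {
  land <- fake_landscape(all16(1L, list("{1,0,1;1}" = 200L)))
  config <- evolution_config(fitness_provider_surrogate(land), N = 30,
                             mu = 0.02, max_generations = 1000)
  run <- run_evolution(config, seed = 5)
  expect_true(run$fixed)
  expect_lt(run$fixation_generation, 1000)
  expect_true(all(abs(rowSums(run$freq) - 1) < 1e-12))
  expect_equal(ncol(run$parents), 30L)
  # every generation's frequencies are over exactly N swarms
  expect_equal(nrow(run$freq), run$fixation_generation + 1L)
  # the focal genealogy is a connected path back to generation 0
  cls <- classify_genealogy(run)
  expect_length(cls$lineage_labels, run$fixation_generation + 1L)
})

test_that("mu = 0 leaves the population on the initial genotype until the guard", {
  land <- fake_landscape(all16(1L))
  config <- evolution_config(fitness_provider_surrogate(land), N = 10,
                             mu = 0, max_generations = 25)
  run <- run_evolution(config, seed = 1)
  expect_false(run$fixed)
  expect_true(all(run$freq[, "{0,0,0;0}"] == 1))
  expect_error(classify_genealogy(run), "fixation")
})

test_that("neutral drift fixes a genotype at its initial frequency", {
  # k/N oracle: with constant fitness and no mutation, a genotype starting
  # at count k fixes with probability k/N
  land <- fake_landscape(all16(1L))
  N <- 8L; k <- 2L
  config <- evolution_config(fitness_provider_surrogate(land), N = N, mu = 0,
                             stop_genotype = "{1,0,1;1}",
                             max_generations = 120)
  G <- matrix(rep(c(0L, 0L, 0L, 0L), each = N), nrow = N)
  G[seq_len(k), ] <- matrix(rep(c(1L, 0L, 1L, 1L), each = k), nrow = k)
  set.seed(31)
  seeds <- sample.int(1e6, 600)
  wins <- vapply(seeds, function(s) {
    run <- run_evolution(config, seed = s, initial_genotypes = G)
    run$fixed
  }, logical(1))
  p <- mean(wins)
  se <- sqrt(p * (1 - p) / length(wins))
  expect_lt(abs(p - k / N), 4 * se + 0.01)
})

test_that("genealogies classify by mutation order and shortest-path membership", {
  b3_first <- c("{0,0,0;0}", "{1,0,0;0}", "{1,0,0;0}", "{1,0,1;0}",
                "{1,0,1;0}", "{1,0,1;1}")
  expect_equal(classify_lineage(b3_first)$class, "b3_first")
  expect_equal(classify_lineage(b3_first)$precedence, "b3")
  p_first <- c("{1,0,0;0}", "{1,0,0;1}", "{1,0,1;1}")
  expect_equal(classify_lineage(p_first)$class, "p_first")
  expect_equal(classify_lineage(p_first)$precedence, "p")
  irregular <- c("{1,0,0;0}", "{1,1,0;0}", "{1,1,1;0}", "{1,1,1;1}", "{1,0,1;1}")
  cls <- classify_lineage(irregular)
  expect_equal(cls$class, "irregular")
  expect_equal(cls$precedence, "b3")  # b3 still rose before p
  # lineage that never carries the {1,0,0;0} anchor
  odd <- c("{0,0,0;0}", "{0,0,1;0}", "{1,0,1;0}", "{1,0,1;1}")
  expect_equal(classify_lineage(odd)$class, "irregular")
})

test_that("origin peak frequency reads the resident peak before the focal mutations", {
  land <- fake_landscape(all16(1L, list("{1,0,0;0}" = 50L, "{1,0,1;0}" = 50L,
                                        "{1,0,1;1}" = 400L)))
  config <- evolution_config(fitness_provider_surrogate(land), N = 40,
                             mu = 0.01, max_generations = 4000)
  for (s in c(3, 11)) {
    run <- run_evolution(config, seed = s)
    if (!run$fixed) next
    peak <- origin_peak_frequency(run)
    expect_gte(peak, 0)
    expect_lte(peak, 1)
  }
})
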