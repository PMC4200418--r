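#' GA configuration for the SG engine
#'
#' Collects the tunable parameters of the hybrid annealed genetic search.
#' Defaults follow the published algorithm where it states values (population
#' of 20 chromosomes, champion stalled for 30 generations as the stopping
#' rule) and conventional GA practice where it does not (adaptive
#' mutation/crossover parameters, geometric cooling).
#'
#' @param population_size Chromosomes per shape run (default 20). See
#'   [population_size_for()] for the recommended schedule at larger `n`.
#' @param pm1,pm2 Adaptive mutation parameters, `0 < pm2 < pm1 < 1`. The
#'   self-adaptive frequency assigns `pm1` to individuals at or below average
#'   fitness and interpolates down to `pm2` at the population maximum.
#' @param pc1,pc2 Adaptive crossover parameters, same constraint and form
#'   (computed from the fitter parent of each pair).
#' @param t0 Initial annealing temperature (> 0; fitness lives in `[0, 1]`).
#' @param cooling Geometric cooling factor in (0, 1): `T_{g+1} = cooling * T_g`.
#' @param stall_limit Stop a shape's run once the best-ever fitness has been
#'   unchanged ("championed") for this many consecutive generations.
#' @param max_generations Hard cap on generations per shape run.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param engine `"compiled"` (C++ inner loop, the default) or `"reference"`
#'   (pure-R loop built from the exported operators; identical semantics,
#'   for cross-checking at small n).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 20L,
                      pm1 = 0.1, pm2 = 0.01,
                      pc1 = 0.9, pc2 = 0.6,
                      t0 = 0.1, cooling = 0.95,
                      stall_limit = 30L, max_generations = 2000L,
                      seed = NULL, engine = c("compiled", "reference")) {
  stopifnot(population_size >= 2L)
  stopifnot(0 < pm2, pm2 < pm1, pm1 < 1)
  stopifnot(0 < pc2, pc2 < pc1, pc1 < 1)
  stopifnot(t0 > 0, cooling > 0, cooling < 1)
  stopifnot(stall_limit >= 1L, max_generations >= 1L)
  structure(
    list(
      population_size = as.integer(population_size),
      pm1 = pm1, pm2 = pm2, pc1 = pc1, pc2 = pc2,
      t0 = t0, cooling = cooling,
      stall_limit = as.integer(stall_limit),
      max_generations = as.integer(max_generations),
      seed = if (!is.null(seed)) as.integer(seed),
      engine = match.arg(engine)
    ),
    class = "ga_config"
  )
}

#' Recommended population size by sample size
#'
#' The published schedule for the number of chromosomes needed for random
#' clouds of `n` points: 20 up to 30 points, 100 up to 50, 1000 up to 100,
#' 10000 up to 200, and beyond 200 points upwards of 100000 (with a warning,
#' since the runtime is correspondingly large). Gene-expression profiles
#' rarely exceed 50 time points, where 100 individuals suffice.
#'
#' @param n Number of data points (>= 4).
#' @return Integer population size.
#' @export
population_size_for <- function(n) {
  stopifnot(n >= 4)
  if (n <= 30) return(20L)
  if (n <= 50) return(100L)
  if (n <= 100) return(1000L)
  if (n <= 200) return(10000L)
  warning("n > 200: upwards of 100000 individuals are needed; ",
          "expect a long runtime")
  100000L
}

new_chromosome <- function(xgenes, ygenes, fitness = NA_real_) {
  structure(
    list(xgenes = as.integer(xgenes), ygenes = as.integer(ygenes),
         fitness = fitness),
    class = "chromosome"
  )
}

chromosome_fitness <- function(ranked, xgenes, ygenes) {
  score_grid(ranked, grid_partition(xgenes, ygenes, ranked$n))$mic
}

#' Initialize a GA population for one grid shape
#'
#' Each chromosome carries `nx - 1` vertical cut genes and `ny - 1`
#' horizontal cut genes, drawn uniformly without replacement from the
#' candidate cut positions `1..(n-1)` and kept sorted; fitness (the MIC of
#' its grid) is evaluated immediately.
#'
#' @param ranked A [rank_transform()] result.
#' @param shape Integer pair `(nx, ny)`, feasible for `n`.
#' @param config A [ga_config()].
#' @return List of `population_size` chromosomes.
#' @export
init_population <- function(ranked, shape, config = ga_config()) {
  ranked <- as_ranked_pairs(ranked)
  n <- ranked$n
  nx <- shape[[1]]
  ny <- shape[[2]]
  if (nx * ny > bn_threshold(n)) {
    stop("shape (", nx, ", ", ny, ") is infeasible for n = ", n)
  }
  if (nx > n || ny > n) stop("shape exceeds the number of points")
  lapply(seq_len(config$population_size), function(i) {
    xg <- sort(sample.int(n - 1L, nx - 1L))
    yg <- sort(sample.int(n - 1L, ny - 1L))
    new_chromosome(xg, yg, chromosome_fitness(ranked, xg, yg))
  })
}

#' Self-adaptive mutation (or crossover) probability
#'
#' The self-adapting parameter rule: individuals at or below the population's
#' average fitness get the full rate `pm1`; above-average individuals are
#' interpolated linearly down to `pm2` at the population maximum,
#' `pm = pm1 - (pm1 - pm2) * (f - f_ave) / (f_max - f_ave)`. A uniform
#' population (`f_max == f_ave`) gets `pm1`. The same functional form is used
#' for the crossover probability with `(pc1, pc2)`, evaluated at the fitter
#' parent of each pair.
#'
#' @param f Individual fitness.
#' @param f_max,f_ave Maximum and mean fitness of the current population.
#' @param pm1,pm2 Rate bounds, `pm2 < pm1`.
#' @return A rate in `[pm2, pm1]`.
#' @export
adaptive_mutation_prob <- function(f, f_max, f_ave, pm1, pm2) {
  stopifnot(f_ave <= f_max + 1e-12, pm2 < pm1)
  if (f_max <= f_ave || f < f_ave) return(pm1)
  max(pm1 - (pm1 - pm2) * (f - f_ave) / (f_max - f_ave), pm2)
}

#' Mutate one chromosome
#'
#' On each axis, one randomly chosen gene (cut line) is moved: an interior
#' line to a uniform position strictly between its left and right neighbor
#' lines, the first line to a uniform position between the axis start and the
#' second line, and the last line symmetrically. A lone line on its axis is
#' both "first" and "last" and may move anywhere in `1..(n-1)` (without this
#' extension, shapes with a single cut on one axis could never explore). Gene
#' counts — and hence the grid shape — never change; strict ordering is
#' preserved by construction. Fitness is re-evaluated.
#'
#' @param chrom A chromosome (see [init_population()]).
#' @param ranked The [rank_transform()] result the fitness is scored on.
#' @return The mutated chromosome.
#' @export
mutate_chromosome <- function(chrom, ranked) {
  ranked <- as_ranked_pairs(ranked)
  n <- ranked$n
  xg <- move_one_gene(chrom$xgenes, n)
  yg <- move_one_gene(chrom$ygenes, n)
  new_chromosome(xg, yg, chromosome_fitness(ranked, xg, yg))
}

move_one_gene <- function(genes, n) {
  k <- length(genes)
  j <- if (k == 1L) 1L else sample.int(k, 1L)
  lo <- if (j == 1L) 1L else genes[j - 1L] + 1L
  hi <- if (j == k) n - 1L else genes[j + 1L] - 1L
  if (hi >= lo) genes[j] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  genes
}

#' Conditionally mutate a chromosome
#'
#' Draws `u ~ U(0, 1)` and applies [mutate_chromosome()] iff `u < p_mutate`.
#' `p_mutate` is the probability that the mutation happens; the SG engine
#' derives it from the self-adaptive rate `pm` via its trigger rule (see
#' [sg_mic()] details).
#'
#' @inheritParams mutate_chromosome
#' @param p_mutate Probability of mutating, in `[0, 1]`.
#' @return The (possibly unchanged) chromosome.
#' @export
maybe_mutate <- function(chrom, ranked, p_mutate) {
  if (stats::runif(1) < p_mutate) mutate_chromosome(chrom, ranked) else chrom
}

#' Same-axis one-point crossover of two chromosomes
#'
#' With probability `pc`, one-point crossover is applied to the x-gene lists
#' and to the y-gene lists with independent uniform cut points — an x-gene is
#' only ever exchanged with another x-gene, a y-gene with another y-gene, so
#' the grid shape is preserved. The crossover point `c` is uniform over
#' `0..k` for a `k`-gene axis: the genes after position `c` are swapped
#' (`c = 0` exchanges the whole axis, `c = k` leaves it alone). Children's
#' gene lists are re-sorted; a duplicate created by the exchange is repaired
#' by resampling it uniformly from the free cut positions. With probability
#' `1 - pc` the children are plain copies.
#'
#' @param p1,p2 Parent chromosomes of the same shape.
#' @param ranked The [rank_transform()] result fitness is scored on.
#' @param pc Crossover probability.
#' @return List of two child chromosomes.
#' @export
crossover_chromosomes <- function(p1, p2, ranked, pc) {
  ranked <- as_ranked_pairs(ranked)
  if (length(p1$xgenes) != length(p2$xgenes) ||
      length(p1$ygenes) != length(p2$ygenes)) {
    stop("parents must have the same grid shape")
  }
  if (stats::runif(1) >= pc) return(list(p1, p2))
  n <- ranked$n
  cx <- cross_axis(p1$xgenes, p2$xgenes, n)
  cy <- cross_axis(p1$ygenes, p2$ygenes, n)
  c1 <- new_chromosome(cx[[1]], cy[[1]])
  c2 <- new_chromosome(cx[[2]], cy[[2]])
  c1$fitness <- chromosome_fitness(ranked, c1$xgenes, c1$ygenes)
  c2$fitness <- chromosome_fitness(ranked, c2$xgenes, c2$ygenes)
  list(c1, c2)
}

cross_axis <- function(a, b, n) {
  k <- length(a)
  cpt <- sample.int(k + 1L, 1L) - 1L  # 0..k
  if (cpt < k) {
    tail_idx <- (cpt + 1L):k
    tmp <- a[tail_idx]
    a[tail_idx] <- b[tail_idx]
    b[tail_idx] <- tmp
  }
  list(repair_axis(a, n), repair_axis(b, n))
}

repair_axis <- function(genes, n) {
  genes <- sort(genes)
  while (anyDuplicated(genes)) {
    dup <- which(duplicated(genes))[1]
    free <- setdiff(seq_len(n - 1L), genes)
    genes[dup] <- free[sample.int(length(free), 1L)]
    genes <- sort(genes)
  }
  genes
}

#' Fitness-proportional (roulette) selection
#'
#' Samples `length(fitness)` indices with replacement, with probability
#' proportional to fitness (MIC values, hence non-negative). If every fitness
#' is zero, sampling falls back to uniform.
#'
#' @param fitness Non-negative fitness vector.
#' @return Integer vector of selected indices, same length.
#' @export
select_proportional <- function(fitness) {
  stopifnot(all(fitness >= 0))
  m <- length(fitness)
  if (sum(fitness) == 0) {
    sample.int(m, m, replace = TRUE)
  } else {
    sample.int(m, m, replace = TRUE, prob = fitness)
  }
}

#' Metropolis acceptance
#'
#' The annealed reproduction filter: a fitness change `delta >= 0` is always
#' accepted; a deterioration is accepted with probability
#' `exp(delta / temperature)`, allowing escape from local optima early in the
#' run while the temperature is high.
#'
#' @param delta_fitness Fitness change of the proposed replacement.
#' @param temperature Current annealing temperature (> 0).
#' @return Logical: accept the proposal?
#' @export
metropolis_accept <- function(delta_fitness, temperature) {
  stopifnot(temperature > 0)
  if (delta_fitness >= 0) return(TRUE)
  stats::runif(1) < exp(delta_fitness / temperature)
}

#' Maximal information coefficient by annealed genetic search
#'
#' The package's main engine. For each feasible grid shape `(nx, ny)` under
#' the `B(n)` budget it runs a genetic algorithm over cut-line chromosomes:
#' proportional selection, same-axis one-point crossover with self-adaptive
#' probability, self-adaptive mutation of one line per axis, a
#' Metropolis-filtered replacement step against the selected parent under a
#' geometrically cooled temperature, and elitist preservation of the best
#' chromosome ever seen. A shape's run stops when its champion fitness has
#' been unchanged for `stall_limit` generations (or at `max_generations`);
#' the final MIC is the maximum over shapes. Deterministic for a fixed seed.
#'
#' Mutation trigger: each chromosome draws `u ~ U(0,1)` and mutates iff
#' `u >= pm`, where `pm` is the self-adaptive rate — i.e. `pm` acts as a
#' *protection* probability, so fitter individuals (smaller `pm`) are
#' perturbed more while the champion is preserved by elitism. This follows
#' the published trigger rule as printed; see the methods vignette for the
#' discussion of this convention.
#'
#' Because every chromosome respects the budget, `sg_mic` can never exceed
#' [exhaustive_mic()] on the same sample; with the default stall settings it
#' matches the exhaustive optimum on small samples in almost every seeded
#' run, which is the practical meaning of the engine's convergence guarantee.
#'
#' @param sample A [paired_sample()].
#' @param alpha Budget exponent, see [bn_threshold()].
#' @param config A [ga_config()].
#' @return A [mic_result()] with method `"sg"`; `diagnostics` holds
#'   per-generation champion fitness for the winning shape, the count of
#'   accepted deteriorations, total evaluations and generations.
#' @examples
#' s <- random_cloud(20, seed = 7)
#' sg_mic(s, config = ga_config(seed = 1))
#' @export
sg_mic <- function(sample, alpha = 0.6, config = ga_config()) {
  ranked <- as_ranked_pairs(sample)
  n <- ranked$n
  shapes <- feasible_shapes(n, alpha)
  if (!is.null(config$seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(config$seed)
  }
  runner <- if (config$engine == "compiled") sg_run_shape_compiled
            else sg_run_shape_reference
  best <- NULL
  tot_evals <- 0L
  tot_gens <- 0L
  tot_worse <- 0L
  for (i in seq_len(nrow(shapes))) {
    run <- runner(ranked, shapes[i, 1], shapes[i, 2], config)
    tot_evals <- tot_evals + run$evaluations
    tot_gens <- tot_gens + run$generations
    tot_worse <- tot_worse + run$accepted_worse
    if (is.null(best) || run$fitness > best$fitness) best <- run
  }
  grid <- grid_partition(best$xgenes, best$ygenes, n)
  res <- score_grid(ranked, grid, method = "sg")
  res$evaluations <- tot_evals
  res$generations <- tot_gens
  res$seed <- config$seed
  res$diagnostics <- list(
    generations_run = tot_gens,
    best_by_generation = best$best_by_generation,
    accepted_worse_moves = tot_worse,
    evaluations = tot_evals,
    winning_shape = c(nx = length(best$xgenes) + 1L,
                      ny = length(best$ygenes) + 1L)
  )
  res
}

sg_run_shape_compiled <- function(ranked, nx, ny, config) {
  out <- sg_run_shape_cpp(
    ranked$xr, ranked$yr, nx - 1L, ny - 1L,
    config$population_size, config$pm1, config$pm2, config$pc1, config$pc2,
    config$t0, config$cooling, config$stall_limit, config$max_generations
  )
  out
}

# Pure-R mirror of the compiled shape run, built from the exported operators.
# Same semantics and loop structure; RNG draw order differs, so results for a
# given seed agree in distribution, not bitwise.
sg_run_shape_reference <- function(ranked, nx, ny, config) {
  n <- ranked$n
  pop <- init_population(ranked, c(nx, ny), config)
  m <- config$population_size
  evals <- m
  fit <- vapply(pop, `[[`, numeric(1), "fitness")
  b <- which.max(fit)
  best <- pop[[b]]
  best_by_gen <- numeric(0)
  temp <- config$t0
  stall <- 0L
  gen <- 0L
  worse <- 0L
  while (gen < config$max_generations && stall < config$stall_limit) {
    gen <- gen + 1L
    idx <- select_proportional(fit)
    parents <- pop[idx]
    pfit <- fit[idx]
    children <- parents
    f_max <- max(pfit)
    f_ave <- mean(pfit)
    for (p in seq_len(m %/% 2L)) {
      i1 <- 2L * p - 1L
      i2 <- 2L * p
      pc <- adaptive_mutation_prob(max(pfit[i1], pfit[i2]), f_max, f_ave,
                                   config$pc1, config$pc2)
      kids <- crossover_chromosomes(children[[i1]], children[[i2]], ranked, pc)
      if (!identical(kids[[1]], children[[i1]])) evals <- evals + 2L
      children[[i1]] <- kids[[1]]
      children[[i2]] <- kids[[2]]
    }
    cfit <- vapply(children, `[[`, numeric(1), "fitness")
    f_max <- max(cfit)
    f_ave <- mean(cfit)
    for (i in seq_len(m)) {
      pm <- adaptive_mutation_prob(cfit[i], f_max, f_ave,
                                   config$pm1, config$pm2)
      mutated <- maybe_mutate(children[[i]], ranked, 1 - pm)
      if (!identical(mutated, children[[i]])) evals <- evals + 1L
      children[[i]] <- mutated
    }
    cfit <- vapply(children, `[[`, numeric(1), "fitness")
    for (i in seq_len(m)) {
      delta <- cfit[i] - pfit[i]
      if (metropolis_accept(delta, temp)) {
        if (delta < 0) worse <- worse + 1L
      } else {
        children[[i]] <- parents[[i]]
        cfit[i] <- pfit[i]
      }
    }
    g_best <- max(cfit)
    if (g_best > best$fitness) {
      best <- children[[which.max(cfit)]]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    w <- which.min(cfit)
    children[[w]] <- best
    cfit[w] <- best$fitness
    pop <- children
    fit <- cfit
    best_by_gen <- c(best_by_gen, best$fitness)
    temp <- temp * config$cooling
  }
  list(
    xgenes = best$xgenes, ygenes = best$ygenes, fitness = best$fitness,
    generations = gen, evaluations = evals, accepted_worse = worse,
    best_by_generation = best_by_gen
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
}
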