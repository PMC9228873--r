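## Genetic-algorithm hyperparameter search for the adversarial autoencoder.
##
## Genomes are fixed-length integer vectors indexing into the published
## hyperparameter vocabulary (layer count, width pattern, base width,
## activations, learning rate, dropout); fitness is the mean per-cluster KL
## divergence of the resulting embedding (minimised).  Tournament selection
## with uniform crossover, per-gene mutation and elitism of one.

#' The hyperparameter search space
#'
#' @return a `ga_space`: list of genes, each a vector of admissible values.
#'   Width patterns are `constant` (same width each layer), `decreasing`
#'   (halving per layer) and `increasing` (doubling per layer); the base
#'   width is clamped during decoding so every layer width stays inside
#'   {4, ..., 512}.
#' @export
ga_space <- function() {
  structure(list(
    n_layers = c(2L, 3L),
    pattern = c("constant", "decreasing", "increasing"),
    base_width = c(4L, 8L, 16L, 32L, 64L, 128L, 256L, 512L),
    ae_activation = c("sigmoid", "tanh", "relu"),
    disc_activation = c("sigmoid", "relu"),
    learning_rate = c(0.01, 0.005, 0.001, 0.0005, 0.0001),
    dropout = c(0, 0.1, 0.2, 0.3, 0.4)
  ), class = "ga_space")
}

## genome = integer index per gene
random_genome <- function(space) {
  vapply(space, function(g) sample.int(length(g), 1L), 0L)
}

#' Decode a genome into an autoencoder configuration
#'
#' @param genome integer vector of gene indices (one per [ga_space()] gene).
#' @param space a `ga_space`.
#' @param ... extra arguments passed to [aae_config()] (e.g. `mode`,
#'   `max_epochs`, `seed`).
#' @return an [aae_config()].
#' @export
decode_genome <- function(genome, space = ga_space(), ...) {
  stopifnot(length(genome) == length(space))
  g <- mapply(function(vals, i) vals[[i]], space, genome,
              SIMPLIFY = FALSE)
  vocab <- space$base_width
  L <- g$n_layers
  bi <- match(g$base_width, vocab)
  widths <- switch(g$pattern,
    constant = rep(g$base_width, L),
    decreasing = {                 # e.g. 16, 8, 4 for 3 layers
      bi <- max(bi, L)
      vocab[seq(bi, bi - L + 1L)]
    },
    increasing = {                 # e.g. 4, 8, 16 for 3 layers
      bi <- min(bi, length(vocab) - L + 1L)
      vocab[seq(bi, bi + L - 1L)]
    })
  aae_config(widths = widths, ae_activation = g$ae_activation,
             disc_activation = g$disc_activation,
             learning_rate = g$learning_rate, dropout = g$dropout, ...)
}

#' Configuration of the genetic algorithm
#'
#' @param population_size individuals per generation (default 50).
#' @param generations number of generations (default 10).
#' @param n_parents tournament-selected parents per generation (default 10).
#' @param tournament_size individuals per tournament (default 3).
#' @param mutation_prob per-gene mutation probability (default 0.05).
#' @param seed master seed.
#' @return a `ga_config` object.
#' @export
ga_config <- function(population_size = 50L, generations = 10L,
                      n_parents = 10L, tournament_size = 3L,
                      mutation_prob = 0.05, seed = 1L) {
  stopifnot(population_size >= 2L, generations >= 1L,
            n_parents >= 2L, n_parents <= population_size,
            tournament_size >= 1L, mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 n_parents = as.integer(n_parents),
                 tournament_size = as.integer(tournament_size),
                 mutation_prob = mutation_prob, seed = as.integer(seed)),
            class = "ga_config")
}

#' Evolve hyperparameters by genetic search
#'
#' Minimises `fitness_fn(genome)` over the gene space.  Each generation
#' keeps the best individual (elitism of 1), selects `n_parents` parents by
#' tournament, and fills the population with uniform-crossover offspring
#' subject to per-gene mutation.  A genome whose fitness evaluation fails is
#' assigned infinite fitness (with a warning) and selection continues.
#'
#' @param fitness_fn function taking a genome (integer vector) and returning
#'   a scalar to minimise.
#' @param space a [ga_space()].
#' @param config a [ga_config()].
#' @return list with `best_genome`, `best_fitness`, and `history` (data
#'   frame `generation, best_fitness, mean_fitness, best_genome_json`).
#' @export
evolve <- function(fitness_fn, space = ga_space(), config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  with_seed(config$seed, {
    pop <- replicate(config$population_size, random_genome(space),
                     simplify = FALSE)
    eval_one <- function(g) {
      val <- tryCatch(fitness_fn(g), error = function(e) {
        warning(sprintf("fitness evaluation failed (%s); assigning Inf",
                        conditionMessage(e)))
        Inf
      })
      if (!is.finite(val)) Inf else val
    }
    fit <- vapply(pop, eval_one, 0)
    history <- data.frame(generation = integer(), best_fitness = numeric(),
                          mean_fitness = numeric(),
                          best_genome_json = character())
    record <- function(gen) {
      b <- which.min(fit)
      rbind(history, data.frame(
        generation = gen, best_fitness = fit[b],
        mean_fitness = mean(fit[is.finite(fit)]),
        best_genome_json = as.character(
          jsonlite::toJSON(pop[[b]], auto_unbox = FALSE))))
    }
    history <- record(0L)
    for (gen in seq_len(config$generations)) {
      elite_i <- which.min(fit)
      elite <- pop[[elite_i]]
      elite_fit <- fit[elite_i]
      parents <- lapply(seq_len(config$n_parents), function(i) {
        cand <- sample.int(length(pop), config$tournament_size)
        pop[[cand[which.min(fit[cand])]]]
      })
      offspring <- vector("list", config$population_size - 1L)
      for (i in seq_along(offspring)) {
        pa <- parents[[sample.int(length(parents), 1L)]]
        pb <- parents[[sample.int(length(parents), 1L)]]
        pick <- stats::runif(length(pa)) < 0.5   # uniform crossover
        child <- ifelse(pick, pa, pb)
        for (gidx in seq_along(child)) {        # per-gene mutation
          if (stats::runif(1) < config$mutation_prob) {
            child[gidx] <- sample.int(length(space[[gidx]]), 1L)
          }
        }
        offspring[[i]] <- as.integer(child)
      }
      pop <- c(list(elite), offspring)
      fit <- c(elite_fit, vapply(offspring, eval_one, 0))
      history <- record(gen)
    }
    b <- which.min(fit)
    list(best_genome = pop[[b]], best_fitness = fit[b], history = history)
  })
}

#' Cross-validated KL fitness for the genetic search
#'
#' Returns a fitness closure that decodes a genome, trains the autoencoder
#' on the requested folds at a reduced epoch budget, and returns the mean
#' validation KL divergence — the quantity the search minimises.
#'
#' @param database a split `artificial_database`.
#' @param mixture a [prior_mixture()].
#' @param folds which CV folds to average over (default 1; use 1:5 for the
#'   full rotation).
#' @param epochs epoch cap per training run.
#' @param mode autoencoder mode.
#' @param seed training seed.
#' @return function(genome) -> mean validation KL.
#' @export
aae_kl_fitness <- function(database, mixture = prior_mixture(), folds = 1L,
                           epochs = 20L, mode = "unsupervised", seed = 1L) {
  force(database); force(mixture)
  function(genome) {
    vals <- vapply(folds, function(f) {
      cfg <- decode_genome(genome, mode = mode, max_epochs = epochs,
                           patience = epochs, seed = seed)
      data <- collect_fold(database, f)
      fit <- train_aae(data, cfg, mixture)
      zval <- encode(fit, data$validation$X)
      mean_cluster_kl(zval, data$validation$labels, mixture)
    }, 0)
    mean(vals)
  }
}

#' Write GA history to CSV
#' @param result an [evolve()] result.
#' @param path output path.
#' @export
write_ga_history <- function(result, path) {
  utils::write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
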