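## Pipeline orchestration and command-line entry point.
##
## A single run directory holds everything one reproducible experiment
## produces: emulated protocol motions, artificial databases, trained
## models, latent evaluations, reward sequences and bandit summaries, each
## stage stamped with a manifest echoing its configuration.  One master
## seed fans out deterministically to per-stage seeds.

#' Save a trained autoencoder as a JSON checkpoint
#'
#' Single-file archive holding the config echo, all parameter tensors and
#' the training history.
#'
#' @param trained a `trained_aae`.
#' @param path output `.json` path.
#' @export
save_aae <- function(trained, path) {
  pack_net <- function(net) {
    list(sizes = net$sizes, acts = net$acts, W = net$W, b = net$b)
  }
  obj <- list(config = unclass(trained$config),
              mixture = list(n_components = trained$mixture$n_components,
                             means = trained$mixture$means,
                             covs = trained$mixture$covs),
              encoder = pack_net(trained$encoder),
              decoder = pack_net(trained$decoder),
              discriminator = pack_net(trained$discriminator),
              history = trained$history,
              best_epoch = trained$best_epoch,
              val_metric = trained$val_metric)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Load a trained autoencoder checkpoint written by [save_aae()]
#' @param path checkpoint path.
#' @return a `trained_aae`.
#' @export
load_aae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack_net <- function(n) {
    list(sizes = as.integer(n$sizes),
         W = lapply(n$W, function(w) {
           m <- as.matrix(w); dimnames(m) <- NULL; m
         }),
         b = lapply(n$b, as.numeric), acts = unlist(n$acts))
  }
  cfg <- do.call(aae_config, obj$config[c(
    "widths", "ae_activation", "disc_activation", "learning_rate",
    "dropout", "batch_size", "latent_dim", "mode", "max_epochs",
    "patience", "seed")])
  mix <- prior_mixture(obj$mixture$n_components)
  mix$means <- as.matrix(obj$mixture$means)
  dimnames(mix$means) <- NULL
  covs <- obj$mixture$covs
  if (is.array(covs) && length(dim(covs)) == 3L) {
    # jsonlite simplifies a list of equal-shape matrices to a 3-D array
    covs <- lapply(seq_len(dim(covs)[1L]), function(i) covs[i, , ])
  }
  mix$covs <- lapply(covs, function(S) {
    m <- as.matrix(S); dimnames(m) <- NULL; m
  })
  structure(list(encoder = unpack_net(obj$encoder),
                 decoder = unpack_net(obj$decoder),
                 discriminator = unpack_net(obj$discriminator),
                 config = cfg, mixture = mix,
                 history = as.data.frame(obj$history),
                 best_epoch = obj$best_epoch, val_metric = obj$val_metric),
            class = "trained_aae")
}

#' Run the full pipeline (or selected stages) into a run directory
#'
#' Stages: `generate` (protocol emulation + artificial databases),
#' `train` (one AAE per database and mode), `evaluate` (KL, k-NN accuracy,
#' centroids, reward sequences), `bandit` (episodes per agent kind with the
#' cumulative weighted-probability error summarised at checkpoints), `ga`
#' (reduced-budget hyperparameter search).
#'
#' @param out_dir run directory (created if needed).
#' @param stages subset of
#'   `c("generate", "train", "evaluate", "bandit", "ga")`.
#' @param codes database codes to process (default `"XYR"`).
#' @param modes autoencoder modes to train (default both).
#' @param seed master seed; fans out per stage via [derive_seed()].
#' @param epochs training epoch cap.
#' @param widths autoencoder hidden widths.
#' @param checkpoints bandit summary iterations.
#' @param kinds bandit agent kinds.
#' @param ga_population,ga_generations reduced GA budget.
#' @param quiet suppress progress messages.
#' @return invisibly, a list of stage results.
#' @export
run_pipeline <- function(out_dir, stages = c("generate", "train", "evaluate",
                                             "bandit"),
                         codes = "XYR",
                         modes = c("unsupervised", "semi_supervised"),
                         seed = 1L, epochs = 60L, widths = c(64L, 64L),
                         checkpoints = c(5L, 10L, 30L, 60L),
                         kinds = bandit_kinds(), ga_population = 8L,
                         ga_generations = 3L, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  results <- list()

  manifest <- list(seed = seed, codes = codes, modes = modes,
                   epochs = epochs, widths = widths,
                   checkpoints = checkpoints, kinds = kinds,
                   stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  if ("generate" %in% stages) {
    say("generate", "emulating collection protocol")
    motions <- emulate_protocol(protocol_spec(),
                                seed = derive_seed(seed, "protocol"))
    write_motion_csv(motions, file.path(out_dir, "motions.csv"))
    for (code in codes) {
      cfg <- augmentation_config(code,
                                 seed = derive_seed(seed, paste0("db-", code)))
      db <- build_database(source_pool(motions), cfg)
      db <- split_database(db, seed = derive_seed(seed,
                                                  paste0("split-", code)))
      write_database(db, file.path(out_dir, paste0("database_", code)))
      say("generate", "database %s written (%d datasets)", code,
          length(db$datasets))
    }
    results$generate <- TRUE
  }

  mixture <- prior_mixture()

  if ("train" %in% stages) {
    for (code in codes) {
      db <- read_database(file.path(out_dir, paste0("database_", code)))
      data <- collect_fold(db, 1L)
      for (mode in modes) {
        cfg <- aae_config(widths = widths, mode = mode, max_epochs = epochs,
                          patience = max(10L, epochs %/% 5L),
                          seed = derive_seed(seed, paste0(code, "-", mode)))
        say("train", "%s / %s: training (max %d epochs)", code, mode, epochs)
        fit <- train_aae(data, cfg, mixture)
        save_aae(fit, file.path(out_dir,
                                sprintf("aae_%s_%s.json", code, mode)))
        write_training_log(fit, file.path(out_dir,
                                          sprintf("log_%s_%s.csv", code,
                                                  mode)))
        say("train", "%s / %s: best epoch %d, val %.4f", code, mode,
            fit$best_epoch, fit$val_metric)
      }
    }
    results$train <- TRUE
  }

  if ("evaluate" %in% stages) {
    report <- list()
    for (code in codes) {
      db <- read_database(file.path(out_dir, paste0("database_", code)))
      data <- collect_fold(db, 1L)
      motions <- read_motion_csv(file.path(out_dir, "motions.csv"))
      for (mode in modes) {
        fit <- load_aae(file.path(out_dir,
                                  sprintf("aae_%s_%s.json", code, mode)))
        ev <- evaluate_latent(fit, data)
        # target centroids from the reference (collected) motions
        zref <- encode(fit, motions)
        cent <- compute_centroids(zref, vapply(motions, `[[`, "", "label"))
        rewards <- lapply(db$split$test, function(i) {
          latent_distances(embed_dataset(fit, db$datasets[[i]]), cent)
        })
        names(rewards) <- as.character(db$split$test)
        write_reward_csv(rewards,
                         file.path(out_dir,
                                   sprintf("rewards_%s_%s.csv", code, mode)))
        report[[paste(code, mode, sep = "_")]] <-
          list(mean_kl = ev$mean_kl, knn_accuracy = ev$knn_accuracy,
               centroids = unclass(as.data.frame(cent)))
        say("evaluate", "%s / %s: knn %.3f, KL %.3f", code, mode,
            ev$knn_accuracy, ev$mean_kl)
      }
    }
    jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    results$evaluate <- report
  }

  if ("bandit" %in% stages) {
    rows <- list()
    for (code in codes) {
      for (mode in modes) {
        f <- file.path(out_dir, sprintf("rewards_%s_%s.csv", code, mode))
        if (!file.exists(f)) next
        rewards <- read_reward_csv(f)
        for (kind in kinds) {
          for (si in seq_along(rewards)) {
            cfg <- bandit_config(kind,
                                 horizon = nrow(rewards[[si]]),
                                 seed = derive_seed(seed,
                                                    paste(code, mode, kind,
                                                          si, sep = "-")))
            ep <- run_episode(cfg, rewards[[si]])
            for (cp in checkpoints) {
              rows[[length(rows) + 1L]] <- data.frame(
                database = code, mode = mode, agent = kind,
                subject = names(rewards)[si], checkpoint = cp,
                ae = ep$ae[min(cp, length(ep$ae))])
            }
          }
        }
      }
    }
    summary <- do.call(rbind, rows)
    utils::write.csv(summary, file.path(out_dir, "bandit_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    say("bandit", "wrote %d summary rows", nrow(summary))
    results$bandit <- summary
  }

  if ("ga" %in% stages) {
    code <- codes[1L]
    db <- read_database(file.path(out_dir, paste0("database_", code)))
    fitness <- aae_kl_fitness(db, mixture, folds = 1L, epochs = 5L,
                              mode = "semi_supervised",
                              seed = derive_seed(seed, "ga-fitness"))
    res <- evolve(fitness, ga_space(),
                  ga_config(population_size = ga_population,
                            generations = ga_generations,
                            n_parents = max(2L, ga_population %/% 4L),
                            seed = derive_seed(seed, "ga")))
    write_ga_history(res, file.path(out_dir, "ga_history.csv"))
    say("ga", "best fitness %.4f", res$best_fitness)
    results$ga <- res
  }

  invisible(results)
}

## one source pool per the per-participant reading: augmentation draws its
## source motions from a single participant's collected set
source_pool <- function(motions, participant = 1L) {
  keep <- vapply(motions, function(m) {
    isTRUE(m$participant == participant)
  }, TRUE)
  if (!any(keep)) return(motions)
  structure(motions[keep], class = "motion_set")
}

#' Read reward sequences written by [write_reward_csv()]
#' @param path CSV path.
#' @return named list of reward matrices.
#' @export
read_reward_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$subject), function(d) {
    labs <- unique(d$label)
    m <- vapply(labs, function(l) d$distance[d$label == l],
                numeric(max(d$t)))
    colnames(m) <- labs
    m[, intersect(motion_shapes(), labs), drop = FALSE]
  })
}

#' Command-line entry point
#'
#' Subcommands: `generate`, `train`, `evaluate`, `bandit`, `ga`, `all`.
#' Common flags: `--out DIR` (required), `--seed N`, `--codes X,XYR`,
#' `--modes unsupervised,semi_supervised`, `--epochs N`,
#' `--checkpoints 5,10,30,60`, `--quick` (reduced budget).
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 success, 2 usage error).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: motionbandit <generate|train|evaluate|bandit|ga|all>",
    "--out DIR [--seed N] [--codes X,XYR] [--modes u,ss] [--epochs N]",
    "[--checkpoints 5,10,30,60] [--quick]")
  if (length(argv) < 1L ||
      !argv[1L] %in% c("generate", "train", "evaluate", "bandit", "ga",
                       "all")) {
    message(usage)
    return(2L)
  }
  cmd <- argv[1L]
  opts <- list(out = NULL, seed = 1L, codes = "XYR",
               modes = c("unsupervised", "semi_supervised"),
               epochs = 60L, checkpoints = c(5L, 10L, 30L, 60L),
               quick = FALSE)
  i <- 2L
  while (i <= length(argv)) {
    a <- argv[i]
    take <- function() {
      if (i + 1L > length(argv)) stop_bad("flag %s needs a value", a)
      argv[i + 1L]
    }
    switch(a,
      "--out" = { opts$out <- take(); i <- i + 2L },
      "--seed" = { opts$seed <- as.integer(take()); i <- i + 2L },
      "--codes" = { opts$codes <- toupper(strsplit(take(), ",")[[1L]])
                    i <- i + 2L },
      "--modes" = {
        m <- strsplit(take(), ",")[[1L]]
        m[m %in% c("u", "uaae")] <- "unsupervised"
        m[m %in% c("ss", "ssaae")] <- "semi_supervised"
        opts$modes <- m; i <- i + 2L
      },
      "--epochs" = { opts$epochs <- as.integer(take()); i <- i + 2L },
      "--checkpoints" = {
        opts$checkpoints <- as.integer(strsplit(take(), ",")[[1L]])
        i <- i + 2L
      },
      "--quick" = { opts$quick <- TRUE; i <- i + 1L },
      { message(sprintf("unknown flag: %s", a)); message(usage)
        return(2L) })
  }
  if (is.null(opts$out)) {
    message(usage)
    return(2L)
  }
  if (opts$quick) opts$epochs <- min(opts$epochs, 15L)
  stages <- if (cmd == "all") {
    c("generate", "train", "evaluate", "bandit")
  } else cmd
  status <- tryCatch({
    run_pipeline(opts$out, stages = stages, codes = opts$codes,
                 modes = opts$modes, seed = opts$seed,
                 epochs = opts$epochs, checkpoints = opts$checkpoints)
    0L
  }, error = function(e) {
    message(sprintf("error: %s", conditionMessage(e)))
    1L
  })
  status
}
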