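Package: motionbandit
Title: Latent-Space Embedding of Hand Motions and Non-Stationary Bandits
    for Dynamic Difficulty Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for motion-based dynamic difficulty adjustment in
    rehabilitation games.  Generates synthetic 2-D hand-motion trajectories
    for six reference shapes, builds artificial motion databases by scheduled
    stretch/rotation augmentation with noise replication, embeds motions into
    a two-dimensional latent space with an adversarial autoencoder trained
    against a polar-rose Gaussian mixture prior (unsupervised or
    semi-supervised), evaluates embeddings by per-cluster Gaussian
    Kullback-Leibler divergence and k-nearest-neighbour accuracy, converts
    latent distances to per-movement reward sequences, and runs five
    non-stationary multi-armed-bandit agents (Boltzmann, Boltzmann UCB,
    Sibling Kalman filter, Kalman IUCB, Kalman Thompson sampling) scored by a
    cumulative weighted-probability error.  Includes a genetic-algorithm
    hyperparameter search and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
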