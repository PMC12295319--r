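# Shared fixtures, all generated in code. Expensive objects are cached per
# test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small separable 3-class synthetic dataset at 32 px.
small_synth <- function(n_per = 10L, seed = 77L) {
  cached(paste0("synth_", n_per, "_", seed), function() {
    generate_dataset(default_texture_specs(), rep(n_per, 3L),
                     seed = seed, size = 32L)
  })
}

# Quick desk-scale training configuration.
quick_config <- function(epochs = 5L, lr = 3e-3, seed = 1L,
                         patience = max(2L, epochs - 1L)) {
  training_config(learning_rate = lr, max_epochs = epochs, batch_size = 16L,
                  patience = patience, unfrozen_top_layers = 2L, seed = seed)
}

# Random probability vector on the c-simplex.
random_simplex <- function(c_) {
  v <- stats::rexp(c_)
  v / sum(v)
}

# Oracle-vs-noise branch outputs for the fusion-gate recovery scenario:
# branch a is a sharp, mostly correct classifier; branch b is uninformative.
oracle_noise_case <- function(n = 200L, c_ = 3L, d = 8L, seed = 1L,
                              oracle_error = 0.05) {
  set.seed(seed)
  labels <- sample(seq_len(c_) - 1L, n, replace = TRUE)
  oracle <- t(vapply(seq_len(n), function(i) {
    p <- rep(0.1 / (c_ - 1L), c_)
    p[labels[i] + 1L] <- 0.9
    p <- p / sum(p)
    if (stats::runif(1) < oracle_error) p <- sample(p)
    p
  }, numeric(c_)))
  noise <- t(vapply(seq_len(n), function(i) random_simplex(c_), numeric(c_)))
  list(labels = labels, oracle = oracle, noise = noise,
       pooled_a = matrix(stats::rnorm(n * d), n, d),
       pooled_b = matrix(stats::rnorm(n * d), n, d))
}

# Planted-signal fixture: a shared background texture; class 1 carries a
# dark-nuclei disc covering 10% of the image.
planted_fixture <- function(n_per = 30L, size = 32L, seed = 21L) {
  cached(paste0("planted_", n_per, "_", size, "_", seed), function() {
    bg <- default_texture_specs("stroma")[[1]]
    sig <- planted_signal(size, area_fraction = 0.1, amplitude = 0.9)
    imgs <- list()
    labels <- integer()
    for (j in seq_len(n_per)) {
      imgs[[length(imgs) + 1L]] <- generate_patch(bg, seed, size, item = j)
      labels <- c(labels, 0L)
      base <- generate_patch(bg, seed + 1L, size, item = j)
      imgs[[length(imgs) + 1L]] <- plant_signal(base, sig, seed = j)$image
      labels <- c(labels, 1L)
    }
    list(dataset = patch_dataset(imgs, labels, c("background", "lesion")),
         signal = sig)
  })
}
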