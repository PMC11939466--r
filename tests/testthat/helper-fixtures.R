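# Shared fixtures, all generated in code.  Expensive objects are built once
# per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

random_rgb <- function(h, w, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3L))
}

# a patch whose pixel values encode their own grid position, handy for
# checking geometric reindexing exactly
indexed_patch <- function(h = 4, w = 5) {
  array(seq_len(h * w * 3) / (h * w * 3), dim = c(h, w, 3L))
}

# small synthetic study: 256-px slides, 48-px patches, two-block network
tiny_synth_config <- function(seed = 11, n_images = 8) {
  synthetic_config(image_size = 256L, patch_size = 48L, n_images = n_images,
                   seed = seed)
}

tiny_arch <- function(color_space = "YCbCr", ...) {
  arch_config(blocks = lapply(c(8L, 16L), conv_block_config),
              global_pool = "GAP", hidden_width = 32L, input_side = 48L,
              color_space = color_space, ...)
}

tiny_library <- function() {
  fixture("tiny_library", function() {
    lib <- generate_library(tiny_synth_config())
    augment_minority(lib)
  })
}

# one small trained model shared by tests that need any trained network
tiny_trained_model <- function() {
  fixture("tiny_trained", function() {
    lib <- tiny_library()
    m <- build_network(tiny_arch(), seed = 5)
    train_network(m, lib$train,
                  training_config(epochs = 3, seed = 5,
                                  early_stop_acc = 0.995))
  })
}

# a signature tibble with given per-label counts and trivially small patches
dummy_signatures <- function(counts, patch_side = 4, image_id = "img1") {
  labels <- rep(names(counts), counts)
  tibble::tibble(
    image_id = image_id,
    origin_row = 1L, origin_col = 1L,
    label = factor(labels, levels = oed_classes()),
    augmentation = NA_character_,
    patch = lapply(seq_along(labels), function(i) {
      array(runif(patch_side^2 * 3), dim = c(patch_side, patch_side, 3L))
    })
  )
}

# ground-truth oracle scorer for sliding-window evaluation: scores each
# window by the coverage fraction of each class mask (others = remainder)
oracle_scorer <- function(slides) {
  function(patches) {
    image <- attr(patches, "image")
    origins <- attr(patches, "origins")
    win <- attr(patches, "window")
    sums <- vapply(slides, function(sl) sum(sl$image), 0)
    sl <- slides[[which.min(abs(sums - sum(image)))]]
    t(vapply(seq_along(patches), function(k) {
      r <- origins[k, 1]; c <- origins[k, 2]
      cov <- vapply(oed_classes()[2:3], function(cl) {
        m <- sl$masks[[cl]]
        if (is.null(m)) 0 else mean(m[r:(r + win - 1L), c:(c + win - 1L)])
      }, 0)
      p <- c(max(0, 1 - sum(cov)), cov)
      p / sum(p)
    }, numeric(3)))
  }
}
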