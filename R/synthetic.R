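# Synthetic H&E-like slides with per-class ground-truth masks.  The
# generator targets statistical structure, not biological realism: an
# eosin-pink background carrying ordered rows ("strata") of
# hematoxylin-purple nucleus dots; irregular-stratification regions where
# the dots are jittered and crowded; and teardrop-shaped purple blobs
# (broad base, narrow top) standing in for bulbous rete ridges.

#' Synthetic-slide generator configuration
#'
#' @param image_size slide side in pixels (default 384).
#' @param n_images number of slides a library draws from (default 20).
#' @param seed master seed; the full output is reproducible byte-for-byte.
#' @param palette list with RGB triplets in `[0, 1]`: `background`
#'   (eosin pink) and `nucleus` (hematoxylin purple).
#' @param n_ridges integer range (length-2) or single count of bulbous
#'   blobs per slide.
#' @param stratification_disorder positional jitter of nucleus dots inside
#'   the irregular region, as a fraction of the dot spacing, in `[0, 1]`
#'   (default 0.8).
#' @param crowding extra dot density inside the irregular region, as a
#'   fraction of the baseline (default 0.5).
#' @param noise_sd Gaussian pixel-noise standard deviation (default 0.03).
#' @param patch_size signature side for library building (default 96;
#'   350 reproduces the full-scale geometry).
#' @param stride extraction stride (default `patch_size / 2`).
#' @param dot_spacing lattice spacing of nucleus dots (default 10).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(image_size = 384L, n_images = 20L, seed = 1L,
                             palette = list(background = c(0.91, 0.73, 0.80),
                                            nucleus = c(0.36, 0.20, 0.50)),
                             n_ridges = c(1L, 3L),
                             stratification_disorder = 0.8,
                             crowding = 0.5,
                             noise_sd = 0.03,
                             patch_size = 96L,
                             stride = NULL,
                             dot_spacing = 10L) {
  if (length(n_ridges) == 1L) n_ridges <- rep(n_ridges, 2L)
  stopifnot(image_size >= patch_size, n_images >= 1,
            stratification_disorder >= 0, stratification_disorder <= 1,
            noise_sd >= 0, n_ridges[1] >= 0, n_ridges[2] >= n_ridges[1])
  if (is.null(stride)) stride <- max(1L, patch_size %/% 2L)
  structure(list(image_size = as.integer(image_size),
                 n_images = as.integer(n_images), seed = as.integer(seed),
                 palette = palette, n_ridges = as.integer(n_ridges),
                 stratification_disorder = stratification_disorder,
                 crowding = crowding, noise_sd = noise_sd,
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 dot_spacing = as.integer(dot_spacing)),
            class = "synthetic_config")
}

# paint filled discs of `radius` at (rows, cols) with colour `col`
paint_dots <- function(img, rows, cols, radius, col) {
  if (!length(rows)) return(img)
  s <- dim(img)[1]
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  pr <- rep(round(rows), each = nrow(off)) + off$dr
  pc <- rep(round(cols), each = nrow(off)) + off$dc
  ok <- pr >= 1 & pr <= s & pc >= 1 & pc <= dim(img)[2]
  pr <- pr[ok]; pc <- pc[ok]
  for (ch in 1:3) img[cbind(pr, pc, ch)] <- col[ch]
  img
}

teardrop_mask <- function(s, center_col, base_row, height, base_width) {
  # broad base at `base_row`, tapering to a narrow top `height` rows above
  mask <- matrix(FALSE, s, s)
  rows <- seq.int(max(1L, base_row - height + 1L), min(s, base_row))
  t <- (base_row - rows) / height                   # 0 at base -> 1 at top
  hw <- (base_width / 2) * cos(pi * t / 2)^0.7
  for (k in seq_along(rows)) {
    c0 <- max(1L, ceiling(center_col - hw[k]))
    c1 <- min(s, floor(center_col + hw[k]))
    if (c0 <= c1) mask[rows[k], c0:c1] <- TRUE
  }
  mask
}

#' Generate one synthetic slide with ground-truth masks
#'
#' The background is a layered stipple: rows of nucleus dots on a regular
#' lattice over an eosin-pink field.  One rectangular
#' irregular-stratification region re-draws its dots with positional
#' jitter scaled by `stratification_disorder` plus extra crowding; bulbous
#' rete ridges are filled teardrop blobs (broad base, narrow top) in the
#' hematoxylin hue, placed disjoint from the stratification region and
#' from each other.  Gaussian pixel noise is added last.  The two
#' ground-truth masks are binary and class-disjoint.
#'
#' @param config a [synthetic_config()].
#' @param index slide index; `(seed, index)` determines the slide.
#' @return a list: `image` (RGB array), `masks` (named list of logical
#'   matrices for `irregular_stratification` and `bulbous_rete_ridge`),
#'   `image_id`.
#' @export
generate_slide <- function(config = synthetic_config(), index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  s <- config$image_size
  sp <- config$dot_spacing
  pal <- config$palette
  slide_seed <- ((as.numeric(config$seed) * 10007) %% 2147482) * 1000 + index
  with_local_seed(slide_seed, {
    img <- array(rep(pal$background, each = s * s), dim = c(s, s, 3L))

    # irregular-stratification rectangle, kept in the upper part of the
    # slide so the rete ridges can hang below it (as they do in tissue)
    bh <- round(config$patch_size * runif(1, 1.05, 1.3))
    bw <- round(s * runif(1, 0.55, 0.8))
    bh <- min(bh, s - 2L); bw <- min(bw, s - 2L)
    r0_max <- max(1L, min(s - bh, round(0.12 * s)))
    br0 <- sample.int(r0_max, 1L)
    bc0 <- sample.int(s - bw, 1L)
    strat <- matrix(FALSE, s, s)
    strat[br0:(br0 + bh - 1L), bc0:(bc0 + bw - 1L)] <- TRUE

    # ordered lattice of dots (brick offset on alternate rows)
    ys <- seq(sp %/% 2, s, by = sp)
    xs <- seq(sp %/% 2, s, by = sp)
    grid <- expand.grid(r = ys, c = xs)
    grid$c <- grid$c + ifelse((match(grid$r, ys) %% 2L) == 0L, sp %/% 2L, 0L)
    grid$r <- grid$r + runif(nrow(grid), -0.05, 0.05) * sp
    grid$c <- grid$c + runif(nrow(grid), -0.05, 0.05) * sp
    inside <- strat[cbind(pmin(pmax(round(grid$r), 1L), s),
                          pmin(pmax(round(grid$c), 1L), s))]
    jit <- config$stratification_disorder * sp
    grid$r[inside] <- grid$r[inside] + runif(sum(inside), -jit, jit)
    grid$c[inside] <- grid$c[inside] + runif(sum(inside), -jit, jit)
    img <- paint_dots(img, grid$r, grid$c, radius = 2L, col = pal$nucleus)
    # crowding: extra dots uniformly inside the irregular region
    n_extra <- round(config$crowding * bh * bw / sp^2)
    if (n_extra > 0) {
      img <- paint_dots(img,
                        runif(n_extra, br0, br0 + bh - 1L),
                        runif(n_extra, bc0, bc0 + bw - 1L),
                        radius = 2L, col = pal$nucleus)
    }

    # bulbous blobs, disjoint from the stratification region and each other
    n_blobs <- if (config$n_ridges[1] == config$n_ridges[2]) {
      config$n_ridges[1]
    } else {
      sample(config$n_ridges[1]:config$n_ridges[2], 1L)
    }
    bulb <- matrix(FALSE, s, s)
    if (n_blobs > 0L) {
      # one horizontal slot per blob below the stratification band; this
      # layout always fits when the slide leaves enough room
      top_free <- br0 + bh + 5L                      # first usable row
      max_h <- round(config$patch_size * 1.4)
      min_h <- round(config$patch_size * 1.1)
      if (top_free + min_h + 6L >= s) {
        abort(sprintf("bulbous regions cannot fit below the stratification band on a %d-pixel slide; enlarge `image_size`",
                      s))
      }
      slot_w <- (s - 4L) %/% n_blobs
      min_w <- round(config$patch_size * 0.95)
      if (slot_w - 6L < min_w) {
        abort(sprintf("%d bulbous regions cannot fit side by side on a %d-pixel slide; enlarge `image_size` or lower `n_ridges`",
                      n_blobs, s))
      }
      for (b in seq_len(n_blobs)) {
        height <- min(round(config$patch_size * runif(1, 1.1, 1.4)),
                      s - top_free - 6L)
        width <- round(min(config$patch_size * runif(1, 0.95, 1.2),
                           slot_w - 6L))
        slot_lo <- 2L + (b - 1L) * slot_w
        c_lo <- slot_lo + ceiling(width / 2) + 1L
        c_hi <- slot_lo + slot_w - ceiling(width / 2) - 2L
        center_col <- if (c_hi > c_lo) sample(seq.int(c_lo, c_hi), 1L) else c_lo
        b_lo <- top_free + height
        b_hi <- s - 3L
        base_row <- if (b_hi > b_lo) sample(seq.int(b_lo, b_hi), 1L) else b_lo
        cand <- teardrop_mask(s, center_col, base_row, height, width)
        bulb <- bulb | cand
        dark <- pal$nucleus * 0.85
        idx <- which(cand)
        ri <- (idx - 1L) %% s + 1L; cj <- (idx - 1L) %/% s + 1L
        for (ch in 1:3) img[cbind(ri, cj, ch)] <- dark[ch]
        # internal chromatin speckle so the blob is textured, not flat
        n_spk <- max(1L, length(idx) %/% 40L)
        spk <- sample(length(idx), n_spk)
        for (ch in 1:3) {
          img[cbind(ri[spk], cj[spk], ch)] <- pmin(1, pal$nucleus[ch] * 1.5)
        }
      }
    }

    if (config$noise_sd > 0) {
      img <- img + array(rnorm(length(img), sd = config$noise_sd), dim = dim(img))
      img <- pmin(pmax(img, 0), 1)
    }
    list(image = img,
         masks = list(irregular_stratification = strat,
                      bulbous_rete_ridge = bulb),
         image_id = sprintf("synthetic_%03d", index))
  })
}

#' Generate a synthetic signature library
#'
#' Draws `n_images` slides, extracts labelled signatures from each
#' ([extract_signatures()] with the config's patch size, stride and a 0.5
#' coverage threshold) and splits them 80/20 into train and test by slide,
#' so the two sets share no source image.
#'
#' Grid cells whose largest feature coverage is ambiguous (at least
#' `ambiguous_low` but below `positive_fraction`) are excluded: a patch
#' half-filled by a blob is neither clean background nor a clean feature
#' example, and keeping such label noise out of the library is the usual
#' practice when patch libraries are curated.
#'
#' @param config a [synthetic_config()].
#' @param positive_fraction coverage threshold for patch labelling.
#' @param ambiguous_low lower edge of the excluded coverage band
#'   (default 0.2); set equal to `positive_fraction` to keep every cell.
#' @return a `signature_library`; also carries the generated slides in the
#'   `slides` attribute for downstream blind-set evaluation.
#' @export
generate_library <- function(config = synthetic_config(),
                             positive_fraction = 0.5,
                             ambiguous_low = 0.2) {
  slides <- lapply(seq_len(config$n_images), function(i) {
    generate_slide(config, index = i)
  })
  sigs <- purrr::map(slides, function(sl) {
    anns <- purrr::imap(sl$masks, function(m, cl) {
      if (!any(m)) return(NULL)
      list(feature_class = cl, mask = m)
    })
    extract_signatures(sl$image, purrr::compact(anns), image_id = sl$image_id,
                       patch_size = config$patch_size, stride = config$stride,
                       positive_fraction = positive_fraction,
                       ambiguous_band = c(ambiguous_low, positive_fraction))
  })
  n_test <- max(1L, round(0.2 * config$n_images))
  test_idx <- seq.int(config$n_images - n_test + 1L, config$n_images)
  train <- dplyr::bind_rows(sigs[-test_idx])
  test <- dplyr::bind_rows(sigs[test_idx])
  if (any(table(train$label) == 0L)) {
    abort(paste("a class is absent from the generated training signatures;",
                "increase `n_images`, lower `positive_fraction` or enlarge regions"))
  }
  lib <- signature_library(train, test)
  attr(lib, "slides") <- slides
  lib
}

#' Write synthetic slides and masks to disk
#'
#' Slides go to `<out_dir>/<id>.png` and the per-class masks to
#' `<out_dir>/<id>.<class>.png`, the annotation naming convention the
#' library builder reads back.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return tibble of written paths, invisibly.
#' @export
write_synthetic_slides <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(seq_len(config$n_images), function(i) {
    sl <- generate_slide(config, index = i)
    p_img <- file.path(out_dir, paste0(sl$image_id, ".png"))
    write_image_png(sl$image, p_img)
    p_masks <- purrr::imap_chr(sl$masks, function(m, cl) {
      p <- file.path(out_dir, sprintf("%s.%s.png", sl$image_id, cl))
      write_mask(m, p)
      p
    })
    tibble(image_id = sl$image_id, image = p_img,
           masks = list(p_masks))
  })
  invisible(dplyr::bind_rows(rows))
}
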