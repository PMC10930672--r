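#' Steatosis grade from fat-area fraction
#'
#' Standard semi-quantitative staging of steatosis by the fraction of
#' tissue area occupied by fat: below 5 percent is grade 0, 5-33 grade 1,
#' 33-66 grade 2, above 66 grade 3. Shared boundaries are resolved with a
#' half-open convention, closed on the left of each upper grade:
#' `[0, 0.05) -> 0`, `[0.05, 0.33) -> 1`, `[0.33, 0.66) -> 2`,
#' `[0.66, 1] -> 3`.
#'
#' @param fraction Numeric vector of fat-area fractions in `[0, 1]`.
#' @return Integer grades 0-3.
#' @examples
#' grade_from_fat_fraction(c(0.04, 0.20, 0.50, 0.70))
#' @export
grade_from_fat_fraction <- function(fraction) {
  fraction <- as.numeric(fraction)
  if (any(is.na(fraction)) || any(fraction < 0 | fraction > 1)) {
    stop("fat fraction must be in [0, 1]")
  }
  findInterval(fraction, c(0.05, 0.33, 0.66))
}

#' Binary transplant-suitability label from steatosis grade
#'
#' Grades 0 and 1 mark livers suitable for transplantation, grades 2 and 3
#' not suitable.
#'
#' @param grade Integer vector of grades in `{0, 1, 2, 3}`.
#' @return Character vector `"suitable"` / `"not_suitable"`.
#' @export
binarize_grade <- function(grade) {
  grade <- as.integer(grade)
  if (any(is.na(grade)) || any(!grade %in% 0:3)) {
    stop("grade must be one of 0, 1, 2, 3")
  }
  ifelse(grade <= 1L, "suitable", "not_suitable")
}

#' Cut a slide image into non-overlapping square tiles
#'
#' Row-major grid; partial tiles at the right/bottom edges are discarded.
#' Each tile records its (row, col) grid position so a prediction heatmap
#' can be reassembled later.
#'
#' @param image RGB array `(H, W, 3)`.
#' @param tile_px Tile side in pixels (default 1024, the sample size used
#'   for grading).
#' @return List of tiles, each a list with `pixels`, `row`, `col`. An
#'   image smaller than one tile yields an empty list with a warning.
#' @export
tile_slide <- function(image, tile_px = 1024L) {
  d <- dim(image)
  tile_px <- as.integer(tile_px)
  nr <- d[1] %/% tile_px
  nc <- d[2] %/% tile_px
  if (nr == 0L || nc == 0L) {
    warning("image (", d[1], "x", d[2], ") smaller than one ", tile_px,
            "px tile; returning no tiles")
    return(list())
  }
  tiles <- vector("list", nr * nc)
  k <- 1L
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      tiles[[k]] <- list(
        pixels = image[((r - 1L) * tile_px + 1L):(r * tile_px),
                       ((cl - 1L) * tile_px + 1L):(cl * tile_px), ,
                       drop = FALSE],
        row = r, col = cl)
      k <- k + 1L
    }
  }
  tiles
}

#' Center-crop a tile
#'
#' @param tile RGB array `(H, W, 3)` or a graded tile list with a `pixels`
#'   field; metadata fields are carried over unchanged.
#' @param out_px Output side in pixels (default 258, the training input
#'   size).
#' @return The cropped tile in the same form as the input.
#' @export
center_crop <- function(tile, out_px = 258L) {
  out_px <- as.integer(out_px)
  px <- if (is.list(tile)) tile$pixels else tile
  d <- dim(px)
  if (out_px < 1L || out_px > min(d[1], d[2])) {
    stop("out_px must be between 1 and the tile side (", min(d[1], d[2]), ")")
  }
  r0 <- (d[1] - out_px) %/% 2L
  c0 <- (d[2] - out_px) %/% 2L
  cropped <- px[(r0 + 1L):(r0 + out_px), (c0 + 1L):(c0 + out_px), ,
                drop = FALSE]
  if (is.list(tile)) {
    tile$pixels <- cropped
    tile
  } else {
    cropped
  }
}

#' Generative recipe for one synthetic steatosis tile
#'
#' The generator emulates a hematoxylin-eosin-stained parenchyma patch:
#' a smooth pink background, white rounded fat droplets whose total pixel
#' fraction is driven to the requested target, and optional irregular
#' elongated white shapes standing in for vessels and tissue artifacts.
#' Only the geometric cue that pathologists use - size and rounded shape -
#' separates droplets from confounders; no histological realism beyond
#' that is claimed.
#'
#' @param side_px Tile side in pixels.
#' @param target_fat_fraction Requested droplet area fraction in `[0, 1]`.
#' @param droplet_radius_range Droplet radius range in pixels; default
#'   scales with the tile side (2 to 5.5 percent of the side, floor 1.5 px).
#' @param n_confounders Number of vessel/artifact shapes.
#' @param seed Integer seed; the emitted tile is a pure function of the
#'   spec.
#' @return A `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(side_px = 258L, target_fat_fraction = 0.2,
                                 droplet_radius_range = NULL,
                                 n_confounders = 0L, seed = 1L) {
  side_px <- as.integer(side_px)
  if (side_px < 8L) stop("side_px must be at least 8")
  if (target_fat_fraction < 0 || target_fat_fraction > 1) {
    stop("target_fat_fraction must be in [0, 1]")
  }
  if (is.null(droplet_radius_range)) {
    droplet_radius_range <- pmax(c(0.02, 0.055) * side_px, 1.5)
  }
  structure(list(side_px = side_px,
                 target_fat_fraction = target_fat_fraction,
                 droplet_radius_range = droplet_radius_range,
                 n_confounders = as.integer(n_confounders),
                 seed = as.integer(seed)),
            class = "synthetic_slide_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# smooth pink field: coarse gaussian grid, bilinearly upsampled
synth_background <- function(side) {
  base <- c(0.90, 0.70, 0.77)
  coarse_n <- max(4L, side %/% 24L)
  grid <- matrix(stats::rnorm(coarse_n^2, sd = 0.035), coarse_n, coarse_n)
  # bilinear interpolation onto side x side
  pos <- seq(1, coarse_n, length.out = side)
  i0 <- pmin(floor(pos), coarse_n - 1L)
  fr <- pos - i0
  up <- grid[i0, ] * (1 - fr) + grid[i0 + 1L, ] * fr
  up <- up[, i0] * rep(1 - fr, each = side) + up[, i0 + 1L] * rep(fr, each = side)
  img <- array(0, c(side, side, 3))
  for (ch in 1:3) {
    img[, , ch] <- pmin(pmax(base[ch] + up +
                               stats::rnorm(side^2, sd = 0.012), 0.35), 0.86)
  }
  img
}

# rasterize one rounded ellipse; returns a logical mask of side x side
raster_ellipse <- function(side, cx, cy, a, b, phi, wobble = 0) {
  rmax <- max(a, b) * (1 + abs(wobble))
  xs <- max(1L, floor(cx - rmax)):min(side, ceiling(cx + rmax))
  ys <- max(1L, floor(cy - rmax)):min(side, ceiling(cy + rmax))
  if (length(xs) == 0L || length(ys) == 0L) {
    return(NULL)
  }
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  rr <- u^2 + v^2
  if (wobble > 0) {
    ang <- atan2(v, u)
    lim <- (1 + wobble * sin(3 * ang + phi) + wobble * 0.6 * sin(5 * ang))^2
  } else {
    lim <- 1
  }
  list(xs = xs, ys = ys, inside = rr <= lim)
}

#' Synthesize one ground-truthed steatosis tile
#'
#' Droplets are added one at a time until the realized white-droplet pixel
#' fraction reaches the target; the recorded `fat_fraction` is the realized
#' mask fraction (confounder pixels are excluded), so the grade and label
#' are exact by construction. The tile is deterministic given the spec.
#'
#' @param spec A [synthetic_slide_spec()].
#' @return A `graded_tile`: list with `pixels` (RGB array in `[0,1]`),
#'   `fat_fraction`, `grade`, `label`, `provenance = "synthetic"` and
#'   `seed`.
#' @export
synthesize_tile <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  with_seed(spec$seed, synthesize_tile_impl(spec))
}

synthesize_tile_impl <- function(spec) {
  side <- spec$side_px
  img <- synth_background(side)
  total <- side * side

  # confounders first (drawn under droplets, excluded from the fraction)
  confounder_mask <- matrix(FALSE, side, side)
  for (i in seq_len(spec$n_confounders)) {
    major <- stats::runif(1, 0.08, 0.18) * side
    minor <- major * stats::runif(1, 0.15, 0.35)
    e <- raster_ellipse(side, stats::runif(1, 1, side),
                        stats::runif(1, 1, side), major, minor,
                        stats::runif(1, 0, pi), wobble = 0.3)
    if (!is.null(e)) {
      sub <- confounder_mask[e$xs, e$ys]
      sub[e$inside] <- TRUE
      confounder_mask[e$xs, e$ys] <- sub
    }
  }

  droplet_mask <- matrix(FALSE, side, side)
  target <- spec$target_fat_fraction
  rr <- spec$droplet_radius_range
  budget <- 200L + ceiling(20 * target * total / (pi * mean(rr)^2))
  n_drops <- 0L
  while (sum(droplet_mask) / total < target && n_drops < budget) {
    r <- stats::runif(1, rr[1], rr[2])
    # near the target, shrink the next droplet towards the remaining
    # deficit so the overshoot stays within the fraction tolerance
    remaining <- target * total - sum(droplet_mask)
    r <- min(r, max(sqrt(remaining / pi) * 1.25, 1.0))
    ratio <- stats::runif(1, 0.9, 1.0) # rounded: circularity stays > 0.9
    e <- raster_ellipse(side, stats::runif(1, 1, side),
                        stats::runif(1, 1, side), r, r * ratio,
                        stats::runif(1, 0, pi))
    if (!is.null(e)) {
      sub <- droplet_mask[e$xs, e$ys]
      sub[e$inside] <- TRUE
      droplet_mask[e$xs, e$ys] <- sub
    }
    n_drops <- n_drops + 1L
  }
  realized <- sum(droplet_mask) / total
  if (abs(realized - target) > 0.03) {
    stop("could not realize target fat fraction ",
         format(target), " (got ", format(round(realized, 4)),
         ") for spec with seed ", spec$seed, ", side ", side, "px")
  }

  white <- confounder_mask | droplet_mask
  n_white <- sum(white)
  if (n_white > 0) {
    shade <- 0.97 + stats::runif(n_white, 0, 0.03)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[white] <- shade
      img[, , ch] <- plane
    }
  }

  grade <- grade_from_fat_fraction(realized)
  structure(list(pixels = img, fat_fraction = realized, grade = grade,
                 label = binarize_grade(grade), provenance = "synthetic",
                 seed = spec$seed),
            class = "graded_tile")
}

#' @export
print.graded_tile <- function(x, ...) {
  cat("<graded_tile> ", dim(x$pixels)[1], "px, fat fraction ",
      round(x$fat_fraction, 4), ", grade ", x$grade, " (", x$label, ")\n",
      sep = "")
  invisible(x)
}

grade_target_interval <- function(grade) {
  # 0.01 margin away from the shared staging boundaries so that the
  # realized fraction (within +- droplet granularity) keeps the grade
  switch(as.character(grade),
         "0" = c(0.00, 0.04),
         "1" = c(0.06, 0.32),
         "2" = c(0.34, 0.65),
         "3" = c(0.67, 0.96))
}

#' Build a balanced graded dataset of synthetic tiles
#'
#' Emits `n_per_grade` tiles per steatosis grade (targets drawn uniformly
#' inside each grade's staging interval, 0.01 away from shared
#' boundaries), so the two binary suitability classes are balanced by
#' construction. With `dir` given, tiles are written as PNG files plus a
#' `manifest.csv`; with `render = FALSE` only the manifest is produced
#' (fat_fraction then records the target).
#'
#' @param n_per_grade Tiles per grade (the full-scale reference dataset
#'   uses 1100, i.e. 4400 tiles).
#' @param side_px Tile side in pixels.
#' @param n_confounders Confounders per tile (single value or range).
#' @param seed Base seed; tile i uses a seed derived from it.
#' @param dir Output directory for PNGs + manifest (created if needed).
#' @param render If `FALSE`, skip image synthesis and emit the manifest
#'   only.
#' @param n_patients Number of synthetic patients the tiles are attributed
#'   to (default about one per 100 tiles, mirroring the scale of a real
#'   slide archive).
#' @return The manifest data frame (columns path, fat_fraction, grade,
#'   label, patient_id, seed).
#' @export
build_balanced_dataset <- function(n_per_grade, side_px = 64L,
                                   n_confounders = c(0L, 2L), seed = 1L,
                                   dir = NULL, render = !is.null(dir),
                                   n_patients = NULL) {
  n_per_grade <- as.integer(n_per_grade)
  if (n_per_grade < 1L) stop("n_per_grade must be >= 1")
  total <- 4L * n_per_grade
  if (is.null(n_patients)) n_patients <- max(1L, ceiling(total / 100L))
  grades <- rep(0:3, each = n_per_grade)
  set.seed(as.integer(seed))
  targets <- vapply(grades, function(g) {
    iv <- grade_target_interval(g)
    stats::runif(1, iv[1], iv[2])
  }, numeric(1))
  conf_vals <- seq(min(n_confounders), max(n_confounders))
  nconf <- conf_vals[sample.int(length(conf_vals), total, replace = TRUE)]
  seeds <- vapply(seq_len(total), function(i) epoch_seed(seed, 100L + i),
                  integer(1))
  patient <- sprintf("synthetic_patient_%03d",
                     ((seq_len(total) - 1L) %% n_patients) + 1L)
  rows <- data.frame(
    path = NA_character_,
    fat_fraction = targets,
    target_fat_fraction = targets,
    n_confounders = nconf,
    grade = grades,
    label = binarize_grade(grades),
    patient_id = patient,
    seed = seeds,
    stringsAsFactors = FALSE)
  if (render) {
    if (!is.null(dir) && !dir.exists(dir)) {
      dir.create(dir, recursive = TRUE)
    }
    for (i in seq_len(total)) {
      spec <- synthetic_slide_spec(side_px, targets[i],
                                   n_confounders = nconf[i],
                                   seed = seeds[i])
      tl <- synthesize_tile(spec)
      rows$fat_fraction[i] <- tl$fat_fraction
      rows$grade[i] <- tl$grade
      rows$label[i] <- tl$label
      if (!is.null(dir)) {
        rows$path[i] <- file.path(dir, sprintf("tile_%05d.png", i))
        write_tile_png(tl$pixels, rows$path[i])
      }
    }
  }
  if (!is.null(dir)) {
    write_manifest(rows, file.path(dir, "manifest.csv"))
  }
  rows
}

#' In-memory balanced synthetic dataset
#'
#' Convenience wrapper used throughout the test suite: generates a
#' grade-balanced set of tiles directly into a [tile_dataset()] without
#' touching the filesystem.
#'
#' @inheritParams build_balanced_dataset
#' @return A [tile_dataset()] with a metadata frame holding fat_fraction,
#'   grade and patient_id.
#' @export
synth_dataset <- function(n_per_grade, side_px = 32L,
                          n_confounders = c(0L, 2L), seed = 1L) {
  manifest <- build_balanced_dataset(n_per_grade, side_px, n_confounders,
                                     seed, dir = NULL, render = FALSE)
  total <- nrow(manifest)
  images <- array(0, c(total, side_px, side_px, 3))
  for (i in seq_len(total)) {
    spec <- synthetic_slide_spec(side_px, manifest$target_fat_fraction[i],
                                 n_confounders = manifest$n_confounders[i],
                                 seed = manifest$seed[i])
    tl <- synthesize_tile(spec)
    images[i, , , ] <- tl$pixels
    manifest$fat_fraction[i] <- tl$fat_fraction
    manifest$grade[i] <- tl$grade
    manifest$label[i] <- tl$label
  }
  tile_dataset(images, manifest$label, meta = manifest)
}

#' Read and write dataset manifests
#'
#' CSV with header, columns path, fat_fraction, grade, label, patient_id,
#' seed. Duplicate paths and grades outside 0-3 are rejected.
#'
#' @param manifest Manifest data frame.
#' @param path CSV file path.
#' @return `read_manifest()` returns the validated data frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  need <- c("path", "fat_fraction", "grade", "label")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("manifest lacks columns: ", paste(missing, collapse = ", "))
  }
  real_paths <- m$path[!is.na(m$path)]
  if (anyDuplicated(real_paths)) stop("manifest contains duplicate paths")
  if (any(!m$grade %in% 0:3)) stop("manifest grades must be in 0..3")
  invisible(m)
}

#' Load a tile dataset from a manifest of PNG files
#'
#' @param manifest Manifest data frame or path to a manifest CSV.
#' @return A [tile_dataset()] with the manifest as metadata.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (any(is.na(manifest$path))) {
    stop("manifest has unrendered rows (path = NA); ",
         "build the dataset with render = TRUE")
  }
  first <- read_tile_png(manifest$path[1])
  px <- dim(first)[1]
  n <- nrow(manifest)
  images <- array(0, c(n, px, px, 3))
  images[1, , , ] <- first
  for (i in seq_len(n)[-1]) {
    images[i, , , ] <- read_tile_png(manifest$path[i])
  }
  tile_dataset(images, manifest$label, meta = manifest)
}

#' PNG tile input/output
#'
#' @param pixels RGB array `(H, W, 3)` in `[0, 1]`.
#' @param path File path.
#' @return `read_tile_png()` returns the `(H, W, 3)` array.
#' @export
write_tile_png <- function(pixels, path) {
  png::writePNG(pixels, path)
  invisible(path)
}

#' @rdname write_tile_png
#' @export
read_tile_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
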