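#' @include AllClasses.R dataset.R
NULL

fundusClassNames <- function() {
  c("Central_Serous_Chorioretinopathy", "Diabetic_Retinopathy", "Disc_Edema",
    "Glaucoma", "Healthy", "Macular_Scar", "Myopia", "Pterygium",
    "Retinal_Detachment", "Retinitis_Pigmentosa")
}

#' Default per-class image counts
#'
#' The four counts printed for the study dataset (Diabetic Retinopathy 1509,
#' Glaucoma 1349, Central Serous Chorioretinopathy 101, Pterygium 17); the
#' remaining six classes are approximations chosen so the ten classes total
#' 5335 images.
#'
#' @return Named integer vector over the ten classes.
#' @export
defaultClassCounts <- function() {
  c(Central_Serous_Chorioretinopathy = 101L, Diabetic_Retinopathy = 1509L,
    Disc_Edema = 396L, Glaucoma = 1349L, Healthy = 575L, Macular_Scar = 462L,
    Myopia = 399L, Pterygium = 17L, Retinal_Detachment = 289L,
    Retinitis_Pigmentosa = 238L)
}

#' Synthetic-fundus generator configuration
#'
#' @param counts Named integer vector of per-class image counts (default
#'   \code{\link{defaultClassCounts}}); every count must be at least 2 so
#'   SMOTE can interpolate.
#' @param imageSize Square image size in pixels (at least 32).
#' @param seed Integer base seed; each image derives its own seed from it.
#' @return A validated list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(counts = defaultClassCounts(), imageSize = 150L,
                            seed = 1L) {
  stopifnot(all(counts >= 2L), imageSize >= 32L,
            all(sort(names(counts)) == names(counts)))
  structure(list(counts = counts, imageSize = as.integer(imageSize),
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

gaussBlob <- function(dist2, r) exp(-dist2 / r^2)

bboxFromField <- function(field, thresh, margin, size) {
  hit <- which(field > thresh, arr.ind = TRUE)
  if (!nrow(hit)) return(c(0L, size, 0L, size))
  c(max(0L, min(hit[, 1]) - 1L - margin),
    min(size, max(hit[, 1]) + margin),
    max(0L, min(hit[, 2]) - 1L - margin),
    min(size, max(hit[, 2]) + margin))
}

#' Render one synthetic fundus image
#'
#' Draws a circular retinal field (radial brightness falloff, warm
#' coloration, smooth low-frequency texture, a small optic disc) and plants
#' the class-specific lesion program: scattered dark microlesions for
#' Diabetic Retinopathy, an enlarged pale cup for Glaucoma, a swollen bright
#' disc for Disc Edema, a central serous blister for CSC, a pale macular
#' patch for Macular Scar, a nasal wedge for Pterygium, a pale peripheral
#' fold for Retinal Detachment, peripheral pigment speckle for Retinitis
#' Pigmentosa, tessellated texture for Myopia and a clean field for Healthy.
#' The lesion programs are separability caricatures for pipeline testing, not
#' clinical renderings. The lesion bounding region (0-based, half-open pixel
#' intervals, with margin) is returned with the image; for classes without a
#' localized lesion it spans the whole field and \code{localized} is FALSE.
#'
#' @param className One of \code{fundusnet:::fundusClassNames()}.
#' @param size Image size in pixels.
#' @param seed Integer seed; identical (class, size, seed) gives bit-identical
#'   output.
#' @return List with \code{image} (size x size x 3 array in [0, 1]),
#'   \code{bbox} (y0, y1, x0, x1) and \code{localized} (logical).
#' @export
generateFundusImage <- function(className, size = 150L, seed = 1L) {
  allCls <- fundusClassNames()
  if (!className %in% allCls)
    stop("unknown class '", className, "'")
  set.seed(seed)
  S <- as.integer(size)
  jit <- function(a, b) stats::runif(1, a, b)
  cy <- S * (0.5 + jit(-0.015, 0.015))
  cx <- S * (0.5 + jit(-0.015, 0.015))
  R0 <- 0.46 * S * jit(0.95, 1.05)
  rows <- matrix(seq_len(S), S, S)
  cols <- matrix(seq_len(S), S, S, byrow = TRUE)
  d2 <- (rows - cy)^2 + (cols - cx)^2
  d <- sqrt(d2)
  fall <- pmax(0, 1 - (d / R0)^1.8)
  bright <- jit(0.9, 1.1)
  lum <- (0.30 + 0.52 * fall) * bright
  # smooth low-frequency texture
  noise <- .cpp_bilinear_resize(matrix(stats::runif(100, -1, 1), 10, 10), S, S)
  lum <- lum + 0.05 * noise
  base <- array(0, c(S, S, 3L))
  base[, , 1] <- lum * 1.00
  base[, , 2] <- lum * 0.56
  base[, , 3] <- lum * 0.28
  # optic disc (temporal side)
  ody <- cy + S * jit(-0.02, 0.02)
  odx <- cx + 0.24 * S * jit(0.9, 1.1)
  od2 <- (rows - ody)^2 + (cols - odx)^2
  odr <- 0.055 * S * jit(0.9, 1.1)
  odb <- gaussBlob(od2, odr)
  base[, , 1] <- base[, , 1] + 0.30 * odb
  base[, , 2] <- base[, , 2] + 0.28 * odb
  base[, , 3] <- base[, , 3] + 0.12 * odb
  les <- matrix(0, S, S)  # lesion saliency field, for the bounding region
  # the bounding region includes a margin of about half a deep-layer tap cell
  # (the network pools by 16x overall), since CAM peaks are quantized to that
  # grid; localization claims cannot be sharper than the tap resolution
  margin <- as.integer(round(0.12 * S))
  localized <- TRUE
  addBlob <- function(y0, x0, r, w) {
    b2 <- (rows - y0)^2 + (cols - x0)^2
    g <- gaussBlob(b2, r)
    for (ch in 1:3) base[, , ch] <<- base[, , ch] + w[ch] * g
    les <<- les + abs(max(abs(w))) * g
  }
  if (className == "Diabetic_Retinopathy") {
    nd <- 12L + sample.int(5L, 1L) - 1L
    for (i in seq_len(nd)) {
      ang <- jit(0, 2 * pi); rad <- jit(0.1, 0.62) * R0
      addBlob(cy + rad * sin(ang), cx + rad * cos(ang),
              S * jit(0.013, 0.02), c(-0.25, -0.5, -0.35))
    }
    # diffuse ischemic darkening: a consistent hue shift that separates the
    # class from a healthy field beyond the randomly placed microlesions
    base[, , 2] <- base[, , 2] * 0.88
    base[, , 3] <- base[, , 3] * 0.84
    localized <- FALSE
  } else if (className == "Glaucoma") {
    # enlarged cupped disc: bright pale neuroretinal ring around a dark cup
    rr <- 0.10 * S * jit(0.9, 1.1)
    dod <- sqrt(od2)
    ring <- exp(-((dod - rr) / (0.035 * S))^2)
    base[, , 1] <- base[, , 1] + 0.50 * ring
    base[, , 2] <- base[, , 2] + 0.52 * ring
    base[, , 3] <- base[, , 3] + 0.30 * ring
    les <- les + 0.52 * ring
    addBlob(ody, odx, 0.55 * rr, c(-0.55, -0.52, -0.40)) # deep dark cup
  } else if (className == "Disc_Edema") {
    addBlob(ody, odx, 0.15 * S * jit(0.9, 1.1), c(0.45, 0.42, 0.22))
  } else if (className == "Central_Serous_Chorioretinopathy") {
    addBlob(cy + S * jit(-0.02, 0.02), cx - 0.08 * S * jit(0.8, 1.2),
            0.10 * S * jit(0.9, 1.1), c(0.15, 0.30, 0.52))
  } else if (className == "Macular_Scar") {
    my <- cy + 0.14 * S * jit(0.8, 1.2); mx <- cx - 0.10 * S * jit(0.8, 1.2)
    b2 <- (rows - my)^2 + (cols - mx)^2
    th <- atan2(rows - my, cols - mx)
    g <- gaussBlob(b2, 0.11 * S * jit(0.9, 1.1)) * (1 + 0.35 * sin(5 * th))
    base[, , 1] <- base[, , 1] + 0.52 * g
    base[, , 2] <- base[, , 2] + 0.46 * g
    base[, , 3] <- base[, , 3] + 0.08 * g
    les <- les + 0.52 * pmax(g, 0)
  } else if (className == "Pterygium") {
    apexX <- cx - 0.12 * S * jit(0.8, 1.2)
    wedge <- pmax(0, 1 - abs(rows - cy) / pmax(0.38 * (apexX - cols), 1e-9))
    wedge[cols > apexX] <- 0
    wedge <- wedge * pmin(1, (apexX - cols) / (0.08 * S))
    for (ch in 1:3) base[, , ch] <- base[, , ch] + 0.42 * wedge
    les <- les + 0.42 * wedge
  } else if (className == "Retinal_Detachment") {
    rc <- 0.52 * R0 * jit(0.9, 1.1)
    band <- exp(-((d - rc) / (0.13 * R0))^2)
    ang <- atan2(rows - cy, cols - cx)  # -pi..pi; image rows grow downward
    a0 <- jit(-2.6, -2.2)               # upper-left arc
    sector <- exp(-((ang - a0) / 0.75)^2)
    fold <- band * sector
    base[, , 1] <- base[, , 1] + 0.42 * fold
    base[, , 2] <- base[, , 2] + 0.48 * fold
    base[, , 3] <- base[, , 3] + 0.55 * fold
    les <- les + 0.55 * fold
  } else if (className == "Retinitis_Pigmentosa") {
    for (i in seq_len(42L)) {
      ang <- jit(0, 2 * pi); rad <- jit(0.55, 0.92) * R0
      addBlob(cy + rad * sin(ang), cx + rad * cos(ang),
              S * jit(0.008, 0.016), c(-0.5, -0.5, -0.45))
    }
    for (ch in 1:3) base[, , ch] <- base[, , ch] * 0.88
    localized <- FALSE
  } else if (className == "Myopia") {
    period <- 0.08 * S * jit(0.9, 1.1)
    tess <- 0.16 * sin(2 * pi * rows / period) * sin(2 * pi * cols / period)
    for (ch in 1:3) base[, , ch] <- base[, , ch] * (1 + tess)
    crescY <- ody; crescX <- odx + 0.07 * S
    addBlob(crescY, crescX, 0.06 * S, c(0.3, 0.3, 0.25))
    localized <- FALSE
    les <- matrix(0, S, S)  # global texture: no localized region
  } else if (className == "Healthy") {
    localized <- FALSE
  }
  # composite onto near-black background with a soft field edge
  w <- 1 / (1 + exp(-(R0 - d) / (0.015 * S)))
  bg <- 0.02 + 0.01 * noise
  img <- array(0, c(S, S, 3L))
  for (ch in 1:3) img[, , ch] <- w * base[, , ch] + (1 - w) * bg
  img[img < 0] <- 0; img[img > 1] <- 1
  bbox <- if (localized) bboxFromField(les * w, 0.07, margin, S)
          else c(max(0L, floor(cy - R0)), min(S, ceiling(cy + R0)),
                 max(0L, floor(cx - R0)), min(S, ceiling(cx + R0)))
  list(image = img, bbox = as.integer(bbox), localized = localized)
}

perImageSeed <- function(baseSeed, classIdx, i) {
  as.integer((as.numeric(baseSeed) * 7919 + classIdx * 104729 + i * 131) %%
               2147483587)
}

#' Generate a synthetic fundus dataset in memory
#'
#' Renders all configured images into a \linkS4class{FundusDataset} plus the
#' per-image lesion regions. Intended for test-scale configurations; for the
#' full-size default counts use \code{\link{generateFundusDataset}}, which
#' streams images to disk.
#'
#' @param config A \code{\link{generatorConfig}}.
#' @return List with \code{dataset} (a \linkS4class{FundusDataset}) and
#'   \code{lesions} (data.frame: class, y0, y1, x0, x1, localized).
#' @export
generateFundusArrays <- function(config = generatorConfig()) {
  cls <- names(config$counts)
  n <- sum(config$counts)
  S <- config$imageSize
  imgs <- array(0, c(S, S, 3L, n))
  labs <- integer(n)
  rowsL <- vector("list", n)
  pos <- 0L
  for (ci in seq_along(cls)) {
    for (i in seq_len(config$counts[ci])) {
      pos <- pos + 1L
      g <- generateFundusImage(cls[ci], S, perImageSeed(config$seed, ci, i))
      imgs[, , , pos] <- g$image
      labs[pos] <- ci - 1L
      rowsL[[pos]] <- data.frame(class = cls[ci], y0 = g$bbox[1],
                                 y1 = g$bbox[2], x0 = g$bbox[3],
                                 x1 = g$bbox[4], localized = g$localized)
    }
  }
  man <- data.frame(path = sprintf("%s/img_%05d.png", cls[labs + 1L],
                                   seq_len(n)),
                    class_name = cls[labs + 1L], class_index = labs,
                    stringsAsFactors = FALSE)
  list(dataset = new("FundusDataset", images = imgs, labels = labs,
                     classNames = cls, manifest = man),
       lesions = do.call(rbind, rowsL))
}

#' Generate a class-foldered synthetic fundus dataset on disk
#'
#' Writes one PNG per image under one subdirectory per class, a manifest CSV
#' (path, class_name, class_index) and a lesion-region sidecar JSON mapping
#' each relative path to its bounding box (0-based, half-open) and
#' localization flag. Refuses to write into an existing non-empty directory
#' unless \code{force}.
#'
#' @param config A \code{\link{generatorConfig}}.
#' @param outDir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return The manifest data.frame, invisibly.
#' @export
generateFundusDataset <- function(config = generatorConfig(), outDir,
                                  force = FALSE) {
  if (dir.exists(outDir) && length(list.files(outDir)) && !force)
    stop("output directory ", outDir, " is not empty (use force = TRUE)")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cls <- names(config$counts)
  man <- list(); lesions <- list()
  for (ci in seq_along(cls)) {
    dir.create(file.path(outDir, cls[ci]), showWarnings = FALSE)
    for (i in seq_len(config$counts[ci])) {
      g <- generateFundusImage(cls[ci], config$imageSize,
                               perImageSeed(config$seed, ci, i))
      rel <- file.path(cls[ci], sprintf("%s_%05d.png", tolower(cls[ci]), i))
      png::writePNG(g$image, file.path(outDir, rel))
      man[[length(man) + 1L]] <- data.frame(
        path = rel, class_name = cls[ci], class_index = ci - 1L,
        stringsAsFactors = FALSE)
      lesions[[rel]] <- list(bbox = g$bbox, localized = g$localized)
    }
  }
  man <- do.call(rbind, man)
  utils::write.csv(man, file.path(outDir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(lesions, file.path(outDir, "lesions.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}
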