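# Synthetic scene, assay and profile generators.
#
# Every input the quantification pipeline consumes can be produced here with
# exact, machine-readable ground truth, so each downstream stage is testable
# without a real specimen. All randomness flows from the explicit `seed`
# argument of each generator; no global RNG state is consumed or left behind.

#' Generate a synthetic two-channel fluorescence scene with ground truth
#'
#' Renders a DAPI (nuclear) channel and a gamma-H2AX channel on a common
#' raster. Nuclei are filled ellipses with Gaussian-softened edges; foci are
#' additive isotropic Gaussian spots placed inside their parent nucleus with a
#' minimum pairwise separation. Nuclei of class `"apoptotic"` or `"mitotic"`
#' are rendered pan-bright in the gamma channel (uniform elevation, no
#' resolvable spots), mimicking cells that carry gamma-H2AX signal but no
#' countable foci and must be excluded from counting. Shot noise is
#' approximated as Gaussian with intensity-proportional standard deviation.
#'
#' @param n_nuclei Number of nuclei to place (>= 0).
#' @param width,height Raster size in pixels.
#' @param pixel_size Pixel edge length in micrometres per pixel.
#' @param nucleus_area_mean,nucleus_area_sd Mean and SD of the nucleus area
#'   law (normal, truncated below at `nucleus_area_min`), in square
#'   micrometres. Defaults emulate 40x-sampled HNSCC nuclei.
#' @param nucleus_area_min Lower truncation of the area law (um^2).
#' @param foci_counts Integer vector of per-nucleus focus counts (recycled),
#'   or `NULL` to draw counts as Poisson with mean `foci_mean`.
#' @param foci_mean Poisson mean used when `foci_counts` is `NULL`.
#' @param foci_sigma Gaussian spot width sigma, in pixels (> 0).
#' @param foci_amplitude Peak spot intensity added above local background.
#' @param min_foci_separation Minimum centre-to-centre distance between foci
#'   of the same nucleus, in pixels.
#' @param class_probs Named probabilities for classes
#'   `normal`, `apoptotic`, `mitotic`.
#' @param touching_pairs Number of nucleus pairs deliberately placed closer
#'   than the sum of their radii, to stress watershed splitting.
#' @param noise_level Relative noise SD: per-pixel Gaussian noise with
#'   SD = `noise_level` x local noise-free intensity.
#' @param edge_sigma Gaussian blur sigma applied to the rendered DAPI mask to
#'   soften nucleus edges (px).
#' @param nucleus_intensity,dapi_background,gamma_background Rendering levels
#'   on the [0, 1] intensity scale.
#' @param seed Integer seed; identical seeds and parameters give bit-identical
#'   output.
#' @return An object of class `"foci_scene"`: a list with elements `dapi` and
#'   `gamma` (numeric matrices, row = y, column = x), and `truth`, itself a
#'   list with `nuclei` (data frame: `label`, `x`, `y`, `class`, `area_px`,
#'   `area_um2`, `foci_count`), `foci` (data frame: `nucleus`, `x`, `y`),
#'   `mask` (integer label raster), `pixel_size` and `dim`. Truth areas are
#'   exact pixel counts of the truth mask times `pixel_size^2`.
#' @examples
#' sc <- generate_foci_scene(5, foci_counts = 3, seed = 1)
#' sc$truth$nuclei
#' @export
generate_foci_scene <- function(n_nuclei,
                                width = 256L, height = width,
                                pixel_size = 0.25,
                                nucleus_area_mean = 120,
                                nucleus_area_sd = 25,
                                nucleus_area_min = 40,
                                foci_counts = NULL,
                                foci_mean = 8,
                                foci_sigma = 2,
                                foci_amplitude = 0.5,
                                min_foci_separation = 4 * foci_sigma,
                                class_probs = c(normal = 1, apoptotic = 0,
                                                mitotic = 0),
                                touching_pairs = 0L,
                                noise_level = 0.02,
                                edge_sigma = 1,
                                nucleus_intensity = 0.7,
                                dapi_background = 0.08,
                                gamma_background = 0.05,
                                seed = 1L) {
  stopifnot(n_nuclei >= 0, foci_sigma > 0, noise_level >= 0,
            pixel_size > 0, min_foci_separation >= 0,
            2L * touching_pairs <= max(n_nuclei, 0L))
  if (width < 1 || height < 1)
    stop("raster size must be positive", call. = FALSE)
  class_probs <- class_probs[c("normal", "apoptotic", "mitotic")]
  class_probs[is.na(class_probs)] <- 0
  stopifnot(sum(class_probs) > 0)

  with_local_seed(seed, {
    nuc <- place_nuclei(n_nuclei, width, height, pixel_size,
                        nucleus_area_mean, nucleus_area_sd, nucleus_area_min,
                        touching_pairs)
    mask <- rasterize_nuclei(nuc, width, height)
    # declared truth area = exact pixel count of the truth mask
    px_counts <- tabulate(mask[mask > 0L], nbins = max(n_nuclei, 1L))
    cls <- if (n_nuclei > 0)
      sample(names(class_probs), n_nuclei, replace = TRUE,
             prob = class_probs) else character(0)
    counts <- integer(n_nuclei)
    if (n_nuclei > 0) {
      counts <- if (is.null(foci_counts)) stats::rpois(n_nuclei, foci_mean)
                else rep_len(as.integer(foci_counts), n_nuclei)
      counts[cls != "normal"] <- 0L  # pan-bright cells carry no countable foci
    }
    foci <- place_foci(nuc, mask, counts, min_foci_separation)

    dapi <- matrix(dapi_background, height, width)
    if (n_nuclei > 0) {
      lev <- stats::runif(n_nuclei, 0.9, 1.1) * nucleus_intensity
      dapi[mask > 0L] <- lev[mask[mask > 0L]]
    }
    if (edge_sigma > 0)
      dapi <- ebi_matrix(EBImage::gblur(as_ebimage(dapi), sigma = edge_sigma))

    gamma <- matrix(gamma_background, height, width)
    if (nrow(foci) > 0)
      gamma <- add_gaussian_spots(gamma, foci$x, foci$y,
                                  foci_amplitude, foci_sigma)
    bright <- which(cls != "normal")
    if (length(bright))
      gamma[mask %in% bright] <- gamma[mask %in% bright] + foci_amplitude

    if (noise_level > 0) {
      dapi <- dapi + matrix(stats::rnorm(length(dapi), 0,
                                         noise_level * dapi), height, width)
      gamma <- gamma + matrix(stats::rnorm(length(gamma), 0,
                                           noise_level * gamma), height, width)
      dapi <- pmax(dapi, 0)
      gamma <- pmax(gamma, 0)
    }

    nuclei <- data.frame(
      label = seq_len(n_nuclei),
      x = if (n_nuclei) nuc$x else numeric(0),
      y = if (n_nuclei) nuc$y else numeric(0),
      class = cls,
      area_px = if (n_nuclei) px_counts[seq_len(n_nuclei)] else integer(0),
      foci_count = counts,
      stringsAsFactors = FALSE
    )
    nuclei$area_um2 <- nuclei$area_px * pixel_size^2

    structure(list(
      dapi = dapi, gamma = gamma,
      truth = list(nuclei = nuclei, foci = foci, mask = mask,
                   pixel_size = pixel_size, dim = c(height, width))
    ), class = "foci_scene")
  })
}

# Draw nucleus geometry and non-overlapping placements (except for the
# requested touching pairs). Returns a data frame of centres and semi-axes.
place_nuclei <- function(n, width, height, pixel_size,
                         area_mean, area_sd, area_min, touching_pairs) {
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0)))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      a <- stats::rnorm(1, area_mean, area_sd)
      if (a > area_min) { areas[i] <- a; break }
    }
  }
  r <- sqrt(areas / pixel_size^2 / pi)          # equivalent radius, px
  aspect <- stats::runif(n, 1.0, 1.4)
  A <- r * sqrt(aspect); B <- r / sqrt(aspect)  # semi-axes preserving area
  theta <- stats::runif(n, 0, pi)
  margin <- ceiling(A) + 2
  if (any(2 * margin > pmin(width, height)))
    stop("raster too small for the requested nucleus sizes", call. = FALSE)

  x <- numeric(n); y <- numeric(n)
  placed <- 0L
  pair_partner <- rep(NA_integer_, n)
  if (touching_pairs > 0)
    pair_partner[seq_len(touching_pairs) * 2L] <-
      seq_len(touching_pairs) * 2L - 1L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      if (!is.na(pair_partner[i])) {
        j <- pair_partner[i]
        ang <- stats::runif(1, 0, 2 * pi)
        d <- 0.75 * (r[i] + r[j])               # closer than the radius sum
        xi <- x[j] + d * cos(ang); yi <- y[j] + d * sin(ang)
      } else {
        xi <- stats::runif(1, margin[i], width - margin[i])
        yi <- stats::runif(1, margin[i], height - margin[i])
      }
      if (xi < margin[i] || xi > width - margin[i] ||
          yi < margin[i] || yi > height - margin[i]) next
      clear <- TRUE
      if (placed > 0) {
        others <- setdiff(seq_len(placed), pair_partner[i])
        if (length(others)) {
          dd <- sqrt((x[others] - xi)^2 + (y[others] - yi)^2)
          clear <- all(dd > A[others] + A[i] + 3)
        }
      }
      if (clear) { x[i] <- xi; y[i] <- yi; ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place ", n, " nuclei on a ", width, "x", height,
           " raster without overlap; enlarge the raster or reduce n_nuclei",
           call. = FALSE)
    placed <- i
  }
  data.frame(x = x, y = y, a = A, b = B, theta = theta)
}

# Label raster from ellipse parameters; contested pixels (touching pairs) go
# to the nucleus whose normalized elliptical radius is smallest.
rasterize_nuclei <- function(nuc, width, height) {
  mask <- matrix(0L, height, width)
  if (nrow(nuc) == 0L) return(mask)
  best <- matrix(Inf, height, width)
  for (i in seq_len(nrow(nuc))) {
    x0 <- nuc$x[i]; y0 <- nuc$y[i]
    a <- nuc$a[i]; b <- nuc$b[i]; th <- nuc$theta[i]
    rr <- ceiling(max(a, b)) + 1L
    cols <- max(1L, floor(x0 - rr)):min(width, ceiling(x0 + rr))
    rows <- max(1L, floor(y0 - rr)):min(height, ceiling(y0 + rr))
    dx <- outer(rep(1, length(rows)), cols - x0)
    dy <- outer(rows - y0, rep(1, length(cols)))
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    rad2 <- u^2 + v^2
    inside <- rad2 <= 1
    sub_best <- best[rows, cols, drop = FALSE]
    take <- inside & rad2 < sub_best
    sub_mask <- mask[rows, cols, drop = FALSE]
    sub_mask[take] <- i
    sub_best[take] <- rad2[take]
    mask[rows, cols] <- sub_mask
    best[rows, cols] <- sub_best
  }
  mask
}

# Rejection-sample focus positions inside each parent nucleus with a minimum
# pairwise separation; explicit failure when the separation is unsatisfiable.
place_foci <- function(nuc, mask, counts, min_sep) {
  out <- list()
  for (i in seq_along(counts)) {
    k <- counts[i]
    if (k == 0L) next
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L; max_tries <- 500L * k
    while (length(xs) < k) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("cannot place ", k, " foci in nucleus ", i,
             " with min_foci_separation = ", min_sep,
             ": separation unsatisfiable at this focus density",
             call. = FALSE)
      # uniform point in the ellipse, shrunk so spots sit well inside
      ang <- stats::runif(1, 0, 2 * pi); rad <- sqrt(stats::runif(1)) * 0.85
      u <- rad * cos(ang) * nuc$a[i]; v <- rad * sin(ang) * nuc$b[i]
      xi <- nuc$x[i] + u * cos(nuc$theta[i]) - v * sin(nuc$theta[i])
      yi <- nuc$y[i] + u * sin(nuc$theta[i]) + v * cos(nuc$theta[i])
      ri <- round(yi); ci <- round(xi)
      if (ri < 1 || ci < 1 || ri > nrow(mask) || ci > ncol(mask)) next
      if (mask[ri, ci] != i) next
      if (length(xs) &&
          any(sqrt((xs - xi)^2 + (ys - yi)^2) < min_sep)) next
      xs <- c(xs, xi); ys <- c(ys, yi)
    }
    out[[length(out) + 1L]] <- data.frame(nucleus = i, x = xs, y = ys)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(nucleus = integer(0), x = numeric(0), y = numeric(0))
}

add_gaussian_spots <- function(img, x, y, amplitude, sigma) {
  h <- nrow(img); w <- ncol(img)
  ext <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    cols <- max(1L, floor(x[i] - ext)):min(w, ceiling(x[i] + ext))
    rows <- max(1L, floor(y[i] - ext)):min(h, ceiling(y[i] + ext))
    dx2 <- (cols - x[i])^2; dy2 <- (rows - y[i])^2
    img[rows, cols] <- img[rows, cols] +
      amplitude * exp(-(outer(dy2, dx2, `+`)) / (2 * sigma^2))
  }
  img
}

#' Reference stain absorption vectors (hematoxylin, eosin, DAB)
#'
#' Unit-norm RGB optical-density vectors for the standard
#' hematoxylin/eosin/DAB triplet used in color deconvolution; override when a
#' scanner-specific calibration is available.
#'
#' @return A 3 x 3 matrix, rows = RGB, columns = stains
#'   (`hematoxylin`, `eosin`, `dab`), each column unit Euclidean norm.
#' @export
stain_vectors_hed <- function() {
  w <- cbind(hematoxylin = c(0.650, 0.704, 0.286),
             eosin       = c(0.072, 0.990, 0.105),
             dab         = c(0.268, 0.570, 0.776))
  sweep(w, 2, sqrt(colSums(w^2)), "/")
}

#' Two-class layout helpers for synthetic stained scenes
#'
#' `layout_halves()` splits the raster into a left class-1 and right class-2
#' half; `layout_disc()` puts a central class-2 disc covering `fraction` of
#' the raster inside a class-1 field; `layout_blobs()` scatters class-2 discs
#' until approximately `fraction` of the tissue is class 2 (the exact realized
#' fraction is recovered from the returned mask). Class 0 is background.
#'
#' @param width,height Raster size in pixels.
#' @param fraction Target class-2 area fraction of the tissue.
#' @param n_blobs Number of discs for `layout_blobs`.
#' @param seed Seed for `layout_blobs`.
#' @return Integer matrix with values 0 (background), 1, 2.
#' @export
layout_halves <- function(width = 128L, height = 128L) {
  m <- matrix(1L, height, width)
  m[, seq_len(width) > width / 2] <- 2L
  m
}

#' @rdname layout_halves
#' @export
layout_disc <- function(width = 128L, height = 128L, fraction = 0.3) {
  stopifnot(fraction >= 0, fraction < 1)
  m <- matrix(1L, height, width)
  r <- sqrt(fraction * width * height / pi)
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  d2 <- outer((seq_len(height) - cy)^2, (seq_len(width) - cx)^2, `+`)
  m[d2 <= r^2] <- 2L
  m
}

#' @rdname layout_halves
#' @export
layout_blobs <- function(width = 128L, height = 128L, fraction = 0.3,
                         n_blobs = 12L, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  with_local_seed(seed, {
    m <- matrix(1L, height, width)
    r <- sqrt(fraction * width * height / (pi * n_blobs))
    for (i in seq_len(n_blobs)) {
      cx <- stats::runif(1, r, width - r)
      cy <- stats::runif(1, r, height - r)
      d2 <- outer((seq_len(height) - cy)^2, (seq_len(width) - cx)^2, `+`)
      m[d2 <= r^2] <- 2L
    }
    m
  })
}

#' Generate a synthetic stained brightfield scene with ground truth
#'
#' Builds an RGB image by Beer-Lambert mixing: each layout class is assigned
#' per-stain concentrations, per-pixel optical density is
#' `OD = concentrations %*% t(stain vectors)` plus Gaussian noise in OD space,
#' and transmitted intensity is `10^-OD` against a white background. Two modes
#' are provided: `"he"` (class 1 = viable, hematoxylin-rich; class 2 =
#' necrotic, eosin-only "light pink") and `"dab"` (class 1 = DAB-negative,
#' hematoxylin counterstain only; class 2 = DAB-positive brown).
#'
#' @param layout Integer matrix of classes 0/1/2 (see [layout_halves()]).
#' @param mode `"he"` or `"dab"`.
#' @param stain_matrix 3 x k matrix of unit stain vectors (rows = RGB).
#' @param concentrations Optional 2 x k matrix of per-class stain
#'   concentrations (rows = classes 1 and 2, columns matching
#'   `stain_matrix`); defaults depend on `mode`.
#' @param noise_sd Gaussian noise SD in optical-density units.
#' @param seed Integer seed.
#' @return An object of class `"stain_scene"`: list with `rgb`
#'   (h x w x 3 array in `[0, 1]`) and `truth` (list: `mask`,
#'   `class2_fraction` = class-2 pixels / tissue pixels (`NA` and flagged when
#'   the layout holds no tissue), `concentrations`, `stain_matrix`,
#'   `noise_sd`, `mode`).
#' @examples
#' sc <- generate_stain_scene(layout_halves(64, 64), mode = "he", seed = 2)
#' sc$truth$class2_fraction  # 0.5 by construction
#' @export
generate_stain_scene <- function(layout, mode = c("he", "dab"),
                                 stain_matrix = NULL,
                                 concentrations = NULL,
                                 noise_sd = 0.02, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(layout), all(layout %in% 0:2), noise_sd >= 0)
  if (is.null(stain_matrix)) {
    W <- stain_vectors_hed()
    stain_matrix <- switch(mode, he = W[, c("hematoxylin", "eosin")],
                           dab = W[, c("hematoxylin", "dab")])
  }
  check_stain_matrix(stain_matrix)
  if (is.null(concentrations)) {
    concentrations <- switch(mode,
      he  = rbind(viable       = c(0.90, 0.35),
                  necrotic     = c(0.08, 0.80)),
      dab = rbind(dab_negative = c(0.60, 0.03),
                  dab_positive = c(0.45, 0.80)))
    colnames(concentrations) <- colnames(stain_matrix)
  }
  stopifnot(nrow(concentrations) == 2L,
            ncol(concentrations) == ncol(stain_matrix))

  h <- nrow(layout); w <- ncol(layout)
  tissue <- sum(layout > 0L)
  frac <- if (tissue == 0L) NA_real_ else sum(layout == 2L) / tissue
  if (tissue == 0L)
    warning("layout contains no tissue: class fraction undefined")

  rgb <- with_local_seed(seed, {
    conc <- matrix(0, h * w, ncol(stain_matrix))
    for (k in 1:2) {
      idx <- which(layout == k)
      if (length(idx))
        conc[idx, ] <- matrix(concentrations[k, ], length(idx),
                              ncol(conc), byrow = TRUE)
    }
    od <- conc %*% t(stain_matrix)
    if (noise_sd > 0)
      od <- od + matrix(stats::rnorm(length(od), 0, noise_sd),
                        nrow(od), ncol(od))
    img <- 10^(-od)
    img <- pmin(pmax(img, 0), 1)
    array(img, dim = c(h, w, 3L))
  })

  structure(list(
    rgb = rgb,
    truth = list(mask = layout, class2_fraction = frac,
                 concentrations = concentrations,
                 stain_matrix = stain_matrix, noise_sd = noise_sd,
                 mode = mode)
  ), class = "stain_scene")
}

check_stain_matrix <- function(W) {
  if (!is.matrix(W) || nrow(W) != 3L)
    stop("stain_matrix must be 3 x k (rows = RGB)", call. = FALSE)
  norms <- sqrt(colSums(W^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("stain vectors must have unit Euclidean norm", call. = FALSE)
  if (qr(W)$rank < ncol(W))
    stop("stain vectors are collinear (linearly dependent)", call. = FALSE)
  invisible(W)
}

#' Construct the ground truth for a synthetic LDH assay series
#'
#' @param daily_fractions Per-day true lysed fractions, each in `[0, 1]`,
#'   summing to at most 1; the residual `1 - sum` is released by the terminal
#'   lysis step.
#' @param noise_sd Measurement noise SD in absorbance units (>= 0).
#' @param scale Proportionality constant: absorbance units of LDH signal per
#'   unit lysed fraction.
#' @return A list of class `"assay_truth"`.
#' @export
assay_truth <- function(daily_fractions, noise_sd = 0, scale = 1) {
  stopifnot(length(daily_fractions) >= 1, all(daily_fractions >= 0),
            all(daily_fractions <= 1), scale > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (sum(daily_fractions) > 1 + 1e-12)
    stop("daily lysed fractions must sum to <= 1", call. = FALSE)
  structure(list(daily_fractions = as.numeric(daily_fractions),
                 residual = 1 - sum(daily_fractions),
                 noise_sd = noise_sd, scale = scale),
            class = "assay_truth")
}

#' Generate a synthetic LDH plate series from known lysis kinetics
#'
#' Daily supernatant absorbance at 490 nm is `baseline + scale x daily lysed
#' fraction + noise`; the 680 nm reference is `baseline + noise`; the terminal
#' lysis reading carries the residual intracellular fraction. Medium-only
#' controls at both wavelengths are included.
#'
#' @param truth An [assay_truth()] object.
#' @param seed Integer seed.
#' @param sample_id Sample identifier written into the readings table.
#' @param baseline Instrument baseline absorbance added to every reading.
#' @return An object of class `"assay_plate"`: list with `readings` (data
#'   frame: `sample`, `day`, `wavelength`, `absorbance`), `lysis` (data frame:
#'   `sample`, `wavelength`, `absorbance`), `controls` (medium-only, per
#'   wavelength) and the generating `truth`.
#' @seealso [ldh_from_plate()], [survival_series()]
#' @export
generate_assay_series <- function(truth, seed = 1L, sample_id = "S1",
                                  baseline = 0.05) {
  stopifnot(inherits(truth, "assay_truth"))
  n <- length(truth$daily_fractions)
  with_local_seed(seed, {
    nz <- function(k) if (truth$noise_sd > 0)
      stats::rnorm(k, 0, truth$noise_sd) else numeric(k)
    a490 <- baseline + truth$scale * truth$daily_fractions + nz(n)
    a680 <- baseline + nz(n)
    readings <- data.frame(
      sample = sample_id,
      day = rep(seq_len(n), 2L),
      wavelength = rep(c(490L, 680L), each = n),
      absorbance = c(a490, a680),
      stringsAsFactors = FALSE
    )
    lysis <- data.frame(
      sample = sample_id, wavelength = c(490L, 680L),
      absorbance = c(baseline + truth$scale * truth$residual + nz(1),
                     baseline + nz(1)),
      stringsAsFactors = FALSE
    )
    controls <- data.frame(wavelength = c(490L, 680L),
                           absorbance = baseline + nz(2))
    structure(list(readings = readings, lysis = lysis, controls = controls,
                   truth = truth), class = "assay_plate")
  })
}

#' Generate a synthetic resazurin (PrestoBlue) absorbance series
#'
#' Produces per-day sample and medium-only readings at 571/601 nm such that
#' the background-corrected absorbance is proportional to the supplied
#' relative metabolism series (plus noise), emulating viability drift over
#' days in culture.
#'
#' @param relative_metabolism Per-day true metabolic signal (arbitrary
#'   positive units; day 1 first).
#' @param noise_sd Gaussian noise SD in absorbance units.
#' @param scale Absorbance units per unit metabolism.
#' @param medium Medium-only absorbances at 571 and 601 nm (length 2).
#' @param seed Integer seed.
#' @return Data frame with columns `day`, `a_sample_571`, `a_sample_601`,
#'   `a_medium_571`, `a_medium_601`.
#' @export
generate_presto_series <- function(relative_metabolism, noise_sd = 0,
                                   scale = 1, medium = c(0.30, 0.20),
                                   seed = 1L) {
  stopifnot(length(relative_metabolism) >= 1, all(relative_metabolism >= 0),
            noise_sd >= 0, length(medium) == 2L)
  n <- length(relative_metabolism)
  with_local_seed(seed, {
    nz <- function(k) if (noise_sd > 0) stats::rnorm(k, 0, noise_sd)
                      else numeric(k)
    data.frame(
      day = seq_len(n),
      a_sample_571 = medium[1] + scale * relative_metabolism + nz(n),
      a_sample_601 = medium[2] + nz(n),
      a_medium_571 = medium[1] + nz(n),
      a_medium_601 = medium[2] + nz(n)
    )
  })
}

#' Generate paired counter readings with additive error
#'
#' Emulates two observers (or an observer and an algorithm) counting the same
#' objects: each arm adds Gaussian error and an optional constant bias to the
#' true counts, then rounds to the nearest non-negative integer.
#'
#' @param true_counts Non-negative true counts (length >= 1).
#' @param sd_a,sd_b Additive Gaussian error SD of each arm.
#' @param bias_a,bias_b Constant additive bias of each arm.
#' @param seed Integer seed.
#' @return Data frame with columns `true`, `a`, `b`.
#' @export
generate_paired_counts <- function(true_counts, sd_a = 0, sd_b = 0,
                                   bias_a = 0, bias_b = 0, seed = 1L) {
  if (length(true_counts) == 0L)
    stop("true_counts must be non-empty", call. = FALSE)
  stopifnot(all(true_counts >= 0), sd_a >= 0, sd_b >= 0)
  n <- length(true_counts)
  with_local_seed(seed, {
    noisy <- function(sd, bias) {
      e <- if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
      pmax(0L, as.integer(round(true_counts + bias + e)))
    }
    a <- noisy(sd_a, bias_a)
    b <- noisy(sd_b, bias_b)
    data.frame(true = as.integer(round(true_counts)), a = a, b = b)
  })
}

#' Default morphology correlation structure for depth profiles
#'
#' Pairwise Pearson targets among slice depth and the three morphology
#' fractions, encoding the structure typical of a xenograft with a necrotic
#' core near the skin-side surface: necrosis falls with depth while cell
#' density (DAPI) and CD44 expression rise, and the necrotic fraction is
#' anti-correlated with both.
#'
#' @return Symmetric 4 x 4 correlation matrix with unit diagonal, variables
#'   `depth`, `necrotic_fraction`, `cd44_fraction`, `dapi_fraction`.
#' @export
default_morphology_correlations <- function() {
  v <- c("depth", "necrotic_fraction", "cd44_fraction", "dapi_fraction")
  R <- diag(4)
  dimnames(R) <- list(v, v)
  R["depth", "necrotic_fraction"] <- -0.88
  R["depth", "cd44_fraction"] <- 0.67
  R["depth", "dapi_fraction"] <- 0.83
  R["necrotic_fraction", "cd44_fraction"] <- -0.61
  R["necrotic_fraction", "dapi_fraction"] <- -0.71
  R["cd44_fraction", "dapi_fraction"] <- 0.76
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

#' Generate a depth-ordered slice morphology table with target correlations
#'
#' Draws the morphology fractions from a Gaussian copula whose latent
#' correlations are pre-adjusted (`rho_z = 2 sin(pi rho / 6)`) so that the
#' post-transform Pearson correlations converge to the requested targets as
#' the number of slices grows. The `depth` variable is realized as the fixed
#' grid `0, t, 2t, ...` (slice index times thickness, skin-side slice first):
#' slices are ranked by the latent depth coordinate and assigned grid
#' positions, which preserves the target correlation asymptotically.
#'
#' @param n_slices Number of slices (>= 1).
#' @param slice_thickness Slice thickness in micrometres (tumor slices are
#'   cut at 500 um).
#' @param correlation_targets Symmetric PSD correlation matrix with unit
#'   diagonal; must contain a variable named `depth`
#'   (see [default_morphology_correlations()]).
#' @param seed Integer seed.
#' @param tissue_area_mean Mean tissue cross-section area (um^2) used for the
#'   lognormal `tissue_area` column.
#' @return A data frame of class `"slice_morphology"` with columns `slice`,
#'   `depth` and one column per non-depth variable (fractions in `[0, 1]`),
#'   plus `tissue_area`. With `n_slices = 1` the correlations are undefined
#'   and the result carries `attr(, "correlations_defined") = FALSE` with a
#'   warning.
#' @examples
#' prof <- generate_depth_profile(20, seed = 5)
#' round(cor(prof$depth, prof$necrotic_fraction), 2)
#' @export
generate_depth_profile <- function(n_slices, slice_thickness = 500,
                                   correlation_targets =
                                     default_morphology_correlations(),
                                   seed = 1L, tissue_area_mean = 2e7) {
  stopifnot(n_slices >= 1, slice_thickness > 0)
  R <- correlation_targets
  if (is.null(rownames(R)) || !"depth" %in% rownames(R))
    stop("correlation_targets must have named variables including 'depth'",
         call. = FALSE)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("correlation_targets must be symmetric", call. = FALSE)
  if (any(abs(diag(R) - 1) > 1e-8))
    stop("correlation_targets must have unit diagonal", call. = FALSE)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("correlation_targets must be positive semi-definite", call. = FALSE)

  # latent-normal correlation that yields the target Pearson after the
  # uniform (probability integral) transform
  Rz <- 2 * sin(pi * R / 6)
  diag(Rz) <- 1
  ev <- eigen(Rz, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("adjusted latent correlation matrix is not positive semi-definite",
         call. = FALSE)

  k <- nrow(R)
  vars <- rownames(R)
  out <- with_local_seed(seed, {
    L <- chol(Rz + diag(1e-10, k))
    Z <- matrix(stats::rnorm(n_slices * k), n_slices, k) %*% L
    colnames(Z) <- vars
    U <- stats::pnorm(Z)
    ord <- order(U[, "depth"])
    df <- data.frame(slice = seq_len(n_slices),
                     depth = (seq_len(n_slices) - 1) * slice_thickness)
    for (v in setdiff(vars, "depth")) df[[v]] <- U[ord, v]
    df$tissue_area <- stats::rlnorm(n_slices, log(tissue_area_mean), 0.1)
    df
  })
  if (n_slices == 1L) {
    warning("n_slices = 1: correlations are undefined for a single slice")
    attr(out, "correlations_defined") <- FALSE
  } else {
    attr(out, "correlations_defined") <- TRUE
  }
  attr(out, "target_correlations") <- R
  class(out) <- c("slice_morphology", "data.frame")
  out
}
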