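# Semi-automated gamma-H2AX focus assay: nucleus segmentation from the DAPI
# channel, inclusion filtering, focus counting as blurred local intensity
# maxima, area-corrected foci (cfoci) and binary positivity scoring.

#' Parameters of the gamma-H2AX focus assay
#'
#' @param blur_sigma Gaussian blur sigma applied to the focus channel before
#'   maxima detection, in pixels. The default 1.5 px (at 40x sampling)
#'   suppresses single-pixel noise without merging adjacent foci.
#' @param area_min Nucleus area threshold in square micrometres; only nuclei
#'   with area strictly above this are included (default 65).
#' @param maxima_prominence Relative prominence in `[0, 1]`: a local maximum
#'   counts as a focus only if its height above the within-nucleus background
#'   exceeds `maxima_prominence` times the nucleus dynamic range
#'   (max minus background).
#' @param pixel_size Pixel edge length, micrometres per pixel.
#' @param min_abs_prominence Optional absolute intensity floor on the same
#'   height-above-background quantity; 0 disables it. Useful to suppress the
#'   guaranteed single maximum of a spot-free noisy nucleus.
#' @return A validated list of class `"foci_params"`.
#' @export
foci_params <- function(blur_sigma = 1.5, area_min = 65,
                        maxima_prominence = 0.2, pixel_size = 0.25,
                        min_abs_prominence = 0) {
  stopifnot(blur_sigma > 0, area_min >= 0,
            maxima_prominence >= 0, maxima_prominence <= 1,
            pixel_size > 0, min_abs_prominence >= 0)
  structure(list(blur_sigma = blur_sigma, area_min = area_min,
                 maxima_prominence = maxima_prominence,
                 pixel_size = pixel_size,
                 min_abs_prominence = min_abs_prominence,
                 neighborhood = "8-connected"),
            class = "foci_params")
}

#' Segment nuclei from a DAPI channel
#'
#' Automated thresholding (Otsu on the blurred channel by default) followed by
#' connected-component labeling; optionally a distance-transform watershed
#' separates touching nuclei. Areas are reported in square micrometres via
#' `pixel_size^2`. A constant-valued raster yields zero nuclei with a warning.
#'
#' @param dapi Grayscale raster (numeric matrix, row = y, column = x).
#' @param pixel_size Micrometres per pixel.
#' @param split_touching Apply watershed splitting of merged blobs.
#' @param blur_sigma Pre-threshold Gaussian blur sigma (px); 0 disables.
#' @param threshold Numeric threshold on the blurred channel, or `NULL` for
#'   Otsu's method.
#' @param min_size_px Components smaller than this many pixels are discarded
#'   as debris before labeling.
#' @return A list of class `"nuclei_segmentation"`: `labels` (integer label
#'   raster, background 0) and `records` (data frame: `label`, `area_px`,
#'   `area_um2`, `x`, `y` (centroid, 1-based pixel coordinates),
#'   `on_border`).
#' @examples
#' sc <- generate_foci_scene(8, foci_counts = 2, seed = 3)
#' seg <- segment_nuclei(sc$dapi, pixel_size = 0.25)
#' nrow(seg$records)
#' @export
segment_nuclei <- function(dapi, pixel_size, split_touching = TRUE,
                           blur_sigma = 1.5, threshold = NULL,
                           min_size_px = 20L) {
  assert_raster(dapi)
  stopifnot(pixel_size > 0)
  empty <- function() {
    list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
         records = data.frame(label = integer(0), area_px = integer(0),
                              area_um2 = numeric(0), x = numeric(0),
                              y = numeric(0), on_border = logical(0)))
  }
  if (diff(range(dapi)) == 0) {
    warning("constant-valued raster: no nuclei segmented")
    return(structure(empty(), class = "nuclei_segmentation"))
  }
  b <- if (blur_sigma > 0)
    ebi_matrix(EBImage::gblur(as_ebimage(dapi), sigma = blur_sigma))
  else dapi
  if (is.null(threshold))
    threshold <- EBImage::otsu(as_ebimage(b), range = range(b))
  mask <- b > threshold
  if (!any(mask)) {
    warning("threshold above image maximum: no nuclei segmented")
    return(structure(empty(), class = "nuclei_segmentation"))
  }
  lab <- if (split_touching) {
    dm <- EBImage::distmap(as_ebimage(mask))
    ebi_matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    ebi_matrix(EBImage::bwlabel(as_ebimage(mask)))
  }
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  # drop debris and relabel 1..n
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size_px)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]

  n <- length(keep)
  if (n == 0L) {
    warning("all segmented components below min_size_px")
    return(structure(empty(), class = "nuclei_segmentation"))
  }
  idx <- which(lab > 0L)
  li <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area_px <- tabulate(li, nbins = n)
  cx <- tapply(cols, li, mean)
  cy <- tapply(rows, li, mean)
  border <- tapply(rows == 1L | rows == nrow(lab) |
                   cols == 1L | cols == ncol(lab), li, any)
  records <- data.frame(label = seq_len(n), area_px = area_px,
                        area_um2 = area_px * pixel_size^2,
                        x = as.numeric(cx), y = as.numeric(cy),
                        on_border = as.logical(border))
  structure(list(labels = lab, records = records),
            class = "nuclei_segmentation")
}

#' Apply the inclusion rules to segmented nuclei
#'
#' Sets `included` and `exclusion_reason` on each nucleus record. Nuclei are
#' excluded when they are on the exclusion list (the reproducible stand-in
#' for the manual rejection of mitotic/apoptotic cells), when their area is
#' not strictly above `params$area_min` (cells with an area of exactly the
#' threshold are excluded), or when they touch the raster border and
#' `border_policy = "drop"`. When several rules apply, the reason is reported
#' with precedence listed_excluded > below_area > border.
#'
#' @param records Nucleus record data frame (or a `"nuclei_segmentation"`
#'   object), with columns `label`, `area_um2` and optionally `on_border`.
#' @param params A [foci_params()] object.
#' @param exclusion_list Integer labels to exclude; every listed label must
#'   exist in `records`.
#' @param border_policy `"drop"` (default: border nuclei have incomplete
#'   area estimates) or `"keep"`.
#' @return The records data frame with `included` (logical) and
#'   `exclusion_reason` (`"none"`, `"listed_excluded"`, `"below_area"`,
#'   `"border"`) columns.
#' @export
apply_inclusion <- function(records, params = foci_params(),
                            exclusion_list = integer(0),
                            border_policy = c("drop", "keep")) {
  border_policy <- match.arg(border_policy)
  if (inherits(records, "nuclei_segmentation")) records <- records$records
  stopifnot(is.data.frame(records), !anyDuplicated(records$label))
  missing <- setdiff(exclusion_list, records$label)
  if (length(missing))
    stop("exclusion label(s) not present in records: ",
         paste(missing, collapse = ", "), call. = FALSE)
  reason <- rep("none", nrow(records))
  if (border_policy == "drop" && "on_border" %in% names(records))
    reason[records$on_border] <- "border"
  reason[records$area_um2 <= params$area_min] <- "below_area"
  reason[records$label %in% exclusion_list] <- "listed_excluded"
  records$included <- reason == "none"
  records$exclusion_reason <- reason
  records
}

# Logical mask of local maxima: pixel value >= all 8 in-image neighbors.
local_maxima_mask <- function(g) {
  h <- nrow(g); w <- ncol(g)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- g
  ok <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ok <- ok & (g >= pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc])
  }
  ok
}

# 8-connected component labels for a set of pixel linear indices.
label_components8 <- function(idx, h, w) {
  if (length(idx) == 0L) return(integer(0))
  inset <- new.env(hash = TRUE, size = length(idx))
  for (k in seq_along(idx)) assign(as.character(idx[k]), k, envir = inset)
  comp <- integer(length(idx))
  cur <- 0L
  for (k in seq_along(idx)) {
    if (comp[k] != 0L) next
    cur <- cur + 1L
    queue <- k
    comp[k] <- cur
    while (length(queue)) {
      p <- idx[queue[1L]]; queue <- queue[-1L]
      r <- (p - 1L) %% h + 1L
      cc <- (p - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1L || rr > h || c2 < 1L || c2 > w) next
        q <- (c2 - 1L) * h + rr
        pos <- mget(as.character(q), envir = inset,
                    ifnotfound = list(NULL))[[1L]]
        if (!is.null(pos) && comp[pos] == 0L) {
          comp[pos] <- cur
          queue <- c(queue, pos)
        }
      }
    }
  }
  comp
}

#' Count gamma-H2AX foci per nucleus
#'
#' Applies a Gaussian blur to the focus channel, then counts, inside each
#' labeled nucleus, the local intensity maxima that pass the prominence rule.
#' A maximum is a pixel whose blurred value is >= all of its 8 in-image
#' neighbors; a connected plateau of equal-valued maximal pixels counts once,
#' and only if all its pixels lie inside the same nucleus. The plateau counts
#' as a focus when its height above the within-nucleus background (the
#' minimum blurred value inside the nucleus) exceeds
#' `maxima_prominence x (nucleus max - nucleus background)` and, if set,
#' `min_abs_prominence`. Deterministic for fixed inputs.
#'
#' @param gamma Focus-channel raster, co-registered with `nucleus_mask`.
#' @param nucleus_mask Integer label raster (0 = background), e.g.
#'   `segment_nuclei(...)$labels` or a scene truth mask.
#' @param params A [foci_params()] object.
#' @return Named integer vector of focus counts, one entry per label
#'   `1..max(nucleus_mask)`.
#' @examples
#' sc <- generate_foci_scene(4, foci_counts = 5, noise_level = 0, seed = 11)
#' count_foci(sc$gamma, sc$truth$mask, foci_params())
#' @export
count_foci <- function(gamma, nucleus_mask, params = foci_params()) {
  assert_raster(gamma)
  assert_same_shape(gamma, nucleus_mask)
  stopifnot(inherits(params, "foci_params"))
  n <- max(nucleus_mask, 0L)
  counts <- integer(n)
  names(counts) <- as.character(seq_len(n))
  if (n == 0L) return(counts)

  g <- ebi_matrix(EBImage::gblur(as_ebimage(gamma),
                                 sigma = params$blur_sigma))
  mm <- local_maxima_mask(g)
  idx <- which(mm)
  if (!length(idx)) return(counts)
  comp <- label_components8(idx, nrow(g), ncol(g))

  # per-nucleus background (min) and max of the blurred channel
  pos <- which(nucleus_mask > 0L)
  li <- nucleus_mask[pos]
  gv <- g[pos]
  bg <- rep(Inf, n); mx <- rep(-Inf, n)
  bmin <- tapply(gv, li, min); bmax <- tapply(gv, li, max)
  bg[as.integer(names(bmin))] <- bmin
  mx[as.integer(names(bmax))] <- bmax

  for (cid in unique(comp)) {
    pix <- idx[comp == cid]
    labs <- unique(nucleus_mask[pix])
    if (length(labs) != 1L || labs == 0L) next  # not strictly inside one
    lab <- labs
    v <- g[pix[1L]]
    height <- v - bg[lab]
    if (height > params$maxima_prominence * (mx[lab] - bg[lab]) &&
        height > params$min_abs_prominence)
      counts[lab] <- counts[lab] + 1L
  }
  counts
}

#' Area-corrected foci (cfoci)
#'
#' Normalizes each nucleus's focus count by the ratio of the treatment-group
#' mean nucleus area to the individual nucleus area:
#' `cfoci_i = foci_i * mean_area / area_i`. This removes the sampling bias by
#' which larger nuclear cross-sections collect more foci. Excluded nuclei
#' (if an `included` column is present) do not enter the group mean and get
#' `cfoci = 0` (not evaluated).
#'
#' @param records Nucleus record data frame with `area_um2` and `foci_count`
#'   columns (and optionally `included`).
#' @param mean_area Group mean area in square micrometres; default is the
#'   mean area of the included nuclei in `records`.
#' @return `records` with a `cfoci` column; the mean area used is attached as
#'   `attr(, "mean_area")`.
#' @export
compute_cfoci <- function(records, mean_area = NULL) {
  stopifnot(is.data.frame(records),
            all(c("area_um2", "foci_count") %in% names(records)))
  inc <- if ("included" %in% names(records)) records$included
         else rep(TRUE, nrow(records))
  if (any(records$area_um2[inc] <= 0))
    stop("non-positive nucleus area: cfoci undefined", call. = FALSE)
  if (is.null(mean_area)) {
    if (!any(inc)) stop("no included nuclei to define the group mean area",
                        call. = FALSE)
    mean_area <- mean(records$area_um2[inc])
  }
  stopifnot(mean_area > 0)
  records$cfoci <- ifelse(inc,
                          records$foci_count * mean_area / records$area_um2,
                          0)
  attr(records, "mean_area") <- mean_area
  records
}

#' Per-group summary of the focus assay
#'
#' @param records Nucleus records with `included`, `area_um2`, `foci_count`
#'   and `cfoci` columns.
#' @param group Group label (single value or per-record vector).
#' @return Data frame with one row per group: `group`, `n_included`,
#'   `mean_area`, `mean_foci`, `mean_cfoci`.
#' @export
group_summary <- function(records, group = "all") {
  stopifnot(is.data.frame(records))
  g <- rep_len(as.character(group), nrow(records))
  inc <- if ("included" %in% names(records)) records$included
         else rep(TRUE, nrow(records))
  spl <- split(seq_len(nrow(records)), g)
  out <- do.call(rbind, Map(function(gname, i) {
    i <- i[inc[i]]
    data.frame(group = gname,
               n_included = length(i),
               mean_area = if (length(i)) mean(records$area_um2[i]) else NA,
               mean_foci = if (length(i)) mean(records$foci_count[i]) else NA,
               mean_cfoci = if (length(i) && "cfoci" %in% names(records))
                 mean(records$cfoci[i]) else NA)
  }, names(spl), spl))
  rownames(out) <- NULL
  out
}

#' Binary gamma-H2AX positivity per nucleus
#'
#' For tissue where foci are not resolvable as distinct spots, nuclei are
#' scored positive or negative: a nucleus is positive when its summary signal
#' (mean, or an upper quantile) in the focus channel exceeds
#' `threshold x` slide background, the background being the median signal
#' outside all nuclei.
#'
#' @param gamma Focus-channel raster.
#' @param nucleus_mask Integer label raster.
#' @param threshold Multiple of the slide background a nucleus must exceed.
#' @param stat `"mean"` or `"quantile"` summary of the within-nucleus signal.
#' @param q Quantile used when `stat = "quantile"`.
#' @param records Optional records with `included`; the positive fraction is
#'   then computed over included nuclei only.
#' @return List with `positive` (named logical per label) and `fraction`
#'   (positive fraction among evaluated nuclei; `NA` with a warning when no
#'   nucleus is evaluated).
#' @export
score_binary_positivity <- function(gamma, nucleus_mask, threshold = 2,
                                    stat = c("mean", "quantile"), q = 0.9,
                                    records = NULL) {
  stat <- match.arg(stat)
  assert_raster(gamma)
  assert_same_shape(gamma, nucleus_mask)
  n <- max(nucleus_mask, 0L)
  eval_set <- seq_len(n)
  if (!is.null(records) && "included" %in% names(records))
    eval_set <- records$label[records$included]
  if (n == 0L || length(eval_set) == 0L) {
    warning("no nuclei to evaluate: positive fraction undefined")
    return(list(positive = stats::setNames(logical(n),
                                    as.character(seq_len(n))),
                fraction = NA_real_))
  }
  background <- stats::median(gamma[nucleus_mask == 0L])
  positive <- stats::setNames(rep(FALSE, n), as.character(seq_len(n)))
  for (lab in eval_set) {
    v <- gamma[nucleus_mask == lab]
    s <- if (stat == "mean") mean(v) else stats::quantile(v, q, names = FALSE)
    positive[lab] <- s > threshold * background
  }
  list(positive = positive,
       fraction = mean(positive[as.character(eval_set)]))
}

#' Run the whole focus assay on a pair of channels
#'
#' Convenience wrapper chaining [segment_nuclei()], [apply_inclusion()],
#' [count_foci()] and [compute_cfoci()]. Excluded nuclei are reported with
#' `foci_count = 0` (not evaluated).
#'
#' @param dapi,gamma Co-registered DAPI and focus-channel rasters.
#' @param params A [foci_params()] object.
#' @param exclusion_list Labels to exclude (e.g. visually flagged
#'   mitotic/apoptotic cells).
#' @param border_policy Passed to [apply_inclusion()].
#' @param split_touching Passed to [segment_nuclei()].
#' @return List with `records` (full nucleus table including `foci_count` and
#'   `cfoci`), `labels` (label raster) and `summary` (see [group_summary()]).
#' @examples
#' sc <- generate_foci_scene(6, foci_counts = 4, seed = 9)
#' res <- foci_pipeline(sc$dapi, sc$gamma,
#'                      params = foci_params(pixel_size = 0.25))
#' res$summary
#' @export
foci_pipeline <- function(dapi, gamma, params = foci_params(),
                          exclusion_list = integer(0),
                          border_policy = "drop", split_touching = TRUE) {
  seg <- segment_nuclei(dapi, pixel_size = params$pixel_size,
                        split_touching = split_touching,
                        blur_sigma = params$blur_sigma)
  rec <- apply_inclusion(seg$records, params, exclusion_list, border_policy)
  counts <- count_foci(gamma, seg$labels, params)
  rec$foci_count <- ifelse(rec$included,
                           as.integer(counts[as.character(rec$label)]), 0L)
  if (any(rec$included)) rec <- compute_cfoci(rec) else rec$cfoci <- numeric(nrow(rec))
  list(records = rec, labels = seg$labels,
       summary = group_summary(rec))
}
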