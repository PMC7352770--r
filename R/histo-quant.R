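# Stained-section morphology: color deconvolution in optical-density space,
# necrotic fraction from H&E, positive-area fractions (DAB/CD44, DAPI) and
# depth-profile assembly.

#' Color deconvolution of a brightfield RGB image
#'
#' Converts the image to optical density, `OD = -log10((I + eps) / white)`,
#' and decomposes each pixel's OD vector onto the supplied stain vectors by
#' least squares (Beer-Lambert mixing). Negative concentrations are clipped
#' at zero.
#'
#' @param rgb `h x w x 3` array with values in `[0, 1]`.
#' @param stain_matrix 3 x k matrix of unit-norm stain OD vectors (rows =
#'   RGB); must be of full column rank. See [stain_vectors_hed()].
#' @param white White reference intensity (default 1).
#' @param eps Small offset avoiding `log(0)` on saturated pixels.
#' @return `h x w x k` array of per-stain concentration rasters, dimnames on
#'   the third margin matching `colnames(stain_matrix)`.
#' @examples
#' sc <- generate_stain_scene(layout_halves(32, 32), mode = "he",
#'                            noise_sd = 0, seed = 1)
#' conc <- separate_stains(sc$rgb, sc$truth$stain_matrix)
#' dim(conc)
#' @export
separate_stains <- function(rgb, stain_matrix = stain_vectors_hed(),
                            white = 1, eps = 1e-6) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L, white > 0)
  check_stain_matrix(stain_matrix)
  if (all(rgb <= eps))
    stop("all-black image: optical densities unbounded", call. = FALSE)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]; k <- ncol(stain_matrix)
  od <- -log10((matrix(rgb, h * w, 3L) + eps) / white)
  # least squares onto the stain vectors: conc = (W'W)^-1 W' od
  conc <- od %*% stain_matrix %*% solve(crossprod(stain_matrix))
  conc <- pmax(conc, 0)
  out <- array(conc, dim = c(h, w, k))
  dimnames(out) <- list(NULL, NULL, colnames(stain_matrix))
  out
}

#' Reconstruct the optical-density image from separated stains
#'
#' Inverse of [separate_stains()] (up to the non-negativity clip); used to
#' check that unmixing followed by re-mixing reproduces the OD image on
#' noise-free scenes.
#'
#' @param concentrations `h x w x k` concentration array.
#' @param stain_matrix The 3 x k stain matrix used for separation.
#' @return `h x w x 3` optical-density array.
#' @export
remix_stains <- function(concentrations, stain_matrix) {
  d <- dim(concentrations)
  od <- matrix(concentrations, d[1] * d[2], d[3]) %*% t(stain_matrix)
  array(od, dim = c(d[1], d[2], 3L))
}

#' Necrotic fraction of an H&E-stained section
#'
#' Tissue is the set of pixels whose total optical density exceeds
#' `tissue_od_min`; necrosis is the subset with low hematoxylin and high
#' eosin concentration (eosinophilic, nucleus-poor "light pink" areas), after
#' morphological opening and closing to remove speckle. The fraction is
#' necrotic pixels over tissue pixels.
#'
#' @param he_rgb `h x w x 3` H&E image in `[0, 1]`.
#' @param stain_matrix 3 x 2 hematoxylin/eosin matrix.
#' @param tissue_od_min Total-OD threshold separating tissue from background.
#' @param hematoxylin_max Hematoxylin concentration below which a tissue
#'   pixel can be called necrotic.
#' @param eosin_min Eosin concentration above which it can be called
#'   necrotic.
#' @param smooth_radius Disc radius (px) of the opening/closing; 0 disables.
#' @return List with `fraction` (`NA` with a warning when the image contains
#'   no tissue), `tissue_mask` and `necrosis_mask` (logical matrices).
#' @examples
#' sc <- generate_stain_scene(layout_halves(64, 64), mode = "he", seed = 4)
#' necrotic_fraction(sc$rgb)$fraction
#' @export
necrotic_fraction <- function(he_rgb,
                              stain_matrix =
                                stain_vectors_hed()[, c("hematoxylin",
                                                        "eosin")],
                              tissue_od_min = 0.15,
                              hematoxylin_max = 0.45,
                              eosin_min = 0.40,
                              smooth_radius = 2L) {
  conc <- separate_stains(he_rgb, stain_matrix)
  od_total <- -log10(pmax(apply(he_rgb, c(1, 2), mean), 1e-6))
  tissue <- od_total > tissue_od_min
  if (!any(tissue)) {
    warning("no tissue detected: necrotic fraction undefined")
    return(list(fraction = NA_real_, tissue_mask = tissue,
                necrosis_mask = tissue))
  }
  hema <- conc[, , "hematoxylin"]
  eos <- conc[, , "eosin"]
  necro <- tissue & (hema < hematoxylin_max) & (eos > eosin_min)
  if (smooth_radius > 0) {
    brush <- EBImage::makeBrush(2L * smooth_radius + 1L, shape = "disc")
    necro <- ebi_matrix(EBImage::closing(
      EBImage::opening(as_ebimage(necro * 1), brush), brush)) > 0.5
    necro <- necro & tissue
  }
  list(fraction = sum(necro) / sum(tissue),
       tissue_mask = tissue, necrosis_mask = necro)
}

#' Positive-area fraction of a stain or marker
#'
#' Fraction of tissue pixels whose concentration (or fluorescence intensity)
#' exceeds a threshold; the common operator behind DAB/CD44-positive area and
#' DAPI-positive area.
#'
#' @param stain_raster Concentration or intensity matrix.
#' @param tissue_mask Logical matrix of tissue pixels, co-registered.
#' @param threshold Concentration threshold; pixels strictly above it count
#'   as positive.
#' @return Positive fraction in `[0, 1]`.
#' @export
positive_area_fraction <- function(stain_raster, tissue_mask, threshold) {
  assert_same_shape(stain_raster, tissue_mask)
  if (!any(tissue_mask))
    stop("empty tissue mask: positive fraction undefined", call. = FALSE)
  sum(stain_raster[tissue_mask] > threshold) / sum(tissue_mask)
}

#' Assemble an ordered depth profile from per-slice morphology results
#'
#' Slices are ordered by their index (the cutting order from the skin-side
#' surface toward the muscle); depth is `(rank - 1) x slice_thickness`, i.e.
#' the first slice sits at depth 0. Input row order is irrelevant.
#'
#' @param per_slice Data frame with a `slice` column (unique orderable ids)
#'   and one column per morphology measure.
#' @param slice_thickness Slice thickness in micrometres (500 for tumor
#'   slices).
#' @return The input rows sorted by slice with a `depth` column prepended
#'   after `slice`; class `"slice_morphology"`.
#' @export
build_depth_profile <- function(per_slice, slice_thickness = 500) {
  stopifnot(is.data.frame(per_slice), "slice" %in% names(per_slice),
            slice_thickness > 0)
  if (anyDuplicated(per_slice$slice))
    stop("duplicate slice indices", call. = FALSE)
  out <- per_slice[order(per_slice$slice), , drop = FALSE]
  rownames(out) <- NULL
  depth <- (seq_len(nrow(out)) - 1) * slice_thickness
  out <- cbind(out[, "slice", drop = FALSE], depth = depth,
               out[, setdiff(names(out), "slice"), drop = FALSE])
  class(out) <- c("slice_morphology", "data.frame")
  out
}
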