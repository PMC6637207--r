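#' Construct a dual-channel single-cell image
#'
#' Container for co-registered SiR-actin (`sa`), phalloidin (`ph`) and
#' nuclear (`nuc`) channels of one field.
#'
#' @param sa,ph,nuc Numeric matrices of identical dimensions with
#'   non-negative intensities.
#' @param pixel_size Physical pixel size (length per pixel), metadata
#'   only.
#' @return A `dual_channel_image` object.
#' @export
dual_channel_image <- function(sa, ph, nuc, pixel_size = 1) {
  stopifnot(is.matrix(sa), is.matrix(ph), is.matrix(nuc))
  if (!identical(dim(sa), dim(ph)) || !identical(dim(sa), dim(nuc)))
    stop("channel dimensions differ")
  if (min(sa) < 0 || min(ph) < 0 || min(nuc) < 0)
    stop("intensities must be non-negative")
  structure(list(sa = sa, ph = ph, nuc = nuc, pixel_size = pixel_size),
            class = "dual_channel_image")
}

empty_segmentation <- function(dims) {
  structure(list(nuclei_labels = matrix(0L, dims[1], dims[2]),
                 cell_labels = matrix(0L, dims[1], dims[2]),
                 n_cells = 0L, border_excluded = 0L),
            class = "segmentation_result")
}

border_labels <- function(lab) {
  setdiff(unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])), 0)
}

relabel_consecutive <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

#' Nuclei-seeded segmentation of dual-stained cells
#'
#' Reconstructs a CellProfiler-style two-stage recipe: nuclei are
#' detected on the nuclear channel (Otsu threshold, hole filling,
#' connected components, small-object removal) and serve as seeds; the
#' cytoskeletal mask is a global Otsu threshold of the summed SA +
#' phalloidin signal; cell bodies are then assigned by seeded region
#' propagation of the nuclei labels within the cytoskeletal mask, which
#' splits touching cells between their nuclei. Cells touching the image
#' border are excluded and counted.
#'
#' @param img A `dual_channel_image`.
#' @param min_nucleus_area Smallest accepted nucleus (pixels, default 15).
#' @return A `segmentation_result` with `nuclei_labels`, `cell_labels`
#'   (consecutive positive integers, 0 = background), `n_cells`,
#'   `border_excluded`. A field with no detectable nuclei yields an empty
#'   result with `n_cells = 0`.
#' @export
segment_cells <- function(img, min_nucleus_area = 15) {
  stopifnot(inherits(img, "dual_channel_image"))
  dims <- dim(img$nuc)

  nmax <- max(img$nuc)
  if (nmax <= 0 || diff(range(img$nuc)) == 0) return(empty_segmentation(dims))
  nscaled <- img$nuc / nmax
  nthr <- EBImage::otsu(EBImage::Image(nscaled))
  nmask <- nscaled > nthr
  if (!any(nmask)) return(empty_segmentation(dims))
  nmask <- EBImage::fillHull(EBImage::Image(nmask))
  nlab <- EBImage::bwlabel(nmask)
  sizes <- table(as.vector(EBImage::imageData(nlab)))
  small <- as.integer(names(sizes)[as.integer(names(sizes)) > 0 &
                                     sizes < min_nucleus_area])
  nlab <- EBImage::imageData(nlab)
  if (length(small)) nlab[nlab %in% small] <- 0L
  if (!any(nlab > 0)) return(empty_segmentation(dims))

  combined <- img$sa + img$ph
  cmax <- max(combined)
  if (cmax <= 0 || diff(range(combined)) == 0) return(empty_segmentation(dims))
  cscaled <- combined / cmax
  cthr <- EBImage::otsu(EBImage::Image(cscaled))
  cmask <- cscaled > cthr
  cmask <- cmask | nlab > 0   # seeds always inside their cell body
  cmask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(cmask))) > 0

  clab <- EBImage::propagate(EBImage::Image(cscaled),
                             seeds = EBImage::Image(nlab),
                             mask = cmask, lambda = 1e-4)
  clab <- EBImage::imageData(clab)
  storage.mode(clab) <- "integer"

  drop <- border_labels(clab)
  if (length(drop)) {
    clab[clab %in% drop] <- 0L
    nlab[nlab %in% drop] <- 0L
  }
  clab <- relabel_consecutive(clab)
  structure(list(nuclei_labels = nlab, cell_labels = clab,
                 n_cells = length(setdiff(unique(as.vector(clab)), 0)),
                 border_excluded = length(drop)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d cells (%d excluded at border)\n",
              x$n_cells, x$border_excluded))
  invisible(x)
}
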