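#' The versioned 41-descriptor set
#'
#' Names of the single-cell descriptor set: 9 shape, 3 intensity
#' statistics per stain channel (SiR-actin `sa`, phalloidin `ph`), and 13
#' co-occurrence texture statistics per stain channel. The exact
#' composition is a documented reconstruction of a shape / intensity /
#' Haralick feature panel and is versioned so downstream reports can
#' record which panel produced them.
#'
#' @return Character vector of 41 feature names, with attribute
#'   `version`.
#' @export
feature_names <- function() {
  shape <- c("area", "perimeter", "eccentricity", "solidity", "extent",
             "major_axis_length", "minor_axis_length", "form_factor",
             "compactness")
  intens <- as.vector(outer(c("sa", "ph"),
                            c("mean_intensity", "integrated_intensity",
                              "std_intensity"),
                            function(ch, s) paste(ch, s, sep = "_")))
  har <- as.vector(t(outer(c("sa", "ph"), haralick_names(),
                           function(ch, s) paste(ch, "haralick", s, sep = "_"))))
  structure(c(shape, sort(intens), har), version = "sp-41-v1")
}

# Shoelace area of the convex hull of the pixel corner points.
convex_hull_area <- function(rows, cols) {
  pr <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  pc <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  h <- grDevices::chull(pc, pr)
  if (length(h) < 3) return(0)
  xc <- pc[h]; yc <- pr[h]
  abs(sum(xc * c(yc[-1], yc[1]) - c(xc[-1], xc[1]) * yc)) / 2
}

#' Shape descriptors of a binary region
#'
#' Computes the 9 shape features of a segmented cell from its pixel set:
#' area (pixel count), perimeter (count of exposed 4-connected pixel
#' faces), eccentricity and ellipse axis lengths from the second central
#' moments of the pixel coordinates (axes = 4 sqrt(eigenvalue), the
#' equivalent-ellipse convention; eccentricity 0 for isotropic regions
#' such as squares), solidity (area over convex-hull area of the pixel
#' corners), extent (area over bounding-box area), form factor
#' `4 pi A / P^2` and its reciprocal-style compactness `P^2 / (4 pi A)`.
#'
#' @param mask Logical matrix marking the region.
#' @return Named numeric vector of the 9 shape features.
#' @export
shape_features <- function(mask) {
  stopifnot(is.matrix(mask) || is.array(mask))
  idx <- which(mask, arr.ind = TRUE)
  a <- nrow(idx)
  if (a == 0) stop("empty region")
  rows <- idx[, 1]; cols <- idx[, 2]

  # exposed faces: a face is exposed if the 4-neighbour is outside
  padded <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  per <- 0
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- padded[cbind(rows + 1 + d[1], cols + 1 + d[2])]
    per <- per + sum(!nb)
  }

  mur <- mean(rows); muc <- mean(cols)
  crr <- mean((rows - mur)^2); ccc <- mean((cols - muc)^2)
  crc <- mean((rows - mur) * (cols - muc))
  tr <- crr + ccc; det2 <- crr * ccc - crc^2
  disc <- sqrt(max(0, (tr / 2)^2 - det2))
  l1 <- tr / 2 + disc; l2 <- max(0, tr / 2 - disc)
  ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0

  hull <- convex_hull_area(rows, cols)
  solidity <- if (hull > 0) min(1, a / hull) else 1
  bbox <- (diff(range(rows)) + 1) * (diff(range(cols)) + 1)
  ff <- if (per > 0) 4 * pi * a / per^2 else 1
  cp <- if (per > 0) per^2 / (4 * pi * a) else 1

  c(area = a, perimeter = per, eccentricity = ecc, solidity = solidity,
    extent = a / bbox, major_axis_length = 4 * sqrt(l1),
    minor_axis_length = 4 * sqrt(l2), form_factor = ff, compactness = cp)
}

intensity_features <- function(x, mask, prefix) {
  v <- x[mask]
  out <- c(mean(v), sum(v), if (length(v) > 1) stats::sd(v) else 0)
  names(out) <- paste(prefix, c("mean_intensity", "integrated_intensity",
                                "std_intensity"), sep = "_")
  out
}

#' Extract the 41 descriptors of one segmented cell
#'
#' Computes the full shape / intensity / texture vector for a single cell
#' of a dual-channel image. Texture statistics are computed on the cell's
#' bounding-box patch, min-max quantized within the cell mask to
#' `n_levels` gray levels, distance 1, averaged over the 4 standard
#' directions. Degenerate regions (too few pixels to form co-occurrence
#' pairs) yield `NULL` with a message, and are dropped by
#' [extract_all_features()].
#'
#' @param img A `dual_channel_image` (see [dual_channel_image()]).
#' @param seg A `segmentation_result` (see [segment_cells()]).
#' @param cell_id A label present in `seg$cell_labels`.
#' @param n_levels Gray levels for texture quantization (default 8).
#' @return Named numeric vector of 41 features, or `NULL` for a
#'   degenerate region.
#' @export
extract_features <- function(img, seg, cell_id, n_levels = 8) {
  stopifnot(inherits(img, "dual_channel_image"),
            inherits(seg, "segmentation_result"))
  mask <- seg$cell_labels == cell_id
  if (!any(mask)) stop("cell_id ", cell_id, " not present in segmentation")

  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  mcrop <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  sa <- img$sa[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  ph <- img$ph[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]

  sa_h <- haralick_features(sa, mcrop, n_levels = n_levels)
  ph_h <- haralick_features(ph, mcrop, n_levels = n_levels)
  if (anyNA(sa_h) || anyNA(ph_h)) {
    message("cell ", cell_id, " dropped: degenerate region, ",
            "texture undefined (", sum(mask), " px)")
    return(NULL)
  }
  names(sa_h) <- paste("sa", "haralick", names(sa_h), sep = "_")
  names(ph_h) <- paste("ph", "haralick", names(ph_h), sep = "_")

  out <- c(shape_features(mcrop),
           intensity_features(sa, mcrop, "sa"),
           intensity_features(ph, mcrop, "ph"),
           sa_h, ph_h)
  out[feature_names()]
}

#' Feature table for every segmented cell of an image
#'
#' @inheritParams extract_features
#' @param condition Optional condition label attached to every row.
#' @return Data frame with `cell_id`, optional `condition`, and the 41
#'   feature columns; degenerate cells are dropped.
#' @export
extract_all_features <- function(img, seg, condition = NULL, n_levels = 8) {
  ids <- setdiff(sort(unique(as.vector(seg$cell_labels))), 0)
  rows <- lapply(ids, function(id) {
    f <- extract_features(img, seg, id, n_levels = n_levels)
    if (is.null(f)) return(NULL)
    cbind(data.frame(cell_id = id), as.data.frame(as.list(f)))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- as.data.frame(matrix(numeric(0), 0, 42))
    names(out) <- c("cell_id", feature_names())
  } else out <- do.call(rbind, rows)
  if (!is.null(condition)) out <- cbind(data.frame(condition = condition), out)
  rownames(out) <- NULL
  out
}
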