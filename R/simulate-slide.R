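# Slide-level simulators: tissue-class label maps with blob-shaped epithelial
# islands in stroma, and cell point patterns whose marker-positive intensity
# depends on the signed distance to the epithelium-stroma boundary. These
# emulate the segmentation outputs of a digital image analysis platform
# (tissue classifier + nucleus/marker segmentation) so that the grid,
# interface-zone and indicator stages can be validated against known ground
# truth.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Simulate a tissue-class label map
#'
#' Generates a raster with `n_blobs` epithelial islands (unions of discs,
#' optionally with lobed boundary noise) embedded in stroma, with an optional
#' background border. This emulates an epithelium/stroma/background tissue
#' segmentation of a region containing curved epithelium-stroma interfaces.
#'
#' @param field_width_um,field_height_um Physical extent of the field.
#' @param pixel_size_um Raster resolution (default 2; a diagnostic-scanner
#'   resolution of 0.5 is supported but quadratically more expensive).
#' @param n_blobs Number of epithelial islands (>= 1).
#' @param blob_radius_um Nominal disc radius.
#' @param radius_jitter_um Uniform jitter applied to each disc radius.
#' @param n_lobes Discs per blob; values > 1 add boundary lobes that make the
#'   interface irregular (lobe centers within half a radius of the blob
#'   center, lobe radii 40-80% of the blob radius).
#' @param background_border_um Width of a background/debris frame around the
#'   field (0 for none).
#' @param seed Integer seed; identical seed and configuration reproduce the
#'   raster bit for bit.
#' @return A [tissue_map()].
#' @export
#' @examples
#' tm <- simulate_tissue_map(2000, 2000, pixel_size_um = 4, n_blobs = 1,
#'                           blob_radius_um = 500, seed = 1)
simulate_tissue_map <- function(field_width_um, field_height_um,
                                pixel_size_um = 2, n_blobs = 3,
                                blob_radius_um = 300, radius_jitter_um = 0,
                                n_lobes = 1, background_border_um = 0,
                                seed = NULL) {
  if (field_width_um <= 0 || field_height_um <= 0 || pixel_size_um <= 0) {
    abort("field extent and pixel size must be positive.")
  }
  if (n_blobs < 1) abort("`n_blobs` must be >= 1.")
  max_r <- blob_radius_um + radius_jitter_um
  if (2 * max_r >= min(field_width_um, field_height_um)) {
    abort("blob diameter exceeds the field; reduce `blob_radius_um`.")
  }
  with_seed(seed, {
    nc <- ceiling(field_width_um / pixel_size_um)
    nr <- ceiling(field_height_um / pixel_size_um)
    xs <- (seq_len(nc) - 0.5) * pixel_size_um
    ys <- (seq_len(nr) - 0.5) * pixel_size_um
    epi <- matrix(FALSE, nr, nc)
    for (b in seq_len(n_blobs)) {
      r_b <- blob_radius_um + runif(1, -radius_jitter_um, radius_jitter_um)
      cx <- runif(1, max_r, field_width_um - max_r)
      cy <- runif(1, max_r, field_height_um - max_r)
      discs <- list(c(cx, cy, r_b))
      if (n_lobes > 1) {
        for (l in seq_len(n_lobes - 1)) {
          ang <- runif(1, 0, 2 * pi)
          d <- runif(1, 0, r_b / 2)
          discs <- c(discs, list(c(cx + d * cos(ang), cy + d * sin(ang),
                                   r_b * runif(1, 0.4, 0.8))))
        }
      }
      for (dsc in discs) {
        dx2 <- (xs - dsc[1])^2
        dy2 <- (ys - dsc[2])^2
        epi <- epi | (outer(dy2, dx2, `+`) <= dsc[3]^2)
      }
    }
    labels <- matrix(2L, nr, nc)
    labels[epi] <- 1L
    if (background_border_um > 0) {
      bpx <- round(background_border_um / pixel_size_um)
      if (bpx > 0) {
        labels[seq_len(min(bpx, nr)), ] <- 0L
        labels[seq(max(1, nr - bpx + 1), nr), ] <- 0L
        labels[, seq_len(min(bpx, nc))] <- 0L
        labels[, seq(max(1, nc - bpx + 1), nc)] <- 0L
      }
    }
    tissue_map(labels, pixel_size_um)
  })
}

#' Signed distance to the epithelium-stroma boundary
#'
#' Euclidean distance transform of the label raster: positive inside
#' epithelium (distance to the nearest non-epithelium pixel), negative in
#' stroma/background (distance to the nearest epithelium pixel), in
#' micrometers. The sign convention matches the interface-zone ranks
#' (positive into epithelium).
#'
#' @param tissue A [tissue_map()].
#' @return A numeric matrix of signed distances, same shape as the raster.
#' @export
signed_interface_distance <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_map"))
  epi <- tissue$labels == 1L
  if (!any(epi) || all(epi)) {
    abort("signed distance requires both epithelium and non-epithelium pixels.")
  }
  d_in <- EBImage::distmap(matrix(as.numeric(epi), nrow(epi)))
  d_out <- EBImage::distmap(matrix(as.numeric(!epi), nrow(epi)))
  (ifelse(epi, as.numeric(d_in), -as.numeric(d_out))) * tissue$pixel_size_um
}

#' Simulate cell centroids with an interface density gradient
#'
#' Places marker-positive (CD8+) cells by an inhomogeneous Poisson process
#' whose intensity is a step function of the signed distance to the
#' epithelium-stroma boundary, in five bands: deep stroma, near stroma, the
#' edge band straddling the boundary, near epithelium and deep epithelium.
#' Marker-negative cells are placed homogeneously over tissue. No cells fall
#' on background pixels.
#'
#' @param tissue A [tissue_map()].
#' @param lambda Named numeric vector of CD8+ intensities in cells/mm^2 with
#'   entries `stroma_far`, `stroma_near`, `edge`, `epi_near`, `epi_far`.
#' @param band_width_um Width of each distance band (the edge band spans
#'   `[-band_width_um/2, band_width_um/2]` around the boundary).
#' @param background_negative_lambda Intensity of CD8- cells over tissue,
#'   cells/mm^2.
#' @param seed Integer seed.
#' @return A cell tibble (`x_um`, `y_um`, `cd8_positive`).
#' @export
simulate_cells <- function(tissue,
                           lambda = c(stroma_far = 200, stroma_near = 200,
                                      edge = 100, epi_near = 50, epi_far = 50),
                           band_width_um = 100,
                           background_negative_lambda = 500,
                           seed = NULL) {
  stopifnot(inherits(tissue, "tissue_map"))
  needed <- c("stroma_far", "stroma_near", "edge", "epi_near", "epi_far")
  if (!all(needed %in% names(lambda))) {
    abort(sprintf("`lambda` must name intensities %s", paste(needed, collapse = ", ")))
  }
  if (any(lambda < 0) || background_negative_lambda < 0) {
    abort("intensities must be >= 0.")
  }
  sdist <- signed_interface_distance(tissue)
  px <- tissue$pixel_size_um
  tissue_px <- tissue$labels != 0L
  bw <- band_width_um
  band <- matrix(NA_character_, nrow(sdist), ncol(sdist))
  band[tissue_px & sdist < -1.5 * bw] <- "stroma_far"
  band[tissue_px & sdist >= -1.5 * bw & sdist < -0.5 * bw] <- "stroma_near"
  band[tissue_px & sdist >= -0.5 * bw & sdist <= 0.5 * bw] <- "edge"
  band[tissue_px & sdist > 0.5 * bw & sdist <= 1.5 * bw] <- "epi_near"
  band[tissue_px & sdist > 1.5 * bw] <- "epi_far"

  with_seed(seed, {
    place_in_pixels <- function(idx, n) {
      pick <- idx[sample.int(length(idx), n, replace = TRUE)]
      rw <- (pick - 1L) %% nrow(sdist) + 1L
      cl <- (pick - 1L) %/% nrow(sdist) + 1L
      tibble(
        x_um = tissue$origin_um[[1]] + (cl - runif(n)) * px,
        y_um = tissue$origin_um[[2]] + (rw - runif(n)) * px
      )
    }
    parts <- list()
    for (b in needed) {
      idx <- which(band == b)
      if (length(idx) == 0 || lambda[[b]] == 0) next
      area_mm2 <- length(idx) * px^2 / 1e6
      n <- rpois(1, lambda[[b]] * area_mm2)
      if (n == 0) next
      parts[[b]] <- place_in_pixels(idx, n) |> mutate(cd8_positive = TRUE)
    }
    if (background_negative_lambda > 0) {
      idx <- which(tissue_px)
      if (length(idx) > 0) {
        n <- rpois(1, background_negative_lambda * length(idx) * px^2 / 1e6)
        if (n > 0) {
          parts[["negative"]] <- place_in_pixels(idx, n) |>
            mutate(cd8_positive = FALSE)
        }
      }
    }
    if (length(parts) == 0) {
      return(tibble(x_um = numeric(), y_um = numeric(), cd8_positive = logical()))
    }
    list_rbind(parts)
  })
}
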