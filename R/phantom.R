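#' Specification of a synthetic cell-image phantom
#'
#' Describes a single cell rendered into a 4-channel z-stack (actin, DAPI,
#' PCNT, POI) with known geometry and known intensity structure: a cortical
#' band of configurable enrichment of the protein of interest, a nucleus with
#' a configurable nuclear-to-cytoplasmic ratio, and punctate centrosome foci.
#' The generator is a pure function of the spec (including its seed), so every
#' downstream measurement can be checked against ground truth.
#'
#' Intensity structure of the POI channel: cytoplasm interior takes the base
#' level `poi_cyto`; the true cortical band takes `enrichment_fold *
#' poi_cyto`; the nucleus takes `nc_ratio * mean(cytoplasm)`, where cytoplasm
#' means the whole cell minus the nucleus (the convention used for N/C
#' quantification). Edges are crisp: no point-spread blur is simulated.
#'
#' @param image_size_px Square image side in pixels.
#' @param pixel_size_um Pixel size, micrometres.
#' @param cell_radius_um Radius of the cell body disk.
#' @param n_protrusions Number of protrusions (0 = rounded cell).
#' @param protrusion_length_um,protrusion_width_um Protrusion geometry.
#' @param nucleus_radius_um,nucleus_offset_um Nucleus disk radius and offset
#'   of its centre from the cell centre (along +x).
#' @param enrichment_fold Cortical enrichment fold E (> 0) of the POI: mean
#'   cortical-band intensity over mean interior-cytoplasm intensity.
#' @param nc_ratio Nuclear-to-cytoplasmic ratio rho (> 0) of the POI.
#' @param ring_thickness_um Width of the true cortical band.
#' @param centrosome_foci Data frame (or NULL for one default focus) with
#'   columns `x_um`, `y_um` (offsets from cell centre), `amplitude` (peak,
#'   in `[0, 1]` units) and `sigma_um`.
#' @param background Background intensity level.
#' @param poi_cyto Base cytoplasmic POI level.
#' @param n_z Number of z-planes; the central plane carries full signal.
#' @param noise Noise model: `list(type = "gaussian", sd_frac = ...)` with sd
#'   expressed as a fraction of the POI signal amplitude, or
#'   `list(type = "poisson", photons = ...)` for shot noise at a mean photon
#'   count of `photons` per unit intensity, or `NULL` for noiseless output.
#' @param seed Integer seed; fixes the output exactly.
#' @return An object of class `cell_phantom_spec`.
#' @export
cell_phantom_spec <- function(image_size_px = 160, pixel_size_um = 0.25,
                              cell_radius_um = 12, n_protrusions = 0,
                              protrusion_length_um = 6, protrusion_width_um = 2.5,
                              nucleus_radius_um = 5, nucleus_offset_um = 0,
                              enrichment_fold = 1, nc_ratio = 1,
                              ring_thickness_um = 2, centrosome_foci = NULL,
                              background = 0.03, poi_cyto = 0.2, n_z = 3,
                              noise = list(type = "gaussian", sd_frac = 0.05),
                              seed = 1L) {
  if (enrichment_fold <= 0) stop("cell_phantom_spec: enrichment_fold must be > 0")
  if (nc_ratio <= 0) stop("cell_phantom_spec: nc_ratio must be > 0")
  if (nucleus_offset_um + nucleus_radius_um >= cell_radius_um - ring_thickness_um)
    stop("cell_phantom_spec: nucleus must fit inside the cell interior, ",
         "clear of the cortical band")
  half_um <- image_size_px * pixel_size_um / 2
  if (cell_radius_um + (n_protrusions > 0) * protrusion_length_um >= half_um)
    stop("cell_phantom_spec: cell (with protrusions) does not fit in the image")
  if (enrichment_fold * poi_cyto + background > 1)
    stop("cell_phantom_spec: enrichment_fold * poi_cyto exceeds the [0, 1] range")
  if (!is.null(noise) && !noise$type %in% c("gaussian", "poisson"))
    stop("cell_phantom_spec: unknown noise type")
  spec <- as.list(environment())
  if (is.null(centrosome_foci))
    spec$centrosome_foci <- data.frame(
      x_um = nucleus_offset_um + nucleus_radius_um + 1, y_um = 0,
      amplitude = 0.7, sigma_um = 0.5)
  structure(spec, class = "cell_phantom_spec")
}

#' Render a cell phantom and its ground truth
#'
#' @param spec A [cell_phantom_spec()].
#' @return List with `stack` (an [image_stack()] with channels
#'   `actin, dapi, pcnt, poi`) and `truth`, a list carrying the true `cell`,
#'   `nucleus`, `ring` and `centrosome` masks, the true `enrichment_fold` and
#'   `nc_ratio`, and the generating `spec`. The true ring is the set of cell
#'   pixels within the rasterized ring thickness of the cell outline —
#'   identical to [cortical_ring()] applied to the true cell mask.
#' @export
make_cell_image <- function(spec) {
  stopifnot(inherits(spec, "cell_phantom_spec"))
  n <- spec$image_size_px
  px <- spec$pixel_size_um
  c_px <- floor(n / 2) + 1     # integer centre pixel
  yy <- matrix(seq_len(n) - c_px, n, n)
  xx <- t(yy)

  cell <- (xx^2 + yy^2) * px^2 <= spec$cell_radius_um^2
  prot <- matrix(FALSE, n, n)
  if (spec$n_protrusions > 0) {
    phase <- with_seed(spec$seed, stats::runif(1, 0, 2 * pi))
    ang <- phase + 2 * pi * (seq_len(spec$n_protrusions) - 1) / spec$n_protrusions
    reach <- spec$cell_radius_um + spec$protrusion_length_um
    for (a in ang) {
      u <- c(cos(a), sin(a))
      along <- (xx * u[1] + yy * u[2]) * px
      perp <- (-xx * u[2] + yy * u[1]) * px
      prot <- prot | (along >= 0 & along <= reach &
                      abs(perp) <= spec$protrusion_width_um / 2)
    }
  }
  cell <- cell | prot
  nuc_cx <- spec$nucleus_offset_um / px
  nucleus <- ((xx - nuc_cx)^2 + yy^2) * px^2 <= spec$nucleus_radius_um^2
  ring <- cortical_ring(cell, thickness_um = spec$ring_thickness_um,
                        pixel_size_um = px)
  if (any(ring & nucleus))
    stop("make_cell_image: nucleus overlaps the cortical band")

  interior <- cell & !ring & !nucleus
  cyto <- cell & !nucleus
  bg <- spec$background
  e_val <- spec$enrichment_fold * spec$poi_cyto
  mean_cyto <- (e_val * sum(ring) + spec$poi_cyto * sum(interior)) / sum(cyto)
  nuc_val <- spec$nc_ratio * mean_cyto

  poi <- matrix(bg, n, n)
  poi[interior] <- spec$poi_cyto
  poi[ring] <- e_val
  poi[nucleus] <- nuc_val

  actin <- matrix(bg, n, n)
  actin[cell] <- 0.35
  actin[ring | prot] <- 0.8

  dapi <- matrix(bg, n, n)
  dapi[nucleus] <- 0.8

  pcnt <- matrix(bg, n, n)
  cent_truth <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(spec$centrosome_foci))) {
    f <- spec$centrosome_foci[i, ]
    d2 <- ((xx - f$x_um / px)^2 + (yy - f$y_um / px)^2) * px^2
    pcnt <- pcnt + f$amplitude * exp(-d2 / (2 * f$sigma_um^2))
    cent_truth <- cent_truth | d2 <= (1.1774 * f$sigma_um)^2  # half-max radius
  }
  pcnt <- pmin(pcnt, 1)

  z_w <- z_profile(spec$n_z)
  arr <- array(0, dim = c(4, spec$n_z, n, n))
  tmpl <- list(actin, dapi, pcnt, poi)
  for (ch in 1:4) for (z in seq_len(spec$n_z))
    arr[ch, z, , ] <- bg + z_w[z] * (tmpl[[ch]] - bg)

  arr <- with_seed(spec$seed, add_noise(arr, spec$noise,
                                        amplitude = max(poi) - bg))
  stack <- image_stack(arr, px, c(actin = 1, dapi = 2, pcnt = 3, poi = 4))
  truth <- list(cell = cell, nucleus = nucleus, ring = ring,
                centrosome = cent_truth, enrichment_fold = spec$enrichment_fold,
                nc_ratio = spec$nc_ratio, spec = spec)
  list(stack = stack, truth = truth)
}

# Per-plane signal weights: the central plane carries the in-focus signal
# (weight 1, so a max projection returns the template exactly); flanking
# planes are attenuated.
z_profile <- function(n_z) {
  mid <- (n_z + 1) / 2
  w <- 0.6^abs(seq_len(n_z) - mid)
  w / max(w)
}

add_noise <- function(arr, noise, amplitude) {
  if (is.null(noise)) return(arr)
  if (noise$type == "gaussian") {
    if (noise$sd_frac <= 0) return(arr)
    arr <- arr + stats::rnorm(length(arr), sd = noise$sd_frac * amplitude)
    arr[arr < 0] <- 0
  } else if (noise$type == "poisson") {
    ph <- noise$photons
    arr[] <- stats::rpois(length(arr), lambda = pmax(arr, 0) * ph) / ph
  }
  arr
}
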