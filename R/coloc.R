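#' Parameters for synthetic two-channel colocalization images
#'
#' Describes a synthetic field of cells for nuclear-translocation analysis:
#' a DAPI-like channel with disk nuclei and a Cy3-like immunolabel channel
#' whose per-cell intensity is split between nucleus and cytoplasmic annulus
#' according to `nuclear_fraction`.
#'
#' @param image_shape Integer length-2, image size in pixels (rows, cols).
#' @param n_cells Number of cells to place (non-overlapping).
#' @param nucleus_radius Nucleus radius, pixels.
#' @param nuclear_fraction Fraction of per-cell immunolabel intensity inside
#'   the nucleus, in [0, 1].
#' @param background_sd Gaussian background noise SD, intensity units.
#' @return A list of class `coloc_image_params`.
#' @export
coloc_image_params <- function(image_shape = c(150, 180), n_cells = 30,
                               nucleus_radius = 6, nuclear_fraction = 0.2,
                               background_sd = 5) {
  ok <- length(image_shape) == 2 && all(image_shape >= 20) &&
    n_cells >= 1 && nucleus_radius >= 2 &&
    nuclear_fraction >= 0 && nuclear_fraction <= 1 && background_sd >= 0
  if (!ok) {
    abort("invalid colocalization image parameters",
          class = "wntwave_parameter_error")
  }
  structure(
    list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
         nucleus_radius = nucleus_radius, nuclear_fraction = nuclear_fraction,
         background_sd = background_sd),
    class = "coloc_image_params"
  )
}

#' Default treatment-group image presets
#'
#' Control cells keep most beta-catenin immunolabel in the cytoplasm
#' (nuclear fraction 0.2); treated cells translocate it to the nucleus
#' (nuclear fraction 0.75).
#'
#' @param group `"control"` or `"treated"`.
#' @param ... Overrides passed to [coloc_image_params()].
#' @return A `coloc_image_params` object.
#' @export
coloc_group_preset <- function(group = c("control", "treated"), ...) {
  group <- match.arg(group)
  f <- if (group == "control") 0.2 else 0.75
  coloc_image_params(nuclear_fraction = f, ...)
}

disk_pixels <- function(shape, cy, cx, r) {
  ys <- max(1, floor(cy - r)):min(shape[1], ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(shape[2], ceiling(cx + r))
  g <- expand.grid(y = ys, x = xs)
  g <- g[(g$y - cy)^2 + (g$x - cx)^2 <= r^2, ]
  cbind(g$y, g$x)
}

#' Simulate a two-channel image set with nucleus masks
#'
#' Nuclei are placed on a jittered grid so they never overlap. Each cell's
#' immunolabel intensity budget is split: `nuclear_fraction` spread uniformly
#' over the nucleus disk and the remainder over the cytoplasmic annulus
#' (radius 1-2 nucleus radii). Gaussian background noise is added to both
#' channels and clipped at zero.
#'
#' @param params A [coloc_image_params()] object (or one built by
#'   [coloc_group_preset()]).
#' @param group Group label carried into downstream records.
#' @param seed Integer seed.
#' @return A list of class `coloc_images`: `dapi` and `cy3` intensity
#'   matrices, `masks` (integer-labelled nuclei), `cells` tibble
#'   (`cell_id`, `y`, `x`), `group`, `params`.
#' @export
simulate_coloc_images <- function(params = coloc_image_params(),
                                  group = "control", seed = 1) {
  stopifnot(inherits(params, "coloc_image_params"))
  shape <- params$image_shape
  r <- params$nucleus_radius
  spacing <- ceiling(5 * r)
  rows <- floor(shape[1] / spacing)
  cols <- floor(shape[2] / spacing)
  if (rows * cols < params$n_cells) {
    abort("image too small to place nuclei without overlap",
          class = "wntwave_layout_error")
  }
  jitter_max <- max(0, spacing / 2 - 2 * r - 1)
  centers <- withr::with_seed(seed, {
    grid <- expand.grid(
      cy = spacing / 2 + spacing * (seq_len(rows) - 1),
      cx = spacing / 2 + spacing * (seq_len(cols) - 1)
    )
    grid <- grid[sample.int(nrow(grid), params$n_cells), ]
    grid$cy <- grid$cy + stats::runif(params$n_cells, -jitter_max, jitter_max)
    grid$cx <- grid$cx + stats::runif(params$n_cells, -jitter_max, jitter_max)
    grid
  })
  dapi <- matrix(0, shape[1], shape[2])
  cy3 <- matrix(0, shape[1], shape[2])
  masks <- matrix(0L, shape[1], shape[2])
  total_intensity <- 5000
  for (i in seq_len(params$n_cells)) {
    nuc <- disk_pixels(shape, centers$cy[i], centers$cx[i], r)
    cell <- disk_pixels(shape, centers$cy[i], centers$cx[i], 2 * r)
    ann <- cell[!paste(cell[, 1], cell[, 2]) %in% paste(nuc[, 1], nuc[, 2]), ,
                drop = FALSE]
    dapi[nuc] <- 200
    masks[nuc] <- i
    f <- params$nuclear_fraction
    if (nrow(nuc) > 0 && f > 0) {
      cy3[nuc] <- cy3[nuc] + f * total_intensity / nrow(nuc)
    }
    if (nrow(ann) > 0 && f < 1) {
      cy3[ann] <- cy3[ann] + (1 - f) * total_intensity / nrow(ann)
    }
  }
  if (params$background_sd > 0) {
    noise <- withr::with_seed(seed + 10000L, {
      list(d = matrix(rnorm(length(dapi), sd = params$background_sd),
                      shape[1], shape[2]),
           c = matrix(rnorm(length(cy3), sd = params$background_sd),
                      shape[1], shape[2]))
    })
    dapi <- pmax(dapi + noise$d, 0)
    cy3 <- pmax(cy3 + noise$c, 0)
  }
  structure(
    list(dapi = dapi, cy3 = cy3, masks = masks,
         cells = tibble(cell_id = seq_len(params$n_cells),
                        y = centers$cy, x = centers$cx),
         group = group, params = params),
    class = "coloc_images"
  )
}

#' Pearson colocalization coefficient over a pixel mask
#'
#' @param channel_a,channel_b Intensity matrices of identical dimensions.
#' @param mask Logical matrix (same dimensions) selecting the ROI pixels.
#' @return One-row tibble: `pearson_r`, `n_pixels`, `flag` (`"ok"` or
#'   `"constant_channel"`; the coefficient is undefined, and `NA`, when a
#'   channel is constant on the mask).
#' @export
pearson_coefficient <- function(channel_a, channel_b, mask) {
  if (!all(dim(channel_a) == dim(channel_b)) ||
      !all(dim(channel_a) == dim(mask))) {
    abort("channel and mask dimensions differ", class = "wntwave_input_error")
  }
  a <- channel_a[mask]
  b <- channel_b[mask]
  if (length(a) < 10) {
    abort("mask must contain >= 10 pixels", class = "wntwave_input_error")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(tibble(pearson_r = NA_real_, n_pixels = length(a),
                  flag = "constant_channel"))
  }
  tibble(pearson_r = cor(a, b), n_pixels = length(a), flag = "ok")
}

#' Per-cell Pearson colocalization records
#'
#' Computes one Pearson coefficient (immunolabel vs nuclear channel) per
#' labelled cell. In `"cell"` mode (default) the ROI is a whole-cell disk:
#' the nucleus mask dilated to twice its equivalent radius around the
#' nucleus centroid. In `"nucleus"` mode only the nucleus pixels are used.
#'
#' @param images A `coloc_images` object, or a list with `dapi` and `cy3`
#'   matrices.
#' @param masks Integer-labelled nucleus mask matrix (defaults to
#'   `images$masks`).
#' @param roi_mode `"cell"` or `"nucleus"`.
#' @param group Group label (defaults to `images$group`).
#' @return Tibble of records: `cell_id`, `group`, `pearson_r`, `n_pixels`,
#'   `flag`.
#' @export
per_cell_coloc <- function(images, masks = NULL, roi_mode = c("cell", "nucleus"),
                           group = NULL) {
  roi_mode <- match.arg(roi_mode)
  masks <- masks %||% images$masks
  group <- group %||% images$group %||% "unknown"
  dapi <- images$dapi
  cy3 <- images$cy3
  if (!all(dim(masks) == dim(dapi))) {
    abort("mask does not align with image", class = "wntwave_input_error")
  }
  labels <- sort(setdiff(unique(as.vector(masks)), 0L))
  purrr::map_dfr(labels, function(lb) {
    px <- which(masks == lb, arr.ind = TRUE)
    if (nrow(px) == 0) {
      warn(paste0("empty mask label skipped: ", lb))
      return(NULL)
    }
    roi <- matrix(FALSE, nrow(dapi), ncol(dapi))
    if (roi_mode == "nucleus") {
      roi[px] <- TRUE
    } else {
      cyx <- colMeans(px)
      r_eq <- sqrt(nrow(px) / pi)
      roi[disk_pixels(dim(dapi), cyx[1], cyx[2], 2 * r_eq)] <- TRUE
    }
    pc <- pearson_coefficient(cy3, dapi, roi)
    tibble(cell_id = lb, group = group, pearson_r = pc$pearson_r,
           n_pixels = pc$n_pixels, flag = pc$flag)
  })
}

#' Compare per-cell colocalization between two groups
#'
#' Two-sided Mann-Whitney test on the per-cell Pearson coefficients.
#'
#' @param records Tibble of [per_cell_coloc()] records (both groups).
#' @param group_a,group_b Group labels to compare.
#' @return One-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `u`,
#'   `p_value`, `method`.
#' @export
compare_coloc_groups <- function(records, group_a, group_b) {
  records <- as_tibble(records)
  a <- records$pearson_r[records$group == group_a & is.finite(records$pearson_r)]
  b <- records$pearson_r[records$group == group_b & is.finite(records$pearson_r)]
  if (length(a) < 3 || length(b) < 3) {
    abort("each group needs >= 3 records", class = "wntwave_input_error")
  }
  mw <- mann_whitney_u(a, b)
  tibble(group_a = group_a, group_b = group_b, n_a = mw$n_x, n_b = mw$n_y,
         u = mw$u, p_value = mw$p_value, method = mw$method)
}
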