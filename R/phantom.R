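# Digital breast phantoms: voxelized fat / fibroglandular / chest-wall
# (optionally lesion) label grids with per-label optical properties,
# emulating anthropomorphic breast phantoms by a thresholded smoothed
# random field.  Labels: 1 fat, 2 fibroglandular, 3 chest wall, 4 lesion.

.PHANTOM_LABELS <- c(fat = 1L, fibroglandular = 2L, chest_wall = 3L, lesion = 4L)

#' Voxel phantom container
#'
#' @param grid integer 3D array of labels (1 fat, 2 fibroglandular,
#'   3 chest wall, 4 lesion); z axis points into the tissue from the
#'   probe surface.
#' @param spacing voxel size, cm (isotropic).
#' @param label_props named list mapping label names to
#'   \code{optical_props}.
#' @param chest_depth measurement-time chest-wall depth below the surface, cm.
#' @param chest_tilt interface tilt, degrees.
#' @param provenance list of seeds / generation parameters.
#' @return object of class \code{voxel_phantom}.
#' @export
voxel_phantom <- function(grid, spacing, label_props,
                          chest_depth = NA_real_, chest_tilt = 0,
                          provenance = list()) {
  if (spacing <= 0) stop("spacing must be positive (cm)")
  labs <- sort(unique(as.vector(grid)))
  have <- .PHANTOM_LABELS[names(label_props)]
  if (!all(labs %in% have))
    stop("every label present in the grid needs optical properties")
  structure(list(grid = grid, spacing = spacing, label_props = label_props,
                 chest_depth = chest_depth, chest_tilt = chest_tilt,
                 provenance = provenance),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("voxel phantom: %d x %d x %d voxels at %.2f mm, chest depth %.2f cm\n",
              d[1], d[2], d[3], x$spacing * 10, x$chest_depth))
  fr <- table(factor(as.vector(x$grid), levels = .PHANTOM_LABELS,
                     labels = names(.PHANTOM_LABELS))) / length(x$grid)
  print(round(fr, 3))
  invisible(x)
}

# label grid -> mua / musp arrays
phantom_property_arrays <- function(phantom) {
  mua <- array(NA_real_, dim(phantom$grid))
  musp <- array(NA_real_, dim(phantom$grid))
  for (nm in names(phantom$label_props)) {
    lab <- .PHANTOM_LABELS[[nm]]
    sel <- phantom$grid == lab
    mua[sel] <- phantom$label_props[[nm]]$mua
    musp[sel] <- phantom$label_props[[nm]]$musp
  }
  if (any(is.na(mua))) stop("grid contains labels without optical properties")
  list(mua = mua, musp = musp)
}

# Trilinear upsampling of a coarse 3D array onto fine per-axis coordinates in
# [1, dim] index units, done as three successive matrix products.
interp3_linear <- function(coarse, fx, fy, fz) {
  axis_weights <- function(f, n) {
    i0 <- pmin(pmax(floor(f), 1), n - 1)
    w <- pmin(pmax(f - i0, 0), 1)
    M <- matrix(0, length(f), n)
    M[cbind(seq_along(f), i0)] <- 1 - w
    M[cbind(seq_along(f), i0 + 1)] <- w
    M
  }
  d <- dim(coarse)
  Wx <- axis_weights(fx, d[1]); Wy <- axis_weights(fy, d[2])
  Wz <- axis_weights(fz, d[3])
  a <- Wx %*% matrix(coarse, d[1], d[2] * d[3])          # nx x (d2 d3)
  a <- array(a, c(length(fx), d[2], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- Wy %*% matrix(a, d[2], length(fx) * d[3])
  a <- array(a, c(length(fy), length(fx), d[3]))
  a <- aperm(a, c(3, 2, 1))
  a <- Wz %*% matrix(a, d[3], length(fx) * length(fy))
  a <- array(a, c(length(fz), length(fx), length(fy)))
  aperm(a, c(2, 3, 1))
}

#' Generate a heterogeneous digital breast phantom
#'
#' Builds a labelled voxel grid (default 14 x 14 x 8 cm at 0.5 mm voxels)
#' with fibroglandular tissue carved out of the breast volume by
#' thresholding a smoothed Gaussian random field, so its spatial texture is
#' blobby and its realized volume fraction matches \code{fibro_fraction} to
#' within one voxel (rank-based threshold).  The chest wall fills all
#' voxels below the interface.  \code{chest_depth} is the measurement-time
#' (compressed) depth; in the uncompressed grid the interface sits at
#' \code{chest_depth * size_z / compressed_thickness} so that numerical
#' compression restores it.
#'
#' @param fibro_fraction target fibroglandular volume fraction (0.2 - 0.8).
#' @param chest_depth chest-wall depth after compression, cm (1.5 - 2.5).
#' @param seed RNG seed for the random field.
#' @param lesion optional list(center = c(x, y, z) cm, radius cm, mua, musp)
#'   describing a spherical inclusion (z measured in compressed units).
#' @param spacing voxel size, cm.
#' @param size_xy,size_z lateral / depth extent, cm.
#' @param compressed_thickness thickness after numerical compression, cm.
#' @param fat_props,fibro_props,chest_props per-label \code{optical_props}.
#' @param texture_scale correlation length of the fibroglandular blobs, cm.
#' @return a \code{voxel_phantom} (uncompressed; see
#'   [compress_and_downsample()]).
#' @export
generate_digital_phantom <- function(fibro_fraction, chest_depth, seed = 1,
                                     lesion = NULL, spacing = 0.05,
                                     size_xy = 14, size_z = 8,
                                     compressed_thickness = 5,
                                     fat_props = optical_props(0.02, 5),
                                     fibro_props = optical_props(0.04, 8),
                                     chest_props = optical_props(0.1, 7),
                                     texture_scale = 1.5) {
  if (fibro_fraction < 0.2 - 1e-9 || fibro_fraction > 0.8 + 1e-9)
    stop("fibro_fraction must lie in [0.2, 0.8]")
  if (chest_depth < 0.5 || chest_depth > compressed_thickness)
    stop("chest_depth outside the phantom")
  nxy <- round(size_xy / spacing)
  nz <- round(size_z / spacing)
  depth_uncompressed <- chest_depth * size_z / compressed_thickness
  n_breast_z <- min(nz, floor(depth_uncompressed / spacing + 1e-9))
  grid <- array(.PHANTOM_LABELS[["chest_wall"]], c(nxy, nxy, nz))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nc <- max(4L, ceiling(size_xy / texture_scale) + 1L)
  ncz <- max(4L, ceiling(size_z / texture_scale) + 1L)
  coarse <- array(stats::rnorm(nc * nc * ncz), c(nc, nc, ncz))
  fx <- seq(1, nc, length.out = nxy)
  fz <- seq(1, ncz, length.out = nz)
  field <- interp3_linear(coarse, fx, fx, fz)

  breast_field <- field[, , seq_len(n_breast_z)]
  nb <- length(breast_field)
  n_fibro <- round(fibro_fraction * nb)
  # rank threshold: exactly n_fibro voxels (ties are measure-zero)
  kth <- nb - n_fibro
  labels_breast <- array(.PHANTOM_LABELS[["fat"]], dim(breast_field))
  if (n_fibro > 0) {
    thr <- sort(as.vector(breast_field), partial = kth)[kth]
    labels_breast[breast_field > thr] <- .PHANTOM_LABELS[["fibroglandular"]]
  }
  grid[, , seq_len(n_breast_z)] <- labels_breast

  props <- list(fat = fat_props, fibroglandular = fibro_props,
                chest_wall = chest_props)
  if (!is.null(lesion)) {
    zc_scale <- size_z / compressed_thickness
    ctr <- lesion$center
    xc <- (seq_len(nxy) - 0.5) * spacing - size_xy / 2
    zc <- (seq_len(nz) - 0.5) * spacing
    dx2 <- outer((xc - ctr[1])^2, rep(1, nxy))
    dy2 <- outer(rep(1, nxy), (xc - ctr[2])^2)
    lz <- ctr[3] * zc_scale          # lesion depth in uncompressed units
    rz <- lesion$radius * zc_scale   # compression stretches z back
    inside_xy <- dx2 + dy2
    for (k in seq_len(nz)) {
      dz2 <- ((zc[k] - lz) / rz)^2
      if (dz2 <= 1) {
        sel <- inside_xy / lesion$radius^2 + dz2 <= 1
        gk <- grid[, , k]
        gk[sel] <- .PHANTOM_LABELS[["lesion"]]
        grid[, , k] <- gk
      }
    }
    if (!any(grid == .PHANTOM_LABELS[["lesion"]]))
      stop("lesion sphere lies outside the phantom grid")
    props$lesion <- optical_props(lesion$mua, lesion$musp)
  }
  voxel_phantom(grid, spacing, props,
                chest_depth = chest_depth, chest_tilt = 0,
                provenance = list(seed = seed,
                                  fibro_fraction = fibro_fraction,
                                  texture_scale = texture_scale,
                                  size_xy = size_xy, size_z = size_z,
                                  compressed_thickness = compressed_thickness))
}

#' Numerically compress and downsample a phantom
#'
#' Rescales the z axis to \code{target_thickness} by nearest-neighbour label
#' lookup (emulating compression by the hand-held probe) and then resamples
#' all axes to \code{target_spacing}, preserving the label set.
#'
#' @param p a \code{voxel_phantom}.
#' @param target_thickness compressed thickness, cm.
#' @param target_spacing output voxel size, cm.
#' @return a \code{voxel_phantom} on the coarser compressed grid.
#' @export
compress_and_downsample <- function(p, target_thickness = 5,
                                    target_spacing = 0.25) {
  stopifnot(inherits(p, "voxel_phantom"))
  d <- dim(p$grid)
  thick <- d[3] * p$spacing
  if (thick < target_thickness)
    stop("phantom thinner than the requested compressed thickness")
  # compression: compressed layer centre (j - 0.5) maps to source layer
  # (j - 0.5) * thick / target (both grids share the fine spacing)
  nz_c <- round(target_thickness / p$spacing)
  zsrc <- pmin(pmax(round((seq_len(nz_c) - 0.5) *
                            thick / target_thickness + 0.5), 1), d[3])
  compressed <- p$grid[, , zsrc, drop = FALSE]
  # downsample: nearest neighbour at the coarse voxel centres
  f <- target_spacing / p$spacing
  pick <- function(n_fine, n_coarse)
    pmin(pmax(round((seq_len(n_coarse) - 0.5) * f + 0.5), 1), n_fine)
  nx_c <- floor(d[1] / f); ny_c <- floor(d[2] / f)
  nzz <- floor(nz_c / f)
  out <- compressed[pick(d[1], nx_c), pick(d[2], ny_c), pick(nz_c, nzz),
                    drop = FALSE]
  voxel_phantom(out, target_spacing, p$label_props,
                chest_depth = p$chest_depth, chest_tilt = p$chest_tilt,
                provenance = c(p$provenance,
                               list(compressed_to = target_thickness,
                                    downsampled_to = target_spacing)))
}

#' Weighted-average ground truth for the breast tissue
#'
#' Volume-fraction-weighted mean of the per-label absorption and reduced
#' scattering over fat and fibroglandular voxels only; chest-wall and lesion
#' voxels are excluded.  This is the ground truth against which average
#' breast-tissue estimates are scored for heterogeneous phantoms.
#'
#' @param p a \code{voxel_phantom} with at least one breast-tissue voxel.
#' @return an \code{optical_props}.
#' @export
weighted_average_truth <- function(p) {
  stopifnot(inherits(p, "voxel_phantom"))
  n_fat <- sum(p$grid == .PHANTOM_LABELS[["fat"]])
  n_fib <- sum(p$grid == .PHANTOM_LABELS[["fibroglandular"]])
  if (n_fat + n_fib == 0) stop("phantom has no breast-tissue voxels")
  w <- c(n_fat, n_fib) / (n_fat + n_fib)
  grab <- function(nm, field) {
    pr <- p$label_props[[nm]]
    if (is.null(pr)) 0 else pr[[field]]
  }
  optical_props(
    w[1] * grab("fat", "mua") + w[2] * grab("fibroglandular", "mua"),
    w[1] * grab("fat", "musp") + w[2] * grab("fibroglandular", "musp"))
}

#' Write / read a voxel phantom as text files
#'
#' The label grid is stored run-length encoded (two-column CSV: label,
#' run length, in column-major voxel order) beside a JSON sidecar holding
#' the grid dimensions, voxel spacing, chest-wall geometry and the
#' label-to-properties map.
#'
#' @param p a \code{voxel_phantom}.
#' @param prefix path prefix; writes \code{<prefix>_labels.csv} and
#'   \code{<prefix>_meta.json}.
#' @return \code{phantom_from_files} returns the \code{voxel_phantom}.
#' @export
phantom_to_files <- function(p, prefix) {
  stopifnot(inherits(p, "voxel_phantom"))
  r <- rle(as.vector(p$grid))
  utils::write.csv(data.frame(label = r$values, run = r$lengths),
                   paste0(prefix, "_labels.csv"), row.names = FALSE)
  props <- lapply(p$label_props, function(x) list(mua = x$mua, musp = x$musp))
  jsonlite::write_json(list(dim = dim(p$grid), spacing = p$spacing,
                            chest_depth = p$chest_depth,
                            chest_tilt = p$chest_tilt,
                            label_props = props,
                            provenance = p$provenance),
                       paste0(prefix, "_meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname phantom_to_files
#' @export
phantom_from_files <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  r <- utils::read.csv(paste0(prefix, "_labels.csv"))
  grid <- array(inverse.rle(structure(list(lengths = r$run,
                                           values = as.integer(r$label)),
                                      class = "rle")),
                dim = meta$dim)
  props <- lapply(meta$label_props, function(x) optical_props(x$mua, x$musp))
  voxel_phantom(grid, meta$spacing, props,
                chest_depth = meta$chest_depth, chest_tilt = meta$chest_tilt,
                provenance = as.list(meta$provenance))
}
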