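# ---------------------------------------------------------------------------
# CT -> voxel phantom: load a DICOM CT series, optionally resample, and map
# HU to material indices and mass densities through a user conversion table.
# Internal units: mm and g/cm3 (DICOM LPS patient coordinates); the egsphant
# writer converts boundaries to cm per EGS convention.
# ---------------------------------------------------------------------------

#' Construct an image volume
#'
#' @param hu 3-D array of Hounsfield units, indexed `[x, y, z]`
#' @param spacing_mm voxel spacing, 3-vector (mm)
#' @param origin_mm patient coordinates of the center of voxel (1,1,1) (mm)
#' @return an `rtmc_volume`
#' @export
image_volume <- function(hu, spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(hu)) == 3, all(dim(hu) >= 1), all(spacing_mm > 0),
            length(spacing_mm) == 3, length(origin_mm) == 3)
  structure(list(hu = hu, dims = dim(hu), spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "rtmc_volume")
}

#' @export
print.rtmc_volume <- function(x, ...) {
  cat("<rtmc_volume>", paste(x$dims, collapse = "x"), "voxels,",
      paste(format(x$spacing_mm), collapse = "x"), "mm, HU range",
      paste(format(range(x$hu)), collapse = ".."), "\n")
  invisible(x)
}

#' Load a DICOM CT series from a directory
#'
#' Slices are sorted by the z component of ImagePositionPatient; stored pixel
#' values are mapped to HU via RescaleSlope/RescaleIntercept.  All slices
#' must belong to one series, share in-plane geometry, and be uniformly
#' spaced along z within 1%.
#'
#' @param directory directory containing the `.dcm` slices of one CT series
#' @return an `rtmc_volume`
#' @export
load_ct_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) abort(paste0("no DICOM files in ", directory))
  slices <- lapply(files, dcm_read)
  mods <- vapply(slices, function(s) dcm_get(s, "Modality", ""), character(1))
  if (!all(mods == "CT")) abort("directory contains non-CT DICOM files",
                                class = "rtmc_series_error")
  uids <- vapply(slices, function(s) dcm_get(s, "SeriesInstanceUID", ""), character(1))
  if (length(unique(uids)) != 1) {
    abort("mixed SeriesInstanceUID in CT directory", class = "rtmc_series_error")
  }
  z <- vapply(slices, function(s) dcm_get(s, "ImagePositionPatient")[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  if (anyDuplicated(z)) abort("duplicate slice positions", class = "rtmc_series_error")

  ps <- lapply(slices, function(s) dcm_get(s, "PixelSpacing"))
  if (!all(vapply(ps, function(p) isTRUE(all.equal(p, ps[[1]])), logical(1)))) {
    abort("non-uniform in-plane pixel spacing across slices", class = "rtmc_geometry_error")
  }
  nxy <- c(dcm_get(slices[[1]], "Columns"), dcm_get(slices[[1]], "Rows"))
  nz <- length(slices)
  if (nz > 1) {
    gaps <- diff(z)
    if ((max(gaps) - min(gaps)) > 0.01 * mean(gaps)) {
      abort(sprintf("non-uniform slice spacing: gaps %.4g..%.4g mm",
                    min(gaps), max(gaps)), class = "rtmc_geometry_error")
    }
    dz <- mean(gaps)
  } else {
    dz <- dcm_get(slices[[1]], "SliceThickness", 1)
  }
  hu <- array(0, dim = c(nxy[1], nxy[2], nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    bits <- dcm_get(s, "BitsAllocated", 16)
    if (bits != 16) abort("only 16-bit CT pixel data supported")
    signed <- identical(dcm_get(s, "PixelRepresentation", 0L), 1L)
    px <- readBin(dcm_get(s, "PixelData"), "integer",
                  n = nxy[1] * nxy[2], size = 2, signed = signed, endian = "little")
    slope <- dcm_get(s, "RescaleSlope", 1)
    inter <- dcm_get(s, "RescaleIntercept", 0)
    # PixelData is row-major (column fastest): fill [x, y]
    hu[, , k] <- matrix(px * slope + inter, nrow = nxy[1], ncol = nxy[2])
  }
  ipp <- dcm_get(slices[[1]], "ImagePositionPatient")
  # DICOM PixelSpacing is (row spacing, column spacing) = (dy, dx)
  image_volume(hu, spacing_mm = c(ps[[1]][2], ps[[1]][1], dz),
               origin_mm = c(ipp[1], ipp[2], z[1]))
}

# 1-D overlap weight matrix mapping n_old cells of width d_old onto cells of
# width d_new covering the same extent; rows sum to 1 (volume-weighted mean)
.overlap_weights <- function(n_old, d_old, d_new) {
  extent <- n_old * d_old
  n_new <- max(1L, as.integer(ceiling(extent / d_new - 1e-9)))
  W <- matrix(0, n_new, n_old)
  for (i in seq_len(n_new)) {
    a <- (i - 1) * d_new
    b <- min(i * d_new, extent)
    j0 <- max(1L, as.integer(floor(a / d_old - 1e-12)) + 1L)
    j1 <- min(n_old, as.integer(ceiling(b / d_old + 1e-12)))
    for (j in j0:j1) {
      ov <- max(0, min(b, j * d_old) - max(a, (j - 1) * d_old))
      W[i, j] <- ov
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

# nearest-neighbour index map for upsampling an axis
.nearest_index <- function(n_old, d_old, d_new) {
  extent <- n_old * d_old
  n_new <- max(1L, as.integer(ceiling(extent / d_new - 1e-9)))
  centers <- ((seq_len(n_new)) - 0.5) * d_new
  pmin(n_old, pmax(1L, as.integer(floor(centers / d_old)) + 1L))
}

#' Resample an image volume to a new voxel spacing
#'
#' Downsampling (coarser spacing) averages HU with volume weights: each
#' source voxel contributes in proportion to the volume fraction it occupies
#' in the target voxel.  Upsampling (finer spacing) replicates the nearest
#' source voxel.  The choice is made per axis, and the physical extent is
#' preserved to within one target voxel.
#'
#' @param vol an `rtmc_volume`
#' @param new_spacing_mm target spacing, 3-vector (mm)
#' @return an `rtmc_volume` on the new grid
#' @export
resample_volume <- function(vol, new_spacing_mm) {
  stopifnot(inherits(vol, "rtmc_volume"), length(new_spacing_mm) == 3)
  new_spacing_mm <- as.numeric(new_spacing_mm)
  if (any(new_spacing_mm <= 0)) abort("new spacing must be positive")
  extent <- vol$dims * vol$spacing_mm
  if (any(new_spacing_mm > extent + 1e-9)) {
    abort("requested spacing exceeds the volume extent", class = "rtmc_geometry_error")
  }
  if (isTRUE(all.equal(new_spacing_mm, vol$spacing_mm))) return(vol)

  hu <- vol$hu
  for (ax in 1:3) {
    d_old <- vol$spacing_mm[ax]; d_new <- new_spacing_mm[ax]
    n_old <- dim(hu)[ax]
    if (isTRUE(all.equal(d_old, d_new))) next
    if (d_new >= d_old) {
      W <- .overlap_weights(n_old, d_old, d_new)
      hu <- .apply_axis(hu, ax, function(M) W %*% M)
    } else {
      idx <- .nearest_index(n_old, d_old, d_new)
      hu <- .apply_axis(hu, ax, function(M) M[idx, , drop = FALSE])
    }
  }
  corner <- vol$origin_mm - vol$spacing_mm / 2
  image_volume(hu, new_spacing_mm, corner + new_spacing_mm / 2)
}

# apply f to a matrix whose rows run along axis ax
.apply_axis <- function(arr, ax, f) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  M <- matrix(aperm(arr, perm), nrow = d[ax])
  R <- f(M)
  out <- array(R, dim = c(nrow(R), d[setdiff(1:3, ax)]))
  aperm(out, order(perm))
}

#' HU conversion table
#'
#' @param material_bins data frame with columns `hu_low`, `hu_high`,
#'   `material_name`, `material_index`; bins must be contiguous,
#'   non-overlapping and ordered
#' @param density_breakpoints data frame with columns `hu`, `density_g_cm3`;
#'   strictly increasing in HU, nonnegative density
#' @return an `rtmc_hu_table`
#' @export
hu_table <- function(material_bins, density_breakpoints) {
  mb <- as.data.frame(material_bins)
  db <- as.data.frame(density_breakpoints)
  stopifnot(all(c("hu_low", "hu_high", "material_name", "material_index") %in% names(mb)),
            all(c("hu", "density_g_cm3") %in% names(db)))
  mb <- mb[order(mb$hu_low), ]
  if (any(mb$hu_high <= mb$hu_low)) abort("empty material bin")
  if (nrow(mb) > 1 && any(abs(mb$hu_low[-1] - mb$hu_high[-nrow(mb)]) > 1e-9)) {
    abort("material bins must be contiguous and non-overlapping")
  }
  if (any(diff(db$hu) <= 0)) abort("density breakpoints must be strictly increasing in HU")
  if (any(db$density_g_cm3 < 0)) abort("negative density breakpoint")
  structure(list(material_bins = mb, density_breakpoints = db),
            class = "rtmc_hu_table")
}

#' Default 4-material HU conversion table
#'
#' Air / lung / soft tissue / bone with conventional breakpoints; intended
#' for the synthetic fixtures and as a template for user-supplied tables.
#' @export
default_hu_table <- function() {
  hu_table(
    material_bins = data.frame(
      hu_low = c(-1100, -850, -150, 300),
      hu_high = c(-850, -150, 300, 3100),
      material_name = c("AIR", "LUNG", "TISSUE", "BONE"),
      material_index = 1:4),
    density_breakpoints = data.frame(
      hu = c(-1000, -800, -200, 0, 300, 1200, 3000),
      density_g_cm3 = c(0.0012, 0.26, 0.92, 1.0, 1.10, 1.76, 2.8)))
}

#' Read an HU conversion table from YAML or CSV
#'
#' YAML layout: top-level keys `materials` (list of `{hu_low, hu_high,
#' name, index}`) and `density` (list of `{hu, density_g_cm3}`).  CSV layout:
#' the two tables concatenated with a `kind` column (`material`/`density`).
#'
#' @param path file path (`.yaml`/`.yml` or `.csv`)
#' @return an `rtmc_hu_table`
#' @export
read_hu_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    mb <- bind_rows(lapply(y$materials, function(m)
      tibble(hu_low = m$hu_low, hu_high = m$hu_high,
             material_name = m$name, material_index = m$index)))
    db <- bind_rows(lapply(y$density, function(d)
      tibble(hu = d$hu, density_g_cm3 = d$density_g_cm3)))
    hu_table(mb, db)
  } else if (ext == "csv") {
    x <- utils::read.csv(path)
    hu_table(x[x$kind == "material",
               c("hu_low", "hu_high", "material_name", "material_index")],
             x[x$kind == "density", c("hu", "density_g_cm3")])
  } else {
    abort("conversion table must be .yaml/.yml or .csv")
  }
}

#' Convert an image volume to a voxel phantom
#'
#' Per voxel, the material is the bin containing its HU and the density is
#' the piecewise-linear interpolation of the density breakpoints at its HU,
#' clamped to the first/last breakpoint outside the tabulated range.
#'
#' @param vol an `rtmc_volume`
#' @param table an `rtmc_hu_table` (default [default_hu_table()])
#' @return an `rtmc_phantom` with fields `material` (index array), `density`
#'   (g/cm3), `material_names`, and grid geometry
#' @export
apply_conversion <- function(vol, table = default_hu_table()) {
  stopifnot(inherits(vol, "rtmc_volume"), inherits(table, "rtmc_hu_table"))
  mb <- table$material_bins; db <- table$density_breakpoints
  hu <- as.numeric(vol$hu)
  breaks <- c(mb$hu_low, mb$hu_high[nrow(mb)])
  bin <- findInterval(hu, breaks, rightmost.closed = TRUE)
  bad <- bin < 1 | bin > nrow(mb)
  if (any(bad)) {
    abort(sprintf("HU value %.6g falls in no material bin", hu[which(bad)[1]]),
          class = "rtmc_conversion_error")
  }
  material <- array(mb$material_index[bin], dim = vol$dims)
  dens <- approx(db$hu, db$density_g_cm3, xout = hu, rule = 2)$y
  density <- array(dens, dim = vol$dims)
  structure(list(material = material, density = density,
                 dims = vol$dims, spacing_mm = vol$spacing_mm,
                 origin_mm = vol$origin_mm,
                 material_names = setNames(mb$material_name, mb$material_index)),
            class = "rtmc_phantom")
}

#' @export
print.rtmc_phantom <- function(x, ...) {
  cat("<rtmc_phantom>", paste(x$dims, collapse = "x"), "voxels,",
      length(x$material_names), "materials, density",
      paste(format(range(x$density), digits = 4), collapse = ".."), "g/cm3\n")
  invisible(x)
}

#' Construct a voxel phantom directly
#' @param material integer index array; @param density g/cm3 array
#' @param spacing_mm,origin_mm grid geometry (mm)
#' @param material_names named character vector, names are indices
#' @export
voxel_phantom <- function(material, density, spacing_mm, origin_mm = c(0, 0, 0),
                          material_names = NULL) {
  stopifnot(identical(dim(material), dim(density)), all(density >= 0))
  idx <- sort(unique(as.integer(material)))
  if (is.null(material_names)) {
    material_names <- setNames(paste0("MAT", idx), idx)
  }
  if (!all(as.character(idx) %in% names(material_names))) {
    abort("every material index must appear in material_names")
  }
  structure(list(material = material, density = density, dims = dim(material),
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 material_names = material_names),
            class = "rtmc_phantom")
}

#' Total mass of a phantom (g)
#' @param phantom an `rtmc_phantom`
#' @export
phantom_mass_g <- function(phantom) {
  sum(phantom$density) * prod(phantom$spacing_mm / 10)
}
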