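# ---------------------------------------------------------------------------
# Voxel phantom writers/readers.
#
# egsphant: the EGS text layout (material count, names, dummy ESTEPE line,
# voxel counts, x/y/z boundary arrays in cm, per-slice single-character
# material maps, per-slice density blocks).
#
# PenVox: this package's documented ASCII dialect --
#   line 1: nx ny nz
#   line 2: dx dy dz            (cm)
#   line 3: ox oy oz            (mm, center of voxel (1,1,1))
#   line 4: nmat idx1:name1 ... idxN:nameN   (original indices preserved)
#   then nx*ny*nz lines "material_index density_g_cm3", x-fastest, then y,
#   then z.
# Both formats round-trip exactly for materials and to <=1e-6 relative for
# density.
# ---------------------------------------------------------------------------

# single-character medium codes: digits, letters, then other printable ASCII
.egs_codes <- strsplit(paste0(
  "123456789",
  "ABCDEFGHIJKLMNOPQRSTUVWXYZ",
  "abcdefghijklmnopqrstuvwxyz",
  "!#$%&()*+,-./:;<=>?@[]^_{|}~"), "")[[1]]

.phantom_media <- function(phantom) {
  idx <- sort(unique(as.integer(phantom$material)))
  list(idx = idx, names = unname(phantom$material_names[as.character(idx)]))
}

.fmt_num <- function(x) sprintf("%.8e", x)

#' Write a voxel phantom in egsphant format
#'
#' Boundaries are written in cm (EGS convention); densities in g/cm3.
#' Media are renumbered 1..N in ascending phantom-index order.
#'
#' @param phantom an `rtmc_phantom`
#' @param path output file
#' @export
write_egsphant <- function(phantom, path) {
  stopifnot(inherits(phantom, "rtmc_phantom"))
  if (any(phantom$density < 0)) abort("negative density in phantom")
  med <- .phantom_media(phantom)
  nmat <- length(med$idx)
  if (nmat > length(.egs_codes)) {
    abort(sprintf("%d materials exceed the single-character code space (%d)",
                  nmat, length(.egs_codes)), class = "rtmc_capacity_error")
  }
  code_of <- setNames(.egs_codes[seq_len(nmat)], med$idx)
  d <- phantom$dims; sp <- phantom$spacing_mm
  corner_cm <- (phantom$origin_mm - sp / 2) / 10
  bounds <- function(ax) .fmt_num(corner_cm[ax] + (0:d[ax]) * sp[ax] / 10)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", nmat), con)
  writeLines(med$names, con)
  writeLines(paste(rep("0.0", nmat), collapse = " "), con)  # dummy ESTEPE
  writeLines(sprintf("%d %d %d", d[1], d[2], d[3]), con)
  writeLines(paste(bounds(1), collapse = " "), con)
  writeLines(paste(bounds(2), collapse = " "), con)
  writeLines(paste(bounds(3), collapse = " "), con)
  codes <- array(code_of[as.character(phantom$material)], dim = d)
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      writeLines(paste(codes[, j, k], collapse = ""), con)
    }
    writeLines("", con)
  }
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      writeLines(paste(.fmt_num(phantom$density[, j, k]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_egsphant
#' @export
read_egsphant <- function(path) {
  lines <- readLines(path)
  p <- 1L
  nmat <- as.integer(lines[p]); p <- p + 1L
  nms <- lines[p:(p + nmat - 1L)]; p <- p + nmat
  p <- p + 1L  # ESTEPE dummy
  d <- as.integer(strsplit(trimws(lines[p]), "\\s+")[[1]]); p <- p + 1L
  xb <- as.numeric(strsplit(trimws(lines[p]), "\\s+")[[1]]); p <- p + 1L
  yb <- as.numeric(strsplit(trimws(lines[p]), "\\s+")[[1]]); p <- p + 1L
  zb <- as.numeric(strsplit(trimws(lines[p]), "\\s+")[[1]]); p <- p + 1L
  stopifnot(length(xb) == d[1] + 1, length(yb) == d[2] + 1, length(zb) == d[3] + 1)
  material <- array(0L, dim = d)
  code_idx <- setNames(seq_along(.egs_codes), .egs_codes)
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      material[, j, k] <- code_idx[strsplit(lines[p], "")[[1]]]
      p <- p + 1L
    }
    p <- p + 1L  # blank
  }
  density <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      density[, j, k] <- as.numeric(strsplit(trimws(lines[p]), "\\s+")[[1]])
      p <- p + 1L
    }
    p <- p + 1L
  }
  spacing_mm <- c(mean(diff(xb)), mean(diff(yb)), mean(diff(zb))) * 10
  origin_mm <- c(xb[1], yb[1], zb[1]) * 10 + spacing_mm / 2
  voxel_phantom(material, density, spacing_mm, origin_mm,
                material_names = setNames(nms, seq_len(nmat)))
}

#' Write a voxel phantom in the PenVox dialect
#'
#' See the format description at the top of this file's documentation;
#' records are `material_index density` per voxel, x-fastest.
#'
#' @param phantom an `rtmc_phantom`
#' @param path output file
#' @export
write_penvox <- function(phantom, path) {
  stopifnot(inherits(phantom, "rtmc_phantom"))
  if (any(phantom$density < 0)) abort("negative density in phantom")
  med <- .phantom_media(phantom)
  d <- phantom$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %d", d[1], d[2], d[3]), con)
  writeLines(paste(.fmt_num(phantom$spacing_mm / 10), collapse = " "), con)
  writeLines(paste(.fmt_num(phantom$origin_mm), collapse = " "), con)
  # original material indices are preserved: "nmat idx:name ..."
  writeLines(paste(c(length(med$idx),
                     sprintf("%d:%s", med$idx, med$names)), collapse = " "), con)
  writeLines(sprintf("%d %s", as.integer(phantom$material),
                     .fmt_num(phantom$density)), con)
  invisible(path)
}

#' @rdname write_penvox
#' @export
read_penvox <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  d <- as.integer(strsplit(trimws(readLines(con, 1)), "\\s+")[[1]])
  sp_cm <- as.numeric(strsplit(trimws(readLines(con, 1)), "\\s+")[[1]])
  orig <- as.numeric(strsplit(trimws(readLines(con, 1)), "\\s+")[[1]])
  hdr <- strsplit(trimws(readLines(con, 1)), "\\s+")[[1]]
  nmat <- as.integer(hdr[1])
  pairs <- strsplit(hdr[-1], ":")
  stopifnot(length(pairs) == nmat)
  idx <- vapply(pairs, function(p) as.integer(p[1]), integer(1))
  nms <- vapply(pairs, `[[`, character(1), 2)
  rec <- utils::read.table(con, col.names = c("mat", "density"),
                           colClasses = c("integer", "numeric"))
  nvox <- prod(d)
  if (nrow(rec) != nvox) abort("PenVox record count does not match dims")
  voxel_phantom(array(rec$mat, dim = d), array(rec$density, dim = d),
                spacing_mm = sp_cm * 10, origin_mm = orig,
                material_names = setNames(nms, idx))
}
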