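# ---------------------------------------------------------------------------
# Phase-space files, simplified IAEA-style dialect: a text header terminated
# by "$END_HEADER", then packed little-endian binary records.  The header
# declares the original-history and particle counts and the record layout;
# the default layout packs, per particle:
#   type (uint8), energy_mev, x_mm, y_mm, z_mm, u, v, w, weight (float32),
# 33 bytes per record.  Real IAEA files carry extra-long variables and a
# separate .IAEAheader; adapting the reader to them is an extension point.
# ---------------------------------------------------------------------------

.phsp_fields <- c("energy_mev", "x_mm", "y_mm", "z_mm", "u", "v", "w", "weight")

#' In-memory phase space
#'
#' @param records tibble/data frame with columns `type`, `energy_mev`,
#'   `x_mm`, `y_mm`, `z_mm`, `u`, `v`, `w`, `weight`
#' @param n_original_histories number of source histories that produced the
#'   particles
#' @return an `rtmc_phsp`
#' @export
phase_space <- function(records, n_original_histories) {
  records <- as_tibble(records)
  stopifnot(all(c("type", .phsp_fields) %in% names(records)),
            n_original_histories >= 0)
  nrm <- sqrt(records$u^2 + records$v^2 + records$w^2)
  if (nrow(records) > 0 && any(abs(nrm - 1) > 1e-5)) {
    abort("direction cosines are not unit-norm within 1e-5")
  }
  structure(list(records = records,
                 n_original_histories = as.numeric(n_original_histories),
                 n_particles = nrow(records),
                 record_layout = c("type", .phsp_fields)),
            class = "rtmc_phsp")
}

#' @export
print.rtmc_phsp <- function(x, ...) {
  cat("<rtmc_phsp>", x$n_particles, "particles from",
      format(x$n_original_histories), "original histories\n")
  invisible(x)
}

#' Write / read the phase-space dialect
#' @param phsp an `rtmc_phsp`; @param path file path
#' @export
write_phsp <- function(phsp, path) {
  stopifnot(inherits(phsp, "rtmc_phsp"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("$PHSP_DIALECT 1",
           sprintf("$N_ORIGINAL_HISTORIES %.0f", phsp$n_original_histories),
           sprintf("$N_PARTICLES %d", phsp$n_particles),
           paste("$RECORD_LAYOUT", paste(phsp$record_layout, collapse = " ")),
           "$END_HEADER")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  r <- phsp$records
  if (nrow(r) > 0) {
    buf <- raw(0)
    type_raw <- as.raw(r$type)
    flt <- matrix(0, nrow(r), length(.phsp_fields))
    for (j in seq_along(.phsp_fields)) flt[, j] <- r[[.phsp_fields[j]]]
    # interleave: 1 type byte + 8 float32 per record
    frow <- writeBin(as.numeric(t(flt)), raw(), size = 4, endian = "little")
    fmat <- matrix(frow, nrow = 32)
    rec <- rbind(matrix(type_raw, nrow = 1), matrix(as.raw(fmat), nrow = 32))
    writeBin(as.raw(rec), con)
  }
  invisible(path)
}

#' @rdname write_phsp
#' @export
read_phsp <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  # locate header terminator
  txt_end <- .find_phsp_header_end(buf)
  hdr <- strsplit(rawToChar(buf[seq_len(txt_end$hdr_len)]), "\n")[[1]]
  get <- function(key) {
    ln <- grep(paste0("^\\$", key, " "), hdr, value = TRUE)
    if (length(ln) == 0) abort(paste0("phase-space header missing $", key),
                               class = "rtmc_format_error")
    sub(paste0("^\\$", key, " "), "", ln[1])
  }
  n_orig <- as.numeric(get("N_ORIGINAL_HISTORIES"))
  n_part <- as.integer(get("N_PARTICLES"))
  layout <- strsplit(get("RECORD_LAYOUT"), "\\s+")[[1]]
  if (!identical(layout, c("type", .phsp_fields))) {
    abort(paste0("unsupported record layout: ", paste(layout, collapse = " ")),
          class = "rtmc_format_error")
  }
  body <- buf[(txt_end$body_start):length(buf)]
  if (length(body) != n_part * 33) {
    abort(sprintf("phase-space body has %d bytes where %d expected",
                  length(body), n_part * 33), class = "rtmc_format_error")
  }
  if (n_part == 0) {
    rec <- tibble(type = integer(0))
    for (f in .phsp_fields) rec[[f]] <- numeric(0)
    return(phase_space(rec, n_orig))
  }
  m <- matrix(body, nrow = 33)
  type <- as.integer(m[1, ])
  flt <- readBin(as.raw(m[-1, ]), "numeric", n = 8 * n_part, size = 4,
                 endian = "little")
  fm <- matrix(flt, nrow = 8)
  rec <- tibble(type = type)
  for (j in seq_along(.phsp_fields)) rec[[.phsp_fields[j]]] <- fm[j, ]
  phase_space(rec, n_orig)
}

.find_phsp_header_end <- function(buf) {
  marker <- charToRaw("$END_HEADER\n")
  limit <- min(length(buf), 4096L)
  for (i in seq_len(limit - length(marker) + 1L)) {
    if (identical(buf[i:(i + length(marker) - 1L)], marker)) {
      return(list(hdr_len = i + length(marker) - 1L,
                  body_start = i + length(marker)))
    }
  }
  abort("no $END_HEADER marker: not a phase-space file of this dialect",
        class = "rtmc_format_error")
}

#' Merge phase-space files
#'
#' Records are concatenated in input order; the merged header carries the
#' sum of original histories and of particle counts.  All inputs must share
#' the record layout.
#'
#' @param files phase-space files in this package's dialect
#' @param out optional output path
#' @return an `rtmc_phsp`
#' @export
merge_phsp <- function(files, out = NULL) {
  stopifnot(length(files) >= 1)
  parts <- lapply(files, read_phsp)
  merged <- phase_space(bind_rows(lapply(parts, `[[`, "records")),
                        sum(vapply(parts, `[[`, numeric(1), "n_original_histories")))
  if (!is.null(out)) write_phsp(merged, out)
  merged
}
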