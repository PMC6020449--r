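# ---------------------------------------------------------------------------
# Reducer: statistical combination of per-worker outputs.  Independent runs
# with histories h_i are merged with weights w_i = h_i / sum(h): dose is the
# weighted mean, and the absolute 1-sigma uncertainty combines as
# sqrt(sum(w_i^2 s_i^2)) (propagation of independent estimates).  Binary
# dose files carry an opaque header (copied verbatim from the first input),
# then the dose array, then the uncertainty array, little endian.
# ---------------------------------------------------------------------------

#' Describe the layout of a binary dose file
#'
#' @param header_bytes opaque header size (bytes, >= 0)
#' @param n_values voxel count of each of the two arrays
#' @param precision `"single"` or `"double"`
#' @param uncertainty_kind only `"ABSOLUTE_1SIGMA"` is implemented; the slot
#'   exists so other conventions can be declared in a model manifest
#' @return an `rtmc_dose_layout`
#' @export
dose_layout <- function(header_bytes, n_values,
                        precision = c("double", "single"),
                        uncertainty_kind = "ABSOLUTE_1SIGMA") {
  precision <- match.arg(precision)
  if (!identical(uncertainty_kind, "ABSOLUTE_1SIGMA")) {
    abort("only ABSOLUTE_1SIGMA uncertainties are implemented")
  }
  structure(list(header_bytes = as.integer(header_bytes),
                 n_values = as.integer(n_values),
                 precision = precision,
                 word = if (precision == "double") 8L else 4L,
                 uncertainty_kind = uncertainty_kind),
            class = "rtmc_dose_layout")
}

.layout_size <- function(layout) layout$header_bytes + 2 * layout$n_values * layout$word

#' Read / write a binary dose file per layout
#' @param path file; @param layout an `rtmc_dose_layout`
#' @return list with `header` (raw), `dose`, `sigma`
#' @export
read_binary_dose <- function(path, layout) {
  sz <- file.size(path)
  if (is.na(sz) || sz != .layout_size(layout)) {
    abort(sprintf("%s: size %s does not match layout (%d expected)",
                  path, format(sz), .layout_size(layout)),
          class = "rtmc_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = layout$header_bytes)
  dose <- readBin(con, "numeric", n = layout$n_values, size = layout$word,
                  endian = "little")
  sigma <- readBin(con, "numeric", n = layout$n_values, size = layout$word,
                   endian = "little")
  list(header = header, dose = dose, sigma = sigma)
}

#' @rdname read_binary_dose
#' @param header raw vector of `layout$header_bytes` bytes
#' @param dose,sigma numeric vectors of `layout$n_values`
#' @export
write_binary_dose <- function(path, header, dose, sigma, layout) {
  stopifnot(length(header) == layout$header_bytes,
            length(dose) == layout$n_values, length(sigma) == layout$n_values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(as.numeric(dose), con, size = layout$word, endian = "little")
  writeBin(as.numeric(sigma), con, size = layout$word, endian = "little")
  invisible(path)
}

#' Merge per-worker binary dose files
#'
#' With weights `w_i = histories_i / sum(histories)`, the merged dose is
#' `sum(w_i d_i)` per voxel and the merged absolute 1-sigma uncertainty is
#' `sqrt(sum(w_i^2 s_i^2))`.  The header of the first file is copied
#' verbatim into the result.
#'
#' @param files binary dose files, all matching `layout`
#' @param layout an `rtmc_dose_layout`
#' @param histories per-file positive history counts (same length as `files`)
#' @param out optional path; when given, the merged result is also written
#'   in the same layout
#' @return list with `header`, `dose`, `sigma`, `histories` (total)
#' @export
merge_binary_dose <- function(files, layout, histories, out = NULL) {
  stopifnot(length(files) >= 1, length(histories) == length(files),
            all(histories > 0))
  w <- histories / sum(histories)
  acc_d <- numeric(layout$n_values)
  acc_v <- numeric(layout$n_values)
  header <- NULL
  for (i in seq_along(files)) {
    x <- read_binary_dose(files[i], layout)
    if (i == 1) header <- x$header
    acc_d <- acc_d + w[i] * x$dose
    acc_v <- acc_v + (w[i] * x$sigma)^2
  }
  res <- list(header = header, dose = acc_d, sigma = sqrt(acc_v),
              histories = sum(histories))
  if (!is.null(out)) write_binary_dose(out, header, res$dose, res$sigma, layout)
  res
}

#' Merge column-format text tallies
#'
#' Key columns must be identical across files (verified row by row); value /
#' uncertainty column pairs are combined with the same history-weighted
#' formulas as [merge_binary_dose()].
#'
#' @param files text files readable by `read.table`
#' @param histories per-file history counts
#' @param value_col,uncertainty_col column indices of the tally value and its
#'   absolute 1-sigma uncertainty
#' @return merged tibble with the key columns and combined value/uncertainty
#' @export
merge_column_tallies <- function(files, histories, value_col, uncertainty_col) {
  stopifnot(length(files) >= 1, length(histories) == length(files))
  tabs <- lapply(files, utils::read.table)
  n_row <- nrow(tabs[[1]])
  key_cols <- setdiff(seq_len(ncol(tabs[[1]])), c(value_col, uncertainty_col))
  for (i in seq_along(tabs)[-1]) {
    if (nrow(tabs[[i]]) != n_row) {
      abort(sprintf("%s: %d rows where %d expected", files[i], nrow(tabs[[i]]), n_row),
            class = "rtmc_alignment_error")
    }
    for (kc in key_cols) {
      diffrow <- which(tabs[[i]][[kc]] != tabs[[1]][[kc]])
      if (length(diffrow) > 0) {
        abort(sprintf("%s: key column %d differs first at row %d",
                      files[i], kc, diffrow[1]), class = "rtmc_alignment_error")
      }
    }
  }
  w <- histories / sum(histories)
  val <- Reduce(`+`, lapply(seq_along(tabs), function(i) w[i] * tabs[[i]][[value_col]]))
  unc <- sqrt(Reduce(`+`, lapply(seq_along(tabs), function(i)
    (w[i] * tabs[[i]][[uncertainty_col]])^2)))
  out <- tabs[[1]]
  out[[value_col]] <- val
  out[[uncertainty_col]] <- unc
  as_tibble(out)
}

#' Mean relative dose uncertainty in a region
#'
#' Over the masked voxels whose dose exceeds 50% of the in-mask maximum,
#' returns the mean of `100 * k * sigma / dose` — the coverage-factor-scaled
#' relative uncertainty in percent (k = 2 reports the conventional 2-sigma
#' figure).
#'
#' @param grid an `rtmc_dose_grid` (see [dose_grid()])
#' @param mask logical array congruent with the grid (default: whole grid)
#' @param k coverage factor
#' @return percentage (scalar)
#' @export
region_uncertainty <- function(grid, mask = NULL, k = 2) {
  stopifnot(inherits(grid, "rtmc_dose_grid"))
  if (is.null(mask)) mask <- array(TRUE, dim = grid$dims)
  if (!any(mask)) abort("empty mask", class = "rtmc_evaluation_error")
  d <- grid$dose[mask]
  s <- grid$sigma[mask]
  dmax <- max(d)
  if (dmax <= 0) abort("no positive dose in mask", class = "rtmc_evaluation_error")
  sel <- d > 0.5 * dmax
  mean(100 * k * s[sel] / d[sel])
}

#' Dose grid container
#'
#' @param dose,sigma 3-D arrays (per-history dose units; sigma is absolute
#'   1-sigma)
#' @param spacing_mm,origin_mm grid geometry (mm, LPS)
#' @param histories total contributing histories
#' @param unit unit tag carried along (default "Gy_per_history")
#' @export
dose_grid <- function(dose, sigma, spacing_mm, origin_mm = c(0, 0, 0),
                      histories = 1L, unit = "Gy_per_history") {
  stopifnot(identical(dim(dose), dim(sigma)), all(sigma >= 0), histories > 0)
  structure(list(dose = dose, sigma = sigma, dims = dim(dose),
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 histories = as.numeric(histories), unit = unit),
            class = "rtmc_dose_grid")
}

#' @export
print.rtmc_dose_grid <- function(x, ...) {
  cat("<rtmc_dose_grid>", paste(x$dims, collapse = "x"),
      "voxels, max dose", format(max(x$dose), digits = 4), x$unit,
      "| histories:", format(x$histories), "\n")
  invisible(x)
}
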