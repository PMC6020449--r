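#' @importFrom ggplot2 ggplot aes geom_step geom_raster labs
#'   scale_fill_viridis_c autoplot theme_minimal coord_equal
NULL

#' Plot a cumulative DVH
#'
#' @param object an `rtmc_dvh`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.rtmc_dvh <- function(object, ...) {
  ggplot(object, aes(x = .data$dose_gy, y = .data$volume_pct)) +
    geom_step(direction = "hv", linewidth = 0.7) +
    labs(x = "Dose (Gy)", y = "Volume (%)", title = "Cumulative DVH") +
    theme_minimal()
}

#' Plot one slice of a dose grid
#'
#' @param grid an `rtmc_dose_grid`
#' @param k slice index (default central slice)
#' @param what `"dose"`, `"sigma"` or `"relative_sigma"` (percent, voxels
#'   above 1% of max dose)
#' @return a ggplot
#' @export
plot_dose_slice <- function(grid, k = NULL, what = c("dose", "sigma", "relative_sigma")) {
  stopifnot(inherits(grid, "rtmc_dose_grid"))
  what <- match.arg(what)
  if (is.null(k)) k <- ceiling(grid$dims[3] / 2)
  sl <- switch(what,
    dose = grid$dose[, , k],
    sigma = grid$sigma[, , k],
    relative_sigma = {
      m <- grid$dose[, , k]
      r <- 100 * grid$sigma[, , k] / pmax(m, 1e-300)
      r[m < 0.01 * max(grid$dose)] <- NA
      r
    })
  df <- expand.grid(
    x = grid$origin_mm[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing_mm[1],
    y = grid$origin_mm[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing_mm[2])
  df$value <- as.numeric(sl)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = what) +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)",
         title = sprintf("%s, slice %d", what, k)) +
    theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-worker summary of a simulation
#'
#' @param x an `rtmc_simulation`
#' @param ... unused
#' @return tibble: one row per worker with node, beam, histories, seeds,
#'   exit status, wall time and finish order
#' @export
tidy.rtmc_simulation <- function(x, ...) {
  as_tibble(x$items[, c("node_id", "beam_id", "histories", "seed1", "seed2",
                        "status", "wall_s", "finish_order")])
}

#' One-row summary of a simulation
#'
#' @param x an `rtmc_simulation`
#' @param ... unused
#' @export
glance.rtmc_simulation <- function(x, ...) {
  tibble(id = x$id, state = x$state, failed = x$failed,
         n_workers = nrow(x$items),
         n_failed = length(x$failed_nodes),
         total_histories = sum(x$items$histories),
         total_wall_s = sum(x$items$wall_s, na.rm = TRUE))
}

#' Deliverable segments of a parsed plan
#'
#' @param x an `rtmc_plan`
#' @param ... unused
#' @return the segments tibble (one row per deliverable segment/arclet)
#' @export
tidy.rtmc_plan <- function(x, ...) x$segments

#' One-row summary of a plan
#' @param x an `rtmc_plan`
#' @param ... unused
#' @export
glance.rtmc_plan <- function(x, ...) {
  tibble(technique = x$technique, n_beams = length(x$beams),
         n_segments = nrow(x$segments), total_mu = x$total_mu,
         patient_id = x$patient_id)
}

#' @importFrom rlang .data
NULL
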