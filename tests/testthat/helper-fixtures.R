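# shared helpers: tiny phantoms, beams, and toy-model scaffolding built in
# code at test time

water_phantom <- function(n = 16, spacing = 10) {
  d <- rep(n, 3)
  voxel_phantom(array(1L, d), array(1.0, d),
                spacing_mm = rep(spacing, 3),
                origin_mm = -(d - 1) * spacing / 2,
                material_names = c("1" = "WATER"))
}

open_field_beam <- function(mu = 100, gantry = 0, half = 50) {
  tibble::tibble(
    beam_id = "B1", gantry_deg = gantry, collimator_deg = 0, table_deg = 0,
    iso_x_mm = 0, iso_y_mm = 0, iso_z_mm = 0,
    jaw_x1_mm = -half, jaw_x2_mm = half, jaw_y1_mm = -half, jaw_y2_mm = half,
    mlc_a_mm = list(rep(-half, 20)), mlc_b_mm = list(rep(half, 20)), mu = mu)
}

# create model + phantom once per session; returns list(model, phantom_path)
toy_setup <- local({
  cache <- NULL
  function(ledger = FALSE) {
    key <- paste0("L", as.integer(ledger))
    if (!is.null(cache[[key]])) return(cache[[key]])
    base <- file.path(tempdir(), paste0("rtmc_setup_", key))
    unlink(base, recursive = TRUE)
    dir.create(base, recursive = TRUE)
    pp <- file.path(base, "water.penvox")
    write_penvox(water_phantom(), pp)
    mf <- create_toy_model(file.path(base, "model"), ledger = ledger)
    out <- list(model = load_model(mf), phantom_path = pp, dir = base)
    cache[[key]] <<- out
    out
  }
})

# run an open-field simulation split over n workers; returns merged dose grid
run_split_field <- function(total_histories, n_workers, master_seed,
                            ledger = FALSE, work_tag = "w") {
  ts <- toy_setup(ledger = ledger)
  beams <- open_field_beam()
  items <- distribute_work(beams, n_workers, "EQUAL", total_histories,
                           master_seed = master_seed)
  wd <- file.path(ts$dir, paste0(work_tag, "_", master_seed, "_", n_workers))
  unlink(wd, recursive = TRUE)
  items <- bind_work_items(ts$model, beams, items, wd, ts$phantom_path)
  for (bd in items$bound_dir) toy_mc_run(bd)
  d <- c(16L, 16L, 16L)
  merged <- merge_binary_dose(file.path(items$bound_dir, "dose.bin"),
                              toy_dose_layout(d), items$histories)
  grid <- dose_grid(array(merged$dose, d), array(merged$sigma, d),
                    rep(10, 3), -(d - 1) * 5, merged$histories)
  list(grid = grid, items = items, layout = toy_dose_layout(d))
}

# per-worker statistics recomputed directly from a raw per-history ledger
# (independent accumulation path used as the reduction oracle)
ledger_stats <- function(ledger_file, n_hist, n_vox) {
  led <- utils::read.delim(ledger_file)
  s <- rep(0, n_vox); q <- rep(0, n_vox)
  ss <- rowsum(led$dose, led$voxel)
  s[as.integer(rownames(ss))] <- ss[, 1]
  qq <- rowsum(led$dose^2, led$voxel)
  q[as.integer(rownames(qq))] <- qq[, 1]
  list(sum = s, sumsq = q, mean = s / n_hist,
       sig2 = pmax((q - s^2 / n_hist) / (n_hist * (n_hist - 1)), 0))
}

# write a tiny binary dose file with given arrays (shared layout helpers)
tiny_dose_file <- function(path, dose, sigma, layout,
                           header = as.raw(seq_len(layout$header_bytes) %% 256)) {
  write_binary_dose(path, header, dose, sigma, layout)
  path
}
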