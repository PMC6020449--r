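# ---------------------------------------------------------------------------
# Toy MC dose engine, R surface.  The engine honors the parametrized-model
# contract: it is driven entirely by two text input files in its input
# directory, mirroring a PenEasy-style split --
#   engine.in : histories, time limit, random seeds, phantom/output paths
#   beam.in   : gantry/collimator/table angles, isocenter, jaws, MLC banks,
#               leaf boundaries, attenuation coefficient, energy per history
# and writes a binary dose file (opaque 72-byte header, then dose and
# absolute 1-sigma arrays in double precision), an optional per-history
# ledger (for reduction oracles), and an optional exit phase space.
# ---------------------------------------------------------------------------

DOSE_HEADER_BYTES <- 72L

make_dose_header <- function(dims, spacing_mm, origin_mm, word = 8L) {
  c(charToRaw("RTMCDOSE"),
    writeBin(as.integer(c(dims, word)), raw(), size = 4, endian = "little"),
    writeBin(as.numeric(c(spacing_mm, origin_mm)), raw(), size = 8, endian = "little"))
}

parse_dose_header <- function(header) {
  stopifnot(length(header) == DOSE_HEADER_BYTES,
            identical(rawToChar(header[1:8]), "RTMCDOSE"))
  ints <- readBin(header[9:24], "integer", n = 4, size = 4, endian = "little")
  dbls <- readBin(header[25:72], "numeric", n = 6, size = 8, endian = "little")
  list(dims = ints[1:3], word = ints[4], spacing_mm = dbls[1:3], origin_mm = dbls[4:6])
}

#' Layout of the toy engine's binary dose output
#' @param dims phantom dims (3-vector)
#' @export
toy_dose_layout <- function(dims) {
  dose_layout(DOSE_HEADER_BYTES, prod(dims), "double")
}

.read_kv_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  setNames(lapply(toks, function(t) t[-1]), vapply(toks, `[[`, character(1), 1))
}

#' Parse the toy engine's input directory into a beam configuration
#' @param input_dir directory holding `engine.in` and `beam.in`
#' @return an `rtmc_toy_config`
#' @export
parse_toy_config <- function(input_dir) {
  ef <- file.path(input_dir, "engine.in")
  bf <- file.path(input_dir, "beam.in")
  if (!file.exists(ef) || !file.exists(bf)) {
    abort(paste0("input directory must contain engine.in and beam.in: ", input_dir))
  }
  e <- .read_kv_file(ef)
  b <- .read_kv_file(bf)
  num <- function(kv, key, n = 1) {
    v <- kv[[key]]
    if (is.null(v)) abort(paste0("missing key ", key), class = "rtmc_format_error")
    if (length(v) < n) abort(paste0(key, ": expected ", n, " values"))
    as.numeric(v[seq_len(n)])
  }
  cfg <- list(
    histories = as.integer(num(e, "NHIST")),
    time_limit = num(e, "TIMELIMIT"),
    seeds = c(as.numeric(e$SEED1[1]), as.numeric(e$SEED2[1])),
    phantom_path = e$PHANTOM[1],
    output_path = e$OUTPUT[1] %||% "dose.bin",
    phsp_path = e$PHSP[1] %||% "none",
    ledger = identical(e$LEDGER[1], "1"),
    gantry_deg = num(b, "GANTRY"),
    collimator_deg = num(b, "COLLIMATOR"),
    table_deg = num(b, "TABLE"),
    isocenter_mm = num(b, "ISOCENTER", 3),
    jaws_mm = num(b, "JAWS", 4),
    mlc_a_mm = as.numeric(b$MLCA),
    mlc_b_mm = as.numeric(b$MLCB),
    leaf_bounds_mm = as.numeric(b$LEAFBOUNDS),
    sad_mm = num(b, "SAD"),
    mu_attenuation_cm2_g = num(b, "MUATT"),
    energy_per_history = num(b, "EPH"),
    phsp_ecut_frac = num(b, "PHSPFRAC"))
  if (cfg$histories <= 0) abort("zero or negative histories", class = "rtmc_format_error")
  if (cfg$mu_attenuation_cm2_g <= 0) abort("mu_attenuation must be > 0")
  if (length(cfg$leaf_bounds_mm) != length(cfg$mlc_a_mm) + 1) {
    abort("LEAFBOUNDS must have one more entry than MLCA")
  }
  structure(cfg, class = "rtmc_toy_config")
}

#' Run the toy dose engine on a bound input directory
#'
#' For each history a ray is sampled uniformly over the open jaw/MLC
#' aperture from a virtual point source rotated by the gantry (and table)
#' about the isocenter, traversed through the density grid with a 3-D DDA,
#' depositing `E * (1 - exp(-mu * rho * L))` in each crossed voxel; dose is
#' deposit over voxel mass, tallied per history for the uncertainty
#' estimator `s^2 = (sum d^2 - (sum d)^2 / n) / (n (n - 1))`.  Identical
#' seeds and inputs reproduce bit-identical outputs.
#'
#' @param input_dir directory with `engine.in` / `beam.in` (see
#'   [create_toy_model()] for the template)
#' @param phantom optional `rtmc_phantom` or path, overriding the PHANTOM
#'   entry of `engine.in`
#' @return invisible list: `dose_file`, `grid` (an `rtmc_dose_grid`),
#'   `config`, `ledger` (tibble or NULL), `phsp_file` (or NULL),
#'   `aperture_closed`
#' @export
toy_mc_run <- function(input_dir, phantom = NULL) {
  cfg <- parse_toy_config(input_dir)
  if (is.null(phantom)) phantom <- cfg$phantom_path
  if (is.character(phantom)) {
    pp <- phantom
    if (!grepl("^/", pp)) pp <- file.path(input_dir, pp)
    if (!file.exists(pp)) abort(paste0("phantom file not found: ", pp))
    phantom <- read_penvox(pp)
  }
  stopifnot(inherits(phantom, "rtmc_phantom"))
  emit_phsp <- !identical(cfg$phsp_path, "none")
  t0 <- proc.time()[["elapsed"]]
  res <- toy_engine_run_cpp(
    density = as.numeric(phantom$density), dims = as.integer(phantom$dims),
    spacing_mm = phantom$spacing_mm, origin_mm = phantom$origin_mm,
    gantry_deg = cfg$gantry_deg, coll_deg = cfg$collimator_deg,
    table_deg = cfg$table_deg, iso_mm = cfg$isocenter_mm,
    jaws_mm = cfg$jaws_mm, mlc_a = cfg$mlc_a_mm, mlc_b = cfg$mlc_b_mm,
    leaf_bounds_mm = cfg$leaf_bounds_mm, sad_mm = cfg$sad_mm,
    mu_att_cm2g = cfg$mu_attenuation_cm2_g,
    e_per_hist = cfg$energy_per_history, nhist = cfg$histories,
    seed1 = as.integer(cfg$seeds[1] %% 2^31), seed2 = as.integer(cfg$seeds[2] %% 2^31),
    ledger = cfg$ledger, emit_phsp = emit_phsp,
    phsp_ecut_frac = cfg$phsp_ecut_frac)
  wall <- proc.time()[["elapsed"]] - t0
  if (res$aperture_closed) {
    warn("aperture fully closed: all-zero dose")
  }
  layout <- toy_dose_layout(phantom$dims)
  header <- make_dose_header(phantom$dims, phantom$spacing_mm, phantom$origin_mm)
  dose_file <- file.path(input_dir, cfg$output_path)
  write_binary_dose(dose_file, header, res$dose, res$sigma, layout)

  ledger <- NULL
  if (cfg$ledger) {
    ledger <- as_tibble(res$ledger)
    utils::write.table(ledger, file.path(input_dir, "ledger.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  phsp_file <- NULL
  if (emit_phsp) {
    m <- res$phsp
    rec <- tibble(type = as.integer(m[, "type"]), energy_mev = m[, "energy_mev"],
                  x_mm = m[, "x_mm"], y_mm = m[, "y_mm"], z_mm = m[, "z_mm"],
                  u = m[, "u"], v = m[, "v"], w = m[, "w"], weight = m[, "weight"])
    phsp_file <- file.path(input_dir, cfg$phsp_path)
    write_phsp(phase_space(rec, cfg$histories), phsp_file)
  }
  log <- list(histories = cfg$histories, seeds = cfg$seeds,
              wall_time_s = wall, aperture_area_mm2 = res$aperture_area_mm2,
              aperture_closed = res$aperture_closed)
  jsonlite::write_json(log, file.path(input_dir, "run.log.json"), auto_unbox = TRUE)
  grid <- dose_grid(array(res$dose, dim = phantom$dims),
                    array(res$sigma, dim = phantom$dims),
                    phantom$spacing_mm, phantom$origin_mm,
                    histories = cfg$histories)
  invisible(list(dose_file = dose_file, grid = grid, config = cfg,
                 ledger = ledger, phsp_file = phsp_file,
                 aperture_closed = res$aperture_closed))
}

#' Closed-form expectation of the engine's central-axis depth dose
#'
#' For a homogeneous phantom the engine's expected per-history dose in a
#' central-axis voxel at depth `d` (cm below the entry surface) is
#' proportional to `exp(-mu * rho * d)`; with a finite source distance the
#' inverse-square fluence factor `(ssd / (ssd + d))^2` multiplies in.  Used
#' to validate the stochastic engine in the large-N limit; returns the
#' unnormalized expectation (compare ratios between depths).
#'
#' @param depth_cm depth(s) below the entry surface, cm
#' @param config list with `mu_attenuation_cm2_g`, `density_g_cm3`, and
#'   optionally `ssd_cm` (source-to-surface distance; omit for a parallel
#'   beam, i.e. pure exponential)
#' @param phantom optional `rtmc_phantom`; if given, its density must be
#'   homogeneous (heterogeneous phantoms are unsupported by the closed form)
#' @export
analytic_depth_dose <- function(depth_cm, config, phantom = NULL) {
  rho <- config$density_g_cm3
  if (!is.null(phantom)) {
    rng <- range(phantom$density)
    if (diff(rng) > 1e-9 * max(rng)) {
      abort("heterogeneous phantom: closed-form depth dose unsupported")
    }
    rho <- rng[1]
  }
  mu <- config$mu_attenuation_cm2_g
  f <- exp(-mu * rho * depth_cm)
  if (!is.null(config$ssd_cm)) {
    f <- f * (config$ssd_cm / (config$ssd_cm + depth_cm))^2
  }
  f
}

#' Create a toy MC model (template directory + manifest)
#'
#' Writes `engine.in` / `beam.in` templates with declared parameter
#' locations and a YAML manifest wired for [load_model()].  The MLC bank
#' lines are sized to `n_leaves`; leaf boundaries are baked into the
#' template (they are case geometry, not a per-worker parameter).
#'
#' @param dir directory to create
#' @param n_leaves number of MLC leaf pairs
#' @param leaf_bounds_mm leaf boundary positions at the isocenter plane
#'   (`n_leaves + 1` values); default spans -100..100 mm uniformly
#' @param mu_attenuation_cm2_g effective mass attenuation coefficient
#'   (default 0.05, a megavoltage-photon-like value in water)
#' @param energy_per_history source energy per history (arbitrary unit)
#' @param sad_mm source-axis distance
#' @param emit_phsp whether workers also write an exit phase space
#' @param ledger whether workers dump the per-history ledger
#' @return path to the manifest (`model.yaml`) inside `dir`
#' @export
create_toy_model <- function(dir, n_leaves = 20,
                             leaf_bounds_mm = seq(-100, 100, length.out = n_leaves + 1),
                             mu_attenuation_cm2_g = 0.05,
                             energy_per_history = 1.0, sad_mm = 1000,
                             emit_phsp = FALSE, ledger = FALSE) {
  tdir <- file.path(dir, "template")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  open_a <- rep(-50, n_leaves); open_b <- rep(50, n_leaves)
  writeLines(c(
    "NHIST      1000",
    "TIMELIMIT  1e30",
    "SEED1      1",
    "SEED2      2",
    "PHANTOM    phantom.penvox",
    "OUTPUT     dose.bin",
    sprintf("PHSP       %s", if (emit_phsp) "exit.phsp" else "none"),
    sprintf("LEDGER     %d", as.integer(ledger))),
    file.path(tdir, "engine.in"))
  writeLines(c(
    "GANTRY     0.000",
    "COLLIMATOR 0.000",
    "TABLE      0.000",
    "ISOCENTER  0.0 0.0 0.0",
    "JAWS       -50.0 50.0 -50.0 50.0",
    paste("MLCA      ", paste(sprintf("%.3f", open_a), collapse = " ")),
    paste("MLCB      ", paste(sprintf("%.3f", open_b), collapse = " ")),
    paste("LEAFBOUNDS", paste(sprintf("%.3f", leaf_bounds_mm), collapse = " ")),
    sprintf("SAD        %.3f", sad_mm),
    sprintf("MUATT      %.6f", mu_attenuation_cm2_g),
    sprintf("EPH        %.6f", energy_per_history),
    "PHSPFRAC   0.05"),
    file.path(tdir, "beam.in"))
  manifest <- list(
    template_dir = "template",
    executable = "builtin:toyengine",
    descriptors = list(
      list(file = "engine.in", line = 1, token = 2, kind = "HISTORIES", format = "%d"),
      list(file = "engine.in", line = 2, token = 2, kind = "TIME_LIMIT", format = "%g"),
      list(file = "engine.in", line = 3, token = 2, kind = "SEED1", format = "%d"),
      list(file = "engine.in", line = 4, token = 2, kind = "SEED2", format = "%d"),
      list(file = "engine.in", line = 5, token = 2, kind = "PHANTOM_PATH", format = "%s"),
      list(file = "engine.in", line = 6, token = 2, kind = "OUTPUT_PATH", format = "%s"),
      list(file = "beam.in", line = 1, token = 2, kind = "GANTRY", format = "%.4f"),
      list(file = "beam.in", line = 2, token = 2, kind = "COLLIMATOR", format = "%.4f"),
      list(file = "beam.in", line = 3, token = 2, kind = "TABLE", format = "%.4f"),
      list(file = "beam.in", line = 4, token = 2, kind = "ISOCENTER_X", format = "%.4f"),
      list(file = "beam.in", line = 4, token = 3, kind = "ISOCENTER_Y", format = "%.4f"),
      list(file = "beam.in", line = 4, token = 4, kind = "ISOCENTER_Z", format = "%.4f"),
      list(file = "beam.in", line = 5, token = 2, kind = "JAW_X1", format = "%.4f"),
      list(file = "beam.in", line = 5, token = 3, kind = "JAW_X2", format = "%.4f"),
      list(file = "beam.in", line = 5, token = 4, kind = "JAW_Y1", format = "%.4f"),
      list(file = "beam.in", line = 5, token = 5, kind = "JAW_Y2", format = "%.4f"),
      list(file = "beam.in", line = 6, token = 2, kind = "MLC_BANK_A", format = "%.4f"),
      list(file = "beam.in", line = 7, token = 2, kind = "MLC_BANK_B", format = "%.4f")),
    output_spec = list(
      list(pattern = "dose.bin", format = "BINARY_DOSE"),
      if (emit_phsp) list(pattern = "exit.phsp", format = "IAEA_PHSP")),
    layout = list(header_bytes = DOSE_HEADER_BYTES, precision = "double",
                  uncertainty_kind = "ABSOLUTE_1SIGMA"))
  manifest$output_spec <- Filter(Negate(is.null), manifest$output_spec)
  mf <- file.path(dir, "model.yaml")
  yaml::write_yaml(manifest, mf)
  mf
}
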