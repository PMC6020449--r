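# ---------------------------------------------------------------------------
# Geometry mapper: bind per-beam geometry, histories and seeds into
# parametrized MC input templates, and apportion beams over worker nodes.
# ---------------------------------------------------------------------------

.descriptor_kinds <- c("HISTORIES", "TIME_LIMIT", "SEED1", "SEED2", "GANTRY",
                       "COLLIMATOR", "TABLE", "ISOCENTER_X", "ISOCENTER_Y",
                       "ISOCENTER_Z", "JAW_X1", "JAW_X2", "JAW_Y1", "JAW_Y2",
                       "MLC_BANK_A", "MLC_BANK_B", "PHSP_PATH", "OUTPUT_PATH",
                       "PHANTOM_PATH")
.vector_kinds <- c("MLC_BANK_A", "MLC_BANK_B")

#' Load a parametrized MC model manifest
#'
#' The manifest (YAML) declares `template_dir`, `executable`, a `descriptors`
#' list of `{file, line, token, kind, format}` entries and an `output_spec`
#' list of `{pattern, format}` entries (formats: `BINARY_DOSE`,
#' `COLUMN_TEXT`, `IAEA_PHSP`).  Relative template paths resolve against the
#' manifest's directory.
#'
#' @param path manifest file
#' @return an `rtmc_model`
#' @export
load_model <- function(path) {
  y <- yaml::read_yaml(path)
  tdir <- y$template_dir
  if (!is.null(tdir) && !grepl("^/", tdir)) {
    tdir <- file.path(dirname(normalizePath(path)), tdir)
  }
  descs <- lapply(y$descriptors, function(d) {
    if (!(d$kind %in% .descriptor_kinds)) {
      abort(paste0("unknown parameter kind: ", d$kind))
    }
    list(file = d$file, line = as.integer(d$line), token = as.integer(d$token),
         kind = d$kind, format = d$format %||% "%s")
  })
  model <- structure(list(template_dir = tdir, descriptors = descs,
                          executable = y$executable,
                          output_spec = y$output_spec,
                          layout = y$layout),
                     class = "rtmc_model")
  validate_model(model)
}

#' @rdname load_model
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "rtmc_model"))
  if (length(model$output_spec) == 0) abort("model output_spec is empty")
  for (d in model$descriptors) {
    f <- file.path(model$template_dir, d$file)
    if (!file.exists(f)) {
      abort(paste0("descriptor file missing from template: ", d$file),
            class = "rtmc_template_error")
    }
    lines <- readLines(f)
    if (d$line > length(lines)) {
      abort(sprintf("template %s has no line %d (descriptor %s)",
                    d$file, d$line, d$kind), class = "rtmc_template_error")
    }
    toks <- strsplit(trimws(lines[d$line]), "\\s+")[[1]]
    if (d$token > length(toks)) {
      abort(sprintf("template %s line %d has no token %d (descriptor %s)",
                    d$file, d$line, d$token, d$kind), class = "rtmc_template_error")
    }
  }
  model
}

#' Distribute beams and histories over worker nodes
#'
#' `EQUAL` gives each beam `floor(n_nodes / n_beams)` nodes with the
#' remainder on the earliest beams.  `MU_WEIGHTED` apportions nodes by
#' largest remainder (Hamilton) on the quotas `n_nodes * mu_b / sum(mu)`,
#' with a floor of one node per beam and lowest-index tie-breaks.  The beam
#' history budget (`total_histories * mu_b / sum(mu)` for `MU_WEIGHTED`, an
#' equal split for `EQUAL`, both integerized by largest remainder so the
#' total is conserved exactly) divides evenly over the beam's nodes with the
#' remainder on its first node.
#'
#' @param beams static-beam tibble from [discretize_plan()]
#' @param n_nodes number of worker nodes (>= number of beams)
#' @param mode `"EQUAL"` or `"MU_WEIGHTED"`
#' @param total_histories total histories over the whole simulation
#' @param master_seed integer driving [assign_seeds()]
#' @return a tibble of work items: `node_id`, `beam_id`, `beam_index`,
#'   `histories`, `seed1`, `seed2`
#' @export
distribute_work <- function(beams, n_nodes, mode = c("MU_WEIGHTED", "EQUAL"),
                            total_histories, master_seed = 1L) {
  mode <- match.arg(mode)
  n_nodes <- as.integer(n_nodes)
  total_histories <- as.integer(total_histories)
  nb <- nrow(beams)
  if (n_nodes < nb) {
    abort(sprintf("infeasible: %d nodes for %d beams (every beam needs one node)",
                  n_nodes, nb), class = "rtmc_infeasible_error")
  }
  if (total_histories < n_nodes) abort("total_histories must be >= n_nodes")
  mu <- beams$mu
  if (mode == "EQUAL") {
    nodes <- rep(n_nodes %/% nb, nb)
    extra <- n_nodes - sum(nodes)
    if (extra > 0) nodes[seq_len(extra)] <- nodes[seq_len(extra)] + 1L
    hist_beam <- largest_remainder(rep(1, nb) / nb * total_histories, total_histories)
  } else {
    if (sum(mu) <= 0) abort("MU_WEIGHTED requires positive total MU")
    nodes <- apportion_mu_weighted(mu, n_nodes)
    hist_beam <- largest_remainder(mu / sum(mu) * total_histories, total_histories)
  }
  rows <- list()
  node_id <- 0L
  for (b in seq_len(nb)) {
    nh <- hist_beam[b] %/% nodes[b]
    rem <- hist_beam[b] - nh * nodes[b]
    for (k in seq_len(nodes[b])) {
      rows[[length(rows) + 1L]] <- tibble(
        node_id = node_id, beam_id = beams$beam_id[b], beam_index = b,
        histories = nh + as.integer(k == 1) * rem)
      node_id <- node_id + 1L
    }
  }
  items <- bind_rows(rows)
  if (any(items$histories <= 0)) {
    abort("some node received zero histories; increase total_histories")
  }
  seeds <- assign_seeds(nrow(items), master_seed)
  items$seed1 <- seeds$seed1
  items$seed2 <- seeds$seed2
  attr(items, "mode") <- mode
  attr(items, "master_seed") <- as.integer(master_seed)
  items
}

#' Largest-remainder integer apportionment
#'
#' Rounds nonnegative quotas (summing to `total`) down and hands the
#' leftover units to the largest fractional remainders, lowest index first
#' on ties.
#' @param quota numeric quotas; @param total integer total to apportion
#' @keywords internal
#' @export
largest_remainder <- function(quota, total) {
  base <- floor(quota)
  rem <- quota - base
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' MU-weighted node apportionment with a one-node floor
#'
#' Hamilton apportionment of `n_nodes * mu / sum(mu)`; beams rounded to zero
#' are raised to one node, taking nodes from the largest allocations
#' (highest index on ties) so the total is preserved.
#' @param mu per-beam monitor units; @param n_nodes total nodes
#' @export
apportion_mu_weighted <- function(mu, n_nodes) {
  nb <- length(mu)
  stopifnot(n_nodes >= nb)
  nodes <- largest_remainder(n_nodes * mu / sum(mu), n_nodes)
  while (any(nodes == 0L)) {
    z <- which(nodes == 0L)[1]
    donor <- which(nodes == max(nodes))
    donor <- donor[length(donor)]
    nodes[donor] <- nodes[donor] - 1L
    nodes[z] <- 1L
  }
  nodes
}

# exact (a*b) mod 2^31 in doubles via a 15-bit split of b
.mulmod31 <- function(a, b) {
  m <- 2^31
  b1 <- b %/% 2^15
  b0 <- b - b1 * 2^15
  (((a * b1) %% m) * 2^15 + a * b0) %% m
}

# invertible mixing on [0, 2^31): odd-multiplier and xor-shift are bijections
.mix31 <- function(x) {
  x <- .mulmod31(x, 506952113)                       # odd multiplier
  x <- as.double(bitwXor(as.integer(x), as.integer(x %/% 2^16)))
  .mulmod31(x, 1597334677)                           # odd multiplier
}

#' Deterministic distinct seed pairs
#'
#' Counter-based derivation: item `k` receives the images of counters
#' `2k-2` and `2k-1` (offset by a master-seed term) under a bijective mixing
#' of the 31-bit integers, so all values are pairwise distinct, positive,
#' and a pure function of `master_seed`.
#'
#' @param n_items number of work items
#' @param master_seed integer
#' @return tibble with columns `seed1`, `seed2`
#' @export
assign_seeds <- function(n_items, master_seed) {
  stopifnot(n_items >= 1)
  m <- 2^31
  base <- (as.double(master_seed) * 2^20) %% m
  ctr <- (base + (seq_len(2 * n_items) - 1)) %% m
  v <- .mix31(ctr) + 1   # positive
  tibble(seed1 = v[seq(1, 2 * n_items, by = 2)],
         seed2 = v[seq(2, 2 * n_items, by = 2)])
}

#' Bind work-item parameters into a copy of the model template
#'
#' Copies `template_dir` and substitutes each descriptor's value at its
#' (file, line, token) locator using its printf format.  Scalar kinds
#' replace one whitespace-delimited token in place; vector kinds (MLC banks)
#' replace the tokens from `token` to the end of the line.  All locators are
#' validated before any file is written.  Every byte outside descriptor
#' locations is preserved.
#'
#' @param model an `rtmc_model`
#' @param beam one-row static-beam tibble (or NULL for beam-less models)
#' @param item one-row work-item tibble from [distribute_work()]
#' @param bound_dir target directory (created; must not exist)
#' @param paths named list for `PHSP_PATH` / `OUTPUT_PATH` / `PHANTOM_PATH`
#'   kinds, e.g. `list(PHANTOM_PATH = "...", OUTPUT_PATH = "dose.bin")`
#' @return `bound_dir`, invisibly
#' @export
bind_parameters <- function(model, beam, item, bound_dir, paths = list()) {
  validate_model(model)
  value_of <- function(kind) {
    switch(kind,
      HISTORIES = item$histories, TIME_LIMIT = 1e30,
      SEED1 = item$seed1, SEED2 = item$seed2,
      GANTRY = beam$gantry_deg, COLLIMATOR = beam$collimator_deg,
      TABLE = beam$table_deg,
      ISOCENTER_X = beam$iso_x_mm, ISOCENTER_Y = beam$iso_y_mm,
      ISOCENTER_Z = beam$iso_z_mm,
      JAW_X1 = beam$jaw_x1_mm, JAW_X2 = beam$jaw_x2_mm,
      JAW_Y1 = beam$jaw_y1_mm, JAW_Y2 = beam$jaw_y2_mm,
      MLC_BANK_A = beam$mlc_a_mm[[1]], MLC_BANK_B = beam$mlc_b_mm[[1]],
      PHSP_PATH = paths$PHSP_PATH %||% "",
      OUTPUT_PATH = paths$OUTPUT_PATH %||% "dose.bin",
      PHANTOM_PATH = paths$PHANTOM_PATH %||% "")
  }
  # stage all edits in memory first: template errors must precede any write
  files <- unique(vapply(model$descriptors, `[[`, character(1), "file"))
  contents <- lapply(files, function(f) readLines(file.path(model$template_dir, f)))
  names(contents) <- files
  for (d in model$descriptors) {
    lines <- contents[[d$file]]
    val <- value_of(d$kind)
    fmt <- function(v) {
      if (grepl("%[0-9.+ #-]*[dxoi]", d$format)) sprintf(d$format, as.integer(v))
      else if (grepl("%[0-9.+ #-]*s", d$format)) sprintf(d$format, as.character(v))
      else sprintf(d$format, as.numeric(v))
    }
    rendered <- vapply(val, fmt, character(1))
    if (any(nchar(gsub(" ", "", rendered)) == 0)) {
      abort(sprintf("descriptor %s renders empty with format '%s'", d$kind, d$format),
            class = "rtmc_format_error")
    }
    contents[[d$file]] <- .substitute_tokens(
      lines, d$line, d$token, rendered,
      to_eol = d$kind %in% .vector_kinds, file = d$file, kind = d$kind)
  }
  if (dir.exists(bound_dir)) abort(paste0("bound directory already exists: ", bound_dir))
  ok <- dir.create(bound_dir, recursive = TRUE)
  if (!ok) abort(paste0("cannot create ", bound_dir))
  # verbatim copy of every template file, then overwrite the edited ones
  all_files <- list.files(model$template_dir, recursive = TRUE)
  for (f in all_files) {
    dest <- file.path(bound_dir, f)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(model$template_dir, f), dest)
  }
  for (f in names(contents)) {
    writeLines(contents[[f]], file.path(bound_dir, f))
  }
  invisible(bound_dir)
}

# replace token(s) on one line, preserving all other whitespace bytes
.substitute_tokens <- function(lines, line_no, token_no, rendered, to_eol,
                               file, kind) {
  if (line_no > length(lines)) {
    abort(sprintf("template %s has no line %d (descriptor %s)", file, line_no, kind),
          class = "rtmc_template_error")
  }
  l <- lines[line_no]
  m <- gregexpr("\\S+", l)[[1]]
  if (m[1] == -1 || token_no > length(m)) {
    abort(sprintf("template %s line %d has no token %d (descriptor %s)",
                  file, line_no, token_no, kind), class = "rtmc_template_error")
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  from <- starts[token_no]
  if (to_eol) {
    prefix <- substr(l, 1, from - 1)
    lines[line_no] <- paste0(prefix, paste(rendered, collapse = " "))
  } else {
    stopifnot(length(rendered) == 1)
    lines[line_no] <- paste0(substr(l, 1, from - 1), rendered,
                             substr(l, from + lens[token_no], nchar(l)))
  }
  lines
}

#' Bind every work item of a simulation
#'
#' Convenience wrapper around [bind_parameters()]: creates one bound
#' directory per work item under `work_dir` (`worker_<node_id>`), wiring the
#' phantom path and per-worker output paths.
#'
#' @inheritParams bind_parameters
#' @param beams static-beam tibble; @param items work-item tibble
#' @param work_dir parent directory for bound worker directories
#' @param phantom_path path to the phantom file workers read
#' @return items tibble with a `bound_dir` column added
#' @export
bind_work_items <- function(model, beams, items, work_dir, phantom_path) {
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  items$bound_dir <- vapply(seq_len(nrow(items)), function(i) {
    it <- items[i, ]
    bd <- file.path(work_dir, sprintf("worker_%04d", it$node_id))
    bind_parameters(model, beams[it$beam_index, ], it, bd,
                    paths = list(PHANTOM_PATH = phantom_path,
                                 OUTPUT_PATH = "dose.bin",
                                 PHSP_PATH = "exit.phsp"))
    bd
  }, character(1))
  items
}
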