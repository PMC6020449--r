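# ---------------------------------------------------------------------------
# Map phase orchestration: run bound worker directories as local forked
# processes (a sliding window of at most max_parallel), collect outputs into
# a results directory as workers finish, and track the simulation state
# machine: INACTIVE -> DOWNLOADING_FILES -> SIMULATING -> UPLOADING_RESULTS
# -> FINISHED.  "Downloading"/"uploading" map to staging files into and out
# of the results directory; there is no retry policy (fail fast).
# ---------------------------------------------------------------------------

SIMULATION_STATES <- c("INACTIVE", "DOWNLOADING_FILES", "SIMULATING",
                       "UPLOADING_RESULTS", "FINISHED")

#' Run the map phase of a simulation
#'
#' Executes every bound work item exactly once.  The model's `executable` is
#' either `"builtin:toyengine"` (the bundled engine runs in a forked child
#' process) or a shell command invoked as `<executable> <bound_dir>`.
#' Workers run concurrently up to `max_parallel`; as each finishes, its
#' output files (per the model `output_spec`) are staged into
#' `results_dir/worker_<node_id>/`.  Any nonzero worker exit marks the
#' simulation failed with the failing node ids; partial outputs are kept for
#' diagnosis.
#'
#' @param model an `rtmc_model`
#' @param items work-item tibble with a `bound_dir` column (see
#'   [bind_work_items()])
#' @param max_parallel maximum concurrent workers
#' @param results_dir staging directory for collected outputs (created)
#' @return an `rtmc_simulation`: fields `state`, `failed`, `failed_nodes`,
#'   `items` (with per-worker status, wall time and finish order), `outputs`
#'   (list of per-worker staged file sets), `state_log`
#' @export
run_simulation <- function(model, items, max_parallel = 2L,
                           results_dir = file.path(tempdir(), "rtmc_results")) {
  stopifnot(inherits(model, "rtmc_model"))
  if (nrow(items) == 0) abort("nothing to simulate: no work items")
  if (!("bound_dir" %in% names(items))) abort("work items are not bound (no bound_dir)")
  if (!all(dir.exists(items$bound_dir))) abort("some bound directories are missing")

  sim_id <- sprintf("sim-%s", format(Sys.time(), "%Y%m%d%H%M%S"))
  state_log <- list()
  log_state <- function(state, note = "") {
    state_log[[length(state_log) + 1L]] <<- list(
      t = as.numeric(Sys.time()), state = state, note = note)
  }
  log_state("INACTIVE")

  log_state("DOWNLOADING_FILES", "staging bound inputs")
  dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

  run_one <- function(i) {
    it <- items[i, ]
    t0 <- proc.time()[["elapsed"]]
    status <- tryCatch({
      if (identical(model$executable, "builtin:toyengine")) {
        toy_mc_run(it$bound_dir)
        0L
      } else {
        system2(model$executable, shQuote(it$bound_dir),
                stdout = file.path(it$bound_dir, "stdout.log"),
                stderr = file.path(it$bound_dir, "stderr.log"))
      }
    }, error = function(e) {
      writeLines(conditionMessage(e), file.path(it$bound_dir, "error.log"))
      1L
    })
    list(i = i, status = as.integer(status),
         wall_s = proc.time()[["elapsed"]] - t0)
  }

  log_state("SIMULATING", sprintf("%d work items, max_parallel=%d",
                                  nrow(items), max_parallel))
  n <- nrow(items)
  status <- integer(n); wall <- numeric(n); finish_order <- integer(n)
  outputs <- vector("list", n)
  next_i <- 1L; running <- list(); done <- 0L
  collect_result <- function(r) {
    i <- r$i
    status[i] <<- r$status; wall[i] <<- r$wall_s
    done <<- done + 1L
    finish_order[i] <<- done
    # stream this worker's outputs into the results dir as it finishes
    wdir <- file.path(results_dir, sprintf("worker_%04d", items$node_id[i]))
    dir.create(wdir, showWarnings = FALSE, recursive = TRUE)
    staged <- character(0)
    if (r$status == 0L) {
      for (os in model$output_spec) {
        fs <- Sys.glob(file.path(items$bound_dir[i], os$pattern))
        for (f in fs) {
          file.copy(f, file.path(wdir, basename(f)), overwrite = TRUE)
          staged <- c(staged, file.path(wdir, basename(f)))
        }
      }
      lg <- file.path(items$bound_dir[i], "run.log.json")
      if (file.exists(lg)) file.copy(lg, file.path(wdir, "run.log.json"), overwrite = TRUE)
    }
    outputs[[i]] <<- staged
  }
  if (max_parallel <= 1L || .Platform$OS.type != "unix") {
    for (i in seq_len(n)) collect_result(run_one(i))
  } else {
    while (done < n) {
      while (length(running) < max_parallel && next_i <= n) {
        running[[as.character(next_i)]] <- parallel::mcparallel(run_one(next_i))
        next_i <- next_i + 1L
      }
      res <- parallel::mccollect(running, wait = FALSE, timeout = 0.05)
      fin <- names(res)[!vapply(res, is.null, logical(1))]
      for (key in fin) {
        r <- res[[key]]
        job_key <- which(vapply(running, function(j) as.character(j$pid) == key,
                                logical(1)))
        if (inherits(r, "try-error") || !is.list(r)) {
          idx <- as.integer(names(running)[job_key])
          r <- list(i = idx, status = 1L, wall_s = NA_real_)
        }
        collect_result(r)
        running[[job_key]] <- NULL
      }
    }
  }

  failed_nodes <- items$node_id[status != 0L]
  failed <- length(failed_nodes) > 0
  log_state("UPLOADING_RESULTS", "collecting worker outputs")
  items$status <- status
  items$wall_s <- wall
  items$finish_order <- finish_order
  final_state <- if (failed) "UPLOADING_RESULTS" else "FINISHED"
  if (!failed) log_state("FINISHED")
  sim <- structure(
    list(id = sim_id, state = final_state, failed = failed,
         failed_nodes = failed_nodes, items = items,
         outputs = outputs[status == 0L], results_dir = results_dir,
         model = model, state_log = state_log),
    class = "rtmc_simulation")
  .write_state_log(sim)
  if (failed) {
    warn(sprintf("simulation failed on node(s) %s; partial outputs kept in %s",
                 paste(failed_nodes, collapse = ","), results_dir))
  }
  sim
}

.write_state_log <- function(sim) {
  f <- file.path(sim$results_dir, "simulation.log.jsonl")
  con <- file(f, "w")
  on.exit(close(con))
  for (e in sim$state_log) {
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE), con)
  }
  for (i in seq_len(nrow(sim$items))) {
    it <- sim$items[i, ]
    writeLines(jsonlite::toJSON(list(
      t = NA, worker = it$node_id, beam = it$beam_id,
      histories = it$histories, status = it$status, wall_s = it$wall_s),
      auto_unbox = TRUE, na = "null"), con)
  }
  invisible(f)
}

#' @export
print.rtmc_simulation <- function(x, ...) {
  cat("<rtmc_simulation>", x$id, "state:", x$state,
      "| workers:", nrow(x$items),
      if (x$failed) paste0("| FAILED nodes: ", paste(x$failed_nodes, collapse = ","))
      else "", "\n")
  invisible(x)
}

#' Reduce a finished simulation's dose outputs
#'
#' Merges every successful worker's `dose.bin` with [merge_binary_dose()]
#' (weights from the per-item history counts) and reconstructs the dose grid
#' geometry from the binary header.
#'
#' @param sim an `rtmc_simulation`
#' @param out optional path for the merged binary file
#' @return an `rtmc_dose_grid`
#' @export
reduce_simulation <- function(sim, out = NULL) {
  stopifnot(inherits(sim, "rtmc_simulation"))
  ok <- sim$items$status == 0L
  if (!any(ok)) abort("no successful workers to reduce")
  dirs <- file.path(sim$results_dir, sprintf("worker_%04d", sim$items$node_id[ok]))
  files <- file.path(dirs, "dose.bin")
  if (!all(file.exists(files))) abort("missing dose.bin in results directory")
  hdr <- parse_dose_header(readBin(files[1], "raw", n = DOSE_HEADER_BYTES))
  layout <- toy_dose_layout(hdr$dims)
  merged <- merge_binary_dose(files, layout, sim$items$histories[ok], out = out)
  dose_grid(array(merged$dose, dim = hdr$dims),
            array(merged$sigma, dim = hdr$dims),
            spacing_mm = hdr$spacing_mm, origin_mm = hdr$origin_mm,
            histories = merged$histories)
}
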