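#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr bind_rows mutate filter arrange group_by summarise ungroup
#' @importFrom purrr map map_dbl map_int map_chr
NULL

# ---------------------------------------------------------------------------
# RT plan model: parse DICOM RTPLAN files and discretize dynamic techniques
# (mArc arclets, step-and-shoot IMRT) into static beams an MC run can
# calculate.
#
# Control-point contract (used both by the parser and the fixture writer):
# a deliverable segment / arclet is a maximal run of consecutive control
# points joined by nonzero cumulative-meterset-weight increments.  Beam-off
# travel between segments is encoded by zero-increment control points.  The
# aperture (jaws + MLC) must be constant while the beam is on; the gantry may
# move during a run (mArc arclet) or not (static segment).
# ---------------------------------------------------------------------------

#' Parse a DICOM RT plan
#'
#' Reads BeamSequence/ControlPointSequence/FractionGroupSequence, carries
#' machine state forward across control points, extracts deliverable
#' segments, and classifies the delivery technique:
#' * `STATIC` — every beam delivers a single fixed-gantry segment,
#' * `STEP_AND_SHOOT` — fixed-gantry beams with multiple MLC segments,
#' * `MARC` — beam-on intervals along a rotating gantry (arclets).
#'
#' Per-segment MU is `BeamMeterset x (cumulative weight at segment end -
#' at segment start)`; `total_mu` is the left-to-right sum of segment MUs
#' (and is validated against the fraction-group metersets).
#'
#' @param rtplan_file path to a DICOM RTPLAN file
#' @return an object of class `rtmc_plan` with fields `technique`, `beams`,
#'   `segments` (a tibble, one row per deliverable segment), `total_mu` and
#'   `patient_id`
#' @export
parse_rtplan <- function(rtplan_file) {
  ds <- dcm_read(rtplan_file)
  modality <- dcm_get(ds, "Modality", "")
  if (!identical(modality, "RTPLAN")) {
    abort(paste0("not an RTPLAN dataset (Modality='", modality, "')"),
          class = "rtmc_format_error")
  }
  beam_seq <- dcm_get(ds, "BeamSequence")
  if (is.null(beam_seq) || length(beam_seq) == 0) {
    abort("RTPLAN has no BeamSequence (300A,00B0)", class = "rtmc_plan_content_error")
  }
  # metersets by referenced beam number
  fg <- dcm_get(ds, "FractionGroupSequence")
  metersets <- list()
  if (!is.null(fg)) {
    for (g in fg) {
      for (rb in dcm_get(g, "ReferencedBeamSequence") %||% list()) {
        bn <- as.character(dcm_get(rb, "ReferencedBeamNumber"))
        metersets[[bn]] <- dcm_get(rb, "BeamMeterset")
      }
    }
  }

  beams <- lapply(beam_seq, function(b) .parse_beam(b, metersets))
  segments <- bind_rows(lapply(beams, `[[`, "segments"))
  if (nrow(segments) == 0) {
    abort("plan contains no deliverable segments", class = "rtmc_plan_content_error")
  }
  technique <- .classify_technique(beams, segments)
  total_mu <- sum(segments$mu)
  ms_total <- sum(unlist(metersets))
  if (length(metersets) > 0 && ms_total > 0 &&
      abs(total_mu - ms_total) > 1e-6 * ms_total) {
    warn(sprintf("segment MU sum (%.6g) differs from fraction-group metersets (%.6g)",
                 total_mu, ms_total))
  }
  structure(
    list(technique = technique,
         beams = beams,
         segments = segments,
         total_mu = total_mu,
         patient_id = dcm_get(ds, "PatientID", "") %||% "",
         plan_label = dcm_get(ds, "RTPlanLabel", "") %||% "",
         source = rtplan_file),
    class = "rtmc_plan")
}

# state carried across control points of one beam
.parse_beam <- function(b, metersets) {
  bn <- dcm_get(b, "BeamNumber", NA)
  bname <- dcm_get(b, "BeamName", paste0("beam", bn))
  cps <- dcm_get(b, "ControlPointSequence")
  if (is.null(cps) || length(cps) < 2) {
    abort(paste0("beam ", bn, ": ControlPointSequence (300A,0111) absent or too short"),
          class = "rtmc_plan_content_error")
  }
  meterset <- metersets[[as.character(bn)]] %||% NA_real_
  # leaf boundaries from the beam-level MLC description, if present
  leaf_bounds <- NULL
  for (bld in dcm_get(b, "BeamLimitingDeviceSequence") %||% list()) {
    if (identical(dcm_get(bld, "RTBeamLimitingDeviceType"), "MLCX")) {
      leaf_bounds <- dcm_get(bld, "LeafPositionBoundaries")
    }
  }

  state <- list(gantry = NA_real_, coll = 0, table = 0,
                iso = c(NA_real_, NA_real_, NA_real_),
                jaws = NULL, mlc_a = NULL, mlc_b = NULL)
  rows <- vector("list", length(cps))
  for (i in seq_along(cps)) {
    cp <- cps[[i]]
    w <- dcm_get(cp, "CumulativeMetersetWeight")
    if (is.null(w)) {
      abort(paste0("beam ", bn, " control point ", i,
                   ": missing CumulativeMetersetWeight (300A,0134)"),
            class = "rtmc_plan_content_error")
    }
    g <- dcm_get(cp, "GantryAngle"); if (!is.null(g)) state$gantry <- g %% 360
    cl <- dcm_get(cp, "BeamLimitingDeviceAngle"); if (!is.null(cl)) state$coll <- cl
    tb <- dcm_get(cp, "PatientSupportAngle"); if (!is.null(tb)) state$table <- tb
    is3 <- dcm_get(cp, "IsocenterPosition"); if (!is.null(is3)) state$iso <- is3
    for (bldp in dcm_get(cp, "BeamLimitingDevicePositionSequence") %||% list()) {
      typ <- dcm_get(bldp, "RTBeamLimitingDeviceType")
      pos <- dcm_get(bldp, "LeafJawPositions")
      if (typ %in% c("X", "ASYMX")) state$jaws[c(1, 2)] <- pos
      else if (typ %in% c("Y", "ASYMY")) state$jaws[c(3, 4)] <- pos
      else if (typ %in% c("MLCX", "MLCY")) {
        n <- length(pos) / 2
        state$mlc_a <- pos[seq_len(n)]
        state$mlc_b <- pos[n + seq_len(n)]
      }
    }
    if (i == 1) {
      if (is.null(state$jaws)) {
        abort(paste0("beam ", bn, ": missing jaw positions (300A,011A/011C, X/Y)"),
              class = "rtmc_plan_content_error")
      }
      if (is.null(state$mlc_a)) {
        abort(paste0("beam ", bn, ": missing MLC positions (300A,011C, MLCX)"),
              class = "rtmc_plan_content_error")
      }
    }
    rows[[i]] <- tibble(
      cp = i - 1L, weight = w, gantry_deg = state$gantry,
      collimator_deg = state$coll, table_deg = state$table,
      iso = list(state$iso), jaws = list(state$jaws),
      mlc_a = list(state$mlc_a), mlc_b = list(state$mlc_b))
  }
  cp_tab <- bind_rows(rows)
  if (any(diff(cp_tab$weight) < 0)) {
    abort(paste0("beam ", bn, ": cumulative meterset weights are not nondecreasing"),
          class = "rtmc_plan_content_error")
  }
  segs <- .extract_segments(cp_tab, bname, bn, meterset)
  list(beam_number = bn, beam_name = bname, meterset = meterset,
       leaf_bounds = leaf_bounds, control_points = cp_tab, segments = segs)
}

# maximal runs of consecutive control points with nonzero weight increments
.extract_segments <- function(cp_tab, bname, bn, meterset) {
  dw <- diff(cp_tab$weight)
  on <- dw > 0
  if (!any(on)) return(tibble())
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(seq_along(keep), function(k) {
    i0 <- starts[keep[k]]          # first interval index -> cp row i0
    i1 <- ends[keep[k]] + 1L       # last cp row of the run
    seg_cps <- cp_tab[i0:i1, ]
    gantry_moves <- length(unique(round(seg_cps$gantry_deg, 6))) > 1
    ap_const <- all(vapply(seq_len(nrow(seg_cps) - 1L), function(j) {
      isTRUE(all.equal(seg_cps$mlc_a[[j]], seg_cps$mlc_a[[j + 1]])) &&
        isTRUE(all.equal(seg_cps$mlc_b[[j]], seg_cps$mlc_b[[j + 1]])) &&
        isTRUE(all.equal(seg_cps$jaws[[j]], seg_cps$jaws[[j + 1]]))
    }, logical(1)))
    if (!ap_const) {
      abort(paste0("beam ", bn, ": aperture changes during a beam-on interval; ",
                   "dynamic-MLC delivery is not expressible as static segments"),
            class = "rtmc_unsupported_technique")
    }
    dwseg <- cp_tab$weight[i1] - cp_tab$weight[i0]
    tibble(
      beam_number = bn, beam_name = bname, segment = k,
      cp_start = cp_tab$cp[i0], cp_end = cp_tab$cp[i1],
      gantry_start_deg = seg_cps$gantry_deg[1],
      gantry_end_deg = seg_cps$gantry_deg[nrow(seg_cps)],
      gantry_moves = gantry_moves,
      collimator_deg = seg_cps$collimator_deg[1],
      table_deg = seg_cps$table_deg[1],
      iso = seg_cps$iso[1], jaws = seg_cps$jaws[1],
      mlc_a = seg_cps$mlc_a[1], mlc_b = seg_cps$mlc_b[1],
      dweight = dwseg, mu = meterset * dwseg)
  })
  bind_rows(rows)
}

.classify_technique <- function(beams, segments) {
  if (any(segments$gantry_moves)) return("MARC")
  per_beam <- table(segments$beam_number)
  if (all(per_beam == 1)) "STATIC" else "STEP_AND_SHOOT"
}

#' Circular midpoint of a gantry arc
#'
#' The arc runs from `start` to `end` in the direction of increasing angle
#' (mod 360); the midpoint of an arclet spanning 358 to 2 degrees is 0.
#' @keywords internal
arc_central_angle <- function(start_deg, end_deg) {
  width <- (end_deg - start_deg) %% 360
  (start_deg + width / 2) %% 360
}

#' Discretize a treatment plan into static beams
#'
#' Static and step-and-shoot segments are copied verbatim (one static beam
#' per deliverable segment).  mArc beam-on intervals become static beams at
#' the arclet's central gantry angle carrying the arclet's MU, with the
#' aperture held at the interval's state.  Delivery order is preserved and
#' the output MU total equals `plan$total_mu` exactly.
#'
#' @param plan an `rtmc_plan` from [parse_rtplan()] or [plan_from_beams()]
#' @return a tibble of static beams with columns `beam_id`, `gantry_deg`,
#'   `collimator_deg`, `table_deg`, `iso_x_mm`..`iso_z_mm`,
#'   `jaw_x1_mm`..`jaw_y2_mm`, list columns `mlc_a_mm`/`mlc_b_mm`, and `mu`
#' @export
discretize_plan <- function(plan) {
  stopifnot(inherits(plan, "rtmc_plan"))
  segs <- plan$segments
  if (plan$technique == "MARC") {
    bad <- segs$gantry_moves & (((segs$gantry_end_deg - segs$gantry_start_deg) %% 360) >= 360)
    if (any(bad)) abort("arclet spans a full circle", class = "rtmc_unsupported_technique")
    gantry <- ifelse(segs$gantry_moves,
                     arc_central_angle(segs$gantry_start_deg, segs$gantry_end_deg),
                     segs$gantry_start_deg)
  } else {
    gantry <- segs$gantry_start_deg
  }
  out <- tibble(
    beam_id = sprintf("B%02d.S%02d", segs$beam_number, segs$segment),
    gantry_deg = gantry %% 360,
    collimator_deg = segs$collimator_deg,
    table_deg = segs$table_deg,
    iso_x_mm = map_dbl(segs$iso, 1), iso_y_mm = map_dbl(segs$iso, 2),
    iso_z_mm = map_dbl(segs$iso, 3),
    jaw_x1_mm = map_dbl(segs$jaws, 1), jaw_x2_mm = map_dbl(segs$jaws, 2),
    jaw_y1_mm = map_dbl(segs$jaws, 3), jaw_y2_mm = map_dbl(segs$jaws, 4),
    mlc_a_mm = segs$mlc_a, mlc_b_mm = segs$mlc_b,
    mu = segs$mu)
  .validate_static_beams(out)
  lb <- plan$beams[[1]]$leaf_bounds
  if (!is.null(lb)) attr(out, "leaf_bounds_mm") <- lb
  out
}

.validate_static_beams <- function(beams) {
  stopifnot(all(beams$mu >= 0))
  if (any(beams$jaw_x1_mm > beams$jaw_x2_mm) || any(beams$jaw_y1_mm > beams$jaw_y2_mm)) {
    abort("invalid jaws: X1 > X2 or Y1 > Y2", class = "rtmc_plan_content_error")
  }
  for (i in seq_len(nrow(beams))) {
    a <- beams$mlc_a_mm[[i]]; b <- beams$mlc_b_mm[[i]]
    if (length(a) != length(b)) {
      abort("MLC banks have unequal leaf counts", class = "rtmc_plan_content_error")
    }
    if (any(a > b + 1e-9)) {
      abort("MLC bank A leaf beyond bank B", class = "rtmc_plan_content_error")
    }
  }
  invisible(beams)
}

#' Rebuild a static plan from discretized beams
#'
#' Produces an `rtmc_plan` (technique `STATIC`) whose deliverable segments
#' are exactly the given static beams; discretizing it returns the beams
#' unchanged, which makes discretization idempotent.
#'
#' @param beams a static-beam tibble as produced by [discretize_plan()]
#' @param patient_id patient identifier carried on the plan
#' @return an `rtmc_plan`
#' @export
plan_from_beams <- function(beams, patient_id = "") {
  .validate_static_beams(beams)
  segs <- tibble(
    beam_number = seq_len(nrow(beams)), beam_name = beams$beam_id, segment = 1L,
    cp_start = 0L, cp_end = 1L,
    gantry_start_deg = beams$gantry_deg, gantry_end_deg = beams$gantry_deg,
    gantry_moves = FALSE,
    collimator_deg = beams$collimator_deg, table_deg = beams$table_deg,
    iso = lapply(seq_len(nrow(beams)), function(i)
      c(beams$iso_x_mm[i], beams$iso_y_mm[i], beams$iso_z_mm[i])),
    jaws = lapply(seq_len(nrow(beams)), function(i)
      c(beams$jaw_x1_mm[i], beams$jaw_x2_mm[i], beams$jaw_y1_mm[i], beams$jaw_y2_mm[i])),
    mlc_a = beams$mlc_a_mm, mlc_b = beams$mlc_b_mm,
    dweight = 1, mu = beams$mu)
  structure(
    list(technique = "STATIC",
         beams = lapply(seq_len(nrow(beams)), function(i)
           list(beam_number = i, beam_name = beams$beam_id[i],
                meterset = beams$mu[i],
                leaf_bounds = attr(beams, "leaf_bounds_mm"),
                control_points = NULL, segments = segs[i, ])),
         segments = segs,
         total_mu = sum(beams$mu),
         patient_id = patient_id, plan_label = "rebuilt", source = NA_character_),
    class = "rtmc_plan")
}

#' @export
print.rtmc_plan <- function(x, ...) {
  cat("<rtmc_plan> technique:", x$technique,
      "| beams:", length(x$beams),
      "| segments:", nrow(x$segments),
      "| total MU:", format(x$total_mu), "\n")
  invisible(x)
}

#' Write static beams to the documented JSON schema
#'
#' The schema is an object with `leaf_bounds_mm` (nullable array) and
#' `beams`, an array of objects mirroring the static-beam tibble columns
#' (`mlc_a_mm`/`mlc_b_mm` as arrays).
#'
#' @param beams static-beam tibble
#' @param path output path
#' @export
write_beams_json <- function(beams, path) {
  obj <- list(
    leaf_bounds_mm = attr(beams, "leaf_bounds_mm"),
    beams = lapply(seq_len(nrow(beams)), function(i) {
      r <- beams[i, ]
      list(beam_id = r$beam_id, gantry_deg = r$gantry_deg,
           collimator_deg = r$collimator_deg, table_deg = r$table_deg,
           isocenter_mm = c(r$iso_x_mm, r$iso_y_mm, r$iso_z_mm),
           jaws_mm = c(r$jaw_x1_mm, r$jaw_x2_mm, r$jaw_y1_mm, r$jaw_y2_mm),
           mlc_a_mm = r$mlc_a_mm[[1]], mlc_b_mm = r$mlc_b_mm[[1]], mu = r$mu)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_beams_json
#' @export
read_beams_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(obj$beams, function(b) {
    tibble(beam_id = b$beam_id, gantry_deg = b$gantry_deg,
           collimator_deg = b$collimator_deg, table_deg = b$table_deg,
           iso_x_mm = b$isocenter_mm[[1]], iso_y_mm = b$isocenter_mm[[2]],
           iso_z_mm = b$isocenter_mm[[3]],
           jaw_x1_mm = b$jaws_mm[[1]], jaw_x2_mm = b$jaws_mm[[2]],
           jaw_y1_mm = b$jaws_mm[[3]], jaw_y2_mm = b$jaws_mm[[4]],
           mlc_a_mm = list(unlist(b$mlc_a_mm)), mlc_b_mm = list(unlist(b$mlc_b_mm)),
           mu = b$mu)
  })
  out <- bind_rows(rows)
  if (!is.null(obj$leaf_bounds_mm)) attr(out, "leaf_bounds_mm") <- unlist(obj$leaf_bounds_mm)
  out
}
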