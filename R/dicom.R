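#' @useDynLib rtmc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn %||%
#' @importFrom stats approx sd setNames
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# Minimal DICOM codec: explicit-VR little-endian only, which is the transfer
# syntax this package writes (1.2.840.10008.1.2.1).  Datasets are named lists
# keyed "GGGGEEEE" (upper-case hex); each element is list(vr, value).  SQ
# values are lists of nested datasets.  Only the RT tags the pipeline needs
# are in the dictionary; unknown tags round-trip as raw payloads.
# ---------------------------------------------------------------------------

DICOM_TRANSFER_SYNTAX <- "1.2.840.10008.1.2.1"
UID_ROOT <- "1.2.826.0.1.3680043.10.424"

# keyword, group, element, vr
.dcm_dict_raw <- c(
  "SOPClassUID",              "0008", "0016", "UI",
  "SOPInstanceUID",           "0008", "0018", "UI",
  "Modality",                 "0008", "0060", "CS",
  "SeriesDescription",        "0008", "103E", "LO",
  "PatientName",              "0010", "0010", "PN",
  "PatientID",                "0010", "0020", "LO",
  "SliceThickness",           "0018", "0050", "DS",
  "StudyInstanceUID",         "0020", "000D", "UI",
  "SeriesInstanceUID",        "0020", "000E", "UI",
  "InstanceNumber",           "0020", "0013", "IS",
  "ImagePositionPatient",     "0020", "0032", "DS",
  "ImageOrientationPatient",  "0020", "0037", "DS",
  "FrameOfReferenceUID",      "0020", "0052", "UI",
  "SamplesPerPixel",          "0028", "0002", "US",
  "PhotometricInterpretation","0028", "0004", "CS",
  "NumberOfFrames",           "0028", "0008", "IS",
  "Rows",                     "0028", "0010", "US",
  "Columns",                  "0028", "0011", "US",
  "PixelSpacing",             "0028", "0030", "DS",
  "BitsAllocated",            "0028", "0100", "US",
  "BitsStored",               "0028", "0101", "US",
  "HighBit",                  "0028", "0102", "US",
  "PixelRepresentation",      "0028", "0103", "US",
  "RescaleIntercept",         "0028", "1052", "DS",
  "RescaleSlope",             "0028", "1053", "DS",
  "DoseUnits",                "3004", "0002", "CS",
  "DoseType",                 "3004", "0004", "CS",
  "DoseSummationType",        "3004", "000A", "CS",
  "GridFrameOffsetVector",    "3004", "000C", "DS",
  "DoseGridScaling",          "3004", "000E", "DS",
  "RTPlanLabel",              "300A", "0002", "SH",
  "FractionGroupSequence",    "300A", "0070", "SQ",
  "NumberOfFractionsPlanned", "300A", "0078", "IS",
  "BeamMeterset",             "300A", "0086", "DS",
  "FinalCumulativeMetersetWeight", "300A", "010E", "DS",
  "BeamSequence",             "300A", "00B0", "SQ",
  "BeamLimitingDeviceSequence","300A","00B6", "SQ",
  "RTBeamLimitingDeviceType", "300A", "00B8", "CS",
  "NumberOfLeafJawPairs",     "300A", "00BC", "IS",
  "LeafPositionBoundaries",   "300A", "00BE", "DS",
  "BeamNumber",               "300A", "00C0", "IS",
  "BeamName",                 "300A", "00C2", "LO",
  "BeamType",                 "300A", "00C4", "CS",
  "RadiationType",            "300A", "00C6", "CS",
  "NumberOfControlPoints",    "300A", "0110", "IS",
  "ControlPointSequence",     "300A", "0111", "SQ",
  "ControlPointIndex",        "300A", "0112", "IS",
  "NominalBeamEnergy",        "300A", "0114", "DS",
  "BeamLimitingDevicePositionSequence", "300A", "011A", "SQ",
  "LeafJawPositions",         "300A", "011C", "DS",
  "GantryAngle",              "300A", "011E", "DS",
  "GantryRotationDirection",  "300A", "011F", "CS",
  "BeamLimitingDeviceAngle",  "300A", "0120", "DS",
  "PatientSupportAngle",      "300A", "0122", "DS",
  "IsocenterPosition",        "300A", "012C", "DS",
  "CumulativeMetersetWeight", "300A", "0134", "DS",
  "ReferencedBeamSequence",   "300C", "0004", "SQ",
  "ReferencedBeamNumber",     "300C", "0006", "IS",
  "StructureSetLabel",        "3006", "0002", "SH",
  "StructureSetROISequence",  "3006", "0020", "SQ",
  "ROINumber",                "3006", "0022", "IS",
  "ROIName",                  "3006", "0026", "LO",
  "ROIContourSequence",       "3006", "0039", "SQ",
  "ContourSequence",          "3006", "0040", "SQ",
  "ContourGeometricType",     "3006", "0042", "CS",
  "NumberOfContourPoints",    "3006", "0046", "IS",
  "ContourData",              "3006", "0050", "DS",
  "ReferencedROINumber",      "3006", "0084", "IS",
  "PixelData",                "7FE0", "0010", "OW"
)

.dcm_dict <- local({
  m <- matrix(.dcm_dict_raw, ncol = 4, byrow = TRUE)
  d <- data.frame(keyword = m[, 1], group = m[, 2], element = m[, 3],
                  vr = m[, 4], stringsAsFactors = FALSE)
  d$key <- paste0(d$group, d$element)
  d
})

dcm_tag_key <- function(keyword) {
  i <- match(keyword, .dcm_dict$keyword)
  if (is.na(i)) abort(paste0("unknown DICOM keyword: ", keyword))
  .dcm_dict$key[i]
}

dcm_vr_of <- function(keyword) .dcm_dict$vr[match(keyword, .dcm_dict$keyword)]

# string VRs stored as character; numeric-string VRs parsed to numeric
.vr_string  <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST",
                 "TM", "UI", "UC", "UR", "UT")
.vr_numstr  <- c("DS", "IS")
.vr_4len    <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Build a DICOM data element
#'
#' @param keyword dictionary keyword (e.g. "GantryAngle")
#' @param value element value: character for string VRs, numeric for DS/IS/
#'   US/UL/FL/FD, raw for OB/OW, list of datasets for SQ
#' @return a tagged element suitable for [dcm_write()]
#' @keywords internal
dcm_element <- function(keyword, value) {
  vr <- dcm_vr_of(keyword)
  if (is.na(vr)) abort(paste0("unknown DICOM keyword: ", keyword))
  structure(list(vr = vr, value = value), key = dcm_tag_key(keyword))
}

#' Assemble a DICOM dataset from keyword/value pairs
#' @param ... named arguments, names are dictionary keywords
#' @keywords internal
dcm_dataset <- function(...) {
  args <- list(...)
  ds <- list()
  for (kw in names(args)) {
    el <- dcm_element(kw, args[[kw]])
    ds[[attr(el, "key")]] <- list(vr = el$vr, value = el$value)
  }
  ds
}

dcm_set <- function(ds, keyword, value) {
  el <- dcm_element(keyword, value)
  ds[[attr(el, "key")]] <- list(vr = el$vr, value = el$value)
  ds
}

#' Get a value from a parsed DICOM dataset by keyword
#' @param ds dataset as returned by [dcm_read()]
#' @param keyword dictionary keyword
#' @param default value when the element is absent
#' @keywords internal
dcm_get <- function(ds, keyword, default = NULL) {
  el <- ds[[dcm_tag_key(keyword)]]
  if (is.null(el)) default else el$value
}

dcm_has <- function(ds, keyword) !is.null(ds[[dcm_tag_key(keyword)]])

# --- serialization ---------------------------------------------------------

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) {
  x <- as.numeric(x)
  x <- ifelse(x > 2147483647, x - 4294967296, x)   # wrap to signed for writeBin
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

.dcm_encode_value <- function(vr, value) {
  if (vr %in% .vr_string) {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    b
  } else if (vr %in% .vr_numstr) {
    s <- paste(vapply(value, function(v) {
      if (vr == "IS") sprintf("%d", as.integer(v)) else sprintf("%.10g", v)
    }, character(1)), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) b <- c(b, charToRaw(" "))
    b
  } else if (vr %in% c("US", "SS")) {
    .u16(value)
  } else if (vr %in% c("UL", "SL")) {
    .u32(value)
  } else if (vr == "FL") {
    writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    stopifnot(is.raw(value))
    if (length(value) %% 2L == 1L) c(value, as.raw(0)) else value
  } else if (vr == "SQ") {
    items <- lapply(value, function(item_ds) {
      body <- .dcm_encode_dataset(item_ds)
      c(.u16(c(0xFFFE, 0xE000)), .u32(length(body)), body)
    })
    do.call(c, c(list(raw(0)), items))
  } else {
    abort(paste0("cannot encode VR ", vr))
  }
}

.dcm_encode_element <- function(key, el) {
  grp <- strtoi(substr(key, 1, 4), 16L)
  elm <- strtoi(substr(key, 5, 8), 16L)
  body <- .dcm_encode_value(el$vr, el$value)
  hdr <- c(.u16(c(grp, elm)), charToRaw(el$vr))
  if (el$vr %in% .vr_4len) {
    c(hdr, as.raw(c(0, 0)), .u32(length(body)), body)
  } else {
    c(hdr, .u16(length(body)), body)
  }
}

.dcm_encode_dataset <- function(ds) {
  keys <- sort(names(ds))  # DICOM requires ascending tag order
  parts <- lapply(keys, function(k) .dcm_encode_element(k, ds[[k]]))
  do.call(c, c(list(raw(0)), parts))
}

#' Write a DICOM Part-10 file (explicit VR little endian)
#'
#' @param ds dataset (named element list); must contain SOPClassUID and
#'   SOPInstanceUID, which are mirrored into the file meta group
#' @param path output file
#' @keywords internal
dcm_write <- function(ds, path) {
  sop_class <- dcm_get(ds, "SOPClassUID")
  sop_inst  <- dcm_get(ds, "SOPInstanceUID")
  if (is.null(sop_class) || is.null(sop_inst)) {
    abort("dataset must carry SOPClassUID and SOPInstanceUID")
  }
  meta_el <- function(grp, elm, vr, body) {
    hdr <- c(.u16(c(grp, elm)), charToRaw(vr))
    if (vr %in% .vr_4len) c(hdr, as.raw(c(0, 0)), .u32(length(body)), body)
    else c(hdr, .u16(length(body)), body)
  }
  ui <- function(s) {
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) c(b, as.raw(0)) else b
  }
  meta_body <- c(
    meta_el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    meta_el(0x0002, 0x0002, "UI", ui(sop_class)),
    meta_el(0x0002, 0x0003, "UI", ui(sop_inst)),
    meta_el(0x0002, 0x0010, "UI", ui(DICOM_TRANSFER_SYNTAX)),
    meta_el(0x0002, 0x0012, "UI", ui(paste0(UID_ROOT, ".1")))
  )
  meta <- c(meta_el(0x0002, 0x0000, "UL", .u32(length(meta_body))), meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(.dcm_encode_dataset(ds), con)
  invisible(path)
}

# --- parsing ---------------------------------------------------------------

.rd_u16 <- function(buf, pos) {
  sum(as.integer(buf[pos:(pos + 1L)]) * c(1L, 256L))
}
.rd_u32 <- function(buf, pos) {
  sum(as.numeric(buf[pos:(pos + 3L)]) * c(1, 256, 65536, 16777216))
}

.dcm_decode_value <- function(vr, body) {
  if (vr %in% .vr_string) {
    while (length(body) && body[length(body)] == as.raw(0)) body <- body[-length(body)]
    s <- sub(" +$", "", rawToChar(body))
    strsplit(s, "\\\\")[[1]] %||% character(0)
  } else if (vr %in% .vr_numstr) {
    while (length(body) && body[length(body)] == as.raw(0)) body <- body[-length(body)]
    s <- sub(" +$", "", rawToChar(body))
    if (nchar(s) == 0) return(numeric(0))
    as.numeric(strsplit(s, "\\\\")[[1]])
  } else if (vr %in% c("US", "SS")) {
    readBin(body, "integer", n = length(body) / 2L, size = 2,
            signed = (vr == "SS"), endian = "little")
  } else if (vr %in% c("UL", "SL")) {
    v <- readBin(body, "integer", n = length(body) / 4L, size = 4, endian = "little")
    if (vr == "UL") ifelse(v < 0, as.numeric(v) + 4294967296, as.numeric(v)) else v
  } else if (vr == "FL") {
    readBin(body, "numeric", n = length(body) / 4L, size = 4, endian = "little")
  } else if (vr == "FD") {
    readBin(body, "numeric", n = length(body) / 8L, size = 8, endian = "little")
  } else {
    body  # OB/OW/UN payloads stay raw
  }
}

# parse one dataset from buf[pos..limit]; returns list(ds=, pos=)
.dcm_parse_dataset <- function(buf, pos, limit) {
  ds <- list()
  while (pos <= limit) {
    grp <- .rd_u16(buf, pos); elm <- .rd_u16(buf, pos + 2L)
    # sequence/item delimiters
    if (grp == 0xFFFE) {
      if (elm == 0xE00D || elm == 0xE0DD) return(list(ds = ds, pos = pos + 8L))
      abort("unexpected item tag inside dataset")
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      abort("implicit-VR or corrupted DICOM stream; only explicit VR little endian is supported")
    }
    if (vr %in% .vr_4len) {
      len <- .rd_u32(buf, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- .rd_u16(buf, pos + 6L)
      pos <- pos + 8L
    }
    key <- sprintf("%04X%04X", grp, elm)
    if (vr == "SQ") {
      if (len == 4294967295) {  # undefined length
        res <- .dcm_parse_sq(buf, pos, limit, undefined = TRUE)
      } else {
        res <- .dcm_parse_sq(buf, pos, pos + len - 1L, undefined = FALSE)
      }
      ds[[key]] <- list(vr = "SQ", value = res$items)
      pos <- res$pos
    } else {
      if (len == 4294967295) abort("undefined length on non-SQ element unsupported")
      body <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0)
      ds[[key]] <- list(vr = vr, value = .dcm_decode_value(vr, body))
      pos <- pos + len
    }
  }
  list(ds = ds, pos = pos)
}

.dcm_parse_sq <- function(buf, pos, limit, undefined) {
  items <- list()
  repeat {
    if (!undefined && pos > limit) break
    grp <- .rd_u16(buf, pos); elm <- .rd_u16(buf, pos + 2L)
    if (grp == 0xFFFE && elm == 0xE0DD) { pos <- pos + 8L; break }  # SQ delimiter
    if (!(grp == 0xFFFE && elm == 0xE000)) abort("malformed sequence: missing item tag")
    ilen <- .rd_u32(buf, pos + 4L)
    pos <- pos + 8L
    if (ilen == 4294967295) {
      res <- .dcm_parse_dataset(buf, pos, length(buf))  # ends at item delimiter
    } else {
      res <- .dcm_parse_dataset(buf, pos, pos + ilen - 1L)
    }
    items[[length(items) + 1L]] <- res$ds
    pos <- res$pos
  }
  list(items = items, pos = pos)
}

#' Read a DICOM Part-10 file
#'
#' Supports the explicit-VR little-endian transfer syntax this package writes.
#'
#' @param path DICOM file
#' @return named dataset list (see [dcm_get()])
#' @keywords internal
dcm_read <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM") {
    abort(paste0("not a DICOM part-10 file: ", path))
  }
  pos <- 133L
  # file meta group (always explicit LE); group length tells us where it ends
  grp <- .rd_u16(buf, pos)
  if (grp != 2L) abort("missing DICOM file meta group")
  vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
  len <- .rd_u16(buf, pos + 6L)
  meta_len <- .rd_u32(buf, pos + 8L)
  pos <- pos + 12L
  meta_end <- pos + meta_len - 1L
  meta <- .dcm_parse_dataset(buf, pos, meta_end)
  ts <- dcm_get2(meta$ds, "00020010")
  if (!is.null(ts) && ts != DICOM_TRANSFER_SYNTAX) {
    abort(paste0("unsupported transfer syntax: ", ts,
                 " (only explicit VR little endian is supported)"))
  }
  res <- .dcm_parse_dataset(buf, meta$pos, length(buf))
  res$ds
}

dcm_get2 <- function(ds, key) {
  el <- ds[[key]]
  if (is.null(el)) NULL else el$value
}

#' Deterministic DICOM UID generation
#'
#' UIDs derive from a seed and a counter so identical fixture specifications
#' produce byte-identical files.
#' @keywords internal
dcm_uid <- function(seed, ...) {
  parts <- c(as.character(seed %% 100000000), vapply(list(...), as.character, character(1)))
  paste(c(UID_ROOT, parts), collapse = ".")
}
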