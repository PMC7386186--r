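# Minimal DICOM PS3.10 writer/reader for RT Plan objects, explicit-VR
# little-endian only. Covers exactly the tag subset documented below —
# enough to carry beams, monitor units, machine, energy, dose rate and
# gantry to any standards-conforming reader. Not a general DICOM toolkit.
#
# Tag subset written (all explicit VR little endian, defined lengths):
#   0008,0016 UI SOPClassUID (RT Plan Storage 1.2.840.10008.5.1.4.1.1.481.5)
#   0008,0018 UI SOPInstanceUID      0008,0020 DA StudyDate
#   0008,0060 CS Modality (RTPLAN)
#   0010,0010 PN PatientName         0010,0020 LO PatientID
#   300A,0002 SH RTPlanLabel         300A,0003 LO RTPlanName
#   300A,0070 SQ FractionGroupSequence
#     300A,0071 IS FractionGroupNumber  300A,0078 IS NumberOfFractionsPlanned
#     300A,0080 IS NumberOfBeams
#     300C,0004 SQ ReferencedBeamSequence
#       300A,0086 DS BeamMeterset       300C,0006 IS ReferencedBeamNumber
#   300A,00B0 SQ BeamSequence
#     300A,00B2 SH TreatmentMachineName 300A,00C0 IS BeamNumber
#     300A,00C2 LO BeamName            300A,00C3 ST BeamDescription ("TOTAL")
#     300A,00C4 CS BeamType (STATIC)   300A,00C6 CS RadiationType (PHOTON)
#     300A,0110 IS NumberOfControlPoints
#     300A,0111 SQ ControlPointSequence
#       300A,0112 IS ControlPointIndex 300A,0114 DS NominalBeamEnergy
#       300A,0115 DS DoseRateSet       300A,011E DS GantryAngle

dcm_uint <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_string_value <- function(value, vr) {
  s <- as.character(value)
  bytes <- charToRaw(s)
  if (length(bytes) %% 2 == 1) {
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  bytes
}

dcm_element <- function(group, elem, vr, bytes) {
  header <- c(dcm_uint(group, 2), dcm_uint(elem, 2), charToRaw(vr))
  if (vr %in% dcm_long_vrs) {
    c(header, as.raw(c(0, 0)), dcm_uint(length(bytes), 4), bytes)
  } else {
    c(header, dcm_uint(length(bytes), 2), bytes)
  }
}

dcm_str <- function(group, elem, vr, value) {
  dcm_element(group, elem, vr, dcm_string_value(value, vr))
}

# DS values: shortest exact-enough decimal representation, <= 16 chars
dcm_ds <- function(group, elem, value) {
  dcm_str(group, elem, "DS", formatC(value, format = "g", digits = 10))
}

dcm_item <- function(bytes) {
  c(dcm_uint(0xFFFE, 2), dcm_uint(0xE000, 2), dcm_uint(length(bytes), 4), bytes)
}

dcm_sequence <- function(group, elem, items) {
  dcm_element(group, elem, "SQ", unlist(items) %||% raw(0))
}

plan_instance_uid <- function(plan) {
  h <- digest::digest(list(plan$plan_name, plan$patient_id,
                           plan$fields$mu, format(plan$created)),
                      algo = "sha256")
  # 12 hex chars < 2^48, exact in double
  paste0("2.25.", format(strtoi(substr(h, 1, 6), 16L) * 2^24 +
                           strtoi(substr(h, 7, 12), 16L),
                         scientific = FALSE))
}

#' Write a plan as a minimal DICOM RT Plan file
#'
#' Explicit-VR little-endian DICOM with the standard 128-byte preamble and
#' file meta group; the tag subset (documented in the package source)
#' carries plan identity, one beam per treatment field with machine,
#' energy, dose rate and gantry in a single control point, and per-beam
#' metersets in the fraction group. Readable by any conforming DICOM
#' library.
#'
#' @param plan A `tbi_plan`.
#' @param path Output path (`.dcm`).
#' @return `path`, invisibly.
#' @export
dicom_write_rtplan <- function(plan, path) {
  validate_plan(plan)
  f <- plan$fields
  n <- nrow(f)
  uid <- plan_instance_uid(plan)
  sop_class <- "1.2.840.10008.5.1.4.1.1.481.5"

  ref_beams <- lapply(seq_len(n), function(i) dcm_item(c(
    dcm_ds(0x300A, 0x0086, f$mu[i]),
    dcm_str(0x300C, 0x0006, "IS", i)
  )))
  fraction_group <- dcm_item(c(
    dcm_str(0x300A, 0x0071, "IS", 1),
    dcm_str(0x300A, 0x0078, "IS", plan$num_fractions %||% 1),
    dcm_str(0x300A, 0x0080, "IS", n),
    dcm_sequence(0x300C, 0x0004, ref_beams)
  ))
  beams <- lapply(seq_len(n), function(i) {
    cp <- dcm_item(c(
      dcm_str(0x300A, 0x0112, "IS", 0),
      dcm_ds(0x300A, 0x0114, as.numeric(gsub("[^0-9.]", "", f$energy[i]))),
      dcm_ds(0x300A, 0x0115, f$dose_rate[i]),
      dcm_ds(0x300A, 0x011E, f$gantry[i])
    ))
    dcm_item(c(
      dcm_str(0x300A, 0x00B2, "SH", plan$machine %||% ""),
      dcm_str(0x300A, 0x00C0, "IS", i),
      dcm_str(0x300A, 0x00C2, "LO", f$name[i]),
      dcm_str(0x300A, 0x00C3, "ST", f$technique[i]),
      dcm_str(0x300A, 0x00C4, "CS", "STATIC"),
      dcm_str(0x300A, 0x00C6, "CS", "PHOTON"),
      dcm_str(0x300A, 0x0110, "IS", 1),
      dcm_sequence(0x300A, 0x0111, list(cp))
    ))
  })
  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", sop_class),
    dcm_str(0x0008, 0x0018, "UI", uid),
    dcm_str(0x0008, 0x0020, "DA", format(plan$created, "%Y%m%d")),
    dcm_str(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_str(0x0010, 0x0010, "PN", plan$patient_name),
    dcm_str(0x0010, 0x0020, "LO", plan$patient_id),
    dcm_str(0x300A, 0x0002, "SH", substr(plan$plan_name, 1, 16)),
    dcm_str(0x300A, 0x0003, "LO", plan$plan_name),
    dcm_sequence(0x300A, 0x0070, list(fraction_group)),
    dcm_sequence(0x300A, 0x00B0, beams)
  )
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", sop_class),
    dcm_str(0x0002, 0x0003, "UI", uid),
    dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_str(0x0002, 0x0012, "UI", "2.25.990017")
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint(length(meta_body), 4)),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

# --- reader ----------------------------------------------------------------

dcm_parse <- function(bytes, pos, end) {
  u16 <- function(p) as.integer(bytes[p]) + 256L * as.integer(bytes[p + 1])
  u32 <- function(p) u16(p) + 65536 * u16(p + 2)
  out <- list()
  while (pos <= end) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% dcm_long_vrs) {
      len <- u32(pos + 8)
      vpos <- pos + 12
    } else {
      len <- u16(pos + 6)
      vpos <- pos + 8
    }
    key <- sprintf("%04X,%04X", group, elem)
    if (vr == "SQ") {
      items <- list()
      ipos <- vpos
      iend <- vpos + len - 1
      while (ipos <= iend) {
        stopifnot(u16(ipos) == 0xFFFE, u16(ipos + 2) == 0xE000)
        ilen <- u32(ipos + 4)
        items[[length(items) + 1]] <-
          dcm_parse(bytes, ipos + 8, ipos + 8 + ilen - 1)
        ipos <- ipos + 8 + ilen
      }
      out[[key]] <- items
    } else if (len > 0) {
      raw_val <- bytes[vpos:(vpos + len - 1)]
      out[[key]] <- switch(
        vr,
        UL = u32(vpos),
        OB = raw_val,
        {
          s <- sub(" +$", "", rawToChar(raw_val[raw_val != as.raw(0)]))
          if (vr %in% c("IS", "DS")) as.numeric(s) else s
        }
      )
    } else {
      out[[key]] <- NULL
    }
    pos <- vpos + len
  }
  out
}

#' Read back a minimal DICOM RT Plan file
#'
#' Parses the explicit-VR little-endian files written by
#' [dicom_write_rtplan()] (defined-length sequences) and returns the plan
#' identity plus one row per beam.
#'
#' @param path Path to a `.dcm` file.
#' @return List with `patient_id`, `patient_name`, `plan_name`,
#'   `num_fractions` and a `beams` tibble (`number`, `name`, `machine`,
#'   `technique`, `energy_mv`, `dose_rate`, `gantry`, `mu`).
#' @export
dicom_read_rtplan <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(bytes[129:132]) != "DICM") {
    tbi_abort(paste0("not a DICOM file: ", path), "tbi_load_error")
  }
  ds <- dcm_parse(bytes, 133, length(bytes))
  fg <- ds[["300A,0070"]][[1]]
  metersets <- purrr::map_dfr(fg[["300C,0004"]], function(item) {
    tibble::tibble(number = item[["300C,0006"]], mu = item[["300A,0086"]])
  })
  beams <- purrr::map_dfr(ds[["300A,00B0"]], function(item) {
    cp <- item[["300A,0111"]][[1]]
    tibble::tibble(
      number = item[["300A,00C0"]],
      name = item[["300A,00C2"]],
      machine = item[["300A,00B2"]],
      technique = item[["300A,00C3"]],
      energy_mv = cp[["300A,0114"]],
      dose_rate = cp[["300A,0115"]],
      gantry = cp[["300A,011E"]]
    )
  })
  list(
    patient_id = ds[["0010,0020"]],
    patient_name = ds[["0010,0010"]],
    plan_name = ds[["300A,0003"]],
    num_fractions = fg[["300A,0078"]],
    beams = dplyr::left_join(beams, metersets, by = "number")
  )
}
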