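# Minimal single-frame CT DICOM I/O (explicit VR, little endian).
# Scope: uncompressed monochrome 16-bit CT slices with the geometry tags this
# pipeline needs. Compressed transfer syntaxes, sequences and multi-frame
# objects are out of scope.

# keyword -> c(group, element, VR)
.dicom_dict <- list(
  SOPClassUID              = c(0x0008L, 0x0016L, "UI"),
  SOPInstanceUID           = c(0x0008L, 0x0018L, "UI"),
  StudyDate                = c(0x0008L, 0x0020L, "DA"),
  SeriesDate               = c(0x0008L, 0x0021L, "DA"),
  AcquisitionDate          = c(0x0008L, 0x0022L, "DA"),
  ContentDate              = c(0x0008L, 0x0023L, "DA"),
  Modality                 = c(0x0008L, 0x0060L, "CS"),
  SeriesDescription        = c(0x0008L, 0x103EL, "LO"),
  DerivationDescription    = c(0x0008L, 0x2111L, "ST"),
  PatientName              = c(0x0010L, 0x0010L, "PN"),
  PatientID                = c(0x0010L, 0x0020L, "LO"),
  PatientBirthDate         = c(0x0010L, 0x0030L, "DA"),
  SliceThickness           = c(0x0018L, 0x0050L, "DS"),
  SpacingBetweenSlices     = c(0x0018L, 0x0088L, "DS"),
  StudyInstanceUID         = c(0x0020L, 0x000DL, "UI"),
  SeriesInstanceUID        = c(0x0020L, 0x000EL, "UI"),
  InstanceNumber           = c(0x0020L, 0x0013L, "IS"),
  ImagePositionPatient     = c(0x0020L, 0x0032L, "DS"),
  ImageOrientationPatient  = c(0x0020L, 0x0037L, "DS"),
  SamplesPerPixel          = c(0x0028L, 0x0002L, "US"),
  PhotometricInterpretation= c(0x0028L, 0x0004L, "CS"),
  Rows                     = c(0x0028L, 0x0010L, "US"),
  Columns                  = c(0x0028L, 0x0011L, "US"),
  PixelSpacing             = c(0x0028L, 0x0030L, "DS"),
  BitsAllocated            = c(0x0028L, 0x0100L, "US"),
  BitsStored               = c(0x0028L, 0x0101L, "US"),
  HighBit                  = c(0x0028L, 0x0102L, "US"),
  PixelRepresentation      = c(0x0028L, 0x0103L, "US"),
  RescaleIntercept         = c(0x0028L, 0x1052L, "DS"),
  RescaleSlope             = c(0x0028L, 0x1053L, "DS"),
  PixelData                = c(0x7FE0L, 0x0010L, "OW")
)

.dicom_tagkey <- function(group, element) sprintf("%04X%04X", group, element)
.dicom_keyword_by_tag <- local({
  m <- new.env(parent = emptyenv())
  for (kw in names(.dicom_dict)) {
    d <- .dicom_dict[[kw]]
    assign(sprintf("%04X%04X", as.integer(d[1]), as.integer(d[2])), kw, envir = m)
  }
  m
})

.uid_counter <- local({e <- new.env(); e$n <- 0L; e})

#' Generate a fresh DICOM UID
#'
#' Returns a new unique identifier under the 2.25 (UUID-derived) root. Two
#' calls never return the same value, independent of the global RNG state.
#'
#' @return Character scalar UID.
#' @export
new_uid <- function() {
  .uid_counter$n <- .uid_counter$n + 1L
  sprintf("2.25.%d%.0f%d%d",
          as.integer(Sys.getpid()) %% 100000L,
          floor(as.numeric(Sys.time()) * 1000) %% 2^31,
          .uid_counter$n,
          sample.int(.Machine$integer.max, 1, useHash = TRUE))
}

.uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.uint32 <- function(x) {
  # writeBin has no unsigned 32-bit; lengths here stay below 2^31
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

.encode_element <- function(group, element, vr, value) {
  body <- switch(vr,
    US = .uint16(value),
    UL = .uint32(value),
    OB = as.raw(value),
    OW = value,  # already raw
    {
      s <- paste(value, collapse = "\\")
      b <- charToRaw(s)
      if (length(b) %% 2 == 1) b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
      b
    })
  hdr <- c(.uint16(group), .uint16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
    c(hdr, as.raw(c(0, 0)), .uint32(length(body)), body)
  } else {
    if (length(body) > 65534) stop("element too long for short VR form")
    c(hdr, .uint16(length(body)), body)
  }
}

.encode_keyword <- function(keyword, value) {
  d <- .dicom_dict[[keyword]]
  if (is.null(d)) stop("unknown DICOM keyword: ", keyword)
  .encode_element(as.integer(d[1]), as.integer(d[2]), d[3], value)
}

.fmt_ds <- function(x) sprintf("%.10g", x)

.write_dicom_file <- function(path, tags, pixel_raw) {
  sop_uid <- tags$SOPInstanceUID
  meta <- c(
    .encode_element(0x0002L, 0x0001L, "OB", c(0L, 1L)),
    .encode_element(0x0002L, 0x0002L, "UI", tags$SOPClassUID),
    .encode_element(0x0002L, 0x0003L, "UI", sop_uid),
    .encode_element(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1"),
    .encode_element(0x0002L, 0x0012L, "UI", "2.25.731854902641")
  )
  grouplen <- .encode_element(0x0002L, 0x0000L, "UL", length(meta))
  order_keys <- names(.dicom_dict)[names(.dicom_dict) != "PixelData"]
  body <- raw(0)
  for (kw in order_keys) {
    if (!is.null(tags[[kw]])) {
      v <- tags[[kw]]
      if (.dicom_dict[[kw]][3] == "DS") v <- .fmt_ds(as.numeric(v))
      if (.dicom_dict[[kw]][3] == "IS") v <- format(as.integer(v))
      body <- c(body, .encode_keyword(kw, v))
    }
  }
  body <- c(body, .encode_keyword("PixelData", pixel_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), grouplen, meta, body), con)
  invisible(path)
}

#' Write a CT volume as a DICOM series
#'
#' Writes one explicit-VR little-endian single-frame CT file per slice along
#' the third (normal) axis. Intensities are stored as signed 16-bit integers
#' after inverting the rescale transform `HU = slope * stored + intercept`.
#'
#' @param vol A [ct_volume()].
#' @param out_dir Output directory (created if missing).
#' @param tags Named list of template metadata merged over the defaults; use
#'   it to carry e.g. `SeriesDescription` or a `DerivationDescription`
#'   provenance note. Per-slice geometry tags are always derived from `vol`.
#' @param slope,intercept Rescale transform used for storage.
#' @return Character vector of file paths, one per slice, in slice order.
#' @export
write_dicom_series <- function(vol, out_dir, tags = list(),
                               slope = 1, intercept = -1024) {
  stopifnot(inherits(vol, "ct_volume"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stored <- round((vol$data - intercept) / slope)
  if (min(stored) < -32768 || max(stored) > 32767) {
    bad <- if (max(stored) > 32767) max(vol$data) else min(vol$data)
    stop(sprintf("intensity %g HU is outside the signed 16-bit stored range", bad))
  }
  g <- vol$geometry
  base <- list(
    SOPClassUID = "1.2.840.10008.5.1.4.1.1.2",  # CT Image Storage
    StudyDate = "20200101", Modality = "CT",
    PatientName = "", PatientID = "",
    StudyInstanceUID = new_uid(), SeriesInstanceUID = new_uid(),
    SamplesPerPixel = 1L, PhotometricInterpretation = "MONOCHROME2",
    Rows = g$size[2], Columns = g$size[1],
    BitsAllocated = 16L, BitsStored = 16L, HighBit = 15L,
    PixelRepresentation = 1L,
    RescaleIntercept = intercept, RescaleSlope = slope,
    SliceThickness = vol$tags$SliceThickness %||% g$spacing[3],
    SpacingBetweenSlices = g$spacing[3]
  )
  base[names(tags)] <- tags
  nz <- g$size[3]
  paths <- character(nz)
  for (k in seq_len(nz)) {
    ipp <- voxel_to_world(g, c(0, 0, k - 1))
    t <- base
    t$SOPInstanceUID <- new_uid()
    t$InstanceNumber <- k
    t$ImagePositionPatient <- ipp
    t$ImageOrientationPatient <- c(g$direction[, 1], g$direction[, 2])
    t$PixelSpacing <- c(g$spacing[2], g$spacing[1])  # (row, column) spacing
    # pixel data row-major: slice array is [column, row]
    pix <- writeBin(as.integer(stored[, , k]), raw(), size = 2, endian = "little")
    paths[k] <- file.path(out_dir, sprintf("slice_%04d.dcm", k))
    .write_dicom_file(paths[k], t, pix)
  }
  paths
}

.parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  tags <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (implicit VR?) encoding in ", path)
    if (vr %in% c("OB", "OW", "OF", "UN", "UT", "SQ")) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (vstart + len - 1L > n) stop("truncated DICOM element in ", path)
    val_raw <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    kw <- get0(.dicom_tagkey(group, element), envir = .dicom_keyword_by_tag)
    if (!is.null(kw)) {
      vr_dict <- .dicom_dict[[kw]][3]
      tags[[kw]] <- switch(vr_dict,
        US = u16(vstart),
        UL = u32(vstart),
        OW = val_raw,
        DS = as.numeric(strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1]]),
        IS = as.integer(trimws(rawToChar(val_raw))),
        {
          s <- rawToChar(val_raw[val_raw != as.raw(0)])
          trimws(s)
        })
    }
    pos <- vstart + len
  }
  tags
}

#' Read a DICOM CT series as a geometric volume
#'
#' Reads every `.dcm` file in `directory`, sorts slices by the projection of
#' `ImagePositionPatient` onto the slice normal, applies the rescale transform
#' so intensities are Hounsfield units, and assembles the geometry from the
#' position/orientation/spacing tags.
#'
#' Rejected inputs: mixed `SeriesInstanceUID`s, inconsistent orientation,
#' non-uniform rescale slope/intercept, and inter-slice spacing that is not
#' uniform within `spacing_tol` millimetres.
#'
#' @param directory Directory containing the slice files of one series.
#' @param spacing_tol Allowed deviation of consecutive inter-slice gaps (mm).
#' @return A [ct_volume()]; shared metadata is kept in `$tags`.
#' @export
read_dicom_series <- function(directory, spacing_tol = 1e-2) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("no .dcm files in ", directory)
  slices <- lapply(files, .parse_dicom_file)
  uid <- unique(vapply(slices, function(s) s$SeriesInstanceUID %||% "", ""))
  if (length(uid) != 1) stop("mixed SeriesInstanceUIDs in one directory")
  iops <- vapply(slices, function(s) s$ImageOrientationPatient, numeric(6))
  if (max(abs(iops - iops[, 1])) > 1e-6) stop("inconsistent orientation across slices")
  rs <- vapply(slices, function(s) c(s$RescaleSlope %||% 1, s$RescaleIntercept %||% 0),
               numeric(2))
  if (max(abs(rs - rs[, 1])) > 0) stop("non-uniform rescale slope/intercept across slices")
  row_dir <- iops[1:3, 1]; col_dir <- iops[4:6, 1]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  proj <- vapply(slices, function(s) sum(s$ImagePositionPatient * normal), 0)
  ord <- order(proj)
  slices <- slices[ord]; proj <- proj[ord]
  nz <- length(slices)
  if (nz > 1) {
    gaps <- diff(proj)
    if (max(gaps) - min(gaps) > spacing_tol)
      stop("non-uniform inter-slice spacing (range ",
           signif(max(gaps) - min(gaps), 3), " mm)")
    dz <- mean(gaps)
    if (dz < 0) stop("degenerate slice positions")
    # orient the third axis along the actual position increments
    step <- (slices[[nz]]$ImagePositionPatient - slices[[1]]$ImagePositionPatient) / ((nz - 1) * dz)
    normal_used <- step / sqrt(sum(step^2))
  } else {
    dz <- slices[[1]]$SliceThickness %||% 1
    normal_used <- normal
  }
  s1 <- slices[[1]]
  ncol_px <- s1$Columns; nrow_px <- s1$Rows
  arr <- array(0, c(ncol_px, nrow_px, nz))
  for (k in seq_len(nz)) {
    sk <- slices[[k]]
    v <- readBin(sk$PixelData, "integer", n = ncol_px * nrow_px,
                 size = 2, signed = sk$PixelRepresentation %||% 1L == 1L,
                 endian = "little")
    arr[, , k] <- matrix(v, nrow = ncol_px)  # row-major stream -> [col, row]
  }
  hu <- rs[1, 1] * arr + rs[2, 1]
  geom <- volume_geometry(
    origin = s1$ImagePositionPatient,
    spacing = c(s1$PixelSpacing[2], s1$PixelSpacing[1], dz),
    direction = cbind(row_dir, col_dir, normal_used, deparse.level = 0),
    size = c(ncol_px, nrow_px, nz))
  shared <- s1[setdiff(names(s1), c("PixelData", "ImagePositionPatient",
                                    "InstanceNumber", "SOPInstanceUID"))]
  ct_volume(hu, geom, tags = shared)
}

#' Deidentify DICOM metadata
#'
#' Empties patient name/identifier tags, replaces every date tag by January 1
#' of its original year, and assigns fresh study/series/instance UIDs. Missing
#' tags are skipped silently; two calls on the same input yield distinct UIDs.
#'
#' @param tags Named list of DICOM metadata (keyword names, `DA` dates as
#'   `YYYYMMDD` strings).
#' @return The deidentified tag list.
#' @export
deidentify <- function(tags) {
  for (kw in c("PatientName", "PatientID")) {
    if (!is.null(tags[[kw]])) tags[[kw]] <- ""
  }
  date_keys <- names(tags)[grepl("Date$", names(tags))]
  for (kw in date_keys) {
    v <- tags[[kw]]
    if (is.character(v) && nchar(v) >= 4)
      tags[[kw]] <- paste0(substr(v, 1, 4), "0101")
  }
  for (kw in c("StudyInstanceUID", "SeriesInstanceUID", "SOPInstanceUID")) {
    if (!is.null(tags[[kw]])) tags[[kw]] <- new_uid()
  }
  tags
}

`%||%` <- function(a, b) if (is.null(a)) b else a
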