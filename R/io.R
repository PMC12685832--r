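# File formats ----------------------------------------------------------------
#
# NPY single-array files for waveforms/images (v1.0, C-order), the device
# CSV dialect for 12-lead exports, PNG images, and a minimal explicit-VR
# little-endian DICOM reader (uncompressed pixel data only). No R package in
# the dependency set reads NPY or DICOM, so both parsers are implemented
# here against the published format layouts.

#' Write a numeric array to an NPY file
#'
#' NPY version 1.0, little-endian float64 (`<f8`) or int32 (`<i4`), C-order.
#'
#' @param x Numeric/integer vector, matrix or array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
npy_write <- function(x, path) {
  dims <- dim(x) %||% length(x)
  descr <- if (is.integer(x)) "<i4" else "<f8"
  shape <- if (length(dims) == 1) paste0("(", dims, ",)") else
    paste0("(", paste(dims, collapse = ", "), ")")
  header <- paste0("{'descr': '", descr,
                   "', 'fortran_order': False, 'shape': ", shape, ", }")
  pad <- (64 - (10 + nchar(header) + 1) %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  # C-order = last index fastest; R arrays are column-major, so permute
  v <- if (length(dims) > 1) as.vector(aperm(x, rev(seq_along(dims)))) else
    as.vector(x)
  if (is.integer(x)) {
    writeBin(v, con, size = 4, endian = "little")
  } else {
    writeBin(as.double(v), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read an NPY file
#'
#' Supports v1.0/2.0 headers with dtypes `<f8`, `<f4`, `<i4`, `<i8`, `|u1`,
#' `|i1`, C- or Fortran-order.
#'
#' @param path NPY file path.
#' @return Numeric vector/matrix/array with the stored shape.
#' @export
npy_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  assert_that(identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))),
              "not an NPY file: ", path, class = "coopAS_format_error")
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2) {
    readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  dims <- dims[!is.na(dims)]
  n <- if (length(dims) == 0) 1L else prod(dims)
  data <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    "<i8" = as.integer(readBin(con, "double", n, size = 8,
                               endian = "little")),
    "|u1" = as.integer(readBin(con, "raw", n)),
    "|i1" = readBin(con, "integer", n, size = 1),
    stop_coop("unsupported NPY dtype: ", descr,
              class = "coopAS_format_error"))
  if (length(dims) <= 1) return(data)
  if (fortran) array(data, dims) else aperm(array(data, rev(dims)),
                                            rev(seq_along(dims)))
}

#' Read a 12-lead ECG device CSV export
#'
#' Expects one numeric column per lead in mV, optionally headed by lead
#' names; headed files may list leads in any order and are mapped back to
#' the canonical order I, II, III, aVR, aVL, aVF, V1-V6. Headerless files
#' are assumed to already follow that order.
#'
#' @param path CSV file path.
#' @param fs Sampling rate the export is asserted to carry (default 500 Hz;
#'   recorded as an attribute).
#' @return 12 x N numeric matrix in mV, rows named by lead, with attribute
#'   `fs`.
#' @export
load_ecg_csv <- function(path, fs = 500) {
  assert_that(file.exists(path), "file not found: ", path)
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  canon <- ecg_lead_names()
  has_header <- all(toupper(trimws(as.character(first[1, ]))) %in%
                      toupper(canon))
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  if (ncol(df) != 12) {
    stop_coop("expected 12 lead columns (", paste(canon, collapse = ", "),
              "), found ", ncol(df), class = "coopAS_format_error")
  }
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) {
    stop_coop("non-numeric values in lead column(s): ",
              paste(names(df)[!num], collapse = ", "),
              class = "coopAS_format_error")
  }
  m <- t(as.matrix(df))
  if (has_header) {
    idx <- match(toupper(canon), toupper(rownames(m)))
    m <- m[idx, , drop = FALSE]
  }
  rownames(m) <- canon
  attr(m, "fs") <- fs
  m
}

# Minimal explicit-VR little-endian DICOM parser: enough to recover
# uncompressed grayscale pixel data plus the geometry/photometric tags.
read_dicom_minimal <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  assert_that(length(raw) > 132 &&
                rawToChar(raw[129:132]) == "DICM",
              "not a DICOM file (missing DICM magic): ", path,
              class = "coopAS_format_error")
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  pos <- 133L
  tags <- list()
  pixel <- NULL
  while (pos + 8 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop_coop("implicit-VR DICOM is not supported",
                class = "coopAS_format_error")
    }
    if (vr %in% long_vrs) {
      len <- u32(pos + 8)
      body <- pos + 12L
    } else {
      len <- u16(pos + 6)
      body <- pos + 8L
    }
    if (len == 4294967295) {
      stop_coop("undefined-length DICOM elements are not supported",
                class = "coopAS_format_error")
    }
    if (body + len - 1 > length(raw)) {
      stop_coop("truncated DICOM element at byte ", pos,
                class = "coopAS_format_error")
    }
    key <- sprintf("%04x,%04x", group, elem)
    if (group == 0x7FE0 && elem == 0x0010) {
      pixel <- raw[body:(body + len - 1)]
      break
    }
    if (key %in% c("0028,0004", "0028,0010", "0028,0011",
                   "0028,0100", "0028,0103")) {
      tags[[key]] <- if (vr == "US") u16(body) else
        trimws(rawToChar(raw[body:(body + len - 1)]))
    }
    pos <- body + len
  }
  assert_that(!is.null(pixel), "DICOM file carries no pixel data",
              class = "coopAS_format_error")
  rows <- tags[["0028,0010"]]; cols <- tags[["0028,0011"]]
  bits <- tags[["0028,0100"]] %||% 8L
  photometric <- tags[["0028,0004"]] %||% "MONOCHROME2"
  assert_that(!is.null(rows) && !is.null(cols),
              "DICOM file lacks Rows/Columns tags",
              class = "coopAS_format_error")
  vals <- if (bits <= 8) {
    as.integer(pixel[seq_len(rows * cols)])
  } else {
    p <- pixel[seq_len(2 * rows * cols)]
    as.integer(p[c(TRUE, FALSE)]) + 256L * as.integer(p[c(FALSE, TRUE)])
  }
  m <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  if (toupper(photometric) == "MONOCHROME1") {
    # inverted grayscale: smallest stored value displays white
    m <- as.integer(2^as.integer(bits) - 1) - m
  } else if (toupper(photometric) != "MONOCHROME2") {
    stop_coop("unsupported photometric interpretation: ", photometric,
              class = "coopAS_format_error")
  }
  list(pixels = m, bits = as.integer(bits), photometric = photometric)
}

#' Load a grayscale image (PNG or DICOM)
#'
#' PNG files pass through with 8-bit metadata (multi-channel files are
#' collapsed by channel mean). DICOM files (explicit VR, little endian,
#' uncompressed) have their pixel data extracted, with MONOCHROME1
#' photometric inversion applied and the stored bit depth recorded.
#'
#' @param path Image file path.
#' @return List with `pixels` (integer matrix), `bits` (bit depth) and,
#'   for DICOM, `photometric`.
#' @export
load_image <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path), error = function(e) {
      stop_coop("unreadable PNG: ", conditionMessage(e),
                class = "coopAS_format_error")
    })
    if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
    list(pixels = matrix(as.integer(round(arr * 255)),
                         nrow(arr), ncol(arr)),
         bits = 8L)
  } else if (ext %in% c("dcm", "dicom")) {
    read_dicom_minimal(path)
  } else {
    stop_coop("unsupported image format: .", ext,
              class = "coopAS_format_error")
  }
}

#' Save / load a cohort directory
#'
#' One directory per cohort: per record, the waveform, image and (when
#' present) signal mask as NPY files, plus a `manifest.csv` with ids, study
#' days, echo measurements, label and (synthetic cohorts) severity.
#' Round-trips arrays bit-exactly.
#'
#' @param cohort A `coop_cohort`.
#' @param dir Output directory (created if needed).
#' @return `save_cohort` returns `dir` invisibly; `load_cohort` the cohort.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in cohort) {
    npy_write(unclass(r$ecg), file.path(dir, paste0(r$record_id, "_ecg.npy")))
    npy_write(r$image, file.path(dir, paste0(r$record_id, "_cxr.npy")))
    if (!is.null(r$signal_mask)) {
      npy_write(matrix(as.integer(r$signal_mask), nrow(r$signal_mask)),
                file.path(dir, paste0(r$record_id, "_mask.npy")))
    }
  }
  man <- cohort_manifest(cohort)
  man$severity <- vapply(cohort, function(r)
    r$severity %||% NA_real_, numeric(1))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  assert_that(file.exists(man_path), "no manifest.csv in ", dir)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(man)), function(i) {
    rid <- man$record_id[i]
    ecg <- npy_read(file.path(dir, paste0(rid, "_ecg.npy")))
    rownames(ecg) <- ecg_lead_names()
    mask_path <- file.path(dir, paste0(rid, "_mask.npy"))
    list(patient_id = man$patient_id[i],
         record_id = rid,
         ecg = ecg,
         image = npy_read(file.path(dir, paste0(rid, "_cxr.npy"))),
         signal_mask = if (file.exists(mask_path))
           npy_read(mask_path) == 1L,
         echo = echo_measurements(man$peak_velocity[i],
                                  man$mean_gradient[i],
                                  man$valve_area[i]),
         label = as.logical(man$label[i]),
         severity = man$severity[i],
         echo_day = man$echo_day[i],
         cxr_day = man$cxr_day[i],
         ecg_day = man$ecg_day[i])
  })
  structure(records, class = "coop_cohort")
}
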