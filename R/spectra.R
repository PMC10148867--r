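# Peak-list ingestion (MGF; mzML via mzR when available), spectrum
# preprocessing, and ppm tolerance arithmetic.

#' Read a peak list into a spectrum table
#'
#' Parses an MGF file (BEGIN IONS/END IONS blocks with TITLE, PEPMASS,
#' CHARGE, RTINSECONDS, SCANS) into one row per MS2 scan. TPP-style titles
#' (`file.scan.scan.charge`) are parsed into the `file` and `scan` columns.
#' Spectra lacking a CHARGE line default to charge 2, with a warning. Peaks
#' are returned sorted by ascending m/z. mzML files are read through the
#' mzR package when it is installed (uncompressed binary arrays).
#'
#' @param path Path to the peak-list file.
#' @param format `"mgf"` or `"mzml"`; default guesses from the extension.
#' @return A tibble of class `spectra_tbl` with columns `file`, `scan`,
#'   `title`, `premz`, `charge`, `rt`, `n_peaks` and `peaks` (list column
#'   of tibbles with `mz`, `intensity`).
#' @export
read_peaklist <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "mgf"
  }
  if (format == "mzml") return(.read_mzml(path))
  read_mgf(path)
}

#' @rdname read_peaklist
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) abort(paste0("Peak list not found: ", path))
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    abort(paste0("Malformed MGF '", path, "': unbalanced BEGIN/END IONS"))
  }
  if (length(begins) == 0L) abort(paste0("No spectra in MGF '", path, "'"))

  n_nocharge <- 0L
  specs <- vector("list", length(begins))
  for (s in seq_along(begins)) {
    block <- lines[(begins[s] + 1L):(ends[s] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_

    title <- getv("TITLE")
    pepmass <- getv("PEPMASS")
    if (is.na(pepmass)) {
      abort(paste0("Malformed MGF '", path, "': spectrum ", s,
                   " (line ", begins[s], ") has no PEPMASS"))
    }
    premz <- as.numeric(stringr::str_split_1(trimws(pepmass), "\\s+")[1])
    ch_txt <- getv("CHARGE")
    if (is.na(ch_txt)) {
      charge <- 2L
      n_nocharge <- n_nocharge + 1L
    } else {
      charge <- as.integer(sub("\\+$", "", trimws(ch_txt)))
    }
    rt <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    scan_txt <- getv("SCANS")

    peak_lines <- block[!is_kv & nzchar(trimws(block))]
    if (length(peak_lines)) {
      pm <- do.call(rbind, strsplit(trimws(peak_lines), "[ \t]+"))
      mz <- as.numeric(pm[, 1])
      intensity <- as.numeric(pm[, 2])
      if (anyNA(mz) || anyNA(intensity)) {
        abort(paste0("Malformed MGF '", path, "': non-numeric peak in ",
                     "spectrum ", s, " (line ", begins[s], ")"))
      }
    } else {
      mz <- numeric(0); intensity <- numeric(0)
    }
    o <- order(mz)

    file_scan <- .parse_tpp_title(title)
    scan <- if (!is.na(scan_txt)) as.integer(scan_txt) else file_scan$scan
    specs[[s]] <- tibble::tibble(
      file = file_scan$file %||% basename(path),
      scan = scan %||% s,
      title = title %||% NA_character_,
      premz = premz,
      charge = charge,
      rt = rt,
      n_peaks = length(mz),
      peaks = list(tibble::tibble(mz = mz[o], intensity = intensity[o]))
    )
  }
  if (n_nocharge > 0L) {
    warn(paste0(n_nocharge, " spectrum/spectra in '", path,
                "' had no CHARGE line; defaulting to 2+"))
  }
  out <- dplyr::bind_rows(specs)
  class(out) <- unique(c("spectra_tbl", class(out)))
  out
}

.parse_tpp_title <- function(title) {
  if (is.null(title) || is.na(title)) return(list(file = NULL, scan = NULL))
  m <- stringr::str_match(title, "^(.*)\\.([0-9]+)\\.([0-9]+)\\.[0-9]+")
  if (!is.na(m[1, 1])) {
    return(list(file = m[1, 2], scan = as.integer(m[1, 3])))
  }
  m2 <- stringr::str_match(title, "scan=([0-9]+)")
  list(file = NULL,
       scan = if (!is.na(m2[1, 2])) as.integer(m2[1, 2]) else NULL)
}

.read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("Reading mzML requires the mzR package; convert to MGF instead.")
  }
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  ms2 <- which(h$msLevel == 2L)
  specs <- lapply(ms2, function(i) {
    pk <- mzR::peaks(ms, i)
    o <- order(pk[, 1])
    tibble::tibble(
      file = basename(path),
      scan = h$acquisitionNum[i],
      title = NA_character_,
      premz = h$precursorMZ[i],
      charge = max(1L, h$precursorCharge[i]),
      rt = h$retentionTime[i],
      n_peaks = nrow(pk),
      peaks = list(tibble::tibble(mz = pk[o, 1], intensity = pk[o, 2]))
    )
  })
  out <- dplyr::bind_rows(specs)
  class(out) <- unique(c("spectra_tbl", class(out)))
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra A spectrum tibble as from [read_mgf()].
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    pk <- spectra$peaks[[i]]
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", if (!is.na(spectra$title[i])) spectra$title[i] else
        paste0(spectra$file[i], ".", spectra$scan[i], ".", spectra$scan[i],
               ".", spectra$charge[i])),
      paste0("PEPMASS=", sprintf("%.6f", spectra$premz[i])),
      paste0("CHARGE=", spectra$charge[i], "+"),
      if (!is.na(spectra$rt[i])) paste0("RTINSECONDS=",
                                        sprintf("%.3f", spectra$rt[i])),
      paste0("SCANS=", spectra$scan[i]),
      sprintf("%.6f %.4f", pk$mz, pk$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Retain the top-N most intense peaks
#'
#' Keeps the `top_n` most abundant product ions of each spectrum (ties at
#' the cutoff resolved in favour of the lower m/z peak), restores ascending
#' m/z order and records the retained count in `n_peaks`.
#'
#' @param spectra Spectrum tibble.
#' @param top_n Number of peaks to retain (default 100).
#' @return The preprocessed spectrum tibble.
#' @export
preprocess_spectra <- function(spectra, top_n = 100L) {
  stopifnot(top_n >= 1L)
  spectra$peaks <- purrr::map(spectra$peaks, function(pk) {
    if (nrow(pk) <= top_n) return(pk)
    o <- order(-pk$intensity, pk$mz, method = "radix")
    keep <- sort(o[seq_len(top_n)])
    pk[keep, , drop = FALSE]
  })
  spectra$n_peaks <- vapply(spectra$peaks, nrow, integer(1))
  spectra
}

#' Relative mass error and tolerance match
#'
#' The signed error is `(observed - theoretical) / theoretical * 1e6` ppm;
#' a match requires `|error| <= tol` (inclusive bounds).
#'
#' @param observed,theoretical Positive m/z values (vectorized).
#' @param tol Tolerance in ppm.
#' @return A tibble with columns `error_ppm` and `match`.
#' @export
#' @examples
#' ppm_match(1000.02, 1000, tol = 20)
ppm_match <- function(observed, theoretical, tol = 20) {
  err <- ppm_error(observed, theoretical)
  tibble::tibble(error_ppm = err, match = abs(err) <= tol)
}

#' @rdname ppm_match
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
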