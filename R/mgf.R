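# Mascot generic format (MGF) reading and writing.
#
# MGF is the text interchange format the marker-ion workflow consumes:
# BEGIN IONS / TITLE / PEPMASS mz [intensity] / RTINSECONDS / CHARGE blocks
# with "mz intensity" peak lines. The parser is deliberately strict about
# the fields the downstream contract needs (precursor m/z) and tolerant
# about optional ones (intensity, RT, charge).

#' Construct an MS/MS spectrum
#'
#' @param scan_id scan identifier (TITLE).
#' @param precursor_mz precursor m/z in Da (> 0).
#' @param precursor_intensity precursor intensity in counts (`NA` if absent).
#' @param rt retention time in minutes (`NA` if absent).
#' @param peaks two-column numeric matrix (mz, intensity); will be sorted by
#'   ascending m/z.
#' @param charge integer charge state or `NA`.
#' @return an object of class `msms_spectrum`.
#' @export
msms_spectrum <- function(scan_id, precursor_mz, precursor_intensity = NA_real_,
                          rt = NA_real_, peaks = NULL, charge = NA_integer_) {
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L ||
      !is.finite(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be a single positive number")
  if (is.null(peaks)) peaks <- matrix(numeric(0), ncol = 2)
  peaks <- matrix(as.numeric(peaks), ncol = 2,
                  dimnames = list(NULL, c("mz", "intensity")))
  if (any(peaks[, "intensity"] < 0)) stop("peak intensities must be >= 0")
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  structure(list(scan_id = as.character(scan_id),
                 precursor_mz = precursor_mz,
                 precursor_intensity = as.numeric(precursor_intensity),
                 rt = as.numeric(rt),
                 charge = as.integer(charge),
                 peaks = peaks),
            class = "msms_spectrum")
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("<msms_spectrum> %s  precursor %.4f m/z  rt %.2f min  %d peaks\n",
              x$scan_id, x$precursor_mz, x$rt, nrow(x$peaks)))
  invisible(x)
}

#' Read MS/MS spectra from an MGF file
#'
#' @param path path to a `.mgf` file.
#' @return a list of [msms_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  lapply(seq_along(begin), function(i) {
    block <- lines[(begin[i] + 1):(end[i] - 1)]
    is_header <- grepl("=", block, fixed = TRUE)
    headers <- block[is_header]
    keys <- toupper(sub("=.*$", "", headers))
    vals <- sub("^[^=]*=", "", headers)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pepmass <- strsplit(trimws(get("PEPMASS")), "[ \t]+")[[1]]
    rt_s <- suppressWarnings(as.numeric(get("RTINSECONDS")))
    charge <- suppressWarnings(as.integer(sub("[+-]$", "", get("CHARGE"))))
    peak_lines <- trimws(block[!is_header])
    peak_lines <- peak_lines[nzchar(peak_lines)]
    peaks <- if (length(peak_lines)) {
      fields <- strsplit(peak_lines, "[ \t]+")
      matrix(as.numeric(unlist(lapply(fields, `[`, 1:2))),
             ncol = 2, byrow = TRUE)
    } else NULL
    msms_spectrum(
      scan_id = if (is.na(get("TITLE"))) sprintf("scan_%d", i) else get("TITLE"),
      precursor_mz = as.numeric(pepmass[1]),
      precursor_intensity = if (length(pepmass) > 1)
        as.numeric(pepmass[2]) else NA_real_,
      rt = rt_s / 60,
      peaks = peaks,
      charge = charge
    )
  })
}

#' Write MS/MS spectra to an MGF file
#'
#' Numbers are formatted at fixed precision so identical spectra always
#' serialize byte-identically.
#'
#' @param spectra list of [msms_spectrum()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(sp) {
    header <- c(
      "BEGIN IONS",
      paste0("TITLE=", sp$scan_id),
      sprintf("PEPMASS=%.5f %.2f", sp$precursor_mz,
              ifelse(is.na(sp$precursor_intensity), 0, sp$precursor_intensity)),
      if (!is.na(sp$rt)) sprintf("RTINSECONDS=%.3f", sp$rt * 60),
      if (!is.na(sp$charge)) sprintf("CHARGE=%d+", sp$charge)
    )
    peaks <- if (nrow(sp$peaks))
      sprintf("%.5f %.2f", sp$peaks[, "mz"], sp$peaks[, "intensity"])
    paste(c(header, peaks, "END IONS"), collapse = "\n")
  }, character(1))
  writeLines(blocks, path, sep = "\n\n")
  invisible(path)
}
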