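# File formats. Spectra travel as two-column CSV with '#'-prefixed header
# metadata; cubes as a structured text container (a JSON header line with
# geometry/axis/mask, then the [frequency x pixels] gain matrix as TSV,
# serialized with full float precision); maps as one 32-bit float TIFF per
# quantity with a JSON sidecar. Masked pixels encode as NaN in TIFF and as
# an explicit mask in the cube container.

fmtFull <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write / read a spectrum as CSV
#'
#' Two columns (\code{frequency_ghz}, \code{gain}) preceded by '#'-prefixed
#' metadata lines (integration time, DC level, seed). The roundtrip
#' reproduces values to full double precision.
#'
#' @param spectrum a \code{\link{BrillouinSpectrum}}.
#' @param path file path.
#' @return \code{writeSpectrumCsv} returns \code{path} invisibly;
#'   \code{readSpectrumCsv} returns a \code{\link{BrillouinSpectrum}}.
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  stopIfNot(is(spectrum, "BrillouinSpectrum"), "'spectrum' must be a BrillouinSpectrum")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# integration_time_ms: %s", fmtFull(spectrum@integrationTimeMs)),
    sprintf("# dc_level: %s", fmtFull(spectrum@dcLevel)),
    sprintf("# seed: %s", ifelse(is.na(spectrum@seed), "NA", spectrum@seed)),
    "frequency_ghz,gain",
    paste(fmtFull(spectrum@freqGHz), fmtFull(spectrum@gain), sep = ",")), con)
  invisible(path)
}

#' @rdname writeSpectrumCsv
#' @export
readSpectrumCsv <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in metaLines) {
    kv <- regmatches(m, regexec("^#\\s*([a-z_]+):\\s*(.*)$", m))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || !identical(body[1], "frequency_ghz,gain"))
    stop("missing 'frequency_ghz,gain' column header in ", path)
  dat <- read.table(text = body[-1], sep = ",", col.names = c("f", "g"))
  if (any(diff(dat$f) <= 0))
    stop("frequency axis in ", path, " is not strictly increasing")
  seed <- suppressWarnings(as.integer(meta$seed))
  BrillouinSpectrum(
    freqGHz = dat$f, gain = dat$g,
    integrationTimeMs = as.numeric(meta$integration_time_ms %||% 20),
    dcLevel = as.numeric(meta$dc_level %||% 100),
    seed = if (length(seed) && !is.na(seed)) seed else NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

geometryToList <- function(g) list(
  nx = g@nx, ny = g@ny, nz = g@nz, step_x_um = g@stepX, step_y_um = g@stepY,
  step_z_um = g@stepZ, pixel_time_ms = g@pixelTimeMs, n_freq = g@nFreq,
  serpentine = g@serpentine, z_flip = g@zFlip,
  stage_delay_ms = g@stageDelayMs, shift_direction = g@shiftDirection)

geometryFromList <- function(l) {
  need <- c("nx", "ny", "nz", "step_x_um", "step_y_um", "step_z_um",
            "pixel_time_ms", "n_freq", "serpentine", "z_flip",
            "stage_delay_ms", "shift_direction")
  miss <- setdiff(need, names(l))
  if (length(miss))
    stop("missing geometry attribute(s): ", paste(miss, collapse = ", "))
  ScanGeometry(nx = as.integer(l$nx), ny = as.integer(l$ny),
               nz = as.integer(l$nz), stepX = l$step_x_um,
               stepY = l$step_y_um, stepZ = l$step_z_um,
               pixelTimeMs = l$pixel_time_ms, nFreq = as.integer(l$n_freq),
               serpentine = as.logical(l$serpentine),
               zFlip = as.logical(l$z_flip), stageDelayMs = l$stage_delay_ms,
               shiftDirection = l$shift_direction)
}

#' Write / read a spectral cube
#'
#' Text container for a \code{\link{SpectralCube}}: a JSON header line
#' (prefixed \code{#}) carrying the geometry attributes, followed by
#' \code{#axis} and \code{#mask} header lines and the [frequency x pixels]
#' gain matrix as tab-separated rows, all numbers written with full float
#' precision so the roundtrip is bit-exact. Missing geometry attributes on
#' read are an error naming the attribute.
#'
#' @param cube a \code{\link{SpectralCube}}.
#' @param path file path (conventionally ".sbscube.tsv").
#' @return \code{writeCube} returns \code{path} invisibly; \code{readCube}
#'   returns a \code{\link{SpectralCube}}.
#' @export
writeCube <- function(cube, path) {
  stopIfNot(is(cube, "SpectralCube"), "'cube' must be a SpectralCube")
  hdr <- jsonlite::toJSON(list(
    format = "sbs-cube-v1",
    geometry = geometryToList(scanGeometry(cube))), auto_unbox = TRUE,
    digits = NA)
  A <- SummarizedExperiment::assay(cube, "gain")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  writeLines(paste0("#axis\t",
                    paste(fmtFull(frequencyAxis(cube)), collapse = "\t")), con)
  writeLines(paste0("#mask\t",
                    paste(as.integer(pixelMask(cube)), collapse = "\t")), con)
  writeLines(apply(A, 1L, function(r) paste(fmtFull(r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname writeCube
#' @export
readCube <- function(path) {
  lines <- readLines(path)
  stopIfNot(length(lines) >= 4L && startsWith(lines[1], "#"),
            "not a cube container: missing JSON header line")
  hdr <- jsonlite::fromJSON(substring(lines[1], 2L))
  stopIfNot(identical(hdr$format, "sbs-cube-v1"),
            "unrecognized cube container format")
  geom <- geometryFromList(hdr$geometry)
  stopIfNot(startsWith(lines[2], "#axis\t") && startsWith(lines[3], "#mask\t"),
            "missing #axis / #mask header lines")
  ax <- as.numeric(strsplit(substring(lines[2], 7L), "\t", fixed = TRUE)[[1]])
  mask <- as.integer(strsplit(substring(lines[3], 7L), "\t", fixed = TRUE)[[1]]) > 0L
  A <- do.call(rbind, lapply(lines[-(1:3)], function(r)
    suppressWarnings(as.numeric(strsplit(r, "\t", fixed = TRUE)[[1]]))))
  stopIfNot(nrow(A) == geom@nFreq,
            "gain matrix row count does not match geometry n_freq")
  SpectralCube(A, ax, geom, mask = mask)
}

#' Export Brillouin maps as 32-bit float TIFF
#'
#' Writes one 32-bit float TIFF per map quantity (masked pixels as NaN) plus
#' a JSON sidecar with the units, pixel steps in micrometres and the
#' masked-pixel sentinel. Multi-plane maps become multi-directory TIFFs.
#'
#' @param maps a \code{\link{BrillouinMaps}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of files written (including the
#'   sidecar).
#' @export
writeMapsTiff <- function(maps, dir) {
  stopIfNot(is(maps, "BrillouinMaps"), "'maps' must be a BrillouinMaps")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- maps@geometry
  files <- character(0)
  for (nm in names(maps@maps)) {
    arr <- maps@maps[[nm]]
    arr[is.na(arr)] <- NaN
    # TIFF planes are [row(y) x col(x)]
    planes <- lapply(seq_len(g@nz), function(iz) t(arr[, , iz]))
    f <- file.path(dir, paste0(nm, ".tiff"))
    writeFloatTiff(planes, f)
    files[nm] <- f
  }
  sidecar <- file.path(dir, "maps.json")
  jsonlite::write_json(list(
    units = list(shift = "GHz", linewidth = "GHz", amplitude = "a.u.",
                 gain = "dimensionless", snr = "dimensionless",
                 n_peaks = "count", metric = "fraction"),
    pixel_step_um = list(x = g@stepX, y = g@stepY, z = g@stepZ),
    masked_sentinel = "NaN",
    maps = as.list(basename(files))), sidecar, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  files["sidecar"] <- sidecar
  invisible(files)
}

#' Read back one exported map
#'
#' @param path a TIFF written by \code{\link{writeMapsTiff}}.
#' @return Numeric (nx, ny, nz) array with NaN decoded back to NA.
#' @export
readMapTiff <- function(path) {
  pl <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pl)) pl <- list(pl)
  arr <- array(NA_real_, c(ncol(pl[[1]]), nrow(pl[[1]]), length(pl)))
  for (iz in seq_along(pl)) arr[, , iz] <- t(pl[[iz]])
  arr[is.nan(arr)] <- NA_real_
  arr
}

#' Read and validate a run configuration
#'
#' Loads a YAML or JSON configuration describing an analysis run (frequency
#' axis, pulse scheme, scan geometry, fit, classification and seed options)
#' and validates it against the expected schema. All physical quantities
#' carry their unit in the field name.
#'
#' @param path a .yaml/.yml or .json file.
#' @return A validated named list with classes constructed where applicable
#'   (\code{$geometry} as \code{\link{ScanGeometry}}, \code{$pulse} as
#'   \code{\link{PulseScheme}}).
#' @export
readRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else stop("config must be .yaml, .yml or .json")
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  stopIfNot(is.list(cfg), "config must be a mapping")
  out <- list()
  ax <- cfg$axis
  stopIfNot(!is.null(ax) && all(c("start_ghz", "end_ghz", "n_points") %in% names(ax)),
            "config$axis needs start_ghz, end_ghz, n_points")
  out$axis <- makeFrequencyAxis(ax$start_ghz, ax$end_ghz, ax$n_points)
  if (!is.null(cfg$pulse)) {
    p <- cfg$pulse
    stopIfNot(all(c("pulse_width_ns", "rep_rate_mhz") %in% names(p)),
              "config$pulse needs pulse_width_ns and rep_rate_mhz")
    out$pulse <- PulseScheme(pulseWidthNs = p$pulse_width_ns,
                             repRateMHz = p$rep_rate_mhz,
                             avgPumpMw = p$avg_pump_mw %||% NA_real_,
                             avgProbeMw = p$avg_probe_mw %||% NA_real_)
  }
  if (!is.null(cfg$geometry)) out$geometry <- geometryFromList(cfg$geometry)
  fit <- cfg$fit %||% list()
  out$fit <- list(
    n_peaks = as.integer(fit$n_peaks %||% 1L),
    noise_window_ghz = fit$noise_window_ghz,
    filter_cutoff_hz = fit$filter_cutoff_hz)
  stopIfNot(out$fit$n_peaks %in% 1:3, "config$fit$n_peaks must be 1, 2 or 3")
  cls <- cfg$classification %||% list()
  out$classification <- list(
    offset_min = cls$offset_min %||% -0.5,
    offset_max = cls$offset_max %||% 0.5,
    n_offsets = as.integer(cls$n_offsets %||% 21L))
  out$seed <- if (is.null(cfg$seed)) NULL else as.integer(cfg$seed)
  out$snr <- cfg$snr %||% Inf
  out$dc_level <- cfg$dc_level %||% 100
  out$output_dir <- cfg$output_dir %||% "."
  out
}

# Minimal IEEE-float32 TIFF writer (little-endian, one uncompressed strip
# per directory). The installed TIFF bindings read float TIFFs via libtiff
# but can only write data clamped to [0, 1], which cannot represent
# Brillouin shift maps; parameter maps need raw 32-bit float samples with
# NaN for masked pixels.
writeFloatTiff <- function(planes, path) {
  stopIfNot(is.list(planes) && length(planes) >= 1L,
            "'planes' must be a non-empty list of matrices")
  h <- nrow(planes[[1L]]); w <- ncol(planes[[1L]])
  nIfd <- length(planes)
  dataSize <- 4L * w * h
  dataOff <- 8L + (seq_len(nIfd) - 1L) * dataSize
  ifdSize <- 2L + 10L * 12L + 4L
  ifdOff <- 8L + nIfd * dataSize + (seq_len(nIfd) - 1L) * ifdSize
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifdOff[1L], con, size = 4, endian = "little")
  for (p in planes)
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  for (i in seq_len(nIfd)) {
    writeBin(10L, con, size = 2, endian = "little")    # entry count
    entry(256, 4, 1, w)                                 # ImageWidth
    entry(257, 4, 1, h)                                 # ImageLength
    entry(258, 3, 1, 32)                                # BitsPerSample
    entry(259, 3, 1, 1)                                 # no compression
    entry(262, 3, 1, 1)                                 # BlackIsZero
    entry(273, 4, 1, dataOff[i])                        # StripOffsets
    entry(277, 3, 1, 1)                                 # SamplesPerPixel
    entry(278, 4, 1, h)                                 # RowsPerStrip
    entry(279, 4, 1, dataSize)                          # StripByteCounts
    entry(339, 3, 1, 3)                                 # SampleFormat: IEEEFP
    writeBin(if (i < nIfd) ifdOff[i + 1L] else 0L, con, size = 4,
             endian = "little")
  }
  invisible(path)
}
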