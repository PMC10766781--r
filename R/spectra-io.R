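#' Create a centroided spectrum
#'
#' Sticks are sorted by m/z and coincident centroids (identical m/z after
#' rounding to 1e-6 Da) are summed, so the stored arrays satisfy the
#' strictly-ascending invariant.
#'
#' @param mz m/z values (Da).
#' @param intensity intensities, parallel to `mz`.
#' @param conditionSetId design run id (1..81) or NA.
#' @param replicate replicate index or NA.
#' @param sample sample label.
#' @return A [Spectrum-class].
#' @examples
#' Spectrum(c(902.8, 918.8), c(100, 25), sample = "oil")
#' @export
Spectrum <- function(mz, intensity, conditionSetId = NA_integer_,
                     replicate = NA_integer_, sample = "") {
    mz <- as.numeric(mz)
    intensity <- as.numeric(intensity)
    if (length(mz) != length(intensity))
        stop("'mz' and 'intensity' must have equal length")
    if (any(!is.finite(mz)) || any(!is.finite(intensity)))
        stop("'mz' and 'intensity' must be finite (no NA/NaN)")
    if (length(mz)) {
        key <- round(mz, 6)
        agg <- rowsum(intensity, group = key, reorder = TRUE)
        mz <- as.numeric(rownames(agg))
        intensity <- as.numeric(agg[, 1L])
    }
    new("Spectrum", mz = mz, intensity = intensity,
        conditionSetId = as.integer(conditionSetId),
        replicate = as.integer(replicate), sample = as.character(sample))
}

#' Read a FIA-MS spectrum from CSV or mzML
#'
#' CSV files must have a `mz,intensity` header (dot decimal). mzML files are
#' read through \pkg{mzR}; all scans of an FIA run are summed into one
#' composite spectrum (the selectivity factor is invariant to this scaling).
#'
#' @param path file path.
#' @param format "auto" (by extension), "csv" or "mzml".
#' @param conditionSetId,replicate,sample metadata attached to the spectrum.
#' @return A [Spectrum-class].
#' @export
readSpectrum <- function(path, format = c("auto", "csv", "mzml"),
                         conditionSetId = NA_integer_,
                         replicate = NA_integer_, sample = "") {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- if (ext %in% c("mzml", "mzxml")) "mzml" else "csv"
    }
    if (format == "csv") {
        df <- utils::read.csv(path, stringsAsFactors = FALSE)
        if (!all(c("mz", "intensity") %in% names(df)))
            stop("spectrum CSV '", path, "' must have columns mz,intensity")
        if (anyNA(df$mz) || anyNA(df$intensity))
            stop("spectrum CSV '", path, "' contains NA values")
        mz <- df$mz; int <- df$intensity
    } else {
        fh <- mzR::openMSfile(path)
        on.exit(mzR::close(fh))
        n <- nrow(mzR::header(fh))
        mz <- numeric(0); int <- numeric(0)
        for (i in seq_len(n)) {
            p <- mzR::peaks(fh, i)
            mz <- c(mz, p[, 1L]); int <- c(int, p[, 2L])
        }
    }
    if (!length(mz))
        warning("empty spectrum read from '", path, "'")
    Spectrum(mz, int, conditionSetId = conditionSetId, replicate = replicate,
             sample = sample)
}

#' Write a spectrum to CSV or mzML
#'
#' The mzML writer emits a minimal single-scan mzML 1.1.0 document
#' (centroided, 64-bit uncompressed arrays) readable by standard mzML
#' parsers.
#'
#' @param s a [Spectrum-class].
#' @param path output path.
#' @param format "auto" (by extension), "csv" or "mzml".
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(s, path, format = c("auto", "csv", "mzml")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (tolower(tools::file_ext(path)) == "mzml") "mzml"
                  else "csv"
    if (format == "csv") {
        utils::write.csv(data.frame(mz = s@mz, intensity = s@intensity),
                         path, row.names = FALSE, quote = FALSE)
    } else {
        writeLines(.mzmlDocument(list(s@mz), list(s@intensity)), path)
    }
    invisible(path)
}

.b64doubles <- function(x) {
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con))
    writeBin(as.numeric(x), con, size = 8, endian = "little")
    gsub("[\r\n]", "", jsonlite::base64_enc(rawConnectionValue(con)))
}

.mzmlBinaryArray <- function(x, accession, name, unitAcc, unitName) {
    b64 <- .b64doubles(x)
    c(sprintf('          <binaryDataArray encodedLength="%d">', nchar(b64)),
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      sprintf('            <cvParam cvRef="MS" accession="%s" name="%s" value="" unitCvRef="MS" unitAccession="%s" unitName="%s"/>',
              accession, name, unitAcc, unitName),
      sprintf('            <binary>%s</binary>', b64),
      '          </binaryDataArray>')
}

## mz / intensity are parallel lists, one element per scan
.mzmlDocument <- function(mz, intensity) {
    scans <- unlist(lapply(seq_along(mz), function(i) {
        c(sprintf(
            '      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
            i - 1L, i, length(mz[[i]])),
          '        <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
          '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
          '        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
          '        <binaryDataArrayList count="2">',
          .mzmlBinaryArray(mz[[i]], "MS:1000514", "m/z array", "MS:1000040",
                           "m/z"),
          .mzmlBinaryArray(intensity[[i]], "MS:1000515", "intensity array",
                           "MS:1000131", "number of detector counts"),
          '        </binaryDataArrayList>',
          '      </spectrum>')
    }))
    c('<?xml version="1.0" encoding="utf-8"?>',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
      '  <cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
      '  <fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/><cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/></fileContent></fileDescription>',
      '  <softwareList count="1"><software id="sw" version="1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="oxSelMS"/></software></softwareList>',
      '  <instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
      '  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
      '  <run id="run" defaultInstrumentConfigurationRef="ic">',
      sprintf('    <spectrumList count="%d" defaultDataProcessingRef="dp">',
              length(mz)),
      scans,
      '    </spectrumList>',
      '  </run>',
      '</mzML>')
}

#' Summed intensity within a mass window
#'
#' Windows are half-open: a centroid at exactly `hi` is excluded.
#'
#' @param s a [Spectrum-class].
#' @param w a [MassWindow-class].
#' @return data.frame: label, area, n_peaks.
#' @examples
#' s <- Spectrum(c(900, 950), c(10, 5))
#' windowArea(s, massWindow("nonox", 880, 910, "nonox"))
#' @export
windowArea <- function(s, w) {
    stopifnot(is(s, "Spectrum"), is(w, "MassWindow"))
    sel <- s@mz >= w@lo & s@mz < w@hi
    data.frame(label = w@label, area = sum(s@intensity[sel]),
               n_peaks = sum(sel))
}

#' Extracted-ion area around a target ion
#'
#' Sums intensity within `|mz - ion mz| <= tol`. A warning is issued when
#' another supplied target ion lies within `2 * tol` (ambiguous assignment).
#'
#' @param s a [Spectrum-class].
#' @param ion a [TargetIon-class].
#' @param tol extraction half-width in Da (default 0.35, unit-resolution
#'   quadrupole).
#' @param otherIons optional list of other [TargetIon-class] objects checked
#'   for overlap.
#' @return data.frame: label, area, n_peaks.
#' @export
eicArea <- function(s, ion, tol = 0.35, otherIons = NULL) {
    stopifnot(is(s, "Spectrum"), is(ion, "TargetIon"), tol > 0)
    if (!is.null(otherIons)) {
        oth <- vapply(otherIons, ionMz, 0)
        oth <- oth[abs(oth - ion@mz) > 1e-9]
        if (any(abs(oth - ion@mz) < 2 * tol))
            warning(sprintf(
                "target ions within 2*tol of m/z %.4f: ambiguous assignment",
                ion@mz))
    }
    sel <- abs(s@mz - ion@mz) <= tol
    data.frame(label = sprintf("%dox-%s %s", ion@nOx, ion@species@name,
                               ion@adduct@label),
               area = sum(s@intensity[sel]), n_peaks = sum(sel))
}

#' Replicate mean and spread
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator); with a
#' single replicate the SD is 0 and the result is flagged.
#'
#' @param x numeric vector of per-replicate values.
#' @return list: mean, sd, n, flag ("" or "single_replicate").
#' @examples
#' averageReplicates(c(4, 6))
#' @export
averageReplicates <- function(x) {
    x <- as.numeric(x)
    if (!length(x))
        stop("at least one replicate is required")
    n <- length(x)
    list(mean = mean(x), sd = if (n > 1L) stats::sd(x) else 0, n = n,
         flag = if (n == 1L) "single_replicate" else "")
}

#' Read a campaign manifest
#'
#' CSV mapping spectrum files to their acquisition metadata, with columns
#' `path`, `condition_set`, `replicate`, `sample`.
#'
#' @param path manifest CSV path.
#' @param dir optional directory prepended to relative paths.
#' @return data.frame.
#' @export
readManifest <- function(path, dir = NULL) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("path", "condition_set", "replicate", "sample")
    if (!all(need %in% names(df)))
        stop("manifest must contain columns: ", paste(need, collapse = ", "))
    if (!is.null(dir))
        df$path <- file.path(dir, df$path)
    df
}
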