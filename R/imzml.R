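# Minimal continuous-mode imzML reader/writer. imzML stores spectral metadata
# in an mzML-style XML file and the binary arrays in a companion .ibd file
# whose first 16 bytes are a UUID echoed in the XML. Only what the pipeline
# needs is implemented: continuous and processed modes, 32/64-bit float
# arrays, no compression.

.ims_ns <- "http://psi.hupo.org/ms/mzml"

io_error <- function(msg, path) {
  stop(errorCondition(paste0(msg, " [", path, "]"),
                      class = c("bromsi_io_error", "error")))
}

ibd_path <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

# deterministic RFC4122-shaped UUID from an integer seed (keeps two writes
# with the same seed byte-identical); global RNG state is preserved
.uuid_bytes <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  b <- sample.int(256L, 16L, replace = TRUE) - 1L
  b[7L] <- bitwOr(bitwAnd(b[7L], 0x0FL), 0x40L)  # version 4
  b[9L] <- bitwOr(bitwAnd(b[9L], 0x3FL), 0x80L)  # variant
  as.raw(b)
}

.uuid_string <- function(bytes) {
  h <- format(bytes)
  paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
         paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
         paste(h[11:16], collapse = ""))
}

#' Write an MSI dataset as continuous-mode imzML
#'
#' Writes `<path>.imzML` plus the companion `.ibd` binary file (64-bit float
#' arrays, no compression). The ibd UUID is derived deterministically from
#' `uuid_seed`, so two writes of the same dataset with the same seed produce
#' byte-identical files.
#'
#' @param dataset An [msi_dataset].
#' @param path Output path ending in `.imzML`.
#' @param uuid_seed Integer seed for the ibd UUID.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path, uuid_seed = 1L) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (n_pixels(dataset) == 0L) io_error("refusing to write empty dataset", path)
  ibd <- ibd_path(path)
  uuid <- .uuid_bytes(uuid_seed)
  nbins <- length(dataset$mz)
  np <- n_pixels(dataset)

  con <- file(ibd, "wb")
  ok <- FALSE
  tryCatch({
    writeBin(uuid, con)
    writeBin(as.numeric(dataset$mz), con, size = 8, endian = "little")
    for (i in seq_len(np)) {
      writeBin(as.numeric(dataset$intensities[i, ]), con, size = 8,
               endian = "little")
    }
    ok <- TRUE
  }, finally = close(con))
  if (!ok) io_error("failed writing ibd", ibd)
  md5 <- unname(tools::md5sum(ibd))

  mz_off <- 16
  int_off <- function(i) 16 + 8 * nbins + (i - 1) * 8 * nbins
  nx <- max(dataset$coords[, "x"]) + 1L
  ny <- max(dataset$coords[, "y"]) + 1L

  head <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<mzML xmlns="%s" version="1.1">
  <cvList count="3">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>
    <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>
      <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>
    </fileContent>
  </fileDescription>
  <referenceableParamGroupList count="2">
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <softwareList count="1">
    <software id="bromsi" version="0.1.0">
      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="bromsi"/>
    </software>
  </softwareList>
  <scanSettingsList count="1">
    <scanSettings id="scanSettings1">
      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x=y)" value="%g" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>
    </scanSettings>
  </scanSettingsList>
  <instrumentConfigurationList count="1">
    <instrumentConfiguration id="IC1"/>
  </instrumentConfigurationList>
  <dataProcessingList count="1">
    <dataProcessing id="dp1">
      <processingMethod order="1" softwareRef="bromsi">
        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>
      </processingMethod>
    </dataProcessing>
  </dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="%d" defaultDataProcessingRef="dp1">',
    .ims_ns, .uuid_string(uuid), md5, nx, ny, dataset$pitch_um, np)

  spec <- sprintf(
'      <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">
        <scanList count="1">
          <scan>
            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>',
    seq_len(np), seq_len(np) - 1L, nbins,
    dataset$coords[, "x"] + 1L, dataset$coords[, "y"] + 1L,
    nbins, 8L * nbins, mz_off,
    nbins, 8L * nbins, vapply(seq_len(np), int_off, numeric(1)))

  tail <- "    </spectrumList>\n  </run>\n</mzML>\n"
  writeLines(c(head, spec, tail), path, sep = "\n")
  invisible(path)
}

.cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

.read_array <- function(con, offset, length, size) {
  seek(con, where = offset, origin = "start")
  readBin(con, "double", n = length, size = size, endian = "little")
}

#' Read an imzML dataset
#'
#' Reads continuous- or processed-mode imzML. Processed-mode spectra are
#' resampled onto a common uniform axis with TIC-preserving rebinning.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit beside it).
#' @return An [msi_dataset].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) io_error("imzML file not found", path)
  ibd <- ibd_path(path)
  if (!file.exists(ibd)) io_error("companion ibd file not found", ibd)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) io_error(
                    paste0("malformed imzML XML: ", conditionMessage(e)), path))
  xml2::xml_ns_strip(doc)

  fc <- xml2::xml_find_first(doc, ".//fileContent")
  continuous <- !inherits(
    xml2::xml_find_first(fc, ".//cvParam[@accession='IMS:1000030']"),
    "xml_missing")
  processed <- !inherits(
    xml2::xml_find_first(fc, ".//cvParam[@accession='IMS:1000031']"),
    "xml_missing")
  if (!continuous && !processed) io_error("neither continuous nor processed mode declared", path)

  # per-group precision (bytes per value)
  grp_size <- function(id) {
    g <- xml2::xml_find_first(doc,
      sprintf(".//referenceableParamGroup[@id='%s']", id))
    if (!inherits(g, "xml_missing") &&
        !inherits(xml2::xml_find_first(
          g, ".//cvParam[@accession='MS:1000521']"), "xml_missing")) 4L else 8L
  }
  sizes <- c(mzArray = grp_size("mzArray"),
             intensityArray = grp_size("intensityArray"))

  pitch <- .cv_value(doc, "IMS:1000046")
  pitch <- if (is.na(pitch)) 60 else as.numeric(pitch)

  specs <- xml2::xml_find_all(doc, ".//spectrum")
  if (!length(specs)) io_error("no spectra in file", path)

  parse_spec <- function(s) {
    x <- as.integer(.cv_value(s, "IMS:1000050"))
    y <- as.integer(.cv_value(s, "IMS:1000051"))
    arrays <- xml2::xml_find_all(s, ".//binaryDataArray")
    info <- list(x = x, y = y)
    for (a in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, ".//referenceableParamGroupRef"), "ref")
      key <- if (identical(ref, "mzArray")) "mz" else "int"
      info[[paste0(key, "_off")]] <- as.numeric(.cv_value(a, "IMS:1000102"))
      info[[paste0(key, "_len")]] <- as.integer(.cv_value(a, "IMS:1000103"))
      info[[paste0(key, "_size")]] <- unname(
        sizes[if (key == "mz") "mzArray" else "intensityArray"])
    }
    info
  }
  meta <- lapply(specs, parse_spec)
  coords <- cbind(x = vapply(meta, `[[`, integer(1), "x") - 1L,
                  y = vapply(meta, `[[`, integer(1), "y") - 1L)
  if (anyDuplicated(coords)) io_error("duplicate pixel coordinates in file", path)

  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  uuid_file <- readBin(con, "raw", 16L)
  uuid_xml <- gsub("[{}-]", "", .cv_value(doc, "IMS:1000080"))
  if (!is.na(uuid_xml) && nzchar(uuid_xml) &&
      !identical(tolower(paste(format(uuid_file), collapse = "")),
                 tolower(uuid_xml))) {
    io_error("ibd UUID does not match imzML header", ibd)
  }

  if (continuous) {
    m1 <- meta[[1L]]
    mz <- .read_array(con, m1$mz_off, m1$mz_len, m1$mz_size)
    ints <- matrix(0, nrow = length(meta), ncol = length(mz))
    for (i in seq_along(meta)) {
      m <- meta[[i]]
      ints[i, ] <- .read_array(con, m$int_off, m$int_len, m$int_size)
    }
    return(msi_dataset(coords, mz, ints, pitch_um = pitch,
                       metadata = list(mode = "continuous")))
  }

  # processed mode: read each spectrum, then rebin onto a common uniform axis
  raw <- lapply(meta, function(m) {
    list(mz = .read_array(con, m$mz_off, m$mz_len, m$mz_size),
         intensity = .read_array(con, m$int_off, m$int_len, m$int_size))
  })
  lo <- min(vapply(raw, function(s) min(s$mz), numeric(1)))
  hi <- max(vapply(raw, function(s) max(s$mz), numeric(1)))
  dx <- stats::median(unlist(lapply(raw, function(s) diff(s$mz))))
  axis <- seq(lo, hi + dx, by = dx)
  ints <- t(vapply(raw, function(s) {
    resample_tic_preserving(msi_spectrum(s$mz, s$intensity), axis)$intensity
  }, numeric(length(axis))))
  msi_dataset(coords, axis, ints, pitch_um = pitch,
              metadata = list(mode = "processed"))
}
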