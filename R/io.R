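#' Write a dataset to the documented CSV dialect
#'
#' Three files in `dir`: `spectra.csv` (long format: leaf_id,
#' measurement_idx, band_id, frequency_hz, magnitude_db, phase_rad),
#' `annotations.csv` (leaf_id, measurement_idx, fm_g, tm_g, dm_g,
#' rwc) and `config.json` (generator configuration + seed).
#'
#' @param dataset a [RusDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRusDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "RusDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- list(); ann <- list(); k <- 0L
  for (rec in leafRecords(dataset)) {
    for (j in seq_along(rec@measurements)) {
      m <- rec@measurements[[j]]
      k <- k + 1L
      ann[[k]] <- data.frame(
        leaf_id = rec@leafId, measurement_idx = j,
        fm_g = m$freshMass, tm_g = rec@turgidMass, dm_g = rec@dryMass,
        rwc = m$rwc, stringsAsFactors = FALSE)
      spec[[k]] <- do.call(rbind, lapply(m$bands, function(b)
        data.frame(leaf_id = rec@leafId, measurement_idx = j,
                   band_id = bandId(b), frequency_hz = frequencies(b),
                   magnitude_db = magnitudeDb(b), phase_rad = phaseRad(b),
                   stringsAsFactors = FALSE)))
    }
  }
  utils::write.csv(do.call(rbind, spec), file.path(dir, "spectra.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, ann), file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = dataset@seed, config = dataset@config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset written by [writeRusDataset()]
#'
#' RWC annotations are recomputed from the stored masses, so the
#' round-trip identity `rwc = (FM - DM)/(TM - DM)` holds exactly on
#' the read values.
#'
#' @param dir directory holding `spectra.csv`, `annotations.csv` and
#'   `config.json`.
#' @return a [RusDataset-class].
#' @export
readRusDataset <- function(dir) {
  spec <- utils::read.csv(file.path(dir, "spectra.csv"),
                          stringsAsFactors = FALSE)
  ann <- utils::read.csv(file.path(dir, "annotations.csv"),
                         stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  specByLeaf <- split(spec, spec$leaf_id)
  records <- lapply(split(ann, ann$leaf_id), function(a) {
    a <- a[order(a$measurement_idx), , drop = FALSE]
    sl <- specByLeaf[[a$leaf_id[1]]]
    meas <- lapply(a$measurement_idx, function(j) {
      sm <- sl[sl$measurement_idx == j, , drop = FALSE]
      bands <- lapply(split(sm, sm$band_id), function(sb) {
        o <- order(sb$frequency_hz)
        new("BandSpectrum", bandId = sb$band_id[1],
            frequency = sb$frequency_hz[o],
            magnitudeDb = sb$magnitude_db[o], phaseRad = sb$phase_rad[o])
      })
      bands <- bands[order(vapply(bands, function(b)
        min(frequencies(b)), numeric(1)))]
      row <- a[a$measurement_idx == j, ]
      list(freshMass = row$fm_g,
           rwc = computeRwc(row$fm_g, row$tm_g, row$dm_g),
           bands = unname(bands))
    })
    new("LeafRecord", leafId = a$leaf_id[1], turgidMass = a$tm_g[1],
        dryMass = a$dm_g[1], measurements = meas)
  })
  ids <- vapply(records, leafId, character(1))
  new("RusDataset", records = unname(records[order(ids)]),
      config = as.list(meta$config), seed = as.integer(meta$seed))
}

#' Write resampled spectra as a wide CSV
#'
#' One row per sample: leaf_id, measurement_idx, method, rwc, then
#' 601 magnitude columns (`mag_0001`..) and 601 phase columns
#' (`phase_0001`..).
#'
#' @param spectra a [RusSpectra-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectraCsv <- function(spectra, path) {
  stopifnot(is(spectra, "RusSpectra"))
  cd <- as.data.frame(colData(spectra))[
    , c("leaf_id", "measurement_idx", "method", "rwc")]
  mag <- t(assay(spectra, "magnitude"))
  ph <- t(assay(spectra, "phase"))
  colnames(mag) <- sprintf("mag_%04d", seq_len(ncol(mag)))
  colnames(ph) <- sprintf("phase_%04d", seq_len(ncol(ph)))
  utils::write.csv(cbind(cd, mag, ph), path, row.names = FALSE)
  invisible(path)
}

#' Write the feature table as CSV
#'
#' @param features a [featureTable()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeaturesCsv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
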