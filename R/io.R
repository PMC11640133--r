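# Plain-text cohort container: a directory holding one CSV matrix per image
# (rows = pixels in column-major plane order, columns = the 3 x L flattened
# decay samples), a JSON metadata sidecar per image, and a manifest.csv
# mirroring the layout (patient_id, tissue_type, diagnosis, path).

#' Write a cohort to a directory container
#'
#' @param cohort A `maflim_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "maflim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- attr(cohort, "spec")
  manifest <- list()
  for (ps in cohort) {
    for (tt in c("lesion", "healthy")) {
      img <- ps[[tt]]
      d <- dim(img$data)
      stem <- sprintf("patient%03d_%s", img$patient_id, tt)
      mat <- matrix(img$data, d[1] * d[2], d[3] * d[4])
      data.table::fwrite(data.table::as.data.table(mat),
                         file.path(dir, paste0(stem, ".csv")),
                         col.names = FALSE)
      meta <- list(patient_id = img$patient_id, tissue_type = tt,
                   diagnosis = img$diagnosis, dim = d,
                   calibration = img$calibration)
      jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                           auto_unbox = TRUE, digits = NA)
      manifest[[length(manifest) + 1L]] <-
        data.frame(patient_id = img$patient_id, tissue_type = tt,
                   diagnosis = img$diagnosis, path = paste0(stem, ".csv"))
    }
  }
  manifest <- do.call(rbind, manifest)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  if (!is.null(spec)) {
    jsonlite::write_json(
      list(n_benign = spec$n_benign, n_malignant = spec$n_malignant,
           height = spec$height, width = spec$width,
           class_effect = spec$class_effect,
           benign_effect = spec$benign_effect,
           patient_effect = spec$patient_effect, noise_sd = spec$noise_sd,
           gain_sd = spec$gain_sd, seed = spec$seed),
      file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}

#' Read a cohort from a directory container
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `maflim_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  by_patient <- split(manifest, manifest$patient_id)
  samples <- lapply(by_patient, function(rows) {
    imgs <- lapply(seq_len(nrow(rows)), function(i) {
      stem <- sub("\\.csv$", "", rows$path[i])
      meta <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                                  simplifyVector = TRUE)
      mat <- as.matrix(data.table::fread(file.path(dir, rows$path[i]),
                                         header = FALSE))
      new_maflim_image(array(mat, dim = meta$dim),
                       patient_id = meta$patient_id,
                       tissue_type = meta$tissue_type,
                       diagnosis = meta$diagnosis,
                       calibration = as.numeric(meta$calibration))
    })
    names(imgs) <- rows$tissue_type
    structure(list(patient_id = rows$patient_id[1],
                   diagnosis = rows$diagnosis[rows$tissue_type == "lesion"],
                   lesion = imgs$lesion, healthy = imgs$healthy),
              class = "patient_sample")
  })
  names(samples) <- NULL
  structure(samples[order(vapply(samples, `[[`, numeric(1), "patient_id"))],
            class = "maflim_cohort")
}
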