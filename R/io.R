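#' Write a recording to TSV + JSON sidecar
#'
#' The intensity matrix goes to `<prefix>.tsv` (a `time` column plus
#' one column per channel-wavelength, named `ch<channel>_<wavelength>`)
#' and all metadata (geometry, sampling rate, paradigm blocks,
#' wavelengths, subject, group, seed) to `<prefix>.json`.
#'
#' @param rec A `nirs_recording`.
#' @param prefix Output path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  n <- nrow(rec$intensity)
  df <- data.frame(time = (seq_len(n) - 1) / rec$fs, rec$intensity,
                   check.names = FALSE)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  par <- rec$paradigm
  meta <- list(
    fs = rec$fs,
    wavelengths = rec$wavelengths,
    subject_id = rec$subject_id,
    group = rec$group,
    seed = rec$seed,
    geometry = as.data.frame(rec$geometry),
    paradigm = list(
      blocks = data.frame(onset = par$onset, duration = par$duration,
                          condition = par$condition),
      n_trials = attr(par, "n_trials"),
      session_duration = attr(par, "session_duration")
    )
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `nirs_recording`.
#' @export
read_recording <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  if (!file.exists(tsv)) abort(paste0("Missing data file: ", tsv))
  if (!file.exists(js)) abort(paste0("Missing sidecar file: ", js))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  for (field in c("fs", "wavelengths", "geometry", "paradigm")) {
    if (is.null(meta[[field]])) {
      abort(paste0("Sidecar schema violation: missing field '", field, "'."))
    }
  }
  for (field in c("channel", "source_id", "detector_id", "separation_mm",
                  "region", "class")) {
    if (is.null(meta$geometry[[field]])) {
      abort(paste0("Sidecar schema violation: geometry lacks '", field, "'."))
    }
  }
  df <- utils::read.table(tsv, header = TRUE, sep = "\t", check.names = FALSE)
  intensity <- as.matrix(df[setdiff(names(df), "time")])
  blocks <- meta$paradigm$blocks
  par <- tibble::new_tibble(
    tibble::tibble(onset = blocks$onset, duration = blocks$duration,
                   condition = blocks$condition),
    class = "stim_paradigm"
  )
  attr(par, "n_trials") <- meta$paradigm$n_trials
  attr(par, "session_duration") <- meta$paradigm$session_duration
  structure(
    list(
      geometry = tibble::as_tibble(meta$geometry),
      fs = meta$fs,
      paradigm = par,
      wavelengths = meta$wavelengths,
      intensity = intensity,
      subject_id = meta$subject_id,
      group = meta$group,
      seed = meta$seed,
      artifacts = NULL,
      provenance = list(source = prefix)
    ),
    class = "nirs_recording"
  )
}

#' Write region HbO series to TSV (+ JSON sidecar)
#'
#' @param regions A `region_series`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_region_series <- function(regions, prefix) {
  utils::write.table(as.data.frame(regions), paste0(prefix, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = attr(regions, "fs"),
         subject_id = attr(regions, "subject_id"),
         group = attr(regions, "group")),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' Read region HbO series written by [write_region_series()]
#' @param prefix Path prefix.
#' @return A `region_series`.
#' @export
read_region_series <- function(prefix) {
  df <- utils::read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  out <- tibble::new_tibble(tibble::as_tibble(df), class = "region_series")
  attr(out, "fs") <- meta$fs
  attr(out, "subject_id") <- meta$subject_id
  attr(out, "group") <- meta$group
  out
}

#' Write a long connectivity table as TSV
#' @param long Tibble from [bind_connectivity()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(long, path) {
  utils::write.table(as.data.frame(long), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a connectivity TSV
#' @param path File written by [write_connectivity()].
#' @return Tibble.
#' @export
read_connectivity <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}
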