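#' Generate a seeded synthetic cohort
#'
#' Produces one raw recording per subject for each group profile, with
#' per-subject seeds derived deterministically from `master_seed`, and
#' a cohort manifest (subject, group, seed, trials) attached as an
#' attribute.
#'
#' @param profiles List of [group_profile()] objects (distinct names).
#' @param geometry Montage, see [default_geometry()].
#' @param fs Sampling rate, Hz.
#' @param master_seed Integer master seed.
#' @param task_s,rest_s,lead_in_s Block durations passed to
#'   [build_paradigm()] (per-profile trial counts come from the
#'   profiles).
#' @param n_spikes,n_shifts Motion artifacts injected per recording
#'   (defaults 3 spikes, 1 baseline shift; motion is inevitable during
#'   a bimanual cutting task, and the PCA stage exists to remove it).
#' @return A list of `nirs_recording`s (class `nirs_cohort`) with a
#'   `manifest` attribute (tibble).
#' @export
#' @examples
#' profs <- list(
#'   group_profile("expert", 2, coupling = coupling_spec("CPFC-SMA", 0.3)),
#'   group_profile("novice", 2, coupling = coupling_spec("CPFC-SMA", 0.9))
#' )
#' cohort <- generate_cohort(profs, fs = 5, master_seed = 7,
#'                           task_s = 60, rest_s = 30)
#' cohort_manifest(cohort)
generate_cohort <- function(profiles, geometry = default_geometry(), fs = 10,
                            master_seed = 1, task_s = 300, rest_s = 60,
                            lead_in_s = 30, n_spikes = 3, n_shifts = 1) {
  if (length(profiles) == 0) abort("`profiles` must be non-empty.")
  nm <- vapply(profiles, function(p) p$name, "")
  if (anyDuplicated(nm)) abort("Duplicate group names yield duplicate subject ids.")
  recs <- list()
  manifest <- list()
  counter <- 0L
  for (p in profiles) {
    paradigm <- build_paradigm(p$n_trials, task_s = task_s, rest_s = rest_s,
                               lead_in_s = lead_in_s)
    for (j in seq_len(p$n_subjects)) {
      counter <- counter + 1L
      seed_i <- subject_seed(master_seed, counter)
      sid <- sprintf("%s_%02d", p$name, j)
      hbo <- simulate_region_hbo(paradigm, p, fs = fs, seed = seed_i)
      rec <- forward_optics(
        hbo, geometry,
        systemic = p$noise[c("cardiac", "respiratory", "myogenic", "endothelial")],
        seed = seed_i + 1L, subject_id = sid, group = p$name
      )
      rec <- inject_artifacts(rec, n_spikes = n_spikes, n_shifts = n_shifts,
                              seed = seed_i + 2L)
      recs[[sid]] <- rec
      manifest[[sid]] <- tibble::tibble(
        subject_id = sid, group = p$name, seed = seed_i,
        n_trials = p$n_trials
      )
    }
  }
  out <- structure(recs, class = "nirs_cohort")
  attr(out, "manifest") <- dplyr::bind_rows(manifest)
  out
}

# Deterministic per-subject seed stream, kept inside 32-bit range.
subject_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 7919 + index * 104729) %% 2147483646) + 1L
}

#' Cohort manifest
#' @param cohort A `nirs_cohort`.
#' @return Tibble with `subject_id`, `group`, `seed`, `n_trials`.
#' @export
cohort_manifest <- function(cohort) attr(cohort, "manifest")

#' @export
print.nirs_cohort <- function(x, ...) {
  m <- cohort_manifest(x)
  cat("<nirs_cohort> ", length(x), " recordings; groups: ",
      paste(sprintf("%s (n=%d)", names(table(m$group)), table(m$group)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
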