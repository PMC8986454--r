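#' Published per-patient Echo vs fiducial-point differences
#'
#' The individual Echo minus SCG-fiducial differences (ms) for the 20
#' traditional-waveform patients of the benchmark study, one column per
#' valve event.  These printed values are the input for the reproduction
#' of the group statistics, reference-range counts and significance tests.
#'
#' @return data frame with columns `subject`, `MC`, `AO`, `AC`, `MO`.
#' @export
echo_fp_differences <- function() {
  read.csv(system.file("extdata", "echo_fp_differences.csv", package = "scgcti"))
}

#' Healthy-subject reference statistics
#'
#' Mean, SD and group size of the Echo vs fiducial-point differences
#' reported for healthy subjects, per valve event.
#'
#' @return data frame with columns `event`, `mean_ms`, `sd_ms`, `n`.
#' @export
healthy_reference <- function() {
  read.csv(system.file("extdata", "healthy_reference.csv", package = "scgcti"))
}

#' Published (rounded) 95% reference ranges
#'
#' The healthy-subject 95% ranges as printed (center plus/minus
#' half-width, ms).  The printed rounding is not exactly
#' `1.96 * SD` (e.g. `1.96 * 12 = 23.5` printed as 23), which is why both
#' a printed and an exact mode exist in [reference_range()].
#'
#' @return data frame with columns `event`, `center`, `halfwidth`.
#' @export
printed_reference_ranges <- function() {
  read.csv(system.file("extdata", "printed_reference_ranges.csv", package = "scgcti"))
}

#' Study cohort classification fixture
#'
#' Per-patient diagnosis group, ejection-fraction band and waveform class
#' for the 90-patient study cohort.  The marginal counts (diagnosis by
#' class, and EF band by class) equal the published prevalence tables; the
#' *joint* assignment of diagnosis to EF band is not published and is a
#' synthetic completion consistent with all margins (hence the
#' `_synthetic` file name).  Note the published text mentions five
#' patients with unavailable EF while the printed EF strata sum to 86 of
#' 90, which forces exactly four unavailable; the fixture follows the
#' printed strata.
#'
#' @return data frame with columns `patient_id`, `diagnosis`, `ef_band`
#'   (`">50%"`, `"40-50%"`, `"<40%"` or NA) and `waveform_class`.
#' @export
study_cohort <- function() {
  df <- read.csv(system.file("extdata", "cohort_classifications_synthetic.csv",
                             package = "scgcti"))
  df$ef_band[df$ef_band == ""] <- NA_character_
  df
}
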