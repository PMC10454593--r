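# Shared helpers: normal copy number by sex, sample panels, interval overlap.

#' Normal (germline) total copy number of a chromosome
#'
#' Autosomes carry two germline copies. In a male genome chrX and chrY carry
#' one copy each; in a female genome chrX carries two and chrY none. The
#' result feeds the denominator of the VAF model, so getting chrX right
#' matters whenever X-linked genes (e.g. AR) are analysed in male patients.
#'
#' @param chrom Character vector of chromosome names (`"chrX"`, `"X"`, ...).
#' @param sex `"male"` or `"female"`.
#' @return Integer vector of germline copy numbers (0, 1 or 2).
#' @examples
#' normal_copy_number(c("chr1", "chrX", "chrY"), sex = "male")
#' @export
normal_copy_number <- function(chrom, sex = c("male", "female")) {
  sex <- match.arg(sex)
  nm <- sub("^chr", "", as.character(chrom))
  out <- rep(2L, length(nm))
  if (sex == "male") {
    out[nm %in% c("X", "Y")] <- 1L
  } else {
    out[nm == "Y"] <- 0L
  }
  out
}

#' Build a sample panel
#'
#' The panel records, per tumor sample, the purity (tumor cell fraction of
#' the specimen), an orderable collection date and the patient sex. These are
#' inputs the pipeline consumes; purity is typically the ASCAT-style estimate
#' produced alongside the copy-number segments.
#'
#' @param sample_id Character vector of tumor sample names.
#' @param purity Numeric in (0, 1], one per sample.
#' @param date Numeric or otherwise orderable collection dates (e.g. years).
#' @param sex `"male"` or `"female"` (one value for the patient).
#' @return A tibble with columns `sample_id`, `purity`, `date`, `sex`.
#' @examples
#' sample_panel(c("NE_2012", "NE_2015"), purity = c(0.7, 0.65),
#'              date = c(2012, 2015), sex = "male")
#' @export
sample_panel <- function(sample_id, purity, date, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (any(purity <= 0 | purity > 1)) {
    abort("purity must lie in (0, 1]")
  }
  if (anyDuplicated(sample_id)) abort("sample_id values must be unique")
  if (length(purity) != length(sample_id) || length(date) != length(sample_id)) {
    abort("purity and date must have one value per sample")
  }
  tibble::tibble(
    sample_id = as.character(sample_id),
    purity = as.numeric(purity),
    date = date,
    sex = sex
  )
}

# Overlap join between point positions and segments of one sample.
# Returns the input positions with segment columns bound on (NA when
# uncovered). Segments are assumed non-overlapping (enforced at read time).
locate_in_segments <- function(positions, segments) {
  seg <- dplyr::select(segments, "chrom", "start", "end", "n_major", "n_minor")
  joined <- dplyr::left_join(positions, seg, by = "chrom",
                             relationship = "many-to-many")
  hit <- dplyr::filter(joined, .data$pos >= .data$start, .data$pos <= .data$end)
  dplyr::left_join(positions, dplyr::select(hit, -"start", -"end"),
                   by = c("chrom", "pos"))
}

# Deterministic fixed-format number rendering for TSV outputs (round-trip to
# full printed precision).
fmt_num <- function(x, digits = 6) {
  out <- formatC(x, format = "f", digits = digits)
  out[is.na(x)] <- "NA"
  out
}

log_msg <- function(...) {
  message(sprintf(...))
}
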