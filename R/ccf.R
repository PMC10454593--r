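# Cancer cell fraction estimation: purity- and copy-number-corrected
# conversion of observed allele counts.
#
# Model: a variant present in a fraction phi of tumor cells, on m of the
# locus's tumor copies, in a sample of purity rho with tumor total copy
# number n_t and germline copy number n_n, has expected VAF
#
#   E[VAF] = phi * rho * m / (rho * n_t + (1 - rho) * n_n)
#
# Inverting at the estimated multiplicity gives the CCF.

#' Expected variant allele frequency under the CCF model
#'
#' @param ccf Cancer cell fraction in \[0, 1\].
#' @param purity Sample purity in (0, 1\].
#' @param total_cn Tumor total copy number at the locus.
#' @param multiplicity Mutated copies per tumor cell.
#' @param normal_cn Germline copy number (2 for autosomes, 1 for chrX/chrY
#'   in males).
#' @return Expected VAF.
#' @export
expected_vaf <- function(ccf, purity, total_cn, multiplicity, normal_cn = 2) {
  ccf * purity * multiplicity / (purity * total_cn + (1 - purity) * normal_cn)
}

#' Estimate mutation multiplicity from the observed VAF
#'
#' Chooses the number of mutated copies `m` in `1..n_major` whose clonal
#' (CCF = 1) expected VAF is closest to the observed VAF; ties go to the
#' smaller `m`. The search is capped at the major allele copy number because
#' a point mutation arises on one parental haplotype and can only be
#' multiplied up to that haplotype's copy number (e.g. by whole genome
#' doubling).
#'
#' @param vaf Observed alt/(alt+ref) fraction (vectorised).
#' @param purity Sample purity in (0, 1].
#' @param n_major,n_minor Major/minor allele copy numbers at the locus.
#' @param normal_cn Germline copy number.
#' @return Integer multiplicity, same length as `vaf`.
#' @examples
#' estimate_multiplicity(0.5, purity = 1, n_major = 2, n_minor = 2)  # 2
#' @export
estimate_multiplicity <- function(vaf, purity, n_major, n_minor, normal_cn = 2) {
  n <- max(length(vaf), length(purity), length(n_major), length(n_minor),
           length(normal_cn))
  vaf <- rep_len(vaf, n); purity <- rep_len(purity, n)
  n_major <- rep_len(n_major, n); n_minor <- rep_len(n_minor, n)
  normal_cn <- rep_len(normal_cn, n)
  if (any(purity <= 0 | purity > 1)) abort("purity must lie in (0, 1]")
  if (any(n_major < 1)) abort("multiplicity undefined where n_major < 1")
  vapply(seq_len(n), function(i) {
    m <- seq_len(n_major[i])
    err <- abs(vaf[i] - expected_vaf(1, purity[i], n_major[i] + n_minor[i],
                                     m, normal_cn[i]))
    m[which.min(err)]  # which.min takes the first minimum: ties -> smaller m
  }, integer(1))
}

#' Cancer cell fraction from VAF at a given multiplicity
#'
#' Inverts the expected-VAF model:
#' `ccf = vaf * (purity * total_cn + (1 - purity) * normal_cn) /
#' (purity * multiplicity)`.
#'
#' @inheritParams estimate_multiplicity
#' @param multiplicity Mutated copies (from [estimate_multiplicity()]).
#' @return Raw (unclipped) CCF, same length as `vaf`.
#' @examples
#' compute_ccf(0.25, purity = 0.5, n_major = 1, n_minor = 1, multiplicity = 1)
#' @export
compute_ccf <- function(vaf, purity, n_major, n_minor, multiplicity,
                        normal_cn = 2) {
  if (any(purity * multiplicity == 0)) {
    abort("purity * multiplicity must be positive")
  }
  vaf * (purity * (n_major + n_minor) + (1 - purity) * normal_cn) /
    (purity * multiplicity)
}

#' Build the per-variant per-sample CCF matrix
#'
#' Locates every SNV in each sample's copy-number segments, estimates
#' multiplicity per sample independently (copy number can differ between
#' samples, e.g. before and after a focal amplification), and converts the
#' observed VAF to a CCF. Variants are excluded — with a logged reason — if
#' in any tumor sample they fall outside segment coverage, in a
#' zero-total-copy region, or below the minimum depth; indels are excluded
#' as well. Raw CCFs above 1 are reported in `ccf_raw` and clipped to 1 in
#' `ccf_clipped` (the clustering input); values above `ccf_cap` are flagged.
#'
#' @param variants Long variant tibble from [read_vcf()].
#' @param segments Multi-sample segment tibble from [read_segments()].
#' @param panel Sample panel from [sample_panel()].
#' @param min_depth Minimum read depth required in every sample
#'   (default 10).
#' @param ccf_cap Raw CCF above this is flagged `above_cap` (default 1.2).
#' @return A tibble of class `ccf_matrix`: one row per (variant, tumor
#'   sample) with columns `variant_id`, `sample_id`, `gene`, `chrom`, `pos`,
#'   `ref_count`, `alt_count`, `depth`, `vaf`, `n_major`, `n_minor`,
#'   `total_cn`, `normal_cn`, `multiplicity`, `ccf_raw`, `ccf_clipped`,
#'   `flag`.
#' @export
build_ccf_matrix <- function(variants, segments, panel, min_depth = 10,
                             ccf_cap = 1.2) {
  sex <- unique(panel$sex)
  variants <- dplyr::filter(variants, .data$sample_id %in% panel$sample_id)
  if (nrow(variants) == 0) abort("no usable SNVs")

  indels <- unique(variants$variant_id[variants$is_indel])
  if (length(indels) > 0) {
    log_msg("excluding %d indel(s) from CCF estimation", length(indels))
    variants <- dplyr::filter(variants, !.data$is_indel)
  }
  if (nrow(variants) == 0) abort("no usable SNVs")

  located <- purrr::map_dfr(panel$sample_id, function(s) {
    vs <- dplyr::filter(variants, .data$sample_id == s)
    seg <- dplyr::filter(segments, .data$sample_id == s)
    pos <- dplyr::distinct(dplyr::select(vs, "variant_id", "chrom", "pos"))
    hit <- locate_in_segments(dplyr::select(pos, "chrom", "pos"), seg)
    dplyr::left_join(vs, dplyr::bind_cols(pos["variant_id"],
                                          hit[c("n_major", "n_minor")]),
                     by = "variant_id")
  })

  located <- dplyr::mutate(located,
    depth = .data$ref_count + .data$alt_count,
    total_cn = .data$n_major + .data$n_minor
  )

  bad <- dplyr::summarise(
    dplyr::group_by(located, .data$variant_id),
    uncovered = anyNA(.data$n_major),
    zero_cn = any(!is.na(.data$total_cn) & .data$total_cn == 0),
    shallow = any(.data$depth < min_depth)
  )
  excl <- dplyr::filter(bad, .data$uncovered | .data$zero_cn | .data$shallow)
  if (nrow(excl) > 0) {
    log_msg("excluding %d variant(s): %d uncovered, %d zero-copy, %d below depth %d",
            nrow(excl), sum(excl$uncovered), sum(excl$zero_cn),
            sum(excl$shallow), min_depth)
  }
  located <- dplyr::filter(located, !.data$variant_id %in% excl$variant_id)
  if (nrow(located) == 0) abort("no usable SNVs after exclusions")

  located <- dplyr::left_join(located,
    dplyr::select(panel, "sample_id", "purity"), by = "sample_id")
  located <- dplyr::mutate(located,
    normal_cn = normal_copy_number(.data$chrom, sex),
    vaf = ifelse(.data$depth > 0, .data$alt_count / .data$depth, 0),
    multiplicity = estimate_multiplicity(.data$vaf, .data$purity,
                                         .data$n_major, .data$n_minor,
                                         .data$normal_cn),
    ccf_raw = compute_ccf(.data$vaf, .data$purity, .data$n_major,
                          .data$n_minor, .data$multiplicity, .data$normal_cn),
    ccf_clipped = pmin(.data$ccf_raw, 1),
    flag = ifelse(.data$ccf_raw > ccf_cap, "above_cap", "")
  )
  out <- dplyr::select(located, "variant_id", "sample_id", "gene", "chrom",
                       "pos", "ref_count", "alt_count", "depth", "vaf",
                       "n_major", "n_minor", "total_cn", "normal_cn",
                       "purity", "multiplicity", "ccf_raw", "ccf_clipped",
                       "flag")
  out <- dplyr::arrange(out, .data$chrom, .data$pos, .data$variant_id,
                        match(.data$sample_id, panel$sample_id))
  class(out) <- c("ccf_matrix", class(out))
  out
}
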