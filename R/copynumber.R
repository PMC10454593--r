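# Interpretation of allele-specific copy-number profiles: ploidy, whole
# genome doubling, LOH, arm-level gain/loss, focal amplification.

#' Length-weighted tumor ploidy and whole-genome-doubling call
#'
#' Ploidy is the length-weighted mean total copy number over all segments of
#' one sample, with segment length `end - start + 1`. Whole genome doubling
#' (WGD) is called when ploidy exceeds 3 (strict inequality): a doubled
#' genome that has since lost material still sits well above 3, while a
#' diploid genome with typical gains stays below.
#'
#' @param segments Segment tibble for a single sample (columns `chrom`,
#'   `start`, `end`, `n_major`, `n_minor`).
#' @return A one-row tibble with columns `ploidy` and `wgd`.
#' @examples
#' seg <- tibble::tibble(chrom = "chr1", start = 1, end = 1e8,
#'                       n_major = 2L, n_minor = 2L)
#' compute_ploidy(seg)   # ploidy 4, wgd TRUE
#' @export
compute_ploidy <- function(segments) {
  if (nrow(segments) == 0) abort("cannot compute ploidy from an empty segment list")
  len <- segments$end - segments$start + 1
  tot <- segments$n_major + segments$n_minor
  ploidy <- sum(len * tot) / sum(len)
  tibble::tibble(ploidy = ploidy, wgd = ploidy > 3)
}

#' Per-sample ploidy table
#'
#' Convenience wrapper applying [compute_ploidy()] to each sample of a
#' multi-sample segment tibble.
#'
#' @param segments Segment tibble with a `sample_id` column.
#' @return Tibble with columns `sample_id`, `ploidy`, `wgd`.
#' @export
ploidy_by_sample <- function(segments) {
  dplyr::reframe(dplyr::group_by(segments, .data$sample_id),
                 compute_ploidy(dplyr::pick(dplyr::everything())))
}

#' Call gene-level copy-number events in one sample
#'
#' For each gene span, using the segments covering it:
#' * **LOH** — minor allele copy number is 0 across the whole span.
#' * **loss** — minimum total copy number over the span is below
#'   `round(ploidy)`. Loss is relative to sample ploidy so that, after whole
#'   genome doubling, dropping to e.g. 2 copies in a tetraploid genome is
#'   still recognised as a loss.
#' * **focal_amplification** — some covering segment has total copy number
#'   at least `amp_factor * ploidy` (default factor 2) and is shorter than
#'   `focal_max_len` (default 10 Mb).
#'
#' When a gene straddles segments in different states the most extreme state
#' decides per event kind (minimum copy state for loss/LOH, maximum for
#' amplification) and a warning is logged. Genes not fully covered by
#' segments are reported as no-calls.
#'
#' On germline-hemizygous chromosomes (chrX/chrY in a male genome) minor
#' copy 0 is the germline state, so LOH is never called there, and the
#' loss baseline is scaled to half ploidy (`round(ploidy * normal_cn / 2)`).
#'
#' @param segments Segment tibble for a single sample.
#' @param gene_table Tibble with `chrom`, `start`, `end`, `name`
#'   (see [default_gene_table()]).
#' @param ploidy_call Output of [compute_ploidy()] for the same sample.
#' @param sex Patient sex, for the no-call bookkeeping of sex chromosomes.
#' @param amp_factor Amplification threshold as a multiple of ploidy.
#' @param focal_max_len Maximum span (bp) for an amplification to count as
#'   focal.
#' @return Tibble with columns `target`, `scope` (`"gene"`), `kind`
#'   (`LOH`, `loss`, `gain`, `focal_amplification`, or `no_call`) — one row
#'   per called event, genes with no event absent except for no-calls.
#' @export
call_gene_events <- function(segments, gene_table, ploidy_call,
                             sex = "male", amp_factor = 2,
                             focal_max_len = 10e6) {
  ploidy <- ploidy_call$ploidy
  out <- purrr::map_dfr(seq_len(nrow(gene_table)), function(i) {
    g <- gene_table[i, ]
    ncn <- normal_copy_number(g$chrom, sex)
    if (ncn == 0) {
      return(tibble::tibble(target = g$name, scope = "gene", kind = "no_call"))
    }
    cov <- dplyr::filter(segments, .data$chrom == g$chrom,
                         .data$start <= g$end, .data$end >= g$start)
    if (nrow(cov) == 0) {
      return(tibble::tibble(target = g$name, scope = "gene", kind = "no_call"))
    }
    covered <- sum(pmin(cov$end, g$end) - pmax(cov$start, g$start) + 1)
    if (covered < g$end - g$start + 1) {
      return(tibble::tibble(target = g$name, scope = "gene", kind = "no_call"))
    }
    if (nrow(cov) > 1 &&
        (dplyr::n_distinct(cov$n_major) > 1 || dplyr::n_distinct(cov$n_minor) > 1)) {
      warn(sprintf("gene %s straddles segments in different states; using extremes", g$name))
    }
    tot <- cov$n_major + cov$n_minor
    kinds <- character(0)
    if (ncn == 2 && max(cov$n_minor) == 0) kinds <- c(kinds, "LOH")
    if (min(tot) < round(ploidy * ncn / 2)) kinds <- c(kinds, "loss")
    amp_seg <- tot >= amp_factor * ploidy &
      (cov$end - cov$start + 1) <= focal_max_len
    if (any(amp_seg)) kinds <- c(kinds, "focal_amplification")
    if (length(kinds) == 0) return(NULL)
    tibble::tibble(target = g$name, scope = "gene", kind = kinds)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(target = character(), scope = character(),
                          kind = character())
  }
  out
}

#' Call arm-level copy-number events in one sample
#'
#' Per chromosome arm, relative to sample ploidy:
#' * **gain** — length-weighted arm total copy number is at least
#'   `ploidy + arm_gain_margin` (default margin 0.6).
#' * **loss** — length-weighted arm total copy number is at most
#'   `ploidy - arm_gain_margin`.
#' * **LOH** — at least `arm_frac` (default 0.9) of the covered arm length
#'   has minor allele copy number 0.
#'
#' Arms with less than half their length covered by segments are no-calls.
#' As for genes, LOH is only defined on germline-diploid chromosomes and
#' the gain/loss baseline on male chrX/chrY is half ploidy.
#'
#' @param segments Segment tibble for a single sample.
#' @param arm_table Tibble with `chrom`, `start`, `end`, `name`
#'   (see [default_arm_table()]).
#' @param ploidy_call Output of [compute_ploidy()].
#' @param arm_gain_margin Copy-number margin above/below ploidy for
#'   gain/loss.
#' @param arm_frac Minimum fraction of arm length at minor copy 0 for LOH.
#' @param sex Patient sex (for the germline state of chrX/chrY).
#' @return Tibble with columns `target`, `scope` (`"arm"`), `kind`.
#' @export
call_arm_events <- function(segments, arm_table, ploidy_call,
                            arm_gain_margin = 0.6, arm_frac = 0.9,
                            sex = "male") {
  ploidy <- ploidy_call$ploidy
  out <- purrr::map_dfr(seq_len(nrow(arm_table)), function(i) {
    a <- arm_table[i, ]
    ncn <- normal_copy_number(a$chrom, sex)
    if (ncn == 0) {
      return(tibble::tibble(target = a$name, scope = "arm", kind = "no_call"))
    }
    cov <- dplyr::filter(segments, .data$chrom == a$chrom,
                         .data$start <= a$end, .data$end >= a$start)
    arm_len <- a$end - a$start + 1
    if (nrow(cov) == 0) {
      return(tibble::tibble(target = a$name, scope = "arm", kind = "no_call"))
    }
    seg_len <- pmin(cov$end, a$end) - pmax(cov$start, a$start) + 1
    if (sum(seg_len) < 0.5 * arm_len) {
      warn(sprintf("arm %s covered < 50%%; no-call", a$name))
      return(tibble::tibble(target = a$name, scope = "arm", kind = "no_call"))
    }
    tot <- cov$n_major + cov$n_minor
    wmean <- sum(seg_len * tot) / sum(seg_len)
    expected <- ploidy * ncn / 2
    kinds <- character(0)
    if (wmean >= expected + arm_gain_margin) kinds <- c(kinds, "gain")
    if (wmean <= expected - arm_gain_margin) kinds <- c(kinds, "loss")
    if (ncn == 2 &&
        sum(seg_len[cov$n_minor == 0]) >= arm_frac * sum(seg_len)) {
      kinds <- c(kinds, "LOH")
    }
    if (length(kinds) == 0) return(NULL)
    tibble::tibble(target = a$name, scope = "arm", kind = kinds)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(target = character(), scope = character(),
                          kind = character())
  }
  out
}

#' Call gene and arm events for every sample
#'
#' @param segments Multi-sample segment tibble.
#' @param gene_table,arm_table Region tables; `NULL` skips that scope.
#' @param panel Sample panel (for sex).
#' @param ... Passed to [call_gene_events()] and [call_arm_events()].
#' @return Tibble with columns `sample_id`, `target`, `scope`, `kind`
#'   (no-calls removed).
#' @export
call_events_by_sample <- function(segments, gene_table = default_gene_table(),
                                  arm_table = default_arm_table(),
                                  panel = NULL, ...) {
  dots <- list(...)
  gene_args <- dots[intersect(names(dots), c("amp_factor", "focal_max_len"))]
  arm_args <- dots[intersect(names(dots), c("arm_gain_margin", "arm_frac"))]
  sex <- if (is.null(panel)) "male" else unique(panel$sex)
  purrr::map_dfr(unique(segments$sample_id), function(s) {
    seg <- dplyr::filter(segments, .data$sample_id == s)
    pl <- compute_ploidy(seg)
    ev <- NULL
    if (!is.null(gene_table)) {
      ev <- dplyr::bind_rows(ev, do.call(call_gene_events,
        c(list(seg, gene_table, pl, sex = sex), gene_args)))
    }
    if (!is.null(arm_table)) {
      ev <- dplyr::bind_rows(ev, do.call(call_arm_events,
        c(list(seg, arm_table, pl, sex = sex), arm_args)))
    }
    ev <- dplyr::filter(ev, .data$kind != "no_call")
    if (nrow(ev) == 0) return(NULL)
    dplyr::mutate(ev, sample_id = s, .before = 1)
  })
}

#' Partition events into shared and private sets across samples
#'
#' Events (identified by scope, target and kind) are classified by the set
#' of samples carrying them: shared by all samples, shared by a proper
#' subset, or private to one sample. Ordering is deterministic (by scope,
#' target, kind).
#'
#' @param events Per-sample event tibble from [call_events_by_sample()].
#' @param sample_ids All tumor sample ids (so absence is well defined).
#' @return Tibble with columns `scope`, `target`, `kind`, `samples`
#'   (comma-separated carriers), `n_samples`, `sharing`
#'   (`"all"`, `"subset"`, `"private"`).
#' @export
compare_events_across_samples <- function(events, sample_ids) {
  if (length(sample_ids) < 2) abort("need at least 2 samples to compare events")
  if (nrow(events) == 0) {
    return(tibble::tibble(scope = character(), target = character(),
                          kind = character(), samples = character(),
                          n_samples = integer(), sharing = character()))
  }
  ord <- match(events$sample_id, sample_ids)
  events <- events[order(ord), ]
  out <- dplyr::summarise(
    dplyr::group_by(events, .data$scope, .data$target, .data$kind),
    samples = paste(unique(.data$sample_id), collapse = ","),
    n_samples = dplyr::n_distinct(.data$sample_id),
    .groups = "drop"
  )
  out <- dplyr::mutate(out, sharing = dplyr::case_when(
    .data$n_samples == length(sample_ids) ~ "all",
    .data$n_samples == 1L ~ "private",
    TRUE ~ "subset"
  ))
  dplyr::arrange(out, .data$scope, .data$target, .data$kind)
}
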