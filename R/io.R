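# File formats consumed and produced by the pipeline.
#
# Coordinate convention: VCF positions and segment coordinates are 1-based
# and inclusive at both ends, throughout the package.

#' Read somatic SNV calls from a multi-sample VCF
#'
#' Parses a VCF containing one matched normal and one or more tumor samples
#' with AD-style per-sample allelic depths, and returns a long tibble with
#' one row per variant per tumor sample. Indels are parsed and flagged
#' (`is_indel`) but are excluded from CCF estimation and clustering
#' downstream: the clonal deconvolution model is defined for SNVs.
#'
#' @param path Path to a VCF (v4.x) file. May be bgzipped.
#' @param tumor_sample_ids Character vector of tumor sample names, as they
#'   appear in the VCF header.
#' @param normal_sample_id Name of the matched normal sample.
#' @param skip_nonpass Drop rows whose FILTER is neither `PASS` nor `.`
#'   (default `TRUE`; upstream variant filtering is assumed done).
#' @param multiallelic `"skip"` (default) drops rows with more than one ALT
#'   allele; `"split"` emits one record per ALT allele, all sharing the REF
#'   depth.
#' @return A tibble with columns `variant_id` (`chrom:pos:ref:alt`), `chrom`,
#'   `pos`, `ref`, `alt`, `gene` (from an INFO `GENE=` tag when present,
#'   else `NA`), `is_indel`, `sample_id`, `ref_count`, `alt_count`.
#' @examples
#' sim <- simulate_case(sim_preset("null_single_clone"), out_dir = tempfile())
#' vars <- read_vcf(sim$paths$vcf, sim$panel$sample_id, "NORMAL")
#' dplyr::count(vars, sample_id)
#' @export
read_vcf <- function(path, tumor_sample_ids, normal_sample_id,
                     skip_nonpass = TRUE,
                     multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(v)
  if (is.null(dim(fix_mat))) {  # single-row VCFs come back as a bare vector
    fix_mat <- matrix(fix_mat, nrow = 1, dimnames = list(NULL, names(fix_mat)))
  }
  fix <- tibble::as_tibble(as.data.frame(fix_mat, stringsAsFactors = FALSE))
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(c(tumor_sample_ids, normal_sample_id), vcf_samples)
  if (length(missing) > 0) {
    abort(paste0("sample(s) not present in VCF: ", paste(missing, collapse = ", ")))
  }
  fmt <- v@gt[, "FORMAT", drop = TRUE]
  if (nrow(fix) > 0 && !all(grepl("(^|:)AD(:|$)", fmt))) {
    bad <- which(!grepl("(^|:)AD(:|$)", fmt))[1]
    abort(sprintf("VCF row %d (%s:%s) has no AD field in FORMAT", bad,
                  fix$CHROM[bad], fix$POS[bad]))
  }
  keep <- rep(TRUE, nrow(fix))
  if (skip_nonpass && nrow(fix) > 0) {
    filt <- fix$FILTER
    keep <- is.na(filt) | filt %in% c("PASS", ".")
  }
  multi <- grepl(",", fix$ALT %||% character(0))
  if (multiallelic == "skip") keep <- keep & !multi

  ad <- vcfR::extract.gt(v, element = "AD")
  gene <- vcfR::extract.info(v, element = "GENE")

  rows <- which(keep)
  if (length(rows) == 0) {
    return(tibble::tibble(
      variant_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), gene = character(),
      is_indel = logical(), sample_id = character(),
      ref_count = integer(), alt_count = integer()
    ))
  }

  recs <- purrr::map_dfr(rows, function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    purrr::map_dfr(seq_along(alts), function(a) {
      counts <- purrr::map_dfr(tumor_sample_ids, function(s) {
        parts <- strsplit(ad[i, s], ",", fixed = TRUE)[[1]]
        if (length(parts) < a + 1 || anyNA(suppressWarnings(as.integer(parts)))) {
          abort(sprintf("malformed AD '%s' for sample %s at %s:%s",
                        ad[i, s], s, fix$CHROM[i], fix$POS[i]))
        }
        tibble::tibble(sample_id = s,
                       ref_count = as.integer(parts[1]),
                       alt_count = as.integer(parts[a + 1]))
      })
      tibble::tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        gene = if (is.null(gene)) NA_character_ else gene[i],
        is_indel = nchar(fix$REF[i]) != 1L | nchar(alts[a]) != 1L,
        counts
      )
    })
  })
  recs <- dplyr::mutate(recs,
    variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"),
    .before = 1
  )
  no_alt <- dplyr::summarise(dplyr::group_by(recs, .data$variant_id),
                             tot = sum(.data$ref_count + .data$alt_count))
  dead <- no_alt$variant_id[no_alt$tot == 0]
  if (length(dead) > 0) {
    warn(sprintf("%d variant(s) with zero total depth in all tumor samples dropped",
                 length(dead)))
    recs <- dplyr::filter(recs, !.data$variant_id %in% dead)
  }
  recs
}

#' Read allele-specific copy-number segments
#'
#' Reads a tab-separated table of ASCAT-style allele-specific copy-number
#' segments: columns `sample`, `chrom`, `start`, `end`, `nMajor`, `nMinor`,
#' one row per segment. Coordinates are 1-based inclusive. Lines starting
#' with `#` are comments. Segments of one sample must not overlap.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_major`, `n_minor`, sorted by sample, chromosome and start.
#' @export
read_segments <- function(path) {
  seg <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("sample", "chrom", "start", "end", "nMajor", "nMinor")
  if (!all(need %in% names(seg))) {
    abort(paste0("segment file must have columns: ", paste(need, collapse = ", ")))
  }
  seg <- tibble::tibble(
    sample_id = as.character(seg$sample), chrom = as.character(seg$chrom),
    start = as.numeric(seg$start), end = as.numeric(seg$end),
    n_major = as.integer(seg$nMajor), n_minor = as.integer(seg$nMinor)
  )
  validate_segments(seg)
}

validate_segments <- function(seg) {
  if (any(is.na(seg$start) | is.na(seg$end) | seg$start > seg$end | seg$start < 1)) {
    abort("malformed segment coordinates (need 1 <= start <= end)")
  }
  if (any(seg$n_minor > seg$n_major)) {
    abort("segment with nMinor > nMajor (allele-specific convention violated)")
  }
  if (any(seg$n_minor < 0)) abort("negative copy number")
  seg <- dplyr::arrange(seg, .data$sample_id, .data$chrom, .data$start)
  ov <- dplyr::summarise(
    dplyr::group_by(seg, .data$sample_id, .data$chrom),
    bad = any(.data$start[-1] <= .data$end[-dplyr::n()]) && dplyr::n() > 1
  )
  if (any(ov$bad)) {
    abort(sprintf("overlapping segments for sample %s on %s",
                  ov$sample_id[ov$bad][1], ov$chrom[ov$bad][1]))
  }
  seg
}

#' Read a gene or chromosome-arm coordinate table
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `name` (1-based
#' inclusive, header row required, `#` comments allowed). The package ships
#' hg38 defaults for the genes and arms most relevant to prostate cancer
#' evolution (PTEN, RB1, TP53, AR; 1p, 3p, 4p, 6q, 13q, 17p, Xq):
#' see [default_gene_table()].
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_region_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("chrom", "start", "end", "name")
  if (!all(need %in% names(tab))) {
    abort(paste0("region table must have columns: ", paste(need, collapse = ", ")))
  }
  tibble::tibble(chrom = as.character(tab$chrom), start = as.numeric(tab$start),
                 end = as.numeric(tab$end), name = as.character(tab$name))
}

#' @rdname read_region_table
#' @export
default_gene_table <- function() {
  read_region_table(system.file("extdata", "genes_hg38.tsv",
                                package = "clonetrace", mustWork = TRUE))
}

#' @rdname read_region_table
#' @export
default_arm_table <- function() {
  read_region_table(system.file("extdata", "arms_hg38.tsv",
                                package = "clonetrace", mustWork = TRUE))
}

#' Read a sample panel file
#'
#' TSV with columns `sample`, `purity`, `date`, `sex`.
#'
#' @param path Path to the TSV file.
#' @return A sample panel tibble (see [sample_panel()]).
#' @export
read_panel <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("sample", "purity", "date", "sex")
  if (!all(need %in% names(tab))) {
    abort(paste0("panel file must have columns: ", paste(need, collapse = ", ")))
  }
  sample_panel(tab$sample, tab$purity, tab$date, sex = unique(tab$sex))
}

#' Write all pipeline results to a directory
#'
#' Emits `ccf.tsv` (per-variant per-sample VAF, multiplicity, total copy
#' number, raw and clipped CCF, flags), `clusters.tsv`, `assignments.tsv`,
#' `events.tsv`, `timed_events.tsv` (when timing was run), `tree.json`
#' (nodes, edges, per-node per-sample CCF centers, attached copy-number
#' events) and `tree.nwk` (Newick; branch lengths are the child cluster's
#' SNV count). Numeric columns are written with 6 fixed decimals so files
#' re-read to the printed precision.
#'
#' @param ccf_matrix Output of [build_ccf_matrix()].
#' @param cluster_result Output of [dp_cluster()].
#' @param clone_tree Output of [build_tree()].
#' @param events Output of [compare_events_across_samples()] (may be `NULL`).
#' @param out_dir Directory to create/write into.
#' @param timed Optional output of [time_events()].
#' @return Invisibly, a named character vector of the files written.
#' @export
write_results <- function(ccf_matrix, cluster_result, clone_tree, events,
                          out_dir, timed = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output directory %s", out_dir))
  paths <- c()

  ccf_out <- dplyr::mutate(ccf_matrix, dplyr::across(
    dplyr::all_of(c("vaf", "ccf_raw", "ccf_clipped")), ~fmt_num(.x)))
  p <- file.path(out_dir, "ccf.tsv")
  readr::write_tsv(ccf_out, p, progress = FALSE)
  paths["ccf"] <- p

  cl <- summarize_clusters(cluster_result)
  cl_out <- dplyr::mutate(cl, dplyr::across(dplyr::starts_with("ccf_"), ~fmt_num(.x)))
  p <- file.path(out_dir, "clusters.tsv")
  readr::write_tsv(dplyr::select(cl_out, -"variants"), p, progress = FALSE)
  paths["clusters"] <- p

  p <- file.path(out_dir, "assignments.tsv")
  readr::write_tsv(cluster_result$assignments, p, progress = FALSE)
  paths["assignments"] <- p

  if (!is.null(events)) {
    p <- file.path(out_dir, "events.tsv")
    readr::write_tsv(events, p, progress = FALSE)
    paths["events"] <- p
  }
  if (!is.null(timed)) {
    p <- file.path(out_dir, "timed_events.tsv")
    readr::write_tsv(timed, p, progress = FALSE)
    paths["timed_events"] <- p
  }

  p <- file.path(out_dir, "tree.json")
  jsonlite::write_json(tree_to_list(clone_tree), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths["tree_json"] <- p

  p <- file.path(out_dir, "tree.nwk")
  writeLines(write_newick(clone_tree), p)
  paths["tree_newick"] <- p

  invisible(paths)
}

# Minimal VCF 4.2 writer used by the simulator; emits GT:AD:DP for the
# normal plus all tumor samples. `variants` is the long tibble shape of
# read_vcf(); counts for the normal are ref-only at the tumor-average depth.
write_vcf <- function(variants, tumor_sample_ids, normal_sample_id, path,
                      filter = NULL) {
  wide <- tidyr::pivot_wider(
    variants,
    id_cols = c("variant_id", "chrom", "pos", "ref", "alt", "gene"),
    names_from = "sample_id", values_from = c("ref_count", "alt_count")
  )
  wide <- dplyr::arrange(wide, .data$chrom, .data$pos, .data$alt)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", normal_sample_id, tumor_sample_ids), collapse = "\t")
  )
  filt <- if (is.null(filter)) rep("PASS", nrow(wide)) else filter
  body <- vapply(seq_len(nrow(wide)), function(i) {
    r <- wide[i, ]
    tum <- vapply(tumor_sample_ids, function(s) {
      rc <- r[[paste0("ref_count_", s)]]
      ac <- r[[paste0("alt_count_", s)]]
      sprintf("0/1:%d,%d:%d", rc, ac, rc + ac)
    }, character(1))
    ndp <- round(mean(vapply(tumor_sample_ids, function(s)
      r[[paste0("ref_count_", s)]] + r[[paste0("alt_count_", s)]], numeric(1))))
    info <- if (is.na(r$gene)) "." else paste0("GENE=", r$gene)
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", filt[i], info,
            "GT:AD:DP", sprintf("0/0:%d,0:%d", ndp, ndp), tum),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_segments <- function(segments, path) {
  out <- tibble::tibble(sample = segments$sample_id, chrom = segments$chrom,
                        start = segments$start, end = segments$end,
                        nMajor = segments$n_major, nMinor = segments$n_minor)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

write_panel <- function(panel, path) {
  out <- tibble::tibble(sample = panel$sample_id, purity = panel$purity,
                        date = panel$date, sex = panel$sex)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
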