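# Synthetic patient generator: emits VCF + segments + panel + ground truth
# with the statistical structure the downstream analysis assumes.
#
# Read-count model per SNV of clone k, sample s:
#   expected VAF = phi_ks * purity_s * m / (purity_s * cn + (1-purity_s) * ncn)
#   depth ~ Poisson(mean depth);  alt ~ Binomial(depth, expected VAF)
# where cn is the locus total copy number in that sample's (clonal) segment
# profile, ncn the germline copy number, and m the multiplicity: SNVs of
# clones ancestral to (or carrying) the whole-genome doubling get
# m = n_major at the locus — doubling carries the mutated haplotype with it,
# which is what keeps truncal SNVs at CCF ~ 1 after WGD — and all later
# SNVs get m = 1.

default_sim_genome <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr3", "chr4", "chr6", "chr8", "chr10", "chr13",
              "chr17", "chrX"),
    length = c(248956422, 198295559, 190214555, 170805979, 145138636,
               133797422, 114364328, 83257441, 156040895)
  )
}

#' Specify a synthetic patient
#'
#' Declares the clone tree (per-sample CCFs and SNV counts per clone), the
#' clonal copy-number alterations each clone carries, sample purities and
#' dates, sequencing depth and patient sex. The configuration is validated
#' up front: clone CCFs must satisfy the sum rule and the presence-subset
#' rule exactly, since they are the ground truth the phylogeny is scored
#' against.
#'
#' @param samples Tibble with `sample_id`, `purity`, `date`.
#' @param clones Tibble with `clone`, `parent` (`NA` for the root),
#'   `n_snvs`, one CCF column per sample (named as the sample), and an
#'   optional `genes` list column naming genes (from
#'   [default_gene_table()]) in which to place annotated SNVs.
#' @param cnas Tibble with `name`, `chrom`, `start`, `end`, `n_major`,
#'   `n_minor`, `clone` (the clone carrying the alteration), or `NULL`.
#'   States are the post-WGD states seen in carrying samples.
#' @param wgd_clone Clone carrying a whole-genome doubling (doubles the
#'   baseline profile in every sample where that clone's CCF exceeds 0.5),
#'   or `NULL`.
#' @param depth Mean sequencing depth (Poisson), default 100 — matching
#'   typical exome coverage.
#' @param sex `"male"` or `"female"`.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param genome Chromosome length table (default: the nine chromosomes the
#'   shipped gene/arm tables cover, hg38 lengths).
#' @return A `sim_config` object.
#' @export
sim_config <- function(samples, clones, cnas = NULL, wgd_clone = NULL,
                       depth = 100, sex = c("male", "female"), seed = 1,
                       genome = default_sim_genome()) {
  sex <- match.arg(sex)
  if (depth <= 0) abort("depth must be positive")
  sids <- samples$sample_id
  if (!all(sids %in% names(clones))) {
    abort("clones must have one CCF column per sample")
  }
  phi <- as.matrix(clones[, sids])
  rownames(phi) <- clones$clone
  if (any(phi < 0 | phi > 1)) abort("clone CCFs must lie in [0, 1]")
  if (sum(is.na(clones$parent)) != 1) abort("exactly one root clone required")
  # exact sum + subset rules on the declared truth
  for (p in clones$clone) {
    kids <- clones$clone[!is.na(clones$parent) & clones$parent == p]
    if (length(kids) == 0) next
    for (k in kids) {
      if (any(phi[k, ] > 0 & phi[p, ] == 0)) {
        abort(sprintf("clone %s present where its parent %s is absent", k, p))
      }
    }
    ksum <- colSums(phi[kids, , drop = FALSE])
    if (any(ksum > phi[p, ] + 1e-9)) {
      abort(sprintf("clone CCFs violate the sum rule under parent %s", p))
    }
  }
  if (!is.null(cnas) && nrow(cnas) > 0) {
    if (!all(cnas$clone %in% clones$clone)) abort("cna clone not in clone table")
    if (any(cnas$n_minor > cnas$n_major)) abort("cna state with n_minor > n_major")
  }
  if (!is.null(wgd_clone) && !wgd_clone %in% clones$clone) {
    abort("wgd_clone not in clone table")
  }
  structure(list(samples = samples, clones = clones, cnas = cnas,
                 wgd_clone = wgd_clone, depth = depth, sex = sex,
                 seed = seed, genome = genome),
            class = "sim_config")
}

# is clone `a` an ancestor of (or equal to) clone `b`?
is_ancestor <- function(clones, a, b) {
  cur <- b
  repeat {
    if (identical(cur, a)) return(TRUE)
    nxt <- clones$parent[clones$clone == cur]
    if (is.na(nxt)) return(FALSE)
    cur <- nxt
  }
}

# clonal segment profile of one sample: baseline diploid (haploid X/Y for
# males), doubled where the WGD clone dominates, CNA states painted over
# the spans of dominant carrying clones.
sample_segments <- function(config, sample_id) {
  phi <- as.matrix(config$clones[, config$samples$sample_id])
  rownames(phi) <- config$clones$clone
  active <- function(clone) phi[clone, sample_id] > 0.5
  wgd <- !is.null(config$wgd_clone) && active(config$wgd_clone)

  purrr::map_dfr(seq_len(nrow(config$genome)), function(ci) {
    chrom <- config$genome$chrom[ci]
    len <- config$genome$length[ci]
    ncn <- normal_copy_number(chrom, config$sex)
    if (ncn == 0) return(NULL)
    base_major <- if (ncn == 1) 1L else 1L
    base_minor <- if (ncn == 1) 0L else 1L
    if (wgd) { base_major <- 2L * base_major; base_minor <- 2L * base_minor }
    bp <- c(1, len + 1)
    cn <- config$cnas
    here <- if (is.null(cn)) NULL else
      cn[cn$chrom == chrom & vapply(cn$clone, active, logical(1)), ]
    if (!is.null(here) && nrow(here) > 0) {
      bp <- sort(unique(c(bp, here$start, here$end + 1)))
    }
    purrr::map_dfr(seq_len(length(bp) - 1), function(j) {
      s <- bp[j]; e <- bp[j + 1] - 1
      maj <- base_major; mnr <- base_minor
      if (!is.null(here) && nrow(here) > 0) {
        hit <- which(here$start <= s & here$end >= e)
        if (length(hit) > 0) {
          h <- hit[length(hit)]  # later-declared CNA wins on overlap
          maj <- as.integer(here$n_major[h]); mnr <- as.integer(here$n_minor[h])
        }
      }
      tibble::tibble(sample_id = sample_id, chrom = chrom, start = s, end = e,
                     n_major = maj, n_minor = mnr)
    })
  })
}

#' Simulate a synthetic patient
#'
#' Generates the segment profiles, draws SNV positions, simulates binomial
#' read counts under the CCF model, and writes `variants.vcf`,
#' `segments.tsv`, `panel.tsv` and `truth.json` into `out_dir` — exactly
#' the formats the pipeline consumes. Identical (config, seed) pairs
#' produce byte-identical files.
#'
#' @param config A [sim_config()] (or preset name accepted by
#'   [sim_preset()]).
#' @param out_dir Output directory (created if needed).
#' @return A list with `paths` (named file paths), `panel`, `variants`
#'   (long tibble as [read_vcf()] returns), `segments`, `truth` (list:
#'   `assignments`, `clone_ccf`, `tree`, `ploidy`, `events`).
#' @examples
#' sim <- simulate_case(sim_preset("null_single_clone"), out_dir = tempfile())
#' sim$truth$ploidy
#' @export
simulate_case <- function(config, out_dir) {
  if (is.character(config)) config <- sim_preset(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  panel <- sample_panel(config$samples$sample_id, config$samples$purity,
                        config$samples$date, config$sex)
  segments <- purrr::map_dfr(panel$sample_id,
                             ~sample_segments(config, .x))

  phi <- as.matrix(config$clones[, panel$sample_id])
  rownames(phi) <- config$clones$clone
  gene_tab <- default_gene_table()

  # SNV positions: gene-targeted SNVs at gene midpoints, the rest uniform
  # over the simulated genome (unique chrom:pos)
  placed <- tibble::tibble(clone = character(), chrom = character(),
                           pos = numeric(), gene = character())
  for (i in seq_len(nrow(config$clones))) {
    cl <- config$clones$clone[i]
    genes <- if ("genes" %in% names(config$clones))
      config$clones$genes[[i]] else NULL
    n_free <- config$clones$n_snvs[i] - length(genes)
    if (n_free < 0) abort("n_snvs smaller than the gene SNV list")
    if (length(genes) > 0) {
      g <- gene_tab[match(genes, gene_tab$name), ]
      if (anyNA(g$chrom)) abort("unknown gene in clone gene list")
      placed <- dplyr::bind_rows(placed, tibble::tibble(
        clone = cl, chrom = g$chrom, pos = floor((g$start + g$end) / 2),
        gene = g$name))
    }
    while (n_free > 0) {
      ch <- sample(config$genome$chrom, n_free, replace = TRUE,
                   prob = config$genome$length)
      pos <- floor(runif(n_free) *
                     config$genome$length[match(ch, config$genome$chrom)]) + 1
      cand <- tibble::tibble(clone = cl, chrom = ch, pos = pos,
                             gene = NA_character_)
      cand <- dplyr::anti_join(cand, placed, by = c("chrom", "pos"))
      cand <- dplyr::distinct(cand, .data$chrom, .data$pos, .keep_all = TRUE)
      placed <- dplyr::bind_rows(placed, cand)
      n_free <- n_free - nrow(cand)
    }
  }
  bases <- c("A", "C", "G", "T")
  placed$ref <- sample(bases, nrow(placed), replace = TRUE)
  placed$alt <- vapply(placed$ref,
                       function(r) sample(setdiff(bases, r), 1), character(1))
  placed <- dplyr::mutate(placed,
    variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"))

  # per-sample counts
  variants <- purrr::map_dfr(panel$sample_id, function(s) {
    seg <- dplyr::filter(segments, .data$sample_id == s)
    loc <- locate_in_segments(dplyr::select(placed, "chrom", "pos"), seg)
    cn <- loc$n_major + loc$n_minor
    ncn <- normal_copy_number(placed$chrom, config$sex)
    pre_wgd <- if (is.null(config$wgd_clone)) rep(FALSE, nrow(placed)) else
      vapply(placed$clone, function(cl)
        is_ancestor(config$clones, cl, config$wgd_clone), logical(1))
    m <- ifelse(pre_wgd, loc$n_major, 1L)
    m <- pmin(pmax(m, 1L), pmax(loc$n_major, 1L))
    rho <- panel$purity[panel$sample_id == s]
    ev <- phi[placed$clone, s] * rho * m / (rho * cn + (1 - rho) * ncn)
    dp <- rpois(nrow(placed), config$depth)
    ac <- rbinom(nrow(placed), dp, ev)
    tibble::tibble(variant_id = placed$variant_id, chrom = placed$chrom,
                   pos = placed$pos, ref = placed$ref, alt = placed$alt,
                   gene = placed$gene, is_indel = FALSE, sample_id = s,
                   ref_count = dp - ac, alt_count = ac)
  })

  # ground truth
  ploidy_truth <- purrr::map_dfr(panel$sample_id, function(s) {
    seg <- dplyr::filter(segments, .data$sample_id == s)
    len <- seg$end - seg$start + 1
    pl <- sum(len * (seg$n_major + seg$n_minor)) / sum(len)
    tibble::tibble(sample_id = s, ploidy = pl, wgd = pl > 3)
  })
  event_truth <- NULL
  if (!is.null(config$cnas) && nrow(config$cnas) > 0) {
    event_truth <- purrr::map_dfr(seq_len(nrow(config$cnas)), function(i) {
      cl <- config$cnas$clone[i]
      present <- panel$sample_id[phi[cl, ] > 0.5]
      tibble::tibble(name = config$cnas$name[i], clone = cl,
                     samples = paste(present, collapse = ","))
    })
    event_truth <- dplyr::bind_cols(event_truth,
      dplyr::select(time_events(
        dplyr::rename(event_truth, target = "name"), panel),
        "status", "interval_start", "interval_end"))
  }
  truth <- list(
    assignments = tibble::tibble(variant_id = placed$variant_id,
                                 clone = placed$clone),
    clone_ccf = phi,
    tree = tibble::tibble(clone = config$clones$clone,
                          parent = config$clones$parent),
    ploidy = ploidy_truth,
    events = event_truth,
    wgd_clone = config$wgd_clone,
    seed = config$seed
  )

  paths <- c(vcf = file.path(out_dir, "variants.vcf"),
             segments = file.path(out_dir, "segments.tsv"),
             panel = file.path(out_dir, "panel.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_vcf(variants, panel$sample_id, "NORMAL", paths["vcf"])
  write_segments(segments, paths["segments"])
  write_panel(panel, paths["panel"])
  jsonlite::write_json(list(
    assignments = truth$assignments,
    clone_ccf = as.data.frame(cbind(clone = rownames(phi), as.data.frame(phi))),
    tree = truth$tree, ploidy = truth$ploidy, events = truth$events,
    wgd_clone = truth$wgd_clone, seed = truth$seed
  ), paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(paths = paths, panel = panel, variants = variants,
       segments = segments, truth = truth, config = config)
}

#' Preset synthetic-patient configurations
#'
#' * `"case1_like"` — four dated samples (one ductal-morphology region, two
#'   time points after the first), truncal whole-genome doubling, a
#'   truncal 53-SNV clone carrying a PTEN SNV at CCF 1 everywhere, a focal
#'   chrX (AR) amplification arising after the first sample, a
#'   ductal-private clone with private CNAs (1p LOH, 6q gain), and a
#'   34-SNV clone private to the last sample. Five clones in total.
#' * `"case2_like"` — two regions from one time point (ordered labels):
#'   shared trunk carrying 13q LOH (hence RB1 loss), a neuroendocrine
#'   branch carrying 3p gain, 4p LOH and 17p LOH (TP53), and an
#'   adenocarcinoma-private clone.
#' * `"null_single_clone"` — one clone at CCF 1 in two samples, diploid, no
#'   CNAs.
#'
#' @param name Preset name.
#' @param depth Override the preset's mean depth.
#' @param purity Override purity (recycled across samples).
#' @param seed Seed stored in the configuration.
#' @return A `sim_config`.
#' @export
sim_preset <- function(name, depth = NULL, purity = NULL, seed = 1) {
  presets <- c("case1_like", "case2_like", "null_single_clone")
  if (!name %in% presets) {
    abort(sprintf("unknown preset '%s'; available: %s", name,
                  paste(presets, collapse = ", ")))
  }
  cfg <- switch(name,
    case1_like = {
      samples <- tibble::tibble(
        sample_id = c("NE_2012", "NE_2015", "DUCTAL_2015", "NE_2017"),
        purity = c(0.75, 0.70, 0.65, 0.70),
        date = c(2012, 2015, 2015, 2017))
      clones <- tibble::tibble(
        clone  = c("A", "C", "E", "D", "B"),
        parent = c(NA, "A", "C", "C", "C"),
        n_snvs = c(53L, 30L, 20L, 25L, 34L),
        NE_2012     = c(1, 0, 0, 0, 0),
        NE_2015     = c(1, 1, 0.5, 0, 0),
        DUCTAL_2015 = c(1, 1, 0, 0.85, 0),
        NE_2017     = c(1, 1, 0, 0, 0.75),
        genes = list("PTEN", NULL, NULL, NULL, NULL))
      cnas <- tibble::tibble(
        name = c("AR_amp", "1p_LOH", "6q_gain"),
        chrom = c("chrX", "chr1", "chr6"),
        start = c(67000000, 1, 59800000),
        end = c(68000000, 123400000, 170805979),
        n_major = c(10L, 2L, 4L),
        n_minor = c(0L, 0L, 2L),
        clone = c("C", "D", "D"))
      sim_config(samples, clones, cnas, wgd_clone = "A", depth = 100,
                 sex = "male", seed = seed)
    },
    case2_like = {
      samples <- tibble::tibble(
        sample_id = c("ADENO", "TNEPC"),
        purity = c(0.70, 0.65),
        date = c(1, 2))
      clones <- tibble::tibble(
        clone  = c("A", "B", "C"),
        parent = c(NA, "A", "A"),
        n_snvs = c(60L, 40L, 30L),
        ADENO = c(1, 0, 0.6),
        TNEPC = c(1, 0.7, 0))
      cnas <- tibble::tibble(
        name = c("13q_LOH", "3p_gain", "4p_LOH", "17p_LOH"),
        chrom = c("chr13", "chr3", "chr4", "chr17"),
        start = c(17700000, 1, 1, 1),
        end = c(114364328, 90900000, 50000000, 25100000),
        n_major = c(1L, 2L, 1L, 1L),
        n_minor = c(0L, 1L, 0L, 0L),
        clone = c("A", "B", "B", "B"))
      sim_config(samples, clones, cnas, depth = 100, sex = "male",
                 seed = seed)
    },
    null_single_clone = {
      samples <- tibble::tibble(sample_id = c("S1", "S2"),
                                purity = c(0.7, 0.7), date = c(1, 2))
      clones <- tibble::tibble(clone = "A", parent = NA_character_,
                               n_snvs = 60L, S1 = 1, S2 = 1)
      sim_config(samples, clones, depth = 100, sex = "male", seed = seed)
    })
  if (!is.null(depth)) cfg$depth <- depth
  if (!is.null(purity)) {
    cfg$samples$purity <- rep_len(purity, nrow(cfg$samples))
  }
  cfg$seed <- seed
  cfg
}
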