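# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# a fast clustering configuration for tests that only need the plumbing,
# not full posterior quality
quick_config <- function(seed = 1, ...) {
  clone_config(sweeps = 400, burn_in = 100, seed = seed, ...)
}

seg_tbl <- function(..., sample_id = "S1") {
  # seg_tbl(c("chr1", 1, 1e8, 1, 1), ...) -> segment tibble
  rows <- list(...)
  tibble::tibble(
    sample_id = sample_id,
    chrom = vapply(rows, function(r) as.character(r[[1]]), character(1)),
    start = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    end = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
    n_major = vapply(rows, function(r) as.integer(r[[4]]), integer(1)),
    n_minor = vapply(rows, function(r) as.integer(r[[5]]), integer(1))
  )
}

# a minimal handwritten VCF for parser tests
write_test_vcf <- function(path, rows,
                           samples = c("NORMAL", "T1", "T2")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, rows), path)
  path
}

# three-clone configuration used by clustering recovery tests: a truncal
# clone plus two branch clones private to one sample each, separated by
# >= 0.3 in at least one sample
three_clone_config <- function(seed, n_per_clone = 100, depth = 100,
                               purity = 0.7) {
  samples <- tibble::tibble(sample_id = c("S1", "S2"),
                            purity = rep(purity, 2), date = c(1, 2))
  clones <- tibble::tibble(
    clone = c("A", "B", "C"), parent = c(NA, "A", "A"),
    n_snvs = rep(as.integer(n_per_clone), 3),
    S1 = c(1, 0.55, 0), S2 = c(1, 0, 0.55))
  sim_config(samples, clones, depth = depth, sex = "male", seed = seed)
}

# truth clone CCFs reshaped as a summarize_clusters()-style table, for
# feeding the phylogeny module with noise-free centers
truth_cluster_summary <- function(sim) {
  phi <- sim$truth$clone_ccf
  out <- tibble::tibble(cluster = rownames(phi),
                        size = sim$config$clones$n_snvs)
  for (s in colnames(phi)) out[[paste0("ccf_", s)]] <- phi[, s]
  out$presence <- vapply(seq_len(nrow(phi)), function(i)
    paste(colnames(phi)[phi[i, ] > 0], collapse = ","), character(1))
  out
}
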