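test_that("multiplicity estimation picks the nearest clonal VAF, ties to smaller m", {
  expect_equal(estimate_multiplicity(0.5, 1, 1, 1), 1L)
  expect_equal(estimate_multiplicity(0.5, 1, 2, 2), 2L)
  expect_equal(estimate_multiplicity(0.25, 0.5, 1, 1), 1L)
  # exact tie between m=1 (0.25) and m=3 at vaf 0.5 in 2+2, purity 1:
  # candidates 0.25, 0.5, 0.75 -> 0.5 is closest at m=2; construct a true
  # tie at vaf 0.375 between m=1 and m=2 -> smaller m wins
  expect_equal(estimate_multiplicity(0.375, 1, 2, 2), 1L)
  expect_error(estimate_multiplicity(0.5, 0, 1, 1), "purity")
  expect_error(estimate_multiplicity(0.5, 1, 0, 0), "n_major")
})

test_that("ccf inverts the VAF model", {
  expect_equal(compute_ccf(0.5, 1, 1, 1, 1), 1)
  expect_equal(compute_ccf(0, 1, 1, 1, 1), 0)
  expect_equal(compute_ccf(0.25, 0.5, 1, 1, 1), 1)
  expect_error(compute_ccf(0.5, 1, 1, 1, 0), "positive")
})

test_that("noise-free expected VAFs map back to the generating CCF exactly", {
  cn_states <- list(c(1, 0), c(1, 1), c(2, 1), c(2, 2))
  for (purity in c(0.3, 0.5, 0.8, 1.0)) {
    for (cn in cn_states) {
      for (m in seq_len(cn[1])) {
        vaf <- expected_vaf(1, purity, sum(cn), m, normal_cn = 2)
        m_hat <- estimate_multiplicity(vaf, purity, cn[1], cn[2])
        expect_identical(m_hat, as.integer(m))
        ccf <- compute_ccf(vaf, purity, cn[1], cn[2], m_hat)
        expect_equal(ccf, 1, tolerance = 1e-12)
      }
      # subclonal single-copy mutations over a CCF grid
      for (phi in seq(0.05, 1, by = 0.05)) {
        vaf <- expected_vaf(phi, purity, sum(cn), 1, normal_cn = 2)
        m_hat <- estimate_multiplicity(vaf, purity, cn[1], cn[2])
        expect_identical(m_hat, 1L)
        expect_equal(compute_ccf(vaf, purity, cn[1], cn[2], m_hat), phi,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("ccf is strictly increasing in vaf, all else fixed", {
  vafs <- seq(0.01, 0.6, by = 0.01)
  ccfs <- compute_ccf(vafs, 0.7, 2, 1, 1)
  expect_true(all(diff(ccfs) > 0))
})

test_that("the ccf matrix covers every variant-sample pair with sex-aware normals", {
  panel <- sample_panel(c("T1", "T2"), c(0.8, 0.8), c(1, 2), "male")
  variants <- tidyr::crossing(
    tibble::tibble(chrom = c("chr1", "chrX"), pos = c(1000L, 5000L),
                   ref = "A", alt = "T"),
    sample_id = c("T1", "T2")) |>
    dplyr::mutate(variant_id = paste(chrom, pos, ref, alt, sep = ":"),
                  gene = NA_character_, is_indel = FALSE,
                  ref_count = 50L, alt_count = 30L)
  segments <- dplyr::bind_rows(
    seg_tbl(c("chr1", 1, 1e6, 1, 1), c("chrX", 1, 1e6, 1, 0), sample_id = "T1"),
    seg_tbl(c("chr1", 1, 1e6, 1, 1), c("chrX", 1, 1e6, 1, 0), sample_id = "T2"))
  m <- build_ccf_matrix(variants, segments, panel)
  expect_equal(nrow(m), 4)
  expect_equal(unique(m$normal_cn[m$chrom == "chrX"]), 1L)
  expect_equal(unique(m$normal_cn[m$chrom == "chr1"]), 2L)
})

test_that("variants below the depth floor in any sample are excluded", {
  panel <- sample_panel(c("T1", "T2"), c(0.8, 0.8), c(1, 2), "male")
  variants <- tidyr::crossing(
    tibble::tibble(chrom = "chr1", pos = c(1000L, 2000L), ref = "A", alt = "T"),
    sample_id = c("T1", "T2")) |>
    dplyr::mutate(variant_id = paste(chrom, pos, ref, alt, sep = ":"),
                  gene = NA_character_, is_indel = FALSE,
                  ref_count = dplyr::if_else(pos == 2000L & sample_id == "T2",
                                             3L, 50L),
                  alt_count = dplyr::if_else(pos == 2000L & sample_id == "T2",
                                             2L, 30L))
  segments <- dplyr::bind_rows(
    seg_tbl(c("chr1", 1, 1e6, 1, 1), sample_id = "T1"),
    seg_tbl(c("chr1", 1, 1e6, 1, 1), sample_id = "T2"))
  m <- build_ccf_matrix(variants, segments, panel, min_depth = 10)
  expect_equal(unique(m$pos), 1000L)
})

test_that("mean absolute CCF error shrinks as depth grows", {
  err_at <- function(depth, seed) {
    sim <- simulate_case(sim_preset("null_single_clone", depth = depth,
                                    seed = seed),
                         out_dir = withr::local_tempdir())
    m <- build_ccf_matrix(sim$variants, sim$segments, sim$panel)
    mean(abs(m$ccf_raw - 1))
  }
  errs <- vapply(c(50, 200, 1000), err_at, numeric(1), seed = 21)
  expect_true(errs[2] < errs[1])
  expect_true(errs[3] < errs[2])
})
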