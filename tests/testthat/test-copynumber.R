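test_that("ploidy is the length-weighted mean total copy number", {
  expect_equal(compute_ploidy(seg_tbl(c("chr1", 1, 1e8, 1, 1)))$ploidy, 2)
  expect_false(compute_ploidy(seg_tbl(c("chr1", 1, 1e8, 1, 1)))$wgd)

  p <- compute_ploidy(seg_tbl(c("chr1", 1, 1e8, 2, 2),
                              c("chr2", 1, 5e7, 2, 2)))
  expect_equal(p$ploidy, 4)
  expect_true(p$wgd)

  # 100 Mb at total 3 plus 50 Mb at total 4: (100*3 + 50*4) / 150
  p <- compute_ploidy(seg_tbl(c("chr1", 1, 100e6, 2, 1),
                              c("chr2", 1, 50e6, 2, 2)))
  expect_equal(p$ploidy, (300 + 200) / 150)
  expect_true(p$wgd)

  expect_error(compute_ploidy(seg_tbl()[0, ]), "empty")
})

test_that("the WGD call is a strict ploidy > 3 threshold", {
  # equal lengths at total 4 and total 2 -> ploidy exactly 3, not WGD
  at3 <- seg_tbl(c("chr1", 1, 1e6, 2, 2), c("chr2", 1, 1e6, 1, 1))
  expect_equal(compute_ploidy(at3)$ploidy, 3)
  expect_false(compute_ploidy(at3)$wgd)
  above <- seg_tbl(c("chr1", 1, 1e6 + 2, 2, 2), c("chr2", 1, 1e6, 1, 1))
  expect_true(compute_ploidy(above)$wgd)
})

test_that("ploidy is invariant to splitting segments into equal-state pieces", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 6
    seg <- tibble::tibble(
      sample_id = "S1", chrom = paste0("chr", 1:n),
      start = 1, end = round(runif(n, 1e6, 2e8)),
      n_major = sample(1:4, n, TRUE), n_minor = sample(0:1, n, TRUE))
    cut <- round(seg$end / 3)
    split <- dplyr::bind_rows(
      dplyr::mutate(seg, end = cut),
      dplyr::mutate(seg, start = cut + 1))
    expect_equal(compute_ploidy(split)$ploidy, compute_ploidy(seg)$ploidy)
  }
})

test_that("gene events: LOH+loss, focal amplification, and the null case", {
  genes <- default_gene_table()
  diploid2 <- tibble::tibble(ploidy = 2, wgd = FALSE)

  # RB1 over a 1+0 segment in a diploid sample: LOH and loss
  seg <- seg_tbl(c("chr13", 1, 114000000, 1, 0))
  ev <- call_gene_events(seg, genes[genes$name == "RB1", ], diploid2)
  expect_setequal(ev$kind, c("LOH", "loss"))

  # chrX gene in a male, 1 Mb segment at total 8, sample ploidy 3.8:
  # 8 >= 2 * 3.8 -> focal amplification
  segx <- seg_tbl(c("chrX", 67000000, 68000000, 8, 0))
  ev <- call_gene_events(segx, genes[genes$name == "AR", ],
                         tibble::tibble(ploidy = 3.8, wgd = TRUE),
                         sex = "male")
  expect_equal(ev$kind, "focal_amplification")
  # same state over a 60 Mb segment is not focal
  segw <- seg_tbl(c("chrX", 4e7, 1e8, 8, 0))
  ev <- call_gene_events(segw, genes[genes$name == "AR", ],
                         tibble::tibble(ploidy = 3.8, wgd = TRUE))
  expect_false("focal_amplification" %in% ev$kind)

  # 1+1 in a diploid sample: no event
  ev <- call_gene_events(seg_tbl(c("chr10", 1, 133797422, 1, 1)),
                         genes[genes$name == "PTEN", ], diploid2)
  expect_equal(nrow(ev), 0)

  # uncovered gene: no-call
  ev <- call_gene_events(seg_tbl(c("chr10", 1, 100, 1, 1)),
                         genes[genes$name == "PTEN", ], diploid2)
  expect_equal(ev$kind, "no_call")
})

test_that("male chrX hemizygosity is not reported as LOH or loss", {
  genes <- default_gene_table()
  # baseline male X doubled by WGD: 2+0 in a ploidy-4 genome
  seg <- seg_tbl(c("chrX", 1, 156040895, 2, 0))
  ev <- call_gene_events(seg, genes[genes$name == "AR", ],
                         tibble::tibble(ploidy = 4, wgd = TRUE), sex = "male")
  expect_equal(nrow(ev), 0)
  ev <- call_arm_events(seg, default_arm_table(),
                        tibble::tibble(ploidy = 4, wgd = TRUE), sex = "male")
  expect_false(any(ev$kind %in% c("LOH", "loss")))
})

test_that("arm events: LOH, gain, and the null case", {
  arms <- default_arm_table()
  diploid2 <- tibble::tibble(ploidy = 2, wgd = FALSE)

  ev <- call_arm_events(seg_tbl(c("chr4", 1, 190214555, 2, 0)),
                        arms[arms$name == "4p", ], diploid2)
  expect_true("LOH" %in% ev$kind)

  ev <- call_arm_events(seg_tbl(c("chr3", 1, 198295559, 2, 1)),
                        arms[arms$name == "3p", ], diploid2)
  expect_equal(ev$kind, "gain")

  ev <- call_arm_events(seg_tbl(c("chr3", 1, 198295559, 1, 1)),
                        arms[arms$name == "3p", ], diploid2)
  expect_equal(nrow(ev), 0)

  expect_warning(
    ev <- call_arm_events(seg_tbl(c("chr3", 1, 3e7, 2, 0)),
                          arms[arms$name == "3p", ], diploid2),
    "50%")
  expect_equal(ev$kind, "no_call")
})

test_that("events partition into shared-by-all, subset and private", {
  ev <- tibble::tibble(
    sample_id = c("S1", "S2", "S1"),
    target = c("RB1", "RB1", "TP53"),
    scope = "gene", kind = "LOH")
  cmp <- compare_events_across_samples(ev, c("S1", "S2"))
  expect_equal(cmp$sharing[cmp$target == "RB1"], "all")
  expect_equal(cmp$sharing[cmp$target == "TP53"], "private")

  cmp <- compare_events_across_samples(ev[1:2, ], c("S1", "S2"))
  expect_true(all(cmp$sharing == "all"))

  ev3 <- tibble::tibble(sample_id = c("S2", "S3"), target = "6q",
                        scope = "arm", kind = "gain")
  cmp <- compare_events_across_samples(ev3, c("S1", "S2", "S3"))
  expect_equal(cmp$sharing, "subset")
  expect_equal(cmp$samples, "S2,S3")

  expect_error(compare_events_across_samples(ev, "S1"), "at least 2")
})

test_that("noise-free simulated profiles yield event calls equal to truth", {
  sim <- simulate_case(sim_preset("case1_like", seed = 9),
                       out_dir = withr::local_tempdir())
  ev <- call_events_by_sample(sim$segments, panel = sim$panel)
  amp <- dplyr::filter(ev, target == "AR", kind == "focal_amplification")
  truth_amp <- strsplit(
    sim$truth$events$samples[sim$truth$events$name == "AR_amp"], ",")[[1]]
  expect_setequal(amp$sample_id, truth_amp)

  loh1p <- dplyr::filter(ev, target == "1p", kind == "LOH")
  expect_equal(loh1p$sample_id, "DUCTAL_2015")

  gain6q <- dplyr::filter(ev, target == "6q", kind == "gain")
  expect_equal(gain6q$sample_id, "DUCTAL_2015")
})
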