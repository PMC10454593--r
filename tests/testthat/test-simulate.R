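test_that("observed VAFs concentrate on the model expectation at high depth", {
  samples <- tibble::tibble(sample_id = c("R1", "R2"), purity = c(1, 1),
                            date = c(1, 2))
  clones <- tibble::tibble(clone = "A", parent = NA_character_,
                           n_snvs = 200L, R1 = 1, R2 = 1)
  cfg <- sim_config(samples, clones, depth = 10000, sex = "female", seed = 14)
  sim <- simulate_case(cfg, out_dir = withr::local_tempdir())
  vaf <- sim$variants$alt_count /
    (sim$variants$ref_count + sim$variants$alt_count)
  expect_gte(mean(abs(vaf - 0.5) <= 0.02), 0.99)
})

test_that("configs violating the clone-tree constraints are rejected upfront", {
  samples <- tibble::tibble(sample_id = c("S1", "S2"), purity = c(0.7, 0.7),
                            date = c(1, 2))
  bad_sum <- tibble::tibble(clone = c("A", "B", "C"), parent = c(NA, "A", "A"),
                            n_snvs = c(10L, 10L, 10L),
                            S1 = c(1, 0.6, 0.6), S2 = c(1, 0, 0))
  expect_error(sim_config(samples, bad_sum), "sum rule")

  bad_subset <- tibble::tibble(clone = c("A", "B"), parent = c(NA, "A"),
                               n_snvs = c(10L, 10L),
                               S1 = c(1, 0.5), S2 = c(0, 0.5))
  expect_error(sim_config(samples, bad_subset), "absent")

  expect_error(sim_preset("no_such_preset"), "case1_like")
})

test_that("case1-like preset is whole-genome doubled with a late chrX amplification", {
  cfg <- sim_preset("case1_like", seed = 2)
  sim <- simulate_case(cfg, out_dir = withr::local_tempdir())
  ploidy <- ploidy_by_sample(read_segments(sim$paths[["segments"]]))
  expect_true(all(ploidy$ploidy > 3))
  expect_true(all(ploidy$wgd))
  ar <- sim$truth$events[sim$truth$events$name == "AR_amp", ]
  expect_equal(ar$status, "timed")
  expect_equal(ar$interval_start, 2012)
  expect_equal(ar$interval_end, 2015)
  expect_equal(sum(cfg$clones$n_snvs[cfg$clones$clone == "A"]), 53L)
  expect_equal(sum(cfg$clones$n_snvs[cfg$clones$clone == "B"]), 34L)
})

test_that("case2-like preset shares the 13q trunk and keeps 17p to one branch", {
  sim <- simulate_case(sim_preset("case2_like", seed = 2),
                       out_dir = withr::local_tempdir())
  ev <- sim$truth$events
  expect_equal(ev$samples[ev$name == "13q_LOH"], "ADENO,TNEPC")
  expect_equal(ev$samples[ev$name == "17p_LOH"], "TNEPC")
  expect_equal(nrow(sim$truth$tree), 3)
})

test_that("the null preset is one diploid clone without copy-number events", {
  sim <- simulate_case(sim_preset("null_single_clone", seed = 2),
                       out_dir = withr::local_tempdir())
  expect_null(sim$truth$events)
  expect_false(any(sim$truth$ploidy$wgd))
  expect_equal(nrow(sim$truth$tree), 1)
})

test_that("simulation output is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_case(sim_preset("case1_like", seed = 77), out_dir = d1)
  simulate_case(sim_preset("case1_like", seed = 77), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  d3 <- withr::local_tempdir()
  simulate_case(sim_preset("case1_like", seed = 78), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "variants.vcf")),
                         readLines(file.path(d3, "variants.vcf"))))
})

test_that("truth files satisfy the phylogeny constraints with zero tolerance", {
  for (preset in c("case1_like", "case2_like", "null_single_clone")) {
    sim <- simulate_case(sim_preset(preset, seed = 19),
                         out_dir = withr::local_tempdir())
    cs <- truth_cluster_summary(sim)
    tree <- build_tree(cs, epsilon = 0)
    expect_true(all(tree$nodes$flag == ""), label = preset)
  }
})

test_that("high-depth simulation yields CCFs within 0.02 of the generating truth", {
  sim <- simulate_case(sim_preset("case2_like", depth = 10000, seed = 23),
                       out_dir = withr::local_tempdir())
  m <- build_ccf_matrix(sim$variants, sim$segments, sim$panel)
  truth <- dplyr::left_join(m, sim$truth$assignments, by = "variant_id")
  phi <- sim$truth$clone_ccf
  truth$ccf_true <- phi[cbind(truth$clone, truth$sample_id)]
  expect_lte(mean(abs(truth$ccf_clipped - truth$ccf_true)), 0.02)
  by_clone <- dplyr::summarise(
    dplyr::group_by(truth, .data$clone, .data$sample_id),
    err = abs(mean(.data$ccf_clipped) - .data$ccf_true[1]), .groups = "drop")
  expect_true(all(by_clone$err <= 0.02))
})
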