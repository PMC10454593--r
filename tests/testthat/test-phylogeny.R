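summary_from_centers <- function(centers, sizes = NULL) {
  out <- tibble::tibble(cluster = rownames(centers),
                        size = sizes %||% rep(10L, nrow(centers)))
  for (s in colnames(centers)) out[[paste0("ccf_", s)]] <- centers[, s]
  out
}

test_that("the MRCA is the cluster clonal in every sample", {
  cs <- summary_from_centers(matrix(
    c(1, 1, 1, 1, 0.6, 0, 0, 0), nrow = 2, byrow = TRUE,
    dimnames = list(c("A", "B"), paste0("S", 1:4))))
  expect_equal(as.character(identify_mrca(cs)), "A")

  single <- summary_from_centers(matrix(c(1, 1), 1,
    dimnames = list("A", c("S1", "S2"))))
  expect_equal(as.character(identify_mrca(single)), "A")

  expect_error(identify_mrca(single[0, ]), "empty")
})

test_that("near-clonal ties merge into a single root clone", {
  cs <- summary_from_centers(matrix(
    c(0.95, 0.92, 0.93, 0.97, 0.3, 0), nrow = 3, byrow = TRUE,
    dimnames = list(c("A", "B", "C"), c("S1", "S2"))))
  expect_warning(ids <- identify_mrca(cs), "merged")
  expect_setequal(as.character(ids), c("A", "B"))

  tree <- suppressWarnings(build_tree(cs))
  expect_equal(tree$root, "A+B")
  expect_equal(nrow(tree$nodes), 2)
  expect_equal(tree$nodes$parent[tree$nodes$cluster == "C"], "A+B")
})

test_that("when no cluster is clonal everywhere the best minimum wins, loudly", {
  cs <- summary_from_centers(matrix(
    c(0.8, 0.7, 0.3, 0.6), nrow = 2, byrow = TRUE,
    dimnames = list(c("A", "B"), c("S1", "S2"))))
  expect_warning(id <- identify_mrca(cs), "caution")
  expect_equal(as.character(id), "A")
  expect_false(attr(id, "qualified"))
})

test_that("constraint-satisfying topology is the one constructed", {
  cs <- summary_from_centers(matrix(
    c(1, 1, 0.7, 0, 0, 0.6), nrow = 3, byrow = TRUE,
    dimnames = list(c("A", "B", "C"), c("S1", "S2"))))
  tree <- build_tree(cs)
  expect_equal(tree$root, "A")
  expect_equal(tree$nodes$parent[tree$nodes$cluster == "B"], "A")
  expect_equal(tree$nodes$parent[tree$nodes$cluster == "C"], "A")
  expect_true(all(tree$nodes$flag == ""))
})

test_that("a cluster violating the constraints everywhere is flagged at the root", {
  # attachment order is A, C, B (decreasing total CCF); B then overfills
  # sample 1 under A (0.5 + 1 > 1 + eps) and under C (1 > 0.5 + eps), and
  # so lands at the root flagged
  cs <- summary_from_centers(matrix(
    c(1, 1, 1, 0, 0.5, 0.9), nrow = 3, byrow = TRUE,
    dimnames = list(c("A", "B", "C"), c("S1", "S2"))))
  tree <- build_tree(cs)
  expect_equal(tree$nodes$flag[tree$nodes$cluster == "B"],
               "unplaced-constraint-violation")
  expect_equal(tree$nodes$parent[tree$nodes$cluster == "B"], "A")
  expect_equal(tree$nodes$parent[tree$nodes$cluster == "C"], "A")
})

test_that("built trees always satisfy the sum and subset rules", {
  for (seed in c(3, 17, 29)) {
    sim <- simulate_case(sim_preset("case1_like", seed = seed),
                         out_dir = withr::local_tempdir())
    cs <- truth_cluster_summary(sim)
    tree <- build_tree(cs, epsilon = 0)
    cn <- tree$centers
    for (p in tree$nodes$cluster) {
      kids <- tree$nodes$cluster[!is.na(tree$nodes$parent) &
                                   tree$nodes$parent == p]
      if (length(kids) == 0) next
      expect_true(all(cn[p, ] >= colSums(cn[kids, , drop = FALSE]) - 1e-9))
      for (k in kids) {
        expect_true(all(!tree$presence[k, ] | tree$presence[p, ]))
      }
    }
  }
})

test_that("noise-free truth centers reproduce the simulated topology", {
  sim <- simulate_case(sim_preset("case1_like", seed = 1),
                       out_dir = withr::local_tempdir())
  ev <- call_events_by_sample(sim$segments, panel = sim$panel)
  sharing <- compare_events_across_samples(ev, sim$panel$sample_id)
  tree <- build_tree(truth_cluster_summary(sim), events = sharing,
                     panel = sim$panel, epsilon = 0)
  edges <- with(tree$nodes[!is.na(tree$nodes$parent), ],
                paste(parent, cluster))
  truth_edges <- with(sim$config$clones[!is.na(sim$config$clones$parent), ],
                      paste(parent, clone))
  expect_setequal(edges, truth_edges)

  # truncal events decorate the root, ductal-private ones the ductal clone
  expect_true(all(tree$events$node[tree$events$sharing == "all"] == "A"))
  expect_equal(unique(tree$events$node[tree$events$target == "1p"]), "D")
})

test_that("event timing brackets acquisitions between dated samples", {
  panel <- sample_panel(c("S1", "S2", "S3"), rep(0.7, 3),
                        c(2012, 2015, 2017), "male")
  timed <- time_events(
    tibble::tibble(target = c("AR_amp", "truncal", "flicker"),
                   samples = c("S2,S3", "S1,S2,S3", "S1")),
    panel)
  ar <- timed[timed$target == "AR_amp", ]
  expect_equal(ar$status, "timed")
  expect_equal(ar$interval_start, 2012)
  expect_equal(ar$interval_end, 2015)

  tr <- timed[timed$target == "truncal", ]
  expect_equal(tr$status, "truncal")
  expect_true(is.na(tr$interval_start))
  expect_equal(tr$interval_end, 2012)

  fl <- timed[timed$target == "flicker", ]
  expect_equal(fl$status, "non_persistent")
  expect_true(is.na(fl$interval_end))
})

test_that("same-date sibling samples do not break persistence", {
  panel <- sample_panel(c("NE_2015", "DUCTAL_2015", "NE_2017"), rep(0.7, 3),
                        c(2015, 2015, 2017), "male")
  timed <- time_events(
    tibble::tibble(target = "both_2015_branches", samples = "NE_2015,NE_2017"),
    panel)
  expect_equal(timed$status, "truncal")
})

test_that("clone trees tidy, glance and serialise consistently", {
  cs <- summary_from_centers(matrix(
    c(1, 1, 0.7, 0, 0, 0.6), nrow = 3, byrow = TRUE,
    dimnames = list(c("A", "B", "C"), c("S1", "S2"))),
    sizes = c(50L, 20L, 10L))
  tree <- build_tree(cs)
  td <- tidy(tree)
  expect_equal(nrow(td), 6)
  gl <- glance(tree)
  expect_equal(gl$n_clones, 3L)
  expect_equal(gl$root, "A")

  nwk <- write_newick(tree)
  expect_equal(nwk, "(B:20,C:10)A:50;")
  skip_if_not_installed("ape")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("B", "C"))
  expect_setequal(phy$edge.length, c(20, 10))
})
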