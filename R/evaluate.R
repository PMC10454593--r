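# Scoring a pipeline run against simulator ground truth.

#' Map inferred clusters to true clones by majority membership
#'
#' Each inferred cluster is assigned the simulated clone contributing most
#' of its member variants.
#'
#' @param fit A `dp_cluster` result.
#' @param truth_assignments Tibble `variant_id`, `clone` (from
#'   `simulate_case()$truth$assignments`).
#' @return Tibble `cluster`, `clone`, `n`, `purity` (fraction of the
#'   cluster's variants belonging to the majority clone).
#' @export
map_clusters_to_clones <- function(fit, truth_assignments) {
  joined <- dplyr::inner_join(fit$assignments, truth_assignments,
                              by = "variant_id")
  best <- dplyr::slice_max(
    dplyr::count(joined, .data$cluster, .data$clone),
    .data$n, n = 1, by = "cluster", with_ties = FALSE)
  tot <- dplyr::count(joined, .data$cluster, name = "total")
  out <- dplyr::left_join(best, tot, by = "cluster")
  dplyr::mutate(out, purity = .data$n / .data$total, total = NULL)
}

#' Does an inferred clone tree match the simulated truth?
#'
#' The inferred clusters are mapped to clones with
#' [map_clusters_to_clones()]; the topology counts as recovered only when
#' that mapping is a bijection onto the true clones and the mapped edge set
#' equals the true edge set.
#'
#' @param tree A `clone_tree` from [build_tree()].
#' @param fit The `dp_cluster` result the tree was built from.
#' @param truth The `truth` element of a [simulate_case()] result.
#' @return A list: `topology` (logical), `mrca` (logical: does the inferred
#'   root map to the true root clone), `mapping` (the cluster-to-clone
#'   table).
#' @export
score_against_truth <- function(tree, fit, truth) {
  mapping <- map_clusters_to_clones(fit, truth$assignments)
  true_root <- truth$tree$clone[is.na(truth$tree$parent)]
  # the inferred root may be a merged label "X+Y"; score via its members
  root_clusters <- strsplit(tree$root, "+", fixed = TRUE)[[1]]
  root_clones <- mapping$clone[mapping$cluster %in% root_clusters]
  mrca_ok <- length(root_clones) > 0 && all(root_clones == true_root)

  clones <- sort(truth$tree$clone)
  bijective <- nrow(mapping) == length(clones) &&
    setequal(mapping$clone, clones) &&
    !anyDuplicated(mapping$clone)
  topo_ok <- FALSE
  if (bijective && all(tree$nodes$flag == "")) {
    lookup <- setNames(mapping$clone, mapping$cluster)
    inferred <- tree$nodes[!is.na(tree$nodes$parent), c("parent", "cluster")]
    inferred_edges <- paste(lookup[inferred$parent], lookup[inferred$cluster])
    true_edges <- with(truth$tree[!is.na(truth$tree$parent), ],
                       paste(parent, clone))
    topo_ok <- setequal(inferred_edges, true_edges)
  }
  list(topology = topo_ok, mrca = mrca_ok, mapping = mapping)
}
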