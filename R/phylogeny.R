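# Clone-tree reconstruction from mutation clusters and CNA sharing
# patterns, MRCA identification, and interval timing of events across dated
# samples.
#
# Tree constraints (checked after construction):
#   * sum rule  — in every sample a parent's CCF center must be at least the
#     sum of its children's centers, minus a tolerance epsilon that absorbs
#     CCF estimation noise;
#   * subset rule — a child clone can only be present in samples where its
#     parent is present.
# CNAs take precedence over SNV clusters in the sense that, when several
# attachment points satisfy both constraints equally, the one consistent
# with the CNA sharing partition is preferred, and CNA events decorate the
# branches whose sample-presence pattern they match.

centers_from_summary <- function(cluster_summary) {
  cols <- grep("^ccf_", names(cluster_summary), value = TRUE)
  cols <- setdiff(cols, grep("^ccf_raw|^ccf_clipped", cols, value = TRUE))
  m <- as.matrix(cluster_summary[, cols])
  rownames(m) <- cluster_summary$cluster
  colnames(m) <- sub("^ccf_", "", cols)
  m
}

#' Identify the most recent common ancestor (MRCA) cluster
#'
#' The MRCA is the cluster whose CCF center reaches `mrca_threshold`
#' (default 0.9) in every sample — the mutation cluster carried by
#' essentially all tumor cells of all samples. If several clusters qualify
#' they are indistinguishable at the resolution of the data and should be
#' merged into a single root clone (done by [build_tree()]); all qualifying
#' ids are returned with a warning. If none qualifies, the cluster
#' maximising its minimum per-sample center is returned with a prominent
#' warning.
#'
#' @param cluster_summary Per-cluster table from [summarize_clusters()].
#' @param mrca_threshold Minimum per-sample CCF center (default 0.9).
#' @return Character vector of qualifying cluster ids (usually length 1),
#'   with attribute `qualified` saying whether the threshold was met.
#' @export
identify_mrca <- function(cluster_summary, mrca_threshold = 0.9) {
  if (nrow(cluster_summary) == 0) abort("empty cluster table")
  cn <- centers_from_summary(cluster_summary)
  minc <- apply(cn, 1, min)
  qual <- names(minc)[minc >= mrca_threshold]
  if (length(qual) == 0) {
    warn(paste("NO cluster reaches the MRCA threshold in all samples;",
               "falling back to the cluster with the largest minimum CCF.",
               "Interpret the root with caution."))
    return(structure(names(minc)[which.max(minc)], qualified = FALSE))
  }
  if (length(qual) > 1) {
    warn(sprintf("%d clusters qualify as MRCA (%s); they will be merged into one root clone",
                 length(qual), paste(qual, collapse = ", ")))
  }
  structure(qual, qualified = TRUE)
}

#' Build the clone tree from clusters and CNA sharing patterns
#'
#' Greedy constrained attachment. The root is the MRCA (qualifying clusters
#' merged, size-weighted centers). Remaining clusters, in order of
#' decreasing total CCF, are attached to the deepest existing node that
#' satisfies the subset rule and the sum rule in every sample. When several
#' candidate parents tie at the same depth, the one whose presence pattern
#' matches a CNA-defined branch containing the cluster is preferred (CNA
#' precedence), then lexicographic order. Clusters satisfying the
#' constraints nowhere are attached to the root and flagged
#' `unplaced-constraint-violation`. Truncal CNAs (shared by all samples)
#' decorate the root; subset-shared and private CNAs decorate the node
#' whose presence pattern matches their sample set.
#'
#' @param cluster_summary Per-cluster table from [summarize_clusters()].
#' @param events Event sharing table from
#'   [compare_events_across_samples()], or `NULL`.
#' @param panel Sample panel (carried along for timing/plots), or `NULL`.
#' @param epsilon Sum-rule tolerance (default 0.15).
#' @param presence_threshold CCF center above which a clone is present in a
#'   sample (default 0.10).
#' @param mrca_threshold Passed to [identify_mrca()].
#' @return An object of class `clone_tree`: list with `nodes` (tibble
#'   `cluster`, `parent`, `depth`, `size`, `flag`), `centers`, `presence`,
#'   `events` (with a `node` placement column), `root`, `samples`, `panel`.
#' @export
build_tree <- function(cluster_summary, events = NULL, panel = NULL,
                       epsilon = 0.15, presence_threshold = 0.1,
                       mrca_threshold = 0.9) {
  cn <- centers_from_summary(cluster_summary)
  samples <- colnames(cn)
  sizes <- setNames(cluster_summary$size, cluster_summary$cluster)

  mrca <- identify_mrca(cluster_summary, mrca_threshold)
  if (length(mrca) > 1) {
    w <- sizes[mrca] / sum(sizes[mrca])
    merged <- colSums(cn[mrca, , drop = FALSE] * w)
    root_id <- paste(as.character(mrca), collapse = "+")
    cn <- rbind(cn[!rownames(cn) %in% mrca, , drop = FALSE],
                matrix(merged, 1, dimnames = list(root_id, samples)))
    sizes <- c(sizes[!names(sizes) %in% mrca],
               setNames(sum(sizes[mrca]), root_id))
  } else {
    root_id <- as.character(mrca)
  }

  presence <- cn > presence_threshold
  others <- setdiff(rownames(cn), root_id)
  others <- others[order(-rowSums(cn[others, , drop = FALSE]), others)]

  parent <- setNames(rep(NA_character_, nrow(cn)), rownames(cn))
  depth <- setNames(rep(0L, nrow(cn)), rownames(cn))
  flag <- setNames(rep("", nrow(cn)), rownames(cn))
  placed <- root_id

  cna_sets <- list()
  if (!is.null(events) && nrow(events) > 0) {
    sub <- events[events$sharing %in% c("subset", "private"), ]
    cna_sets <- unique(lapply(strsplit(sub$samples, ","), sort))
  }

  sum_ok <- function(p, child) {
    kids <- names(parent)[!is.na(parent) & parent == p & flag == ""]
    kid_sum <- if (length(kids)) colSums(cn[kids, , drop = FALSE]) else rep(0, length(samples))
    all(cn[p, ] >= kid_sum + cn[child, ] - epsilon)
  }
  subset_ok <- function(p, child) {
    all(!presence[child, ] | presence[p, ])
  }

  for (cl in others) {
    cand <- placed[vapply(placed, function(p)
      subset_ok(p, cl) && sum_ok(p, cl), logical(1))]
    if (length(cand) == 0) {
      parent[cl] <- root_id
      depth[cl] <- 1L
      flag[cl] <- "unplaced-constraint-violation"
    } else {
      d <- depth[cand]
      cand <- cand[d == max(d)]
      if (length(cand) > 1 && length(cna_sets) > 0) {
        child_set <- sort(samples[presence[cl, ]])
        score <- vapply(cand, function(p) {
          pset <- sort(samples[presence[p, ]])
          any(vapply(cna_sets, function(g)
            setequal(g, pset) && all(child_set %in% g), logical(1)))
        }, logical(1))
        if (any(score)) cand <- cand[score]
      }
      parent[cl] <- sort(cand)[1]
      depth[cl] <- depth[parent[cl]] + 1L
    }
    placed <- c(placed, cl)
  }

  nodes <- tibble::tibble(cluster = rownames(cn),
                          parent = unname(parent[rownames(cn)]),
                          depth = unname(depth[rownames(cn)]),
                          size = unname(as.integer(sizes[rownames(cn)])),
                          flag = unname(flag[rownames(cn)]))
  nodes <- dplyr::arrange(nodes, .data$depth, .data$cluster)

  ev <- NULL
  if (!is.null(events) && nrow(events) > 0) {
    ev <- dplyr::mutate(events, node = NA_character_, placement = "")
    for (i in seq_len(nrow(ev))) {
      if (ev$sharing[i] == "all") {
        ev$node[i] <- root_id; ev$placement[i] <- "truncal"
        next
      }
      eset <- sort(strsplit(ev$samples[i], ",")[[1]])
      match_nodes <- nodes$cluster[vapply(nodes$cluster, function(k)
        setequal(samples[presence[k, ]], eset), logical(1))]
      if (length(match_nodes) > 0) {
        dd <- depth[match_nodes]
        ev$node[i] <- sort(match_nodes[dd == min(dd)])[1]
        ev$placement[i] <- "exact"
      } else {
        sup <- nodes$cluster[vapply(nodes$cluster, function(k)
          all(eset %in% samples[presence[k, ]]), logical(1))]
        if (length(sup) > 0) {
          np <- rowSums(presence[sup, , drop = FALSE])
          ev$node[i] <- sort(sup[np == min(np)])[1]
          ev$placement[i] <- "approximate"
        } else {
          ev$node[i] <- root_id; ev$placement[i] <- "unmatched"
        }
      }
    }
  }

  tree <- structure(list(nodes = nodes, centers = cn, presence = presence,
                         events = ev, root = root_id, samples = samples,
                         panel = panel, epsilon = epsilon,
                         presence_threshold = presence_threshold),
                    class = "clone_tree")
  check_tree_constraints(tree)
  tree
}

# Post-construction assertion of the sum and subset rules for all
# non-flagged nodes; a violation here is a programming error.
check_tree_constraints <- function(tree) {
  cn <- tree$centers
  nodes <- tree$nodes
  ok_nodes <- nodes$cluster[nodes$flag == ""]
  for (p in ok_nodes) {
    kids <- nodes$cluster[!is.na(nodes$parent) & nodes$parent == p &
                            nodes$flag == ""]
    if (length(kids) == 0) next
    kid_sum <- colSums(cn[kids, , drop = FALSE])
    if (any(cn[p, ] < kid_sum - tree$epsilon - 1e-9)) {
      abort(sprintf("internal error: sum rule violated at node %s", p))
    }
    for (k in kids) {
      if (any(tree$presence[k, ] & !tree$presence[p, ])) {
        abort(sprintf("internal error: subset rule violated at node %s", k))
      }
    }
  }
  invisible(tree)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("Clone tree: %d clones, root (MRCA) = %s\n",
              nrow(x$nodes), x$root))
  for (i in seq_len(nrow(x$nodes))) {
    nd <- x$nodes[i, ]
    ind <- strrep("  ", nd$depth)
    evs <- if (!is.null(x$events)) {
      e <- x$events[x$events$node == nd$cluster, ]
      if (nrow(e)) paste0(" [", paste(paste0(e$target, ":", e$kind),
                                      collapse = ", "), "]") else ""
    } else ""
    cat(sprintf("%s%s (n=%d)%s%s\n", ind, nd$cluster, nd$size,
                if (nzchar(nd$flag)) paste0(" <", nd$flag, ">") else "", evs))
  }
  invisible(x)
}

#' Time events across dated samples
#'
#' Assuming persistence (an acquired event is never lost along a lineage),
#' an event absent from some early samples and present in all later ones is
#' timed to the interval between the latest sample lacking it and the
#' earliest sample carrying it. An event present in every sample predates
#' the first sample: its interval is (origin, earliest date]. Presence
#' patterns where the event is absent at a date strictly later than a date
#' where it is present violate persistence across these samples (e.g.
#' region-restricted events) and are flagged `non_persistent` with no
#' interval.
#'
#' @param x A tibble with columns `target` and `samples` (comma-joined
#'   carrier sample ids), e.g. from [compare_events_across_samples()], or a
#'   [summarize_clusters()] table (its `presence` column is used).
#' @param panel Sample panel with `sample_id` and `date`.
#' @return Tibble with columns `target`, `status` (`timed`, `truncal`,
#'   `non_persistent`), `interval_start` (date, or `NA` meaning tumor
#'   origin), `interval_end` (date, or `NA` when non-persistent).
#' @examples
#' panel <- sample_panel(c("S1", "S2", "S3"), c(.7, .7, .7),
#'                       c(2012, 2015, 2017), "male")
#' time_events(tibble::tibble(target = "AR_amp", samples = "S2,S3"), panel)
#' @export
time_events <- function(x, panel) {
  if ("presence" %in% names(x) && !"samples" %in% names(x)) {
    x <- dplyr::rename(x, samples = "presence")
    if ("cluster" %in% names(x) && !"target" %in% names(x)) {
      x <- dplyr::rename(x, target = "cluster")
    }
  }
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    carriers <- strsplit(x$samples[i], ",")[[1]]
    pres <- panel$sample_id %in% carriers
    dates <- panel$date
    row <- function(status, start, end)
      tibble::tibble(target = x$target[i], status = status,
                     interval_start = start, interval_end = end)
    if (all(pres)) return(row("truncal", NA, min(dates)))
    if (!any(pres)) return(row("absent", NA, NA))
    first_present <- min(dates[pres])
    if (any(dates[!pres] > first_present)) {
      return(row("non_persistent", NA, NA))
    }
    before <- dates[!pres & dates < first_present]
    if (length(before) == 0) return(row("truncal", NA, first_present))
    row("timed", max(before), first_present)
  })
}

# ---- serialisation ---------------------------------------------------------

tree_to_list <- function(tree) {
  nodes <- lapply(seq_len(nrow(tree$nodes)), function(i) {
    nd <- tree$nodes[i, ]
    list(id = nd$cluster,
         parent = nd$parent,  # NA serialises as JSON null for the root
         size = nd$size, depth = nd$depth, flag = nd$flag,
         ccf = as.list(setNames(round(tree$centers[nd$cluster, ], 6),
                                tree$samples)),
         presence = tree$samples[tree$presence[nd$cluster, ]])
  })
  edges <- tree$nodes[!is.na(tree$nodes$parent), c("parent", "cluster")]
  list(root = tree$root, samples = as.list(tree$samples), nodes = nodes,
       edges = lapply(seq_len(nrow(edges)), function(i)
         list(from = edges$parent[i], to = edges$cluster[i])),
       events = if (is.null(tree$events)) list() else
         lapply(seq_len(nrow(tree$events)), function(i)
           as.list(tree$events[i, ])))
}

#' Render a clone tree as a Newick string
#'
#' Branch lengths are the SNV count of the child cluster; internal nodes
#' are labelled with cluster ids. A single-clone tree renders as
#' `"(A:n);"`.
#'
#' @param tree A `clone_tree`.
#' @return A single Newick string (terminated by `;`).
#' @export
write_newick <- function(tree) {
  nodes <- tree$nodes
  rec <- function(id) {
    kids <- sort(nodes$cluster[!is.na(nodes$parent) & nodes$parent == id])
    lab <- gsub("[();,: ]", "_", id)
    len <- nodes$size[nodes$cluster == id]
    if (length(kids) == 0) return(sprintf("%s:%d", lab, len))
    sprintf("(%s)%s:%d", paste(vapply(kids, rec, character(1)),
                               collapse = ","), lab, len)
  }
  body <- rec(tree$root)
  kids <- nodes$cluster[!is.na(nodes$parent)]
  if (length(kids) == 0) paste0("(", body, ");") else paste0(body, ";")
}

#' Re-read a written tree.json
#'
#' @param path Path to a `tree.json` written by [write_results()].
#' @return A list with `root`, `samples`, `nodes` (tibble), `edges`
#'   (tibble), mirroring the written structure.
#' @export
read_tree_json <- function(path) {
  x <- jsonlite::read_json(path)
  nodes <- purrr::map_dfr(x$nodes, function(nd) {
    p <- nd$parent
    if (is.null(p) || length(p) == 0) p <- NA_character_
    tibble::tibble(cluster = nd$id,
                   parent = as.character(p),
                   size = as.integer(nd$size), depth = as.integer(nd$depth),
                   flag = nd$flag %||% "")
  })
  edges <- purrr::map_dfr(x$edges, ~tibble::tibble(from = .x$from, to = .x$to))
  centers <- do.call(rbind, lapply(x$nodes, function(nd)
    unlist(nd$ccf)[unlist(x$samples)]))
  rownames(centers) <- nodes$cluster
  list(root = x$root, samples = unlist(x$samples), nodes = nodes,
       edges = edges, centers = centers)
}

#' @describeIn build_tree Tidy node-by-sample table.
#' @param x A `clone_tree` object.
#' @param ... Unused.
#' @export
tidy.clone_tree <- function(x, ...) {
  long <- tibble::tibble(
    cluster = rep(rownames(x$centers), each = length(x$samples)),
    sample_id = rep(x$samples, times = nrow(x$centers)),
    ccf_center = as.numeric(t(x$centers)),
    present = as.logical(t(x$presence))
  )
  dplyr::left_join(long, x$nodes, by = "cluster")
}

#' @describeIn build_tree One-row tree summary.
#' @export
glance.clone_tree <- function(x, ...) {
  tibble::tibble(
    n_clones = nrow(x$nodes),
    root = x$root,
    max_depth = max(x$nodes$depth),
    n_unplaced = sum(x$nodes$flag != ""),
    n_events = if (is.null(x$events)) 0L else nrow(x$events)
  )
}
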