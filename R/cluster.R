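# Dirichlet-process mixture clustering of SNVs by their per-sample CCFs.
#
# Reference semantics: a Chinese-restaurant-process prior over partitions
# with a Gamma(1,1) hyperprior on the concentration, binomial emissions on
# the observed alt counts through the purity/copy-number-corrected VAF
# model, cluster CCFs on a uniform grid over [0,1], collapsed Gibbs
# sampling, and a final hard assignment cut from the posterior co-clustering
# matrix. This is a from-scratch implementation whose model is stated fully
# here rather than delegated to an external mixture library.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Cluster SNVs across samples with a Dirichlet-process mixture
#'
#' Groups variants whose cancer cell fractions co-vary across samples into
#' clusters (candidate clones). The sampler works on the observed read
#' counts, not on point CCF estimates: variant `i` in sample `s` contributes
#' `alt ~ Binomial(depth, phi[k,s] * c[i,s])` where `phi[k,s]` is the CCF of
#' cluster `k` in sample `s` (on a grid over \[0,1\], default step 0.01) and
#' `c[i,s]` is the precomputed coefficient
#' `purity * multiplicity / (purity * total_cn + (1-purity) * normal_cn)`.
#' Each sweep reassigns every variant under the Chinese-restaurant prior,
#' resamples cluster CCFs from their grid conditionals, and resamples the
#' concentration under a Gamma(1,1) hyperprior (Escobar–West). The hard
#' clustering is obtained by average-linkage cutting of the posterior
#' co-clustering matrix at dissimilarity 0.5, which damps Monte-Carlo noise
#' relative to reading off the last sweep; clusters smaller than `min_size`
#' are then merged into the cluster with the nearest CCF center.
#'
#' @param ccf_matrix A `ccf_matrix` tibble from [build_ccf_matrix()].
#' @param sweeps Total Gibbs sweeps (default 2000).
#' @param burn_in Sweeps discarded before accumulating the co-clustering
#'   matrix (default 500).
#' @param grid_step CCF grid resolution (default 0.01).
#' @param alpha_init Initial concentration (default 1).
#' @param alpha_prior Shape and rate of the Gamma hyperprior on the
#'   concentration (default `c(1, 1)`).
#' @param min_size Minimum cluster size; smaller clusters are merged into
#'   the nearest center. Default `max(5, ceiling(0.02 * n_variants))`.
#' @param seed Integer seed driving all randomness; identical
#'   (input, configuration, seed) triples give bit-identical results.
#' @return An object of class `dp_cluster`: a list with `assignments`
#'   (tibble `variant_id`, `cluster`), `centers` (cluster x sample matrix of
#'   CCF centers in \[0,1\]), `sizes`, `trace` (tibble `sweep`,
#'   `n_clusters`, `alpha`), `samples`, `seed`, `settings`.
#' @examples
#' sim <- simulate_case(sim_preset("null_single_clone"), out_dir = tempfile())
#' m <- build_ccf_matrix(read_vcf(sim$paths$vcf, sim$panel$sample_id, "NORMAL"),
#'                       read_segments(sim$paths$segments), sim$panel)
#' fit <- dp_cluster(m, sweeps = 200, burn_in = 50, seed = 1)
#' fit$sizes
#' @export
dp_cluster <- function(ccf_matrix, sweeps = 2000, burn_in = 500,
                       grid_step = 0.01, alpha_init = 1,
                       alpha_prior = c(1, 1), min_size = NULL, seed = 1) {
  samples <- unique(ccf_matrix$sample_id)
  vids <- unique(ccf_matrix$variant_id)
  n <- length(vids)
  S <- length(samples)
  if (n < 1) abort("no variants to cluster")

  wide <- function(col) {
    m <- matrix(NA_real_, n, S, dimnames = list(vids, samples))
    m[cbind(match(ccf_matrix$variant_id, vids),
            match(ccf_matrix$sample_id, samples))] <- ccf_matrix[[col]]
    m
  }
  alt <- wide("alt_count")
  depth <- wide("depth")
  if (anyNA(alt) || anyNA(depth)) abort("ccf_matrix is not complete over variants x samples")
  if (all(depth == 0)) abort("all read depths are zero")
  coef <- wide("purity") * wide("multiplicity") /
    (wide("purity") * wide("total_cn") + (1 - wide("purity")) * wide("normal_cn"))

  if (n == 1) {
    warn("single variant: returning one singleton cluster")
    centers <- matrix(pmin(1, alt / pmax(depth, 1) / coef), 1, S,
                      dimnames = list("A", samples))
    return(new_dp_cluster(
      assignments = tibble::tibble(variant_id = vids, cluster = "A"),
      centers = centers, sizes = c(A = 1L),
      trace = tibble::tibble(sweep = integer(), n_clusters = integer(),
                             alpha = numeric()),
      samples = samples, seed = seed,
      settings = list(sweeps = sweeps, burn_in = burn_in,
                      grid_step = grid_step)))
  }

  grid <- seq(0, 1, by = grid_step)
  G <- length(grid)
  # n x S x G log-likelihood table
  L <- array(0, dim = c(n, S, G))
  for (g in seq_len(G)) {
    p <- pmin(grid[g] * coef, 1 - 1e-12)
    L[, , g] <- dbinom(alt, depth, p, log = TRUE)
  }
  L[!is.finite(L)] <- -1e300
  lognew <- vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(S), function(s) logsumexp(L[i, s, ]) - log(G),
               numeric(1)))
  }, numeric(1))

  set.seed(seed)
  res <- dp_gibbs_cpp(as.numeric(L), lognew, n, S, G, sweeps, burn_in,
                      alpha_init, alpha_prior[1], alpha_prior[2])

  P <- res$coclust / res$n_saved
  diag(P) <- 1
  hard <- if (n > 2) {
    hc <- hclust(as.dist(1 - P), method = "average")
    cutree(hc, h = 0.5)
  } else {
    if (P[1, 2] >= 0.5) c(1L, 1L) else c(1L, 2L)
  }

  center_of <- function(members) {
    vapply(seq_len(S), function(s) {
      ll <- if (length(members) == 1) L[members, s, ] else colSums(L[members, s, ])
      w <- exp(ll - max(ll))
      sum(grid * w) / sum(w)
    }, numeric(1))
  }

  if (is.null(min_size)) min_size <- max(5, ceiling(0.02 * n))
  groups <- split(seq_len(n), hard)
  centers <- t(vapply(groups, center_of, numeric(S)))
  # merge undersized clusters into the nearest center (smallest first)
  repeat {
    sizes <- lengths(groups)
    small <- which(sizes < min_size)
    if (length(small) == 0 || length(groups) == 1) break
    k <- small[which.min(sizes[small])]
    d <- sqrt(rowSums((centers - matrix(centers[k, ], nrow(centers), S,
                                        byrow = TRUE))^2))
    d[k] <- Inf
    tgt <- which.min(d)
    groups[[tgt]] <- sort(c(groups[[tgt]], groups[[k]]))
    groups[[k]] <- NULL
    centers <- t(vapply(groups, center_of, numeric(S)))
  }

  # canonical labels: descending total CCF, then size, for stable output
  ord <- order(-rowSums(centers), -lengths(groups),
               vapply(groups, min, integer(1)))
  groups <- groups[ord]
  centers <- centers[ord, , drop = FALSE]
  labels <- cluster_labels(length(groups))
  rownames(centers) <- labels
  colnames(centers) <- samples
  assign <- character(n)
  for (k in seq_along(groups)) assign[groups[[k]]] <- labels[k]

  new_dp_cluster(
    assignments = tibble::tibble(variant_id = vids, cluster = assign),
    centers = pmin(pmax(centers, 0), 1),
    sizes = setNames(lengths(groups), labels),
    trace = tibble::tibble(sweep = seq_len(sweeps),
                           n_clusters = res$trace_k,
                           alpha = res$trace_alpha),
    samples = samples, seed = seed,
    settings = list(sweeps = sweeps, burn_in = burn_in, grid_step = grid_step,
                    min_size = min_size)
  )
}

cluster_labels <- function(k) {
  if (k <= 26) return(LETTERS[seq_len(k)])
  paste0(LETTERS[((seq_len(k) - 1) %/% 26)], LETTERS[((seq_len(k) - 1) %% 26) + 1])
}

new_dp_cluster <- function(assignments, centers, sizes, trace, samples, seed,
                           settings) {
  structure(list(assignments = assignments, centers = centers, sizes = sizes,
                 trace = trace, samples = samples, seed = seed,
                 settings = settings),
            class = "dp_cluster")
}

#' @export
print.dp_cluster <- function(x, ...) {
  cat(sprintf("Dirichlet-process clustering: %d variants, %d clusters, %d samples (seed %s)\n",
              nrow(x$assignments), nrow(x$centers), length(x$samples),
              format(x$seed)))
  print(round(x$centers, 3))
  invisible(x)
}

#' Summarise a clustering into a per-cluster table
#'
#' One row per cluster: size, per-sample CCF center (columns `ccf_<sample>`),
#' the member variant list, and the sample-presence vector (a cluster is
#' present in a sample when its CCF center exceeds `presence_threshold`).
#'
#' @param cluster_result A `dp_cluster` object.
#' @param ccf_matrix Optional `ccf_matrix`; when given, per-sample member
#'   mean CCFs (`mean_ccf_<sample>`) are added alongside the model centers.
#' @param presence_threshold CCF center above which a cluster counts as
#'   present in a sample (default 0.10).
#' @return Tibble with columns `cluster`, `size`, `ccf_<sample>...`,
#'   `presence` (comma-joined present samples), `variants` (list column).
#' @export
summarize_clusters <- function(cluster_result, ccf_matrix = NULL,
                               presence_threshold = 0.1) {
  cn <- cluster_result$centers
  samples <- colnames(cn)
  out <- tibble::tibble(cluster = rownames(cn),
                        size = as.integer(cluster_result$sizes[rownames(cn)]))
  for (s in samples) out[[paste0("ccf_", s)]] <- cn[, s]
  if (!is.null(ccf_matrix)) {
    mm <- dplyr::left_join(ccf_matrix, cluster_result$assignments,
                           by = "variant_id")
    mc <- dplyr::summarise(dplyr::group_by(mm, .data$cluster, .data$sample_id),
                           m = mean(.data$ccf_clipped), .groups = "drop")
    for (s in samples) {
      v <- mc$m[mc$sample_id == s][match(out$cluster,
                                         mc$cluster[mc$sample_id == s])]
      out[[paste0("mean_ccf_", s)]] <- v
    }
  }
  out$presence <- vapply(out$cluster, function(k) {
    paste(samples[cn[k, ] > presence_threshold], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  out$variants <- lapply(out$cluster, function(k) {
    cluster_result$assignments$variant_id[cluster_result$assignments$cluster == k]
  })
  out
}

#' @describeIn dp_cluster Tidy per-cluster-per-sample table (`cluster`,
#'   `sample_id`, `ccf_center`, `size`).
#' @param x A `dp_cluster` object.
#' @param ... Unused.
#' @export
tidy.dp_cluster <- function(x, ...) {
  cn <- x$centers
  tibble::tibble(
    cluster = rep(rownames(cn), each = ncol(cn)),
    sample_id = rep(colnames(cn), times = nrow(cn)),
    ccf_center = as.numeric(t(cn)),
    size = rep(as.integer(x$sizes[rownames(cn)]), each = ncol(cn))
  )
}

#' @describeIn dp_cluster One-row model summary (`n_variants`, `n_clusters`,
#'   `mean_posterior_k`, `mean_alpha`, `seed`).
#' @export
glance.dp_cluster <- function(x, ...) {
  post <- x$trace[x$trace$sweep > x$settings$burn_in, ]
  tibble::tibble(
    n_variants = nrow(x$assignments),
    n_clusters = nrow(x$centers),
    mean_posterior_k = if (nrow(post)) mean(post$n_clusters) else NA_real_,
    mean_alpha = if (nrow(post)) mean(post$alpha) else NA_real_,
    seed = x$seed
  )
}
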