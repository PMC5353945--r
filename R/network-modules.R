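#' Seeded weighted co-expression network construction
#'
#' Each pathology-correlated seed transcript recruits its top co-expression
#' neighborhood (by signed Pearson correlation); the union of neighborhoods
#' forms one network, which is soft-thresholded, converted to topological
#' overlap and clustered into modules.
#'
#' @name network-modules
NULL

#' Build the seeded network from top co-expression neighborhoods
#'
#' For each seed, all other transcripts are ranked by signed Pearson
#' correlation (descending; co-expression, not anti-correlation) and the top
#' `ceiling(fraction * (N - 1))` are kept. Ties in correlation are broken by
#' transcript identifier so the network is reproducible. Network nodes are
#' the union of all neighborhoods and the seeds themselves.
#'
#' @param study An [expression_study()].
#' @param seeds Character vector of seed transcript identifiers.
#' @param fraction Neighborhood size as a fraction of the other transcripts
#'   (default 0.01, i.e. the top 1 percent).
#' @return A `pm_seeded_network`: `node_ids`, `seed_ids` and the
#'   nodes-by-samples `expr` submatrix.
#' @export
seed_neighborhoods <- function(study, seeds, fraction = 0.01) {
  stopifnot(inherits(study, "expression_study"),
            length(seeds) > 0, fraction > 0, fraction <= 1)
  missing <- setdiff(seeds, rownames(study$expr))
  if (length(missing)) {
    abort(paste0("seeds not in study: ", paste(missing, collapse = ", ")),
          class = "pathmod_missing_seeds")
  }
  n <- nrow(study$expr)
  keep <- ceiling(fraction * (n - 1))
  cors <- suppressWarnings(cor(t(study$expr[seeds, , drop = FALSE]),
                               t(study$expr)))
  neighbors <- unlist(lapply(seeds, function(s) {
    r <- cors[s, ]
    r <- r[setdiff(names(r), s)]
    r[is.na(r)] <- -Inf
    names(r)[order(-r, names(r))[seq_len(keep)]]
  }))
  nodes <- sort(unique(c(seeds, neighbors)))
  structure(list(node_ids = nodes, seed_ids = sort(unique(seeds)),
                 expr = study$expr[nodes, , drop = FALSE]),
            class = "pm_seeded_network")
}

#' @export
print.pm_seeded_network <- function(x, ...) {
  cat(sprintf("<pm_seeded_network> %d nodes (%d seeds) x %d samples\n",
              length(x$node_ids), length(x$seed_ids), ncol(x$expr)))
  invisible(x)
}

network_cor <- function(net) {
  cc <- if (inherits(net, "pm_seeded_network")) cor(t(net$expr)) else as.matrix(net)
  if (any(is.na(cc))) {
    abort("degenerate correlations in network (constant node?)",
          class = "pathmod_degenerate_input")
  }
  cc
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed
#' and the connectivity distribution is tested for scale-free shape: the
#' squared correlation between log10 frequency and log10 connectivity over
#' the occupied connectivity bins. The chosen power is the smallest one
#' reaching `r2_target`; if none does, the power with the best fit is
#' returned with a warning.
#'
#' Any network looks scale-free once raised to a high enough power (the few
#' largest correlations dominate), so candidate powers that over-sparsify
#' the network — mean connectivity below `min_mean_connectivity` — are not
#' eligible.
#'
#' @param net A `pm_seeded_network` (at least 30 nodes) or a correlation
#'   matrix.
#' @param powers Candidate integer powers.
#' @param r2_target Scale-free fit target (default 0.8).
#' @param n_bins Connectivity histogram bins for the fit (default 10).
#' @param min_mean_connectivity Sparsity guard (default 2 connections per
#'   node on average).
#' @return A tibble (`power`, `scale_free_r2`, `mean_connectivity`,
#'   `eligible`) with attributes `chosen_power` and `reached_target`.
#' @export
select_soft_power <- function(net, powers = 1:20, r2_target = 0.8,
                              n_bins = 10, min_mean_connectivity = 2) {
  cc <- network_cor(net)
  if (nrow(cc) < 30) {
    abort("need at least 30 nodes for a meaningful scale-free fit",
          class = "pathmod_insufficient_data")
  }
  a0 <- abs(cc); diag(a0) <- 0
  scan <- map_df(powers, function(beta) {
    a <- a0^beta
    k <- rowSums(a)
    tibble(power = beta, scale_free_r2 = scale_free_fit(k, n_bins),
           mean_connectivity = mean(k))
  })
  scan$eligible <- scan$mean_connectivity >= min_mean_connectivity
  if (!any(scan$eligible)) scan$eligible <- TRUE
  r2 <- ifelse(scan$eligible, scan$scale_free_r2, -Inf)
  hit <- which(scan$eligible & scan$scale_free_r2 >= r2_target)
  if (length(hit)) {
    chosen <- scan$power[hit[1]]
    reached <- TRUE
  } else {
    chosen <- scan$power[which.max(r2)]
    reached <- FALSE
    warn(sprintf(
      "no eligible power reaches scale-free R^2 >= %.2f; using power %d (R^2 = %.2f)",
      r2_target, chosen, max(r2)))
  }
  structure(scan, chosen_power = chosen, reached_target = reached,
            r2_target = r2_target)
}

# squared log-log correlation of the connectivity histogram; a fit over
# fewer than 8 occupied bins is too degenerate to witness scale-free shape
# and scores 0
scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(k) < 3) return(0)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  centre <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0 & centre > 0
  if (sum(ok) < 8) return(0)
  suppressWarnings(cor(log10(freq[ok]), log10(centre[ok]))^2)
}

#' Topological overlap similarity
#'
#' Converts an unsigned weighted adjacency `a_ij = |cor_ij|^beta` (with zero
#' diagonal) into the topological overlap measure
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' a neighborhood-sharing similarity in \[0, 1\] with unit diagonal. Nodes
#' with identical profiles reach overlap 1.
#'
#' @inheritParams select_soft_power
#' @param beta Integer soft-threshold power (>= 1).
#' @return Symmetric nodes-by-nodes similarity matrix.
#' @export
topological_overlap <- function(net, beta) {
  stopifnot(beta >= 1)
  cc <- network_cor(net)
  a <- abs(cc)^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  tom
}

#' Detect modules by average-linkage clustering of topological overlap
#'
#' Clusters nodes on dissimilarity `1 - TOM` by average-linkage hierarchical
#' clustering and applies a static cut at the configured quantile of the
#' merge heights (default 0.9). The quantile adapts the cut to the overlap
#' scale set by the soft-threshold power: tight modules complete their
#' subtrees well below it while unstructured nodes only merge near the root
#' and stay unclustered. An absolute dissimilarity cut is available through
#' `cut_height`. Clusters smaller than `min_module_size` are left
#' unassigned (module 0); surviving clusters are numbered 1..M by
#' decreasing size.
#'
#' @param tom Square symmetric similarity matrix with named rows.
#' @param min_module_size Smallest cluster kept as a module (default 30).
#' @param cut_height_quantile Quantile of merge heights for the static cut
#'   (default 0.9).
#' @param cut_height Optional absolute dissimilarity overriding the
#'   quantile cut.
#' @return A `pm_partition` tibble: `transcript_id`, `module` (0 =
#'   unassigned), `is_seed` (filled by [filter_seeded_modules()]).
#' @export
detect_modules <- function(tom, min_module_size = 30,
                           cut_height_quantile = 0.9, cut_height = NULL) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  ids <- rownames(tom) %||% as.character(seq_len(nrow(tom)))
  if (nrow(tom) < min_module_size) {
    warn("fewer nodes than min_module_size; all nodes unassigned")
    return(new_partition(ids, rep(0L, length(ids))))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  cut_h <- cut_height %||% unname(quantile(hc$height, cut_height_quantile))
  raw <- cutree(hc, h = cut_h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  module <- rep(0L, length(raw))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) module[raw == keep[i]] <- i
  }
  new_partition(ids, module, cut_height = cut_h)
}

new_partition <- function(ids, module, is_seed = rep(NA, length(ids)),
                          ...) {
  out <- tibble(transcript_id = ids, module = as.integer(module),
                is_seed = is_seed)
  structure(out, class = c("pm_partition", class(out)), ...)
}

#' Module sizes of a partition
#'
#' @param partition A `pm_partition`.
#' @return Tibble of `module`, `size` for assigned modules.
#' @export
module_sizes <- function(partition) {
  partition |>
    filter(.data$module > 0) |>
    dplyr::count(.data$module, name = "size")
}

#' Keep only modules containing at least one seed
#'
#' Modules without any pathology-correlated seed transcript are discarded:
#' their nodes move to the unassigned pool while surviving modules retain
#' their numbers.
#'
#' @param partition A `pm_partition`.
#' @param seeds Character vector of seed transcript identifiers.
#' @return A `pm_partition` with `is_seed` filled and attribute
#'   `seeded_modules`.
#' @export
filter_seeded_modules <- function(partition, seeds) {
  is_seed <- partition$transcript_id %in% seeds
  seeded <- sort(unique(partition$module[is_seed & partition$module > 0]))
  if (length(seeded) == 0) {
    warn("no module contains a seed; all nodes unassigned")
  }
  module <- ifelse(partition$module %in% seeded, partition$module, 0L)
  new_partition(partition$transcript_id, module, is_seed,
                seeded_modules = seeded)
}

#' Gene sets of the modules in a partition
#'
#' Collapses each assigned module's transcripts to genes via the study's
#' gene map.
#'
#' @param partition A `pm_partition`.
#' @param study The [expression_study()] the partition was derived from.
#' @return Named list (`"M1"`, `"M2"`, ...) of [gene_set()]s.
#' @export
module_gene_sets <- function(partition, study) {
  mods <- sort(unique(partition$module[partition$module > 0]))
  if (length(mods) == 0) return(list())
  setNames(
    lapply(mods, function(m) {
      tx <- partition$transcript_id[partition$module == m]
      gene_set(study$gene_map$gene[study$gene_map$transcript_id %in% tx],
               paste0("M", m))
    }),
    paste0("M", mods)
  )
}
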