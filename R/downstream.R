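#' Matrix of posterior-mean OD-delta trajectories for one condition
#'
#' @param trajectories A list of `odelta_trajectory` objects for one
#'   condition (one per strain), or a tidy tibble with columns `strain`,
#'   `time`, `mean`.
#' @return A numeric matrix, strains in rows (rownames), grid times in
#'   columns.
#' @export
trajectory_matrix <- function(trajectories) {
  if (is.data.frame(trajectories)) {
    tb <- tibble::as_tibble(trajectories)
    wide <- tidyr::pivot_wider(tb[, c("strain", "time", "mean")],
                               names_from = "time", values_from = "mean")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$strain
  } else {
    strains <- vapply(trajectories, function(t) attr(t, "strain"), "")
    m <- do.call(rbind, lapply(trajectories, function(t) t$mean))
    rownames(m) <- strains
    colnames(m) <- trajectories[[1]]$time
  }
  if (anyNA(m)) abort("trajectory matrix has missing cells",
                      class = "phenogp_validation_error")
  m
}

#' Hierarchical clustering of phenotype trajectories
#'
#' Agglomerative clustering of strains by their posterior-mean OD-delta
#' trajectories under one condition. Deterministic for identical inputs.
#'
#' @param m A [trajectory_matrix()].
#' @param distance `"euclidean"`, `"manhattan"`, `"maximum"`, or
#'   `"pearson"` (one minus the Pearson correlation of trajectories).
#' @param linkage An `stats::hclust` method (default `"complete"`).
#' @param height Cut height for flat clusters; `NULL` returns the tree with
#'   each strain in its own cluster label from a cut at height 0.
#' @return A list of class `trajectory_clustering` with elements `tree`
#'   (an `hclust`) and `clusters` (tibble `strain`, `cluster`).
#' @export
cluster_trajectories <- function(m, distance = "euclidean",
                                 linkage = "complete", height = NULL) {
  if (!is.matrix(m) || nrow(m) < 2) {
    abort("need a trajectory matrix with >= 2 strains",
          class = "phenogp_domain_error")
  }
  d <- switch(distance,
    euclidean = dist(m, method = "euclidean"),
    manhattan = dist(m, method = "manhattan"),
    maximum   = dist(m, method = "maximum"),
    pearson   = stats::as.dist(1 - cor(t(m))),
    abort(paste0("unknown distance: ", distance),
          class = "phenogp_domain_error"))
  tree <- tryCatch(hclust(d, method = linkage),
                   error = function(e) abort(
                     paste0("unknown linkage: ", linkage),
                     class = "phenogp_domain_error"))
  labels <- if (is.null(height)) cutree(tree, h = 0) else
    cutree(tree, h = height)
  structure(list(tree = tree,
                 clusters = tibble::tibble(strain = rownames(m),
                                           cluster = unname(labels))),
            class = "trajectory_clustering")
}

#' @export
print.trajectory_clustering <- function(x, ...) {
  cat(sprintf("<trajectory_clustering> %d strains, %d clusters\n",
              nrow(x$clusters), dplyr::n_distinct(x$clusters$cluster)))
  invisible(x)
}

#' Enrichment of strong phenotype correlations around a focal strain
#'
#' Tests whether a designated member set (e.g. the knockouts of genes a
#' focal regulator controls) is over-represented among the strains whose
#' OD-delta trajectories correlate strongly (rho >= threshold) with the
#' focal strain's, against all other strains, by the upper-tail
#' hypergeometric test.
#'
#' @param m A [trajectory_matrix()] containing the focal strain.
#' @param focal Focal strain label.
#' @param members Character vector of member strains (must not include
#'   `focal`).
#' @param rho_threshold Correlation threshold (default 0.4).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A [hypergeom_overlap()] result tibble with the per-strain
#'   correlations in `attr(, "correlations")`.
#' @export
correlation_enrichment <- function(m, focal, members, rho_threshold = 0.4,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!focal %in% rownames(m)) {
    abort(paste0("focal strain not in matrix: ", focal),
          class = "phenogp_domain_error")
  }
  if (focal %in% members) {
    abort("focal strain must not be in the member set",
          class = "phenogp_domain_error")
  }
  missing_m <- setdiff(members, rownames(m))
  if (length(missing_m) > 0) {
    abort(paste0("member strain(s) not in matrix: ",
                 paste(missing_m, collapse = ", ")),
          class = "phenogp_domain_error")
  }
  others <- setdiff(rownames(m), focal)
  rho <- setNames(
    vapply(others, function(s) cor(m[focal, ], m[s, ], method = method),
           numeric(1)),
    others)
  hits <- names(rho)[rho >= rho_threshold]
  out <- hypergeom_overlap(k = length(intersect(hits, members)),
                           K = length(members),
                           n = length(hits),
                           N = length(others))
  attr(out, "correlations") <- tibble::tibble(strain = others,
                                              rho = unname(rho),
                                              member = others %in% members)
  out
}

#' Classify mutants into phenotype classes across conditions
#'
#' The decision rule, applied to the significance calls over every modeled
#' condition: a mutant significant under the standard condition and at
#' least one stress condition is `"growth & stress"`; otherwise one
#' significant under two or more stress conditions is `"cross-stress"`;
#' otherwise one significant under exactly one condition is
#' `"stress-specific"`; else `"none"`. All conditions other than the
#' declared standard count as stress.
#'
#' @param calls A tibble with columns `strain`, `condition`, `significant`
#'   covering every strain x condition pair (e.g. from
#'   [phenotype_summaries()]).
#' @param standard Label of the standard condition.
#' @return A tibble `strain`, `class`, `n_significant`,
#'   `supporting_conditions` (comma-collapsed).
#' @export
classify_phenotypes <- function(calls, standard = "standard") {
  calls <- tibble::as_tibble(calls)
  need <- c("strain", "condition", "significant")
  if (!all(need %in% names(calls))) {
    abort(paste0("calls must have columns: ", paste(need, collapse = ", ")),
          class = "phenogp_schema_error")
  }
  conds <- sort(unique(calls$condition))
  full <- tidyr::expand_grid(strain = unique(calls$strain), condition = conds)
  missing_pairs <- dplyr::anti_join(full, calls,
                                    by = c("strain", "condition"))
  if (nrow(missing_pairs) > 0) {
    abort(paste0("calls are missing ", nrow(missing_pairs),
                 " strain x condition pair(s), e.g. ",
                 missing_pairs$strain[1], " x ", missing_pairs$condition[1]),
          class = "phenogp_validation_error")
  }
  calls |>
    dplyr::group_by(strain) |>
    dplyr::summarise(
      n_significant = sum(significant),
      sig_standard = any(significant & condition == standard),
      n_sig_stress = sum(significant & condition != standard),
      supporting_conditions = paste(sort(condition[significant]),
                                    collapse = ","),
      .groups = "drop") |>
    dplyr::mutate(class = dplyr::case_when(
      sig_standard & n_sig_stress >= 1 ~ "growth & stress",
      n_sig_stress >= 2 ~ "cross-stress",
      n_significant == 1 ~ "stress-specific",
      TRUE ~ "none")) |>
    dplyr::select("strain", "class", "n_significant",
                  "supporting_conditions")
}

#' Bipartite strain-condition phenotype network
#'
#' Builds an igraph bipartite network with strain and condition nodes and
#' one edge per significant strain x condition call. Edge `weight` is the
#' posterior-median magnitude, edge `sign` the sign of the extremal
#' posterior-mean OD-delta value (+1 faster, -1 slower growth), and strain
#' nodes carry their phenotype `class`.
#'
#' @param summaries A [phenotype_summaries()] tibble (significance already
#'   reflecting any cutoff).
#' @param classification A [classify_phenotypes()] tibble.
#' @return An `igraph` graph.
#' @export
build_phenotype_network <- function(summaries, classification) {
  summaries <- tibble::as_tibble(summaries)
  sig <- summaries[summaries$significant, , drop = FALSE]
  strains <- unique(summaries$strain)
  conds <- unique(summaries$condition)
  verts <- tibble::tibble(
    name = c(strains, conds),
    type = c(rep(FALSE, length(strains)), rep(TRUE, length(conds))),
    kind = c(rep("strain", length(strains)), rep("condition", length(conds))),
    class = c(classification$class[match(strains, classification$strain)],
              rep(NA_character_, length(conds))))
  edges <- tibble::tibble(
    from = sig$strain,
    to = sig$condition,
    weight = sig$norm_median,
    sign = sig$extremal_sign)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Export a phenotype network
#'
#' GraphML keeps all node/edge attributes (`kind`, `class`, `weight`,
#' `sign`); SIF writes one `strain <faster|slower> condition` line per edge
#' for simple graph viewers.
#'
#' @param graph An igraph graph from [build_phenotype_network()].
#' @param path Output path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    rel <- ifelse(el$sign >= 0, "faster", "slower")
    writeLines(paste(el$from, rel, el$to), path)
  }
  invisible(path)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least `k` marked items when drawing `n`
#' items without replacement from a universe of `N` containing `K` marked
#' items: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed overlap.
#' @param K Marked-set size.
#' @param n Draw size.
#' @param N Universe size.
#' @return A `geneset_overlap` one-row tibble `(k, K, n, N, p)`.
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals < 0) || any(vals != round(vals))) {
    abort("k, K, n, N must be nonnegative integers",
          class = "phenogp_domain_error")
  }
  if (K > N || n > N || k > min(K, n)) {
    abort(sprintf(
      "inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N (got k=%d, K=%d, n=%d, N=%d)",
      k, K, n, N),
      class = "phenogp_domain_error")
  }
  p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(tibble::tibble(k = as.integer(k), K = as.integer(K),
                           n = as.integer(n), N = as.integer(N), p = p),
            class = c("geneset_overlap", class(tibble::tibble())))
}

#' Per-category hypergeometric enrichment of a gene set
#'
#' One upper-tail test per functional category (e.g. arCOG): is the
#' category over-represented in `genes` relative to the universe? Every
#' category with at least one member in the universe is tested (a category
#' disjoint from `genes` simply gets p = 1). The universe is a required,
#' explicit argument; raw p-values are always reported, with
#' Benjamini-Hochberg adjusted values in a separate column when requested.
#'
#' @param genes Character vector of gene IDs (must be a subset of
#'   `universe`).
#' @param categories Two-column data frame (`gene`, `category`) or a named
#'   character vector `gene -> category`; every categorized gene must be in
#'   the universe.
#' @param universe Character vector of all gene IDs under consideration.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per category: `category`, `k`, `K`, `n`,
#'   `N`, `p` (and `p_adj` when `adjust = "BH"`), sorted by `p`. Empty for
#'   an empty gene set.
#' @export
category_enrichment <- function(genes, categories, universe,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.data.frame(categories)) {
    cat_map <- setNames(as.character(categories[[2]]),
                        as.character(categories[[1]]))
  } else {
    cat_map <- categories
  }
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  if (length(setdiff(genes, universe)) > 0) {
    abort(paste0("gene(s) outside the universe: ",
                 paste(head(setdiff(genes, universe), 5), collapse = ", ")),
          class = "phenogp_domain_error")
  }
  if (length(setdiff(names(cat_map), universe)) > 0) {
    abort(paste0("categorized gene(s) outside the universe: ",
                 paste(head(setdiff(names(cat_map), universe), 5),
                       collapse = ", ")),
          class = "phenogp_domain_error")
  }
  if (length(genes) == 0) {
    return(tibble::tibble(category = character(0), k = integer(0),
                          K = integer(0), n = integer(0), N = integer(0),
                          p = numeric(0)))
  }
  cats <- sort(unique(unname(cat_map)))
  out <- purrr::map_dfr(cats, function(cc) {
    members <- names(cat_map)[cat_map == cc]
    ov <- hypergeom_overlap(k = length(intersect(genes, members)),
                            K = length(members),
                            n = length(genes),
                            N = length(universe))
    dplyr::bind_cols(tibble::tibble(category = cc), tibble::as_tibble(ov))
  })
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$category), , drop = FALSE]
}
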