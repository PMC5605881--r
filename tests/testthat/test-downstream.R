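toy_matrix <- function() {
  tgrid <- seq(4, 20, by = 1)
  base <- sin(tgrid / 3)
  m <- rbind(a = base, b = base, c = 5 + cos(tgrid / 2))
  m
}

test_that("hierarchical clustering groups identical trajectories first", {
  m <- toy_matrix()
  cl <- cluster_trajectories(m, height = 1)
  expect_identical(cl$tree$merge[1, ], c(-1L, -2L))  # a and b merge first
  expect_identical(cl$clusters$cluster[1], cl$clusters$cluster[2])
  expect_false(cl$clusters$cluster[1] == cl$clusters$cluster[3])

  # k well-separated groups are recovered exactly at a suitable cut
  set.seed(3)
  tgrid <- seq(4, 20, by = 1)
  groups <- purrr::map(1:3, function(k) {
    center <- 10 * k + 0 * tgrid
    do.call(rbind, purrr::map(1:4, function(i)
      center + rnorm(length(tgrid), sd = 0.05)))
  })
  big <- do.call(rbind, groups)
  rownames(big) <- sprintf("s%02d", 1:12)
  cl3 <- cluster_trajectories(big, height = 10)
  expect_equal(dplyr::n_distinct(cl3$clusters$cluster), 3)
  expect_equal(unname(vapply(split(cl3$clusters$strain,
                                   cl3$clusters$cluster), length, 0L)),
               c(4L, 4L, 4L))

  expect_error(cluster_trajectories(m[1, , drop = FALSE]),
               class = "phenogp_domain_error")
  expect_error(cluster_trajectories(m, distance = "mahalanobis"),
               class = "phenogp_domain_error")
  # determinism
  expect_identical(cluster_trajectories(m, height = 1),
                   cluster_trajectories(m, height = 1))
})

test_that("trajectory matrices build from tidy tibbles and trajectory lists", {
  tb <- tidyr::expand_grid(strain = c("a", "b"), time = 1:5) |>
    dplyr::mutate(mean = as.numeric(seq_len(10)))
  m <- trajectory_matrix(tb)
  expect_equal(dim(m), c(2, 5))
  expect_identical(rownames(m), c("a", "b"))

  trajs <- list(
    phenogp:::new_odelta_trajectory(matrix(1, 2, 5), 1:5, "x", "c", "p"),
    phenogp:::new_odelta_trajectory(matrix(2, 2, 5), 1:5, "y", "c", "p"))
  m2 <- trajectory_matrix(trajs)
  expect_identical(rownames(m2), c("x", "y"))
  expect_true(all(m2["y", ] == 2))
})

test_that("correlation enrichment counts members among strongly correlated strains", {
  tgrid <- seq(4, 20, by = 1)
  base <- sin(tgrid / 3)
  m <- rbind(focal = base,
             m1 = base * 2 + 1,       # rho = 1, member
             m2 = base + 0.01 * cos(tgrid),  # rho ~ 1, member
             o1 = -base,              # anti-correlated
             o2 = -2 * base + 3)
  ov <- correlation_enrichment(m, "focal", members = c("m1", "m2"))
  expect_equal(ov$k, 2); expect_equal(ov$K, 2)
  expect_equal(ov$n, 2); expect_equal(ov$N, 4)
  # all hits are members: p is the minimal hypergeometric tail
  expect_equal(ov$p, hyper_tail_enum(2, 2, 2, 4), tolerance = 1e-12)

  # unattainable threshold empties the tail
  ov2 <- correlation_enrichment(m, "focal", members = c("m1", "m2"),
                                rho_threshold = 1.1)
  expect_equal(ov2$k, 0)
  expect_equal(ov2$p, 1)

  expect_error(correlation_enrichment(m, "focal", members = c("focal", "m1")),
               class = "phenogp_domain_error")

  # correlation is invariant to per-strain affine rescaling
  m_scaled <- m
  m_scaled["m1", ] <- 7 * m["m1", ] - 2
  ov3 <- correlation_enrichment(m_scaled, "focal", members = c("m1", "m2"))
  expect_equal(ov3$p, ov$p)
})

test_that("phenotype classification follows the decision rule and partitions", {
  conds <- c("standard", "low_salt", "paraquat", "peroxide")
  calls <- tidyr::expand_grid(strain = c("s1", "s2", "s3", "s4"),
                              condition = conds) |>
    dplyr::mutate(significant = dplyr::case_when(
      strain == "s1" & condition %in% c("paraquat", "peroxide") ~ TRUE,
      strain == "s2" & condition %in% c("standard", "low_salt") ~ TRUE,
      strain == "s3" & condition == "peroxide" ~ TRUE,
      TRUE ~ FALSE))
  cls <- classify_phenotypes(calls, standard = "standard")
  got <- setNames(cls$class, cls$strain)
  expect_identical(got[["s1"]], "cross-stress")
  expect_identical(got[["s2"]], "growth & stress")
  expect_identical(got[["s3"]], "stress-specific")
  expect_identical(got[["s4"]], "none")
  # partition: one class per strain
  expect_equal(nrow(cls), 4)

  expect_error(classify_phenotypes(calls[-1, ], standard = "standard"),
               class = "phenogp_validation_error")
})

test_that("the phenotype network has one signed, weighted edge per significant call", {
  summaries <- tibble::tibble(
    strain = c("s1", "s1", "s2"),
    condition = c("peroxide", "standard", "peroxide"),
    significant = c(TRUE, FALSE, TRUE),
    norm_median = c(0.9, 0.1, 2),
    extremal_sign = c(-1, 1, 1))
  cls <- tibble::tibble(strain = c("s1", "s2"),
                        class = c("stress-specific", "stress-specific"))
  g <- build_phenotype_network(summaries, cls)
  expect_equal(igraph::ecount(g), 2)
  el <- igraph::as_data_frame(g, "edges")
  e1 <- el[el$from == "s1", ]
  expect_equal(e1$weight, 0.9)
  expect_equal(e1$sign, -1)
  expect_true(igraph::bipartite_mapping(g)$res)

  # no significant calls: empty edge set, nodes retained
  g0 <- build_phenotype_network(dplyr::mutate(summaries,
                                              significant = FALSE), cls)
  expect_equal(igraph::ecount(g0), 0)
  expect_gt(igraph::vcount(g0), 0)

  # exports
  p1 <- withr::local_tempfile(fileext = ".graphml")
  p2 <- withr::local_tempfile(fileext = ".sif")
  write_network(g, p1, "graphml")
  g_back <- igraph::read_graph(p1, format = "graphml")
  expect_equal(igraph::ecount(g_back), 2)
  write_network(g, p2, "sif")
  expect_identical(readLines(p2),
                   c("s1 slower peroxide", "s2 faster peroxide"))
})

test_that("hypergeometric tail matches exhaustive enumeration for N <= 12", {
  for (N in c(5, 8, 12)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:min(K, n)) {
          p_pkg <- hypergeom_overlap(k, K, n, N)$p
          p_enum <- hyper_tail_enum(k, K, n, N)
          expect_equal(p_pkg, p_enum, tolerance = 1e-12)
        }
      }
    }
  }
  expect_equal(hypergeom_overlap(2, 4, 3, 10)$p, 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_overlap(0, 4, 3, 10)$p, 1)
  # k = n = K <= N closed form C(K, n) / C(N, n)
  expect_equal(hypergeom_overlap(3, 3, 3, 9)$p,
               choose(3, 3) / choose(9, 3), tolerance = 1e-12)
  expect_error(hypergeom_overlap(4, 3, 3, 9),
               class = "phenogp_domain_error")
  expect_error(hypergeom_overlap(1, 5, 3, 4),
               class = "phenogp_domain_error")
})

test_that("category enrichment tests every category against the universe", {
  universe <- sprintf("g%02d", 1:20)
  cats <- tibble::tibble(
    gene = universe,
    category = rep(c("metabolism", "transport", "stress", "unknown"),
                   each = 5))
  # all members of one category: that category is the clear minimum
  res <- category_enrichment(universe[1:5], cats, universe)
  expect_identical(res$category[1], "metabolism")
  expect_lt(res$p[1], min(res$p[-1]))
  # disjoint category: p = 1
  expect_equal(res$p[res$category == "transport"], 1)

  expect_identical(nrow(category_enrichment(character(0), cats, universe)),
                   0L)
  expect_error(category_enrichment("not_a_gene", cats, universe),
               class = "phenogp_domain_error")

  res_bh <- category_enrichment(universe[1:5], cats, universe,
                                adjust = "BH")
  expect_true("p_adj" %in% names(res_bh))
  expect_true(all(res_bh$p_adj >= res_bh$p - 1e-15))
})
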