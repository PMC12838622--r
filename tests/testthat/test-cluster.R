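test_that("pointwise t map matches the per-cell pooled-t oracle", {
  set.seed(61)
  n1 <- 8; n2 <- 6; H <- 5; W <- 7
  maps <- array(rnorm((n1 + n2) * H * W), c(n1 + n2, H, W))
  maps[(n1 + 1):(n1 + n2), 2, 3] <- maps[(n1 + 1):(n1 + n2), 2, 3] + 1
  set <- spatial_map_set(maps, rep(c("a", "b"), c(n1, n2)))
  tm <- pointwise_t_map(set)
  expect_equal(attr(tm, "df"), n1 + n2 - 2)
  for (r in c(1, 2, 5)) for (cc in c(1, 3, 7)) {
    expect_equal(tm[r, cc],
                 oracle_pooled_t(maps[1:n1, r, cc],
                                 maps[(n1 + 1):(n1 + n2), r, cc]))
  }
})

test_that("identical groups give a zero t map; degenerate inputs error", {
  base <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  maps <- base[c(1:4, 1:4), , ]  # group b duplicates group a
  set <- spatial_map_set(maps, rep(c("a", "b"), each = 4))
  tm <- pointwise_t_map(set)
  expect_true(all(abs(tm) < 1e-10, na.rm = TRUE))

  expect_error(spatial_map_set(base, c("a", "b", "b", "b")),
               ">= 2 maps")
  expect_error(spatial_map_set(base, rep("a", 4)), "two condition labels")

  # zero variance in both groups at one cell -> that cell masked
  maps2 <- array(rnorm(6 * 3 * 3), c(6, 3, 3))
  maps2[, 2, 2] <- 7
  set2 <- spatial_map_set(maps2, rep(c("a", "b"), each = 3))
  expect_true(is.na(pointwise_t_map(set2)[2, 2]))
})

test_that("cluster formation matches the flood-fill oracle", {
  # 5x5 suprathreshold block plus one isolated cell -> one 25-cell cluster
  tm <- matrix(0, 12, 12)
  tm[3:7, 4:8] <- 5
  tm[11, 11] <- 5
  attr(tm, "df") <- 20
  cl <- form_clusters(tm, threshold_p = 0.01)
  expect_length(cl, 1)
  expect_length(cl[[1]]$cells, 25)
  expect_equal(cl[[1]]$mass, 25 * 5)
  expect_equal(cl[[1]]$sign, 1)

  # extent rule: a single suprathreshold cell forms no cluster
  tm1 <- matrix(0, 6, 6); tm1[3, 3] <- 9; attr(tm1, "df") <- 20
  expect_length(form_clusters(tm1), 0)
  # but two adjacent cells do
  tm1[3, 4] <- 9
  expect_length(form_clusters(tm1), 1)

  # no suprathreshold cells -> empty
  tm0 <- matrix(0.5, 6, 6); attr(tm0, "df") <- 20
  expect_length(form_clusters(tm0), 0)

  # random binary grids against the label-propagation oracle
  set.seed(62)
  for (rep in 1:15) {
    bin <- matrix(runif(100) < 0.35, 10, 10)
    tmr <- matrix(0, 10, 10); tmr[bin] <- 6
    attr(tmr, "df") <- 30
    got <- form_clusters(tmr, threshold_p = 0.01, min_size = 1L)
    want <- oracle_components(bin)
    got_cells <- lapply(got, `[[`, "cells")
    expect_equal(length(got_cells), length(want))
    expect_setequal(vapply(got_cells, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
  }
})

test_that("positive and negative clusters are formed separately", {
  tm <- matrix(0, 8, 8)
  tm[2:3, 2:3] <- 6
  tm[6:7, 6:7] <- -6
  attr(tm, "df") <- 25
  cl <- form_clusters(tm)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, `[[`, numeric(1), "sign"), c(1, -1))
  # adjacency never bridges opposite signs
  expect_true(all(vapply(cl, function(x) length(x$cells), numeric(1)) == 4))
})

test_that("permutation test is deterministic and row-order invariant", {
  cfg <- map_gen_config(H = 12, W = 12, n_per_group = 8,
                        effect_rows = 3:6, effect_cols = 3:6,
                        effect_size = 1.6)
  set <- gen_spatial_maps(cfg, seed = 63)
  r1 <- permutation_test(set, n_perm = 300, seed = 9)
  r2 <- permutation_test(set, n_perm = 300, seed = 9)
  expect_identical(r1$null_max_mass, r2$null_max_mass)
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "p_value"),
                   vapply(r2$clusters, `[[`, numeric(1), "p_value"))

  # permute rows within each condition: same t map, same clusters
  perm <- c(sample(1:8), 8 + sample(1:8))
  set_p <- spatial_map_set(set$maps[perm, , ], set$labels[perm])
  r3 <- permutation_test(set_p, n_perm = 300, seed = 9)
  expect_equal(r3$t_map, r1$t_map)
  expect_equal(vapply(r3$clusters, `[[`, numeric(1), "mass"),
               vapply(r1$clusters, `[[`, numeric(1), "mass"))
})

test_that("permutation p-values use the +1 convention and never reach 0", {
  cfg <- map_gen_config(H = 10, W = 10, n_per_group = 6,
                        effect_rows = 2:7, effect_cols = 2:7,
                        effect_size = 10)
  set <- gen_spatial_maps(cfg, seed = 64)
  res <- permutation_test(set, n_perm = 200, seed = 10)
  expect_gte(length(res$clusters), 1)
  p_min <- min(vapply(res$clusters, `[[`, numeric(1), "p_value"))
  expect_gte(p_min, 1 / 201)
  # a mass above every permuted maximum gets exactly 1/(n_perm + 1)
  top_mass <- max(vapply(res$clusters, `[[`, numeric(1), "mass"))
  if (all(res$null_max_mass < top_mass))
    expect_equal(p_min, 1 / 201)
  expect_error(permutation_test(set, n_perm = 1), ">= 2")
  expect_warning(permutation_test(set, n_perm = 50, seed = 1), "coarse")
})

test_that("splitting a cluster cannot increase the maximum mass", {
  tm <- matrix(0, 10, 10)
  tm[3:4, 2:9] <- 4
  attr(tm, "df") <- 30
  whole <- form_clusters(tm)
  expect_length(whole, 1)
  tm_split <- tm
  tm_split[3:4, 5] <- 0  # cut the cluster in two
  parts <- form_clusters(tm_split)
  expect_length(parts, 2)
  expect_lt(max(vapply(parts, `[[`, numeric(1), "mass")),
            whole[[1]]$mass)
})
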