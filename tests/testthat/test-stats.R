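# Correlation machinery: coefficients, p-values, maps, clusters, features.

test_that("pearson_r matches direct evaluation and flags degenerate input", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # hand-computed product-moment value, frozen
  expect_equal(pearson_r(c(1, 0, 1, 0, 1), c(90, 55, 80, 60, 85)),
               0.9672471299, tolerance = 1e-9)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pearson_r is invariant under positive affine maps, sign-flips under negative", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    r <- pearson_r(x, y)
    expect_equal(pearson_r(2.5 * x + 7, y), r)
    expect_equal(pearson_r(x, -3 * y + 1), -r)
  }
})

test_that("pearson_p reproduces the analytic bounds and the t-transform", {
  expect_lt(pearson_p(0.30, 84), 0.01)
  expect_lt(pearson_p(0.40, 84), 0.0005)
  expect_equal(pearson_p(0, 84), 1)
  expect_equal(pearson_p(1, 10), 0)
  # agreement with the standard test on real data
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(30); y <- x + rnorm(30)
    ct <- stats::cor.test(x, y)
    expect_equal(pearson_p(pearson_r(x, y), 30), unname(ct$p.value),
                 tolerance = 1e-12)
  }
  # monotone in |r| at fixed n and in n at fixed |r|
  rs <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(pearson_p(rs, 30)) < 0))
  ns <- seq(5, 100, by = 5)
  expect_true(all(diff(pearson_p(0.3, ns)) < 0))
})

test_that("index/choice correlation is exact on affine scores and calibrated on shuffles", {
  sim <- small_sim(seed = 2L)
  idx <- index_table(sim$cases, pair_A)$index_base
  scores <- 50 + 2.5 * idx
  cc <- index_choice_correlation(sim$cases, scores, "base")
  expect_equal(cc$r, 1)
  expect_equal(cc$n, length(sim$cases))

  # permutation oracle: analytic p consistent with Monte-Carlo shuffle p
  set.seed(99)
  y <- sample(scores)   # break the association
  cc2 <- index_choice_correlation(sim$cases, y, "base")
  perm <- replicate(2000, {
    abs(stats::cor(idx, sample(y)))
  })
  p_mc <- mean(perm >= abs(cc2$r))
  expect_lt(abs(p_mc - cc2$p), 3 * sqrt(0.25 / 2000) + 0.02)
  expect_error(index_choice_correlation(sim$cases[1:2], scores[1:2], "base"),
               "at least 3")
})

test_that("pixel-wise map equals per-location Pearson and masks zero variance", {
  # constructed balanced suite: iv2 lit exactly on the 100-score tests
  z <- class_locations(class_A, "z")
  cases <- lapply(1:8, function(i) {
    lit <- if (i %% 2 == 0) c("iv2", z[1:2]) else z[3:4]
    test_case(pixel_grid(lit), pixel_grid("iii1"), i)
  })
  scores <- ifelse(seq_len(8) %% 2 == 0, 100, 50)
  m <- pixelwise_correlation(cases, scores, side = "Z")
  expect_equal(m$r[parse_locations("iv2")], 1)
  expect_true(m$masked[parse_locations("i1")])       # never lit
  always <- lapply(cases, function(cs)
    test_case(pixel_grid(c(lit_locations(cs$grid_Z), "v4")), cs$grid_H,
              cs$test_id))
  m2 <- pixelwise_correlation(always, scores, side = "Z")
  expect_true(m2$masked[parse_locations("v4")])      # always lit

  # naive double-loop oracle on a seeded synthetic suite
  sim <- small_sim(seed = 6L)
  sc <- test_scores(sim$choices)
  for (side in c("Z", "H")) {
    mp <- pixelwise_correlation(sim$cases, sc, side = side)
    for (loc in all_locations()) {
      idx <- parse_locations(loc)
      x <- vapply(sim$cases, function(cs)
        as.numeric(loc %in% lit_locations(cs[[paste0("grid_", side)]])), 0)
      if (stats::var(x) == 0) {
        expect_true(mp$masked[idx])
      } else {
        expect_equal(mp$r[idx], stats::cor(x, sc$score), tolerance = 1e-12)
      }
    }
  }
})

test_that("cluster extraction matches the published salience topology", {
  # synthetic coefficient map encoding only what the text states: the 8 z
  # and 6 h salient locations reach r >= 0.30, everything else stays below
  s <- salient_sets()
  mk_map <- function(locs) {
    r <- matrix(0.10, 7, 5)
    r[c(1, 7), ] <- NA
    r[parse_locations(locs)] <- 0.40
    r
  }
  cz <- salient_clusters(mk_map(s$Z))
  expect_length(cz$clusters, 4)
  expect_equal(sort(unlist(cz$clusters)), sort(s$Z))
  ch <- salient_clusters(mk_map(s$H))
  expect_length(ch$clusters, 2)
  expect_equal(sort(unlist(ch$clusters)), sort(s$H))
})

test_that("cluster extraction is a maximal partition of the supra-threshold set", {
  empty <- salient_clusters(matrix(0.1, 7, 5))
  expect_length(empty$clusters, 0)
  single <- matrix(0, 7, 5); single[3, 3] <- 0.5
  expect_equal(salient_clusters(single)$clusters, list("iii3"))

  set.seed(12)
  for (i in 1:25) {
    r <- matrix(runif(35, -0.5, 0.6), 7, 5)
    cs <- salient_clusters(r, r_threshold = 0.30)
    supra <- all_locations()[which(t(r) >= 0.30)]
    members <- unlist(cs$clusters)
    expect_setequal(members, supra)
    expect_equal(anyDuplicated(members), 0)
    # maximality: no two distinct clusters contain adjacent cells
    if (length(cs$clusters) >= 2) {
      for (a in seq_along(cs$clusters)) for (b in seq_along(cs$clusters)) {
        if (b <= a) next
        for (la in cs$clusters[[a]]) for (lb in cs$clusters[[b]]) {
          pa <- parse_locations(la); pb <- parse_locations(lb)
          expect_gt(max(abs(pa - pb)), 1)
        }
      }
    }
  }
})

test_that("pooled cluster correlation reduces to and dominates single pixels", {
  sim <- small_sim(seed = 9L)
  sc <- test_scores(sim$choices)
  mp <- pixelwise_correlation(sim$cases, sc, side = "Z")
  # singleton cluster identical to the map value
  loc <- "vi4"
  pc <- pooled_cluster_correlation(sim$cases, sc, loc, side = "Z")
  expect_equal(pc$r, mp$r[parse_locations(loc)], tolerance = 1e-12)

  # two perfectly co-lit pixels: pooled count is twice an indicator, same r
  z <- class_locations(class_A, "z")
  co <- lapply(1:10, function(i) {
    lit <- if (i %% 3 == 0) z[1:2] else z[3]
    test_case(pixel_grid(lit), pixel_grid(), i)
  })
  cosc <- ifelse(seq_len(10) %% 3 == 0, 90, 55 + seq_len(10))
  r_pool <- pooled_cluster_correlation(co, cosc, z[1:2], side = "Z")$r
  r_single <- pixelwise_correlation(co, cosc, side = "Z")$r[parse_locations(z[1])]
  expect_equal(r_pool, r_single, tolerance = 1e-12)
  expect_error(pooled_cluster_correlation(co, cosc, character(), "Z"),
               "empty cluster")

  # planted two-pixel cluster: pooling is at least as good as each member,
  # against an independent recomputation
  clu <- c("vi4", "vi5")
  pooled <- pooled_cluster_correlation(sim$cases, sc, clu, side = "Z")
  manual <- vapply(sim$cases, function(cs)
    length(intersect(lit_locations(cs$grid_Z), clu)), 0L)
  expect_equal(pooled$r, stats::cor(manual, sc$score), tolerance = 1e-12)
})

test_that("feature pairs behave like single pixels when perfectly coupled", {
  z <- class_locations(class_A, "z")
  s <- salient_sets()
  # ii1/ii2 always co-lit: the pair indicator equals either single indicator
  cases <- lapply(1:12, function(i) {
    lit <- if (i %% 2 == 0) c("ii1", "ii2") else z[5]
    test_case(pixel_grid(lit), pixel_grid(s$H[i %% 3 + 1]), i)
  })
  scores <- 50 + 4 * seq_len(12) %% 2 * 10 + seq_len(12)
  fp <- feature_pair_analysis(cases, scores, seed = 4)
  row <- fp$detail[fp$detail$loc1 == "ii1" & fp$detail$loc2 == "ii2", ]
  single <- pixelwise_correlation(cases, scores, "Z")$r[parse_locations("ii1")]
  expect_equal(row$r, unname(single), tolerance = 1e-12)
})

test_that("feature analysis separates planted configural effects from null suites", {
  sim <- small_sim(seed = 14L, n_tests = 40L)
  sc <- test_scores(sim$choices)
  # no configural effect planted: neighbouring and control means are close
  fp0 <- feature_pair_analysis(sim$cases, sc, seed = 4)
  expect_lt(abs(fp0$mean_r_neighbouring - fp0$mean_r_control), 0.25)
  expect_lte(fp0$n_neighbouring, 14)

  # plant a bonus when ii1 and ii2 are conjointly lit in the Z-like member
  bonus <- vapply(sim$cases, function(cs) {
    lit <- lit_locations(cs$grid_Z)
    25 * as.numeric(all(c("ii1", "ii2") %in% lit))
  }, 0)
  sc2 <- sc; sc2$score <- pmin(sc$score + bonus, 100)
  fp1 <- feature_pair_analysis(sim$cases, sc2, seed = 4)
  row <- fp1$detail[fp1$detail$loc1 == "ii1" & fp1$detail$loc2 == "ii2", ]
  mp <- pixelwise_correlation(sim$cases, sc2, "Z")
  expect_gt(row$r, mp$r[parse_locations("ii1")])
  expect_gt(row$r, mp$r[parse_locations("ii2")])
})

test_that("top_salient_locations ranks by coefficient within the core rows", {
  r <- matrix(0, 7, 5)
  r[2, 1] <- 0.5; r[6, 5] <- 0.4; r[1, 1] <- 0.9   # outer row excluded
  map <- structure(list(r = r, p = r * 0, masked = matrix(FALSE, 7, 5),
                        n = 84, side = "Z"), class = "pixel_cor_map")
  expect_equal(top_salient_locations(map, 2), c("ii1", "vi5"))
  expect_equal(top_salient_locations(map, 3, core_only = FALSE)[1], "i1")
})
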