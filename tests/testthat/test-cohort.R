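# Replication, relativity, binomial concordance, inter-individual analyses.

test_that("replication rows carry differences and gaps as constructed", {
  cases <- list(
    test_case(pixel_grid("ii1"), pixel_grid("iii1"), 1, session = 5),
    test_case(pixel_grid("ii1"), pixel_grid("iii1"), 2, session = 33,
              repeat_of = 1))
  same <- replication_table(cases, c(`1` = 70, `2` = 70))
  expect_equal(same$rows$difference, 0)
  rt <- replication_table(cases, c(`1` = 80, `2` = 62))
  expect_equal(rt$rows$difference, -18)
  expect_equal(rt$rows$gap, 28)
  expect_equal(rt$n_repeats, 1)
  bad <- list(
    test_case(pixel_grid("ii1"), pixel_grid("iii1"), 1, session = 20,
              repeat_of = 2),
    test_case(pixel_grid("ii1"), pixel_grid("iii1"), 2, session = 33))
  expect_error(replication_table(bad, c(`1` = 80, `2` = 62)),
               "later session")
})

test_that("a planted per-repeat drift is recovered from a synthetic suite", {
  sim <- small_sim(seed = 21L, n_tests = 60L)
  set.seed(77)
  base <- stats::setNames(runif(60, 55, 95),
                          vapply(sim$cases, `[[`, 1L, "test_id"))
  scores <- base
  for (cs in sim$cases)   # session order: chains through triple repeats
    if (!is.na(cs$repeat_of))
      scores[as.character(cs$test_id)] <-
        scores[as.character(cs$repeat_of)] - 5 + rnorm(1, 0, 1)
  rt <- replication_table(sim$cases, scores)
  expect_gt(rt$n_repeats, 2)
  expect_lt(abs(rt$mean_difference + 5), 2.5)
})

test_that("replication differences centre on zero under an exchangeable null", {
  sim <- small_sim(seed = 5L, n_tests = 40L)
  set.seed(303)
  diffs <- replicate(200, {
    sc <- runif(40, 50, 100)
    replication_table(sim$cases, sc)$mean_difference
  })
  n_rep <- replication_table(sim$cases, runif(40, 50, 100))$n_repeats
  # CLT band: per-row difference sd <= 50/sqrt(3) for uniform(50,100) scores
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se + 1)
})

test_that("part-repeat tracking flags class-preference switches", {
  x <- pixel_grid(c("iv1", "iv2", "iv3"))
  pz <- pixel_grid(class_locations(class_A, "z")[1:6])
  ph <- pixel_grid(class_locations(class_A, "h")[1:6])
  # the same middle pattern read as barely H-like, clearly Z-like, barely H-like
  cases <- list(test_case(pz, x, 1, session = 10),
                test_case(x, ph, 2, session = 15),
                test_case(pz, x, 3, session = 18))
  tab <- part_repeat_table(cases, c(`1` = 54, `2` = 91, `3` = 53))
  xrows <- tab[tab$pattern == pattern_key(x), ]
  expect_equal(nrow(xrows), 2)
  expect_true(all(xrows$flip))
  expect_equal(sum(tab$flip), 2)

  # same pattern, same partner, same score: zero change, no flip
  rep_cases <- list(test_case(pz, x, 1, session = 1),
                    test_case(pz, x, 2, session = 9))
  tab2 <- part_repeat_table(rep_cases, c(`1` = 70, `2` = 70))
  expect_true(all(tab2$change == 0))
  expect_false(any(tab2$flip))
  expect_false(any(tab2$partner_changed))

  # flip count matches a brute-force recount on a synthetic suite
  sim <- small_sim(seed = 33L)
  set.seed(12); sc <- runif(length(sim$cases), 35, 100)
  tab3 <- part_repeat_table(sim$cases, sc)
  ids <- vapply(sim$cases, `[[`, 1L, "test_id")
  manual_flips <- 0L
  occ <- list()
  for (cs in sim$cases[order(vapply(sim$cases, `[[`, 1L, "session"))]) {
    for (side in c("Z", "H")) {
      key <- pattern_key(cs[[paste0("grid_", side)]])
      zl <- if (side == "Z") sc[match(cs$test_id, ids)]
            else 100 - sc[match(cs$test_id, ids)]
      if (!is.null(occ[[key]]) && (occ[[key]] - 50) * (zl - 50) < 0)
        manual_flips <- manual_flips + 1L
      occ[[key]] <- zl
    }
  }
  expect_equal(sum(tab3$flip), manual_flips)
})

test_that("exact binomial tail agrees with full enumeration up to n = 20", {
  # oracle: distribution of fair-coin successes by repeated convolution,
  # equivalent to enumerating all 2^n outcomes
  for (n in 1:20) {
    dist <- 1
    for (i in seq_len(n)) dist <- (c(dist, 0) + c(0, dist)) / 2
    for (k in 0:n) {
      expect_equal(binomial_test(k, n), sum(dist[(k + 1):(n + 1)]),
                   tolerance = 1e-12)
      expect_equal(binomial_test(k, n, alternative = "less"),
                   sum(dist[1:(k + 1)]), tolerance = 1e-12)
    }
  }
})

test_that("binomial bounds and edge cases match the reported significance levels", {
  expect_lt(binomial_test(69, 84), 1e-4)
  expect_equal(binomial_test(21, 30), 0.0213869726, tolerance = 1e-8)
  expect_lt(binomial_test(21, 30), 0.05)
  expect_equal(binomial_test(0, 84), 1)
  expect_lte(binomial_test(10, 20, alternative = "two.sided"), 1)
  expect_error(binomial_test(21, 20), "invalid k/n")
  expect_error(binomial_test(-1, 20), "invalid k/n")
})

test_that("concordance counts strict same-side team preferences", {
  mk <- function(scores_z, scores_h) {
    do.call(rbind, lapply(seq_along(scores_z), function(i) rbind(
      choice_record(i, "p1", "Z+H-", 20, round(scores_z[i] / 5)),
      choice_record(i, "p4", "H+Z-", 20, round(scores_h[i] / 5)))))
  }
  all100 <- mk(rep(100, 10), rep(100, 10))
  res <- team_concordance(all100)
  expect_equal(res$k, 10)
  expect_equal(res$p, 2^-10, tolerance = 1e-12)
  split <- team_concordance(mk(c(60, 80), c(40, 80)))
  expect_equal(split$k, 1)
  tie <- team_concordance(mk(c(50, 80), c(60, 80)))
  expect_equal(tie$k, 1)   # an exact 50 breaks concordance
  one_team <- data.frame(test_id = 1, team = "Z+H-", score = 80)
  expect_error(team_concordance(one_team), "missing team")
})

test_that("concordance is invariant under per-test class relabelling", {
  sim <- small_sim(seed = 40L)
  per_team <- test_scores(sim$choices, by = "team")
  base <- team_concordance(per_team)
  set.seed(2)
  flip <- sample(unique(per_team$test_id), 10)
  relab <- per_team
  relab$score[relab$test_id %in% flip] <-
    100 - relab$score[relab$test_id %in% flip]
  expect_equal(team_concordance(relab)$k, base$k)
})

test_that("shared weights give high concordance, independent weights chance-level", {
  cfg <- sim_config(seed = 51L)
  shared <- simulate_experiment(cfg)
  res_s <- team_concordance(shared$choices)
  expect_gt(res_s$k / res_s$n, 0.8)
  # manual recount oracle
  pt <- test_scores(shared$choices, by = "team")
  wide <- split(pt$score, pt$test_id)
  manual <- sum(vapply(wide, function(v) all(v > 50) || all(v < 50), TRUE))
  expect_equal(res_s$k, manual)

  # independent random weights per bird: concordance collapses to chance
  set.seed(61)
  pigeons <- lapply(1:6, function(i)
    pigeon_model(paste0("p", i), if (i <= 3) "Z+H-" else "H+Z-",
                 matrix(rnorm(35, 0, 1.5), 7, 5)))
  cases <- shared$cases
  choices <- do.call(rbind, lapply(cases, function(cs)
    do.call(rbind, lapply(pigeons, function(pg)
      simulate_choices(pg, cs, 20, beta = 0.1)))))
  res_i <- team_concordance(choices)
  expect_lt(res_i$k / res_i$n, 0.75)
  expect_gt(res_i$k / res_i$n, 0.25)
})

test_that("inter-individual correlations separate teams in the default cohort", {
  sim <- simulate_experiment(sim_config(seed = 71L))
  ii <- interindividual_correlations(sim$choices)
  expect_equal(unname(diag(ii$r)), rep(1, 6))
  expect_equal(dim(ii$r), c(6, 6))
  expect_gt(min(ii$mean_within_team), ii$mean_between_team)

  # two birds with identical score vectors correlate at exactly 1
  dup <- sim$choices
  extra <- dup[dup$pigeon_id == "p1", ]
  extra$pigeon_id <- "p7"
  ii2 <- interindividual_correlations(rbind(dup, extra))
  expect_equal(ii2$r["p1", "p7"], 1)
})
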