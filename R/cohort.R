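# Cohort-level analyses: replication, relativity (part-repeats), exact
# binomial tests, across-team concordance and inter-individual correlations.

TEAM_LABELS <- c("Z+H-", "H+Z-")

#' Build a choice record
#'
#' One pigeon's choice tally on one test. `percent_correct` is the
#' percentage of the test's trials on which the designated unreinforced
#' pattern (the Z-like member for Z+H- birds, the H-like member for H+Z-
#' birds) was chosen.
#'
#' @param test_id,pigeon_id Identifiers.
#' @param team `"Z+H-"` or `"H+Z-"`.
#' @param n_trials Number of test trials (typically 20).
#' @param n_correct Choices of the designated pattern, `0..n_trials`.
#' @return A one-row data frame with a recomputed `percent_correct`.
#' @export
choice_record <- function(test_id, pigeon_id, team, n_trials, n_correct) {
  if (!team %in% TEAM_LABELS)
    stop("unknown team label: ", team, " (expected ",
         paste(TEAM_LABELS, collapse = " or "), ")")
  n_trials <- as.integer(n_trials); n_correct <- as.integer(n_correct)
  if (n_trials < 1L || n_correct < 0L || n_correct > n_trials)
    stop("invalid tallies: n_correct must lie in 0..n_trials")
  data.frame(test_id = as.integer(test_id), pigeon_id = as.character(pigeon_id),
             team = team, n_trials = n_trials, n_correct = n_correct,
             percent_correct = 100 * n_correct / n_trials)
}

check_choices <- function(choices) {
  need <- c("test_id", "pigeon_id", "team", "n_trials", "n_correct",
            "percent_correct")
  miss <- setdiff(need, names(choices))
  if (length(miss)) stop("choice table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !choices$team %in% TEAM_LABELS
  if (any(bad)) stop("unknown team label(s): ",
                     paste(unique(choices$team[bad]), collapse = ", "))
  invisible(choices)
}

#' Per-test choice scores from a choice table
#'
#' Aggregates per-pigeon percent-correct scores to per-test scores: the
#' unweighted mean over pigeons (the default used throughout the analyses)
#' or the pooled-trials percentage.
#'
#' @param choices Choice table (see [choice_record()] / [read_choices()]).
#' @param by `"overall"` (all pigeons), `"team"` or `"pigeon"`.
#' @param method `"mean"` (unweighted mean of percentages, default) or
#'   `"pooled"` (100 * total correct / total trials).
#' @return A data frame: `test_id`, `score`, plus `team` or `pigeon_id`
#'   when grouped.
#' @export
test_scores <- function(choices, by = c("overall", "team", "pigeon"),
                        method = c("mean", "pooled")) {
  by <- match.arg(by); method <- match.arg(method)
  check_choices(choices)
  keys <- switch(by,
                 overall = list(test_id = choices$test_id),
                 team = list(test_id = choices$test_id, team = choices$team),
                 pigeon = list(test_id = choices$test_id,
                               pigeon_id = choices$pigeon_id))
  agg <- if (method == "mean") {
    stats::aggregate(list(score = choices$percent_correct), keys, mean)
  } else {
    num <- stats::aggregate(list(correct = choices$n_correct,
                                 trials = choices$n_trials), keys, sum)
    num$score <- 100 * num$correct / num$trials
    num[, setdiff(names(num), c("correct", "trials"))]
  }
  agg[order(agg$test_id), , drop = FALSE]
}

#' Replication analysis of repeated test pairs
#'
#' One row per repeat event (a case whose `repeat_of` points to the previous
#' presentation of the identical pair): scores on both rounds, the
#' percent-point difference (later minus earlier) and the session gap.
#' Summary statistics give the mean difference and the correlation of
#' differences with gaps.
#'
#' @param cases List of `test_case`s with repeat linkage.
#' @param scores Per-test scores.
#' @return Object of class `replication_summary`: list with the `rows` data
#'   frame, `n_repeats`, `mean_difference`, and `r`/`p` for difference vs
#'   gap (NA when fewer than 3 repeat events).
#' @export
replication_table <- function(cases, scores) {
  ids <- check_cases(cases)
  s <- align_scores(cases, scores)
  names(s) <- ids
  by_id <- stats::setNames(cases, ids)
  rows <- lapply(cases, function(cs) {
    if (is.na(cs$repeat_of)) return(NULL)
    prev <- by_id[[as.character(cs$repeat_of)]]
    if (is.null(prev)) stop("repeat_of refers to unknown test_id ",
                            cs$repeat_of)
    if (prev$session >= cs$session)
      stop("repeat_of pointing to a later session (test ", cs$test_id, ")")
    data.frame(first_id = prev$test_id, second_id = cs$test_id,
               score_first = s[[as.character(prev$test_id)]],
               score_second = s[[as.character(cs$test_id)]],
               difference = s[[as.character(cs$test_id)]] -
                 s[[as.character(prev$test_id)]],
               gap = cs$session - prev$session)
  })
  rows <- do.call(rbind, rows)
  r <- p <- NA_real_
  if (!is.null(rows) && nrow(rows) >= 3L &&
      stats::var(rows$difference) > 0 && stats::var(rows$gap) > 0) {
    r <- pearson_r(rows$difference, rows$gap)
    p <- pearson_p(r, nrow(rows))
  }
  structure(list(rows = rows,
                 n_repeats = if (is.null(rows)) 0L else nrow(rows),
                 mean_difference = if (is.null(rows)) NA_real_
                                   else mean(rows$difference),
                 r = r, p = p),
            class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("%d test replications; mean difference %.1f percent points\n",
              x$n_repeats, x$mean_difference))
  if (!is.na(x$r))
    cat(sprintf("difference vs gap: r = %.2f, p = %.3g\n", x$r, x$p))
  invisible(x)
}

#' Relativity analysis: same pattern, changing partner
#'
#' Tracks every stimulus pattern (content-addressed via [pattern_key()])
#' that recurs across tests and compares its evaluation between consecutive
#' occurrences. A pattern's class preference is expressed as its
#' "Z-likeness": the percent of choices it attracted when it was the Z-like
#' member, or 100 minus the score when it was the H-like member. A flip
#' (preference turning into avoidance of a class) is flagged when the
#' Z-likeness crosses 50% between occurrences.
#'
#' @param cases List of `test_case`s.
#' @param scores Per-test scores.
#' @return Data frame with one row per consecutive recurrence: pattern key,
#'   the two test ids, sides, partner_changed, the two Z-likeness values,
#'   `change` (later minus earlier) and `flip`.
#' @export
part_repeat_table <- function(cases, scores) {
  ids <- check_cases(cases)
  s <- align_scores(cases, scores)
  names(s) <- ids
  occ <- do.call(rbind, lapply(cases, function(cs) {
    sc <- s[[as.character(cs$test_id)]]
    data.frame(
      key = c(pattern_key(cs$grid_Z), pattern_key(cs$grid_H)),
      partner = c(pattern_key(cs$grid_H), pattern_key(cs$grid_Z)),
      test_id = cs$test_id, session = cs$session,
      side = c("Z", "H"),
      z_likeness = c(sc, 100 - sc))
  }))
  occ <- occ[order(occ$key, occ$session), , drop = FALSE]
  out <- NULL
  for (key in unique(occ$key)) {
    grp <- occ[occ$key == key, , drop = FALSE]
    if (nrow(grp) < 2L) next
    for (i in seq_len(nrow(grp) - 1L)) {
      a <- grp[i, ]; b <- grp[i + 1L, ]
      out <- rbind(out, data.frame(
        pattern = key,
        test_id_first = a$test_id, test_id_second = b$test_id,
        side_first = a$side, side_second = b$side,
        partner_changed = a$partner != b$partner,
        z_likeness_first = a$z_likeness, z_likeness_second = b$z_likeness,
        change = b$z_likeness - a$z_likeness,
        flip = (a$z_likeness - 50) * (b$z_likeness - 50) < 0))
    }
  }
  if (is.null(out))
    out <- data.frame(pattern = character(), test_id_first = integer(),
                      test_id_second = integer(), side_first = character(),
                      side_second = character(), partner_changed = logical(),
                      z_likeness_first = numeric(),
                      z_likeness_second = numeric(), change = numeric(),
                      flip = logical())
  rownames(out) <- NULL
  out
}

#' Exact binomial test by tail summation
#'
#' Exact binomial tail probability (no normal approximation): the one-sided
#' upper tail P(X >= k) by default, matching the directional concordance
#' hypothesis; the two-sided option doubles the smaller tail, capped at 1.
#'
#' @param k Number of successes, `0..n`.
#' @param n Number of trials.
#' @param p0 Null success probability, default 0.5.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return The p-value.
#' @examples
#' binomial_test(69, 84)  # < 0.0001
#' binomial_test(21, 30)  # < 0.05
#' @export
binomial_test <- function(k, n, p0 = 0.5,
                          alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(k) == 1L, length(n) == 1L, p0 > 0, p0 < 1)
  k <- as.integer(k); n <- as.integer(n)
  if (n < 1L || k < 0L || k > n) stop("invalid k/n: need 0 <= k <= n, n >= 1")
  upper <- stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)  # P(X >= k)
  lower <- stats::pbinom(k, n, p0)                           # P(X <= k)
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(lower, upper)))
}

#' Across-team concordance of choice preferences
#'
#' A test is concordant when both team mean percent-correct scores fall
#' strictly on the same side of 50%: both teams then judge the pair
#' consistently with the same Z/H-likeness assignment. A team mean of
#' exactly 50 expresses no preference and breaks concordance (conservative
#' tie rule). The concordant count is tested against chance with the exact
#' one-sided binomial test.
#'
#' @param choices Choice table containing both teams on every test, or a
#'   data frame of per-team scores with columns `test_id`, `team`, `score`.
#' @return Object of class `concordance_result`: list with `n`, `k`, `p`
#'   and the per-test table.
#' @export
team_concordance <- function(choices) {
  per_team <- if (all(c("team", "score") %in% names(choices)) &&
                  !"percent_correct" %in% names(choices)) {
    choices
  } else {
    test_scores(choices, by = "team")
  }
  wide <- stats::reshape(per_team[, c("test_id", "team", "score")],
                         idvar = "test_id", timevar = "team",
                         direction = "wide")
  names(wide) <- sub("^score\\.", "", names(wide))
  if (!all(TEAM_LABELS %in% names(wide)) || anyNA(wide[TEAM_LABELS]))
    stop("missing team: both teams must be scored on every test")
  a <- wide[["Z+H-"]]; b <- wide[["H+Z-"]]
  wide$concordant <- (a > 50 & b > 50) | (a < 50 & b < 50)
  k <- sum(wide$concordant); n <- nrow(wide)
  structure(list(n = n, k = k, p = binomial_test(k, n),
                 table = wide[order(wide$test_id), ]),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Teams concordant on %d of %d tests (exact binomial p = %.3g)\n",
              x$k, x$n, x$p))
  invisible(x)
}

#' Inter-individual correlations of choice scores
#'
#' Pairwise Pearson correlations between the pigeons' per-test percent
#' scores over their shared tests, with the mean over all pairs and the
#' within- and between-team means. Pairs sharing fewer than 3 tests are
#' masked (`NA`).
#'
#' @param choices Choice table with at least 2 pigeons.
#' @return List with the correlation matrix `r`, `mean_all`,
#'   `mean_within_team` (named by team), `mean_between_team`, and the
#'   pigeons' team assignment.
#' @export
interindividual_correlations <- function(choices) {
  check_choices(choices)
  per <- test_scores(choices, by = "pigeon")
  wide <- stats::reshape(per, idvar = "test_id", timevar = "pigeon_id",
                         direction = "wide")
  pig <- sub("^score\\.", "", names(wide)[-1L])
  if (length(pig) < 2L) stop("need at least 2 pigeons")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  colnames(m) <- pig
  teams <- vapply(pig, function(pg)
    as.character(choices$team[choices$pigeon_id == pg][1L]), "")
  r <- matrix(NA_real_, length(pig), length(pig), dimnames = list(pig, pig))
  diag(r) <- 1
  for (i in seq_along(pig)) for (j in seq_along(pig)) {
    if (j <= i) next
    shared <- stats::complete.cases(m[, c(i, j)])
    if (sum(shared) < 3L) next
    r[i, j] <- r[j, i] <- pearson_r(m[shared, i], m[shared, j])
  }
  ut <- upper.tri(r)
  same <- outer(teams, teams, `==`)
  list(r = r,
       mean_all = mean(r[ut], na.rm = TRUE),
       mean_within_team = vapply(unique(teams), function(tm)
         mean(r[ut & same & outer(teams == tm, teams == tm, `&`)],
              na.rm = TRUE), 0),
       mean_between_team = mean(r[ut & !same], na.rm = TRUE),
       teams = teams)
}
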