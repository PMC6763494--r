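# Generative simulator: pattern suites and pigeon choices with the
# statistical structure the analysis pipeline assumes.
#
# The choice rule is a logistic on summed per-pixel evidence weights: on each
# trial the bird chooses its designated-correct member with probability
# 1 / (1 + exp(-beta * E)), where E is the weight sum over lit pixels of the
# correct member minus the weight sum over lit pixels of the other member.
# This is the minimal generative model consistent with the evidence-count
# reasoning behind the discriminability index, and makes salience recovery a
# meaningful end-to-end test of the correlation machinery.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 84 test sessions of pattern pairs
#' with 4-26 lit pixels per pair, 17 pairs repeated once and 2 of them twice
#' (19 repeat events), 6 pigeons in two 3-bird teams with opposite reward
#' assignments, 20 test trials per pigeon per test, and per-location lit
#' rates matched to the published presentation-frequency profile (own-class
#' pixels lit in about half the tests, cross-class in about a fifth, the
#' shared zh pixels in about three fifths, inner neutral pixels rarely and
#' the outer rows i/vii almost never). Salience is planted on the canonical
#' 8 z + 6 h cluster locations, which carry most of the evidence weight
#' (ordinary class pixels retain a weak weight, reflecting the finding that
#' a minority of pixel locations dominated the birds' choices); `beta` is
#' calibrated so the default cohort averages roughly 75-80% correct.
#'
#' @param n_tests Number of test sessions.
#' @param richness_range Allowed total lit pixels per pair, `c(min, max)`.
#' @param n_repeat_pairs Pairs presented a second time.
#' @param n_triple_pairs Of those, pairs presented a third time.
#' @param repeat_gap_range Preferred session gap for repeats, `c(min, max)`.
#' @param n_pigeons Cohort size (split half/half into the two teams).
#' @param trials_per_test Test trials per pigeon per session.
#' @param beta Choice sharpness (>= 0); 0 gives chance responding.
#' @param weight_base,weight_salient Absolute evidence weight of ordinary
#'   vs planted-salient class pixels.
#' @param jitter_sd SD of per-pigeon idiosyncratic weight jitter.
#' @param team_jitter_sd SD of a team-level weight component shared by the
#'   birds of one team and independent across teams. This is what makes
#'   within-team score profiles more alike than between-team ones, mirroring
#'   the higher within-team inter-individual correlations observed
#'   behaviourally; with exactly mirrored team weights and only per-bird
#'   jitter the two would coincide.
#' @param lit_rates Named per-location lit probabilities used when sampling
#'   a member: `own`, `cross`, `zh`, `n_inner`, `n_outer`.
#' @param seed Master seed: identical seed gives byte-identical output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_tests = 84L, richness_range = c(4L, 26L),
                       n_repeat_pairs = 17L, n_triple_pairs = 2L,
                       repeat_gap_range = c(8L, 49L),
                       n_pigeons = 6L, trials_per_test = 20L,
                       beta = 0.1, weight_base = 0.25, weight_salient = 3,
                       jitter_sd = 0.2, team_jitter_sd = 1,
                       lit_rates = c(own = 0.51, cross = 0.22, zh = 0.61,
                                     n_inner = 0.19, n_outer = 0.02),
                       seed = 1L) {
  stopifnot(n_tests >= 1, n_pigeons >= 2, n_pigeons %% 2 == 0,
            trials_per_test >= 1, beta >= 0, jitter_sd >= 0,
            team_jitter_sd >= 0,
            weight_base > 0, weight_salient > 0,
            length(richness_range) == 2L,
            richness_range[1L] >= 0, richness_range[2L] <= 70,
            n_repeat_pairs >= 0, n_triple_pairs >= 0,
            n_triple_pairs <= n_repeat_pairs,
            all(c("own", "cross", "zh", "n_inner", "n_outer") %in%
                  names(lit_rates)),
            all(lit_rates >= 0 & lit_rates <= 1))
  n_events <- n_repeat_pairs + n_triple_pairs
  if (n_tests - n_events < n_repeat_pairs)
    stop("infeasible repeat schedule: not enough unique slots")
  structure(list(n_tests = as.integer(n_tests),
                 richness_range = as.integer(richness_range),
                 n_repeat_pairs = as.integer(n_repeat_pairs),
                 n_triple_pairs = as.integer(n_triple_pairs),
                 repeat_gap_range = as.integer(repeat_gap_range),
                 n_pigeons = as.integer(n_pigeons),
                 trials_per_test = as.integer(trials_per_test),
                 beta = beta, weight_base = weight_base,
                 weight_salient = weight_salient, jitter_sd = jitter_sd,
                 team_jitter_sd = team_jitter_sd,
                 lit_rates = lit_rates, seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a test pattern with fixed per-class lit counts
#'
#' Lights a uniform random subset of each pixel class: `n_z` of the 10 z
#' locations, `n_h` of the 10 h locations, `n_zh` of the 3 zh locations and
#' `n_n` of the 12 n locations.
#'
#' @param class_map A `pixel_class_map`.
#' @param n_z,n_h,n_zh,n_n Requested counts (within class capacities).
#' @param seed Optional seed for a locally scoped RNG.
#' @return A `pixel_grid`.
#' @export
sample_test_pattern <- function(class_map, n_z, n_h, n_zh, n_n, seed = NULL) {
  stopifnot(inherits(class_map, "pixel_class_map"))
  want <- c(z = n_z, h = n_h, zh = n_zh, n = n_n)
  cap <- class_map$counts[names(want)]
  if (any(want < 0) || any(want > cap))
    stop("requested class counts exceed capacity (",
         paste(names(want), cap, sep = "<=", collapse = ", "), ")")
  with_seed(seed, {
    lit <- unlist(lapply(names(want), function(cls) {
      locs <- class_locations(class_map, cls)
      if (want[[cls]] == 0L) character() else
        locs[sample.int(length(locs), want[[cls]])]
    }))
    pixel_grid(lit)
  })
}

# draw one pair member by Bernoulli per-class lit rates (inner vs outer n
# locations distinguished by row)
sample_member <- function(class_map, role, rates) {
  own <- if (role == "Z") "z" else "h"
  cross <- if (role == "Z") "h" else "z"
  rate_of <- function(loc) {
    lab <- class_map$labels[parse_locations(loc)]
    row <- parse_locations(loc)[, 1L]
    ifelse(lab == own, rates[["own"]],
      ifelse(lab == cross, rates[["cross"]],
        ifelse(lab == "zh", rates[["zh"]],
          ifelse(row %in% c(1L, 7L), rates[["n_outer"]],
                 rates[["n_inner"]]))))
  }
  locs <- all_locations()
  lit <- locs[stats::runif(length(locs)) < rate_of(locs)]
  pixel_grid(lit)
}

# repeat schedule: which sessions are repeats, and of which earlier session
plan_repeat_schedule <- function(config) {
  n <- config$n_tests
  n_events <- config$n_repeat_pairs + config$n_triple_pairs
  repeat_of_session <- rep(NA_integer_, n)
  if (n_events == 0L) return(repeat_of_session)
  gmin <- config$repeat_gap_range[1L]
  first_allowed <- min(gmin + 1L, n)
  repeat_slots <- sort(sample(seq.int(first_allowed, n), n_events))
  second_slots <- repeat_slots[seq_len(config$n_repeat_pairs)]
  third_slots <- repeat_slots[-seq_len(config$n_repeat_pairs)]
  unique_slots <- setdiff(seq_len(n), repeat_slots)
  taken <- integer()
  for (slot in second_slots) {
    gap <- slot - unique_slots
    eligible <- unique_slots[gap >= config$repeat_gap_range[1L] &
                               gap <= config$repeat_gap_range[2L] &
                               !unique_slots %in% taken]
    if (!length(eligible))
      eligible <- unique_slots[slot - unique_slots >= 1L &
                                 !unique_slots %in% taken]
    if (!length(eligible)) stop("infeasible repeat schedule")
    orig <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    taken <- c(taken, orig)
    repeat_of_session[slot] <- orig
  }
  for (slot in third_slots) {
    eligible <- second_slots[second_slots < slot &
                               !second_slots %in%
                                 repeat_of_session[third_slots]]
    if (!length(eligible)) stop("infeasible repeat schedule")
    prev <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    repeat_of_session[slot] <- prev
  }
  repeat_of_session
}

generate_suite <- function(config, class_map) {
  n <- config$n_tests
  breaks <- round(n * c(61, 74) / 84)
  phase_of <- function(sess)
    if (sess <= breaks[1L]) "I" else if (sess <= breaks[2L]) "II" else "III"
  repeat_of_session <- plan_repeat_schedule(config)
  cases <- vector("list", n)
  for (sess in seq_len(n)) {
    prev <- repeat_of_session[sess]
    if (!is.na(prev)) {
      src <- cases[[prev]]
      cases[[sess]] <- test_case(src$grid_Z, src$grid_H, test_id = sess,
                                 phase = phase_of(sess), session = sess,
                                 repeat_of = src$test_id)
      next
    }
    repeat {
      gZ <- sample_member(class_map, "Z", config$lit_rates)
      gH <- sample_member(class_map, "H", config$lit_rates)
      rich <- count_lit(gZ) + count_lit(gH)
      if (rich >= config$richness_range[1L] &&
          rich <= config$richness_range[2L]) break
    }
    cases[[sess]] <- test_case(gZ, gH, test_id = sess,
                               phase = phase_of(sess), session = sess)
  }
  cases
}

#' Sample a synthetic test suite
#'
#' Generates `n_tests` test cases under the configuration: per-pair richness
#' within the configured range (members drawn by per-class lit rates, with
#' rejection), a repeat schedule reusing earlier pairs at the configured
#' gaps, and strictly increasing session indices. Fully deterministic under
#' the configuration seed.
#'
#' @param config A `sim_config`.
#' @param pair Governing `training_pair` (default pair A).
#' @return List of `test_case`s.
#' @export
sample_test_suite <- function(config, pair = training_pair("A")) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_suite(config, classify_pixels(pair)))
}

#' Construct a pigeon evidence-weight model
#'
#' @param pigeon_id Identifier.
#' @param team `"Z+H-"` or `"H+Z-"`.
#' @param weights 7x5 numeric matrix of per-location evidence weights
#'   (positive = supports choosing a pattern containing that lit pixel).
#' @return Object of class `pigeon_model`.
#' @export
pigeon_model <- function(pigeon_id, team, weights) {
  if (!team %in% TEAM_LABELS) stop("unknown team label: ", team)
  weights <- as.matrix(weights)
  stopifnot(all(dim(weights) == c(N_ROWS, N_COLS)), all(is.finite(weights)))
  dimnames(weights) <- list(ROW_LABELS, as.character(seq_len(N_COLS)))
  structure(list(pigeon_id = as.character(pigeon_id), team = team,
                 weights = weights),
            class = "pigeon_model")
}

generate_cohort <- function(config, class_map, planted = salient_sets()) {
  lab <- class_map$labels
  base <- matrix(0, N_ROWS, N_COLS)
  base[lab == "z"] <- config$weight_base
  base[lab == "h"] <- -config$weight_base
  base[parse_locations(planted$Z)] <- config$weight_salient
  base[parse_locations(planted$H)] <- -config$weight_salient
  per_team <- config$n_pigeons / 2L
  team_jit <- list(
    `Z+H-` = matrix(stats::rnorm(N_ROWS * N_COLS, 0, config$team_jitter_sd),
                    N_ROWS, N_COLS),
    `H+Z-` = matrix(stats::rnorm(N_ROWS * N_COLS, 0, config$team_jitter_sd),
                    N_ROWS, N_COLS))
  lapply(seq_len(config$n_pigeons), function(i) {
    team <- if (i <= per_team) "Z+H-" else "H+Z-"
    sign <- if (team == "Z+H-") 1 else -1
    w <- sign * base + team_jit[[team]] +
      matrix(stats::rnorm(N_ROWS * N_COLS, 0, config$jitter_sd),
             N_ROWS, N_COLS)
    pigeon_model(paste0("p", i), team, w)
  })
}

#' Generate the simulated pigeon cohort
#'
#' Shared team-level base weights (ordinary class pixels at
#' `weight_base`, planted salient locations at `weight_salient`, zh and n
#' pixels at zero) with opposite sign conventions across teams, plus
#' per-pigeon Gaussian idiosyncrasy jitter. Deterministic under the
#' configuration seed.
#'
#' @param config A `sim_config`.
#' @param pair Governing `training_pair`.
#' @param planted List with `Z` and `H` location vectors of planted salient
#'   pixels; default the canonical [salient_sets()].
#' @return List of `pigeon_model`s.
#' @export
make_pigeon_cohort <- function(config, pair = training_pair("A"),
                               planted = salient_sets()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_cohort(config, classify_pixels(pair),
                                         planted))
}

#' Evidence a pigeon accrues on a test pair
#'
#' The summed per-pixel evidence `E`: weight total over lit pixels of the
#' pigeon's designated-correct member minus the weight total over lit pixels
#' of the other member. Positive evidence favours the correct choice.
#'
#' @param pigeon A `pigeon_model`.
#' @param case A `test_case`.
#' @return A single numeric evidence value.
#' @export
choice_evidence <- function(pigeon, case) {
  stopifnot(inherits(pigeon, "pigeon_model"), inherits(case, "test_case"))
  correct <- if (pigeon$team == "Z+H-") case$grid_Z else case$grid_H
  other <- if (pigeon$team == "Z+H-") case$grid_H else case$grid_Z
  sum(pigeon$weights[unclass(correct)]) - sum(pigeon$weights[unclass(other)])
}

#' Simulate one pigeon's choices on one test
#'
#' Computes the evidence `E` = (weight sum over lit pixels of the
#' designated-correct member) minus (weight sum over lit pixels of the other
#' member), where the correct member is the Z-like one for a Z+H- bird and
#' the H-like one for an H+Z- bird, and draws
#' `n_correct ~ Binomial(trials, plogis(beta * E))`.
#'
#' @param pigeon A `pigeon_model`.
#' @param case A `test_case`.
#' @param trials Number of test trials (>= 1).
#' @param beta Choice sharpness (>= 0).
#' @param seed Optional seed for a locally scoped RNG.
#' @return A one-row choice-record data frame (see [choice_record()]).
#' @export
simulate_choices <- function(pigeon, case, trials = 20L, beta = 0.1,
                             seed = NULL) {
  stopifnot(inherits(pigeon, "pigeon_model"), inherits(case, "test_case"),
            trials >= 1, beta >= 0)
  p_correct <- stats::plogis(beta * choice_evidence(pigeon, case))
  n_correct <- with_seed(seed, stats::rbinom(1L, trials, p_correct))
  choice_record(case$test_id, pigeon$pigeon_id, pigeon$team, trials,
                n_correct)
}

#' Simulate a full experiment
#'
#' Generates the test suite and pigeon cohort under the configuration and
#' simulates every pigeon's choices on every test. All randomness flows from
#' the single master seed: identical configurations give byte-identical
#' results.
#'
#' @param config A `sim_config`.
#' @param pair Governing `training_pair`.
#' @param planted Planted salient sets, as for [make_pigeon_cohort()].
#' @return Object of class `pigeonpix_sim`: list with `config`, `pair`,
#'   `class_map`, `cases`, `pigeons` and the `choices` table.
#' @examples
#' sim <- simulate_experiment(sim_config(n_tests = 12, n_repeat_pairs = 2,
#'                                       n_triple_pairs = 0, seed = 7))
#' head(sim$choices)
#' @export
simulate_experiment <- function(config = sim_config(),
                                pair = training_pair("A"),
                                planted = salient_sets()) {
  stopifnot(inherits(config, "sim_config"))
  class_map <- classify_pixels(pair)
  out <- with_seed(config$seed, {
    cases <- generate_suite(config, class_map)
    pigeons <- generate_cohort(config, class_map, planted)
    choices <- do.call(rbind, lapply(cases, function(cs)
      do.call(rbind, lapply(pigeons, function(pg)
        simulate_choices(pg, cs, config$trials_per_test, config$beta)))))
    list(cases = cases, pigeons = pigeons, choices = choices)
  })
  structure(c(list(config = config, pair = pair, class_map = class_map),
              out),
            class = "pigeonpix_sim")
}

#' @export
print.pigeonpix_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated experiment: %d tests x %d pigeons x %d trials (seed %d)\n",
    length(x$cases), length(x$pigeons), x$config$trials_per_test,
    x$config$seed))
  cat(sprintf("mean percent correct: %.1f\n", mean(x$choices$percent_correct)))
  invisible(x)
}
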