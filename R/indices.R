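# Discriminability indices for a test pair.
#
# The base index is z_Z + h_H: the number of lit z pixels in the Z-like
# member plus the number of lit h pixels in the H-like member, ranging 0-20.
# Variants add or subtract the ambiguous (zh), neutral (n) and cross-class
# "inhibitory" (h_Z, z_H) lit counts.

#' Pixel-count breakdown and discriminability indices for one test pair
#'
#' Counts, for each member of the pair, the lit pixels in each class of the
#' governing training pair, and derives the discriminability index variants:
#' \describe{
#'   \item{index_base}{`z_Z + h_H`, range 0-20.}
#'   \item{index_minus_inhib}{`index_base - (h_Z + z_H)`: cross-class lit
#'     pixels treated as inhibitory.}
#'   \item{index_plus_zh}{`index_base + zh_lit` (zh counted over both
#'     members, 0-6).}
#'   \item{index_plus_n}{`index_base + n_lit` (n counted over both members).}
#' }
#' With `adjust_translocation = TRUE` each member is first registered against
#' its own training reference (Z-like against Z*, H-like against H*) by
#' [register_to_reference()], converting matrix-centred to pattern-centred
#' counts for translocated patterns; `richness` (total lit pixels of the
#' pair) always uses the raw grids.
#'
#' @param case A `test_case`.
#' @param pair The governing `training_pair`.
#' @param adjust_translocation Apply pattern-centred registration first?
#' @param max_shift Registration search bound, passed to
#'   [register_to_reference()].
#' @return An object of class `index_breakdown`: a named list of counts,
#'   indices and the applied shifts (`shift_Z`, `shift_H`, both `c(0, 0)`
#'   when no adjustment is requested).
#' @examples
#' pair <- training_pair("A")
#' self_test <- test_case(pair$grid_Z, pair$grid_H, test_id = 1)
#' index_breakdown(self_test, pair)$index_base  # 20
#' @export
index_breakdown <- function(case, pair, adjust_translocation = FALSE,
                            max_shift = c(2L, 2L)) {
  stopifnot(inherits(case, "test_case"), inherits(pair, "training_pair"))
  cm <- classify_pixels(pair)
  gZ <- case$grid_Z; gH <- case$grid_H
  shift_Z <- shift_H <- c(0L, 0L)
  if (adjust_translocation) {
    if (count_lit(gZ) > 0L) {
      regZ <- register_to_reference(gZ, pair$grid_Z, max_shift)
      gZ <- regZ$aligned; shift_Z <- regZ$shift
    }
    if (count_lit(gH) > 0L) {
      regH <- register_to_reference(gH, pair$grid_H, max_shift)
      gH <- regH$aligned; shift_H <- regH$shift
    }
  }
  lab <- cm$labels
  cnt <- function(g, cls) sum(unclass(g) & lab == cls)
  z_Z <- cnt(gZ, "z"); h_Z <- cnt(gZ, "h")
  z_H <- cnt(gH, "z"); h_H <- cnt(gH, "h")
  zh_lit <- cnt(gZ, "zh") + cnt(gH, "zh")
  n_lit <- cnt(gZ, "n") + cnt(gH, "n")
  base <- z_Z + h_H
  structure(list(
    test_id = case$test_id,
    z_Z = z_Z, h_H = h_H, z_H = z_H, h_Z = h_Z,
    zh_lit = zh_lit, n_lit = n_lit,
    richness = count_lit(case$grid_Z) + count_lit(case$grid_H),
    index_base = base,
    index_minus_inhib = base - (h_Z + z_H),
    index_plus_zh = base + zh_lit,
    index_plus_n = base + n_lit,
    shift_Z = shift_Z, shift_H = shift_H),
    class = "index_breakdown")
}

#' @export
print.index_breakdown <- function(x, ...) {
  cat(sprintf(
    "Index breakdown (test %s): base=%d  -inhib=%d  +zh=%d  +n=%d\n",
    x$test_id, x$index_base, x$index_minus_inhib, x$index_plus_zh,
    x$index_plus_n))
  cat(sprintf("  z_Z=%d h_H=%d z_H=%d h_Z=%d zh=%d n=%d richness=%d\n",
              x$z_Z, x$h_H, x$z_H, x$h_Z, x$zh_lit, x$n_lit, x$richness))
  if (any(x$shift_Z != 0L) || any(x$shift_H != 0L))
    cat(sprintf("  registration shifts: Z (%d,%d)  H (%d,%d)\n",
                x$shift_Z[1], x$shift_Z[2], x$shift_H[1], x$shift_H[2]))
  invisible(x)
}

#' Index breakdowns for a list of cases, as a data frame
#'
#' One row per test with every [index_breakdown()] field; the stable column
#' layout is the package's TSV report format.
#'
#' @param cases List of `test_case`s.
#' @param pair The governing `training_pair`.
#' @param ... Passed to [index_breakdown()].
#' @return A data frame with columns `test_id, phase, session, z_Z, h_H, z_H,
#'   h_Z, zh_lit, n_lit, richness, index_base, index_minus_inhib,
#'   index_plus_zh, index_plus_n, shift_Z_row, shift_Z_col, shift_H_row,
#'   shift_H_col`.
#' @export
index_table <- function(cases, pair, ...) {
  check_cases(cases)
  rows <- lapply(cases, function(cs) {
    b <- index_breakdown(cs, pair, ...)
    data.frame(test_id = cs$test_id, phase = cs$phase, session = cs$session,
               z_Z = b$z_Z, h_H = b$h_H, z_H = b$z_H, h_Z = b$h_Z,
               zh_lit = b$zh_lit, n_lit = b$n_lit, richness = b$richness,
               index_base = b$index_base,
               index_minus_inhib = b$index_minus_inhib,
               index_plus_zh = b$index_plus_zh,
               index_plus_n = b$index_plus_n,
               shift_Z_row = b$shift_Z[1], shift_Z_col = b$shift_Z[2],
               shift_H_row = b$shift_H[1], shift_H_col = b$shift_H[2])
  })
  do.call(rbind, rows)
}

#' Select index restricted to the salient cluster pixels
#'
#' The number of lit `select_Z` pixels in the Z-like member plus the number
#' of lit `select_H` pixels in the H-like member. With the canonical 8 z and
#' 6 h salient sets ([salient_sets()]) the range is 0-14.
#'
#' @param case A `test_case`.
#' @param select_Z Character vector of z locations (subset of the class
#'   map's z pixels).
#' @param select_H Character vector of h locations.
#' @param pair The governing `training_pair` (defaults to pair A), used to
#'   validate the select sets and, when requested, to register the members.
#' @param adjust_translocation Register members to their training references
#'   first, as for [index_breakdown()].
#' @param max_shift Registration search bound.
#' @return Integer count.
#' @examples
#' pair <- training_pair("A")
#' s <- salient_sets()
#' select_index(test_case(pair$grid_Z, pair$grid_H, 1), s$Z, s$H)  # 14
#' @export
select_index <- function(case, select_Z, select_H, pair = training_pair("A"),
                         adjust_translocation = FALSE, max_shift = c(2L, 2L)) {
  stopifnot(inherits(case, "test_case"))
  cm <- classify_pixels(pair)
  bad_Z <- setdiff(select_Z, class_locations(cm, "z"))
  if (length(bad_Z)) stop("select_Z contains non-z location(s): ",
                          paste(bad_Z, collapse = ", "))
  bad_H <- setdiff(select_H, class_locations(cm, "h"))
  if (length(bad_H)) stop("select_H contains non-h location(s): ",
                          paste(bad_H, collapse = ", "))
  gZ <- case$grid_Z; gH <- case$grid_H
  if (adjust_translocation) {
    if (count_lit(gZ) > 0L)
      gZ <- register_to_reference(gZ, pair$grid_Z, max_shift)$aligned
    if (count_lit(gH) > 0L)
      gH <- register_to_reference(gH, pair$grid_H, max_shift)$aligned
  }
  length(intersect(lit_locations(gZ), select_Z)) +
    length(intersect(lit_locations(gH), select_H))
}

#' Per-location lit-presentation frequencies across a test suite
#'
#' For each of the 35 locations and each pair side, the number of tests in
#' which that location was lit. Raw (matrix-centred) grids are used:
#' translocation adjustments are disregarded in this compilation.
#'
#' @param cases Non-empty list of `test_case`s.
#' @return A list of class `pixel_freq` with integer 7x5 matrices `Z` and
#'   `H` and the number of cases `n`.
#' @export
pixel_presentation_frequencies <- function(cases) {
  check_cases(cases)
  addup <- function(side) {
    Reduce(`+`, lapply(cases, function(cs) unclass(cs[[side]]) * 1L))
  }
  structure(list(Z = addup("grid_Z"), H = addup("grid_H"),
                 n = length(cases)),
            class = "pixel_freq")
}

#' @export
print.pixel_freq <- function(x, ...) {
  cat("Lit-pixel presentation frequencies over", x$n, "tests\n")
  cat("Z-like side:\n"); print(x$Z)
  cat("H-like side:\n"); print(x$H)
  invisible(x)
}
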