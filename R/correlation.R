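# Correlation machinery: index/choice correlograms and pixel-wise
# classification-image maps. Lit/unlit indicators correlated with percent
# choice scores give the point-biserial case, computed as plain Pearson.

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with the validation the pipeline
#' relies on: equal lengths of at least 3, and `NA` (an undefined-result
#' signal, consumed by masks downstream) when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The correlation coefficient, or `NA_real_` if either vector has
#'   zero variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom. `|r| = 1` returns `p = 0` by convention.
#'
#' @param r Correlation coefficient(s).
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value(s).
#' @examples
#' pearson_p(0.30, 84)  # < 0.01
#' @export
pearson_p <- function(r, n) {
  stopifnot(all(n >= 3), all(abs(r) <= 1, na.rm = TRUE))
  t_stat <- abs(r) * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  p
}

#' Correlate a discriminability index variant with choice scores
#'
#' Computes the chosen per-test index over the cases and its Pearson
#' correlation with the per-test percent choice scores.
#'
#' @param cases List of `test_case`s.
#' @param scores Per-test scores: numeric vector (named by `test_id` or in
#'   case order) or a data frame with `test_id` and `score` columns, e.g.
#'   from [test_scores()].
#' @param variant One of `"base"`, `"richness"`, `"minus_inhib"`,
#'   `"plus_zh"`, `"plus_n"`, `"select"`, `"base_adjusted"`.
#' @param pair Governing `training_pair`.
#' @param select_Z,select_H Salient sets for `variant = "select"`; default
#'   [salient_sets()].
#' @param max_shift Registration bound for `"base_adjusted"` / `"select"`.
#' @return List with `r`, `p`, `n`, `variant` and the per-test `index`
#'   vector.
#' @export
index_choice_correlation <- function(cases, scores,
                                     variant = c("base", "richness",
                                                 "minus_inhib", "plus_zh",
                                                 "plus_n", "select",
                                                 "base_adjusted"),
                                     pair = training_pair("A"),
                                     select_Z = salient_sets()$Z,
                                     select_H = salient_sets()$H,
                                     max_shift = c(2L, 2L)) {
  variant <- match.arg(variant)
  check_cases(cases)
  if (length(cases) < 3L) stop("need at least 3 tests")
  s <- align_scores(cases, scores)
  idx <- switch(variant,
    richness = vapply(cases, function(cs)
      count_lit(cs$grid_Z) + count_lit(cs$grid_H), 0L),
    select = vapply(cases, select_index, 0L, select_Z = select_Z,
                    select_H = select_H, pair = pair,
                    adjust_translocation = TRUE, max_shift = max_shift),
    base_adjusted = vapply(cases, function(cs)
      index_breakdown(cs, pair, adjust_translocation = TRUE,
                      max_shift = max_shift)$index_base, 0L),
    {
      field <- paste0("index_", variant)
      vapply(cases, function(cs) index_breakdown(cs, pair)[[field]], 0L)
    })
  if (stats::var(idx) == 0) stop("constant index: correlation undefined")
  r <- pearson_r(as.numeric(idx), s)
  list(r = r, p = pearson_p(r, length(s)), n = length(s),
       variant = variant, index = idx)
}

#' Pixel-wise salience (classification-image) correlation map
#'
#' For every one of the 35 locations, the Pearson correlation between its
#' lit indicator (1/0 across tests, on the requested pair side) and the
#' per-test choice scores. Locations with zero variance (never or always
#' lit) are masked, not assigned r = 0.
#'
#' @param cases List of at least 3 `test_case`s.
#' @param scores Per-test scores (see [index_choice_correlation()]).
#' @param side `"Z"` or `"H"`: which member of each pair to use.
#' @param pair Optional `training_pair`, required when
#'   `adjust_translocation = TRUE`.
#' @param adjust_translocation Register each member to its training
#'   reference before reading the indicators.
#' @param max_shift Registration bound.
#' @return Object of class `pixel_cor_map`: list with 7x5 matrices `r` and
#'   `p` (`NA` where masked), logical matrix `masked`, the number of tests
#'   `n` and `side`.
#' @export
pixelwise_correlation <- function(cases, scores, side = c("Z", "H"),
                                  pair = NULL, adjust_translocation = FALSE,
                                  max_shift = c(2L, 2L)) {
  side <- match.arg(side)
  check_cases(cases)
  if (length(cases) < 3L) stop("need at least 3 tests")
  s <- align_scores(cases, scores)
  grids <- lapply(cases, `[[`, paste0("grid_", side))
  if (adjust_translocation) {
    if (is.null(pair)) stop("adjust_translocation requires the training pair")
    ref <- pair[[paste0("grid_", side)]]
    grids <- lapply(grids, function(g)
      if (count_lit(g) == 0L) g
      else register_to_reference(g, ref, max_shift)$aligned)
  }
  X <- t(vapply(grids, function(g) as.numeric(unclass(g)),
                numeric(N_ROWS * N_COLS)))      # tests x 35, column-major locs
  dims <- list(ROW_LABELS, as.character(seq_len(N_COLS)))
  r <- p <- matrix(NA_real_, N_ROWS, N_COLS, dimnames = dims)
  masked <- matrix(FALSE, N_ROWS, N_COLS, dimnames = dims)
  for (j in seq_len(ncol(X))) {
    if (stats::var(X[, j]) == 0) { masked[j] <- TRUE; next }
    r[j] <- pearson_r(X[, j], s)
  }
  p[!masked] <- pearson_p(r[!masked], length(s))
  structure(list(r = r, p = p, masked = masked, n = length(s), side = side),
            class = "pixel_cor_map")
}

#' @export
print.pixel_cor_map <- function(x, digits = 2, ...) {
  cat(sprintf("Pixel-wise correlation map (%s-like side, n = %d tests; %d masked)\n",
              x$side, x$n, sum(x$masked)))
  show <- ifelse(x$masked, "  .  ", formatC(x$r, digits = digits,
                                            format = "f", width = 5))
  dimnames(show) <- dimnames(x$r)
  print(noquote(show))
  invisible(x)
}

#' Flatten a pixel correlation map to a data frame
#'
#' Rows in row-major location order with the package's stable TSV columns:
#' `row_label`, `col`, `side`, `r`, `p`, `n`, `masked`.
#'
#' @param x A `pixel_cor_map`.
#' @param ... Unused.
#' @return A data frame with 35 rows.
#' @export
as.data.frame.pixel_cor_map <- function(x, ...) {
  grid <- expand.grid(col = seq_len(N_COLS), row = seq_len(N_ROWS))
  data.frame(row_label = ROW_LABELS[grid$row], col = grid$col,
             side = x$side,
             r = x$r[cbind(grid$row, grid$col)],
             p = x$p[cbind(grid$row, grid$col)],
             n = x$n,
             masked = x$masked[cbind(grid$row, grid$col)])
}

#' Top-ranked salient locations of a correlation map
#'
#' Ranks locations by correlation coefficient and returns the `n_top`
#' highest. Following the convention of the published salience figures, the
#' rarely lit outer rows i and vii are excluded by default: their indicators
#' rest on a handful of presentations and their coefficients are dominated
#' by sampling noise.
#'
#' @param map A `pixel_cor_map`.
#' @param n_top Number of locations to return (default 8).
#' @param core_only Restrict ranking to rows ii-vi (default `TRUE`).
#' @return Character vector of location names, highest coefficient first.
#' @export
top_salient_locations <- function(map, n_top = 8L, core_only = TRUE) {
  stopifnot(inherits(map, "pixel_cor_map"))
  r <- map$r
  r[map$masked] <- NA_real_
  if (core_only) r[c(1L, 7L), ] <- NA_real_
  flat <- as.vector(t(r))               # row-major, matches all_locations()
  ord <- order(flat, decreasing = TRUE, na.last = NA)
  all_locations()[utils::head(ord, n_top)]
}
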