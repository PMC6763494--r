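# Cluster extraction on the 7x5 grid and derived analyses.

# run code with a reproducible, locally scoped RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# neighbour offsets for the two supported connectivities
neighbour_offsets <- function(connectivity) {
  if (connectivity == 8L)
    cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))[-5L, , drop = FALSE]
  else
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
}

#' Extract salient pixel clusters from a correlation map
#'
#' Connected components (default 8-neighbourhood: horizontal, vertical and
#' diagonal adjacency) of the locations whose correlation coefficient
#' reaches the salience threshold. Masked locations never enter a cluster.
#'
#' @param map A `pixel_cor_map`, or a bare 7x5 numeric matrix of
#'   coefficients (`NA` = masked/undefined).
#' @param r_threshold Salience threshold, default 0.30 (p < 0.01 at n = 84).
#' @param connectivity 8 (default) or 4.
#' @return Object of class `cluster_set`: list with `clusters` (list of
#'   character vectors of location names, ordered by first member in
#'   row-major order), `r_threshold` and `connectivity`.
#' @export
salient_clusters <- function(map, r_threshold = 0.30, connectivity = 8L) {
  if (inherits(map, "pixel_cor_map")) {
    r <- map$r
    r[map$masked] <- NA_real_
  } else {
    r <- as.matrix(map)
    if (!all(dim(r) == c(N_ROWS, N_COLS)))
      stop("coefficient matrix must be 7x5")
  }
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  supra <- !is.na(r) & r >= r_threshold
  offs <- neighbour_offsets(connectivity)
  labels <- matrix(0L, N_ROWS, N_COLS)
  next_lab <- 0L
  for (rr in seq_len(N_ROWS)) for (cc in seq_len(N_COLS)) {
    if (!supra[rr, cc] || labels[rr, cc] != 0L) next
    next_lab <- next_lab + 1L
    queue <- list(c(rr, cc)); labels[rr, cc] <- next_lab
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(offs))) {
        nr <- cur[1L] + offs[k, 1L]; nc <- cur[2L] + offs[k, 2L]
        if (nr < 1L || nr > N_ROWS || nc < 1L || nc > N_COLS) next
        if (supra[nr, nc] && labels[nr, nc] == 0L) {
          labels[nr, nc] <- next_lab
          queue[[length(queue) + 1L]] <- c(nr, nc)
        }
      }
    }
  }
  clusters <- lapply(seq_len(next_lab), function(lb) {
    idx <- which(t(labels) == lb)          # row-major ordering
    all_locations()[idx]
  })
  structure(list(clusters = clusters, r_threshold = r_threshold,
                 connectivity = connectivity),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("%d cluster(s) at r >= %.2f (%d-neighbour connectivity)\n",
              length(x$clusters), x$r_threshold, x$connectivity))
  for (i in seq_along(x$clusters))
    cat(sprintf("  [%d] %s\n", i, paste(x$clusters[[i]], collapse = " ")))
  invisible(x)
}

#' Correlation of a pooled cluster lit count with choice scores
#'
#' Pools the lit (1) / unlit (0) states of the cluster members on the given
#' pair side into a per-test count, and correlates that count with the
#' choice scores.
#'
#' @param cases List of `test_case`s.
#' @param scores Per-test scores (see [index_choice_correlation()]).
#' @param cluster Non-empty character vector of location names.
#' @param side `"Z"` or `"H"`.
#' @return List with `r`, `p`, `n` and the per-test pooled `count`.
#' @export
pooled_cluster_correlation <- function(cases, scores, cluster,
                                       side = c("Z", "H")) {
  side <- match.arg(side)
  if (length(cluster) == 0L) stop("empty cluster")
  check_cases(cases)
  s <- align_scores(cases, scores)
  cnt <- vapply(cases, function(cs)
    length(intersect(lit_locations(cs[[paste0("grid_", side)]]), cluster)), 0L)
  if (stats::var(cnt) == 0) stop("constant pooled count: correlation undefined")
  r <- pearson_r(as.numeric(cnt), s)
  list(r = r, p = pearson_p(r, length(s)), n = length(s), count = cnt)
}

# Chebyshev distance between two location names
chebyshev_distance <- function(a, b) {
  pa <- parse_locations(a); pb <- parse_locations(b)
  pmax(abs(pa[, 1L] - pb[, 1L]), abs(pa[, 2L] - pb[, 2L]))
}

# all unordered same-set location pairs at the given Chebyshev distances
location_pairs <- function(locs, dist_ok) {
  if (length(locs) < 2L) return(NULL)
  cmb <- utils::combn(sort(locs), 2L)
  d <- vapply(seq_len(ncol(cmb)), function(j)
    chebyshev_distance(cmb[1L, j], cmb[2L, j]), 0)
  keep <- dist_ok(d)
  if (!any(keep)) return(NULL)
  cmb[, keep, drop = FALSE]
}

#' Two-pixel feature analysis: neighbouring vs non-neighbouring pairs
#'
#' Treats any two vertically, horizontally or diagonally neighbouring
#' conjointly lit pixels of the salient z (or h) sets as a candidate
#' configural feature. For each such pair the feature indicator on a test is
#' 1 iff both pixels are lit in the relevant member (Z-like member for z
#' pairs, H-like for h pairs); the indicator is correlated with the choice
#' scores. The same is done for a seeded sample of clearly non-neighbouring
#' (Chebyshev distance >= 2) same-class control pairs. Similar mean
#' correlations in the two groups argue against a distinct multi-pixel
#' feature-extraction strategy.
#'
#' @param cases List of `test_case`s.
#' @param scores Per-test scores.
#' @param select_Z,select_H Salient location sets; default [salient_sets()].
#' @param n_pairs Target number of pairs per group (default 14). If fewer
#'   are available, all available pairs are used and the counts reported.
#' @param seed Seed for sampling the control pairs.
#' @return List with `mean_r_neighbouring`, `mean_r_control`,
#'   `n_neighbouring`, `n_control` and a `detail` data frame (one row per
#'   pair: `group`, `class`, `loc1`, `loc2`, `r`, `p`).
#' @export
feature_pair_analysis <- function(cases, scores,
                                  select_Z = salient_sets()$Z,
                                  select_H = salient_sets()$H,
                                  n_pairs = 14L, seed = 1L) {
  check_cases(cases)
  if (!length(select_Z) || !length(select_H)) stop("empty select set")
  s <- align_scores(cases, scores)

  collect <- function(locs, cls, dist_ok) {
    prs <- location_pairs(locs, dist_ok)
    if (is.null(prs)) return(NULL)
    data.frame(class = cls, loc1 = prs[1L, ], loc2 = prs[2L, ])
  }
  neigh <- rbind(collect(select_Z, "z", function(d) d == 1),
                 collect(select_H, "h", function(d) d == 1))
  ctrl <- rbind(collect(select_Z, "z", function(d) d >= 2),
                collect(select_H, "h", function(d) d >= 2))
  if (is.null(ctrl) || nrow(ctrl) < 1L)
    stop("not enough non-neighbouring candidate pairs")
  take <- function(df, n) {
    if (is.null(df)) stop("no candidate pairs available")
    if (nrow(df) <= n) df
    else df[with_seed(seed, sample.int(nrow(df), n)), , drop = FALSE]
  }
  neigh <- take(neigh, n_pairs)
  ctrl <- take(ctrl, n_pairs)

  pair_r <- function(df, group) {
    rs <- mapply(function(l1, l2, cls) {
      side <- if (cls == "z") "grid_Z" else "grid_H"
      ind <- vapply(cases, function(cs) {
        lit <- lit_locations(cs[[side]])
        as.numeric(l1 %in% lit && l2 %in% lit)
      }, 0)
      if (stats::var(ind) == 0) NA_real_ else pearson_r(ind, s)
    }, df$loc1, df$loc2, df$class)
    df$group <- group
    df$r <- as.numeric(rs)
    df$p <- ifelse(is.na(df$r), NA_real_, pearson_p(df$r, length(s)))
    df
  }
  neigh <- pair_r(neigh, "neighbouring")
  ctrl <- pair_r(ctrl, "control")
  detail <- rbind(neigh, ctrl)
  rownames(detail) <- NULL
  list(mean_r_neighbouring = mean(neigh$r, na.rm = TRUE),
       mean_r_control = mean(ctrl$r, na.rm = TRUE),
       n_neighbouring = nrow(neigh), n_control = nrow(ctrl),
       detail = detail[, c("group", "class", "loc1", "loc2", "r", "p")])
}
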