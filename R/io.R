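# Plain-text file formats: ".pat" pattern files and the choices CSV.
#
# .pat dialect: a record is a header line ">" + identifier (optionally
# "|key=value" metadata fields), followed by exactly 7 lines of exactly 5
# characters, "#" = lit and "." = unlit. Blank lines between records are
# ignored.

#' Read pixel patterns from a .pat file
#'
#' @param path Path to a `.pat` file.
#' @return Named list of `pixel_grid`s (names are the record identifiers);
#'   any `key=value` header metadata is attached as a `meta` attribute on
#'   each grid.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) { i <- i + 1L; next }
    if (!startsWith(line, ">"))
      stop("line ", i, ": expected a '>' record header, got: ", line)
    fields <- strsplit(sub("^>", "", line), "|", fixed = TRUE)[[1L]]
    id <- trimws(fields[1L])
    if (!nzchar(id)) stop("line ", i, ": empty record identifier")
    if (id %in% names(out)) stop("line ", i, ": duplicate id '", id, "'")
    meta <- list()
    for (f in fields[-1L]) {
      kv <- strsplit(f, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop("line ", i, ": malformed metadata field '", f, "'")
      meta[[trimws(kv[1L])]] <- trimws(kv[2L])
    }
    if (i + N_ROWS > length(lines))
      stop("line ", i, ": truncated record '", id, "'")
    body <- lines[(i + 1L):(i + N_ROWS)]
    m <- matrix(FALSE, N_ROWS, N_COLS)
    for (r in seq_len(N_ROWS)) {
      row <- body[r]
      if (nchar(row) != N_COLS)
        stop("line ", i + r, ": expected ", N_COLS, " characters, got ",
             nchar(row))
      ch <- strsplit(row, "")[[1L]]
      if (!all(ch %in% c("#", ".")))
        stop("line ", i + r, ": illegal character(s) in '", row,
             "' (use '#' and '.')")
      m[r, ] <- ch == "#"
    }
    g <- as_pixel_grid(m)
    if (length(meta)) attr(g, "meta") <- meta
    out[[id]] <- g
    i <- i + N_ROWS + 1L
  }
  out
}

#' Write pixel patterns to a .pat file
#'
#' @param grids Named list of `pixel_grid`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(grids, path) {
  stopifnot(length(grids) >= 1L, !is.null(names(grids)),
            all(nzchar(names(grids))))
  lines <- unlist(lapply(names(grids), function(id) {
    g <- as_pixel_grid(grids[[id]])
    meta <- attr(grids[[id]], "meta")
    hdr <- paste0(">", id,
                  if (length(meta))
                    paste0("|", paste(names(meta), unlist(meta), sep = "=",
                                      collapse = "|"))
                  else "")
    c(hdr, apply(ifelse(unclass(g), "#", "."), 1L, paste0, collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a choice table from CSV
#'
#' Expects columns `test_id, pigeon_id, team, n_trials, n_correct` and
#' optionally `percent_correct`. Percent scores are recomputed from the
#' tallies; if a `percent_correct` column is present it is cross-checked
#' against the tallies to within 0.5 percent points.
#'
#' @param path Path to a CSV file.
#' @return Validated choice-record data frame.
#' @export
read_choices <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("test_id", "pigeon_id", "team", "n_trials", "n_correct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("choices CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad_team <- !df$team %in% TEAM_LABELS
  if (any(bad_team))
    stop("unknown team label(s): ",
         paste(unique(df$team[bad_team]), collapse = ", "))
  if (any(df$n_trials < 1L) || any(df$n_correct < 0L) ||
      any(df$n_correct > df$n_trials))
    stop("invalid tallies: need 0 <= n_correct <= n_trials")
  pct <- 100 * df$n_correct / df$n_trials
  if ("percent_correct" %in% names(df)) {
    off <- abs(df$percent_correct - pct) > 0.5
    if (any(off, na.rm = TRUE))
      stop("percent_correct inconsistent with tallies in row(s): ",
           paste(utils::head(which(off), 5L), collapse = ", "))
  }
  df$percent_correct <- pct
  df[, c("test_id", "pigeon_id", "team", "n_trials", "n_correct",
         "percent_correct")]
}

#' Write a choice table to CSV
#'
#' @param choices Choice-record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_choices <- function(choices, path) {
  check_choices(choices)
  utils::write.csv(choices, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cluster set to JSON
#'
#' @param clusters A `cluster_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  jsonlite::write_json(
    list(r_threshold = clusters$r_threshold,
         connectivity = clusters$connectivity,
         clusters = lapply(clusters$clusters, as.character)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
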