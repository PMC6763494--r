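# 7 x 5 binary pixel grids: the universal stimulus representation.
# Rows are labelled i-vii top to bottom, columns 1-5 left to right, so that
# every pixel can be addressed by field-standard names such as "ii5" or "iv2".

ROW_LABELS <- c("i", "ii", "iii", "iv", "v", "vi", "vii")
N_ROWS <- 7L
N_COLS <- 5L

#' Construct a binary 7x5 pixel grid
#'
#' A `pixel_grid` is a 7-row by 5-column logical matrix representing one LED
#' matrix stimulus: `TRUE` = lit, `FALSE` = unlit. Rows are labelled
#' `i`-`vii` top to bottom and columns `1`-`5` left to right, so a location
#' name is the row label followed by the column number (e.g. `"iv3"` is the
#' matrix centre).
#'
#' @param lit Character vector of lit location names (e.g. `c("ii1", "vi5")`).
#'   Duplicates are allowed and collapse to a single lit pixel.
#' @return An object of class `pixel_grid`: a named logical matrix.
#' @examples
#' g <- pixel_grid(c("ii1", "ii2", "iii3"))
#' count_lit(g)
#' @export
pixel_grid <- function(lit = character()) {
  m <- matrix(FALSE, N_ROWS, N_COLS,
              dimnames = list(ROW_LABELS, as.character(seq_len(N_COLS))))
  if (length(lit)) m[parse_locations(lit)] <- TRUE
  structure(m, class = c("pixel_grid", "matrix", "array"))
}

#' Coerce a 7x5 logical/binary matrix to a pixel grid
#'
#' @param m A 7x5 matrix of logical or 0/1 values.
#' @return A `pixel_grid`.
#' @export
as_pixel_grid <- function(m) {
  if (inherits(m, "pixel_grid")) return(m)
  m <- as.matrix(m)
  if (!all(dim(m) == c(N_ROWS, N_COLS)))
    stop("a pixel grid must be 7 rows by 5 columns, got ",
         nrow(m), "x", ncol(m))
  mm <- matrix(as.logical(m), N_ROWS, N_COLS,
               dimnames = list(ROW_LABELS, as.character(seq_len(N_COLS))))
  if (anyNA(mm)) stop("pixel grid values must be lit or unlit (no NA)")
  structure(mm, class = c("pixel_grid", "matrix", "array"))
}

#' Parse pixel location names into row/column indices
#'
#' @param loc Character vector like `c("ii5", "vi1")`.
#' @return A two-column integer matrix of (row, col) indices.
#' @export
parse_locations <- function(loc) {
  m <- regmatches(loc, regexec("^(vii|vi|v|iv|iii|ii|i)([1-5])$", loc))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed pixel location name(s): ",
         paste(loc[bad], collapse = ", "))
  rows <- match(vapply(m, `[`, "", 2L), ROW_LABELS)
  cols <- as.integer(vapply(m, `[`, "", 3L))
  cbind(row = rows, col = cols)
}

#' Name pixel locations from row/column indices
#'
#' @param row,col Integer vectors of row (1-7) and column (1-5) indices.
#' @return Character vector of location names.
#' @export
location_name <- function(row, col) {
  stopifnot(all(row >= 1 & row <= N_ROWS), all(col >= 1 & col <= N_COLS))
  paste0(ROW_LABELS[row], col)
}

#' All 35 location names in row-major order
#' @return Character vector of length 35.
#' @export
all_locations <- function() {
  as.vector(t(outer(ROW_LABELS, seq_len(N_COLS), paste0)))
}

#' Lit locations of a grid
#'
#' @param grid A `pixel_grid`.
#' @return Character vector of lit location names in row-major order.
#' @export
lit_locations <- function(grid) {
  grid <- as_pixel_grid(grid)
  idx <- which(t(unclass(grid)))          # row-major order
  all_locations()[idx]
}

#' Count lit pixels
#'
#' @param grid A `pixel_grid`.
#' @return Integer in 0..35.
#' @export
count_lit <- function(grid) sum(as_pixel_grid(grid))

#' @export
print.pixel_grid <- function(x, ...) {
  chars <- ifelse(unclass(x), "#", ".")
  cat(paste0(format(ROW_LABELS, width = 4), " ",
             apply(chars, 1L, paste0, collapse = ""),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Translate a pixel grid within the 7x5 frame
#'
#' Every lit pixel moves by `d_row` rows (positive = south/down) and `d_col`
#' columns (positive = east/right). Pixels shifted beyond the frame are
#' dropped (curtailment); vacated locations become unlit. There is no
#' wrap-around: this mirrors the pixel-curtailed translocated stimuli used in
#' generalization testing.
#'
#' @param grid A `pixel_grid`.
#' @param d_row Signed row shift, `|d_row| <= 6`.
#' @param d_col Signed column shift, `|d_col| <= 4`.
#' @return The translated `pixel_grid`.
#' @export
translate_grid <- function(grid, d_row, d_col) {
  grid <- as_pixel_grid(grid)
  stopifnot(length(d_row) == 1L, length(d_col) == 1L)
  if (abs(d_row) > N_ROWS - 1L || abs(d_col) > N_COLS - 1L)
    stop("shift magnitude (", d_row, ", ", d_col, ") outside the frame bounds")
  out <- pixel_grid()
  idx <- which(unclass(grid), arr.ind = TRUE)
  if (nrow(idx)) {
    idx[, 1L] <- idx[, 1L] + as.integer(d_row)
    idx[, 2L] <- idx[, 2L] + as.integer(d_col)
    keep <- idx[, 1L] >= 1L & idx[, 1L] <= N_ROWS &
            idx[, 2L] >= 1L & idx[, 2L] <= N_COLS
    out[idx[keep, , drop = FALSE]] <- TRUE
  }
  out
}

#' Rotate the 5x5 core of a grid by 90 degrees clockwise
#'
#' The central 5x5 block (rows ii-vi) is rotated in place; the outer rows i
#' and vii must be unlit and are left unchanged. Used to build the rotated
#' test pairs.
#'
#' @param grid A `pixel_grid` whose lit pixels all lie in rows ii-vi.
#' @return The rotated `pixel_grid`.
#' @export
rotate90_core <- function(grid) {
  grid <- as_pixel_grid(grid)
  if (any(grid[c(1L, 7L), ]))
    stop("rotate90_core requires all lit pixels within the 5x5 core (rows ii-vi)")
  core <- unclass(grid)[2:6, , drop = FALSE]
  out <- unclass(grid)
  out[2:6, ] <- t(core[5:1, , drop = FALSE])   # clockwise rotation
  as_pixel_grid(out)
}

#' Register a test grid to a reference by translation
#'
#' Searches all integer shifts with `|d_row| <= max_shift[1]` and
#' `|d_col| <= max_shift[2]` and selects the shift of `test_grid` that
#' maximizes the number of lit pixels coinciding with lit pixels of
#' `reference_grid`. Ties are broken by smaller `|d_row| + |d_col|`, then by
#' deterministic scan order (north before south, west before east). This is
#' the pattern-centred re-registration applied to translocated test patterns
#' before pixel classification; shifts beyond `max_shift` are never applied,
#' reflecting the bounded translational invariance observed behaviourally.
#'
#' @param test_grid A `pixel_grid` to align.
#' @param reference_grid The training reference `pixel_grid`.
#' @param max_shift Integer vector `c(rows, cols)`, default `c(2, 2)`.
#' @return A list with elements `shift` (the applied `c(d_row, d_col)`),
#'   `aligned` (the shifted test grid), `overlap` (matched lit count) and
#'   `empty` (`TRUE` when the test grid had no lit pixel, in which case the
#'   shift is `c(0, 0)` and a warning is issued).
#' @export
register_to_reference <- function(test_grid, reference_grid,
                                  max_shift = c(2L, 2L)) {
  test_grid <- as_pixel_grid(test_grid)
  reference_grid <- as_pixel_grid(reference_grid)
  stopifnot(length(max_shift) == 2L, all(max_shift >= 0))
  if (count_lit(test_grid) == 0L) {
    warning("empty test grid: registration shift set to (0, 0)")
    return(list(shift = c(0L, 0L), aligned = test_grid,
                overlap = 0L, empty = TRUE))
  }
  best <- NULL
  for (dr in seq.int(-max_shift[1L], max_shift[1L])) {
    for (dc in seq.int(-max_shift[2L], max_shift[2L])) {
      ov <- sum(translate_grid(test_grid, dr, dc) & reference_grid)
      cand <- list(shift = c(as.integer(dr), as.integer(dc)), overlap = ov)
      if (is.null(best) ||
          ov > best$overlap ||
          (ov == best$overlap &&
           sum(abs(cand$shift)) < sum(abs(best$shift))))
        best <- cand
    }
  }
  list(shift = best$shift,
       aligned = translate_grid(test_grid, best$shift[1L], best$shift[2L]),
       overlap = as.integer(best$overlap), empty = FALSE)
}
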