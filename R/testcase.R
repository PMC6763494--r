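# Test sessions: one generalization test = one pattern pair plus identifiers.

#' Construct a test case
#'
#' One generalization test session: a pair of unreinforced test patterns, the
#' member judged Z-like and the member judged H-like, plus bookkeeping fields
#' used by the replication and cohort analyses.
#'
#' @param grid_Z,grid_H `pixel_grid`s for the Z-like and H-like members.
#' @param test_id Unique integer test identifier.
#' @param phase Experimental phase, `"I"`, `"II"` or `"III"`.
#' @param session Session index (strictly increasing across a suite);
#'   defaults to `test_id`.
#' @param repeat_of `test_id` of the previous presentation of the identical
#'   pair, or `NA` for a first presentation.
#' @param translocated Logical flag: was at least one member shown displaced
#'   from its trained matrix position?
#' @return An object of class `test_case`.
#' @export
test_case <- function(grid_Z, grid_H, test_id, phase = "I",
                      session = test_id, repeat_of = NA_integer_,
                      translocated = FALSE) {
  stopifnot(length(test_id) == 1L, is.finite(test_id),
            phase %in% c("I", "II", "III"),
            length(session) == 1L, is.finite(session))
  structure(list(test_id = as.integer(test_id), phase = phase,
                 session = as.integer(session),
                 grid_Z = as_pixel_grid(grid_Z),
                 grid_H = as_pixel_grid(grid_H),
                 repeat_of = as.integer(repeat_of),
                 translocated = isTRUE(translocated)),
            class = "test_case")
}

#' @export
print.test_case <- function(x, ...) {
  cat(sprintf("Test %d (phase %s, session %d%s%s)\n", x$test_id, x$phase,
              x$session,
              if (!is.na(x$repeat_of)) paste0(", repeat of ", x$repeat_of) else "",
              if (x$translocated) ", translocated" else ""))
  cat("Z-like member:\n"); print(x$grid_Z)
  cat("H-like member:\n"); print(x$grid_H)
  invisible(x)
}

#' Content-addressed identity key of a pattern
#'
#' Serializes a grid to a 35-character bit string (row-major), so that "the
#' same pattern" in the part-repeat/relativity analysis means bit-exact
#' equality of lit locations.
#'
#' @param grid A `pixel_grid`.
#' @return A single character string.
#' @export
pattern_key <- function(grid) {
  paste(as.integer(t(unclass(as_pixel_grid(grid)))), collapse = "")
}

# internal: validate a list of test cases, unique ids
check_cases <- function(cases) {
  if (length(cases) == 0L) stop("empty test case list")
  ok <- vapply(cases, inherits, TRUE, what = "test_case")
  if (!all(ok)) stop("all elements must be test_case objects")
  ids <- vapply(cases, `[[`, 1L, "test_id")
  if (anyDuplicated(ids)) stop("duplicate test_id in case list")
  invisible(ids)
}

# internal: align a named score vector (or data.frame) to cases
align_scores <- function(cases, scores) {
  ids <- vapply(cases, `[[`, 1L, "test_id")
  if (is.data.frame(scores)) {
    stopifnot(all(c("test_id", "score") %in% names(scores)))
    scores <- stats::setNames(scores$score, scores$test_id)
  }
  if (!is.null(names(scores))) {
    miss <- setdiff(as.character(ids), names(scores))
    if (length(miss)) stop("missing scores for test id(s): ",
                           paste(miss, collapse = ", "))
    return(as.numeric(scores[as.character(ids)]))
  }
  if (length(scores) != length(cases))
    stop("unnamed score vector must have one score per case")
  as.numeric(scores)
}
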