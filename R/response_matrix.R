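#' Ordinal response matrix with missing and not-applicable codes
#'
#' Container for persons x items polytomous responses on the integer scale
#' `0 .. m_i - 1`. Two kinds of non-response are kept distinct in storage:
#' ordinary missing values (stored as `NA`, serialized as `"NA"`) and
#' "not applicable" responses (tracked in a parallel logical matrix,
#' serialized as `"NAP"`). Both are treated as ignorable by every
#' downstream likelihood, because a not-applicable answer carries no
#' ordinal information, but the distinction is preserved for reporting.
#'
#' @param x integer matrix (or data frame) of responses, persons in rows.
#'   Entries must lie in `0 .. n_categories[i] - 1` or be `NA`.
#' @param n_categories integer scalar or per-item vector, number of ordered
#'   categories per item (>= 2). Default 5 (five-point Likert).
#' @param polarity character vector, `"positive"` or `"negative"` per item.
#'   Negative items are reverse-worded: raw high codes mean a worse
#'   experience and are flipped by [reverse_score()].
#' @param labels item labels; defaults to the column names of `x`.
#' @param nap logical matrix marking not-applicable entries (these must be
#'   `NA` in `x`).
#' @return An object of class `"response_matrix"`.
#' @seealso [reverse_score()], [read_responses()], [write_responses()]
#' @export
response_matrix <- function(x, n_categories = 5L, polarity = NULL,
                            labels = colnames(x), nap = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  k <- ncol(x)
  if (k < 1L) stop("need at least one item")
  n_categories <- as.integer(rep_len(n_categories, k))
  if (any(n_categories < 2L)) stop("every item needs >= 2 categories")
  if (is.null(labels)) labels <- paste0("I", seq_len(k))
  if (anyDuplicated(labels)) stop("item labels must be unique")
  if (is.null(polarity)) polarity <- rep("positive", k)
  polarity <- match.arg(rep_len(polarity, k), c("positive", "negative"),
                        several.ok = TRUE)
  if (is.null(nap)) {
    nap <- matrix(FALSE, nrow(x), k)
  } else {
    nap <- as.matrix(nap)
    if (!identical(dim(nap), dim(x))) stop("'nap' dimensions must match 'x'")
    if (any(nap & !is.na(x))) stop("NAP entries must be NA in 'x'")
  }
  bad <- sweep(x, 2L, n_categories - 1L, ">") | x < 0L
  if (any(bad, na.rm = TRUE))
    stop("responses outside 0..(n_categories-1) found")
  colnames(x) <- labels
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  structure(x,
            n_categories = n_categories,
            polarity = polarity,
            nap = nap,
            reversed = FALSE,
            class = c("response_matrix", "matrix", "array"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix: %d persons x %d items, %d..%d categories>\n",
              nrow(x), ncol(x), min(n_categories(x)), max(n_categories(x))))
  cat(sprintf("  missing %.1f%%, not-applicable %.1f%%, reverse-scored: %s\n",
              100 * mean(is.na(unclass(x)) & !attr(x, "nap")),
              100 * mean(attr(x, "nap")),
              if (isTRUE(attr(x, "reversed"))) "yes" else "no"))
  invisible(x)
}

#' @rdname response_matrix
#' @param rm a `response_matrix`.
#' @export
n_categories <- function(rm) attr(rm, "n_categories")

#' @rdname response_matrix
#' @export
item_labels <- function(rm) colnames(rm)

#' Observed responses as a plain matrix
#'
#' Returns the integer response matrix with `NA` wherever the entry is
#' missing *or* not applicable — the view every likelihood-based routine
#' consumes.
#'
#' @param rm a [response_matrix()].
#' @return integer matrix with `NA` for all non-responses.
#' @export
observed <- function(rm) {
  out <- unclass(rm)
  attributes(out) <- attributes(out)[c("dim", "dimnames")]
  out
}

#' Reverse-score negatively worded items
#'
#' Flips the codes of items flagged `polarity == "negative"` via
#' `x -> (m - 1) - x`, so that higher codes consistently mean a better
#' experience. The operation is an involution: applying it twice restores
#' the original coding (a `reversed` flag records the current state; the
#' polarity metadata always describes the original wording).
#'
#' @param rm a [response_matrix()].
#' @return the reverse-scored `response_matrix`.
#' @export
reverse_score <- function(rm) {
  neg <- attr(rm, "polarity") == "negative"
  if (any(neg)) {
    m <- attr(rm, "n_categories")
    for (i in which(neg)) rm[, i] <- (m[i] - 1L) - rm[, i]
  }
  attr(rm, "reversed") <- !isTRUE(attr(rm, "reversed"))
  rm
}

is_reversed <- function(rm) isTRUE(attr(rm, "reversed"))

# ensure positive orientation before analysis; no-op if already reversed
ensure_reversed <- function(rm) if (is_reversed(rm)) rm else reverse_score(rm)

#' Read / write response matrices as CSV
#'
#' The on-disk format is a plain CSV with a header row of item labels and a
#' leading `person_id` column. Missing responses are written as the literal
#' string `NA` and not-applicable responses as `NAP` (both case-sensitive).
#'
#' @param path file path.
#' @param n_categories,polarity forwarded to [response_matrix()].
#' @return [read_responses()] returns a `response_matrix`;
#'   [write_responses()] returns `path` invisibly.
#' @export
read_responses <- function(path, n_categories = 5L, polarity = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = character())
  ids <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  nap <- as.matrix(df == "NAP")
  dimnames(nap) <- NULL
  xm <- suppressWarnings(vapply(df, function(col) {
    col[col %in% c("NA", "NAP", "")] <- NA_character_
    as.integer(col)
  }, integer(nrow(df))))
  if (nrow(df) == 1L) xm <- matrix(xm, nrow = 1L, dimnames = list(NULL, names(df)))
  rm <- response_matrix(xm, n_categories = n_categories, polarity = polarity,
                        labels = names(df), nap = nap)
  rownames(rm) <- ids
  rm
}

#' @rdname read_responses
#' @param rm a [response_matrix()].
#' @export
write_responses <- function(rm, path) {
  ch <- matrix(as.character(unclass(rm)), nrow(rm), ncol(rm))
  ch[is.na(unclass(rm))] <- "NA"
  ch[attr(rm, "nap")] <- "NAP"
  df <- data.frame(person_id = rownames(rm), ch, check.names = FALSE)
  names(df) <- c("person_id", colnames(rm))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
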