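# Forward feature selection with redundancy sharing: each introduced
# feature's relevance to the response is divided by its summed redundancy
# (including the self term, which is 1) against everything introduced, and
# candidates are admitted greedily while the shared total keeps growing.

#' Redundancy-shared score of a feature set
#'
#' `sum_{i in E} rel[i] / sum_{j in E} red[i, j]`, where `rel[i]` is the
#' dependence of feature i on the response and `red[i, j]` the pairwise
#' dependence between features i and j (`red[i, i] == 1`).
#'
#' @param relevance Numeric vector of per-feature relevance scores.
#' @param redundancy Symmetric matrix of pairwise feature dependences with
#'   unit diagonal.
#' @param members Integer indices of the feature set E.
#' @return Scalar score.
#' @export
share_score <- function(relevance, redundancy, members) {
  if (!length(members)) return(0)
  sum(vapply(members, function(i)
    relevance[i] / sum(redundancy[i, members]), numeric(1)))
}

#' Forward feature selection with redundancy sharing
#'
#' Greedily introduces the candidate that maximizes the shared score of
#' the enlarged set; stops as soon as no candidate increases the score.
#' With `forced = TRUE` introduction additionally stops once the relative
#' gain drops to 1% or less, trading a slightly smaller set for speed.
#' The dependence measure defaults to [chimic_score()] and must map
#' identical vectors to 1, independent ones towards 0.
#'
#' @param features Numeric matrix, one column per feature (named columns
#'   recommended).
#' @param y Binary response vector (0/1).
#' @param alpha Local-test level passed to the dependence measure.
#' @param forced Apply the 1% relative-gain early stop (default `FALSE`).
#' @param measure Function `(x, y, alpha) -> list(value = ...)` used for
#'   both relevance and redundancy.
#' @return Object of class `chidt_selection`: `selected` (column indices
#'   in introduction order), `names`, `relevance`, `score_history`.
#' @export
select_features <- function(features, y, alpha = 0.05, forced = FALSE,
                            measure = chimic_score) {
  if (!is.matrix(features) || ncol(features) < 1L)
    stop("features must be a matrix with at least one column")
  p <- ncol(features)
  relevance <- vapply(seq_len(p), function(i)
    measure(features[, i], y, alpha)$value, numeric(1))

  redundancy <- matrix(NA_real_, p, p)
  diag(redundancy) <- 1
  red <- function(i, j) {
    if (is.na(redundancy[i, j])) {
      v <- measure(features[, i], features[, j], alpha)$value
      redundancy[i, j] <<- v
      redundancy[j, i] <<- v
    }
    redundancy[i, j]
  }

  selected <- integer()
  score <- 0
  history <- numeric()
  remaining <- seq_len(p)
  repeat {
    if (!length(remaining)) break
    cand_scores <- vapply(remaining, function(cand) {
      e <- c(selected, cand)
      for (s in selected) red(cand, s)     # materialize needed entries
      share_score(relevance, redundancy, e)
    }, numeric(1))
    best <- which.max(cand_scores)          # ties: lowest original index
    cand <- remaining[best]
    new_score <- cand_scores[best]
    if (new_score <= score) break           # no increase: stop, discard
    if (forced && length(selected) &&
        (new_score - score) / score <= 0.01) break
    selected <- c(selected, cand)
    score <- new_score
    history <- c(history, score)
    remaining <- setdiff(remaining, cand)
  }
  structure(list(selected = selected,
                 names = if (!is.null(colnames(features)))
                   colnames(features)[selected] else as.character(selected),
                 relevance = relevance,
                 score_history = history),
            class = "chidt_selection")
}

#' @export
print.chidt_selection <- function(x, ...) {
  cat("Redundancy-shared forward selection:", length(x$selected),
      "features introduced\n")
  if (length(x$selected))
    cat(paste(sprintf("%2d. %s (score %.5f)", seq_along(x$selected),
                      x$names, x$score_history), collapse = "\n"), "\n")
  invisible(x)
}
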