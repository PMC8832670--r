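# End-to-end train / predict / evaluate workflows and the versioned,
# human-readable model file.

MODEL_SCHEMA_VERSION <- 1L

#' Train a succinylation-site prediction model
#'
#' Runs the full pipeline on labelled fragments: key-position selection
#' via compressed-table chi-square, difference-table construction,
#' positional + compositional encoding, redundancy-shared forward feature
#' selection, and the decision-table fit. The difference table and the
#' discretizations are frozen at fit time; prediction-time fragments are
#' encoded against them.
#'
#' @param fragments Labelled `chidt_fragments` (labels 0/1, both present).
#' @param alpha Significance level shared by every local chi-square gate.
#' @param forced Use the 1% relative-gain forced stop in feature
#'   selection (default `TRUE`, as in routine use).
#' @return Object of class `chidt_model`.
#' @export
suc_train <- function(fragments, alpha = 0.05, forced = TRUE) {
  y <- fragments$label
  if (anyNA(y) || length(unique(y)) < 2L)
    stop("training fragments must carry both positive and negative labels")
  keypos <- select_key_positions(fragments, alpha = alpha)
  dtable <- build_difference_table(fragments, keypos$key_offsets)
  X <- encode_features(fragments, keypos, dtable)
  sel <- select_features(X, y, alpha = alpha, forced = forced)
  if (!length(sel$selected)) stop("feature selection retained no feature")
  fit <- chidt_fit(X[, sel$selected, drop = FALSE], y, alpha = alpha)
  structure(list(version = MODEL_SCHEMA_VERSION,
                 flank = attr(fragments, "flank"),
                 alpha = alpha, forced = forced,
                 keypos = keypos, dtable = dtable,
                 selection = sel, fit = fit),
            class = "chidt_model")
}

#' @export
print.chidt_model <- function(x, ...) {
  cat("Succinylation-site model (schema v", x$version, ")\n", sep = "")
  cat("  key offsets:", paste(x$keypos$key_offsets, collapse = ", "),
      " (chi2_ave ", format(x$keypos$chi2_ave), ")\n", sep = "")
  cat("  window:", x$keypos$window[1], "...", x$keypos$window[2], "\n")
  cat("  retained features:", paste(x$selection$names, collapse = ", "), "\n")
  cat("  rules:", length(x$fit$rules$pos_count),
      " theta:", format(x$fit$rules$theta), "\n")
  invisible(x)
}

#' Predict candidate sites with a trained model
#'
#' @param object A `chidt_model`.
#' @param fragments `chidt_fragments` to score (labels ignored).
#' @param method `"chidt"` (weighted decision) or `"majority"` baseline.
#' @param ... Unused.
#' @return Data frame `protein_id`, `position`, `predicted` (0/1).
#' @export
predict.chidt_model <- function(object, fragments,
                                method = c("chidt", "majority"), ...) {
  method <- match.arg(method)
  X <- encode_features(fragments, object$keypos, object$dtable)
  X <- X[, object$fit$feature_names, drop = FALSE]
  data.frame(protein_id = fragments$protein_id,
             position = fragments$position,
             predicted = predict(object$fit, X, method = method),
             stringsAsFactors = FALSE)
}

#' Evaluate predictions against a labelled truth table
#'
#' Rows are aligned on `(protein_id, position)`; a key present on one
#' side only is an error naming the first offenders.
#'
#' @param predictions Data frame from [predict.chidt_model()].
#' @param truth Data frame with `protein_id`, `position`, `label`.
#' @return A `chidt_confusion`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  kp <- paste(predictions$protein_id, predictions$position)
  kt <- paste(truth$protein_id, truth$position)
  miss <- setdiff(kt, kp); extra <- setdiff(kp, kt)
  if (length(miss) || length(extra))
    stop("prediction/truth key mismatch; first offenders: ",
         paste(utils::head(c(miss, extra), 5L), collapse = ", "))
  ord <- match(kt, kp)
  summarize_predictions(truth$label, predictions$predicted[ord])
}

# ---- model serialization --------------------------------------------------

#' Write a trained model to a versioned JSON file
#'
#' All numeric content (difference-table scores, discretization
#' boundaries, rule counts, theta) is stored at full precision; the file
#' is structured text and human-inspectable.
#'
#' @param model A `chidt_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  fit <- model$fit
  obj <- list(
    schema_version = model$version,
    flank = model$flank,
    alpha = model$alpha,
    forced = model$forced,
    keypos = list(chi2 = as.list(model$keypos$chi2),
                  chi2_ave = model$keypos$chi2_ave,
                  key_offsets = model$keypos$key_offsets,
                  window = model$keypos$window,
                  flank = model$keypos$flank),
    dtable = list(scores = model$dtable$scores,
                  offsets = colnames(model$dtable$scores),
                  base_tables = lapply(model$dtable$base_tables, function(t)
                    list(pos = unname(t[1L, ]), neg = unname(t[2L, ])))),
    selection = list(names = model$selection$names,
                     score_history = model$selection$score_history),
    fit = list(
      feature_names = fit$feature_names,
      introduced = fit$introduced,
      alpha = fit$alpha,
      discretizations = lapply(fit$discretizations, function(d)
        if (is.null(d)) NULL else d[c("values", "bin_of_val", "r", "boundaries")]),
      rules = list(conditions = fit$rules$conditions,
                   pos_count = fit$rules$pos_count,
                   neg_count = fit$rules$neg_count,
                   weighted_neg = fit$rules$weighted_neg,
                   n_pos = fit$rules$n_pos, n_neg = fit$rules$n_neg,
                   theta = fit$rules$theta)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `chidt_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != MODEL_SCHEMA_VERSION)
    stop("unsupported model schema version")
  keypos <- structure(list(chi2 = unlist(obj$keypos$chi2),
                           chi2_ave = obj$keypos$chi2_ave,
                           key_offsets = as.integer(obj$keypos$key_offsets),
                           window = as.integer(obj$keypos$window),
                           compressed = NULL,
                           flank = as.integer(obj$keypos$flank)),
                      class = "chidt_keypos")
  scores <- obj$dtable$scores
  if (is.list(scores)) scores <- do.call(rbind, scores)
  scores <- matrix(as.numeric(scores), nrow = 20L,
                   dimnames = list(AA20, obj$dtable$offsets))
  base <- lapply(obj$dtable$base_tables, function(t)
    contingency_table(t$pos, t$neg, AA20))
  names(base) <- obj$dtable$offsets
  dtable <- structure(list(scores = scores, base_tables = base),
                      class = "chidt_dtable")
  fit_obj <- obj$fit
  disc <- lapply(fit_obj$discretizations, function(d) {
    if (is.null(d)) return(NULL)
    list(values = as.numeric(d$values),
         bin_of_val = as.integer(d$bin_of_val),
         r = as.integer(d$r),
         boundaries = as.numeric(d$boundaries))
  })
  names(disc) <- fit_obj$feature_names
  conds <- lapply(fit_obj$rules$conditions, function(cl)
    lapply(cl, function(rng) as.integer(unlist(rng))))
  rules <- structure(list(conditions = conds,
                          pos_count = as.numeric(fit_obj$rules$pos_count),
                          neg_count = as.numeric(fit_obj$rules$neg_count),
                          n_pos = fit_obj$rules$n_pos,
                          n_neg = fit_obj$rules$n_neg,
                          feature_names = fit_obj$feature_names,
                          discretizations = disc,
                          theta = fit_obj$rules$theta,
                          weighted_neg = as.numeric(fit_obj$rules$weighted_neg)),
                     class = "chidt_rules")
  fit <- structure(list(discretizations = disc,
                        introduced = fit_obj$introduced,
                        rules = rules,
                        alpha = fit_obj$alpha,
                        feature_names = fit_obj$feature_names),
                   class = "chidt_fit")
  fit$decisions <- rule_decisions(rules)
  structure(list(version = obj$schema_version,
                 flank = as.integer(obj$flank),
                 alpha = obj$alpha, forced = obj$forced,
                 keypos = keypos, dtable = dtable,
                 selection = list(names = obj$selection$names,
                                  score_history = obj$selection$score_history),
                 fit = fit),
            class = "chidt_model")
}
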