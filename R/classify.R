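# Growth phenotype prediction.
#
# Strain viability is predicted from the binary feasibility profile of a
# knockout. On each training split, variables whose training essentiality
# score exceeds 0.5 are selected as features; a linear soft-margin support
# vector machine then determines an optimal hyperplane separating viable
# from inviable samples, and a test strain is classified by the side of
# the hyperplane its feasibility vector lies on. Repeated randomized
# hold-out validation reports the true positive rate (inviable phenotypes
# correctly predicted) and the false positive rate (viable phenotypes
# predicted inviable).

#' Select feature variables by training-set essentiality score
#'
#' A variable is used as a feature iff its essentiality score computed on
#' the training rows alone is strictly greater than 0.5; variables never
#' blocked in training have an undefined score and are excluded. No
#' test-set information is consulted.
#'
#' @param train_fmatrix a `refnet_fmatrix` restricted to training rows
#'   (see [fm_subset()]).
#' @param train_phenotypes phenotypes of the training rows (defaults to
#'   those stored in the matrix).
#' @return Character vector of feature variable ids (may be empty, with a
#'   warning; the classifier then falls back to the majority class).
#' @export
select_features <- function(train_fmatrix, train_phenotypes = NULL) {
  sc <- essentiality_scores(train_fmatrix, train_phenotypes)
  feats <- sc$variable[!is.na(sc$score) & sc$score > 0.5]
  if (length(feats) == 0L)
    warning("no variable exceeds essentiality score 0.5 in training; ",
            "classifier will predict the majority class", call. = FALSE)
  feats
}

feasibility_design <- function(fmatrix, features) {
  j <- match(features, fmatrix$objects)
  if (anyNA(j))
    stop("feature variables absent from matrix: ",
         paste(features[is.na(j)], collapse = ", "), call. = FALSE)
  x <- 1 - as.matrix(fmatrix$blocked[, j, drop = FALSE]) * 1
  colnames(x) <- features
  x
}

#' Train the max-margin viability classifier
#'
#' Fits a linear soft-margin support vector machine (cost constant 1 by
#' default) on the binary feasibility vectors of the training strains,
#' restricted to the selected feature variables. The decision rule is
#' reduced to an explicit weight vector and offset so prediction is a
#' deterministic sign check; a sample exactly on the hyperplane is
#' predicted viable (conservative toward the majority class).
#'
#' @param train_fmatrix a `refnet_fmatrix` restricted to training rows.
#' @param features feature variable ids from [select_features()].
#' @param train_phenotypes training phenotypes (defaults to stored ones).
#' @param cost soft-margin constant C of the SVM.
#' @return An object of class `refnet_classifier` with the weight vector
#'   (named by feature), offset, and feature list; or a majority-class
#'   fallback model when `features` is empty.
#' @export
train_classifier <- function(train_fmatrix, features,
                             train_phenotypes = NULL, cost = 1) {
  y <- check_phenotypes(train_fmatrix, train_phenotypes)
  if (length(unique(y)) < 2L)
    stop("training set contains a single phenotype class", call. = FALSE)
  if (length(features) == 0L) {
    maj <- names(which.max(table(y)))
    return(structure(list(kind = "majority", majority = maj,
                          features = character()),
                     class = "refnet_classifier"))
  }
  x <- feasibility_design(train_fmatrix, features)
  yf <- factor(y, levels = c("inviable", "viable"))
  fit <- e1071::svm(x = x, y = yf, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))  # decision = x %*% w - rho
  rho <- fit$rho
  # e1071 orients the decision value toward its first encountered label;
  # calibrate the sign so positive always means inviable.
  dec <- drop(x %*% w) - rho
  agree <- mean((dec > 0) == (yf == "inviable"))
  orient <- if (agree >= 0.5) 1 else -1
  structure(list(kind = "svm", weights = orient * w, offset = orient * rho,
                 features = features, cost = cost,
                 svm_fit = fit),
            class = "refnet_classifier")
}

#' @export
print.refnet_classifier <- function(x, ...) {
  if (x$kind == "majority")
    cat(sprintf("<refnet_classifier> majority-class fallback: %s\n",
                x$majority))
  else
    cat(sprintf("<refnet_classifier> linear SVM on %d features (cost %g)\n",
                length(x$features), x$cost))
  invisible(x)
}

#' Predict strain viability
#'
#' Computes the decision value of each sample's feasibility vector and
#' reports `"inviable"` for samples strictly on the inviable side of the
#' hyperplane; boundary samples (decision value 0) are predicted viable.
#'
#' @param object a `refnet_classifier`.
#' @param fmatrix a `refnet_fmatrix` whose columns include the model's
#'   features.
#' @param ... unused.
#' @return Character vector of `"viable"`/`"inviable"` predictions.
#' @export
predict.refnet_classifier <- function(object, fmatrix, ...) {
  n <- nrow(fmatrix$blocked)
  if (object$kind == "majority")
    return(rep(object$majority, n))
  x <- feasibility_design(fmatrix, object$features)
  dec <- drop(x %*% object$weights) - object$offset
  ifelse(dec > 0, "inviable", "viable")
}

#' Hold-out split configuration
#'
#' @param n_train total number of training samples.
#' @param n_train_inviable number of inviable samples among them (the
#'   remaining `n_train - n_train_inviable` are viable); class counts are
#'   fixed by design rather than stratified by proportion.
#' @param n_repeats number of randomized hold-out repetitions.
#' @param seed integer seed making the whole evaluation reproducible.
#' @param cost SVM soft-margin constant.
#' @return A list of class `refnet_split_config`.
#' @export
split_config <- function(n_train, n_train_inviable, n_repeats = 10,
                         seed = 1, cost = 1) {
  stopifnot(n_train_inviable <= n_train, n_repeats >= 1)
  structure(list(n_train = as.integer(n_train),
                 n_train_inviable = as.integer(n_train_inviable),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), cost = cost),
            class = "refnet_split_config")
}

#' Randomized hold-out evaluation of phenotype prediction
#'
#' For each repeat, the configured numbers of inviable and viable samples
#' are drawn at random (without replacement) into the training set and all
#' remaining samples form the test set; features are selected and the
#' classifier trained on the training rows only, then test predictions are
#' scored. TPR is the fraction of inviable test phenotypes correctly
#' predicted, FPR the fraction of viable test phenotypes predicted
#' inviable.
#'
#' @param fmatrix a reduced `refnet_fmatrix`.
#' @param config a `refnet_split_config`.
#' @param phenotypes per-row phenotypes (defaults to stored ones).
#' @return An object of class `refnet_eval`: per-repeat data frame
#'   (`tpr`, `fpr`, `n_features`) plus `tpr_mean`, `tpr_sd`, `fpr_mean`,
#'   `fpr_sd`.
#' @export
evaluate_holdout <- function(fmatrix, config, phenotypes = NULL) {
  phenotypes <- check_phenotypes(fmatrix, phenotypes)
  inv_rows <- which(phenotypes == "inviable")
  via_rows <- which(phenotypes == "viable")
  n_via <- config$n_train - config$n_train_inviable
  if (length(inv_rows) <= config$n_train_inviable ||
      length(via_rows) <= n_via)
    stop(sprintf(
      "insufficient samples for the split: need > %d inviable and > %d viable, have %d and %d",
      config$n_train_inviable, n_via, length(inv_rows), length(via_rows)),
      call. = FALSE)

  reps <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    reps[[r]] <- with_seed((config$seed + 7919L * r) %% 2147483629L, {
      tr <- c(sample(inv_rows, config$n_train_inviable),
              sample(via_rows, n_via))
      te <- setdiff(seq_along(phenotypes), tr)
      train_fm <- fm_subset(fmatrix, tr)
      feats <- suppressWarnings(select_features(train_fm, phenotypes[tr]))
      mdl <- train_classifier(train_fm, feats, phenotypes[tr],
                              cost = config$cost)
      pred <- predict(mdl, fm_subset(fmatrix, te))
      truth <- phenotypes[te]
      data.frame(
        repeat_id = r,
        tpr = mean(pred[truth == "inviable"] == "inviable"),
        fpr = mean(pred[truth == "viable"] == "inviable"),
        n_features = length(feats))
    })
  }
  per <- do.call(rbind, reps)
  structure(list(per_repeat = per,
                 tpr_mean = mean(per$tpr), tpr_sd = stats::sd(per$tpr),
                 fpr_mean = mean(per$fpr), fpr_sd = stats::sd(per$fpr),
                 config = config),
            class = "refnet_eval")
}

#' @export
print.refnet_eval <- function(x, ...) {
  cat(sprintf(
    "<refnet_eval> %d repeats (n_train=%d, inviable=%d): TPR %.3f (SD %.3f), FPR %.3f (SD %.3f)\n",
    nrow(x$per_repeat), x$config$n_train, x$config$n_train_inviable,
    x$tpr_mean, x$tpr_sd, x$fpr_mean, x$fpr_sd))
  invisible(x)
}
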