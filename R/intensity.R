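#' Map a MET value to the three-level exercise-intensity class
#'
#' The standard exercise-intensity table: MET <= 3 is low intensity, 3 to 6
#' is medium, and >= 6 is high. The table's explicit `<= 3` and `>= 6` win at
#' the boundaries, so low = `[0, 3]`, medium = `(3, 6)`, high = `[6, Inf)`.
#' The map is monotone in the order low < medium < high.
#'
#' @param met Non-negative MET (metabolic equivalent of task) value(s).
#' @return Factor with levels `low`, `medium`, `high`, same length as `met`.
#' @export
#' @examples
#' met_to_class(c(2, 4, 7)) # low, medium, high
met_to_class <- function(met) {
  if (any(met < 0)) stop("MET values must be >= 0", call. = FALSE)
  out <- ifelse(met <= 3, "low", ifelse(met < 6, "medium", "high"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Configuration of the intensity SVM
#'
#' Radial-basis-function kernel `exp(-gamma * ||u - v||^2)` with `gamma = 1`
#' and soft-margin penalty `C = 2`, multiclass by one-vs-one pairwise voting
#' — the configuration found to separate the three intensity levels from
#' time-domain HRV features.
#'
#' @param gamma RBF kernel width parameter (> 0). Default 1.
#' @param penalty_C Soft-margin penalty (> 0). Default 2.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(gamma = 1, penalty_C = 2) {
  if (gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  if (penalty_C <= 0) stop("`penalty_C` must be > 0", call. = FALSE)
  structure(list(kernel = "radial", gamma = gamma, penalty_C = penalty_C,
                 multiclass = "one-vs-one"),
            class = "svm_config")
}

.as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- as.matrix(features[, setdiff(colnames(features),
                                             "epoch_start_s"), drop = FALSE])
  } else if (is.list(features) && !is.matrix(features)) {
    features <- do.call(rbind, features)
  }
  as.matrix(features)
}

#' Train the three-level exercise-intensity classifier
#'
#' Standardises the feature columns (training-set mean and sd, stored with
#' the model), then fits pairwise RBF support-vector machines with one-vs-one
#' voting. Prediction breaks vote ties toward the class with the larger
#' aggregate decision margin.
#'
#' @param features Matrix or data frame of per-epoch HRV feature vectors
#'   (rows = epochs), e.g. from [featurize_epochs()] or [hrv_features()].
#' @param labels Factor (or character) of intensity labels, levels
#'   low/medium/high; at least two classes must be present.
#' @param config An [svm_config()].
#' @param seed Integer seed (the fit itself is deterministic; the seed guards
#'   any library-internal randomisation).
#' @return An object of class `intensity_svm` holding the fitted machine and
#'   the standardisation constants.
#' @export
train_intensity_svm <- function(features, labels, config = svm_config(),
                                seed = 1L) {
  x <- .as_feature_matrix(features)
  labels <- factor(as.character(labels), levels = c("low", "medium", "high"))
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) {
    stop("need at least two classes to train", call. = FALSE)
  }
  if (nrow(x) != length(labels)) {
    stop("features and labels disagree in length", call. = FALSE)
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- scale(x, center = mu, scale = sdv)
  set.seed(as.integer(seed))
  fit <- e1071::svm(xs, labels, type = "C-classification",
                    kernel = "radial", gamma = config$gamma,
                    cost = config$penalty_C, scale = FALSE)
  structure(
    list(fit = fit, center = mu, scale = sdv,
         feature_names = colnames(x), config = config,
         levels = levels(labels)),
    class = "intensity_svm"
  )
}

#' Predict exercise-intensity labels
#'
#' Applies the stored standardisation, evaluates every pairwise decision
#' function, and assigns each epoch the class with the most pairwise votes;
#' vote ties are broken toward the class with the larger summed decision
#' margin.
#'
#' @param classifier A [train_intensity_svm()] model.
#' @param features Matrix or data frame of feature vectors with the training
#'   dimensionality.
#' @return Factor of predicted labels with levels low/medium/high.
#' @export
predict_intensity <- function(classifier, features) {
  stopifnot(inherits(classifier, "intensity_svm"))
  x <- .as_feature_matrix(features)
  if (ncol(x) != length(classifier$center)) {
    stop(sprintf("feature dimension %d != training dimension %d",
                 ncol(x), length(classifier$center)), call. = FALSE)
  }
  xs <- scale(x, center = classifier$center, scale = classifier$scale)
  pred <- stats::predict(classifier$fit, xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  lv <- classifier$levels
  if (length(lv) < 3 || is.null(dv)) {
    return(factor(as.character(pred), levels = c("low", "medium", "high")))
  }
  # one-vs-one voting with margin tie-break, from the decision values
  out <- character(nrow(x))
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (i in seq_len(nrow(x))) {
    votes <- stats::setNames(rep(0L, length(lv)), lv)
    margin <- stats::setNames(rep(0, length(lv)), lv)
    for (j in seq_along(pairs)) {
      a <- pairs[[j]][1]; b <- pairs[[j]][2]
      v <- dv[i, j]
      winner <- if (v >= 0) a else b
      votes[winner] <- votes[winner] + 1L
      margin[a] <- margin[a] + v
      margin[b] <- margin[b] - v
    }
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1) top else top[which.max(margin[top])]
  }
  factor(out, levels = c("low", "medium", "high"))
}

#' Score predicted against reference intensity labels
#'
#' Treats each class in turn as the positive class to obtain per-class
#' accuracy, false-negative rate and false-positive rate (all normalised by
#' the total number of epochs), plus the overall accuracy and the unweighted
#' means of the per-class rates.
#'
#' @param predicted,reference Equal-length factors/characters of intensity
#'   labels.
#' @return A list with `overall_accuracy_pct`, `per_class` (data frame with
#'   columns class, accuracy_pct, fn_rate_pct, fp_rate_pct) and
#'   `mean_accuracy_pct`, `mean_fn_rate_pct`, `mean_fp_rate_pct`.
#' @export
evaluate_intensity <- function(predicted, reference) {
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  if (length(predicted) != length(reference)) {
    stop("predicted and reference lengths differ", call. = FALSE)
  }
  n <- length(reference)
  classes <- c("low", "medium", "high")
  classes <- classes[classes %in% union(predicted, reference)]
  rows <- lapply(classes, function(cl) {
    tp <- sum(predicted == cl & reference == cl)
    fp <- sum(predicted == cl & reference != cl)
    fn <- sum(predicted != cl & reference == cl)
    tn <- n - tp - fp - fn
    m <- classification_metrics(confusion_counts(tp, tn, fp, fn))
    data.frame(class = cl,
               accuracy_pct = 100 * m$accuracy,
               fn_rate_pct = 100 * m$fn_rate,
               fp_rate_pct = 100 * m$fp_rate)
  })
  per_class <- do.call(rbind, rows)
  list(overall_accuracy_pct = 100 * mean(predicted == reference),
       per_class = per_class,
       mean_accuracy_pct = average_rates(per_class$accuracy_pct),
       mean_fn_rate_pct = average_rates(per_class$fn_rate_pct),
       mean_fp_rate_pct = average_rates(per_class$fp_rate_pct))
}
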