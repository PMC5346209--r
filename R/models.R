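# Probabilistic classifiers on the two-feature nearest-neighbour
# representation (Tc_most, activity feature).
#
# One global model is trained on pooled (feature, label) pairs across all
# targets. Its inactive probability p_i is the per-target p-value used by
# the multiple-target FDR machinery.

#' Model specification
#'
#' Bundles the configuration of one inference model: classifier backend,
#' bioactivity representation, activity threshold, fingerprint scheme and
#' random seed.
#'
#' @param method `"logistic_regression"` (sigmoid of
#'   `a0 + a1*Tc_most + a2*activity`), `"naive_bayes"` (Gaussian
#'   class-conditionals per feature) or `"random_forest"` (100 trees).
#' @param mode `"explicit"` uses the neighbour's pKi as-is as the activity
#'   feature; `"implicit"` binarises it at `threshold`.
#' @param threshold pKi activity threshold, 5 or 6.
#' @param scheme fingerprint scheme token, `"morgan"` or `"fp2"`.
#' @param seed integer seed controlling every stochastic step downstream.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(method = c("logistic_regression", "naive_bayes", "random_forest"),
                       mode = c("explicit", "implicit"),
                       threshold = 6, scheme = c("morgan", "fp2"), seed = 1L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  if (!threshold %in% c(5, 6))
    stop("activity threshold must be 5 or 6 (pKi scale)")
  structure(list(method = method, mode = mode, threshold = threshold,
                 scheme = scheme, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model spec:", x$method, "|", x$mode, "activity | pKi >=", x$threshold,
      "|", x$scheme, "| seed", x$seed, "\n")
  invisible(x)
}

#' Encode nearest-neighbour pairs as model features
#'
#' In explicit mode the feature vector is (Tc_most, pKi_most); in implicit
#' mode the neighbour's potency is reduced to the 0/1 indicator
#' `pKi_most >= threshold`.
#'
#' @param tc_most numeric vector of nearest-neighbour Tanimoto similarities.
#' @param pki_most numeric vector of nearest-neighbour pKi values.
#' @param mode `"explicit"` or `"implicit"`.
#' @param threshold pKi threshold used for implicit binarisation.
#' @return data.frame with columns `tc_most`, `activity`.
#' @export
encode_features <- function(tc_most, pki_most, mode = c("explicit", "implicit"),
                            threshold = 6) {
  mode <- match.arg(mode)
  stopifnot(length(tc_most) == length(pki_most))
  activity <- if (mode == "explicit") as.numeric(pki_most) else
    as.numeric(label_activity(pki_most, threshold))
  data.frame(tc_most = as.numeric(tc_most), activity = activity)
}

#' Train an inference model
#'
#' Fits the classifier named by `spec` on pooled feature/label pairs.
#' Training is deterministic given `spec$seed`. The logistic backend exposes
#' its fitted coefficients through [coef()][coef.most_model()] in the
#' (a0, a1, a2) parametrisation of the sigmoid
#' `p_a = 1 / (1 + exp(-(a0 + a1*Tc_most + a2*activity)))`.
#'
#' @param features data.frame from [encode_features()].
#' @param labels integer 0/1 truth labels (1 = active); both classes must be
#'   present.
#' @param spec a [model_spec()].
#' @return an object of class `most_model`.
#' @export
most_train <- function(features, labels, spec) {
  stopifnot(inherits(spec, "model_spec"),
            is.data.frame(features),
            all(c("tc_most", "activity") %in% names(features)))
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  if (length(unique(labels)) < 2)
    stop("training data contains a single class; cannot fit a classifier")
  if (spec$mode == "implicit" && !all(features$activity %in% c(0, 1)))
    stop("implicit-mode training features must carry a 0/1 activity indicator")
  features <- features[c("tc_most", "activity")]
  fit <- switch(spec$method,
    logistic_regression = {
      g <- stats::glm(y ~ tc_most + activity,
                      data = cbind(features, y = labels),
                      family = stats::binomial())
      list(coef = stats::setNames(as.numeric(stats::coef(g)),
                                  c("a0", "a1", "a2")))
    },
    naive_bayes = e1071::naiveBayes(features, factor(labels, levels = c(0, 1))),
    random_forest = {
      set.seed(spec$seed)
      randomForest::randomForest(features, factor(labels, levels = c(0, 1)),
                                 ntree = 100)
    })
  structure(list(spec = spec, fit = fit, n_train = length(labels)),
            class = "most_model")
}

#' @export
print.most_model <- function(x, ...) {
  cat("most model (", x$spec$method, ", ", x$spec$mode, " activity, pKi >= ",
      x$spec$threshold, ", ", x$spec$scheme, "), trained on ",
      x$n_train, " pairs\n", sep = "")
  if (x$spec$method == "logistic_regression")
    print(round(x$fit$coef, 4))
  invisible(x)
}

#' Fitted logistic coefficients
#'
#' @param object a `most_model` with logistic-regression backend.
#' @param ... ignored.
#' @return named numeric vector `(a0, a1, a2)`.
#' @export
coef.most_model <- function(object, ...) {
  if (object$spec$method != "logistic_regression")
    stop("coefficients are only defined for the logistic-regression backend")
  object$fit$coef
}

#' Predict activity probabilities
#'
#' Returns the calibrated probability of the query being active (`p_a`) and
#' inactive (`p_i = 1 - p_a`) on the target whose nearest-neighbour features
#' are given. The predicted label is active iff `p_a > p_i`; an exact tie is
#' conservatively called inactive. `p_value` repeats `p_i`, the quantity
#' treated as the per-target p-value for FDR control.
#'
#' @param object a trained `most_model`.
#' @param features data.frame from [encode_features()], encoded in the same
#'   mode the model was trained in.
#' @param ... ignored.
#' @return data.frame with columns `p_a`, `p_i`, `label`, `p_value`.
#' @export
predict.most_model <- function(object, features, ...) {
  stopifnot(is.data.frame(features),
            all(c("tc_most", "activity") %in% names(features)))
  if (object$spec$mode == "implicit" && !all(features$activity %in% c(0, 1)))
    stop("model was trained in implicit mode; activity feature must be 0/1")
  features <- features[c("tc_most", "activity")]
  p_a <- switch(object$spec$method,
    logistic_regression = {
      co <- object$fit$coef
      as.numeric(stats::plogis(co["a0"] + co["a1"] * features$tc_most +
                               co["a2"] * features$activity))
    },
    naive_bayes = {
      pr <- stats::predict(object$fit, features, type = "raw")
      as.numeric(pr[, "1"] / rowSums(pr))
    },
    random_forest = {
      pr <- stats::predict(object$fit, features, type = "prob")
      as.numeric(pr[, "1"])
    })
  p_i <- 1 - p_a
  data.frame(p_a = p_a, p_i = p_i,
             label = as.integer(p_a > p_i), p_value = p_i)
}

#' Save / load a trained model as a text artifact
#'
#' The artifact is a plain-text file: a YAML-style header (format version,
#' model spec, and for the logistic backend the fitted coefficients) followed
#' by an ASCII serialisation of the backend fit, so models survive process
#' restarts without binary files.
#'
#' @param model a `most_model`.
#' @param file path.
#' @return `write_most_model` returns `file` invisibly; `read_most_model`
#'   the reconstructed `most_model`.
#' @export
write_most_model <- function(model, file) {
  stopifnot(inherits(model, "most_model"))
  header <- list(format = "most-model/1", method = model$spec$method,
                 mode = model$spec$mode, threshold = model$spec$threshold,
                 scheme = model$spec$scheme, seed = model$spec$seed,
                 n_train = model$n_train)
  if (model$spec$method == "logistic_regression")
    header$coefficients <- as.list(model$fit$coef)
  payload <- rawToChar(serialize(model$fit, NULL, ascii = TRUE))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(yaml::as.yaml(header), con)
  writeLines("---payload---", con)
  writeLines(payload, con)
  invisible(file)
}

#' @rdname write_most_model
#' @export
read_most_model <- function(file) {
  if (!file.exists(file)) stop("model file not found: ", file)
  lines <- readLines(file)
  sep <- match("---payload---", lines)
  if (is.na(sep)) stop("not a most model artifact (missing payload marker): ", file)
  header <- yaml::yaml.load(paste(lines[seq_len(sep - 1)], collapse = "\n"))
  if (!identical(header$format, "most-model/1"))
    stop("unsupported model artifact format: ", header$format)
  fit <- unserialize(charToRaw(paste(lines[(sep + 1):length(lines)],
                                     collapse = "\n")))
  spec <- model_spec(header$method, header$mode, header$threshold,
                     header$scheme, header$seed)
  structure(list(spec = spec, fit = fit, n_train = header$n_train),
            class = "most_model")
}
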