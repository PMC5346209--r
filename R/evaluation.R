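# Cross-validation, temporal validation, classification metrics and the
# Tc / p-value threshold trade-off analysis.

#' Confusion counts
#'
#' @param truth,predicted integer 0/1 vectors of equal length.
#' @return named integer vector with elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c(0, 1)), all(predicted %in% c(0, 1)))
  c(TP = sum(truth == 1 & predicted == 1),
    TN = sum(truth == 0 & predicted == 0),
    FP = sum(truth == 0 & predicted == 1),
    FN = sum(truth == 1 & predicted == 0))
}

#' Classification accuracy from confusion counts
#'
#' accuracy = (TP + TN) / (TP + FN + TN + FP).
#'
#' @param counts named vector/list with `TP`, `TN`, `FP`, `FN`.
#' @return accuracy in \[0, 1\].
#' @export
accuracy <- function(counts) {
  counts <- unlist(counts)[c("TP", "TN", "FP", "FN")]
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("cannot compute accuracy from zero counts")
  unname((counts["TP"] + counts["TN"]) / total)
}

#' Matthews correlation coefficient from confusion counts
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), a balanced
#' metric in \[-1, 1\] robust to class imbalance. When any factor of the
#' denominator is zero the coefficient is defined as 0 (standard
#' convention for a degenerate margin).
#'
#' @inheritParams accuracy
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(counts) {
  counts <- as.numeric(unlist(counts)[c("TP", "TN", "FP", "FN")])
  stopifnot(all(counts >= 0))
  tp <- counts[1]; tn <- counts[2]; fp <- counts[3]; fn <- counts[4]
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Sevenfold split of a target panel
#'
#' In the default `"partition"` mode the ligands of each target are randomly
#' partitioned into 7 disjoint folds of near-equal size (about 14.3% each);
#' fold i's test set is fold i and its training set the remaining six, so
#' the union of the test sets covers every ligand exactly once.
#' `"resample15"` instead draws, independently seven times, 15% of each
#' target's ligands as the test set (sampling with replacement across
#' repetitions, without within one), which does not guarantee full coverage.
#'
#' @param panel a [target_panel()].
#' @param seed integer seed; the split is a pure function of panel and seed.
#' @param mode `"partition"` or `"resample15"`.
#' @return a list of 7 elements, each a list with `train` and `test`
#'   target panels.
#' @export
sevenfold_split <- function(panel, seed = 1L, mode = c("partition", "resample15")) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  n <- nrow(panel)
  targets <- unique(panel$target_id)
  fold_of <- integer(n)
  test_sets <- vector("list", 7)
  if (mode == "partition") {
    for (t in targets) {
      idx <- which(panel$target_id == t)
      fold_of[idx] <- sample(rep_len(1:7, length(idx)))
    }
    for (k in 1:7) test_sets[[k]] <- fold_of == k
  } else {
    for (k in 1:7) {
      test <- logical(n)
      for (t in targets) {
        idx <- which(panel$target_id == t)
        n_test <- max(1L, round(0.15 * length(idx)))
        test[sample(idx, n_test)] <- TRUE
      }
      test_sets[[k]] <- test
    }
  }
  rel <- attr(panel, "release")
  lapply(test_sets, function(test) {
    list(train = target_panel(as.data.frame(panel)[!test, , drop = FALSE], rel),
         test  = target_panel(as.data.frame(panel)[test, , drop = FALSE], rel))
  })
}

# Nearest-neighbour features of query rows against reference rows, per
# target. `panel_idx` maps rows to precomputed fingerprints `fps` of the
# full panel, so fingerprints are computed once per analysis.
.nn_features <- function(query, reference, fps, query_idx, ref_idx) {
  out <- data.frame(target_id = query$target_id, ligand_id = query$ligand_id,
                    nn_ligand_id = NA_character_, tc_most = NA_real_,
                    pki_most = NA_real_, stringsAsFactors = FALSE)
  for (t in unique(query$target_id)) {
    q_rows <- which(query$target_id == t)
    r_rows <- which(reference$target_id == t)
    if (length(r_rows) == 0) next
    r_ids <- reference$ligand_id[r_rows]
    r_pki <- reference$pKi[r_rows]
    r_fps <- fps[ref_idx[r_rows]]
    for (q in q_rows) {
      nn <- most_similar(fps[[query_idx[q]]], r_ids, r_fps, r_pki)
      out$nn_ligand_id[q] <- nn$ligand_id
      out$tc_most[q] <- nn$tc_most
      out$pki_most[q] <- nn$pki_most
    }
  }
  out
}

# Leave-one-out nearest neighbours within one panel (training-set features):
# each ligand is compared against the remaining ligands of its target.
.nn_features_loo <- function(panel, fps, idx) {
  out <- data.frame(target_id = panel$target_id, ligand_id = panel$ligand_id,
                    nn_ligand_id = NA_character_, tc_most = NA_real_,
                    pki_most = NA_real_, stringsAsFactors = FALSE)
  for (t in unique(panel$target_id)) {
    rows <- which(panel$target_id == t)
    if (length(rows) < 2) next
    ids <- panel$ligand_id[rows]
    pki <- panel$pKi[rows]
    t_fps <- fps[idx[rows]]
    for (j in seq_along(rows)) {
      nn <- most_similar(t_fps[[j]], ids[-j], t_fps[-j], pki[-j])
      out$nn_ligand_id[rows[j]] <- nn$ligand_id
      out$tc_most[rows[j]] <- nn$tc_most
      out$pki_most[rows[j]] <- nn$pki_most
    }
  }
  out
}

.fit_and_score <- function(train_nn, train_pki, test_nn, test_pki, spec) {
  keep_tr <- !is.na(train_nn$tc_most)
  train_nn <- train_nn[keep_tr, , drop = FALSE]
  train_pki <- train_pki[keep_tr]
  keep_te <- !is.na(test_nn$tc_most)
  if (any(!keep_te))
    warning(sum(!keep_te), " test ligand(s) skipped: no training ligands for their target")
  test_nn <- test_nn[keep_te, , drop = FALSE]
  test_pki <- test_pki[keep_te]

  tr_feat <- encode_features(train_nn$tc_most, train_nn$pki_most,
                             spec$mode, spec$threshold)
  tr_lab <- label_activity(train_pki, spec$threshold)
  model <- most_train(tr_feat, tr_lab, spec)

  te_feat <- encode_features(test_nn$tc_most, test_nn$pki_most,
                             spec$mode, spec$threshold)
  pred <- predict(model, te_feat)
  truth <- label_activity(test_pki, spec$threshold)

  trace <- data.frame(target_id = test_nn$target_id,
                      ligand_id = test_nn$ligand_id,
                      nn_ligand_id = test_nn$nn_ligand_id,
                      tc_most = test_nn$tc_most,
                      pki_most = test_nn$pki_most,
                      p_a = pred$p_a, p_value = pred$p_value,
                      truth = truth, predicted = pred$label,
                      stringsAsFactors = FALSE)
  counts <- confusion_counts(truth, pred$label)
  list(model = model, trace = trace, counts = counts,
       accuracy = accuracy(counts), mcc = mcc(counts))
}

#' Sevenfold cross-validation of the nearest-neighbour inference model
#'
#' For every fold, training features are built by leave-one-out search
#' within the training split (each training ligand's most-similar ligand
#' among the remaining training ligands of its target) and one global model
#' is fitted on the pooled pairs; test ligands are matched against the
#' training ligand sets of their targets and scored. Metrics are pooled
#' over targets within each fold, then summarised as mean and standard
#' deviation over the 7 folds.
#'
#' @param panel a curated [target_panel()].
#' @param spec a [model_spec()]; `spec$seed` drives the split and any
#'   stochastic backend.
#' @param split_mode see [sevenfold_split()].
#' @param fold fingerprint fold length, `NULL` for the scheme's native size.
#' @return an object of class `most_cv`: list with `folds` (per-fold
#'   results), `trace` (pooled per-prediction records with a `fold` column)
#'   and `summary` (mean/sd of accuracy and MCC).
#' @export
cross_validate <- function(panel, spec, split_mode = "partition", fold = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  fps <- panel_fingerprints(panel, spec$scheme, fold)
  idx <- seq_len(nrow(panel))
  splits <- sevenfold_split(panel, spec$seed, split_mode)
  row_key <- paste(panel$target_id, panel$ligand_id, sep = "\r")
  folds <- vector("list", 7)
  for (k in 1:7) {
    tr <- splits[[k]]$train
    te <- splits[[k]]$test
    tr_idx <- match(paste(tr$target_id, tr$ligand_id, sep = "\r"), row_key)
    te_idx <- match(paste(te$target_id, te$ligand_id, sep = "\r"), row_key)
    tr_nn <- .nn_features_loo(tr, fps, tr_idx)
    te_nn <- .nn_features(te, tr, fps, te_idx, tr_idx)
    res <- .fit_and_score(tr_nn, tr$pKi, te_nn, te$pKi, spec)
    res$fold <- k
    res$trace <- cbind(fold = k, res$trace)
    folds[[k]] <- res
  }
  acc <- vapply(folds, `[[`, 0, "accuracy")
  mc <- vapply(folds, `[[`, 0, "mcc")
  structure(list(
    spec = spec,
    folds = folds,
    trace = do.call(rbind, lapply(folds, `[[`, "trace")),
    summary = data.frame(metric = c("accuracy", "mcc"),
                         mean = c(mean(acc), mean(mc)),
                         sd = c(stats::sd(acc), stats::sd(mc)))),
    class = "most_cv")
}

#' @export
print.most_cv <- function(x, ...) {
  s <- x$summary
  cat("sevenfold cross-validation (", x$spec$method, ", ", x$spec$mode,
      ", pKi >= ", x$spec$threshold, ", ", x$spec$scheme, ")\n", sep = "")
  cat(sprintf("  accuracy %.3f +/- %.3f   MCC %.3f +/- %.3f\n",
              s$mean[1], s$sd[1], s$mean[2], s$sd[2]))
  invisible(x)
}

#' Temporal validation against newly deposited pairs
#'
#' Trains one global model on the full old-release panel (leave-one-out
#' neighbour features within each target) and scores each newly deposited
#' target-ligand pair against the old release's ligand set for its target.
#' Pairs on targets without old ligands are skipped with a warning.
#'
#' @param old_panel the training-release [target_panel()].
#' @param new_pairs data.frame from [temporal_new_pairs()].
#' @param spec a [model_spec()].
#' @param fold fingerprint fold length.
#' @return a list with `counts`, `accuracy`, `mcc`, `trace` and the trained
#'   `model`.
#' @export
temporal_validate <- function(old_panel, new_pairs, spec, fold = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (nrow(new_pairs) == 0) {
    counts <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
    return(list(counts = counts, accuracy = NA_real_, mcc = 0,
                trace = data.frame(), model = NULL))
  }
  all_smiles <- c(old_panel$smiles, new_pairs$smiles)
  fps <- compute_fingerprint(all_smiles, spec$scheme, fold)
  old_idx <- seq_len(nrow(old_panel))
  new_idx <- nrow(old_panel) + seq_len(nrow(new_pairs))
  tr_nn <- .nn_features_loo(old_panel, fps, old_idx)
  te_nn <- .nn_features(new_pairs, old_panel, fps, new_idx, old_idx)
  res <- .fit_and_score(tr_nn, old_panel$pKi, te_nn, new_pairs$pKi, spec)
  res[c("counts", "accuracy", "mcc", "trace", "model")]
}

#' Threshold trade-off curves over a prediction trace
#'
#' For the positive predictions of a run, computes the fraction of true
#' positives and of false positives retained as a threshold tightens:
#' on the `"tc"` axis the kept region is `tc_most >= k`; on the `"pvalue"`
#' axis it is `p_value <= t`. The difference `f_TP - f_FP` is the trade-off
#' index whose maximiser is the operating threshold that keeps the most
#' true positives per false positive removed.
#'
#' @param trace per-prediction records with columns `tc_most`, `p_value`,
#'   `truth`, `predicted` (as produced by [cross_validate()] or
#'   [temporal_validate()]).
#' @param axis `"tc"` or `"pvalue"`.
#' @param thresholds numeric grid; defaults to 0 to 1 step 0.05 on the Tc
#'   axis and 0.5 down to 0 step 0.025 on the p-value axis.
#' @return data.frame with columns `threshold`, `f_TP`, `f_FP`, `diff`, and
#'   an attribute `"argmax"` giving the threshold maximising `diff`.
#'   A class with no members yields `NA` fractions rather than 0.
#' @export
tradeoff_curve <- function(trace, axis = c("tc", "pvalue"), thresholds = NULL) {
  axis <- match.arg(axis)
  stopifnot(all(c("tc_most", "p_value", "truth", "predicted") %in% names(trace)))
  if (is.null(thresholds))
    thresholds <- if (axis == "tc") seq(0, 1, by = 0.05) else seq(0.5, 0, by = -0.025)
  is_tp <- trace$truth == 1 & trace$predicted == 1
  is_fp <- trace$truth == 0 & trace$predicted == 1
  n_tp <- sum(is_tp); n_fp <- sum(is_fp)
  frac <- function(keep, members, n) if (n == 0) NA_real_ else sum(keep & members) / n
  rows <- lapply(thresholds, function(k) {
    keep <- if (axis == "tc") trace$tc_most >= k else trace$p_value <= k
    data.frame(threshold = k,
               f_TP = frac(keep, is_tp, n_tp),
               f_FP = frac(keep, is_fp, n_fp))
  })
  out <- do.call(rbind, rows)
  out$diff <- out$f_TP - out$f_FP
  argmax <- if (all(is.na(out$diff))) NA_real_ else
    out$threshold[which.max(out$diff)]
  attr(out, "argmax") <- argmax
  out
}
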