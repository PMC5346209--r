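# Multiple-target scanning with false discovery rate control.
#
# Scanning a query against a target panel yields one p-value (the model's
# inactive probability p_i) per target; across hundreds or thousands of
# targets these are corrected by Benjamini-Hochberg adjustment and Storey
# q-values before hits are ranked.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: with the p-values sorted ascending,
#' `p_adj(i) = min over j >= i of min(1, p(j) * m / j)`, mapped back to the
#' input order. Monotone and order-preserving.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 with Storey's fixed-lambda estimator,
#' `pi0 = #\{p > lambda\} / (m * (1 - lambda))` capped at 1, and returns
#' `q(i) = pi0 * p_adj_BH(i)`. When no p-value exceeds lambda (all p tiny)
#' the estimate degenerates to 0; the function then falls back to
#' `pi0 = 1` with a warning, reducing q-values to BH-adjusted values.
#'
#' @inheritParams adjust_bh
#' @param lambda tuning constant in (0, 1) for the pi0 estimate.
#' @return list with `q` (q-values, input order) and `pi0`.
#' @export
estimate_qvalues <- function(pvalues, lambda = 0.5) {
  pvalues <- as.numeric(pvalues)
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(length(lambda) == 1, lambda > 0, lambda < 1)
  m <- length(pvalues)
  pi0 <- sum(pvalues > lambda) / (m * (1 - lambda))
  if (pi0 <= 0) {
    warning("degenerate pi0 estimate (no p-values above lambda); using pi0 = 1")
    pi0 <- 1
  }
  pi0 <- min(pi0, 1)
  list(q = pi0 * adjust_bh(pvalues), pi0 = pi0)
}

#' Rank scanned targets
#'
#' Orders scan results by BH-adjusted p-value ascending, breaking ties by
#' higher nearest-neighbour similarity and then by target id, and assigns
#' ranks 1..m. The order is total and deterministic.
#'
#' @param results data.frame with columns `p_adj_bh`, `tc_most`,
#'   `target_id`.
#' @return the data.frame reordered, with a `rank` column.
#' @export
rank_targets <- function(results) {
  stopifnot(all(c("p_adj_bh", "tc_most", "target_id") %in% names(results)))
  ord <- order(results$p_adj_bh, -results$tc_most, results$target_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Scan a query compound against a target panel
#'
#' For every target with at least one annotated ligand, finds the query's
#' most-similar ligand, scores the (Tc_most, activity) pair with the global
#' model, and treats the inactive probability as that target's raw p-value.
#' Raw p-values are then adjusted over the full scanned set (m = number of
#' scanned targets) by Benjamini-Hochberg, q-values estimated, and hits
#' ranked.
#'
#' @param query_smiles a single SMILES string.
#' @param panel a [target_panel()].
#' @param model a trained [most_train()] model (a single global model
#'   pooled over targets).
#' @param fold fingerprint fold length, `NULL` for native.
#' @param min_tc optional similarity floor: targets whose `tc_most` falls
#'   below it are dropped before adjustment (off by default; scanning
#'   filters by p-value, not Tc).
#' @param fps optional precomputed panel fingerprints
#'   ([panel_fingerprints()]) to amortise repeated scans.
#' @return data.frame of class `target_scan` with columns `target_id`,
#'   `nn_ligand_id`, `tc_most`, `pki_most`, `p_value`, `p_adj_bh`,
#'   `q_value`, `rank`; attribute `"pi0"` carries the Storey estimate.
#' @export
scan_targets <- function(query_smiles, panel, model, fold = NULL,
                         min_tc = 0, fps = NULL) {
  stopifnot(inherits(model, "most_model"), length(query_smiles) == 1)
  if (nrow(panel) == 0) stop("cannot scan an empty target panel")
  query_fp <- compute_fingerprint(query_smiles, model$spec$scheme, fold)
  if (is.null(fps)) fps <- panel_fingerprints(panel, model$spec$scheme, fold)
  targets <- unique(panel$target_id)
  nn <- lapply(targets, function(t) {
    rows <- which(panel$target_id == t)
    most_similar(query_fp, panel$ligand_id[rows], fps[rows], panel$pKi[rows])
  })
  res <- data.frame(
    target_id = targets,
    nn_ligand_id = vapply(nn, `[[`, "", "ligand_id"),
    tc_most = vapply(nn, `[[`, 0, "tc_most"),
    pki_most = vapply(nn, `[[`, 0, "pki_most"),
    stringsAsFactors = FALSE)
  if (min_tc > 0) res <- res[res$tc_most >= min_tc, , drop = FALSE]
  if (nrow(res) == 0) stop("no target passed the similarity floor")
  feat <- encode_features(res$tc_most, res$pki_most,
                          model$spec$mode, model$spec$threshold)
  pred <- predict(model, feat)
  res$p_value <- pred$p_value
  res$p_adj_bh <- adjust_bh(res$p_value)
  qv <- estimate_qvalues(res$p_value)
  res$q_value <- qv$q
  res <- rank_targets(res)
  attr(res, "pi0") <- qv$pi0
  class(res) <- c("target_scan", "data.frame")
  res
}

#' @export
print.target_scan <- function(x, n = 10, ...) {
  cat("target scan:", nrow(x), "target(s); pi0 =",
      signif(attr(x, "pi0"), 3), "\n")
  print(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}
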