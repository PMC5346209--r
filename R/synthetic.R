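# Synthetic bioactivity tables, ligand panels and feature data with known
# ground truth, so curation, similarity search, model fitting, validation
# and FDR control are all testable offline.
#
# Structures come from one combinatorial family: a benzene core carrying a
# target-specific ether/alkyl tail plus, for the ligands of a target, small
# graded substituents. The family is cheap, always parseable, and gives a
# smooth within-target similarity gradient with a star topology: every
# decorated ligand is more similar to its target's undecorated seed than to
# any sibling, so the seed is the nearest neighbour by construction.

# Graded ring substituents with pairwise-distinct leading atoms or
# halogen families, so any two substituents contribute (near-)disjoint
# circular-fingerprint bits. That makes every decorated ligand strictly
# more similar to its undecorated seed than to any sibling (star
# topology), which the panel generator's answer key relies on.
.SUBSTITUENTS <- c("F", "Cl", "Br", "I", "N", "O", "C",
                   "FC", "ClC", "BrC", "IC", "NC", "OC", "SC",
                   "FCC", "ClCC", "BrCC", "ICC", "NCC", "OCC")

.target_tail <- function(t) {
  a <- (t - 1) %% 5 + 1
  b <- (t - 1) %/% 5
  paste0(strrep("OC", a), strrep("C", b))
}

.target_scaffold <- function(t) paste0("c1ccccc1", .target_tail(t))

#' Generator configuration
#'
#' One configuration object drives every synthetic generator; the seed fully
#' determines the output.
#'
#' @param seed integer seed.
#' @param n_targets number of targets.
#' @param ligands_per_target curated ligands per target (at least 4: three
#'   near-duplicate potent seed ligands plus decorated variants).
#' @param coefficients numeric `(a0, a1, a2)` of the planted logistic law
#'   `P(active) = plogis(a0 + a1*Tc_most + a2*pKi_most)`.
#' @param threshold pKi activity threshold the labels are planted around.
#' @param scheme fingerprint scheme the generator uses to realise the
#'   planted similarities.
#' @param dup_same_ref_rate fraction of pairs given extra same-publication
#'   measurements (resolved by the minimum-Ki rule).
#' @param dup_cross_ref_rate fraction of pairs measured in a second
#'   publication (resolved by the cross-publication mean).
#' @param ineffective_rate fraction of extra records made ineffective
#'   (missing units/value/reference, low confidence, ambiguous operator,
#'   unknown unit token).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_targets = 50, ligands_per_target = 20,
                             coefficients = c(-15.5, 6, 2), threshold = 6,
                             scheme = "morgan",
                             dup_same_ref_rate = 0.15,
                             dup_cross_ref_rate = 0.15,
                             ineffective_rate = 0.2) {
  stopifnot(length(coefficients) == 3, n_targets >= 1,
            ligands_per_target >= 4,
            ligands_per_target - 3 <= length(.SUBSTITUENTS))
  structure(list(seed = as.integer(seed), n_targets = n_targets,
                 ligands_per_target = ligands_per_target,
                 coefficients = as.numeric(coefficients),
                 threshold = threshold, scheme = scheme,
                 dup_same_ref_rate = dup_same_ref_rate,
                 dup_cross_ref_rate = dup_cross_ref_rate,
                 ineffective_rate = ineffective_rate),
            class = "generator_config")
}

#' Homologous series on the benzene core
#'
#' Returns the seed structure followed by `n` homologues of increasing
#' alkyl chain length; Tanimoto similarity to the seed decreases along the
#' series, which makes the family's similarity gradient directly testable.
#'
#' @param n number of homologues.
#' @return character vector of `n + 1` SMILES.
#' @export
homologous_series <- function(n) {
  c("c1ccccc1", paste0("c1ccccc1", vapply(seq_len(n), strrep, "", x = "C")))
}

#' Simulate a raw bioactivity table with its curated answer key
#'
#' Emits ChEMBL-style raw records exercising every curation rule:
#' same-publication duplicates (resolved by minimum Ki), cross-publication
#' duplicates (resolved by the mean of per-publication minima), and
#' ineffective records of every kind (missing value/units/reference, low
#' confidence score, ambiguous relation operators, unknown unit tokens).
#' The generator also emits the curated table it expects back, so curation
#' can be golden-tested against the construction.
#'
#' @param cfg a [generator_config()]; `ligands_per_target` here is the
#'   number of clean pairs per target.
#' @return list with `records` (raw data.frame, shuffled) and `answer`
#'   (expected curated pairs: `target_id`, `ligand_id`, `smiles`,
#'   `ki_molar`, `pKi`).
#' @export
simulate_bioactivity_table <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  units_pool <- c("pM", "nM", "uM")
  rows <- list()
  answer <- list()
  for (t in seq_len(cfg$n_targets)) {
    tid <- sprintf("T%03d", t)
    for (j in seq_len(cfg$ligands_per_target)) {
      lid <- sprintf("%s_L%03d", tid, j)
      smi <- paste0(.SUBSTITUENTS[(j - 1) %% length(.SUBSTITUENTS) + 1],
                    .target_scaffold(t))
      true_pki <- stats::runif(1, 4, 9)
      base_ki <- 10^(-true_pki)
      n_refs <- 1 + stats::rbinom(1, 1, cfg$dup_cross_ref_rate)
      ref_minima <- numeric(n_refs)
      for (r in seq_len(n_refs)) {
        ref <- sprintf("REF%04d", (t * 97 + r * 13) %% 5000)
        ref_ki <- base_ki * if (r == 1) 1 else 10^stats::runif(1, -0.5, 0.5)
        n_meas <- 1 + stats::rbinom(1, 2, cfg$dup_same_ref_rate)
        kis <- ref_ki * c(1, 10^stats::runif(n_meas - 1, 0.1, 1))
        ref_minima[r] <- min(kis)
        for (k in kis) {
          u <- sample(units_pool, 1)
          rows[[length(rows) + 1]] <- data.frame(
            target_id = tid, ligand_id = lid, smiles = smi,
            activity_type = "Ki", relation = "=",
            value = k / .KI_UNIT_FACTORS[[.normalize_units(u)]],
            units = u, reference_id = ref, confidence_score = 9L,
            stringsAsFactors = FALSE)
        }
      }
      final_ki <- mean(ref_minima)
      answer[[length(answer) + 1]] <- data.frame(
        target_id = tid, ligand_id = lid, smiles = smi,
        ki_molar = final_ki, pKi = -log10(final_ki),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  # ineffective records: one of each defect kind first (coverage), then random
  defect <- function(df, kind) {
    switch(kind,
           missing_units = { df$units <- NA_character_; df },
           missing_value = { df$value <- NA_real_; df },
           missing_reference = { df$reference_id <- NA_character_; df },
           low_confidence = { df$confidence_score <- 8L; df },
           ambiguous_gt = { df$relation <- ">"; df },
           ambiguous_lt = { df$relation <- "<"; df },
           ambiguous_tilde = { df$relation <- "~"; df },
           unknown_units = { df$units <- "mg/mL"; df },
           wrong_type = { df$activity_type <- "IC50"; df })
  }
  kinds <- c("missing_units", "missing_value", "missing_reference",
             "low_confidence", "ambiguous_gt", "ambiguous_lt",
             "ambiguous_tilde", "unknown_units", "wrong_type")
  n_bad <- max(if (cfg$ineffective_rate > 0) length(kinds) else 0,
               round(cfg$ineffective_rate * nrow(records)))
  if (n_bad > 0) {
    src <- records[sample(nrow(records), n_bad, replace = TRUE), , drop = FALSE]
    bad <- do.call(rbind, lapply(seq_len(n_bad), function(i)
      defect(src[i, , drop = FALSE], kinds[(i - 1) %% length(kinds) + 1])))
    records <- rbind(records, bad)
  }
  records <- records[sample(nrow(records)), , drop = FALSE]
  rownames(records) <- NULL
  ans <- do.call(rbind, answer)
  ans <- ans[order(ans$target_id, ans$ligand_id), , drop = FALSE]
  rownames(ans) <- NULL
  list(records = records, answer = ans)
}

#' Simulate a ligand panel following a planted logistic activity law
#'
#' Each target gets three near-duplicate active "seed" ligands (pKi drawn
#' uniformly in \[6.5, 10\], above both activity thresholds) and decorated
#' variants with graded structural similarity. Nearest-neighbour identity
#' depends only on the structures, so the generator first computes every
#' ligand's realised within-target nearest neighbour, then assigns variant
#' activities by conditional resampling (a short Gibbs sweep over the
#' nearest-neighbour dependency graph) so that each variant's activity
#' label follows the planted law
#' `P(active) = plogis(a0 + a1*tc_most + a2*pKi_most)` given its realised
#' neighbour features; an active variant's pKi lands above the threshold,
#' an inactive one's below it. The expected accuracy of the Bayes-optimal
#' classifier under the planted law is computable from the realised
#' features and stored alongside the panel.
#'
#' @param cfg a [generator_config()].
#' @return a [target_panel()]; attribute `"truth"` holds the per-ligand
#'   answer key (`nn_ligand_id`, realised `tc_most` and `pki_most`, linear
#'   predictor `eta`, `p_active`, `is_seed`) and attribute
#'   `"bayes_accuracy"` the expected Bayes accuracy (a variant is called
#'   correctly with probability `max(p, 1 - p)`; a seed is
#'   deterministically active and called correctly iff `p > 0.5`).
#' @export
simulate_panel <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  a <- cfg$coefficients
  n_lig <- cfg$ligands_per_target
  n_var <- n_lig - 3
  rows <- vector("list", cfg$n_targets)
  truth <- vector("list", cfg$n_targets)
  for (t in seq_len(cfg$n_targets)) {
    tid <- sprintf("T%03d", t)
    scaffold <- .target_scaffold(t)
    seed_smiles <- c(scaffold, paste0(scaffold, "C"), paste0(scaffold, "CC"))
    subs <- sample(.SUBSTITUENTS, n_var)
    smiles <- c(seed_smiles, paste0(subs, scaffold))
    ids <- c(sprintf("%s_S%d", tid, 1:3),
             sprintf("%s_V%03d", tid, seq_len(n_var)))
    fps <- compute_fingerprint(smiles, cfg$scheme)
    mu <- stats::runif(1, 6.5, 10)
    pki <- numeric(n_lig)
    pki[1:3] <- mu + stats::runif(3, -0.2, 0.2)
    margin <- stats::runif(n_lig, 0.2, 2.5)
    is_seed <- c(TRUE, TRUE, TRUE, rep(FALSE, n_var))
    pki[!is_seed] <- cfg$threshold + margin[!is_seed]
    # Joint fixed point of the nearest-neighbour graph and the activity
    # assignment: the graph uses the scanner's own tie-break (higher pKi,
    # then ligand id), which depends on the pKi values, while each
    # variant's label is redrawn from the planted law given its current
    # neighbour's pKi (Gibbs sweeps). Iterate until the graph is stable
    # under the final pKi assignment, so the answer key coincides exactly
    # with what leave-one-out similarity search recovers downstream.
    nn_idx <- integer(n_lig); tc_nn <- numeric(n_lig)
    nn_graph <- function() {
      vapply(seq_len(n_lig), function(i) {
        nn <- most_similar(fps[[i]], ids[-i], fps[-i], pki[-i])
        c(match(nn$ligand_id, ids), nn$tc_most)
      }, numeric(2))
    }
    for (outer in 1:5) {
      g <- nn_graph()
      if (outer > 1 && all(g[1, ] == nn_idx)) break
      nn_idx <- as.integer(g[1, ]); tc_nn <- g[2, ]
      for (sweep in 1:3) {
        for (v in which(!is_seed)) {
          p_act <- stats::plogis(a[1] + a[2] * tc_nn[v] + a[3] * pki[nn_idx[v]])
          active <- stats::rbinom(1, 1, p_act) == 1
          pki[v] <- cfg$threshold + (if (active) margin[v] else -margin[v])
        }
      }
    }
    eta <- a[1] + a[2] * tc_nn + a[3] * pki[nn_idx]
    rows[[t]] <- data.frame(target_id = tid, ligand_id = ids,
                            smiles = smiles, pKi = pki,
                            stringsAsFactors = FALSE)
    truth[[t]] <- data.frame(target_id = tid, ligand_id = ids,
                             is_seed = is_seed, nn_ligand_id = ids[nn_idx],
                             tc_most = tc_nn, pki_most = pki[nn_idx],
                             eta = eta, p_active = stats::plogis(eta),
                             stringsAsFactors = FALSE)
  }
  panel <- target_panel(do.call(rbind, rows), release = "synthetic")
  key <- do.call(rbind, truth)
  contrib <- ifelse(key$is_seed, as.numeric(key$p_active > 0.5),
                    pmax(key$p_active, 1 - key$p_active))
  attr(panel, "truth") <- key
  attr(panel, "bayes_accuracy") <- mean(contrib)
  panel
}

#' Simulate feature/label pairs from the logistic law
#'
#' Draws `tc_most ~ Uniform(0, 1)`, `pki_most` from an equal mixture of
#' N(5, 1) and N(8, 1), and labels from
#' `Bernoulli(plogis(a0 + a1*tc + a2*pki))` — the direct route for logistic
#' parameter-recovery checks.
#'
#' @param n number of pairs.
#' @param coefficients numeric `(a0, a1, a2)`.
#' @param seed integer seed.
#' @return data.frame with columns `tc_most`, `pki_most`, `label`.
#' @export
simulate_feature_data <- function(n, coefficients = c(-10, 6, 1), seed = 1L) {
  stopifnot(length(coefficients) == 3, n >= 1)
  set.seed(as.integer(seed))
  tc <- stats::runif(n)
  comp <- stats::rbinom(n, 1, 0.5)
  pki <- stats::rnorm(n, mean = ifelse(comp == 1, 8, 5), sd = 1)
  eta <- coefficients[1] + coefficients[2] * tc + coefficients[3] * pki
  label <- stats::rbinom(n, 1, stats::plogis(eta))
  data.frame(tc_most = tc, pki_most = pki, label = label)
}
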