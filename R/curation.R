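# Curation of raw Ki bioactivity tables into labelled target-ligand panels.
#
# The raw input is a flat export in the ChEMBL dialect: one row per measurement
# with provenance (reference id, confidence score) and a relation operator.
# Curation keeps only unambiguous direct-binding Ki measurements, resolves
# duplicate measurements of the same target-ligand pair, converts to pKi and
# applies ligand-count filters per target.

.KI_UNIT_FACTORS <- c(pm = 1e-12, nm = 1e-9, um = 1e-6, m = 1)

.normalize_units <- function(units) {
  u <- tolower(trimws(as.character(units)))
  u <- gsub("µ", "u", u)  # micro sign
  u <- gsub("μ", "u", u)  # greek mu
  u
}

#' Read a ChEMBL-style bioactivity table
#'
#' Reads a TSV or CSV file with the columns `target_id`, `ligand_id`,
#' `smiles`, `activity_type`, `relation`, `value`, `units`, `reference_id`
#' and `confidence_score` (any column order; extra columns are ignored).
#' Empty strings and `NA` tokens are read as missing.
#'
#' @param file path to a delimited text file.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`.csv` gives `","`, anything else tab).
#' @return a `data.frame` of raw bioactivity records.
#' @export
read_bioactivity <- function(file, sep = NULL) {
  if (!file.exists(file)) stop("bioactivity file not found: ", file)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(file, header = TRUE, sep = sep, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  required <- c("target_id", "ligand_id", "smiles", "activity_type", "relation",
                "value", "units", "reference_id", "confidence_score")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("bioactivity table ", file, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df[required]
}

#' Drop ineffective bioactivity records
#'
#' Applies the record-quality rules used to build the benchmark Ki panels:
#' a record is kept only when its activity type is `"Ki"`, its confidence
#' score is 9 (direct binding to the assigned target), its concentration
#' value, units and reference are all present, its units token is a known
#' concentration unit, and its relation operator is an exact `"="`.
#' Records with unspecified values/units/references or ambiguous operators
#' (`>`, `<`, `~`, missing) are classified ineffective and removed.
#'
#' The returned data frame carries an `"audit"` attribute: a named integer
#' vector counting how many records each rule removed (a record is counted
#' once, under the first rule it fails). Retrieve it with [curation_audit()].
#'
#' @param records data.frame of raw records as from [read_bioactivity()].
#' @return the retained records, input order preserved, with an audit
#'   attribute.
#' @export
filter_effective <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  rules <- list(
    wrong_type       = function(r) is.na(r$activity_type) | r$activity_type != "Ki",
    low_confidence   = function(r) is.na(r$confidence_score) | r$confidence_score != 9,
    missing_value    = function(r) is.na(r$value) | !is.finite(as.numeric(r$value)) |
                                   as.numeric(r$value) <= 0,
    missing_units    = function(r) is.na(r$units),
    unknown_units    = function(r) !(.normalize_units(r$units) %in% names(.KI_UNIT_FACTORS)),
    missing_reference = function(r) is.na(r$reference_id),
    ambiguous_operator = function(r) is.na(r$relation) | r$relation != "="
  )
  dropped <- rep(FALSE, n)
  audit <- integer(length(rules))
  names(audit) <- names(rules)
  for (i in seq_along(rules)) {
    bad <- !dropped & rules[[i]](records)
    audit[i] <- sum(bad)
    dropped <- dropped | bad
  }
  out <- records[!dropped, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' @rdname filter_effective
#' @param x an object produced by a curation step.
#' @export
curation_audit <- function(x) attr(x, "audit")

#' Convert a Ki concentration to pKi
#'
#' pKi is the negative base-10 logarithm of the inhibition constant expressed
#' in mol/L, so a 1 nM binder has pKi 9. Vectorised over both arguments.
#'
#' @param value positive concentration value(s).
#' @param units units token(s): one of `"pM"`, `"nM"`, `"uM"`, `"M"`
#'   (case-insensitive; the micro sign is accepted for `"uM"`).
#' @return numeric pKi value(s).
#' @export
#' @examples
#' to_pki(1000, "nM")  # 6
#' to_pki(26.8, "uM")  # 4.57
to_pki <- function(value, units) {
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("Ki values must be positive and finite")
  u <- .normalize_units(units)
  unknown <- setdiff(unique(u), names(.KI_UNIT_FACTORS))
  if (length(unknown) > 0)
    stop("unknown concentration unit token(s): ", paste(unknown, collapse = ", "))
  unname(-log10(value * .KI_UNIT_FACTORS[u]))
}

.ki_molar <- function(value, units) as.numeric(value) * .KI_UNIT_FACTORS[.normalize_units(units)]

#' Resolve duplicate measurements of one target-ligand pair
#'
#' Within one publication the smallest Ki (highest pKi) is taken, reflecting
#' experimental optimisation; if measurements from several publications
#' remain, the arithmetic mean of the per-publication minima is taken on the
#' Ki concentration scale before conversion to pKi. Setting
#' `mean_scale = "pKi"` instead averages the per-publication pKi values
#' (a geometric mean on the Ki scale).
#'
#' @param records effective records (after [filter_effective()]).
#' @param mean_scale `"Ki"` (default) or `"pKi"`; scale on which the
#'   cross-publication mean is taken.
#' @return data.frame with one row per (target_id, ligand_id) pair and
#'   columns `target_id`, `ligand_id`, `smiles`, `ki_molar`, `pKi`.
#' @export
deduplicate <- function(records, mean_scale = c("Ki", "pKi")) {
  mean_scale <- match.arg(mean_scale)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0)
    return(data.frame(target_id = character(), ligand_id = character(),
                      smiles = character(), ki_molar = numeric(),
                      pKi = numeric(), stringsAsFactors = FALSE))
  ki <- .ki_molar(records$value, records$units)
  bad <- !is.finite(ki) | ki <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-normalizable units/values rejected")
    records <- records[!bad, , drop = FALSE]
    ki <- ki[!bad]
  }
  pair <- paste(records$target_id, records$ligand_id, sep = "\r")
  refmin <- stats::aggregate(
    ki,
    by = list(pair = pair, reference_id = as.character(records$reference_id)),
    FUN = min)
  agg_fun <- function(k) {
    if (mean_scale == "Ki") mean(k) else 10^(mean(log10(k)))
  }
  final <- stats::aggregate(refmin$x, by = list(pair = refmin$pair), FUN = agg_fun)
  first <- records[!duplicated(pair), , drop = FALSE]
  fpair <- paste(first$target_id, first$ligand_id, sep = "\r")
  idx <- match(final$pair, fpair)
  out <- data.frame(target_id = first$target_id[idx],
                    ligand_id = first$ligand_id[idx],
                    smiles = first$smiles[idx],
                    ki_molar = final$x,
                    stringsAsFactors = FALSE)
  out$pKi <- -log10(out$ki_molar)
  out <- out[order(out$target_id, out$ligand_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label a ligand active or inactive at a pKi threshold
#'
#' @param pki numeric pKi value(s).
#' @param threshold activity threshold on the pKi scale; the benchmark panels
#'   use 5 (10 uM) or 6 (1 uM).
#' @return integer 0/1 vector; 1 iff `pki >= threshold`.
#' @export
label_activity <- function(pki, threshold) {
  if (missing(threshold)) stop("an explicit pKi threshold is required")
  stopifnot(is.numeric(pki), is.numeric(threshold), length(threshold) == 1)
  as.integer(pki >= threshold)
}

#' Construct a target panel from curated pairs
#'
#' A target panel is the curated per-target ligand set representation used
#' throughout the package: a data.frame with columns `target_id`,
#' `ligand_id`, `smiles`, `pKi` (one row per pair, unique within target)
#' plus a release tag.
#'
#' @param pairs data.frame with at least `target_id`, `ligand_id`, `smiles`,
#'   `pKi` columns.
#' @param release free-text provenance tag.
#' @return an object of class `target_panel`.
#' @export
target_panel <- function(pairs, release = NA_character_) {
  required <- c("target_id", "ligand_id", "smiles", "pKi")
  missing <- setdiff(required, names(pairs))
  if (length(missing) > 0)
    stop("panel lacks column(s): ", paste(missing, collapse = ", "))
  pairs <- as.data.frame(pairs)[required]
  if (any(!is.finite(pairs$pKi))) stop("pKi must be finite")
  key <- paste(pairs$target_id, pairs$ligand_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (target_id, ligand_id) pair(s) in panel; curate first")
  rownames(pairs) <- NULL
  structure(pairs, release = release, class = c("target_panel", "data.frame"))
}

#' @export
print.target_panel <- function(x, ...) {
  cat("target panel:", length(unique(x$target_id)), "target(s),",
      nrow(x), "ligand-target pair(s)")
  rel <- attr(x, "release")
  if (!is.na(rel)) cat(" [release ", rel, "]", sep = "")
  cat("\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Filter targets by curated ligand count
#'
#' Targets annotated with fewer than `min_ligands` or more than `max_ligands`
#' ligands are removed from the panel. Counts are taken after deduplication,
#' before activity labelling. Idempotent.
#'
#' @param panel a [target_panel()].
#' @param min_ligands,max_ligands inclusive bounds on ligand count per target.
#' @return the filtered panel.
#' @export
filter_targets <- function(panel, min_ligands = 10, max_ligands = 10000) {
  counts <- table(panel$target_id)
  keep_targets <- names(counts)[counts >= min_ligands & counts <= max_ligands]
  out <- panel[panel$target_id %in% keep_targets, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, release = attr(panel, "release"),
            class = c("target_panel", "data.frame"))
}

#' Full curation pipeline: raw records to target panel
#'
#' Chains [filter_effective()], [deduplicate()] and [filter_targets()], and
#' returns a [target_panel()] whose `"audit"` attribute aggregates the
#' per-rule drop counts of the whole pipeline.
#'
#' @inheritParams filter_effective
#' @inheritParams deduplicate
#' @inheritParams filter_targets
#' @param release provenance tag stored on the panel.
#' @return a `target_panel` with an audit attribute.
#' @export
curate_panel <- function(records, min_ligands = 10, max_ligands = 10000,
                         mean_scale = "Ki", release = NA_character_) {
  eff <- filter_effective(records)
  audit <- curation_audit(eff)
  pairs <- deduplicate(eff, mean_scale = mean_scale)
  audit <- c(audit, duplicate_records = nrow(eff) - nrow(pairs))
  panel <- target_panel(pairs[c("target_id", "ligand_id", "smiles", "pKi")],
                        release = release)
  out <- filter_targets(panel, min_ligands, max_ligands)
  audit <- c(audit, target_size_filter = nrow(panel) - nrow(out))
  attr(out, "audit") <- audit
  out
}

#' Write / read a curated panel as TSV
#'
#' The on-disk format is a tab-separated table with columns `target_id`,
#' `ligand_id`, `smiles`, `pKi` and an optional leading comment line
#' carrying the release tag.
#'
#' @param panel a `target_panel`.
#' @param file path.
#' @return `write_panel` returns `file` invisibly; `read_panel` returns a
#'   `target_panel`.
#' @export
write_panel <- function(panel, file) {
  con <- file(file, "w")
  on.exit(close(con))
  rel <- attr(panel, "release")
  if (!is.null(rel) && !is.na(rel)) writeLines(paste0("# release: ", rel), con)
  utils::write.table(as.data.frame(panel), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_panel
#' @export
read_panel <- function(file) {
  if (!file.exists(file)) stop("panel file not found: ", file)
  head1 <- readLines(file, n = 1)
  release <- if (grepl("^# release: ", head1)) sub("^# release: ", "", head1) else NA_character_
  df <- utils::read.table(file, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  target_panel(df, release = release)
}

#' Target-ligand pairs newly deposited in a later release
#'
#' Given panels curated with identical rules from an older and a newer
#' database release, returns the pairs present in the new panel but absent
#' from the old one, restricted to targets occurring in both releases.
#' This is the test set construction for temporal validation.
#'
#' @param old_panel,new_panel `target_panel` objects.
#' @return a data.frame of new pairs (`target_id`, `ligand_id`, `smiles`,
#'   `pKi`).
#' @export
temporal_new_pairs <- function(old_panel, new_panel) {
  shared <- intersect(unique(old_panel$target_id), unique(new_panel$target_id))
  new_shared <- new_panel[new_panel$target_id %in% shared, , drop = FALSE]
  old_key <- paste(old_panel$target_id, old_panel$ligand_id, sep = "\r")
  new_key <- paste(new_shared$target_id, new_shared$ligand_id, sep = "\r")
  out <- as.data.frame(new_shared[!(new_key %in% old_key), , drop = FALSE])
  rownames(out) <- NULL
  out
}
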