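# Fingerprints, Tanimoto similarity and most-similar ligand search.
#
# Both fingerprint schemes are computed by OpenBabel (through ChemmineOB):
# "morgan" is OpenBabel's ECFP4 circular fingerprint (radius 2, 4096-bit
# space), "fp2" the path-based FP2 (linear fragments up to 7 atoms, 1024
# bits). Similarity always operates on folded bit sets so both schemes share
# one Tanimoto code path.

.FP_SCHEMES <- list(
  morgan = list(ob_name = "ECFP4", length = 4096L),
  fp2    = list(ob_name = "FP2",   length = 1024L)
)

# package-local fingerprint cache, keyed by canonical SMILES + scheme + length
.fp_cache <- new.env(parent = emptyenv())

.parse_molecules <- function(smiles) {
  res <- try(suppressWarnings(
    ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)),
    silent = TRUE)
  if (!inherits(res, "try-error") && length(res) == length(smiles)) return(res)
  # batch parse failed: locate the offending string for a useful error
  for (s in smiles) {
    one <- try(suppressWarnings(
      ChemmineOB::forEachMol("SMILES", s, identity)), silent = TRUE)
    if (inherits(one, "try-error") || length(one) != 1)
      stop("cannot parse SMILES: '", s, "'")
  }
  stop("cannot parse SMILES input")
}

#' Canonical SMILES
#'
#' Canonicalises SMILES strings with OpenBabel, so that different spellings
#' of one molecule map to one cache key and one fingerprint.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  .parse_molecules(smiles)  # validate with a good error message
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste(smiles, collapse = "\n"))
  vapply(strsplit(strsplit(out, "\n")[[1]], "\t"), `[`, "", 1)
}

.fp_from_bitvec <- function(bits, scheme, length) {
  structure(list(scheme = scheme,
                 length = as.integer(length),
                 on_bits = as.integer(which(bits != 0) - 1L)),
            class = "chem_fp")
}

#' Compute molecular fingerprints
#'
#' @param smiles character vector of SMILES strings (all must parse).
#' @param scheme `"morgan"` (ECFP4-like circular, radius 2) or `"fp2"`
#'   (path-based).
#' @param fold optional folded length (a divisor of the native bit-space
#'   size); `NULL` keeps the scheme's native length (4096 for morgan,
#'   1024 for fp2).
#' @return for a single SMILES a `chem_fp` object (scheme, length, sorted
#'   zero-based on-bit set); for several, a list of them.
#' @export
#' @examples
#' \dontrun{
#' fp <- compute_fingerprint("c1ccccc1", "morgan")
#' }
compute_fingerprint <- function(smiles, scheme = c("morgan", "fp2"), fold = NULL) {
  scheme <- match.arg(scheme)
  info <- .FP_SCHEMES[[scheme]]
  len <- if (is.null(fold)) info$length else as.integer(fold)
  if (info$length %% len != 0)
    stop("fold length ", len, " does not divide the native ", info$length,
         "-bit space of scheme '", scheme, "'")
  can <- canonical_smiles(smiles)
  keys <- paste(can, scheme, len, sep = "\r")
  need <- !vapply(keys, exists, TRUE, envir = .fp_cache)
  if (any(need)) {
    idx <- which(need & !duplicated(keys))
    mols <- .parse_molecules(can[idx])
    for (j in seq_along(idx)) {
      bits <- ChemmineOB::fingerprint_OB(mols[j], info$ob_name)
      fp <- .fp_from_bitvec(bits, scheme, info$length)
      if (len < info$length)
        fp <- structure(list(scheme = scheme, length = len,
                             on_bits = sort(unique(fp$on_bits %% len))),
                        class = "chem_fp")
      assign(keys[idx[j]], fp, envir = .fp_cache)
    }
  }
  fps <- lapply(keys, get, envir = .fp_cache)
  if (length(fps) == 1) fps[[1]] else fps
}

#' @export
print.chem_fp <- function(x, ...) {
  cat("<", x$scheme, " fingerprint: ", length(x$on_bits), " on-bits / ",
      x$length, ">\n", sep = "")
  invisible(x)
}

#' Tanimoto coefficient between two fingerprints
#'
#' Tc = |A intersect B| / |A union B| over the on-bit sets, the standard 2D
#' chemical similarity in \[0, 1\]. Two empty fingerprints are defined as
#' dissimilar (Tc 0, with a message): a featureless pair carries no evidence
#' of similarity.
#'
#' @param a,b `chem_fp` objects of the same scheme and length.
#' @return Tanimoto similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "chem_fp"), inherits(b, "chem_fp"))
  if (a$scheme != b$scheme || a$length != b$length)
    stop("fingerprint scheme/length mismatch: ",
         a$scheme, "/", a$length, " vs ", b$scheme, "/", b$length)
  na <- length(a$on_bits); nb <- length(b$on_bits)
  if (na == 0 && nb == 0) {
    message("Tanimoto of two empty fingerprints; returning 0")
    return(0)
  }
  inter <- length(intersect(a$on_bits, b$on_bits))
  inter / (na + nb - inter)
}

# Tc of one query fingerprint against a list of fingerprints (same scheme).
.tanimoto_many <- function(query, fps) {
  q <- query$on_bits
  nq <- length(q)
  vapply(fps, function(f) {
    nf <- length(f$on_bits)
    if (nq == 0 && nf == 0) return(0)
    inter <- length(intersect(q, f$on_bits))
    inter / (nq + nf - inter)
  }, 0)
}

#' Fingerprints for every ligand of a panel
#'
#' @param panel a [target_panel()] (or any data.frame with a `smiles`
#'   column).
#' @param scheme fingerprint scheme, see [compute_fingerprint()].
#' @param fold optional folded length.
#' @return a list of `chem_fp`, parallel to the panel rows.
#' @export
panel_fingerprints <- function(panel, scheme = "morgan", fold = NULL) {
  if (nrow(panel) == 0) return(list())
  fps <- compute_fingerprint(panel$smiles, scheme, fold)
  if (inherits(fps, "chem_fp")) fps <- list(fps)
  fps
}

#' Most-similar ligand of a target for a query
#'
#' Scans the annotated ligand set of one target and returns its
#' most-similar ligand: the nearest neighbour under Tanimoto similarity,
#' whose similarity and potency (`tc_most`, `pki_most`) are the two features
#' of the inference model. Ties on Tc are broken towards the higher pKi,
#' then towards the lexicographically smaller ligand id, so the result does
#' not depend on ligand order.
#'
#' @param query_fp `chem_fp` of the query compound.
#' @param ligand_ids character vector of ligand ids.
#' @param fps list of `chem_fp`, parallel to `ligand_ids`.
#' @param pkis numeric pKi values, parallel to `ligand_ids`.
#' @return a list with elements `ligand_id`, `tc_most`, `pki_most`.
#' @export
most_similar <- function(query_fp, ligand_ids, fps, pkis) {
  n <- length(ligand_ids)
  if (n == 0) stop("target has no ligands; cannot search a nearest neighbour")
  stopifnot(length(fps) == n, length(pkis) == n)
  tc <- .tanimoto_many(query_fp, fps)
  ord <- order(-tc, -pkis, ligand_ids)
  best <- ord[1]
  list(ligand_id = ligand_ids[best], tc_most = tc[best], pki_most = pkis[best])
}

#' Read query compounds from a .smi file
#'
#' Each non-empty line holds a SMILES string and an optional whitespace-
#' separated identifier; missing ids are numbered `query_1`, `query_2`, ...
#'
#' @param file path to a SMILES file.
#' @return data.frame with columns `query_id`, `smiles`.
#' @export
read_smi <- function(file) {
  if (!file.exists(file)) stop("query file not found: ", file)
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[`, "", 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("query_", i)
  }, "")
  data.frame(query_id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Persist fingerprints as a TSV table
#'
#' Columns: `ligand_id`, `scheme`, `length`, comma-separated `on_bits`.
#'
#' @param fps list of `chem_fp`.
#' @param ligand_ids parallel character vector.
#' @param file path.
#' @return `write_fingerprints` returns `file` invisibly; `read_fingerprints`
#'   a list with elements `ligand_ids` and `fps`.
#' @export
write_fingerprints <- function(fps, ligand_ids, file) {
  df <- data.frame(
    ligand_id = ligand_ids,
    scheme = vapply(fps, `[[`, "", "scheme"),
    length = vapply(fps, `[[`, 0L, "length"),
    on_bits = vapply(fps, function(f) paste(f$on_bits, collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  fps <- lapply(seq_len(nrow(df)), function(i) {
    bits <- if (is.na(df$on_bits[i]) || df$on_bits[i] == "") integer() else
      as.integer(strsplit(df$on_bits[i], ",")[[1]])
    structure(list(scheme = df$scheme[i], length = as.integer(df$length[i]),
                   on_bits = bits), class = "chem_fp")
  })
  list(ligand_ids = df$ligand_id, fps = fps)
}
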