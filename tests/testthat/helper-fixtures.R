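# Shared fixture builders. Everything is generated in code; chemistry-free
# tests use hand-built fingerprint objects so they stay fast.

# one raw bioactivity record with overridable fields
record <- function(target_id = "T1", ligand_id = "L1", smiles = "c1ccccc1",
                   activity_type = "Ki", relation = "=", value = 100,
                   units = "nM", reference_id = "R1", confidence_score = 9L) {
  data.frame(target_id = target_id, ligand_id = ligand_id, smiles = smiles,
             activity_type = activity_type, relation = relation,
             value = value, units = units, reference_id = reference_id,
             confidence_score = confidence_score, stringsAsFactors = FALSE)
}

records <- function(...) do.call(rbind, list(...))

# synthetic fingerprint with explicit on-bits (chemistry-free)
fp_of <- function(on_bits, length = 64, scheme = "morgan") {
  structure(list(scheme = scheme, length = as.integer(length),
                 on_bits = as.integer(sort(unique(on_bits)))),
            class = "chem_fp")
}

rand_fp <- function(length = 64, density = 0.2, scheme = "morgan") {
  n_on <- stats::rbinom(1, length, density)
  fp_of(sample(0:(length - 1), n_on), length, scheme)
}

# brute-force Tanimoto from first principles (independent of tanimoto())
tanimoto_oracle <- function(a, b) {
  u <- union(a$on_bits, b$on_bits)
  if (length(u) == 0) return(0)
  length(intersect(a$on_bits, b$on_bits)) / length(u)
}

# brute-force BH step-up adjustment (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, min(1, p[ord[i]] * m / i))
    adj[ord[i]] <- prev
  }
  adj
}

# small chemistry-backed panel, built once per test session
tiny_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_panel(generator_config(seed = 5, n_targets = 6,
                                                ligands_per_target = 10))
    cache
  }
})
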