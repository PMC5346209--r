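test_that("filter_effective drops each kind of ineffective record and keeps order", {
  good1 <- record(ligand_id = "L1")
  good2 <- record(ligand_id = "L2", units = "uM")
  bad <- records(
    record(ligand_id = "B1", units = NA),
    record(ligand_id = "B2", confidence_score = 8L),
    record(ligand_id = "B3", value = NA),
    record(ligand_id = "B4", reference_id = NA),
    record(ligand_id = "B5", relation = ">"),
    record(ligand_id = "B6", relation = "<"),
    record(ligand_id = "B7", relation = "~"),
    record(ligand_id = "B8", relation = NA),
    record(ligand_id = "B9", activity_type = "IC50"),
    record(ligand_id = "B10", units = "mg/mL"),
    record(ligand_id = "B11", value = -5))
  out <- filter_effective(records(good1, bad[1:5, ], good2, bad[6:11, ]))
  expect_identical(out$ligand_id, c("L1", "L2"))
  audit <- curation_audit(out)
  expect_identical(sum(audit), 11L)
  expect_identical(unname(audit["ambiguous_operator"]), 4L)
  expect_identical(unname(audit["low_confidence"]), 1L)
  expect_identical(unname(audit["unknown_units"]), 1L)
})

test_that("filter_effective on an empty table is the identity", {
  empty <- record()[0, ]
  expect_identical(nrow(filter_effective(empty)), 0L)
})

test_that("to_pki converts concentrations on the molar log scale", {
  expect_equal(to_pki(1000, "nM"), 6)
  expect_equal(to_pki(1, "nM"), 9)
  expect_equal(to_pki(26.8, "uM"), -log10(26.8e-6))
  expect_equal(round(to_pki(26.8, "uM"), 2), 4.57)
  expect_equal(to_pki(1, "M"), 0)
  # case-insensitive, micro-sign tolerant, monotone decreasing in value
  expect_equal(to_pki(5, "NM"), to_pki(5, "nM"))
  expect_equal(to_pki(2, "µM"), to_pki(2, "uM"))
  expect_true(to_pki(10, "nM") < to_pki(1, "nM"))
  expect_error(to_pki(1, "furlongs"), "furlongs")
  expect_error(to_pki(-1, "nM"), "positive")
})

test_that("deduplicate takes the per-reference minimum then the cross-reference mean", {
  # same pair, same reference: smallest Ki survives
  same_ref <- records(record(value = 10), record(value = 100))
  out <- deduplicate(same_ref)
  expect_equal(out$ki_molar, 10e-9)
  # same pair, two references: mean of per-reference minima
  cross_ref <- records(record(value = 10, reference_id = "R1"),
                       record(value = 20, reference_id = "R2"))
  expect_equal(deduplicate(cross_ref)$ki_molar, 15e-9)
  # single record passes through unchanged
  expect_equal(deduplicate(record(value = 7))$ki_molar, 7e-9)
  # mixed units are normalised to molar before comparison
  mixed <- records(record(value = 1, units = "uM"),
                   record(value = 50, units = "nM"))
  expect_equal(deduplicate(mixed)$ki_molar, 50e-9)
})

test_that("deduplicate combines both rules and is idempotent", {
  recs <- records(
    record(value = 10, reference_id = "R1"),
    record(value = 100, reference_id = "R1"),
    record(value = 30, reference_id = "R2"),
    record(target_id = "T2", value = 5))
  out <- deduplicate(recs)
  expect_equal(out$ki_molar[out$target_id == "T1"], mean(c(10e-9, 30e-9)))
  expect_equal(out$ki_molar[out$target_id == "T2"], 5e-9)
  expect_false(anyDuplicated(paste(out$target_id, out$ligand_id)) > 0)
  # curated Ki lies between the min and max of the per-reference minima
  expect_true(out$ki_molar[1] >= 10e-9 && out$ki_molar[1] <= 30e-9)
  # feeding curated values back through changes nothing
  redo <- records(record(value = out$ki_molar[1] * 1e9, reference_id = "R1"),
                  record(target_id = "T2", value = 5))
  expect_equal(deduplicate(redo)$ki_molar, out$ki_molar)
})

test_that("pKi-scale averaging option takes the geometric mean", {
  cross_ref <- records(record(value = 10, reference_id = "R1"),
                       record(value = 1000, reference_id = "R2"))
  expect_equal(deduplicate(cross_ref, mean_scale = "pKi")$ki_molar, 100e-9)
  expect_equal(deduplicate(cross_ref, mean_scale = "Ki")$ki_molar, 505e-9)
})

test_that("label_activity is a strict >= threshold rule, monotone across thresholds", {
  expect_identical(label_activity(5.0, 5), 1L)
  expect_identical(label_activity(4.99, 5), 0L)
  expect_identical(label_activity(6.0, 6), 1L)
  pki <- seq(3, 10, by = 0.25)
  expect_true(all(label_activity(pki, 5) >= label_activity(pki, 6)))
})

test_that("filter_targets enforces ligand-count bounds inclusively and idempotently", {
  pairs <- data.frame(
    target_id = c(rep("small", 9), rep("ten", 10), rep("big", 12)),
    ligand_id = paste0("L", 1:31), smiles = "c1ccccc1",
    pKi = 7, stringsAsFactors = FALSE)
  panel <- target_panel(pairs)
  out <- filter_targets(panel, min_ligands = 10, max_ligands = 11)
  expect_setequal(unique(out$target_id), "ten")
  expect_identical(nrow(filter_targets(out, 10, 11)), nrow(out))
  empty <- filter_targets(target_panel(pairs[0, ]))
  expect_identical(nrow(empty), 0L)
})

test_that("target_panel rejects duplicate pairs and non-finite pKi", {
  pairs <- data.frame(target_id = "T1", ligand_id = c("L1", "L1"),
                      smiles = "C", pKi = 7, stringsAsFactors = FALSE)
  expect_error(target_panel(pairs), "duplicate")
  expect_error(target_panel(data.frame(target_id = "T1", ligand_id = "L1",
                                       smiles = "C", pKi = Inf)), "finite")
})

test_that("temporal_new_pairs returns new pairs on shared targets only", {
  old <- target_panel(data.frame(
    target_id = c("T1", "T1"), ligand_id = c("L1", "L2"),
    smiles = "C", pKi = 7, stringsAsFactors = FALSE))
  new <- target_panel(data.frame(
    target_id = c("T1", "T1", "T2"), ligand_id = c("L1", "L3", "L9"),
    smiles = "C", pKi = 7, stringsAsFactors = FALSE))
  out <- temporal_new_pairs(old, new)
  expect_identical(out$ligand_id, "L3")   # L1 known, L9 on unshared target
  expect_identical(nrow(temporal_new_pairs(old, old)), 0L)
})

test_that("panel TSV round-trips with its release tag", {
  panel <- target_panel(data.frame(target_id = "T1", ligand_id = paste0("L", 1:3),
                                   smiles = "c1ccccc1", pKi = c(5, 6, 7),
                                   stringsAsFactors = FALSE),
                        release = "demo19")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, f)
  back <- read_panel(f)
  expect_equal(as.data.frame(back), as.data.frame(panel))
  expect_identical(attr(back, "release"), "demo19")
})

test_that("curate_panel chains the rules and reports an aggregate audit", {
  recs <- do.call(rbind, lapply(1:12, function(i)
    record(ligand_id = paste0("L", i), value = i * 10)))
  recs <- rbind(recs, record(ligand_id = "L1", value = 5),     # same-ref dup
                record(ligand_id = "LX", units = NA))          # ineffective
  panel <- curate_panel(recs, min_ligands = 10, release = "demo")
  expect_s3_class(panel, "target_panel")
  expect_identical(nrow(panel), 12L)
  expect_equal(panel$pKi[panel$ligand_id == "L1"], to_pki(5, "nM"))
  audit <- curation_audit(panel)
  expect_identical(unname(audit["missing_units"]), 1L)
  expect_identical(unname(audit["duplicate_records"]), 1L)
})
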