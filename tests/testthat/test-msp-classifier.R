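# residue localization, MSP calling and compartment tallies

test_that("locate_residue does interval membership with bounds handling", {
  rec <- fx_membrane_record()
  expect_equal(locate_residue(rec, 30), "extracellular")
  expect_equal(locate_residue(rec, 51), "transmembrane")
  expect_equal(locate_residue(rec, 71), "transmembrane")
  expect_equal(locate_residue(rec, 100), "intracellular")
  expect_equal(locate_residue(rec, 121), "position_out_of_bounds")
  expect_equal(locate_residue(rec, 0), "position_out_of_bounds")
  sec <- fx_secreted_record()
  expect_equal(locate_residue(sec, 5), "signal_peptide")
  expect_equal(locate_residue(sec, 50), "unannotated")
})

test_that("overlapping features follow precedence and warn", {
  rec <- protein_record(
    "OVL001", "OVLP1", paste(rep("ARNDCEQGHI", 10), collapse = ""),
    data.frame(kind = c("extracellular", "transmembrane"),
               start = c(1L, 40L), end = c(60L, 60L)))
  expect_warning(loc <- locate_residue(rec, 50), "overlapping")
  expect_equal(loc, "transmembrane")
  # propeptide is reported as signal_peptide (both cleaved)
  rec2 <- protein_record(
    "PRO001", "PROP1", paste(rep("ARNDCEQGHI", 5), collapse = ""),
    data.frame(kind = "propeptide", start = 1L, end = 10L))
  expect_equal(locate_residue(rec2, 5), "signal_peptide")
})

test_that("locate_residue matches a brute-force feature scan on random synthetic positions", {
  # independent oracle: scan every feature linearly, collect all covering
  # kinds, apply the documented precedence by explicit ordering
  oracle <- function(rec, pos) {
    if (pos < 1 || pos > nchar(rec$sequence)) return("position_out_of_bounds")
    kinds <- character()
    f <- rec$features
    for (i in seq_len(nrow(f))) {
      if (pos >= f$start[i] && pos <= f$end[i]) kinds <- c(kinds, f$kind[i])
    }
    if (!base::length(kinds)) return("unannotated")
    for (k in c("transmembrane", "extracellular", "intracellular",
                "lumenal", "signal_peptide", "propeptide")) {
      if (k %in% kinds) return(if (k == "propeptide") "signal_peptide" else k)
    }
  }
  prot <- make_proteome(proteome_spec(n_proteins = 30, seed = 11))
  recs <- prot$store$records
  withr::with_seed(42, {
    for (i in seq_len(1000)) {
      rec <- recs[[sample(base::length(recs), 1)]]
      # include out-of-bounds probes
      pos <- sample.int(nchar(rec$sequence) + 10L, 1)
      expect_identical(suppressWarnings(locate_residue(rec, pos)),
                       oracle(rec, pos))
    }
  })
})

test_that("call_msp applies the surface rule", {
  memb <- fx_membrane_record()
  sec <- fx_secreted_record()
  intr <- fx_intracellular_record()

  # extracellular residue of a membrane protein: MSP
  v <- fx_variant("S1", "MEMB1", "D", 24, "N")  # sequence pos 24 is D
  call <- call_msp(memb, v)
  expect_true(call$is_msp)
  expect_equal(call$reason, "extracellular_domain")

  # mature-chain residue of a secreted protein: MSP
  v <- fx_variant("S1", "SECR1", substring(sec$sequence, 50, 50), 50, "A")
  call <- call_msp(sec, v)
  expect_true(call$is_msp)
  expect_equal(call$reason, "secreted_protein")

  # signal-peptide residue of a secreted protein: cleaved, not an MSP
  v <- fx_variant("S1", "SECR1", substring(sec$sequence, 5, 5), 5, "A")
  call <- call_msp(sec, v)
  expect_false(call$is_msp)
  expect_equal(call$reason, "signal_peptide_excluded")

  # intracellular residue of a membrane protein: not an MSP
  v <- fx_variant("S1", "MEMB1", substring(memb$sequence, 100, 100), 100, "A")
  call <- call_msp(memb, v)
  expect_false(call$is_msp)
  expect_equal(call$reason, "not_surface")

  # intracellular protein: never an MSP
  v <- fx_variant("S1", "INTR1", "M", 1, "V")
  expect_false(call_msp(intr, v)$is_msp)

  # out of bounds
  v <- fx_variant("S1", "MEMB1", "A", 500, "T")
  call <- call_msp(memb, v)
  expect_false(call$is_msp)
  expect_equal(call$reason, "position_out_of_bounds")
})

test_that("reference mismatches are flagged and never MSPs", {
  memb <- fx_membrane_record()
  truth_ref <- substring(memb$sequence, 24, 24)
  wrong <- setdiff(c("A", "R"), truth_ref)[1]
  v <- fx_variant("S1", "MEMB1", wrong, 24, "W")
  call <- call_msp(memb, v)
  expect_true(call$reference_mismatch)
  expect_false(call$is_msp)
  expect_equal(call$reason, "reference_mismatch")
})

test_that("the MSP boolean invariant holds across a synthetic cohort", {
  prot <- make_proteome(proteome_spec(n_proteins = 40, seed = 5))
  cohort <- make_cohort(cohort_spec(n_patients = 10,
                                    count_model = list(fixed = 30),
                                    seed = 5), prot)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(cohort$maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- classify_cohort(read_maf(path)$variants, prot$store)$calls
  clean <- calls[!calls$reference_mismatch, ]
  expect_identical(
    clean$is_msp,
    clean$residue_location == "extracellular" |
      (clean$is_secreted_protein &
         !(clean$residue_location %in% c("signal_peptide", "position_out_of_bounds")))
  )
})

test_that("classify_cohort excludes and logs variants without annotation", {
  store <- fx_store()
  variants <- rbind(
    fx_variant("S1", "MEMB1", "A", 1, "T"),
    fx_variant("S1", "GHOST1", "A", 1, "T"),
    fx_variant("S2", "SECR1", "G", 1, "A"),
    fx_variant("S2", "GHOST2", "A", 2, "T"),
    fx_variant("S2", "INTR1", "M", 1, "V")
  )
  res <- classify_cohort(variants, store)
  expect_equal(nrow(res$calls), 3L)
  expect_equal(nrow(res$exclusions), 2L)
  expect_true(all(res$exclusions$reason == "missing_annotation"))
  expect_equal(res$calls$gene_symbol, c("MEMB1", "SECR1", "INTR1"))  # input order

  empty <- classify_cohort(variants[0, ], store)
  expect_equal(nrow(empty$calls), 0L)
  expect_equal(nrow(empty$exclusions), 0L)
})

test_that("compartment_tally counts by protein label with correct rounding", {
  memb <- fx_membrane_record(labels = c("plasma_membrane", "cell_junction"))
  sec <- fx_secreted_record()
  store <- as_annotation_store(list(memb, sec, fx_intracellular_record()))
  variants <- rbind(
    fx_variant("S1", "MEMB1", "A", 1, "T"),
    fx_variant("S2", "MEMB1", "R", 2, "K"),
    fx_variant("S1", "SECR1", "G", 30, "A"),
    fx_variant("S1", "INTR1", "M", 1, "V"),
    fx_variant("S1", "GHOST1", "A", 1, "T")  # unclassifiable, not in total
  )
  tl <- compartment_tally(variants, store, mode = "overlapping")
  expect_equal(tl$total, 4L)
  expect_equal(unname(tl$counts["plasma_membrane"]), 2L)
  expect_equal(unname(tl$counts["cell_junction"]), 2L)  # overlapping: both labels count
  expect_equal(unname(tl$percentages["plasma_membrane"]), 50.0)

  tx <- compartment_tally(variants, store, mode = "exclusive")
  expect_equal(unname(tx$counts["plasma_membrane"]), 2L)
  expect_equal(unname(tx$counts["cell_junction"]), 0L)  # precedence: plasma membrane wins
  # exclusive conservation: categorized + uncategorized == total
  expect_lte(sum(tx$counts), tx$total)
})

test_that("degenerate empty input tallies to zeros with a flag", {
  store <- fx_store()
  tl <- compartment_tally(fx_variant("S", "G", "A", 1, "T")[0, ], store)
  expect_true(tl$empty_input)
  expect_equal(tl$total, 0L)
  expect_true(all(tl$percentages == 0))
})

test_that("percentages are rounded half-up to one decimal", {
  # 76/1354 = 5.6129 -> 5.6 ; 35/1354 = 2.585 -> 2.6 ; 153/1354 = 11.300 -> 11.3
  expect_equal(mspkit:::round_half_up(100 * 76 / 1354, 1), 5.6)
  expect_equal(mspkit:::round_half_up(100 * 35 / 1354, 1), 2.6)
  expect_equal(mspkit:::round_half_up(100 * 153 / 1354, 1), 11.3)
  expect_equal(mspkit:::round_half_up(0.25, 1), 0.3)  # half-up, not banker's
})
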