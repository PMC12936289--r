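# peptide window design, pair validation and panel selection

test_that("design_window builds the published Flrt2-style pair", {
  # embed the wild-type window at positions 101-114 of a synthetic carrier
  wt_window <- "FSIVRNSLSHPPPD"
  seqc <- paste0(paste(rep("AG", 50), collapse = ""), wt_window,
                 paste(rep("AG", 20), collapse = ""))
  rec <- protein_record("WIN001", "FLRT2L", seqc,
                        data.frame(kind = "extracellular", start = 1L,
                                   end = nchar(seqc)),
                        "plasma_membrane")
  change <- parse_protein_change("p.N106T")  # the N at window offset 6
  w <- design_window(rec, change, length = 14, window_start = 101)
  expect_equal(w$wildtype_seq, "FSIVRNSLSHPPPD")
  expect_equal(w$mutant_seq, "FSIVRTSLSHPPPD")
  expect_equal(w$mutated_offset, 6L)
  expect_equal(w$synthesis_seq, "FSIVRTSLSHPPPDC")
})

test_that("centered policy clamps at both termini", {
  seqc <- paste(rep("ARNDEQGHIK", 4), collapse = "")  # 40 aa, no C, no T
  rec <- protein_record("CLMP01", "CLAMP1", seqc)
  ch1 <- structure(list(ref_aa = "A", position = 1L, alt_aa = "W"),
                   class = "protein_change")
  w <- design_window(rec, ch1, length = 14)
  expect_equal(w$window_start, 1L)
  expect_equal(w$mutated_offset, 1L)
  chN <- structure(list(ref_aa = "K", position = 40L, alt_aa = "W"),
                   class = "protein_change")
  w <- design_window(rec, chN, length = 14)
  expect_equal(w$window_start, 27L)
  expect_equal(w$mutated_offset, 14L)
  # interior mutation sits at offset ceiling(14/2) = 7
  chM <- structure(list(ref_aa = substring(seqc, 20, 20), position = 20L,
                        alt_aa = "W"), class = "protein_change")
  expect_equal(design_window(rec, chM, length = 14)$mutated_offset, 7L)
})

test_that("design errors on reference mismatch and oversized windows", {
  rec <- protein_record("ERR001", "ERRG1", paste(rep("ARNDEQGHIK", 2), collapse = ""))
  bad <- structure(list(ref_aa = "W", position = 3L, alt_aa = "A"),
                   class = "protein_change")
  expect_error(design_window(rec, bad), "reference mismatch")
  ok <- structure(list(ref_aa = "N", position = 3L, alt_aa = "A"),
                  class = "protein_change")
  expect_error(design_window(rec, ok, length = 25), "exceeds protein length")
})

test_that("window invariants hold over random synthetic designs (substring oracle)", {
  prot <- make_proteome(proteome_spec(n_proteins = 20, seed = 23))
  recs <- prot$store$records
  withr::with_seed(99, {
    for (i in seq_len(200)) {
      rec <- recs[[sample(base::length(recs), 1)]]
      pos <- sample.int(nchar(rec$sequence), 1)
      ref <- substring(rec$sequence, pos, pos)
      alt <- sample(setdiff(c("A", "G", "W"), ref), 1)
      ch <- structure(list(ref_aa = ref, position = pos, alt_aa = alt),
                      class = "protein_change")
      w <- suppressWarnings(design_window(rec, ch, length = 14))
      # wild type window is exactly the protein subsequence
      expect_identical(
        w$wildtype_seq,
        substring(rec$sequence, w$window_start, w$window_start + w$length - 1L))
      v <- validate_pair(w$wildtype_seq, w$mutant_seq)
      expect_true(v$pass)
      expect_identical(c(v$ref_aa, v$alt_aa), c(ref, alt))
      expect_equal(v$offset, w$mutated_offset)
      expect_identical(w$synthesis_seq, paste0(w$mutant_seq, "C"))
    }
  })
})

test_that("validate_pair reports the published Cntnap4 substitution and rejects degenerates", {
  v <- validate_pair("RVRNTHSENAHTGV", "RVRNTHSENALTGV")
  expect_true(v$pass)
  expect_identical(c(v$ref_aa, v$offset, v$alt_aa), c("H", "11", "L"))
  expect_equal(v$hamming_distance, 1L)

  expect_false(validate_pair("AAAA", "AAAA")$pass)       # distance 0
  expect_false(validate_pair("AAAA", "TTAA")$pass)       # distance 2
  expect_false(validate_pair("AAAA", "AAA")$pass)        # length mismatch
  expect_false(validate_pair("AXAA", "ATAA")$pass)       # nonstandard residue
})

test_that("all 10 golden pairs pass with the expected offsets", {
  pairs <- read_pair_table(fx_pairs_path())
  expect_equal(nrow(pairs), 10L)
  offsets <- integer(10)
  for (i in seq_len(10)) {
    v <- validate_pair(pairs$wildtype[i], pairs$mutant[i])
    expect_true(v$pass)
    expect_equal(v$hamming_distance, 1L)
    offsets[i] <- v$offset
  }
  expect_equal(offsets, c(6L, 11L, 4L, 11L, 4L, 11L, 11L, 9L, 4L, 9L))
})

make_panel_calls <- function(genes, positions = NULL, reasons = "extracellular_domain") {
  n <- base::length(genes)
  if (is.null(positions)) positions <- rep(30L, n)
  data.frame(sample_id = "S1", gene_symbol = genes, ref_aa = "?",
             position = as.integer(positions), alt_aa = "?",
             accession = genes, residue_location = "extracellular",
             is_secreted_protein = FALSE, is_msp = TRUE,
             reference_mismatch = FALSE,
             reason = rep(reasons, length.out = n), stringsAsFactors = FALSE)
}

# a store of identical membrane proteins under the given gene names, with
# calls at real positions so windows can be designed
panel_fixture <- function(genes) {
  recs <- lapply(seq_along(genes), function(i) {
    r <- fx_membrane_record()
    r$gene_symbol <- genes[i]
    r$accession <- sprintf("PANEL%02d", i)
    r
  })
  store <- as_annotation_store(recs)
  calls <- make_panel_calls(genes)
  calls$ref_aa <- substring(recs[[1]]$sequence, 30, 30)
  calls$alt_aa <- "A"
  list(store = store, calls = calls)
}

test_that("select_panel truncates, deduplicates per gene and honors exclusions", {
  genes <- sprintf("GENE%02d", 1:12)
  fx <- panel_fixture(genes)

  p <- suppressWarnings(select_panel(fx$calls, fx$store, n = 10))
  expect_equal(nrow(p$targets), 10L)
  expect_false(p$shortfall)
  expect_equal(sum(p$excluded$reason == "rank_overflow"), 2L)
  expect_equal(anyDuplicated(p$targets$gene_symbol), 0L)

  # 3 calls in one gene + 9 in others -> one per gene, lowest position wins
  multi <- rbind(fx$calls[rep(1, 3), ], fx$calls[2:10, ])
  multi$position[1:3] <- c(40L, 24L, 33L)
  multi$ref_aa[1:3] <- substring(fx_membrane_record()$sequence, multi$position[1:3],
                                 multi$position[1:3])
  p2 <- suppressWarnings(select_panel(multi, fx$store, n = 10))
  expect_equal(nrow(p2$targets), 10L)
  expect_equal(p2$targets$position[p2$targets$gene_symbol == "GENE01"], 24L)

  # excluding a selected gene promotes the next-ranked one
  p3 <- suppressWarnings(select_panel(fx$calls, fx$store, n = 10,
                                      exclude_genes = "GENE03"))
  expect_false("GENE03" %in% p3$targets$gene_symbol)
  expect_equal(nrow(p3$targets), 10L)
  expect_true("GENE11" %in% p3$targets$gene_symbol)

  # shortfall: fewer eligible genes than n
  suppressWarnings(expect_warning(
    p4 <- select_panel(fx$calls[1:4, ], fx$store, n = 10), "shortfall"))
  expect_equal(nrow(p4$targets), 4L)
  expect_true(p4$shortfall)
})

test_that("panel selection is deterministic and ranks extracellular calls first", {
  genes <- sprintf("GENE%02d", 1:6)
  fx <- panel_fixture(genes)
  fx$calls$reason <- c("secreted_protein", "extracellular_domain",
                       "secreted_protein", "extracellular_domain",
                       "extracellular_domain", "secreted_protein")
  p1 <- suppressWarnings(select_panel(fx$calls, fx$store, n = 4))
  p2 <- suppressWarnings(select_panel(fx$calls, fx$store, n = 4))
  expect_identical(p1$targets, p2$targets)
  expect_equal(p1$targets$gene_symbol, c("GENE02", "GENE04", "GENE05", "GENE01"))
})

test_that("export_panel_fasta writes tagged mutant and untagged wild type", {
  genes <- sprintf("GENE%02d", 1:10)
  fx <- panel_fixture(genes)
  p <- suppressWarnings(select_panel(fx$calls, fx$store, n = 10))
  path <- withr::local_tempfile(fileext = ".fasta")
  export_panel_fasta(p, path)
  seqs <- Biostrings::readAAStringSet(path)
  expect_equal(base::length(seqs), 20L)
  muts <- seqs[grepl("\\|mutant$", names(seqs))]
  wts <- seqs[grepl("\\|wildtype$", names(seqs))]
  expect_true(all(Biostrings::subseq(muts, start = Biostrings::width(muts)) == "C"))
  expect_equal(base::length(wts), 10L)
  expect_true(all(Biostrings::width(wts) == 14L))

  empty <- structure(list(targets = data.frame(), windows = list(),
                          excluded = data.frame(), n_requested = 1L,
                          shortfall = TRUE), class = "panel_selection")
  out <- withr::local_tempfile(fileext = ".fasta")
  expect_warning(export_panel_fasta(empty, out), "empty")
  expect_equal(file.size(out), 0)
})
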