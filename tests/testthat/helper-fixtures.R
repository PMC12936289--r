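# Small in-code fixtures shared across test files.

# a 120-residue membrane protein: extracellular 1-50, transmembrane 51-71,
# intracellular 72-120
fx_membrane_record <- function(labels = "plasma_membrane") {
  protein_record(
    accession = "FXM001", gene_symbol = "MEMB1",
    sequence = paste(rep("ARNDCEQGHILKMFPSTWYV", 6), collapse = ""),
    features = data.frame(
      kind = c("extracellular", "transmembrane", "intracellular"),
      start = c(1L, 51L, 72L), end = c(50L, 71L, 120L)),
    location_labels = labels
  )
}

# a 100-residue secreted protein: signal peptide 1-20, mature chain
# unannotated
fx_secreted_record <- function() {
  protein_record(
    accession = "FXS001", gene_symbol = "SECR1",
    sequence = paste(rep("GAVLIPFMWSTNQYDEKRHG", 5), collapse = ""),
    features = data.frame(kind = "signal_peptide", start = 1L, end = 20L),
    location_labels = "secreted"
  )
}

# an 80-residue intracellular protein
fx_intracellular_record <- function() {
  protein_record(
    accession = "FXI001", gene_symbol = "INTR1",
    sequence = paste(rep("MKLVAGST", 10), collapse = ""),
    features = data.frame(kind = "intracellular", start = 1L, end = 80L),
    location_labels = "intracellular_other"
  )
}

fx_store <- function() {
  as_annotation_store(list(fx_membrane_record(), fx_secreted_record(),
                           fx_intracellular_record()))
}

# write a MAF-dialect TSV from parallel vectors; returns the path
fx_write_maf <- function(gene, class, change, sample,
                         path = withr::local_tempfile(fileext = ".tsv",
                                                      .local_envir = parent.frame())) {
  df <- data.frame(Hugo_Symbol = gene, Variant_Classification = class,
                   HGVSp_Short = change, Tumor_Sample_Barcode = sample,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a variant row as read_maf() produces it
fx_variant <- function(sample_id, gene_symbol, ref_aa, position, alt_aa) {
  data.frame(sample_id = sample_id, gene_symbol = gene_symbol, ref_aa = ref_aa,
             position = as.integer(position), alt_aa = alt_aa,
             classification_label = "Missense_Mutation", stringsAsFactors = FALSE)
}

fx_pairs_path <- function() {
  system.file("extdata", "immunogen_pairs.tsv", package = "mspkit")
}
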