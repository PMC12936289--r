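# UniProt-like protein annotation store: one canonical record per gene with
# sequence, topology features and subcellular-location labels. The store is a
# flat JSON fixture, not a live service; isoform choice happens at store
# construction time so the pipeline is deterministic.

FEATURE_KINDS <- c("signal_peptide", "extracellular", "transmembrane",
                   "intracellular", "lumenal", "propeptide")

LOCATION_VOCAB <- c("plasma_membrane", "cell_junction", "extracellular_matrix",
                    "secreted", "intracellular_other")

#' Construct a validated protein record
#'
#' @param accession unique record identifier.
#' @param gene_symbol gene symbol (matched case-insensitively at lookup).
#' @param sequence amino-acid sequence, canonical 20-letter alphabet.
#' @param features data.frame with columns `kind`, `start`, `end`
#'   (1-based inclusive residue coordinates), or `NULL` for none.
#' @param location_labels character vector drawn from the controlled
#'   vocabulary: plasma_membrane, cell_junction, extracellular_matrix,
#'   secreted, intracellular_other.
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(accession, gene_symbol, sequence,
                           features = NULL, location_labels = character()) {
  if (is.null(features) || NROW(features) == 0L) {
    features <- data.frame(kind = character(), start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
  }
  features <- data.frame(kind = as.character(features$kind),
                         start = as.integer(features$start),
                         end = as.integer(features$end),
                         stringsAsFactors = FALSE)
  rec <- structure(
    list(accession = as.character(accession),
         gene_symbol = as.character(gene_symbol),
         sequence = as.character(sequence),
         features = features,
         location_labels = sort(unique(as.character(location_labels)))),
    class = "protein_record"
  )
  validate_protein_record(rec)
  rec
}

validate_protein_record <- function(rec) {
  acc <- rec$accession
  if (!nzchar(acc)) stop("record with empty accession")
  if (!nzchar(rec$gene_symbol)) stop("record ", acc, ": empty gene_symbol")
  if (!is_canonical_aa(rec$sequence)) {
    stop("record ", acc, ": sequence empty or contains non-canonical residues")
  }
  f <- rec$features
  if (nrow(f)) {
    bad_kind <- setdiff(f$kind, FEATURE_KINDS)
    if (length(bad_kind)) {
      stop("record ", acc, ": unknown feature kind(s): ", paste(bad_kind, collapse = ", "))
    }
    len <- nchar(rec$sequence)
    if (any(is.na(f$start)) || any(is.na(f$end)) ||
        any(f$start < 1L) || any(f$end > len) || any(f$start > f$end)) {
      stop("record ", acc, ": feature coordinates out of bounds (sequence length ", len, ")")
    }
  }
  bad_lab <- setdiff(rec$location_labels, LOCATION_VOCAB)
  if (length(bad_lab)) {
    stop("record ", acc, ": location label(s) outside controlled vocabulary: ",
         paste(bad_lab, collapse = ", "))
  }
  invisible(rec)
}

#' Assemble an annotation store from protein records
#'
#' @param records list of [protein_record()] objects.
#' @return an object of class `annotation_store`. Errors if two records
#'   share a gene symbol (case-insensitive) or an accession: ambiguous
#'   isoform choices must be resolved before the store is built.
#' @export
as_annotation_store <- function(records) {
  for (r in records) {
    if (!inherits(r, "protein_record")) stop("all records must be protein_record objects")
    validate_protein_record(r)
  }
  genes <- toupper(vapply(records, function(r) r$gene_symbol, character(1)))
  accs <- vapply(records, function(r) r$accession, character(1))
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol(s) in store: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(accs)) {
    stop("duplicate accession(s) in store: ",
         paste(unique(accs[duplicated(accs)]), collapse = ", "))
  }
  structure(list(records = stats::setNames(records, genes),
                 coordinate_convention = "1-based-inclusive"),
            class = "annotation_store")
}

#' @export
length.annotation_store <- function(x) length(x$records)

#' @export
print.annotation_store <- function(x, ...) {
  cat("annotation_store with", length(x$records), "protein record(s)\n")
  invisible(x)
}

#' Load an annotation store from its JSON fixture format
#'
#' The fixture is one JSON document: an object with a
#' `coordinate_convention` header field (`"1-based-inclusive"`) and a
#' `records` array, each record `{accession, gene_symbol, sequence,
#' features: [{kind, start, end}], location_labels: [...]}`. Every record is
#' validated on load; a malformed record aborts with its accession named.
#'
#' @param path path to the JSON store file.
#' @return an `annotation_store`.
#' @export
load_store <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = FALSE)
  if (is.null(doc$records)) stop("store file has no 'records' field: ", path)
  records <- lapply(doc$records, function(r) {
    feats <- if (length(r$features)) {
      data.frame(kind = vapply(r$features, function(f) as.character(f$kind), character(1)),
                 start = vapply(r$features, function(f) as.integer(f$start), integer(1)),
                 end = vapply(r$features, function(f) as.integer(f$end), integer(1)),
                 stringsAsFactors = FALSE)
    } else NULL
    protein_record(r$accession, r$gene_symbol, r$sequence, feats,
                   unlist(r$location_labels))
  })
  as_annotation_store(records)
}

#' Serialize an annotation store to its JSON fixture format
#'
#' [load_store()] followed by `write_store()` is byte-identical for files
#' produced by `write_store()` (the canonical form).
#'
#' @param store an `annotation_store`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  recs <- lapply(unname(store$records), function(r) {
    feats <- lapply(seq_len(nrow(r$features)), function(i) {
      list(kind = r$features$kind[i], start = r$features$start[i], end = r$features$end[i])
    })
    list(accession = r$accession, gene_symbol = r$gene_symbol,
         sequence = r$sequence, features = feats,
         location_labels = as.list(r$location_labels))
  })
  doc <- list(coordinate_convention = "1-based-inclusive", records = recs)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Look a gene up in the store
#'
#' Missingness is a value, not an error: genes absent from the store return
#' `NULL`, and callers are expected to log and drop the variant (the
#' elimination rule for genes without usable annotation).
#'
#' @param store an `annotation_store`.
#' @param gene_symbol gene symbol; matching is case-insensitive.
#' @return the `protein_record`, or `NULL` when the gene is not annotated.
#' @export
resolve <- function(store, gene_symbol) {
  store$records[[toupper(gene_symbol)]]
}

#' Export all store sequences as FASTA
#'
#' One entry per record, headed by its accession, for interoperability with
#' standard sequence tooling.
#'
#' @param store an `annotation_store`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
export_store_fasta <- function(store, path) {
  recs <- unname(store$records)
  seqs <- Biostrings::AAStringSet(vapply(recs, function(r) r$sequence, character(1)))
  names(seqs) <- vapply(recs, function(r) r$accession, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
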