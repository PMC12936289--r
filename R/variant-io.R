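# Reading and validating somatic variant tables (MAF-dialect TSV) into the
# pipeline's variant model: one row per accepted missense variant with a
# parsed protein change.

MISSENSE_LABELS <- c("missense_mutation", "missense_variant", "missense")

DEFAULT_MAF_COLUMNS <- c(
  gene_symbol    = "Hugo_Symbol",
  classification = "Variant_Classification",
  protein_change = "HGVSp_Short",
  sample_id      = "Tumor_Sample_Barcode"
)

msp_parse_error <- function(reason, text) {
  structure(
    class = c("msp_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse protein change %s (%s)", deparse(text), reason),
         call = NULL, reason = reason, text = text)
  )
}

#' Parse an HGVS p. protein-change string
#'
#' Accepts simple single-substitution protein changes in 1-letter
#' (`"p.N123T"`) or 3-letter (`"p.Asn123Thr"`) code, with the `"p."`
#' prefix optional. Anything that is not a clean missense substitution —
#' stop gains (`*`/`Ter`), frameshifts (`fs`), indels (`del`/`ins`/`dup`),
#' extensions, synonymous changes — is rejected with a classed condition
#' whose `reason` field is machine readable.
#'
#' @param text a single protein-change string.
#' @return an object of class `protein_change`: a list with `ref_aa`,
#'   `position` (1-based residue index) and `alt_aa`, all in 1-letter code.
#' @section Rejection reasons:
#' `unparseable_hgvs` (malformed or non-missense token), `nonstandard_aa`
#' (B/Z/X/U/O/J residues), `synonymous` (ref equals alt),
#' `missing_field` (empty or `NA` input).
#' @examples
#' parse_protein_change("p.Asn6Thr")
#' parse_protein_change("H4D")
#' @export
parse_protein_change <- function(text) {
  if (length(text) != 1L) stop("parse_protein_change() is scalar; got length ", length(text))
  if (is.na(text) || !nzchar(trimws(text))) stop(msp_parse_error("missing_field", text))
  s <- trimws(text)
  s <- sub("^p\\.", "", s)

  # explicit non-missense tokens before shape matching
  if (grepl("\\*|fs|del|ins|dup|ext|Ter|=", s)) stop(msp_parse_error("unparseable_hgvs", text))

  m1 <- regmatches(s, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", s))[[1]]
  m3 <- regmatches(s, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", s))[[1]]

  if (length(m3) == 4L) {
    ref <- unname(AA_THREE_TO_ONE[m3[2]])
    alt <- unname(AA_THREE_TO_ONE[m3[4]])
    if (is.na(ref) || is.na(alt)) stop(msp_parse_error("unparseable_hgvs", text))
    pos <- as.integer(m3[3])
  } else if (length(m1) == 4L) {
    ref <- toupper(m1[2])
    alt <- toupper(m1[4])
    pos <- as.integer(m1[3])
  } else {
    stop(msp_parse_error("unparseable_hgvs", text))
  }

  if (ref %in% AA_NONSTANDARD || alt %in% AA_NONSTANDARD) {
    stop(msp_parse_error("nonstandard_aa", text))
  }
  if (!(ref %in% AA_CANONICAL) || !(alt %in% AA_CANONICAL)) {
    stop(msp_parse_error("unparseable_hgvs", text))
  }
  if (ref == alt) stop(msp_parse_error("synonymous", text))
  if (pos < 1L) stop(msp_parse_error("unparseable_hgvs", text))

  structure(list(ref_aa = ref, position = pos, alt_aa = alt),
            class = "protein_change")
}

#' Format a protein change back to HGVS p. short notation
#'
#' @param ref_aa,position,alt_aa components of the substitution, or a
#'   `protein_change` object as the first argument.
#' @return character, e.g. `"p.N123T"`.
#' @export
format_protein_change <- function(ref_aa, position = NULL, alt_aa = NULL) {
  if (inherits(ref_aa, "protein_change")) {
    pc <- ref_aa
    return(sprintf("p.%s%d%s", pc$ref_aa, pc$position, pc$alt_aa))
  }
  sprintf("p.%s%d%s", ref_aa, as.integer(position), alt_aa)
}

#' Read a MAF-dialect somatic variant table
#'
#' Reads a TCGA-style tab-separated variant table, keeps rows whose variant
#' classification normalizes to missense and whose protein change parses as
#' a single substitution, and logs every rejected row with a machine-readable
#' reason. Only four logical columns are required; everything else is
#' ignored. Gzip-compressed files are read transparently.
#'
#' @param path path to a TSV (optionally `.gz`) with a header row.
#' @param column_map optional named character vector overriding the default
#'   column names; logical names are `gene_symbol`, `classification`,
#'   `protein_change`, `sample_id` (defaults `Hugo_Symbol`,
#'   `Variant_Classification`, `HGVSp_Short`, `Tumor_Sample_Barcode`).
#' @return a list of class `maf_read_result` with
#' \describe{
#'   \item{variants}{data.frame with one accepted variant per row:
#'     `sample_id`, `gene_symbol`, `ref_aa`, `position`, `alt_aa`,
#'     `classification_label`.}
#'   \item{rejections}{data.frame logging every dropped input row:
#'     `row`, `sample_id`, `gene_symbol`, `protein_change`, `reason`
#'     (`non_missense`, `unparseable_hgvs`, `nonstandard_aa`, `synonymous`,
#'     `missing_field`, `duplicate`).}
#' }
#' Accepted plus rejected rows always account for every data row read.
#' @export
read_maf <- function(path, column_map = NULL) {
  cols <- DEFAULT_MAF_COLUMNS
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cols))
    if (length(bad)) stop("unknown logical column name(s): ", paste(bad, collapse = ", "))
    cols[names(column_map)] <- column_map
  }

  raw <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols)) {
    stop("MAF file is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("empty MAF file: ", path)
    return(empty_maf_result())
  }

  n <- nrow(raw)
  gene   <- trimws(raw[[cols[["gene_symbol"]]]])
  cls    <- trimws(raw[[cols[["classification"]]]])
  change <- trimws(raw[[cols[["protein_change"]]]])
  sample <- trimws(raw[[cols[["sample_id"]]]])

  ref <- character(n); pos <- integer(n); alt <- character(n)
  reason <- character(n)  # "" == accepted

  for (i in seq_len(n)) {
    if (is.na(sample[i]) || !nzchar(sample[i]) || is.na(gene[i]) || !nzchar(gene[i])) {
      reason[i] <- "missing_field"; next
    }
    if (!(tolower(cls[i]) %in% MISSENSE_LABELS)) {
      reason[i] <- "non_missense"; next
    }
    pc <- tryCatch(parse_protein_change(change[i]),
                   msp_parse_error = function(e) e)
    if (inherits(pc, "msp_parse_error")) {
      reason[i] <- pc$reason; next
    }
    ref[i] <- pc$ref_aa; pos[i] <- pc$position; alt[i] <- pc$alt_aa
  }

  acc <- which(reason == "")
  # deduplicate multi-transcript rows: same sample, gene, change
  if (length(acc)) {
    key <- paste(sample[acc], gene[acc], ref[acc], pos[acc], alt[acc], sep = "\r")
    dup <- duplicated(key)
    reason[acc[dup]] <- "duplicate"
    if (any(dup)) {
      message(sum(dup), " duplicate variant row(s) removed (same sample, gene, change)")
    }
    acc <- acc[!dup]
  }

  variants <- data.frame(
    sample_id = sample[acc],
    gene_symbol = gene[acc],
    ref_aa = ref[acc],
    position = pos[acc],
    alt_aa = alt[acc],
    classification_label = cls[acc],
    stringsAsFactors = FALSE
  )
  rej <- which(reason != "")
  rejections <- data.frame(
    row = rej,
    sample_id = sample[rej],
    gene_symbol = gene[rej],
    protein_change = change[rej],
    reason = reason[rej],
    stringsAsFactors = FALSE
  )
  structure(list(variants = variants, rejections = rejections),
            class = "maf_read_result")
}

empty_maf_result <- function() {
  structure(list(
    variants = data.frame(sample_id = character(), gene_symbol = character(),
                          ref_aa = character(), position = integer(),
                          alt_aa = character(), classification_label = character(),
                          stringsAsFactors = FALSE),
    rejections = data.frame(row = integer(), sample_id = character(),
                            gene_symbol = character(), protein_change = character(),
                            reason = character(), stringsAsFactors = FALSE)
  ), class = "maf_read_result")
}

#' Write variants back out as a MAF-dialect TSV
#'
#' Inverse of [read_maf()] for accepted variants: emits the four default
#' MAF columns with the protein change re-serialized to HGVS p. short form.
#' Re-reading the written file yields an identical variant table.
#'
#' @param variants a variant data.frame as returned in
#'   `read_maf()$variants` (the `classification_label` column is optional;
#'   `Missense_Mutation` is written when absent).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path) {
  cls <- if ("classification_label" %in% names(variants) && nrow(variants) > 0) {
    variants$classification_label
  } else {
    rep("Missense_Mutation", nrow(variants))
  }
  out <- data.frame(
    Hugo_Symbol = variants$gene_symbol,
    Variant_Classification = cls,
    HGVSp_Short = sprintf("p.%s%d%s", variants$ref_aa, variants$position, variants$alt_aa),
    Tumor_Sample_Barcode = variants$sample_id,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the normalized variant table
#'
#' @param variants accepted-variant data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(
    variants[, c("sample_id", "gene_symbol", "ref_aa", "position", "alt_aa")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
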