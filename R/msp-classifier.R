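# Residue-level subcellular localization of missense variants and MSP
# (mutated surface protein) calling: a variant is an MSP when its mutated
# residue lies in an extracellular topological domain, or when the protein
# is secreted and the residue survives in the mature protein.

RESIDUE_LOCATIONS <- c("extracellular", "transmembrane", "intracellular",
                       "lumenal", "signal_peptide", "unannotated",
                       "position_out_of_bounds")

# precedence when features overlap; transmembrane is the most structurally
# constrained annotation so it wins. propeptide is treated like the signal
# peptide (both are cleaved from the mature chain).
FEATURE_PRECEDENCE <- c(transmembrane = 1, extracellular = 2, intracellular = 3,
                        lumenal = 4, signal_peptide = 5, propeptide = 6)

#' Locate a residue within a protein's topology
#'
#' Interval lookup of a residue position against the record's topology
#' features. Positions outside `[1, nchar(sequence)]` return
#' `position_out_of_bounds`; positions covered by no feature return
#' `unannotated`; when several features cover the position the precedence
#' transmembrane > extracellular > intracellular > lumenal > signal_peptide
#' applies and a warning is emitted. Residues covered only by a propeptide
#' feature are reported as `signal_peptide` (both segments are cleaved off
#' the mature, antibody-accessible protein).
#'
#' @param record a `protein_record`.
#' @param position 1-based residue index.
#' @return one of `"extracellular"`, `"transmembrane"`, `"intracellular"`,
#'   `"lumenal"`, `"signal_peptide"`, `"unannotated"`,
#'   `"position_out_of_bounds"`.
#' @export
locate_residue <- function(record, position) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > nchar(record$sequence)) {
    return("position_out_of_bounds")
  }
  f <- record$features
  hit <- which(f$start <= position & f$end >= position)
  if (!length(hit)) return("unannotated")
  if (length(hit) > 1L) {
    warning("record ", record$accession, ": ", length(hit),
            " overlapping features at position ", position,
            "; applying precedence", call. = FALSE)
  }
  kinds <- f$kind[hit]
  kind <- kinds[which.min(FEATURE_PRECEDENCE[kinds])]
  if (kind == "propeptide") "signal_peptide" else kind
}

msp_rule <- function(residue_location, is_secreted) {
  residue_location == "extracellular" ||
    (is_secreted && !(residue_location %in% c("signal_peptide", "position_out_of_bounds")))
}

#' Call MSP status for one variant
#'
#' Applies the surface rule: the call is an MSP iff the mutated residue is
#' extracellular, or the protein carries the `secreted` label and the
#' residue is part of the mature protein (not in the signal peptide and not
#' out of bounds). If the record's sequence at the variant position differs
#' from the expected reference residue, the call is flagged
#' `reference_mismatch` and is never an MSP (isoform/version skew makes the
#' localization untrustworthy); such calls keep reason
#' `reference_mismatch`.
#'
#' @param record a `protein_record` resolved for the variant's gene.
#' @param variant one-row variant data.frame (or list) with `sample_id`,
#'   `gene_symbol`, `ref_aa`, `position`, `alt_aa`.
#' @return a one-row data.frame of class `msp_call`: `sample_id`,
#'   `gene_symbol`, `ref_aa`, `position`, `alt_aa`, `accession`,
#'   `residue_location`, `is_secreted_protein`, `is_msp`,
#'   `reference_mismatch`, `reason`.
#' @export
call_msp <- function(record, variant) {
  loc <- locate_residue(record, variant$position)
  secreted <- "secreted" %in% record$location_labels
  mismatch <- loc != "position_out_of_bounds" &&
    substring(record$sequence, variant$position, variant$position) != variant$ref_aa

  if (mismatch) {
    is_msp <- FALSE
    reason <- "reference_mismatch"
  } else {
    is_msp <- msp_rule(loc, secreted)
    reason <- if (loc == "extracellular") {
      "extracellular_domain"
    } else if (is_msp) {
      "secreted_protein"
    } else if (loc == "position_out_of_bounds") {
      "position_out_of_bounds"
    } else if (secreted && loc == "signal_peptide") {
      "signal_peptide_excluded"
    } else {
      "not_surface"
    }
  }

  out <- data.frame(
    sample_id = variant$sample_id, gene_symbol = variant$gene_symbol,
    ref_aa = variant$ref_aa, position = as.integer(variant$position),
    alt_aa = variant$alt_aa, accession = record$accession,
    residue_location = loc, is_secreted_protein = secreted,
    is_msp = is_msp, reference_mismatch = mismatch, reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("msp_call", class(out))
  out
}

#' Classify a cohort of variants against an annotation store
#'
#' Variants whose gene has no record in the store are excluded and logged
#' (mirroring the elimination of entries without usable annotation); the
#' retained calls keep the input order.
#'
#' @param variants accepted-variant data.frame (see [read_maf()]).
#' @param store an `annotation_store`.
#' @return list of class `cohort_classification` with `calls` (data.frame
#'   of MSP calls, one per retained variant, input order) and `exclusions`
#'   (data.frame `row`, `sample_id`, `gene_symbol`, `reason`, with reason
#'   `missing_annotation`).
#' @export
classify_cohort <- function(variants, store) {
  n <- nrow(variants)
  if (n == 0L) {
    return(structure(list(calls = empty_calls(), exclusions = empty_exclusions()),
                     class = "cohort_classification"))
  }
  # vectorized column-wise build (cohorts run to tens of thousands of rows)
  keep <- logical(n)
  accession <- character(n); loc <- character(n); secreted <- logical(n)
  is_msp <- logical(n); mismatch <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    rec <- resolve(store, variants$gene_symbol[i])
    if (is.null(rec)) next
    keep[i] <- TRUE
    li <- locate_residue(rec, variants$position[i])
    si <- "secreted" %in% rec$location_labels
    mi <- li != "position_out_of_bounds" &&
      substring(rec$sequence, variants$position[i], variants$position[i]) != variants$ref_aa[i]
    accession[i] <- rec$accession; loc[i] <- li; secreted[i] <- si; mismatch[i] <- mi
    if (mi) {
      reason[i] <- "reference_mismatch"
    } else {
      is_msp[i] <- msp_rule(li, si)
      reason[i] <- if (li == "extracellular") "extracellular_domain"
        else if (is_msp[i]) "secreted_protein"
        else if (li == "position_out_of_bounds") "position_out_of_bounds"
        else if (si && li == "signal_peptide") "signal_peptide_excluded"
        else "not_surface"
    }
  }
  calls_df <- if (any(keep)) {
    data.frame(sample_id = variants$sample_id[keep],
               gene_symbol = variants$gene_symbol[keep],
               ref_aa = variants$ref_aa[keep],
               position = as.integer(variants$position[keep]),
               alt_aa = variants$alt_aa[keep],
               accession = accession[keep], residue_location = loc[keep],
               is_secreted_protein = secreted[keep], is_msp = is_msp[keep],
               reference_mismatch = mismatch[keep], reason = reason[keep],
               stringsAsFactors = FALSE)
  } else empty_calls()
  excl <- which(!keep)
  exclusions <- data.frame(
    row = excl,
    sample_id = variants$sample_id[excl],
    gene_symbol = variants$gene_symbol[excl],
    reason = rep("missing_annotation", length(excl)),
    stringsAsFactors = FALSE
  )
  structure(list(calls = calls_df, exclusions = exclusions),
            class = "cohort_classification")
}

empty_calls <- function() {
  data.frame(sample_id = character(), gene_symbol = character(),
             ref_aa = character(), position = integer(), alt_aa = character(),
             accession = character(), residue_location = character(),
             is_secreted_protein = logical(), is_msp = logical(),
             reference_mismatch = logical(), reason = character(),
             stringsAsFactors = FALSE)
}

empty_exclusions <- function() {
  data.frame(row = integer(), sample_id = character(), gene_symbol = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Tally variants by protein-level compartment category
#'
#' Counts how many classified variants fall in proteins labeled
#' plasma_membrane, cell_junction or extracellular_matrix. In
#' `"overlapping"` mode a variant contributes to every category its protein
#' is labeled with; in `"exclusive"` mode each variant is assigned to at
#' most one category by the precedence plasma_membrane > cell_junction >
#' extracellular_matrix. The denominator `total` is the number of variants
#' classified (resolvable in the store), including those in no category.
#' Percentages are rounded half-up to one decimal, matching the field's
#' reporting style.
#'
#' @param variants accepted-variant data.frame.
#' @param store an `annotation_store`.
#' @param mode `"exclusive"` or `"overlapping"`.
#' @return list of class `compartment_tally`: `total`, `mode`, `counts`
#'   (named integer), `percentages` (named numeric, one decimal),
#'   `empty_input` flag.
#' @export
compartment_tally <- function(variants, store, mode = c("exclusive", "overlapping")) {
  mode <- match.arg(mode)
  categories <- c("plasma_membrane", "cell_junction", "extracellular_matrix")
  counts <- stats::setNames(integer(3), categories)
  total <- 0L
  for (i in seq_len(nrow(variants))) {
    rec <- resolve(store, variants$gene_symbol[i])
    if (is.null(rec)) next
    total <- total + 1L
    labs <- intersect(categories, rec$location_labels)
    if (!length(labs)) next
    if (mode == "exclusive") labs <- labs[1]  # categories is ordered by precedence
    counts[labs] <- counts[labs] + 1L
  }
  empty <- total == 0L
  pct <- if (empty) stats::setNames(rep(0, 3), categories) else round_half_up(100 * counts / total, 1)
  structure(list(total = total, mode = mode, counts = counts,
                 percentages = pct, empty_input = empty),
            class = "compartment_tally")
}

#' @export
print.compartment_tally <- function(x, ...) {
  cat("compartment tally (", x$mode, " mode), ", x$total, " classified variant(s)\n", sep = "")
  for (cat_i in names(x$counts)) {
    cat(sprintf("  %-22s %6d (%.1f%%)\n", cat_i, x$counts[[cat_i]], x$percentages[[cat_i]]))
  }
  invisible(x)
}
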