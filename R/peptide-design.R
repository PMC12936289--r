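# Mutant/wild-type peptide-window design around targeted mutations, with the
# C-terminal cysteine tag used for carrier-protein (KLH) conjugation, plus
# deterministic oligoclonal panel selection.

#' Design a mutant/wild-type peptide window around a mutation
#'
#' Extracts a window of `length` residues from the protein sequence
#' containing the mutated position, and builds the mutant sequence by
#' substituting the alternate residue. The default `"centered"` policy
#' places the mutated residue at offset `ceiling(length / 2)`, clamping the
#' window so it stays inside the protein near either terminus; an explicit
#' `window_start` overrides placement entirely. When tagging is enabled the
#' synthesis sequence is the mutant peptide plus a C-terminal cysteine for
#' carrier conjugation; a cysteine already present in the window triggers a
#' warning (conjugation-chemistry risk), never a failure.
#'
#' @param record a `protein_record`.
#' @param change a `protein_change` (see [parse_protein_change()]).
#' @param length window length in residues; default 14 (the length of
#'   published immunogen pairs; prose elsewhere says 11-mer — printed
#'   sequences are taken as authoritative and the length stays a parameter).
#' @param policy `"centered"` (default) or `"start"` (window begins at the
#'   mutated residue, clamped).
#' @param window_start optional explicit 1-based window start, overriding
#'   `policy`.
#' @param tag append the C-terminal cysteine to the mutant sequence
#'   (default `TRUE`).
#' @return object of class `peptide_window`: list with `accession`,
#'   `gene_symbol`, `window_start`, `length`, `mutated_offset` (1-based
#'   within the window), `wildtype_seq`, `mutant_seq`, `synthesis_seq`,
#'   `crosses_feature_boundary` and `internal_cysteine` flags.
#' @export
design_window <- function(record, change, length = 14L,
                          policy = c("centered", "start"),
                          window_start = NULL, tag = TRUE) {
  policy <- match.arg(policy)
  len <- as.integer(length)
  pos <- as.integer(change$position)
  plen <- nchar(record$sequence)
  if (len < 1L) stop("window length must be >= 1")
  if (len > plen) {
    stop("record ", record$accession, ": window length ", len,
         " exceeds protein length ", plen)
  }
  if (pos < 1L || pos > plen) {
    stop("record ", record$accession, ": position ", pos,
         " outside protein of length ", plen)
  }
  ref_at <- substring(record$sequence, pos, pos)
  if (ref_at != change$ref_aa) {
    stop("record ", record$accession, ": reference mismatch at position ", pos,
         " (sequence has ", ref_at, ", variant expects ", change$ref_aa, ")")
  }

  if (is.null(window_start)) {
    window_start <- switch(policy,
      centered = pos - as.integer(ceiling(len / 2)) + 1L,
      start = pos
    )
  }
  window_start <- max(1L, min(as.integer(window_start), plen - len + 1L))
  if (pos < window_start || pos > window_start + len - 1L) {
    stop("record ", record$accession, ": window [", window_start, ", ",
         window_start + len - 1L, "] does not contain position ", pos)
  }
  offset <- pos - window_start + 1L

  wt <- substring(record$sequence, window_start, window_start + len - 1L)
  mut <- wt
  substring(mut, offset, offset) <- change$alt_aa

  internal_cys <- grepl("C", wt, fixed = TRUE) || change$alt_aa == "C"
  if (tag && internal_cys) {
    warning("record ", record$accession,
            ": window contains a cysteine; C-terminal conjugation tag may cross-link",
            call. = FALSE)
  }

  # informational flag: does the window leave the feature covering the
  # mutated residue?
  crosses <- FALSE
  f <- record$features
  hit <- which(f$start <= pos & f$end >= pos)
  if (base::length(hit)) {
    crosses <- any(window_start < f$start[hit] | (window_start + len - 1L) > f$end[hit])
  }

  structure(list(
    accession = record$accession, gene_symbol = record$gene_symbol,
    window_start = window_start, length = len, mutated_offset = offset,
    wildtype_seq = wt, mutant_seq = mut,
    synthesis_seq = if (tag) paste0(mut, "C") else mut,
    crosses_feature_boundary = crosses, internal_cysteine = internal_cys
  ), class = "peptide_window")
}

#' Validate a mutant/wild-type peptide pair
#'
#' Checks the single-substitution structure expected of an immunogen pair:
#' equal length, canonical alphabet, and Hamming distance exactly 1. On a
#' pass the substitution triple (wild-type residue, 1-based offset, mutant
#' residue) is reported. Failures are reported, never raised.
#'
#' @param wildtype_seq wild-type peptide sequence.
#' @param mutant_seq mutant peptide sequence.
#' @return list of class `pair_validation`: `pass` (logical), `ref_aa`,
#'   `offset`, `alt_aa` (NA unless pass), `hamming_distance`, `reasons`
#'   (character vector, empty on pass).
#' @export
validate_pair <- function(wildtype_seq, mutant_seq) {
  reasons <- character()
  if (!is_canonical_aa(wildtype_seq)) reasons <- c(reasons, "wildtype_not_canonical")
  if (!is_canonical_aa(mutant_seq)) reasons <- c(reasons, "mutant_not_canonical")
  dist <- NA_integer_
  ref <- NA_character_; alt <- NA_character_; offset <- NA_integer_
  if (nchar(wildtype_seq) != nchar(mutant_seq)) {
    reasons <- c(reasons, "length_mismatch")
  } else if (!length(reasons)) {
    w <- strsplit(wildtype_seq, "")[[1]]
    m <- strsplit(mutant_seq, "")[[1]]
    diff <- which(w != m)
    dist <- length(diff)
    if (dist == 0L) {
      reasons <- c(reasons, "identical_sequences")
    } else if (dist > 1L) {
      reasons <- c(reasons, "multiple_substitutions")
    } else {
      ref <- w[diff]; alt <- m[diff]; offset <- diff
    }
  }
  structure(list(pass = length(reasons) == 0L, ref_aa = ref, offset = offset,
                 alt_aa = alt, hamming_distance = dist, reasons = reasons),
            class = "pair_validation")
}

#' Select a deterministic oligoclonal target panel
#'
#' From a set of MSP calls, selects up to `n` targets in `n` distinct genes
#' and designs a peptide window for each. The rule is fully deterministic:
#' excluded genes are dropped; one call per gene is kept (lowest mutated
#' position wins, then lexicographic on the protein change); candidates are
#' ranked extracellular-domain calls first, then by gene symbol; the first
#' `n` are taken. Fewer than `n` eligible genes yields the full eligible set
#' with a shortfall warning.
#'
#' @param calls data.frame of MSP calls with `is_msp` `TRUE` (rows with
#'   `is_msp` `FALSE` are dropped with a message).
#' @param store an `annotation_store` (windows are designed from it).
#' @param n panel size; default 10.
#' @param exclude_genes optional character vector of gene symbols to skip
#'   (e.g. known oncogenes), matched case-insensitively.
#' @param length,policy passed to [design_window()].
#' @return list of class `panel_selection`: `targets` (data.frame, one row
#'   per selected target: gene, accession, change, window fields, reason),
#'   `windows` (list of `peptide_window`), `excluded` (data.frame with
#'   reasons: `excluded_gene`, `duplicate_gene`, `rank_overflow`,
#'   `not_msp`), `shortfall` (logical).
#' @export
select_panel <- function(calls, store, n = 10L, exclude_genes = NULL,
                         length = 14L, policy = "centered") {
  n <- as.integer(n)
  if (n < 1L) stop("panel size n must be >= 1")
  excluded <- data.frame(gene_symbol = character(), sample_id = character(),
                         position = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  note_excluded <- function(rows, reason) {
    if (!nrow(rows)) return()
    excluded <<- rbind(excluded, data.frame(
      gene_symbol = rows$gene_symbol, sample_id = rows$sample_id,
      position = rows$position, reason = reason, stringsAsFactors = FALSE))
  }

  non_msp <- calls[!calls$is_msp, , drop = FALSE]
  if (nrow(non_msp)) {
    message(nrow(non_msp), " non-MSP call(s) dropped from panel candidates")
    note_excluded(non_msp, "not_msp")
  }
  cand <- calls[calls$is_msp, , drop = FALSE]

  if (!is.null(exclude_genes) && nrow(cand)) {
    drop <- toupper(cand$gene_symbol) %in% toupper(exclude_genes)
    note_excluded(cand[drop, , drop = FALSE], "excluded_gene")
    cand <- cand[!drop, , drop = FALSE]
  }

  if (nrow(cand)) {
    # one call per gene: lowest position wins, protein change as tie-break
    ord <- order(toupper(cand$gene_symbol), cand$position,
                 cand$ref_aa, cand$alt_aa, cand$sample_id)
    cand <- cand[ord, , drop = FALSE]
    dup <- duplicated(toupper(cand$gene_symbol))
    note_excluded(cand[dup, , drop = FALSE], "duplicate_gene")
    cand <- cand[!dup, , drop = FALSE]

    # rank: extracellular-domain calls first, then gene symbol
    ord <- order(cand$reason != "extracellular_domain", toupper(cand$gene_symbol))
    cand <- cand[ord, , drop = FALSE]
    if (nrow(cand) > n) {
      note_excluded(cand[(n + 1L):nrow(cand), , drop = FALSE], "rank_overflow")
      cand <- cand[seq_len(n), , drop = FALSE]
    }
  }
  shortfall <- nrow(cand) < n
  if (shortfall) {
    warning("panel shortfall: ", nrow(cand), " eligible gene(s) for requested n = ", n,
            call. = FALSE)
  }

  windows <- vector("list", nrow(cand))
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rec <- resolve(store, cand$gene_symbol[i])
    ch <- structure(list(ref_aa = cand$ref_aa[i], position = cand$position[i],
                         alt_aa = cand$alt_aa[i]), class = "protein_change")
    w <- design_window(rec, ch, length = length, policy = policy)
    windows[[i]] <- w
    rows[[i]] <- data.frame(
      gene_symbol = cand$gene_symbol[i], accession = w$accession,
      sample_id = cand$sample_id[i],
      protein_change = format_protein_change(ch),
      ref_aa = cand$ref_aa[i], position = cand$position[i], alt_aa = cand$alt_aa[i],
      reason = cand$reason[i], window_start = w$window_start,
      mutated_offset = w$mutated_offset, wildtype_seq = w$wildtype_seq,
      mutant_seq = w$mutant_seq, synthesis_seq = w$synthesis_seq,
      crosses_feature_boundary = w$crosses_feature_boundary,
      internal_cysteine = w$internal_cysteine,
      stringsAsFactors = FALSE
    )
  }
  targets <- if (base::length(rows)) do.call(rbind, rows) else data.frame()
  rownames(targets) <- NULL
  structure(list(targets = targets, windows = windows, excluded = excluded,
                 n_requested = n, shortfall = shortfall),
            class = "panel_selection")
}

#' Export a target panel as FASTA
#'
#' Two entries per target: the mutant synthesis sequence (with conjugation
#' tag) and the untagged wild-type window. Headers encode gene, protein
#' change and window start.
#'
#' @param panel a `panel_selection`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
export_panel_fasta <- function(panel, path) {
  t <- panel$targets
  if (is.null(t) || nrow(t) == 0L) {
    warning("exporting empty panel", call. = FALSE)
    file.create(path)
    return(invisible(path))
  }
  seqs <- character(2L * nrow(t))
  hdrs <- character(2L * nrow(t))
  for (i in seq_len(nrow(t))) {
    base <- sprintf("%s|%s|start=%d", t$gene_symbol[i], t$protein_change[i], t$window_start[i])
    hdrs[2L * i - 1L] <- paste0(base, "|mutant")
    seqs[2L * i - 1L] <- t$synthesis_seq[i]
    hdrs[2L * i] <- paste0(base, "|wildtype")
    seqs[2L * i] <- t$wildtype_seq[i]
  }
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- hdrs
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a mutant/wild-type pair table
#'
#' Reads a TSV with columns `id`, `mutant`, `wildtype` — the format of the
#' bundled golden fixture of ten published immunogen pairs
#' (`system.file("extdata", "immunogen_pairs.tsv", package = "mspkit")`).
#'
#' @param path TSV path.
#' @return data.frame with columns `id`, `mutant`, `wildtype`.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "mutant", "wildtype")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("pair table missing column(s): ", paste(missing, collapse = ", "))
  df[, need]
}
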