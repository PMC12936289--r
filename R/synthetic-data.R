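# Synthetic proteome and tumor-cohort generator with recorded ground truth.
# The generator states a world: membrane proteins tiled with alternating
# extracellular / transmembrane / intracellular segments, secreted proteins
# with a cleavable signal peptide, a heavy-tailed per-patient missense
# burden (log-normal bulk plus a deterministic hypermutator subset), and an
# explicitly injected inter-patient sharing spectrum in which almost all
# variants are private. Sharing and hypermutators are constructed, not
# sampled, so recovery tests are exact.

#' Specification for a synthetic annotated proteome
#'
#' @param n_proteins number of proteins to generate.
#' @param length_range inclusive bounds for protein length (residues).
#' @param class_mix named proportions over `membrane`, `secreted`,
#'   `intracellular`; must sum to 1. Realized counts follow the proportions
#'   exactly (largest remainder), so a minority of residues are surface
#'   accessible, as in real proteomes.
#' @param seed integer seed; all generation is deterministic given it.
#' @return list of class `proteome_spec`.
#' @export
proteome_spec <- function(n_proteins = 60L,
                          length_range = c(120L, 800L),
                          class_mix = c(membrane = 0.35, secreted = 0.15,
                                        intracellular = 0.50),
                          seed = 1L) {
  stopifnot(n_proteins >= 1, length_range[1] >= 60, length_range[1] <= length_range[2],
            abs(sum(class_mix) - 1) < 1e-8,
            all(sort(names(class_mix)) == c("intracellular", "membrane", "secreted")))
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 class_mix = class_mix, seed = as.integer(seed)),
            class = "proteome_spec")
}

# exact integer apportionment by largest remainder
apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

random_aa_seq <- function(len) {
  paste(sample(AA_CANONICAL, len, replace = TRUE), collapse = "")
}

# tile a membrane protein of length len with alternating
# extracellular / transmembrane / intracellular segments (type-I-like,
# N-terminus outside); the last segment is truncated to end exactly at len
tile_membrane <- function(len) {
  kinds <- character(); starts <- integer(); ends <- integer()
  at <- 1L
  state <- 0L  # 0 ext, 1 tm, 2 intra, 3 tm, back to 0
  while (at <= len) {
    kind <- c("extracellular", "transmembrane", "intracellular", "transmembrane")[state + 1L]
    seg <- switch(kind,
      extracellular = sample(25:90, 1),
      transmembrane = sample(18:25, 1),
      intracellular = sample(10:60, 1)
    )
    end <- min(at + seg - 1L, len)
    kinds <- c(kinds, kind); starts <- c(starts, at); ends <- c(ends, end)
    at <- end + 1L
    state <- (state + 1L) %% 4L
  }
  data.frame(kind = kinds, start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated proteome
#'
#' Membrane proteins carry alternating extracellular / transmembrane /
#' intracellular features tiling the full sequence without overlaps or
#' gaps and are labeled `plasma_membrane` (a fraction additionally
#' `cell_junction` or `extracellular_matrix`, feeding the compartment
#' tally). Secreted proteins carry a signal peptide over roughly the first
#' 16-30 residues, the `secreted` label, and an unannotated mature chain.
#' Intracellular proteins carry one intracellular feature spanning the
#' sequence and no surface labels. Output is byte-identical across runs
#' with the same spec.
#'
#' @param spec a [proteome_spec()].
#' @return list of class `synthetic_proteome`: `store` (an
#'   `annotation_store`), and `truth` — per-protein class table
#'   (`gene_symbol`, `accession`, `class`, `signal_peptide_end`) plus the
#'   construction segment lists, used downstream to record variant-level
#'   ground truth independently of the classifier.
#' @export
make_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_proteins
    counts <- apportion(n, spec$class_mix[c("membrane", "secreted", "intracellular")])
    classes <- sample(rep(c("membrane", "secreted", "intracellular"), counts))
    width <- max(3L, nchar(as.character(n)))
    records <- vector("list", n)
    seg_lists <- vector("list", n)
    sp_end <- rep(NA_integer_, n)
    genes <- sprintf("SYNG%0*d", width, seq_len(n))
    accs <- sprintf("SYNP%0*d", width, seq_len(n))

    for (i in seq_len(n)) {
      len <- sample(spec$length_range[1]:spec$length_range[2], 1)
      seqc <- random_aa_seq(len)
      cls <- classes[i]
      if (cls == "membrane") {
        feats <- tile_membrane(len)
        labels <- "plasma_membrane"
        if (stats::runif(1) < 0.15) labels <- c(labels, "cell_junction")
        if (stats::runif(1) < 0.10) labels <- c(labels, "extracellular_matrix")
      } else if (cls == "secreted") {
        spe <- sample(16:30, 1)
        feats <- data.frame(kind = "signal_peptide", start = 1L, end = spe,
                            stringsAsFactors = FALSE)
        labels <- "secreted"
        if (stats::runif(1) < 0.20) labels <- c(labels, "extracellular_matrix")
        sp_end[i] <- spe
      } else {
        feats <- data.frame(kind = "intracellular", start = 1L, end = len,
                            stringsAsFactors = FALSE)
        labels <- "intracellular_other"
      }
      records[[i]] <- protein_record(accs[i], genes[i], seqc, feats, labels)
      seg_lists[[i]] <- feats
    }
    store <- as_annotation_store(records)
    truth <- list(
      classes = data.frame(gene_symbol = genes, accession = accs,
                           class = classes, signal_peptide_end = sp_end,
                           stringsAsFactors = FALSE),
      segments = stats::setNames(seg_lists, genes)
    )
    structure(list(store = store, truth = truth), class = "synthetic_proteome")
  })
}

#' Specification for a synthetic somatic mutation cohort
#'
#' @param n_patients number of patients.
#' @param count_model per-patient missense burden model: either
#'   `list(fixed = k)` for a constant count, or
#'   `list(meanlog =, sdlog =, hypermutator_fraction =,
#'   hypermutator_multiplier =)` — log-normal bulk (default median 75)
#'   with a deterministic hypermutator subset (the first
#'   `ceiling(fraction * n_patients)` patients in id order) whose counts
#'   are multiplied, reproducing the heavy right tail of real tumor
#'   cohorts (per-patient counts spanning roughly 10 to several thousand).
#' @param sharing_plan optional named integer vector `k -> number of
#'   unique variants carried by exactly k patients` (names are k). When the
#'   plan includes `"1"` it fully determines the number of unique variants;
#'   base variants are then apportioned to patients proportionally to the
#'   drawn burden model. Without a `"1"` entry, entries with k >= 2 are
#'   injected into an otherwise all-private cohort by copying chosen
#'   variants into exactly k patients.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 100L,
                        count_model = list(meanlog = log(75), sdlog = 0.6,
                                           hypermutator_fraction = 0.05,
                                           hypermutator_multiplier = 50),
                        sharing_plan = NULL, seed = 1L) {
  stopifnot(n_patients >= 1)
  if (!is.null(sharing_plan)) {
    ks <- as.integer(names(sharing_plan))
    stopifnot(!any(is.na(ks)), all(ks >= 1), all(sharing_plan >= 0))
    if (max(ks) > n_patients) {
      stop("sharing_plan requires a variant shared by ", max(ks),
           " patients but the cohort has only ", n_patients)
    }
  }
  if (!is.null(count_model$hypermutator_fraction)) {
    stopifnot(count_model$hypermutator_fraction >= 0,
              count_model$hypermutator_fraction <= 1)
  }
  structure(list(n_patients = as.integer(n_patients), count_model = count_model,
                 sharing_plan = sharing_plan, seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_patient_counts <- function(cm, n) {
  if (!is.null(cm$fixed)) return(rep(as.integer(cm$fixed), n))
  counts <- pmax(1, round(stats::rlnorm(n, cm$meanlog, cm$sdlog)))
  frac <- if (is.null(cm$hypermutator_fraction)) 0 else cm$hypermutator_fraction
  m <- ceiling(frac * n)
  if (m > 0) {
    counts[seq_len(m)] <- counts[seq_len(m)] * cm$hypermutator_multiplier
  }
  as.integer(counts)
}

# draw n_keys globally distinct (gene, position, ref, alt) substitutions
# from the store, vectorized with redraw on collision
draw_unique_keys <- function(store, n_keys) {
  genes <- names(store$records)
  lens <- vapply(store$records, function(r) nchar(r$sequence), integer(1))
  out <- NULL
  seen <- character()
  while (is.null(out) || nrow(out) < n_keys) {
    need <- n_keys - if (is.null(out)) 0L else nrow(out)
    gi <- sample(length(genes), need, replace = TRUE)
    pos <- vapply(gi, function(j) sample.int(lens[j], 1), integer(1))
    ref <- mapply(function(j, p) substring(store$records[[j]]$sequence, p, p), gi, pos)
    alt <- vapply(ref, function(r) sample(setdiff(AA_CANONICAL, r), 1), character(1),
                  USE.NAMES = FALSE)
    batch <- data.frame(gene_symbol = genes[gi], position = pos,
                        ref_aa = unname(ref), alt_aa = alt, stringsAsFactors = FALSE)
    key <- paste(batch$gene_symbol, batch$position, batch$ref_aa, batch$alt_aa, sep = "|")
    fresh <- !(key %in% seen) & !duplicated(key)
    seen <- c(seen, key[fresh])
    out <- rbind(out, batch[fresh, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

# ground-truth residue location from the generator's own construction
# segments (first covering segment; constructions never overlap)
truth_location <- function(truth, gene, position) {
  segs <- truth$segments[[gene]]
  hit <- which(segs$start <= position & segs$end >= position)
  if (!length(hit)) "unannotated" else segs$kind[hit[1]]
}

#' Generate a synthetic somatic mutation cohort
#'
#' Draws per-patient missense burdens from the count model, assigns
#' globally unique substitutions (uniform protein, uniform position,
#' uniform alternate residue over the 19 non-reference choices), and
#' injects the sharing plan by copying chosen variants into exactly k
#' distinct patients, chosen round-robin — sharing is constructed, not
#' sampled, so the measured spectrum recovers the plan exactly. Every
#' emitted variant gets one ground-truth record (residue location and MSP
#' flag) computed from the generator's own construction segments,
#' independent of the classifier under test.
#'
#' @param spec a [cohort_spec()].
#' @param proteome a `synthetic_proteome` from [make_proteome()].
#' @return list of class `synthetic_cohort`:
#'   `maf` (MAF-dialect data.frame: Hugo_Symbol, Variant_Classification,
#'   HGVSp_Short, Tumor_Sample_Barcode), `truth` (one row per variant:
#'   sample, gene, substitution, true location, true `is_msp`), `counts`
#'   (realized per-patient variant counts, the generating sample),
#'   `injected_sharing` (realized k -> unique-variant histogram), and the
#'   spec echo.
#' @export
make_cohort <- function(spec, proteome) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(proteome, "synthetic_proteome"))
  store <- proteome$store
  if (length(store) == 0L) stop("empty annotation store")
  truth_frag <- proteome$truth

  withr::with_seed(spec$seed, {
    n_pat <- spec$n_patients
    patients <- sprintf("PAT%04d", seq_len(n_pat))
    drawn <- draw_patient_counts(spec$count_model, n_pat)
    plan <- spec$sharing_plan

    if (!is.null(plan) && "1" %in% names(plan)) {
      # full plan: it fixes the unique-variant count; apportion base
      # (owner) variants to patients proportional to the drawn burdens
      n_keys <- sum(plan)
      base_counts <- apportion(n_keys, drawn / sum(drawn))
    } else {
      n_keys <- sum(drawn)
      base_counts <- drawn
      if (!is.null(plan) && sum(plan) > n_keys) {
        stop("sharing_plan asks for ", sum(plan),
             " shared variants but the cohort only has ", n_keys)
      }
    }

    keys <- draw_unique_keys(store, n_keys)
    owner <- rep(seq_len(n_pat), base_counts)
    stopifnot(length(owner) == n_keys)

    # carrier list per key: owner plus, for injected keys, the next k-1
    # patients cyclically after the owner
    carriers <- as.list(owner)
    if (!is.null(plan)) {
      ks <- sort(as.integer(names(plan)), decreasing = TRUE)
      ki <- 1L
      for (k in ks[ks >= 2L]) {
        m <- plan[[as.character(k)]]
        for (j in seq_len(m)) {
          extra <- (owner[ki] + seq_len(k - 1L) - 1L) %% n_pat + 1L
          carriers[[ki]] <- c(owner[ki], extra)
          stopifnot(!anyDuplicated(carriers[[ki]]))
          ki <- ki + 1L
        }
      }
    }

    class_by_gene <- stats::setNames(truth_frag$classes$class,
                                     truth_frag$classes$gene_symbol)
    locs <- vapply(seq_len(n_keys), function(i) {
      truth_location(truth_frag, keys$gene_symbol[i], keys$position[i])
    }, character(1))
    clss <- unname(class_by_gene[keys$gene_symbol])
    msp_flags <- locs == "extracellular" |
      (clss == "secreted" & locs != "signal_peptide")

    sizes <- vapply(carriers, base::length, integer(1))
    idx <- rep(seq_len(n_keys), sizes)
    truth <- data.frame(
      sample_id = patients[unlist(carriers)],
      gene_symbol = keys$gene_symbol[idx], position = keys$position[idx],
      ref_aa = keys$ref_aa[idx], alt_aa = keys$alt_aa[idx],
      true_location = locs[idx], true_is_msp = msp_flags[idx],
      stringsAsFactors = FALSE
    )
    truth <- truth[order(truth$sample_id, truth$gene_symbol, truth$position,
                         truth$alt_aa), , drop = FALSE]
    rownames(truth) <- NULL

    maf <- data.frame(
      Hugo_Symbol = truth$gene_symbol,
      Variant_Classification = "Missense_Mutation",
      HGVSp_Short = sprintf("p.%s%d%s", truth$ref_aa, truth$position, truth$alt_aa),
      Tumor_Sample_Barcode = truth$sample_id,
      stringsAsFactors = FALSE
    )

    counts_tab <- table(factor(truth$sample_id, levels = patients))
    counts <- stats::setNames(as.integer(counts_tab), patients)
    inj <- table(sizes)
    injected <- stats::setNames(as.integer(inj), names(inj))

    structure(list(maf = maf, truth = truth, counts = counts,
                   injected_sharing = injected, spec = spec),
              class = "synthetic_cohort")
  })
}
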