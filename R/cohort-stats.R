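# Per-patient and cohort-level mutation statistics: burden summaries,
# threshold prevalence, the inter-patient sharing spectrum, and the caliper
# tumor-volume utility.

#' Per-patient missense and MSP counts
#'
#' @param calls data.frame of MSP calls (see [classify_cohort()]).
#' @param all_samples optional character vector of sample ids that must
#'   appear in the output even with zero variants (patients with no
#'   classified variant still count toward cohort summaries).
#' @return data.frame `sample_id`, `n_missense`, `n_msp`, one row per
#'   patient, sorted by `sample_id`. Always `n_msp <= n_missense`.
#' @export
patient_summaries <- function(calls, all_samples = NULL) {
  ids <- sort(unique(c(as.character(calls$sample_id), as.character(all_samples))))
  n_mis <- vapply(ids, function(s) sum(calls$sample_id == s), integer(1))
  n_msp <- vapply(ids, function(s) sum(calls$sample_id == s & calls$is_msp), integer(1))
  data.frame(sample_id = ids, n_missense = unname(n_mis), n_msp = unname(n_msp),
             stringsAsFactors = FALSE)
}

five_numbers <- function(x) {
  q <- unname(stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       min = min(x), max = max(x))
}

#' Summarize a cohort's mutation burden
#'
#' Computes the five-number summary (median, quartiles, IQR, min, max) of
#' per-patient missense and MSP counts, plus the fraction of patients at or
#' above each requested threshold. Quartiles use linear interpolation
#' between order statistics (`stats::quantile` type 7; the method is echoed
#' in the output so reports are self-describing). Fractional medians such
#' as 76.5 or 24.75 arise naturally on even-sized cohorts.
#'
#' @param summaries data.frame from [patient_summaries()] (or any frame
#'   with `sample_id`, `n_missense`, `n_msp`).
#' @param thresholds integer vector of "at least n" thresholds evaluated
#'   for both count types; default `10` (the panel-sized threshold).
#' @return list of class `cohort_summary`: `n_patients`, `missense` and
#'   `msp` (each median/q1/q3/iqr/min/max), `fraction_at_least` (data.frame
#'   threshold x {missense, msp} proportions), `quartile_method`.
#' @export
summarize_cohort <- function(summaries, thresholds = 10L) {
  if (nrow(summaries) == 0L) stop("empty cohort: no patients to summarize")
  fr <- data.frame(
    threshold = as.integer(thresholds),
    missense = vapply(thresholds, function(k) fraction_at_least(summaries, k, "missense"), numeric(1)),
    msp = vapply(thresholds, function(k) fraction_at_least(summaries, k, "msp"), numeric(1))
  )
  structure(list(
    n_patients = nrow(summaries),
    missense = five_numbers(summaries$n_missense),
    msp = five_numbers(summaries$n_msp),
    fraction_at_least = fr,
    quartile_method = "linear interpolation between order statistics (type 7)"
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort of", x$n_patients, "patient(s)\n")
  for (w in c("missense", "msp")) {
    s <- x[[w]]
    cat(sprintf("  %-9s median %.6g (Q1 %.6g, Q3 %.6g, IQR %.6g; min %g, max %g)\n",
                w, s$median, s$q1, s$q3, s$iqr, s$min, s$max))
  }
  invisible(x)
}

#' Fraction of patients with at least n variants
#'
#' Exact proportion of patients whose count of the chosen type is `>= n`.
#' Non-increasing in `n`; `n = 0` is vacuously 1.
#'
#' @param summaries data.frame from [patient_summaries()].
#' @param n threshold count.
#' @param which `"missense"` or `"msp"`.
#' @return proportion in `[0, 1]`.
#' @export
fraction_at_least <- function(summaries, n, which = c("missense", "msp")) {
  which <- match.arg(which)
  if (nrow(summaries) == 0L) stop("empty cohort")
  col <- if (which == "missense") summaries$n_missense else summaries$n_msp
  mean(col >= n)
}

#' Inter-patient variant sharing spectrum
#'
#' Keys each variant at the protein level (gene symbol + substitution), and
#' counts how many distinct patients carry each unique key — a patient
#' contributes at most once per key. The histogram maps k (number of
#' patients sharing) to the number of unique keys shared by exactly k
#' patients; conservation identities (sum of histogram = unique keys; sum
#' of k*histogram = patient-key occurrences) hold on every input and are
#' asserted before returning.
#'
#' @param calls data.frame of calls (commonly pre-filtered to
#'   `is_msp == TRUE` for an MSP sharing spectrum).
#' @param key_mode only `"protein_level"` is implemented.
#' @return list of class `sharing_spectrum`: `key_counts` (named integer:
#'   key -> distinct patients), `histogram` (named integer: k -> keys),
#'   `n_unique_keys`, `n_occurrences`, `shared_by_at_least` (named numeric:
#'   k = 2.. -> keys shared by >= k patients, with percentages of unique
#'   keys rounded to three decimals in `shared_by_at_least_pct`).
#' @export
sharing_spectrum <- function(calls, key_mode = "protein_level") {
  key_mode <- match.arg(key_mode, "protein_level")
  if (nrow(calls) == 0L) {
    return(structure(list(key_counts = integer(), histogram = integer(),
                          n_unique_keys = 0L, n_occurrences = 0L,
                          shared_by_at_least = numeric(),
                          shared_by_at_least_pct = numeric()),
                     class = "sharing_spectrum"))
  }
  key <- paste(calls$gene_symbol, calls$position, calls$ref_aa, calls$alt_aa, sep = "|")
  occ <- unique(data.frame(key = key, sample_id = calls$sample_id,
                           stringsAsFactors = FALSE))
  counts <- table(occ$key)
  key_counts <- stats::setNames(as.integer(counts), names(counts))
  hist_tab <- table(key_counts)
  histogram <- stats::setNames(as.integer(hist_tab), names(hist_tab))

  n_unique <- length(key_counts)
  n_occ <- nrow(occ)
  stopifnot(sum(histogram) == n_unique,
            sum(as.integer(names(histogram)) * histogram) == n_occ)

  ks <- 2:max(2L, max(key_counts))
  at_least <- vapply(ks, function(k) sum(key_counts >= k), numeric(1))
  names(at_least) <- ks
  pct <- round(100 * at_least / n_unique, 3)

  structure(list(key_counts = key_counts, histogram = histogram,
                 n_unique_keys = n_unique, n_occurrences = n_occ,
                 shared_by_at_least = at_least, shared_by_at_least_pct = pct),
            class = "sharing_spectrum")
}

#' @export
print.sharing_spectrum <- function(x, ...) {
  cat("sharing spectrum:", x$n_unique_keys, "unique key(s),",
      x$n_occurrences, "patient-key occurrence(s)\n")
  if (length(x$histogram)) {
    for (k in names(x$histogram)) {
      cat(sprintf("  shared by exactly %s patient(s): %d key(s)\n", k, x$histogram[[k]]))
    }
  }
  invisible(x)
}

#' Caliper tumor volume
#'
#' `V = w^2 * l / 2` with width `w` and length `l` in mm. By convention the
#' width is the smaller dimension; inputs are swapped with a warning when
#' `w > l`. Vectorized.
#'
#' @param w tumor width (mm), `>= 0`.
#' @param l tumor length (mm), `>= 0`.
#' @return volume in mm^3.
#' @export
tumor_volume <- function(w, l) {
  if (any(w < 0) || any(l < 0)) stop("tumor dimensions must be non-negative")
  swap <- w > l
  if (any(swap)) {
    warning("width > length for ", sum(swap), " measurement(s); swapping", call. = FALSE)
    tmp <- w[swap]; w[swap] <- l[swap]; l[swap] <- tmp
  }
  w^2 * l / 2
}

#' Concentration of an equal-part antibody cocktail
#'
#' Pooling `n` antibody preparations at `per_antibody` each (equal mass
#' proportions) gives a total cocktail concentration of `n * per_antibody`.
#'
#' @param n number of antibody preparations pooled.
#' @param per_antibody concentration of each component (any unit).
#' @return total cocktail concentration, same unit.
#' @export
cocktail_concentration <- function(n, per_antibody) {
  stopifnot(n >= 0, per_antibody >= 0)
  n * per_antibody
}
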