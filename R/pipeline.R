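# End-to-end pipeline wiring and command-line interface: read variants,
# classify and call MSPs, tally compartments, design and select the peptide
# panel, and compute cohort statistics, with a manifest that is sufficient
# to re-run the analysis identically.

#' Build a validated pipeline run configuration
#'
#' @param maf path to the MAF-dialect variant TSV.
#' @param store path to the annotation-store JSON.
#' @param outdir output directory (created if missing).
#' @param n panel size (default 10).
#' @param window_length peptide window length (default 14).
#' @param policy window placement policy (default `"centered"`).
#' @param tally_mode `"exclusive"` or `"overlapping"`.
#' @param thresholds "at least n" thresholds for prevalence reporting.
#' @param exclude_genes optional path to a one-gene-per-line exclusion list
#'   (e.g. known oncogenes), or a character vector of genes.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(maf, store, outdir, n = 10L, window_length = 14L,
                       policy = "centered", tally_mode = "exclusive",
                       thresholds = c(1L, 5L, 10L), exclude_genes = NULL,
                       seed = 1L) {
  if (!file.exists(maf)) stop("MAF file not found: ", maf)
  if (!file.exists(store)) stop("store file not found: ", store)
  stopifnot(n >= 1, window_length >= 1)
  if (is.character(exclude_genes) && length(exclude_genes) == 1L &&
      file.exists(exclude_genes)) {
    exclude_genes <- readLines(exclude_genes, warn = FALSE)
    exclude_genes <- exclude_genes[nzchar(trimws(exclude_genes))]
  }
  structure(list(maf = maf, store = store, outdir = outdir, n = as.integer(n),
                 window_length = as.integer(window_length), policy = policy,
                 tally_mode = tally_mode, thresholds = as.integer(thresholds),
                 exclude_genes = exclude_genes, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full target-selection pipeline
#'
#' Executes read -> classify -> tally -> design/select -> cohort stats and
#' writes every stage output under `config$outdir`: normalized variants,
#' rejection and exclusion logs, MSP calls, compartment tally, panel
#' manifest and FASTA, per-patient counts, cohort summary, sharing
#' histogram, and a JSON run manifest echoing the configuration and the
#' stage counts (rows read, accepted, classified, MSP calls, panel size).
#' Stage counts form a monotone funnel.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (list; also written as
#'   `manifest.json`). `manifest$status` is `"ok"` or `"shortfall"` (panel
#'   smaller than requested).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)

  maf <- read_maf(config$maf)
  store <- load_store(config$store)
  write_variants(maf$variants, out("variants.tsv"))
  utils::write.table(maf$rejections, out("rejections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cls <- classify_cohort(maf$variants, store)
  utils::write.table(cls$calls, out("msp_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cls$exclusions, out("exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tally <- compartment_tally(maf$variants, store, mode = config$tally_mode)
  jsonlite::write_json(
    list(total = tally$total, mode = tally$mode,
         counts = as.list(tally$counts),
         percentages = as.list(tally$percentages)),
    out("compartment_tally.json"), auto_unbox = TRUE, digits = NA)

  msp_calls <- cls$calls[cls$calls$is_msp, , drop = FALSE]
  panel <- withCallingHandlers(
    select_panel(msp_calls, store, n = config$n,
                 exclude_genes = config$exclude_genes,
                 length = config$window_length, policy = config$policy),
    warning = function(w) {
      message("select_panel: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (nrow(panel$targets)) {
    utils::write.table(panel$targets, out("panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    export_panel_fasta(panel, out("panel.fasta"))
  }

  summaries <- patient_summaries(cls$calls)
  utils::write.table(summaries, out("patient_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spectrum <- sharing_spectrum(msp_calls)
  if (nrow(summaries)) {
    cs <- summarize_cohort(summaries, thresholds = config$thresholds)
    jsonlite::write_json(
      list(n_patients = cs$n_patients, missense = cs$missense, msp = cs$msp,
           fraction_at_least = cs$fraction_at_least,
           quartile_method = cs$quartile_method),
      out("cohort_summary.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
    hist_df <- data.frame(patients = as.integer(names(spectrum$histogram)),
                          unique_variants = unname(spectrum$histogram))
    utils::write.table(hist_df, out("sharing_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    tool = "mspkit", version = as.character(utils::packageVersion("mspkit")),
    seed = config$seed,
    config = config[setdiff(names(config), "outdir")],
    counts = list(
      rows_read = nrow(maf$variants) + nrow(maf$rejections),
      accepted = nrow(maf$variants),
      classified = nrow(cls$calls),
      msp_calls = nrow(msp_calls),
      panel_size = nrow(panel$targets)
    ),
    status = if (panel$shortfall) "shortfall" else "ok"
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Command-line interface
#'
#' Subcommand dispatcher intended for use from `Rscript`; see the package
#' README. Subcommands: `simulate-proteome`, `simulate-cohort`, `run`,
#' `validate-pairs`.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return exit code, invisibly: 0 success, 2 panel shortfall, 1 error.
#'   Call `quit(status = pipeline_cli())` from a wrapper script.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: mspkit <simulate-proteome|simulate-cohort|run|validate-pairs> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  code <- tryCatch(
    switch(cmd,
      "simulate-proteome" = cli_simulate_proteome(rest),
      "simulate-cohort" = cli_simulate_cohort(rest),
      "run" = cli_run(rest),
      "validate-pairs" = cli_validate_pairs(rest),
      { message("unknown subcommand: ", cmd); 1L }
    ),
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
  invisible(code)
}

cli_simulate_proteome <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--n-proteins", type = "integer", default = 60L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "proteome.json")
  )), args = args)
  prot <- make_proteome(proteome_spec(n_proteins = opts$`n-proteins`, seed = opts$seed))
  write_store(prot$store, opts$out)
  export_store_fasta(prot$store, sub("\\.json$", ".fasta", opts$out))
  message("wrote ", opts$out)
  0L
}

cli_simulate_cohort <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--store", type = "character"),
    optparse::make_option("--n-patients", type = "integer", default = 100L),
    optparse::make_option("--proteome-seed", type = "integer", default = 1L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "cohort.maf.tsv")
  )), args = args)
  # the cohort generator needs construction truth, so it regenerates the
  # proteome from its seed rather than loading a bare store
  prot <- make_proteome(proteome_spec(seed = opts$`proteome-seed`))
  cohort <- make_cohort(cohort_spec(n_patients = opts$`n-patients`, seed = opts$seed), prot)
  utils::write.table(cohort$maf, opts$out, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paste0(opts$out, ".truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", opts$out, " (", nrow(cohort$maf), " variant rows)")
  0L
}

cli_run <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--maf", type = "character"),
    optparse::make_option("--store", type = "character"),
    optparse::make_option("--outdir", type = "character", default = "mspkit_out"),
    optparse::make_option("--n", type = "integer", default = 10L),
    optparse::make_option("--window-length", type = "integer", default = 14L),
    optparse::make_option("--tally-mode", type = "character", default = "exclusive"),
    optparse::make_option("--exclude-genes", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L)
  )), args = args)
  cfg <- run_config(opts$maf, opts$store, opts$outdir, n = opts$n,
                    window_length = opts$`window-length`,
                    tally_mode = opts$`tally-mode`,
                    exclude_genes = opts$`exclude-genes`, seed = opts$seed)
  manifest <- run_pipeline(cfg)
  if (manifest$status == "shortfall") 2L else 0L
}

cli_validate_pairs <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--pairs", type = "character",
      default = system.file("extdata", "immunogen_pairs.tsv", package = "mspkit"))
  )), args = args)
  pairs <- read_pair_table(opts$pairs)
  ok <- 0L
  for (i in seq_len(nrow(pairs))) {
    v <- validate_pair(pairs$wildtype[i], pairs$mutant[i])
    status <- if (v$pass) {
      ok <- ok + 1L
      sprintf("pass (%s%d%s)", v$ref_aa, v$offset, v$alt_aa)
    } else {
      paste("FAIL:", paste(v$reasons, collapse = ","))
    }
    message(sprintf("%-12s %s", pairs$id[i], status))
  }
  message(ok, "/", nrow(pairs), " pairs pass")
  if (ok == nrow(pairs)) 0L else 1L
}
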