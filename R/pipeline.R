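## ---- run configuration -----------------------------------------------------

run_config_keys <- list(
  simulate = c("seed", "out_dir", "n_products", "n_insertions", "condition",
               "element_length", "locus_length", "adapter_seq",
               "ref_tail_length", "p_tca", "p_other", "background_p",
               "rnase_h_active", "flank5_top_exposed", "flank3_bottom_exposed",
               "ung_active", "ugi_active", "p_restore", "p_abort",
               "p_inversion"),
  call = c("seed", "out_dir", "fasta", "ref_seed", "element_length",
           "locus_length", "adapter_seq", "ref_tail_length", "vcf"),
  contexts = c("seed", "out_dir", "calls", "coverage", "region", "ref_seed",
               "element_length", "locus_length", "adapter_seq",
               "ref_tail_length"),
  annotate = c("seed", "out_dir", "fasta", "ref_seed", "element_length",
               "locus_length", "adapter_seq", "ref_tail_length"),
  quantify = c("seed", "out_dir", "counts", "control"))

#' Validate a run configuration
#'
#' A run configuration is a named list of subcommand parameters (typically
#' read from a YAML/JSON file via [read_run_config()]). Unknown keys are
#' rejected; a seed is required so that every output can record it.
#'
#' @param config Named list of parameters.
#' @param subcommand One of `simulate`, `call`, `contexts`, `annotate`,
#'   `quantify`.
#' @return The validated config (invisibly usable), with defaults filled in
#'   (`seed = 1`, `out_dir = "."`).
#' @export
validate_run_config <- function(config,
                                subcommand = c("simulate", "call", "contexts",
                                               "annotate", "quantify")) {
  subcommand <- match.arg(subcommand)
  if (is.null(names(config)) && length(config))
    stop_input("config must be a named list")
  unknown <- setdiff(names(config), run_config_keys[[subcommand]])
  if (length(unknown))
    stop_input("unknown config key(s) for '", subcommand, "': ",
               paste(unknown, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) config$out_dir <- "."
  config$seed <- as.integer(config$seed)
  config
}

#' Read a run configuration file (YAML or JSON)
#'
#' @param path Path to a YAML (or JSON, a YAML subset) config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  yaml::read_yaml(path)
}

ref_from_config <- function(config) {
  make_reference(
    element_length = config$element_length %||% 300L,
    adapter_seq = config$adapter_seq %||% leap_oligos()[["adapter_5np1"]],
    locus_length = config$locus_length %||% 1000L,
    seed = config$ref_seed %||% config$seed,
    ref_tail_length = config$ref_tail_length %||% 30L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline subcommands
#'
#' Thin, config-driven entry points tying the modules together; each is pure
#' with respect to (inputs, seed), records the seed in its output headers, and
#' raises an error (nonzero exit under `Rscript`) on any module error.
#'
#' * `run_simulate()` — reference + LEAP products (+ insertions when
#'   `n_insertions` is set): FASTA plus truth TSVs.
#' * `run_call()` — align a product FASTA to the reference and write calls
#'   TSV (optionally VCF).
#' * `run_contexts()` — context table TSV + histogram TSV from a calls TSV.
#' * `run_annotate()` — structural annotation TSV for an insertion FASTA.
#' * `run_quantify()` — normalized retrotransposition TSV from a colony
#'   count TSV.
#'
#' @param config Named list, validated against the subcommand's known keys
#'   (unknown keys are rejected). Common keys: `seed`, `out_dir`; see the
#'   package vignette for the full set.
#' @return Invisibly, the paths written.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config = list()) {
  config <- validate_run_config(config, "simulate")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- ref_from_config(config)
  cond <- leap_condition(config$condition %||% "a3a_rnaseh")
  deam <- if (!is.null(config$p_tca) || !is.null(config$p_other) ||
                !is.null(config$background_p)) {
    deamination_model(p_tca = config$p_tca %||% cond$deam$p_by_context[["TCA"]],
                      p_other = config$p_other %||% 0.042,
                      background_p = config$background_p %||% 0)
  } else cond$deam
  exposure <- exposure_model(
    rnase_h_active = config$rnase_h_active %||% cond$exposure$rnase_h_active,
    flank5_top_exposed = config$flank5_top_exposed %||% FALSE,
    flank3_bottom_exposed = config$flank3_bottom_exposed %||% FALSE)
  structure <- structure_model(p_inversion = config$p_inversion %||% 0.15)

  paths <- character(0)
  sim <- simulate_leap_products(ref, config$n_products %||% 100L,
                                exposure, deam, structure,
                                seed = config$seed)
  paths <- write_leap_sim(sim, config$out_dir)
  if (!is.null(config$n_insertions)) {
    repair <- repair_model(ung_active = config$ung_active %||% TRUE,
                           ugi_active = config$ugi_active %||% TRUE,
                           p_restore = config$p_restore %||% 0.5,
                           p_abort = config$p_abort %||% 0.5)
    isim <- simulate_insertions(ref, config$n_insertions, deam, repair,
                                structure, exposure, seed = config$seed)
    paths <- c(paths, write_insertion_sim(isim, config$out_dir))
  }
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_call <- function(config = list()) {
  config <- validate_run_config(config, "call")
  if (is.null(config$fasta)) stop_input("config key 'fasta' is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- ref_from_config(config)
  products <- read_fasta(config$fasta)
  cs <- call_products(ref, products)
  out <- file.path(config$out_dir, "calls.tsv")
  write_calls(cs, out,
              vcf = if (isTRUE(config$vcf))
                file.path(config$out_dir, "calls.vcf"))
  cov <- file.path(config$out_dir, "coverage.tsv")
  write_tsv_commented(cs$coverage, cov, paste0("seed=", config$seed))
  tails <- file.path(config$out_dir, "tails.tsv")
  write_tsv_commented(cs$tails, tails, paste0("seed=", config$seed))
  invisible(c(calls = out, coverage = cov, tails = tails))
}

#' @rdname pipeline
#' @export
run_contexts <- function(config = list()) {
  config <- validate_run_config(config, "contexts")
  if (is.null(config$calls)) stop_input("config key 'calls' is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- ref_from_config(config)
  calls <- read_tsv_commented(config$calls)
  coverage <- if (!is.null(config$coverage))
    read_tsv_commented(config$coverage) else NULL
  tab <- build_context_table(ref, calls, coverage,
                             region = config$region %||% "internal")
  out <- file.path(config$out_dir, "context_table.tsv")
  write_context_table(tab, out)
  hist <- edits_per_product_histogram(
    calls, product_ids = if (!is.null(coverage)) coverage$product_id)
  hout <- file.path(config$out_dir, "edits_histogram.tsv")
  write_tsv_commented(data.frame(n_edits = as.integer(names(hist)),
                                 n_products = as.integer(hist)),
                      hout, paste0("seed=", config$seed))
  invisible(c(contexts = out, histogram = hout))
}

#' @rdname pipeline
#' @export
run_annotate <- function(config = list()) {
  config <- validate_run_config(config, "annotate")
  if (is.null(config$fasta)) stop_input("config key 'fasta' is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- ref_from_config(config)
  recs <- read_fasta(config$fasta)
  rows <- lapply(seq_len(nrow(recs)), function(i) {
    ann <- annotate_insertion(ref$genomic_locus, recs$sequence[i],
                              ref$element, ref$orf_intervals)
    data.frame(insertion_id = recs$id[i],
               truncation_point = ann$truncation_point,
               inversion = ann$inversion,
               tsd5 = ann$tsd5, tsd3 = ann$tsd3,
               tsd_length = ann$tsd_length, tsd_status = ann$tsd_status,
               n_internal_calls = nrow(ann$internal_calls),
               n_nonsense = sum(ann$internal_calls$consequence == "nonsense"),
               stringsAsFactors = FALSE)
  })
  out <- file.path(config$out_dir, "insertion_annotations.tsv")
  write_tsv_commented(do.call(rbind, rows), out, paste0("seed=", config$seed))
  invisible(c(annotations = out))
}

#' @rdname pipeline
#' @export
run_quantify <- function(config = list()) {
  config <- validate_run_config(config, "quantify")
  if (is.null(config$counts)) stop_input("config key 'counts' is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_tsv_commented(config$counts)
  res <- normalize_retro(counts, control = config$control %||% "control")
  out <- file.path(config$out_dir, "normalized_retrotransposition.tsv")
  write_tsv_commented(res, out, paste0("seed=", config$seed))
  invisible(c(quantify = out))
}
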