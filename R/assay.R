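#' Colony-count experiment table
#'
#' Validates and normalises a colony-count table from a retrotransposition
#' assay run in parallel with its toxicity control: one row per
#' (cofactor, reporter, replicate) with a non-negative G418-resistant colony
#' count. `reporter` distinguishes the retrotransposition indicator (`L1`)
#' from the co-transfected NEO expression control (`NEO_control`); `cofactor`
#' labels the co-expressed protein (e.g. `A3A`, `A3A_C106S`, `control`).
#'
#' @param counts data.frame with columns `cofactor`, `reporter`, `replicate`,
#'   `count`.
#' @return The validated data.frame (class `colony_counts` prepended).
#' @export
colony_counts <- function(counts) {
  need <- c("cofactor", "reporter", "replicate", "count")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols))
    stop_input("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(counts$count < 0)) stop_input("counts must be non-negative")
  cells <- unique(counts[, c("cofactor", "reporter")])
  for (k in seq_len(nrow(cells))) {
    sel <- counts$cofactor == cells$cofactor[k] &
      counts$reporter == cells$reporter[k]
    if (!any(sel)) stop_input("empty cell in the design")
  }
  class(counts) <- c("colony_counts", class(counts))
  counts
}

#' Toxicity-normalized retrotransposition percentages
#'
#' For each cofactor, the raw retrotransposition ratio
#' `mean(L1, cofactor) / mean(L1, control)` is divided by the toxicity ratio
#' `mean(NEO, cofactor) / mean(NEO, control)` (the fraction of NEO-control
#' colonies surviving the cofactor), and scaled to percent. Dividing by the
#' toxicity ratio removes any nonspecific cytotoxicity of the cofactor, so the
#' reported percentage reflects specific inhibition of retrotransposition.
#' The control cofactor is 100% by construction. The SD is the sample
#' (n-1) standard deviation of the per-replicate normalized values
#' (`100 * (L1[cofactor, r] / mean(L1, control)) / toxicity ratio`).
#'
#' @param counts A [colony_counts()] table (plain data.frames are validated
#'   first).
#' @param control Name of the control cofactor (default `"control"`).
#' @param l1_reporter,neo_reporter Reporter labels (defaults `"L1"`,
#'   `"NEO_control"`).
#' @return data.frame with one row per cofactor: `cofactor`, `raw_ratio`,
#'   `toxicity_ratio`, `percent` (mean normalized percent), `sd` (NA for a
#'   single replicate), `n_replicates`; the per-replicate normalized values
#'   are attached as attribute `"per_replicate"`.
#' @examples
#' counts <- data.frame(
#'   cofactor = rep(c("A3A", "control"), each = 2),
#'   reporter = rep(c("L1", "NEO_control"), 2),
#'   replicate = 1, count = c(50, 80, 200, 100))
#' normalize_retro(counts)
#' @export
normalize_retro <- function(counts, control = "control",
                            l1_reporter = "L1", neo_reporter = "NEO_control") {
  if (!inherits(counts, "colony_counts")) counts <- colony_counts(counts)
  cell <- function(cof, rep_) counts$count[counts$cofactor == cof &
                                             counts$reporter == rep_]
  if (!control %in% counts$cofactor)
    stop_input("control cofactor '", control, "' absent from the table")
  l1_ctrl <- mean(cell(control, l1_reporter))
  neo_ctrl <- mean(cell(control, neo_reporter))
  if (!is.finite(l1_ctrl) || l1_ctrl == 0)
    stop_input("control L1 mean count is zero")
  if (!is.finite(neo_ctrl) || neo_ctrl == 0)
    stop_input("control NEO mean count is zero")

  cofs <- unique(counts$cofactor)
  per_rep <- list()
  rows <- lapply(cofs, function(cof) {
    l1 <- cell(cof, l1_reporter)
    neo <- cell(cof, neo_reporter)
    tox <- mean(neo) / neo_ctrl
    if (tox == 0)
      stop(errorCondition(
        paste0("complete toxicity: NEO control count is zero for cofactor '",
               cof, "'"),
        class = c("l1deam_complete_toxicity", "l1deam_input_error", "error")))
    vals <- 100 * (l1 / l1_ctrl) / tox
    per_rep[[cof]] <<- vals
    data.frame(cofactor = cof,
               raw_ratio = mean(l1) / l1_ctrl,
               toxicity_ratio = tox,
               percent = mean(vals),
               sd = if (length(vals) > 1L) sd(vals) else NA_real_,
               n_replicates = length(vals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_replicate") <- per_rep
  out
}

#' Pool normalized results across independent experiments
#'
#' Pools the per-replicate normalized percentages of several
#' [normalize_retro()] results (e.g. three independent experiments of two
#' technical replicates each) and reports, per cofactor, the mean and the
#' sample (n-1) SD over all pooled technical replicates. A single pooled
#' value has an undefined SD, reported as NA.
#'
#' @param results List of [normalize_retro()] outputs.
#' @return data.frame `cofactor`, `percent`, `sd`, `n_replicates`.
#' @export
aggregate_experiments <- function(results) {
  if (!length(results)) stop_input("need at least one result")
  pooled <- list()
  for (res in results) {
    pr <- attr(res, "per_replicate")
    if (is.null(pr)) stop_input("results must come from normalize_retro()")
    for (cof in names(pr)) pooled[[cof]] <- c(pooled[[cof]], pr[[cof]])
  }
  out <- do.call(rbind, lapply(names(pooled), function(cof) {
    v <- pooled[[cof]]
    data.frame(cofactor = cof, percent = mean(v),
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               n_replicates = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
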