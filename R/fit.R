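#' Fit per-context deamination probabilities
#'
#' The estimation layer over the context accounting, in the classic modelling
#' idiom: binomial site-product trials per trinucleotide context, maximum
#' likelihood point estimates (`deaminated / available`) with Wilson score
#' intervals. The fitted object supports `print`, `summary`, `coef`,
#' `confint`, `predict`, `residuals`, `plot` and `simulate` (parametric
#' regeneration of LEAP products from the fitted probabilities).
#'
#' @param ref An [make_reference()] reference set.
#' @param calls Calls data.frame (from [call_products()]`$calls` or a truth
#'   table).
#' @param coverage Aligned-span data.frame (see [build_context_table()]).
#' @param region Region accounted for (default `"internal"`).
#' @param conf.level Confidence level of the intervals.
#' @param n_products Number of products interrogated when `coverage` is
#'   defaulted (see [build_context_table()]).
#' @return Object of class `deam_fit`.
#' @examples
#' ref <- make_reference(seed = 7)
#' cond <- leap_condition("a3a_rnaseh")
#' sim <- simulate_leap_products(ref, 50, cond$exposure, cond$deam, seed = 3)
#' fit <- deamination_fit(ref, sim$truth, n_products = 50)
#' coef(fit)[["TGA"]]
#' @export
deamination_fit <- function(ref, calls, coverage = NULL, region = "internal",
                            conf.level = 0.95, n_products = NULL) {
  table <- build_context_table(ref, calls, coverage, region, n_products)
  estimates <- estimate_context_probabilities(table, conf.level)
  structure(list(table = table, estimates = estimates, region = region,
                 conf.level = conf.level, ref = ref),
            class = "deam_fit")
}

#' @export
coef.deam_fit <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$context)
}

#' @export
confint.deam_fit <- function(object, parm, level, ...) {
  ci <- as.matrix(object$estimates[, c("lower", "upper")])
  rownames(ci) <- object$estimates$context
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.deam_fit <- function(x, ...) {
  cat(sprintf("Per-context deamination fit (%s region, %d products, %d%% Wilson CIs)\n",
              x$region, x$table$n_products, round(100 * x$conf.level)))
  est <- x$estimates
  est$estimate <- sprintf("%.3f", est$estimate)
  est$lower <- sprintf("%.3f", est$lower)
  est$upper <- sprintf("%.3f", est$upper)
  print(est, row.names = FALSE)
  invisible(x)
}

#' @export
summary.deam_fit <- function(object, ...) {
  print(object)
  tga <- object$estimates[object$estimates$context == "TGA", , drop = FALSE]
  if (nrow(tga))
    cat(sprintf(paste0("Minus-strand 5'-TCA-3' consensus (plus-strand TGA): ",
                       "%d of %d sites deaminated (%.1f%%)\n"),
                tga$deaminated, tga$available, 100 * tga$estimate))
  invisible(object)
}

#' @export
predict.deam_fit <- function(object, newdata = NULL, ...) {
  ## expected deaminated counts for given availabilities
  if (is.null(newdata)) {
    newdata <- object$estimates[, c("context", "available")]
  }
  p <- coef(object)[newdata$context]
  unname(p * newdata$available)
}

#' @export
residuals.deam_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  est <- object$estimates
  expected <- est$estimate * est$available
  res <- est$deaminated - expected
  if (type == "pearson") {
    v <- est$available * est$estimate * (1 - est$estimate)
    res <- ifelse(v > 0, res / sqrt(v), 0)
  }
  setNames(res, est$context)
}

#' @export
plot.deam_fit <- function(x, ...) {
  rows <- x$table$rows
  pct <- ifelse(is.na(rows$percent), 0, rows$percent)
  bp <- graphics::barplot(pct, names.arg = rows$context, las = 2,
                          ylab = "% of available sites deaminated",
                          main = sprintf("Deamination by context (%s region)",
                                         x$region), ...)
  invisible(bp)
}

#' @export
simulate.deam_fit <- function(object, nsim = 1, seed = NULL, ...) {
  ## regenerate LEAP products from the fitted per-context probabilities
  if (is.null(seed)) seed <- 1L
  p16 <- setNames(rep(0, 16L), trinucleotides("C"))
  est <- coef(object)
  plus_ctx <- intersect(names(est), trinucleotides("G"))
  p16[revcomp(plus_ctx)] <- est[plus_ctx]
  deam <- deamination_model(p_by_context = p16, p_tca = 0, p_other = 0)
  simulate_leap_products(object$ref, nsim,
                         exposure = exposure_model(rnase_h_active = TRUE),
                         deam = deam, seed = seed)
}
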