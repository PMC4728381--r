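#' Fit a qPCR dilution standard curve
#'
#' Least-squares fit of mean CT against log10 relative input over a dilution
#' series (at least three dilutions). Amplification efficiency is derived from
#' the slope as `E = 10^(-1/slope) - 1`; a perfect doubling per cycle gives
#' slope -3.3219 and E = 1.
#'
#' @param relative_input Dilution fractions (e.g. 1, 0.1, 0.01), distinct,
#'   positive.
#' @param ct_mean Mean CT per dilution, parallel to `relative_input`.
#' @return A `standard_curve` object: list with `slope` (cycles per log10
#'   input), `efficiency` (fraction, e.g. 0.95), `r_squared`, `points`, and
#'   `flags` (contains `"efficiency_out_of_range"` when E falls outside
#'   [0.6, 1.2]).
#' @examples
#' fit_standard_curve(c(1, 0.1, 0.01), c(20, 23.3219, 26.6439))  # E = 1
#' @export
fit_standard_curve <- function(relative_input, ct_mean) {
  if (length(relative_input) < 3L)
    stop("a standard curve needs at least three dilutions")
  if (anyDuplicated(relative_input)) stop("dilutions must be distinct")
  stopifnot(all(relative_input > 0), length(ct_mean) == length(relative_input))
  fit <- stats::lm(ct_mean ~ log10(relative_input))
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("non-amplifying standard curve: slope must be negative, got ", slope)
  eff <- 10^(-1 / slope) - 1
  flags <- character(0)
  if (eff < 0.6 || eff > 1.2) {
    flags <- "efficiency_out_of_range"
    warning("qPCR efficiency ", round(eff, 3), " outside the usual [0.6, 1.2]")
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct_mean - mean(ct_mean))^2)
  structure(list(slope = slope, efficiency = eff,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 points = data.frame(relative_input = relative_input,
                                     ct_mean = ct_mean),
                 flags = flags),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: slope %.4f cycles/log10, E = %.1f%% (R2 %.4f)\n",
              x$slope, 100 * x$efficiency, x$r_squared))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Percent modification from a restriction-digest qPCR assay
#'
#' Percent of modified (cleavage-protected) molecules at the interrogated
#' site, from the CT shift between enzyme-treated and mock-treated aliquots:
#' `percent = 100 / (1 + E)^dCT` with
#' `dCT = mean(ct_treated) - mean(ct_untreated)` and E the amplification
#' efficiency as a fraction (E = 1 means perfect doubling, so each cycle of
#' delay halves the protected fraction). Negative dCT is clamped to 100% and
#' flagged; fewer than four replicates is flagged.
#'
#' @param ct_treated CT replicates of the digested aliquot.
#' @param ct_untreated CT replicates of the mock-digested aliquot.
#' @param curve A `standard_curve`, or a bare efficiency fraction.
#' @return List with `delta_ct`, `percent` (clamped to [0, 100]), `efficiency`
#'   and `flags`.
#' @export
modification_percent <- function(ct_treated, ct_untreated, curve) {
  if (missing(curve) || is.null(curve))
    stop("an efficiency (standard curve) is required")
  eff <- if (inherits(curve, "standard_curve")) curve$efficiency else
    as.numeric(curve)
  stopifnot(is.finite(eff), eff > 0)
  if (length(ct_treated) == 0L || length(ct_untreated) == 0L)
    stop("replicate CT vectors must be non-empty")
  if (any(c(ct_treated, ct_untreated) <= 0) ||
      any(c(ct_treated, ct_untreated) >= 45))
    stop("CT values must lie in (0, 45)")
  flags <- character(0)
  if (length(ct_treated) < 4L || length(ct_untreated) < 4L)
    flags <- c(flags, "fewer_than_four_replicates")
  dct <- mean(ct_treated) - mean(ct_untreated)
  pct <- 100 / (1 + eff)^dct
  if (dct < 0) {
    flags <- c(flags, "negative_delta_ct")
    pct <- 100
  }
  pct <- min(max(pct, 0), 100)
  list(delta_ct = dct, percent = pct, efficiency = eff, flags = flags)
}

#' Known enzyme-pair assay configurations
#'
#' The three methylation-sensitive restriction assays supported: MspI/HpaII
#' (5-mC at the internal CpG of CCGG), TaqI/HpyF30I (5-mC in TCGA), and
#' T4-BGT glucosylation followed by Epi-MspI (5-hmC in CCGG). Each assay
#' reports what its enzyme pair can see; no cross-assay deconvolution of 5-mC
#' vs 5-hmC is attempted.
#'
#' @return Data frame with columns `assay`, `enzyme_pair`, `site`,
#'   `modification_reported`.
#' @export
assay_definitions <- function() {
  data.frame(
    assay = c("mC_CCGG", "mC_TCGA", "hmC_CCGG"),
    enzyme_pair = c("MspI/HpaII", "TaqI/HpyF30I", "T4-BGT+EpiMspI"),
    site = c("CCGG", "TCGA", "CCGG"),
    modification_reported = c("5mC_CpG_CCGG", "5mC_CpG_TCGA", "5hmC_CCGG"))
}

#' Read a long-format qPCR CT table
#'
#' CSV with columns `locus`, `assay`, `stage`, `replicate`, `treatment`
#' (`digested` or `mock`) and `ct`.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_qpcr_ct <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus", "assay", "stage", "replicate", "treatment", "ct")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("CT table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(d$treatment %in% c("digested", "mock")))
    stop("treatment must be 'digested' or 'mock'")
  d$ct <- as.numeric(d$ct)
  if (anyNA(d$ct) || any(d$ct <= 0) || any(d$ct >= 45))
    stop("CT values must be numeric in (0, 45)")
  d
}

#' Read qPCR standard-curve points
#'
#' CSV with columns `assay` (or `locus`), `relative_input`, `ct`.
#'
#' @param path CSV path.
#' @return Data frame of curve points.
#' @export
read_standard_curves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay", "relative_input", "ct")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("curve table lacks column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(d$relative_input > 0))
  d
}

#' Batch percent-modification report
#'
#' Computes percent modification for every (locus, assay, stage) cell of a
#' long-format CT table. Within each biological replicate, dCT is the mean
#' digested CT minus the mean mock CT; the report gives the per-cell mean and
#' standard deviation of percent across replicates (the error bars of a
#' stage-by-stage bar chart).
#'
#' @param ct Long CT table as from [read_qpcr_ct()].
#' @param curves Curve points as from [read_standard_curves()]; one curve per
#'   assay.
#' @return Data frame with one row per (locus, assay, stage): `n_replicates`,
#'   `delta_ct_mean`, `percent_mean`, `percent_sd` (NA for a single
#'   replicate), `efficiency`, `flags` (collapsed, `;`-separated).
#' @export
batch_report <- function(ct, curves) {
  if (nrow(ct) == 0L)
    return(data.frame(locus = character(0), assay = character(0),
                      stage = character(0), n_replicates = integer(0),
                      delta_ct_mean = numeric(0), percent_mean = numeric(0),
                      percent_sd = numeric(0), efficiency = numeric(0),
                      flags = character(0)))
  fitted <- lapply(split(curves, curves$assay), function(d)
    fit_standard_curve(d$relative_input, d$ct))
  cells <- split(ct, interaction(ct$locus, ct$assay, ct$stage, drop = TRUE))
  rows <- lapply(cells, function(d) {
    cv <- fitted[[d$assay[1L]]]
    if (is.null(cv)) stop("no standard curve for assay ", d$assay[1L])
    reps <- split(d, d$replicate)
    res <- lapply(reps, function(r)
      modification_percent(r$ct[r$treatment == "digested"],
                           r$ct[r$treatment == "mock"], cv))
    pct <- vapply(res, `[[`, numeric(1), "percent")
    dct <- vapply(res, `[[`, numeric(1), "delta_ct")
    ## replicate sufficiency is judged on biological replicates per cell, not
    ## on the technical CTs inside one replicate
    flg <- setdiff(unlist(lapply(res, `[[`, "flags")), "fewer_than_four_replicates")
    flg <- sort(unique(c(flg, if (length(reps) < 4L) "fewer_than_four_replicates")))
    data.frame(locus = d$locus[1L], assay = d$assay[1L], stage = d$stage[1L],
               n_replicates = length(reps),
               delta_ct_mean = mean(dct),
               percent_mean = mean(pct),
               percent_sd = if (length(pct) > 1L) stats::sd(pct) else NA_real_,
               efficiency = cv$efficiency,
               flags = paste(flg, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$locus, out$assay, out$stage), , drop = FALSE]
}
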