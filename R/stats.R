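# Quantitative qPCR readouts: delta-delta-Ct relative expression, ChIP-qPCR
# enrichment with respect to input, replicate summaries, and two-tailed
# Student's t-tests with significance flags.

.check_ct_table <- function(table) {
  miss <- setdiff(c("sample", "target", "replicate", "ct"), names(table))
  if (length(miss) > 0L)
    stopf("Ct table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(table$ct)) || any(table$ct <= 0))
    stopf("Ct values must be finite and > 0")
  invisible(table)
}

#' Replicate summary
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator); the
#' SD is NA for a single value.
#'
#' @param values numeric vector (>= 1 value).
#' @return named numeric vector c(mean, sd).
#' @export
replicate_summary <- function(values) {
  if (length(values) == 0L) stopf("no values to summarise")
  c(mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else NA_real_)
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each sample, dCt = mean Ct(target) - mean Ct(reference gene); ddCt =
#' dCt(sample) - dCt(control sample); fold = 2^(-ddCt), assuming 100%
#' amplification efficiency (two-fold per cycle). Replicate SDs are
#' combined in Ct space as sqrt(sd_target^2 + sd_reference^2) and mapped
#' through 2^(-.) at mean +/- sd; the reported fold SD is half that
#' interval. The control sample's fold is exactly 1 by construction.
#'
#' @param table Ct data.frame with columns sample, target, replicate, ct.
#' @param target target assay label.
#' @param reference_gene reference (housekeeping) gene label.
#' @param control_sample sample all folds are relative to.
#' @return data.frame: sample, target, dct, ddct, fold, sd.
#' @export
delta_delta_ct <- function(table, target, reference_gene, control_sample) {
  .check_ct_table(table)
  samples <- unique(table$sample)
  if (!control_sample %in% samples) stopf("control sample '%s' not in table",
                                          control_sample)
  stat <- function(s, g) {
    ct <- table$ct[table$sample == s & table$target == g]
    if (length(ct) == 0L)
      stopf("no Ct rows for sample '%s', target '%s'", s, g)
    replicate_summary(ct)
  }
  rows <- lapply(samples, function(s) {
    ts <- stat(s, target); rs <- stat(s, reference_gene)
    data.frame(sample = s, target = target,
               dct = ts[["mean"]] - rs[["mean"]],
               sd_ct = sqrt(ts[["sd"]]^2 + rs[["sd"]]^2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ddct <- out$dct - out$dct[out$sample == control_sample]
  out$fold <- 2^(-out$ddct)
  out$sd <- (2^(-(out$ddct - out$sd_ct)) - 2^(-(out$ddct + out$sd_ct))) / 2
  out$sd_ct <- NULL
  rownames(out) <- NULL
  out[, c("sample", "target", "dct", "ddct", "fold", "sd")]
}

#' ChIP-qPCR enrichment with respect to input
#'
#' percent_input = 100 x 2^(Ct_input - Ct_IP) x input_dilution for each
#' (antibody sample, amplicon); with mode "relative_to_h3" a mark's percent
#' input is additionally divided by the pan-H3 percent input at the same
#' amplicon.
#'
#' @param table Ct data.frame: `sample` is the antibody/IP label (including
#'   the input), `target` the amplicon.
#' @param input_label sample label of the input chromatin.
#' @param mode "percent_input" or "relative_to_h3".
#' @param h3_label sample label of the pan-H3 IP (relative_to_h3 mode).
#' @param input_dilution multiplier correcting for the input dilution
#'   factor (1 = input Cts already comparable).
#' @return data.frame: sample, target, enrichment (and percent_input in
#'   relative mode), sd (log-space propagated, NA for single replicates).
#' @export
chip_enrichment <- function(table, input_label = "input",
                            mode = c("percent_input", "relative_to_h3"),
                            h3_label = "H3", input_dilution = 1) {
  mode <- match.arg(mode)
  .check_ct_table(table)
  if (!input_label %in% table$sample) stopf("input sample '%s' missing",
                                            input_label)
  amplicons <- unique(table$target)
  ips <- setdiff(unique(table$sample), input_label)
  rows <- list()
  for (amp in amplicons) {
    inp <- table$ct[table$sample == input_label & table$target == amp]
    if (length(inp) == 0L) stopf("no input Cts for amplicon '%s'", amp)
    si <- replicate_summary(inp)
    for (ip in ips) {
      ct <- table$ct[table$sample == ip & table$target == amp]
      if (length(ct) == 0L) next
      sp <- replicate_summary(ct)
      dct <- si[["mean"]] - sp[["mean"]]
      pin <- 100 * 2^dct * input_dilution
      sdct <- sqrt(sp[["sd"]]^2 + si[["sd"]]^2)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = ip, target = amp, percent_input = pin,
        sd = 100 * input_dilution * (2^(dct + sdct) - 2^(dct - sdct)) / 2,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (mode == "percent_input") {
    names(out)[names(out) == "percent_input"] <- "enrichment"
    return(out)
  }
  if (!h3_label %in% out$sample)
    stopf("pan-H3 sample '%s' required for relative_to_h3 mode", h3_label)
  h3 <- out[out$sample == h3_label, c("target", "percent_input")]
  out$enrichment <- out$percent_input /
    h3$percent_input[match(out$target, h3$target)]
  out$sd <- out$sd / h3$percent_input[match(out$target, h3$target)]
  out[, c("sample", "target", "percent_input", "enrichment", "sd")]
}

#' Two-tailed Student's t-test with significance flags
#'
#' Classical equal-variance two-sample t-test (Welch optional) with the
#' conventional flags: "*" for p < 0.05, "**" for p < 0.01, otherwise "ns".
#' A zero pooled variance is an error rather than a silent zero.
#'
#' @param a,b numeric replicate vectors (>= 2 values each).
#' @param var_equal use the pooled-variance Student test (default TRUE).
#' @return list(t, df, p, flag).
#' @export
two_tailed_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs >= 2 replicate values")
  if (stats::var(a) + stats::var(b) == 0)
    stopf("zero pooled variance: t statistic undefined")
  ht <- stats::t.test(a, b, var.equal = var_equal,
                      alternative = "two.sided")
  p <- ht$p.value
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = p,
       flag = if (p < 0.01) "**" else if (p < 0.05) "*" else "ns")
}
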