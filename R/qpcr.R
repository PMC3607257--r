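## Delta-delta-Ct relative quantification of S-phase vs G2 DNA.

#' Relative S-phase quantity at an amplicon by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged per (amplicon, sample);
#' dCt_sample = mean Ct(target, sample) - mean Ct(calibrator, sample),
#' ddCt = dCt_S - dCt_G2, and the S-phase quantity relative to G2 = 1 is
#' 2^(-ddCt).  Amplification efficiency is fixed at 2 (no efficiency
#' correction).  Replicate dispersion is propagated to a quantity
#' interval via the standard errors of the four means.
#'
#' @param ct data.frame(amplicon, sample, ct) with sample in
#'   `S`/`G2` and at least two replicates per (amplicon, sample).
#' @param target amplicon id to quantify.
#' @param calibrator amplicon id of the control region (expected
#'   unreplicated in both samples).
#' @return list(quantity, lo, hi, ddct, degenerate); `degenerate` is TRUE
#'   when target == calibrator (quantity 1 by construction).
#' @export
ddct_quantity <- function(ct, target, calibrator) {
  pick <- function(amp, smp) {
    v <- ct$ct[ct$amplicon == amp & ct$sample == smp]
    if (length(v) == 0) stop("missing sample: ", amp, "/", smp)
    v
  }
  ts <- pick(target, "S"); tg <- pick(target, "G2")
  cs <- pick(calibrator, "S"); cg <- pick(calibrator, "G2")
  ddct <- (mean(ts) - mean(cs)) - (mean(tg) - mean(cg))
  sem2 <- function(v) if (length(v) > 1) stats::var(v) / length(v) else 0
  sd_ddct <- sqrt(sem2(ts) + sem2(cs) + sem2(tg) + sem2(cg))
  list(quantity = 2^(-ddct),
       lo = 2^(-(ddct + sd_ddct)), hi = 2^(-(ddct - sd_ddct)),
       ddct = ddct, degenerate = identical(target, calibrator))
}

#' Quantify every amplicon in a Ct table against one calibrator
#'
#' @inheritParams ddct_quantity
#' @return data.frame(amplicon, quantity, lo, hi).
#' @export
ddct_table <- function(ct, calibrator) {
  amps <- setdiff(unique(ct$amplicon), calibrator)
  out <- do.call(rbind, lapply(amps, function(a) {
    q <- ddct_quantity(ct, a, calibrator)
    data.frame(amplicon = a, quantity = q$quantity, lo = q$lo, hi = q$hi,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
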