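# Recovery-matrix fixtures encoding published per-threshold locus
# counts: every locus gets a constant recovery fraction across samples,
# with band sizes chosen so the threshold sweep reproduces the counts.

# bands: named numeric vector, representative fraction -> locus count.
recoveryFromBands <- function(bands, nSamples = 20, seed = 1) {
  set.seed(seed)
  nl <- sum(bands)
  frac <- rep(as.numeric(names(bands)), bands)
  loci <- sprintf("L%03d", seq_len(nl))
  targetLen <- sample(300:6072, nl, replace = TRUE)
  rec <- round(outer(frac, rep(1, nSamples)) * targetLen)
  rownames(rec) <- loci
  colnames(rec) <- sprintf("ind%02d", seq_len(nSamples))
  RecoveryMatrix(rec, targetLen)
}

# Family-level capture outcome: 469 targeted loci whose recovery bands
# give 468 / 466 / 449 / 331 / 98 loci at the 0/25/50/75/95% length
# thresholds, with 20 flagged loci in the 75/75 set of which 14 are
# true (split) paralogs.
familyFixture <- function(seed = 1) {
  bands <- c("0" = 1, "0.10" = 2, "0.30" = 17, "0.60" = 118,
             "0.85" = 233, "1" = 98)
  rm <- recoveryFromBands(bands, nSamples = 20, seed = seed)
  sel <- selectLoci(rm)
  flagged <- sel[seq_len(20)]
  para <- simulateParalogGeneTrees(20, sprintf("ind%02d", 1:20),
                                   splitLoci = seq_len(14),
                                   seed = seed + 1)
  names(para$trees) <- flagged
  para$truth$locus <- flagged
  list(rm = rm, flagged = flagged, trees = para$trees)
}

# Tribe-level capture outcome: 469 loci, bands giving 469 / 466 / 453 /
# 379 / 170; 24 flagged split-paralog loci of which 23 fall in the
# 75/75 set and one in a poorly recovered locus.
tribeFixture <- function(seed = 1) {
  bands <- c("0.10" = 3, "0.30" = 13, "0.60" = 74, "0.85" = 209,
             "1" = 170)
  rm <- recoveryFromBands(bands, nSamples = 20, seed = seed)
  sel <- selectLoci(rm)
  outside <- setdiff(rownames(rm), sel)
  flagged <- c(sel[seq_len(23)], outside[1])
  para <- simulateParalogGeneTrees(24, sprintf("ind%02d", 1:20),
                                   splitLoci = seq_len(24),
                                   seed = seed + 2)
  names(para$trees) <- flagged
  para$truth$locus <- flagged
  list(rm = rm, flagged = flagged, trees = para$trees)
}

# Apply the QC chain: 75/75 selection, clade-test the flagged loci,
# drop confirmed paralogs from the selected set.
paralogBookkeeping <- function(fx) {
  sel <- selectLoci(fx$rm)
  verdicts <- vapply(names(fx$trees), function(l)
    paralogCladeTest(fx$trees[[l]], locusId = l)$verdict, character(1))
  dropped <- names(verdicts)[verdicts == "drop_locus"]
  retained <- setdiff(sel, dropped)
  list(selected = sel, dropped = dropped, retained = retained,
       sweep = thresholdSweep(fx$rm))
}
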