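# 75/75 selection, sweeps, Venn logic, paralog screening, PIS,
# collapsing, concatenation, concordance, rooting.

rmFixture <- function(frac, targetLen = NULL, group = NULL) {
  # frac: loci x samples matrix of recovery fractions
  if (is.null(targetLen)) targetLen <- rep(1000, nrow(frac))
  RecoveryMatrix(round(frac * targetLen), targetLen, group = group)
}

test_that("selectLoci applies inclusive 75/75 thresholds", {
  fr <- rbind(l1 = c(1, 1, 1, 1), l2 = c(0.8, 0.8, 0.8, 0.5),
              l3 = c(0.74, 1, 1, 1), l4 = c(0, 0, 0, 0))
  x <- rmFixture(fr)
  expect_equal(selectLoci(x), c("l1", "l2", "l3"))
  # l2: exactly 3/4 samples at >= 0.75 -> inclusive pass
  # tiny thresholds keep every locus with any recovery
  expect_equal(selectLoci(x, 1e-9, 1e-9), c("l1", "l2", "l3"))
  # full stringency drops any locus with a single empty cell
  expect_equal(selectLoci(x, 1, 1), "l1")
  bad <- RecoveryMatrix(matrix(1, 1, 2, dimnames = list("z", NULL)), 0)
  expect_error(selectLoci(bad), "zero target length.*z")
})

test_that("selectLoci equals a brute-force double loop on random matrices", {
  set.seed(31)
  for (k in 1:20) {
    nl <- sample(5:15, 1); ns <- sample(4:10, 1)
    fr <- matrix(runif(nl * ns), nl, ns,
                 dimnames = list(paste0("l", 1:nl), paste0("s", 1:ns)))
    fr[sample(length(fr), nl)] <- 0
    x <- rmFixture(fr)
    lf <- runif(1, 0.3, 0.95); sf <- runif(1, 0.3, 0.95)
    want <- character(0)
    for (l in rownames(fr)) {
      nOk <- sum(fr[l, ] >= lf)
      if (nOk / ns >= sf) want <- c(want, l)
    }
    expect_equal(selectLoci(x, lf, sf), want)
  }
})

test_that("selectLoci is monotone in both thresholds", {
  set.seed(37)
  fr <- matrix(runif(200), 20, 10,
               dimnames = list(paste0("l", 1:20), paste0("s", 1:10)))
  x <- rmFixture(fr)
  grid <- seq(0.1, 0.9, by = 0.2)
  for (lf in grid) {
    for (i in seq_len(length(grid) - 1)) {
      expect_true(all(selectLoci(x, lf, grid[i + 1]) %in%
                        selectLoci(x, lf, grid[i])))
      expect_true(all(selectLoci(x, grid[i + 1], lf) %in%
                        selectLoci(x, grid[i], lf)))
    }
  }
})

test_that("threshold sweep matches per-threshold recounts and is monotone", {
  fr <- rbind(l1 = rep(1, 4), l2 = rep(0.9, 4), l3 = rep(0.6, 4),
              l4 = rep(0.3, 4), l5 = rep(0.1, 4), l6 = rep(0, 4))
  x <- rmFixture(fr)
  sw <- thresholdSweep(x)
  expect_equal(unname(sw), c(5L, 4L, 3L, 2L, 1L))
  expect_true(all(diff(sw) <= 0))
  # all-complete matrix: every threshold returns every locus
  full <- rmFixture(matrix(1, 6, 4, dimnames = list(paste0("l", 1:6), NULL)))
  expect_equal(unname(thresholdSweep(full)), rep(6L, 5))
  # random monotonicity
  set.seed(41)
  for (k in 1:10) {
    fr2 <- matrix(runif(60), 10, 6, dimnames = list(paste0("l", 1:10), NULL))
    expect_true(all(diff(thresholdSweep(rmFixture(fr2))) <= 0))
  }
})

test_that("shared-locus sets and Venn regions follow set algebra", {
  set.seed(43)
  fr <- matrix(runif(120, 0.5, 1), 20, 6,
               dimnames = list(paste0("l", 1:20), paste0("s", 1:6)))
  fr[1:5, 1:3] <- 0.1   # absent from group A
  fr[6:10, 4:6] <- 0.1  # absent from group B
  grp <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  x <- rmFixture(fr, group = unname(grp[colnames(fr)]))
  sh <- sharedLocusSets(x)
  setA <- sh$sets$A; setB <- sh$sets$B
  expect_equal(unname(sh$regions["A"]), length(setdiff(setA, setB)))
  expect_equal(unname(sh$regions["B"]), length(setdiff(setB, setA)))
  expect_equal(unname(sh$regions["A+B"]), length(intersect(setA, setB)))
  # identical groups intersect completely
  same <- rmFixture(matrix(1, 4, 4, dimnames = list(paste0("l", 1:4),
                                                    paste0("s", 1:4))),
                    group = c("X", "X", "Y", "Y"))
  sh2 <- sharedLocusSets(same)
  expect_equal(sh2$sets$X, sh2$sets$Y)
  expect_equal(unname(sh2$regions["X+Y"]), 4L)
  expect_equal(unname(sh2$regions["X"]), 0L)
  # disjoint recovery leaves an empty intersection
  disj <- rbind(l1 = c(1, 1, 0, 0), l2 = c(0, 0, 1, 1))
  x3 <- rmFixture(disj, group = c("X", "X", "Y", "Y"))
  sh3 <- sharedLocusSets(x3)
  expect_equal(unname(sh3$regions["X+Y"]), 0L)
})

test_that("three-group Venn regions equal brute-force set algebra", {
  set.seed(47)
  fr <- matrix(runif(30 * 9), 30, 9,
               dimnames = list(paste0("l", 1:30), paste0("s", 1:9)))
  grp <- setNames(rep(c("A", "B", "C"), each = 3), paste0("s", 1:9))
  x <- rmFixture(fr, group = unname(grp[colnames(fr)]))
  sh <- sharedLocusSets(x, lenFrac = 0.5, sampleFrac = 0.5)
  sets <- sh$sets
  combos <- list("A", "B", "C", c("A", "B"), c("A", "C"), c("B", "C"),
                 c("A", "B", "C"))
  for (cm in combos) {
    inside <- Reduce(intersect, sets[cm])
    outside <- unique(unlist(sets[setdiff(c("A", "B", "C"), cm)]))
    expect_equal(unname(sh$regions[paste(cm, collapse = "+")]),
                 length(setdiff(inside, outside)))
  }
})

test_that("paralog clade test keeps allelic splits and drops true paralogs", {
  keep <- ape::read.tree(text = "((X__main,X__alt),(Y__t,Z__t));")
  expect_equal(paralogCladeTest(keep)$verdict, "keep_main")
  drop <- ape::read.tree(text = "((X__main,Y__t),(X__alt,Z__t));")
  expect_equal(paralogCladeTest(drop)$verdict, "drop_locus")
  solo <- ape::read.tree(text = "((A__t,B__t),(C__t,D__t));")
  r <- paralogCladeTest(solo)
  expect_equal(r$verdict, "keep_main")
  expect_match(r$note, "no multi-copy")
})

test_that("paralog verdicts agree with bipartition enumeration on random trees", {
  set.seed(53)
  for (k in 1:20) {
    ns <- sample(5:8, 1)
    samples <- paste0("s", 1:ns)
    multi <- sample(samples, 2)
    tips <- c(paste0(multi, "__main"), paste0(multi, "__alt"),
              paste0(setdiff(samples, multi), "__t"))
    tr <- ape::rtree(length(tips))
    tr$tip.label <- sample(tips)
    got <- paralogCladeTest(tr)
    wantFlags <- vapply(multi, function(s)
      oracleFormsClade(tr, paste0(s, c("__main", "__alt"))), logical(1))
    expect_equal(unname(got$flags[multi]), unname(wantFlags))
    expect_equal(got$verdict,
                 if (all(wantFlags)) "keep_main" else "drop_locus")
  }
})

test_that("countPIS follows the informativeness rule", {
  expect_equal(countPIS(MultiAlign(c(a = "A", b = "A", c = "T", d = "T"))), 1L)
  expect_equal(countPIS(MultiAlign(c(a = "AAAA", b = "AAAA", c = "AAAA"))), 0L)
  # a singleton difference is not informative
  expect_equal(countPIS(MultiAlign(c(a = "A", b = "A", c = "A", d = "T"))), 0L)
  # gaps and N are not states
  expect_equal(countPIS(MultiAlign(c(a = "A", b = "A", c = "-", d = "-",
                                     e = "N", f = "N"))), 0L)
})

test_that("countPIS equals the brute-force scanner and ignores row order", {
  set.seed(59)
  for (k in 1:50) {
    n <- 10; w <- 100
    mm <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * w, TRUE,
                        prob = c(rep(0.22, 4), 0.06, 0.06)), n, w)
    rows <- setNames(apply(mm, 1, paste, collapse = ""), paste0("s", 1:n))
    msa <- MultiAlign(rows)
    got <- countPIS(msa)
    expect_equal(got, oraclePis(mm))
    expect_lte(got, w)
    perm <- sample(n)
    expect_equal(countPIS(MultiAlign(rows[perm])), got)
  }
})

test_that("collapseLowSupport contracts exactly the weak bipartitions", {
  tr <- ape::read.tree(text = "((a,b)5,((c,d)95,e)40,f);")
  out <- collapseLowSupport(tr, threshold = 10)
  # only the support-5 edge goes; {c,d} and {c,d,e} survive
  expect_setequal(oracleSplits(out),
                  oracleSplits(ape::read.tree(
                    text = "(a,b,((c,d)95,e)40,f);")))
  expect_false(any(vapply(list(c("a", "b")), oracleFormsClade,
                          logical(1), tree = out)))
})

test_that("collapse thresholds behave at the extremes and match supports", {
  set.seed(61)
  for (k in 1:15) {
    tr <- randomSupportTree(sample(6:12, 1))
    # threshold 0: nothing is below 0 -> identity
    expect_equal(oracleSplits(collapseLowSupport(tr, 0)), oracleSplits(tr))
    # threshold 101: every internal edge goes -> star
    star <- collapseLowSupport(tr, 101)
    expect_length(oracleSplits(star), 0)
    # general: surviving splits = splits whose support >= threshold
    thr <- sample(20:80, 1)
    out <- collapseLowSupport(tr, thr)
    sup <- as.numeric(tr$node.label)
    ntip <- length(tr$tip.label)
    wanted <- character(0)
    for (nd in seq_len(tr$Nnode)[-1]) {  # skip root
      node <- ntip + nd
      tips <- tr$tip.label[unlist(phangorn::Descendants(tr, node, "tips"))]
      if (length(tips) >= 2 && length(tips) <= ntip - 2 &&
          !is.na(sup[nd]) && sup[nd] >= thr) {
        other <- sort(setdiff(tr$tip.label, tips))
        tips <- sort(tips)
        ka <- paste(tips, collapse = "\r"); kb <- paste(other, collapse = "\r")
        wanted <- c(wanted, if (ka < kb) ka else kb)
      }
    }
    expect_setequal(oracleSplits(out), unique(wanted))
    # all supports at 100 leave the tree unchanged
    tr100 <- randomSupportTree(8, supports = rep(100, 7))
    expect_equal(oracleSplits(collapseLowSupport(tr100, 10)),
                 oracleSplits(tr100))
  }
})

test_that("concatenation gap-fills, partitions, and slices back exactly", {
  m1 <- MultiAlign(c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC"), locusId = "locB")
  m2 <- MultiAlign(c(s1 = "TTTTT", s3 = "AAAAA"), locusId = "locA")
  cc <- concatenateLoci(list(m1, m2))
  expect_equal(cc$partitions$locus, c("locA", "locB"))  # lexicographic
  expect_equal(cc$partitions$start, c(1L, 6L))
  expect_equal(cc$partitions$end, c(5L, 15L))
  sm <- alnStrings(cc$supermatrix)
  expect_equal(nchar(sm[["s2"]]), 15)
  expect_equal(substr(sm[["s2"]], 1, 5), "-----")   # s2 missing from locA
  expect_equal(substr(sm[["s3"]], 6, 15), strrep("-", 10))
  # duplicate samples within a locus are rejected at construction
  expect_error(MultiAlign(c(s1 = "AC", s1 = "GT"), locusId = "locC"),
               "unique")
})

test_that("partition slicing inverts concatenation on random locus sets", {
  set.seed(67)
  for (k in 1:20) {
    nloci <- sample(3:6, 1)
    samples <- paste0("s", 1:sample(4:8, 1))
    msas <- lapply(seq_len(nloci), function(i) {
      w <- sample(5:40, 1)
      present <- sample(samples, sample(2:length(samples), 1))
      MultiAlign(setNames(vapply(present, function(s) randomDna(w), ""),
                          present), locusId = sprintf("loc%02d", i))
    })
    cc <- concatenateLoci(msas, samples = samples)
    expect_equal(alnWidth(cc$supermatrix),
                 sum(vapply(msas, alnWidth, integer(1))))
    for (m in msas) {
      back <- slicePartition(cc$supermatrix, cc$partitions, m@locusId)
      for (s in names(alnStrings(m)))
        expect_equal(alnStrings(back)[[s]], alnStrings(m)[[s]])
      absent <- setdiff(samples, names(alnStrings(m)))
      for (s in absent)
        expect_equal(alnStrings(back)[[s]], strrep("-", alnWidth(m)))
    }
  }
})

test_that("partition file lines follow the expected format", {
  parts <- data.frame(locus = c("locA", "locB"), start = c(1L, 6L),
                      end = c(5L, 15L))
  f <- tempfile()
  writePartitions(parts, f)
  expect_equal(readLines(f), c("DNA, locA = 1-5", "DNA, locB = 6-15"))
})

test_that("branch concordance counts agreeing informative gene trees", {
  st <- ape::read.tree(text = "((a,b),(c,d),e);")
  same <- ape::read.tree(text = "((a,b),(c,d),e);")
  other <- ape::read.tree(text = "((a,c),(b,d),e);")
  bc <- branchConcordance(st, list(same, same, other))
  ab <- bc[bc$split %in% c("a,b", "c,d,e"), ]
  expect_equal(ab$concordance[1], 2 / 3)
  # all gene trees identical -> every branch fully concordant
  bc2 <- branchConcordance(st, list(same, same))
  expect_true(all(bc2$concordance == 1))
  # a gene tree missing one full side is excluded from the denominator
  partial <- ape::read.tree(text = "((a,b),(c,e));")  # one tip of {c,d}
  bc3 <- branchConcordance(st, list(same, partial))
  cd <- bc3[bc3$split %in% c("c,d", "a,b,e"), ]
  expect_equal(cd$n_informative[1], 1L)
})

test_that("outgroup rooting requires a monophyletic outgroup", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  r1 <- rootAtOutgroup(tr, "a")
  expect_true(ape::is.rooted(r1))
  expect_true(ape::is.monophyletic(r1, c("b", "c", "d")))
  r2 <- rootAtOutgroup(tr, c("c", "d"))
  expect_true(ape::is.monophyletic(r2, c("a", "b")))
  expect_true(ape::is.monophyletic(r2, c("c", "d")))
  expect_error(rootAtOutgroup(tr, c("a", "c")), "not monophyletic")
})

test_that("recovery matrix TSV dialect round-trips, HybPiper layout imports", {
  fr <- matrix(round(runif(12, 100, 900)), 3, 4,
               dimnames = list(paste0("l", 1:3), paste0("s", 1:4)))
  x <- RecoveryMatrix(fr, c(1000, 900, 800))
  f <- tempfile(fileext = ".tsv")
  writeRecoveryMatrix(x, f)
  head1 <- readLines(f, n = 2)
  expect_match(head1[1], "^sample\tl1\tl2\tl3$")
  expect_match(head1[2], "^TARGET_LEN\t")
  back <- readRecoveryMatrix(f)
  expect_equal(recoveredLen(back), recoveredLen(x))
  expect_equal(unname(targetLen(back)), unname(targetLen(x)))
  # HybPiper-style: loci as columns, MeanLength row, external targets
  hp <- tempfile(fileext = ".tsv")
  writeLines(c("Species\tl1\tl2", "MeanLength\t500\t400",
               "sampA\t450\t300", "sampB\t100\t0"), hp)
  y <- readRecoveryMatrix(hp, dialect = "hybpiper",
                          targetLen = c(l1 = 500, l2 = 420))
  expect_equal(dim(y), c(2L, 2L))
  expect_equal(unname(targetLen(y)), c(500, 420))
  expect_equal(recoveredLen(y)["l2", "sampA"], 300)
})
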