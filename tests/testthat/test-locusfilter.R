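# Progressive alignment, trimming, exhaustive parsimony, congruence,
# and the selection filters.

test_that("progressive alignment handles identical, gapped and clean cases", {
  p <- randomProtein(40)
  a <- progressiveAlign(c(x = p, y = p))
  expect_equal(unname(alnStrings(a)), c(p, p))  # gap-free
  b <- progressiveAlign(c(x = "MKVL", y = "MKL"))
  m <- alnMatrix(b)
  expect_equal(ncol(m), 4)
  expect_equal(sum(m == "-"), 1)
  # columns where both rows have residues must hold 3 matches
  both <- m[, m[1, ] != "-" & m[2, ] != "-", drop = FALSE]
  expect_equal(sum(both[1, ] == both[2, ]), 3)
  expect_error(progressiveAlign(c(x = "MKVL")), ">= 2")
})

test_that("substitution-only divergence yields a gap-free alignment", {
  set.seed(13)
  anc <- randomProtein(60)
  seqs <- vapply(1:5, function(i) {
    v <- strsplit(anc, "")[[1]]
    at <- sample(60, 4)
    v[at] <- vapply(v[at], function(x) setdiff(AA20, x)[1], "")
    paste(v, collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:5)
  a <- progressiveAlign(seqs)
  expect_equal(alnWidth(a), 60)
  expect_false(any(alnMatrix(a) == "-"))
})

test_that("trimGappy keeps exactly the columns at or below the gap cap", {
  rows <- c(a = "AC-GT-", b = "AC-GTT", c = "A--GTT", d = "ACCG--",
            e = "AC-G--")
  msa <- fixtureMsa(rows)
  tr <- trimGappy(msa, 0.5)
  mm <- do.call(rbind, strsplit(unname(rows), ""))
  keepOracle <- which(colMeans(mm == "-") <= 0.5)
  expect_equal(tr$colMap, keepOracle)
  expect_equal(alnWidth(tr$msa), length(keepOracle))
  # idempotence
  tr2 <- trimGappy(tr$msa, 0.5)
  expect_equal(alnStrings(tr2$msa), alnStrings(tr$msa))
  # gap-free input unchanged
  clean <- fixtureMsa(c(a = "ACGT", b = "ACGT"))
  expect_equal(alnStrings(trimGappy(clean, 0.5)$msa), alnStrings(clean))
})

test_that("trimGappy matches a brute-force column scan on random MSAs", {
  set.seed(17)
  for (k in 1:20) {
    n <- sample(4:8, 1); w <- sample(10:30, 1)
    mm <- matrix(sample(c("A", "C", "G", "T", "-"), n * w, TRUE,
                        prob = c(rep(0.2, 4), 0.2)), n, w)
    rows <- setNames(apply(mm, 1, paste, collapse = ""), paste0("s", 1:n))
    frac <- runif(1, 0.2, 0.8)
    got <- trimGappy(fixtureMsa(rows), frac)
    expect_equal(got$colMap, which(colMeans(mm == "-") <= frac))
  }
})

test_that("a 3-taxon alignment has a single topology", {
  msa <- fixtureMsa(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  r <- inferTopology(msa)
  expect_equal(r$nEvaluated, 1)
  expect_length(r$trees, 1)
})

test_that("high-signal simulation recovers the generating topology uniquely", {
  set.seed(19)
  # sequences supporting ((a,b),(c,d),e): shared blocks of derived states
  n <- 120
  base <- randomDna(n)
  mut <- function(s, at) {
    v <- strsplit(s, "")[[1]]
    v[at] <- vapply(v[at], function(x) setdiff(c("A","C","G","T"), x)[1], "")
    paste(v, collapse = "")
  }
  ab <- mut(base, 1:25); cd <- mut(base, 40:65)
  rows <- c(a = mut(ab, 90:95), b = mut(ab, 100:105),
            c = mut(cd, 70:75), d = mut(cd, 80:85), e = base)
  r <- inferTopology(fixtureMsa(rows))
  expect_equal(r$nEvaluated, 15)
  expect_length(r$trees, 1)
  want <- ape::read.tree(text = "((a,b),(c,d),e);")
  expect_equal(phangorn::RF.dist(r$trees[[1]], want), 0)
})

test_that("all-identical sequences leave every topology co-optimal", {
  rows <- setNames(rep("ACGTACGT", 5), letters[1:5])
  r <- inferTopology(fixtureMsa(rows))
  expect_equal(length(r$trees), 15)
  expect_equal(r$score, 0)
})

test_that("Fitch scores equal phangorn's parsimony over all topologies", {
  set.seed(23)
  for (k in 1:100) {
    ntaxa <- sample(4:5, 1)
    w <- sample(20:60, 1)
    mm <- matrix(sample(c("A", "C", "G", "T"), ntaxa * w, TRUE), ntaxa, w)
    rows <- setNames(apply(mm, 1, paste, collapse = ""),
                     letters[seq_len(ntaxa)])
    msa <- fixtureMsa(rows)
    topos <- enumerateTopologies(letters[seq_len(ntaxa)])
    mine <- vapply(topos, function(tr) fitchScore(msa, tr), numeric(1))
    pd <- phangorn::phyDat(mm, type = "DNA")
    names(pd) <- letters[seq_len(ntaxa)]
    theirs <- vapply(topos, function(tr) phangorn::parsimony(tr, pd),
                     numeric(1))
    expect_equal(mine, theirs)
    r <- inferTopology(msa)
    expect_equal(r$score, min(theirs))
  }
})

test_that("topology enumeration matches phangorn's census", {
  for (n in 4:6) {
    mine <- enumerateTopologies(letters[1:n])
    theirs <- phangorn::allTrees(n, rooted = FALSE,
                                 tip.label = letters[1:n])
    expect_equal(length(mine), length(theirs))
    d <- outer(seq_along(mine), seq_along(theirs),
               Vectorize(function(i, j) phangorn::RF.dist(mine[[i]],
                                                          theirs[[j]])))
    expect_true(all(apply(d == 0, 1, any)))  # every enumerated tree found
    expect_equal(sum(d == 0), length(mine))  # bijection
  }
})

test_that("congruence accepts the published topology and rejects rearrangements", {
  ref <- ape::read.tree(
    text = "((Mkilua,(Monodora,Monanthotaxis)),(Marsypopetalum,Sapranthus));")
  same <- ape::read.tree(
    text = "((Monodora,Monanthotaxis),Mkilua,(Marsypopetalum,Sapranthus));")
  expect_true(isCongruent(same, ref, taxa = ref$tip.label))
  other <- ape::read.tree(
    text = "((Mkilua,Monodora),(Monanthotaxis,(Marsypopetalum,Sapranthus)));")
  expect_false(isCongruent(other, ref, taxa = ref$tip.label))
  # RF oracle via explicit bipartition sets
  expect_false(identical(oracleSplits(ape::unroot(other)),
                         oracleSplits(ape::unroot(ref))))
  # any 3-taxon restriction is congruent
  tri <- ape::read.tree(text = "(Mkilua,Monodora,Sapranthus);")
  expect_true(isCongruent(tri, ref, taxa = tri$tip.label))
  expect_error(isCongruent(same, ref, taxa = c("Mkilua", "nope")),
               "missing")
})

test_that("closest/furthest pairs follow nodal distances on the reference", {
  ref <- ape::read.tree(
    text = "((Mkilua,(Monodora,Monanthotaxis)),(Marsypopetalum,Sapranthus));")
  cf <- closestFurthestPairs(ref$tip.label, ref)
  expect_setequal(vapply(cf$closest, paste, "", collapse = "|"),
                  c("Monanthotaxis|Monodora", "Marsypopetalum|Sapranthus"))
  furthest <- vapply(cf$furthest, paste, "", collapse = "|")
  expect_setequal(furthest,
                  c("Marsypopetalum|Monodora", "Monodora|Sapranthus",
                    "Marsypopetalum|Monanthotaxis",
                    "Monanthotaxis|Sapranthus"))
  # a 3-taxon star: every pair ties as closest and furthest
  star <- ape::read.tree(text = "(a,b,c);")
  cf2 <- closestFurthestPairs(c("a", "b", "c"), star)
  expect_equal(length(cf2$closest), 3)
  expect_equal(length(cf2$furthest), 3)
})

makeGroup <- function(pid, cutoff = 95) {
  methods::new("OrthoGroup", groupId = "sp1|p1",
               members = setNames(paste0("p", 1:5),
                                  c("Mkilua", "Monodora", "Monanthotaxis",
                                    "Marsypopetalum", "Sapranthus")),
               cutoff = cutoff, focal = "Monodora", pairIdentities = pid)
}

refTree <- ape::read.tree(
  text = "((Mkilua,(Monodora,Monanthotaxis)),(Marsypopetalum,Sapranthus));")

uniformPid <- function(value) {
  sps <- sort(c("Mkilua", "Monodora", "Monanthotaxis", "Marsypopetalum",
                "Sapranthus"))
  prs <- utils::combn(sps, 2)
  setNames(rep(value, ncol(prs)),
           apply(prs, 2, function(p) paste(p, collapse = "|")))
}

test_that("selection filters fire on the documented rules", {
  lens <- setNames(rep(400, 5), names(makeGroup(uniformPid(80))@members))
  # rule i: identity above the clustering cutoff
  g <- makeGroup(uniformPid(99.5), cutoff = 99)
  r <- applySelectionFilters(g, lens, filterParams(), refTree)
  expect_equal(filterVerdict(r), "fail")
  expect_equal(filterRules(r)$outcome[filterRules(r)$rule ==
                                        "divergence_below_cutoff"], "fail")
  # rule ii: (320-300)/320 = 0.0625 > 0.05
  g2 <- makeGroup(uniformPid(80))
  lens2 <- lens; lens2[] <- c(300, 320, 310, 305, 315)
  r2 <- applySelectionFilters(g2, lens2, filterParams(), refTree)
  expect_equal(filterRules(r2)$outcome[filterRules(r2)$rule ==
                                         "length_variation"], "fail")
  # boundary: exactly 300 bp passes the length floor
  lens3 <- lens; lens3[] <- 300
  r3 <- applySelectionFilters(g2, lens3, filterParams(), refTree)
  expect_equal(filterRules(r3)$outcome[filterRules(r3)$rule ==
                                         "min_length"], "pass")
  # a clean pass: closest 78, furthest 72, modest variance
  pid <- uniformPid(72)
  pid["Monanthotaxis|Monodora"] <- 78
  pid["Marsypopetalum|Sapranthus"] <- 78
  g4 <- makeGroup(pid)
  lens4 <- lens; lens4[] <- c(400, 410, 405, 402, 408)
  r4 <- applySelectionFilters(g4, lens4, filterParams(), refTree)
  expect_equal(filterVerdict(r4), "pass")
  # long sequences tighten the closest-pair rule
  lens5 <- lens; lens5[] <- 1600
  r5 <- applySelectionFilters(g4, lens5, filterParams(), refTree)
  expect_equal(filterRules(r5)$outcome[filterRules(r5)$rule ==
                                         "long_seq_closest_identity"], "fail")
})

test_that("relaxing any single threshold never turns a pass into a fail", {
  set.seed(29)
  sps <- c("Mkilua", "Monodora", "Monanthotaxis", "Marsypopetalum",
           "Sapranthus")
  for (k in 1:30) {
    pid <- uniformPid(runif(1, 60, 95))
    pid <- pid + runif(length(pid), -5, 5)
    g <- makeGroup(pid, cutoff = sample(c(90, 95, 97, 99), 1))
    lens <- setNames(round(runif(5, 290, 1700)), sps)
    base <- filterParams()
    r0 <- filterVerdict(applySelectionFilters(g, lens, base, refTree))
    relaxed <- list(
      filterParams(minLenNt = 200), filterParams(maxLenVar = 0.2),
      filterParams(closestMin = 50), filterParams(furthestMin = 40),
      filterParams(longLenNt = 5000), filterParams(longClosestMin = 50),
      filterParams(maxIdentityVariance = 1000))
    for (p in relaxed) {
      r1 <- filterVerdict(applySelectionFilters(g, lens, p, refTree))
      expect_false(r0 == "pass" && r1 == "fail")
    }
  }
})

test_that("filter reports export as a rule-per-row TSV", {
  g <- makeGroup(uniformPid(80))
  lens <- setNames(rep(400, 5), names(g@members))
  r <- applySelectionFilters(g, lens, filterParams(), refTree)
  f <- tempfile(fileext = ".tsv")
  writeFilterReports(list(r), f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), nrow(filterRules(r)))
  expect_setequal(colnames(tab),
                  c("group", "rule", "observed", "threshold", "outcome",
                    "verdict"))
})
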