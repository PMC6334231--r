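# Synthetic multi-species transcriptomes with ground truth. The
# generator produces exactly the structure the design arm assumes:
# single-copy orthologous CDS evolved on a known topology, within-
# species duplicate families, splice-isoform redundancy, UTR-flanked
# ORFs, and clade-level substitution-rate heterogeneity; plus the
# capture-recovery and paralog-gene-tree simulators the QC arm needs.

#' Default 5-taxon reference topology
#'
#' The two-subfamily, five-species layout used to design the kit:
#' `((Mkilua,(Monodora,Monanthotaxis)),(Marsypopetalum,Sapranthus))`,
#' with branch lengths in expected nucleotide substitutions per site.
#'
#' @param terminal,internal branch lengths (defaults 0.02 / 0.015).
#' @return a rooted [ape::phylo] with branch lengths.
#' @export
defaultReferenceTopology <- function(terminal = 0.02, internal = 0.015) {
  txt <- sprintf(
    "((Mkilua:%1$f,(Monodora:%1$f,Monanthotaxis:%1$f):%2$f):%2$f,(Marsypopetalum:%1$f,Sapranthus:%1$f):%2$f);",
    terminal, internal)
  ape::read.tree(text = txt)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the toolkit is exercised under:
#' the printed five-taxon topology, one accelerated subfamily-analog
#' clade (rate multiplier 2, mirroring the long-branch/short-branch
#' subfamily contrast), gene lengths of 100-700 codons (covering the
#' 300 bp lower bound and the multi-kb upper range of real targets),
#' a 10% per-gene chance of a within-species duplicate and of a
#' splice isoform, and UTRs of 30-150 bp.
#'
#' @param topology reference topology with branch lengths.
#' @param cladeRateMultiplier rate multiplier applied to every branch
#'   inside (and including the stem of) `acceleratedClade`.
#' @param acceleratedClade tip labels of the accelerated clade.
#' @param nGenes number of ancestral genes.
#' @param geneLenCodons length-2 range of gene lengths in codons
#'   (ATG and stop excluded).
#' @param substRate scaling factor on all branch lengths.
#' @param indelRate expected codon-indel events per codon per branch.
#' @param duplicationProb per-gene probability of a within-species
#'   duplicate copy.
#' @param duplicateDivergence extra substitutions/site on the duplicate.
#' @param isoformProb per-gene probability of an internally deleted
#'   second transcript.
#' @param utrLen length-2 range of UTR lengths (bp, each end).
#' @param seed integer seed; identical seed + config give byte-identical
#'   output.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(topology = defaultReferenceTopology(),
                      cladeRateMultiplier = 2,
                      acceleratedClade = c("Mkilua", "Monodora",
                                           "Monanthotaxis"),
                      nGenes = 200, geneLenCodons = c(100, 700),
                      substRate = 1, indelRate = 0.002,
                      duplicationProb = 0.1, duplicateDivergence = 0.25,
                      isoformProb = 0.1, utrLen = c(30, 150),
                      seed = 1L) {
  stopifnot(length(geneLenCodons) == 2L, length(utrLen) == 2L,
            duplicationProb >= 0, duplicationProb <= 1,
            isoformProb >= 0, isoformProb <= 1, substRate >= 0)
  structure(list(topology = topology,
                 cladeRateMultiplier = cladeRateMultiplier,
                 acceleratedClade = acceleratedClade, nGenes = nGenes,
                 geneLenCodons = geneLenCodons, substRate = substRate,
                 indelRate = indelRate, duplicationProb = duplicationProb,
                 duplicateDivergence = duplicateDivergence,
                 isoformProb = isoformProb, utrLen = utrLen,
                 seed = as.integer(seed)),
            class = "simConfig")
}

.STOPS <- c("TAA", "TAG", "TGA")
.NT <- c("A", "C", "G", "T")

#' @noRd
.randomSenseCodons <- function(n) {
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- paste0(sample(.NT, length(need), replace = TRUE),
                   sample(.NT, length(need), replace = TRUE),
                   sample(.NT, length(need), replace = TRUE))
    ok <- !(cand %in% .STOPS)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

# Mutate a codon vector at per-site probability p, rejecting mutations
# that create stop codons (codon reverted), so the ORF stays open.
#' @noRd
.evolveCodons <- function(codons, p) {
  nt <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(nt)) < p)
  if (length(hit)) {
    for (i in hit) nt[i] <- sample(setdiff(.NT, nt[i]), 1L)
  }
  out <- paste0(nt[c(TRUE, FALSE, FALSE)], nt[c(FALSE, TRUE, FALSE)],
                nt[c(FALSE, FALSE, TRUE)])
  bad <- out %in% .STOPS
  out[bad] <- codons[bad]
  out
}

# Codon-length indels (1-3 codons), insertions of random sense codons,
# deletions of an internal block; count ~ Poisson(rate * length).
#' @noRd
.applyIndels <- function(codons, rate) {
  nEvents <- rpois(1L, rate * length(codons))
  for (k in seq_len(nEvents)) {
    size <- sample(1:3, 1L)
    if (runif(1) < 0.5 && length(codons) > size + 2L) {
      at <- sample(length(codons) - size, 1L)
      codons <- codons[-(at:(at + size - 1L))]
    } else {
      at <- sample(length(codons), 1L)
      codons <- append(codons, .randomSenseCodons(size), after = at)
    }
  }
  codons
}

#' @noRd
.branchRates <- function(tree, clade, mult) {
  inClade <- integer(0)
  if (length(clade) && all(clade %in% tree$tip.label)) {
    mrca <- ape::getMRCA(tree, clade)
    desc <- .descendantNodes(tree, mrca)
    inClade <- which(tree$edge[, 2L] %in% c(mrca, desc))
  }
  r <- rep(1, nrow(tree$edge))
  r[inClade] <- mult
  r
}

#' @noRd
.descendantNodes <- function(tree, node) {
  out <- integer(0)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  for (k in kids) out <- c(out, k, .descendantNodes(tree, k))
  out
}

#' Simulate multi-species transcriptomes with ground truth
#'
#' Per gene: an ancestral open CDS (ATG ... stop, no internal stops) is
#' evolved along the topology under a single-parameter nucleotide model
#' with per-branch rate x clade multiplier and rare codon-preserving
#' indels; with the configured probabilities a within-species duplicate
#' (extra divergence, same species) and an internally deleted isoform
#' are emitted as additional transcripts; every transcript gains random
#' UTRs at both ends.
#'
#' @param config a [simConfig()].
#' @return list with `transcripts` (named list species ->
#'   [Biostrings::DNAStringSet]), `truth` (data.frame: gene, species,
#'   transcript_id, role in main/duplicate/isoform, cds_len), and
#'   `geneTrees` (per-gene [ape::phylo] with the branch lengths
#'   actually applied).
#' @export
simulateTranscriptomes <- function(config = simConfig()) {
  set.seed(config$seed)
  tree <- ape::reorder.phylo(config$topology, "cladewise")
  rates <- .branchRates(tree, config$acceleratedClade,
                        config$cladeRateMultiplier)
  bl <- tree$edge.length * config$substRate * rates
  species <- tree$tip.label
  ntip <- length(species)
  root <- ntip + 1L

  tx <- setNames(lapply(species, function(s) list()), species)
  truthRows <- list()
  geneTrees <- vector("list", config$nGenes)
  scaled <- tree; scaled$edge.length <- bl

  addTranscript <- function(sp, gene, role, copy, codons, cfg) {
    utr5 <- paste(sample(.NT, sample(cfg$utrLen[1]:cfg$utrLen[2], 1L),
                         replace = TRUE), collapse = "")
    utr3 <- paste(sample(.NT, sample(cfg$utrLen[1]:cfg$utrLen[2], 1L),
                         replace = TRUE), collapse = "")
    id <- sprintf("%s_g%03d_%s", sp, gene, copy)
    seq <- paste0(utr5, "ATG", paste(codons, collapse = ""),
                  sample(.STOPS, 1L), utr3)
    tx[[sp]][[id]] <<- seq
    truthRows[[length(truthRows) + 1L]] <<- data.frame(
      gene = sprintf("g%03d", gene), species = sp, transcript_id = id,
      role = role, cds_len = 3L * (length(codons) + 2L),
      stringsAsFactors = FALSE)
  }

  for (g in seq_len(config$nGenes)) {
    ncod <- sample(config$geneLenCodons[1]:config$geneLenCodons[2], 1L)
    nodeSeq <- vector("list", ntip + tree$Nnode)
    nodeSeq[[root]] <- .randomSenseCodons(ncod)
    for (e in seq_len(nrow(tree$edge))) {    # cladewise: parents first
      par <- tree$edge[e, 1L]; chl <- tree$edge[e, 2L]
      s <- .evolveCodons(nodeSeq[[par]], bl[e])
      s <- .applyIndels(s, config$indelRate)
      nodeSeq[[chl]] <- s
    }
    dupSp <- if (runif(1) < config$duplicationProb) sample(species, 1L)
             else NA_character_
    isoSp <- if (runif(1) < config$isoformProb) sample(species, 1L)
             else NA_character_
    for (i in seq_len(ntip)) {
      sp <- species[i]
      addTranscript(sp, g, "main", "t1", nodeSeq[[i]], config)
      if (identical(sp, dupSp)) {
        dup <- .evolveCodons(nodeSeq[[i]], config$duplicateDivergence)
        addTranscript(sp, g, "duplicate", "t2dup", dup, config)
      }
      if (identical(sp, isoSp) && length(nodeSeq[[i]]) >= 30L) {
        n <- length(nodeSeq[[i]])
        cut <- sample(floor(n * 0.1):floor(n * 0.3), 1L)
        at <- sample(n - cut - 1L, 1L) + 1L
        iso <- nodeSeq[[i]][-(at:(at + cut - 1L))]
        addTranscript(sp, g, "isoform", "t3iso", iso, config)
      }
    }
    geneTrees[[g]] <- scaled
  }
  names(geneTrees) <- sprintf("g%03d", seq_len(config$nGenes))
  transcripts <- lapply(tx, function(x)
    Biostrings::DNAStringSet(unlist(x)))
  list(transcripts = transcripts,
       truth = do.call(rbind, truthRows),
       geneTrees = geneTrees)
}

#' Simulate a capture recovery matrix
#'
#' Each cell's recovered length is the locus target length times a Beta
#' draw centred on `meanFrac` (degraded samples use `degradedMeanFrac`),
#' zeroed with probability `dropoutProb`. `concentration = Inf` (or
#' `meanFrac = 1`) gives spread-free draws.
#'
#' @param loci locus ids (or a number of loci).
#' @param samples sample ids (or a number of samples).
#' @param meanFrac mean recovered fraction (default 0.85).
#' @param dropoutProb per-cell probability of total dropout
#'   (default 0.05).
#' @param degradedSamples sample ids with degraded input (herbarium-like
#'   material); they draw from `degradedMeanFrac`.
#' @param degradedMeanFrac mean recovered fraction for degraded samples
#'   (default 0.5).
#' @param concentration Beta concentration parameter (default 25);
#'   larger is tighter around the mean.
#' @param targetLen per-locus target lengths; default uniform integers
#'   on 300-6072 bp (the span real kits target).
#' @param group optional sample group labels.
#' @param seed integer seed.
#' @return a [RecoveryMatrix-class].
#' @export
simulateRecovery <- function(loci, samples, meanFrac = 0.85,
                             dropoutProb = 0.05,
                             degradedSamples = character(0),
                             degradedMeanFrac = 0.5, concentration = 25,
                             targetLen = NULL, group = NULL, seed = 1L) {
  if (length(loci) == 1L && is.numeric(loci))
    loci <- sprintf("locus%04d", seq_len(loci))
  if (length(samples) == 1L && is.numeric(samples))
    samples <- sprintf("sample%02d", seq_len(samples))
  stopifnot(meanFrac >= 0, meanFrac <= 1, dropoutProb >= 0,
            dropoutProb <= 1)
  set.seed(seed)
  if (is.null(targetLen))
    targetLen <- sample(300:6072, length(loci), replace = TRUE)
  nl <- length(loci); ns <- length(samples)
  drawFrac <- function(m, n) {
    if (m >= 1 || m <= 0 || !is.finite(concentration)) rep(m, n)
    else rbeta(n, m * concentration, (1 - m) * concentration)
  }
  fr <- matrix(0, nl, ns, dimnames = list(loci, samples))
  for (j in seq_len(ns)) {
    m <- if (samples[j] %in% degradedSamples) degradedMeanFrac else meanFrac
    fr[, j] <- drawFrac(m, nl)
  }
  fr[matrix(runif(nl * ns) < dropoutProb, nl, ns)] <- 0
  rec <- round(fr * targetLen)
  RecoveryMatrix(rec, targetLen, group = group)
}

#' Simulate gene trees with planted paralog structure
#'
#' For QC-stage testing: each locus gets a gene tree over the samples;
#' `multiCopySamples` carry a `__main` and an `__alt` tip. In "split"
#' loci the main copies and the alt copies form two separate clades
#' (an ancient duplication — a true paralog, which the clade test must
#' drop); otherwise each sample's two copies are sisters (allelic —
#' kept).
#'
#' @param nLoci number of loci.
#' @param samples sample ids.
#' @param splitLoci indices (or logical vector) of loci simulated as
#'   true paralogs.
#' @param nMultiCopy number of multi-copy samples per locus (default 3).
#' @param seed integer seed.
#' @return list with `trees` (named list of [ape::phylo]) and `truth`
#'   (data.frame `locus`, `is_split`).
#' @export
simulateParalogGeneTrees <- function(nLoci, samples, splitLoci = integer(0),
                                     nMultiCopy = 3, seed = 1L) {
  set.seed(seed)
  if (is.logical(splitLoci)) splitLoci <- which(splitLoci)
  nMultiCopy <- min(nMultiCopy, length(samples))
  trees <- list()
  truth <- data.frame(locus = sprintf("locus%04d", seq_len(nLoci)),
                      is_split = seq_len(nLoci) %in% splitLoci,
                      stringsAsFactors = FALSE)
  for (k in seq_len(nLoci)) {
    multi <- sample(samples, nMultiCopy)
    single <- setdiff(samples, multi)
    if (truth$is_split[k]) {
      mainClade <- .randomCladeNewick(c(paste0(multi, "__main"), single))
      altClade <- .randomCladeNewick(paste0(multi, "__alt"))
      txt <- sprintf("(%s,%s);", mainClade, altClade)
    } else {
      tips <- c(lapply(multi, function(s)
        sprintf("(%s__main,%s__alt)", s, s)), as.list(single))
      ord <- sample(length(tips))
      txt <- sprintf("(%s);", paste(unlist(tips)[ord], collapse = ","))
    }
    trees[[truth$locus[k]]] <- ape::read.tree(text = txt)
  }
  list(trees = trees, truth = truth)
}

#' @noRd
.randomCladeNewick <- function(tips) {
  tips <- sample(tips)
  if (length(tips) == 1L) return(tips)
  while (length(tips) > 1L) {
    tips <- c(sprintf("(%s,%s)", tips[1], tips[2]), tips[-(1:2)])
  }
  tips[1L]
}

#' Score ortholog groups against the simulation truth table
#'
#' Maps every group member back to its source transcript (protein ids
#' are `<transcript>|orfK`) and gene, then reports per-group purity and
#' the headline recovery metrics: recall on single-copy genes (genes
#' with no duplicate copy anywhere), the number of mixed groups
#' (members from more than one true gene), and the number of groups
#' containing a duplicate-family transcript.
#'
#' @param groups list of [OrthoGroup-class] objects.
#' @param truth the `truth` data.frame from [simulateTranscriptomes()].
#' @return list with `perGroup` (data.frame: group, n_species, genes,
#'   pure, has_duplicate), `recallSingleCopy`, `nSingleCopy`,
#'   `nMixed`, `nWithDuplicate`.
#' @export
orthologGroupTruth <- function(groups, truth) {
  tx2gene <- setNames(truth$gene, truth$transcript_id)
  tx2role <- setNames(truth$role, truth$transcript_id)
  dupGenes <- unique(truth$gene[truth$role == "duplicate"])
  singleCopy <- setdiff(unique(truth$gene), dupGenes)

  perGroup <- do.call(rbind, lapply(groups, function(g) {
    tx <- sub("\\|orf[0-9]+$", "", unname(groupMembers(g)))
    genes <- unique(unname(tx2gene[tx]))
    data.frame(group = groupId(g), n_species = length(groupMembers(g)),
               genes = paste(genes, collapse = ","),
               pure = length(genes) == 1L && !anyNA(genes),
               has_duplicate = any(tx2role[tx] == "duplicate",
                                   na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  recovered <- unique(unlist(lapply(groups, function(g) {
    tx <- sub("\\|orf[0-9]+$", "", unname(groupMembers(g)))
    genes <- unique(unname(tx2gene[tx]))
    if (length(genes) == 1L && !anyNA(genes)) genes else character(0)
  })))
  list(perGroup = perGroup,
       recallSingleCopy = mean(singleCopy %in% recovered),
       nSingleCopy = length(singleCopy),
       nMixed = sum(!perGroup$pure),
       nWithDuplicate = sum(perGroup$has_duplicate))
}
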