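# Seeded generators: gene orders with known rearrangement truth,
# coding sequences diverged under a GY94-style codon model with known
# omega/kappa, and full annotated genome pairs for end-to-end tests.

#' Canonical metazoan mitochondrial gene inventory
#'
#' 13 protein-coding genes, 22 tRNAs, 2 rRNAs and the control region.
#' @return character vector of 38 labels.
#' @export
canonicalGeneInventory <- function() {
  pcg <- c("COX1", "COX2", "COX3", "ATP6", "ATP8", "CYTB",
           paste0("ND", 1:6), "ND4L")
  trna <- c("trnA-TGC", "trnC-GCA", "trnD-GTC", "trnE-TTC", "trnF-GAA",
            "trnG-TCC", "trnH-GTG", "trnI-GAT", "trnK-TTT", "trnL-TAA",
            "trnL-TAG", "trnM-CAT", "trnN-GTT", "trnP-TGG", "trnQ-TTG",
            "trnR-TCG", "trnS-TCT", "trnS-TGA", "trnT-TGT", "trnV-TAC",
            "trnW-TCA", "trnY-GTA")
  c(pcg, "rrnL", "rrnS", trna, "D-loop")
}

#' Parameters of the codon substitution model
#'
#' @param omega dN/dS ratio (>= 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param t expected substitutions per codon separating the two
#'   descendants (>= 0); each descendant evolves t/2 from the ancestor.
#' @param codonFreqs named 64-vector of equilibrium codon frequencies
#'   (stops must be 0); defaults to uniform over sense codons.
#' @param code a [GeneticCode-class].
#' @return validated parameter list of class "EvolutionParams".
#' @export
evolutionParams <- function(omega = 0.2, kappa = 2, t = 0.3,
                            codonFreqs = NULL, code = geneticCode(5L)) {
  if (!is.finite(omega) || omega < 0) stop("omega must be >= 0")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.finite(t) || t < 0) stop("t must be >= 0")
  if (is.null(codonFreqs)) codonFreqs <- .uniformFreqs(code)
  if (length(codonFreqs) != 64L || is.null(names(codonFreqs)))
    stop("codonFreqs must be a named 64-vector")
  codonFreqs <- codonFreqs[.CODONS]
  if (any(codonFreqs[stopCodons(code)] != 0))
    stop("stop codon frequencies must be exactly 0")
  if (abs(sum(codonFreqs) - 1) > 1e-8) codonFreqs <- codonFreqs / sum(codonFreqs)
  structure(list(omega = omega, kappa = kappa, t = t,
                 codonFreqs = codonFreqs, code = code),
            class = "EvolutionParams")
}

#' Published venerid mitochondrial codon-usage profile
#'
#' Per-codon counts over the protein-coding genes of a venerid clam
#' mitogenome (shipped as plain text in `extdata`), used as the default
#' codon-frequency target of the synthetic generators.
#'
#' @param species which genome's counts to return.
#' @return named numeric vector of codon counts (RNA-alphabet names
#'   converted to DNA).
#' @export
veneridCodonProfile <- function(species = c("Rphilippinarum", "Rvariegatus")) {
  species <- match.arg(species)
  tab <- utils::read.delim(system.file("extdata", "codon_counts_venerids.tsv",
                                       package = "mitocompare"))
  stats::setNames(tab[[paste0("count_", species)]],
                  chartr("U", "T", tab$codon))
}

#' F3x4 codon frequencies fitted to a codon count vector
#'
#' Position-specific nucleotide frequencies of the counted codons,
#' multiplied out per codon with stops zeroed and renormalized.
#' @param counts named codon counts (e.g. a published codon table).
#' @param code a [GeneticCode-class].
#' @return named 64-vector summing to 1.
#' @export
f3x4FromCounts <- function(counts, code = geneticCode(5L)) {
  nm <- chartr("Uu", "Tt", toupper(names(counts)))
  posFreq <- lapply(1:3, function(p) {
    b <- substring(nm, p, p)
    f <- vapply(c("T", "C", "A", "G"),
                function(x) sum(as.numeric(counts)[b == x]), numeric(1))
    f / sum(f)
  })
  pi <- vapply(.CODONS, function(cod) {
    posFreq[[1]][[substr(cod, 1, 1)]] *
      posFreq[[2]][[substr(cod, 2, 2)]] *
      posFreq[[3]][[substr(cod, 3, 3)]]
  }, numeric(1))
  pi[stopCodons(code)] <- 0
  pi / sum(pi)
}

## ---- gene orders ---------------------------------------------------------

#' Random gene order drawn from the canonical inventory
#'
#' Deterministic for a fixed seed.  Takes `nGenes` labels from the
#' non-tRNA inventory (13 PCGs, 2 rRNAs, control region) and `nTrna`
#' tRNA labels, then shuffles them into one circular order.
#'
#' @param nGenes number of non-tRNA genes (<= 16).
#' @param nTrna number of tRNA genes (<= 22).
#' @param seed integer seed.
#' @return a [GeneOrder-class] with all strands "+".
#' @export
makeGeneOrder <- function(nGenes = 16L, nTrna = 22L, seed = 1L) {
  inv <- canonicalGeneInventory()
  trna <- grep("^trn", inv, value = TRUE)
  other <- setdiff(inv, trna)
  if (nGenes > length(other) || nTrna > length(trna))
    stop("inventory holds ", length(other), " non-tRNA and ",
         length(trna), " tRNA genes")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  labs <- c(sample(other, nGenes), sample(trna, nTrna))
  labs <- sample(labs)
  geneOrder(labs, strand = "+", id = paste0("synthetic_order_seed", seed),
            circular = TRUE)
}

#' Apply a rearrangement script to a gene order
#'
#' Operations (applied in sequence): `reversal(from, to)` reverses a
#' block and flips its strands; `tdrl(from, to, retention)` duplicates a
#' block in tandem and keeps first/second/both copies per position;
#' `delete(label)`; `insert(label, pos)`; `duplicate(label)` (tandem
#' copy after the first occurrence).
#'
#' @param order a [GeneOrder-class].
#' @param script list of operations, each a list with `op` and its
#'   parameters (e.g. `list(op="reversal", from=3, to=6)`).
#' @return list with `order` (the rearranged [GeneOrder-class]) and
#'   `truth` (the script plus each intermediate order, sufficient to
#'   replay).
#' @export
applyRearrangements <- function(order, script) {
  labs <- order@labels
  strd <- order@strand
  states <- list(list(labels = labs, strand = strd))
  for (opn in script) {
    op <- opn$op
    if (op == "reversal") {
      i <- opn$from; j <- opn$to
      stopifnot(i >= 1, j >= i, j <= length(labs))
      labs[i:j] <- rev(labs[i:j])
      strd[i:j] <- .flipStrand(rev(strd[i:j]))
    } else if (op == "tdrl") {
      ev <- list(blockStart = opn$from, blockEnd = opn$to,
                 retention = opn$retention)
      keepF <- opn$retention %in% c("first", "both")
      keepS <- opn$retention %in% c("second", "both")
      blkS <- strd[opn$from:opn$to]
      labs <- applyTdrl(labs, ev)
      pre <- if (opn$from > 1) strd[1:(opn$from - 1)] else character(0)
      post <- if (opn$to < length(strd)) strd[(opn$to + 1):length(strd)] else character(0)
      strd <- c(pre, blkS[keepF], blkS[keepS], post)
    } else if (op == "delete") {
      i <- match(opn$label, labs)
      if (is.na(i)) stop("delete: label not present: ", opn$label)
      labs <- labs[-i]; strd <- strd[-i]
    } else if (op == "insert") {
      pos <- min(max(opn$pos, 1L), length(labs) + 1L)
      labs <- append(labs, opn$label, after = pos - 1L)
      strd <- append(strd, opn$strand %||% "+", after = pos - 1L)
    } else if (op == "duplicate") {
      i <- match(opn$label, labs)
      if (is.na(i)) stop("duplicate: label not present: ", opn$label)
      labs <- append(labs, labs[i], after = i)
      strd <- append(strd, strd[i], after = i)
    } else stop("unknown rearrangement op: ", op)
    states[[length(states) + 1L]] <- list(labels = labs, strand = strd)
  }
  newOrder <- geneOrder(labs, strand = strd,
                        id = paste0(order@id, "_rearranged"),
                        circular = order@circular)
  list(order = newOrder, truth = list(script = script, states = states))
}

## ---- coding sequences -----------------------------------------------------

#' Sample a coding sequence matching a codon-usage profile
#'
#' Codons are drawn with probability proportional to the profile weights
#' (family amino-acid usage times within-family RSCU is proportional to
#' raw codon counts, so count vectors are valid profiles).  The CDS
#' starts with ATG, ends with TAA, and contains no internal stop.
#' Deterministic per seed.
#'
#' @param profile named non-negative weights over codons (counts or RSCU
#'   mass); stop codons are ignored.
#' @param nCodons total codons including the start and stop codon
#'   (>= 3).
#' @param code a [GeneticCode-class].
#' @param seed integer seed.
#' @return CDS string of 3 * nCodons bases.
#' @export
sampleCdsFromRscu <- function(profile, nCodons, code = geneticCode(5L),
                              seed = 1L) {
  stopifnot(nCodons >= 3L)
  w <- numeric(64L); names(w) <- .CODONS
  nm <- chartr("Uu", "Tt", toupper(names(profile)))
  w[nm] <- as.numeric(profile)
  w[stopCodons(code)] <- 0
  w[w < 0] <- 0
  if (sum(w) == 0) stop("profile has no mass on sense codons")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  body <- sample(.CODONS, nCodons - 2L, replace = TRUE, prob = w / sum(w))
  paste(c("ATG", body, "TAA"), collapse = "")
}

## ---- codon substitution simulation ----------------------------------------

# per-codon rate structure: for each sense codon, its allowed single-step
# targets with instantaneous rates pi_target * kappa^ts * omega^nonsyn,
# globally scaled so the equilibrium flow is 1 substitution/codon/unit t
.buildRates <- function(params) {
  code <- params$code
  aa <- code@codonToAa
  stops <- stopCodons(code)
  pi <- params$codonFreqs
  sense <- setdiff(.CODONS, stops)
  tgt <- lapply(sense, function(cod) {
    nbs <- .codonNeighbors(cod)
    nbs <- nbs[!(nbs %in% stops)]
    if (!length(nbs))
      return(list(targets = character(0), rates = numeric(0), syn = logical(0)))
    ts <- vapply(seq_along(nbs), function(k) {
      p <- which(strsplit(cod, "")[[1]] != strsplit(nbs[k], "")[[1]])
      .isTransition(substr(cod, p, p), substr(nbs[k], p, p))
    }, logical(1))
    syn <- aa[nbs] == aa[[cod]]
    r <- pi[nbs] * ifelse(ts, params$kappa, 1) *
      ifelse(syn, 1, params$omega)
    list(targets = nbs, rates = unname(r), syn = unname(syn))
  })
  names(tgt) <- sense
  totRate <- vapply(tgt, function(x) sum(x$rates), numeric(1))
  meanRate <- sum(pi[sense] * totRate)
  if (meanRate <= 0) meanRate <- 1
  for (s in sense) tgt[[s]]$rates <- tgt[[s]]$rates / meanRate
  tgt
}

# evolve one codon for time t by exact Gillespie simulation
.evolveCodon <- function(cod, tgt, t) {
  nsyn <- nnon <- 0L
  repeat {
    entry <- tgt[[cod]]
    tot <- sum(entry$rates)
    if (tot <= 0) break
    wait <- stats::rexp(1, tot)
    if (wait > t) break
    t <- t - wait
    k <- sample.int(length(entry$targets), 1L, prob = entry$rates)
    if (entry$syn[k]) nsyn <- nsyn + 1L else nnon <- nnon + 1L
    cod <- entry$targets[k]
  }
  list(codon = cod, nsyn = nsyn, nnon = nnon)
}

#' Evolve a codon sequence pair under the codon model
#'
#' Two descendants evolve independently from the ancestor for t/2 each
#' (star design), under a GY94-style model: the instantaneous rate
#' between codons differing at one position is proportional to
#' pi_target x kappa^[transition] x omega^[nonsynonymous]; multi-position
#' changes and changes to stop codons have rate zero.  Substitution
#' events are simulated exactly per codon and the true synonymous /
#' nonsynonymous event counts are recorded.
#'
#' @param ancestor CDS string (length divisible by 3; stop codons inside
#'   the ancestor are left unevolved).
#' @param params an [evolutionParams()] object.
#' @param seed integer seed.
#' @return list with `seq1`, `seq2`, and `truth` (per-lineage and total
#'   synonymous/nonsynonymous event counts and `n_events`).
#' @export
evolveCodonPair <- function(ancestor, params, seed = 1L) {
  stopifnot(inherits(params, "EvolutionParams"))
  ancestor <- toupper(ancestor)
  if (nchar(ancestor) %% 3L != 0L) stop("ancestor length must be divisible by 3")
  cods <- .splitCodons(ancestor)
  if (any(grepl("[^ACGT]", cods))) stop("ancestor must be over A,C,G,T")
  tgt <- .buildRates(params)
  stops <- stopCodons(params$code)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  evolveLineage <- function() {
    out <- cods
    nsyn <- nnon <- 0L
    for (i in seq_along(cods)) {
      if (cods[i] %in% stops) next
      r <- .evolveCodon(cods[i], tgt, params$t / 2)
      out[i] <- r$codon
      nsyn <- nsyn + r$nsyn; nnon <- nnon + r$nnon
    }
    list(seq = paste(out, collapse = ""), nsyn = nsyn, nnon = nnon)
  }
  l1 <- evolveLineage()
  l2 <- evolveLineage()
  list(seq1 = l1$seq, seq2 = l2$seq,
       truth = list(nsyn1 = l1$nsyn, nnon1 = l1$nnon,
                    nsyn2 = l2$nsyn, nnon2 = l2$nnon,
                    nsyn = l1$nsyn + l2$nsyn,
                    nnon = l1$nnon + l2$nnon,
                    n_events = l1$nsyn + l1$nnon + l2$nsyn + l2$nnon))
}

#' Divergence giving a target synonymous rate under the model
#'
#' Computes, from the rate structure at equilibrium, the total divergence
#' t (substitutions per codon between the two tips) whose expected
#' synonymous substitutions per synonymous site equal `targetKs`.  Sites
#' are counted with the kappa/pi weighting (no omega), matching how Ks
#' denominators are defined.
#'
#' @param params an [evolutionParams()] object (its `t` is ignored).
#' @param targetKs desired synonymous divergence.
#' @return numeric t.
#' @export
divergenceForKs <- function(params, targetKs) {
  tgt <- .buildRates(params)
  pi <- params$codonFreqs
  sense <- names(tgt)
  synRate <- sum(vapply(sense, function(s)
    pi[[s]] * sum(tgt[[s]]$rates[tgt[[s]]$syn]), numeric(1)))
  sBar <- sum(vapply(sense, function(s)
    pi[[s]] * .weightedSites(s, params$code, params$kappa, pi), numeric(1)))
  # per unit t: synRate syn events per codon; sBar syn sites per codon
  targetKs * sBar / synRate
}

## ---- full genome pairs -----------------------------------------------------

.randomSeq <- function(n, atBias = 0.62) {
  p <- c(A = atBias / 2, T = atBias / 2, G = (1 - atBias) * 0.6,
         C = (1 - atBias) * 0.4)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate an annotated genome pair with known truth
#'
#' Builds an ancestral circular genome (gene order from
#' [makeGeneOrder()], PCG sequences from [sampleCdsFromRscu()], random
#' tRNA/rRNA/control-region sequences), then derives two genomes: shared
#' PCGs diverge by [evolveCodonPair()] and genome 2's gene order is
#' transformed by the given rearrangement script.  Both genomes are
#' writable as GenBank files for end-to-end pipeline tests.
#'
#' @param config list; recognised entries (with defaults):
#'   `nGenes` (16), `nTrna` (22), `omega` (0.2), `kappa` (2), `t` (0.3),
#'   `codonFreqs` (F3x4 fitted to the shipped venerid codon-usage
#'   profile, giving realistically AT-rich coding sequences; see
#'   [veneridCodonProfile()]), `script` (empty list), `pcgCodons` (150),
#'   `code` (table 5).
#' @param seed integer seed.
#' @return list with `genome1`, `genome2` ([AnnotatedGenome-class]) and
#'   `truth` (script, per-gene evolution truth, parameters).
#' @export
makeGenomePair <- function(config = list(), seed = 1L) {
  cfg <- list(nGenes = 16L, nTrna = 22L, omega = 0.2, kappa = 2, t = 0.3,
              codonFreqs = NULL, script = list(), pcgCodons = 150L,
              code = geneticCode(5L))
  # plain override, not modifyList: a rearrangement script is a list of
  # unnamed op lists and must replace the default wholesale
  cfg[names(config)] <- config
  if (is.null(cfg$codonFreqs))
    cfg$codonFreqs <- f3x4FromCounts(veneridCodonProfile(), cfg$code)
  params <- evolutionParams(cfg$omega, cfg$kappa, cfg$t, cfg$codonFreqs,
                            cfg$code)
  ord <- makeGeneOrder(cfg$nGenes, cfg$nTrna, seed = seed)
  reb <- applyRearrangements(ord, cfg$script)
  ord2 <- reb$order

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed + 104729L)

  classOf <- function(l) {
    if (grepl("^trn", l)) "tRNA"
    else if (l %in% c("rrnL", "rrnS")) "rRNA"
    else if (l == "D-loop") "control_region"
    else "PCG"
  }
  lenOf <- function(cl) switch(cl, tRNA = 66L, rRNA = 950L,
                               control_region = 800L, PCG = 3L * cfg$pcgCodons)
  # one sequence per distinct label (copies share the ancestral sequence)
  labsAll <- unique(c(ord@labels, ord2@labels))
  seqs1 <- seqs2 <- spacers <- list()
  evoTruth <- list()
  gseed <- seed
  for (l in labsAll) {
    cl <- classOf(l)
    if (cl == "PCG") {
      gseed <- gseed + 1L
      anc <- sampleCdsFromRscu(params$codonFreqs, cfg$pcgCodons,
                               cfg$code, seed = gseed)
      ev <- evolveCodonPair(anc, params, seed = gseed + 7L)
      seqs1[[l]] <- ev$seq1
      seqs2[[l]] <- ev$seq2
      evoTruth[[l]] <- ev$truth
    } else {
      s <- .randomSeq(lenOf(cl))
      seqs1[[l]] <- s
      seqs2[[l]] <- s
    }
    # one spacer per label so identical configs assemble identical genomes
    spacers[[l]] <- .randomSeq(sample(5:20, 1L))
  }
  assemble <- function(ordx, seqs, id) {
    labs <- ordx@labels; strd <- ordx@strand
    pieces <- character(0)
    feats <- .emptyFeatures()
    pos <- 0L
    for (i in seq_along(labs)) {
      s <- seqs[[labs[i]]]
      if (identical(strd[i], "-")) s <- .revComp(s)
      sp <- spacers[[labs[i]]]
      pieces <- c(pieces, sp, s)
      start <- pos + nchar(sp)
      feats <- rbind(feats, data.frame(
        name = labs[i], class = classOf(labs[i]),
        start = start, end = start + nchar(s),
        strand = if (identical(strd[i], "-")) "-" else "+",
        copy_index = 1L, stringsAsFactors = FALSE))
      pos <- start + nchar(s)
    }
    annotatedGenome(id = id, sequence = paste(pieces, collapse = ""),
                    features = feats, circular = TRUE,
                    sourceFormat = "synthetic")
  }
  g1 <- assemble(ord, seqs1, paste0("SYN", seed, "A"))
  g2 <- assemble(ord2, seqs2, paste0("SYN", seed, "B"))
  list(genome1 = g1, genome2 = g2,
       truth = list(script = cfg$script, order1 = ord, order2 = ord2,
                    evolution = evoTruth,
                    params = list(omega = cfg$omega, kappa = cfg$kappa,
                                  t = cfg$t)))
}
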