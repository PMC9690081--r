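# Pairwise Ka/Ks estimation: Nei-Gojobori (1986) counting with
# Jukes-Cantor correction, and a Yang-Nielsen (2000) style approximate
# method with transition/transversion bias (kappa), F3x4 codon
# frequencies and iterative omega-dependent pathway weighting.

## ---- shared pathway machinery ------------------------------------------

# All shortest mutational pathways between two codons; pathways through
# stop codons are excluded.  Each path records per-step synonymy and
# transition status plus the step's target codon.
.pairPaths <- function(c1, c2, aa, stops) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(list())
  perms <- switch(as.character(length(pos)),
                  "1" = list(pos),
                  "2" = list(pos, rev(pos)),
                  "3" = {
                    p <- pos
                    list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                         p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
                  })
  out <- list()
  for (perm in perms) {
    cur <- c1
    syn <- ts <- logical(length(perm))
    tgt <- character(length(perm))
    ok <- TRUE
    for (k in seq_along(perm)) {
      p <- perm[k]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% stops) { ok <- FALSE; break }
      syn[k] <- aa[[cur]] == aa[[nxt]]
      ts[k] <- .isTransition(substr(cur, p, p), substr(nxt, p, p))
      tgt[k] <- nxt
      cur <- nxt
    }
    if (ok) out[[length(out) + 1L]] <- list(syn = syn, ts = ts, targets = tgt)
  }
  out
}

.pairPathsCached <- function(c1, c2, code) {
  key <- paste0("paths_t", code@tableId)
  if (is.null(.codonCache[[key]]))
    .codonCache[[key]] <- new.env(parent = emptyenv())
  env <- .codonCache[[key]]
  pk <- paste0(c1, c2)
  if (is.null(env[[pk]]))
    env[[pk]] <- .pairPaths(c1, c2, code@codonToAa, stopCodons(code))
  env[[pk]]
}

# NG86 synonymous site count of one codon: per position, the fraction of
# the 3 single-base changes that are synonymous (changes to stop codons
# count as nonsynonymous so that S + N = 3 per codon).
.ng86SiteTable <- function(code) {
  key <- paste0("ngsites_t", code@tableId)
  if (!is.null(.codonCache[[key]])) return(.codonCache[[key]])
  aa <- code@codonToAa
  stops <- stopCodons(code)
  bases <- c("T", "C", "A", "G")
  s <- vapply(.CODONS, function(cod) {
    if (cod %in% stops) return(NA_real_)
    tot <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cod, p, p))) {
        nxt <- cod
        substr(nxt, p, p) <- b
        if (!(nxt %in% stops) && aa[[nxt]] == aa[[cod]]) tot <- tot + 1 / 3
      }
    }
    tot
  }, numeric(1))
  .codonCache[[key]] <- s
  s
}

# kappa/pi-weighted synonymous site count (stop targets excluded from
# numerator and denominator; S + N = 3 per codon is preserved).
.weightedSites <- function(cod, code, kappa, pi) {
  aa <- code@codonToAa
  stops <- stopCodons(code)
  bases <- c("T", "C", "A", "G")
  wSyn <- wTot <- 0
  for (p in 1:3) {
    from <- substr(cod, p, p)
    for (b in setdiff(bases, from)) {
      nxt <- cod
      substr(nxt, p, p) <- b
      if (nxt %in% stops) next
      w <- pi[[nxt]] * if (.isTransition(from, b)) kappa else 1
      wTot <- wTot + w
      if (aa[[nxt]] == aa[[cod]]) wSyn <- wSyn + w
    }
  }
  if (wTot == 0) return(0)
  3 * wSyn / wTot
}

.k80 <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(d = NA_real_, A = NA_real_, B = NA_real_))
  list(d = -0.5 * log(w1) - 0.25 * log(w2),
       A = -0.5 * log(w1) + 0.25 * log(w2),
       B = -0.25 * log(w2))
}

# position-wise degeneracy (1..4) of each codon position, for kappa
# estimation from nondegenerate and fourfold-degenerate sites
.positionDegeneracy <- function(code) {
  key <- paste0("posdeg_t", code@tableId)
  if (!is.null(.codonCache[[key]])) return(.codonCache[[key]])
  aa <- code@codonToAa
  stops <- stopCodons(code)
  bases <- c("T", "C", "A", "G")
  m <- matrix(NA_integer_, nrow = 64, ncol = 3, dimnames = list(.CODONS, NULL))
  for (cod in .CODONS) {
    if (cod %in% stops) next
    for (p in 1:3) {
      cnt <- 0L
      for (b in bases) {
        nxt <- cod
        substr(nxt, p, p) <- b
        if (!(nxt %in% stops) && aa[[nxt]] == aa[[cod]]) cnt <- cnt + 1L
      }
      m[cod, p] <- cnt
    }
  }
  .codonCache[[key]] <- m
  m
}

# kappa from nondegenerate (0-fold) and fourfold-degenerate sites via the
# two-parameter (K80) distance, site classes pooled by weighted averages.
.estimateKappa <- function(c1s, c2s, code) {
  deg <- .positionDegeneracy(code)
  cls <- list(`1` = c(0L, 0L, 0L), `4` = c(0L, 0L, 0L))  # n, ts, tv
  for (i in seq_along(c1s)) {
    d1 <- deg[c1s[i], ]; d2 <- deg[c2s[i], ]
    for (p in 1:3) {
      if (is.na(d1[p]) || is.na(d2[p]) || d1[p] != d2[p]) next
      if (!d1[p] %in% c(1L, 4L)) next
      k <- as.character(d1[p])
      b1 <- substr(c1s[i], p, p); b2 <- substr(c2s[i], p, p)
      cls[[k]][1] <- cls[[k]][1] + 1L
      if (b1 != b2) {
        if (.isTransition(b1, b2)) cls[[k]][2] <- cls[[k]][2] + 1L
        else cls[[k]][3] <- cls[[k]][3] + 1L
      }
    }
  }
  num <- den <- 0
  used <- FALSE
  for (k in c("1", "4")) {
    n <- cls[[k]][1]
    if (n == 0L) next
    kk <- .k80(cls[[k]][2] / n, cls[[k]][3] / n)
    if (is.na(kk$A) || is.na(kk$B) || kk$B <= 0) next
    num <- num + n * kk$A
    den <- den + n * kk$B
    used <- TRUE
  }
  if (!used || den <= 0) return(NA_real_)
  num / den
}

# F3x4 equilibrium codon frequencies from both sequences jointly
.f3x4 <- function(c1s, c2s, code) {
  all <- c(c1s, c2s)
  posFreq <- lapply(1:3, function(p) {
    b <- substring(all, p, p)
    f <- vapply(c("T", "C", "A", "G"), function(x) sum(b == x), 0)
    f / sum(f)
  })
  pi <- vapply(.CODONS, function(cod) {
    posFreq[[1]][[substr(cod, 1, 1)]] *
      posFreq[[2]][[substr(cod, 2, 2)]] *
      posFreq[[3]][[substr(cod, 3, 3)]]
  }, numeric(1))
  pi[stopCodons(code)] <- 0
  if (sum(pi) == 0) stop("degenerate codon frequencies")
  pi / sum(pi)
}

.uniformFreqs <- function(code) {
  pi <- rep(1, 64)
  names(pi) <- .CODONS
  pi[stopCodons(code)] <- 0
  pi / sum(pi)
}

.validateAlignmentCodons <- function(caln, code) {
  stops <- stopCodons(code)
  bad <- caln@codons1 %in% stops | caln@codons2 %in% stops
  if (any(bad))
    stop("codon alignment contains stop codons; filter them first")
}

## ---- NG86 ---------------------------------------------------------------

#' Ka/Ks by the Nei-Gojobori (1986) counting method
#'
#' Synonymous site fractions per codon are averaged over the two
#' sequences; differences are counted by averaging over all shortest
#' mutational pathways between differing codons (pathways through stop
#' codons excluded; a codon pair whose every pathway hits a stop is
#' skipped from the difference counts and noted).  Proportions pS =
#' Sd/S and pN = Nd/N are corrected with the one-parameter distance
#' d = -(3/4) ln(1 - (4/3) p); p >= 3/4 leaves the corresponding rate NA.
#'
#' @param caln a [CodonAlignment-class].
#' @param code a [GeneticCode-class].
#' @return a [KaKsResult-class].
#' @export
kaksNG86 <- function(caln, code = geneticCode(5L)) {
  .validateAlignmentCodons(caln, code)
  n <- caln@nCodons
  if (n < 1L) stop("zero aligned codons")
  siteTab <- .ng86SiteTable(code)
  S <- (sum(siteTab[caln@codons1]) + sum(siteTab[caln@codons2])) / 2
  N <- 3 * n - S
  Sd <- Nd <- 0
  notes <- character(0)
  diffIdx <- which(caln@codons1 != caln@codons2)
  for (i in diffIdx) {
    paths <- .pairPathsCached(caln@codons1[i], caln@codons2[i], code)
    if (!length(paths)) {
      notes <- c(notes, paste0("codon pair skipped (all pathways hit stops): ",
                               caln@codons1[i], "/", caln@codons2[i]))
      next
    }
    Sd <- Sd + mean(vapply(paths, function(p) sum(p$syn), numeric(1)))
    Nd <- Nd + mean(vapply(paths, function(p) sum(!p$syn), numeric(1)))
  }
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- if (S > 0) jc(Sd / S) else NA_real_
  ka <- if (N > 0) jc(Nd / N) else NA_real_
  ratio <- if (is.na(ks) || is.na(ka) || ks == 0) NA_real_ else ka / ks
  fp <- tryCatch(fisherKaKs(S, N, Sd, Nd), error = function(e) NA_real_)
  new("KaKsResult", method = "NG86", gene = caln@gene,
      S = S, N = N, Sd = Sd, Nd = Nd, kappa = NA_real_,
      ka = ka, ks = ks, ratio = ratio, fisherP = fp,
      nCodons = n, converged = NA, notes = notes)
}

## ---- YN00 ---------------------------------------------------------------

#' Ka/Ks by an approximate Yang-Nielsen (2000) style method
#'
#' Steps: (i) kappa is estimated from third-position fourfold-degenerate
#' and nondegenerate sites via the two-parameter (K80) distance;
#' (ii) synonymous and nonsynonymous sites are counted weighting each
#' possible change by kappa and by equilibrium codon frequencies (F3x4
#' from both sequences jointly); (iii) differences are counted over
#' shortest pathways weighted by the instantaneous rates (target
#' frequency x kappa^[transition] x omega^[nonsynonymous]);
#' (iv) transition/transversion-split proportions are corrected with the
#' K80 distance separately for synonymous and nonsynonymous sites;
#' (v) the omega-dependent weighting is iterated to convergence
#' (relative change < 1e-6 or 100 iterations; non-convergence is flagged
#' and the last iterate returned).
#'
#' @param caln a [CodonAlignment-class] (>= 10 codons recommended; a
#'   warning is issued below that).
#' @param code a [GeneticCode-class].
#' @param forceKappa fix kappa instead of estimating it (used for
#'   reduction-to-NG86 checks).
#' @param frequencies "f3x4" (default) or "uniform".
#' @param maxIter,tol iteration controls.
#' @return a [KaKsResult-class].
#' @export
kaksYN00 <- function(caln, code = geneticCode(5L), forceKappa = NULL,
                     frequencies = c("f3x4", "uniform"),
                     maxIter = 100L, tol = 1e-6) {
  frequencies <- match.arg(frequencies)
  .validateAlignmentCodons(caln, code)
  n <- caln@nCodons
  if (n < 1L) stop("zero aligned codons")
  if (n < 10L) warning("fewer than 10 aligned codons; estimates will be noisy")
  notes <- character(0)

  kappa <- if (!is.null(forceKappa)) as.numeric(forceKappa)
           else .estimateKappa(caln@codons1, caln@codons2, code)
  if (is.na(kappa) || kappa <= 0) {
    notes <- c(notes, "kappa not estimable from degenerate sites; using kappa = 1")
    kappaUse <- 1
  } else kappaUse <- kappa

  pi <- if (frequencies == "f3x4") .f3x4(caln@codons1, caln@codons2, code)
        else .uniformFreqs(code)

  usedCodons <- unique(c(caln@codons1, caln@codons2))
  siteOf <- vapply(usedCodons, .weightedSites, numeric(1),
                   code = code, kappa = kappaUse, pi = pi)
  S <- (sum(siteOf[caln@codons1]) + sum(siteOf[caln@codons2])) / 2
  N <- 3 * n - S

  # aggregate identical codon-pair columns once
  diffIdx <- which(caln@codons1 != caln@codons2)
  if (!length(diffIdx)) {
    fp <- tryCatch(fisherKaKs(S, N, 0, 0), error = function(e) NA_real_)
    return(new("KaKsResult", method = "YN00", gene = caln@gene,
               S = S, N = N, Sd = 0, Nd = 0, kappa = kappa,
               ka = 0, ks = 0, ratio = NA_real_, fisherP = fp,
               nCodons = n, converged = TRUE, notes = notes))
  }
  keys <- paste(caln@codons1[diffIdx], caln@codons2[diffIdx])
  keyTab <- table(keys)
  pairList <- strsplit(names(keyTab), " ")
  pathsByKey <- lapply(pairList, function(p) .pairPathsCached(p[1], p[2], code))
  blocked <- lengths(pathsByKey) == 0L
  if (any(blocked))
    notes <- c(notes, paste0("codon pair skipped (all pathways hit stops): ",
                             names(keyTab)[blocked]))

  countDiffs <- function(omega) {
    acc <- c(synTs = 0, synTv = 0, nonTs = 0, nonTv = 0)
    for (k in seq_along(pathsByKey)) {
      paths <- pathsByKey[[k]]
      if (!length(paths)) next
      w <- vapply(paths, function(p) {
        prod(pi[p$targets] * ifelse(p$ts, kappaUse, 1) *
               ifelse(p$syn, 1, omega))
      }, numeric(1))
      if (sum(w) <= 0) w <- rep(1, length(w))  # all-zero weights: fall back to equal
      w <- w / sum(w)
      m <- as.numeric(keyTab[k])
      for (j in seq_along(paths)) {
        p <- paths[[j]]
        acc["synTs"] <- acc["synTs"] + m * w[j] * sum(p$syn & p$ts)
        acc["synTv"] <- acc["synTv"] + m * w[j] * sum(p$syn & !p$ts)
        acc["nonTs"] <- acc["nonTs"] + m * w[j] * sum(!p$syn & p$ts)
        acc["nonTv"] <- acc["nonTv"] + m * w[j] * sum(!p$syn & !p$ts)
      }
    }
    acc
  }

  omega <- 0.5
  converged <- FALSE
  acc <- countDiffs(omega)
  dS <- dN <- NA_real_
  for (it in seq_len(maxIter)) {
    kS <- .k80(acc[["synTs"]] / S, acc[["synTv"]] / S)
    kN <- .k80(acc[["nonTs"]] / N, acc[["nonTv"]] / N)
    dS <- kS$d; dN <- kN$d
    if (is.na(dS) || is.na(dN) || dS <= 0) break
    omegaNew <- dN / dS
    if (abs(omegaNew - omega) < tol * max(omega, 1e-8)) {
      omega <- omegaNew
      converged <- TRUE
      acc <- countDiffs(omega)
      kS <- .k80(acc[["synTs"]] / S, acc[["synTv"]] / S)
      kN <- .k80(acc[["nonTs"]] / N, acc[["nonTv"]] / N)
      dS <- kS$d; dN <- kN$d
      break
    }
    omega <- omegaNew
    acc <- countDiffs(omega)
  }
  if (!converged)
    notes <- c(notes, "iteration did not converge; last iterate returned")

  Sd <- acc[["synTs"]] + acc[["synTv"]]
  Nd <- acc[["nonTs"]] + acc[["nonTv"]]
  ratio <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  fp <- tryCatch(fisherKaKs(S, N, Sd, Nd), error = function(e) NA_real_)
  new("KaKsResult", method = "YN00", gene = caln@gene,
      S = S, N = N, Sd = Sd, Nd = Nd, kappa = kappa,
      ka = dN, ks = dS, ratio = ratio, fisherP = fp,
      nCodons = n, converged = converged, notes = notes)
}

## ---- Fisher validation ---------------------------------------------------

#' Two-sided Fisher exact test for a Ka/Ks site/difference table
#'
#' Tests the 2x2 table with rows {synonymous, nonsynonymous} and columns
#' {differences, sites - differences}; real-valued sites and differences
#' are rounded to the nearest integer for the hypergeometric support.
#' The two-sided p sums all tables (with the observed margins) whose
#' probability does not exceed that of the observed table.
#'
#' @param S,N,Sd,Nd sites and differences, or a single
#'   [KaKsResult-class] as the first argument.
#' @return two-sided p in [0, 1].
#' @export
fisherKaKs <- function(S, N = NULL, Sd = NULL, Nd = NULL) {
  if (is(S, "KaKsResult")) {
    r <- S
    S <- r@S; N <- r@N; Sd <- r@Sd; Nd <- r@Nd
  }
  if (any(!is.finite(c(S, N, Sd, Nd))))
    stop("S, N, Sd, Nd must all be finite")
  a <- round(Sd); b <- round(S) - a
  c2 <- round(Nd); d <- round(N) - c2
  if (any(c(a, b, c2, d) < 0))
    stop("negative cell after rounding; differences exceed sites")
  m <- a + b          # synonymous sites
  nn <- c2 + d        # nonsynonymous sites
  kk <- a + c2        # total differences
  if (kk == 0 || m == 0 || nn == 0) return(1)
  supp <- max(0, kk - nn):min(kk, m)
  probs <- stats::dhyper(supp, m, nn, kk)
  pObs <- stats::dhyper(a, m, nn, kk)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## ---- pairwise matrix ------------------------------------------------------

#' Pairwise Ka/Ks table between a query genome and reference genomes
#'
#' One row per (gene, reference pair).  Homologs are matched by canonical
#' gene name using copy_index 1 when a gene is duplicated (configurable
#' via `copyIndex`).  Missing homologs yield a row of NAs with a reason.
#'
#' @param query an [AnnotatedGenome-class].
#' @param references list of [AnnotatedGenome-class] objects.
#' @param genes gene names to compare (default: the query's PCG names).
#' @param method "YN00" (default) or "NG86".
#' @param code a [GeneticCode-class].
#' @param scoring protein alignment scoring, see
#'   [defaultAlignmentScoring()].
#' @param copyIndex which copy of a duplicated gene to use.
#' @return data.frame with columns gene, pair, method, S, N, Sd, Nd,
#'   kappa, Ka, Ks, KaKs, fisher_p, n_codons, note.
#' @export
pairwiseKaKsMatrix <- function(query, references, genes = NULL,
                               method = c("YN00", "NG86"),
                               code = geneticCode(5L),
                               scoring = defaultAlignmentScoring(),
                               copyIndex = 1L) {
  method <- match.arg(method)
  if (is(references, "AnnotatedGenome")) references <- list(references)
  cdsQ <- extractCDS(query, code)
  if (is.null(genes)) genes <- unique(cdsQ$name)
  anyShared <- FALSE
  rows <- list()
  naRow <- function(gene, pair, note)
    data.frame(gene = gene, pair = pair, method = method,
               S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
               kappa = NA_real_, Ka = NA_real_, Ks = NA_real_,
               KaKs = NA_real_, fisher_p = NA_real_, n_codons = NA_integer_,
               note = note, stringsAsFactors = FALSE)
  for (ref in references) {
    cdsR <- extractCDS(ref, code)
    pair <- paste(query@id, "vs", ref@id)
    for (g in genes) {
      q <- cdsQ[cdsQ$name == g & cdsQ$copy_index == copyIndex, , drop = FALSE]
      r <- cdsR[cdsR$name == g & cdsR$copy_index == copyIndex, , drop = FALSE]
      if (!nrow(q) || !nrow(r)) {
        rows[[length(rows) + 1L]] <-
          naRow(g, pair, paste0("missing homolog in ",
                                if (!nrow(q)) query@id else ref@id))
        next
      }
      anyShared <- TRUE
      res <- tryCatch({
        caln <- codonAlign(q$seq[1], r$seq[1], code, gene = g, scoring = scoring)
        if (method == "NG86") kaksNG86(caln, code) else kaksYN00(caln, code)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- naRow(g, pair, conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, pair = pair, method = method,
        S = res@S, N = res@N, Sd = res@Sd, Nd = res@Nd,
        kappa = res@kappa, Ka = res@ka, Ks = res@ks, KaKs = res@ratio,
        fisher_p = res@fisherP, n_codons = res@nCodons,
        note = paste(res@notes, collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  if (!anyShared) stop("no shared genes between query and references")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
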