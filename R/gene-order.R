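# Gene-order comparison: maximal shared clusters (with labels private to
# one order treated as transparent), reversed clusters, noncommon genes,
# duplicates, and single tandem-duplication-random-loss (TDRL) events.

.flipStrand <- function(s) ifelse(is.na(s), NA, ifelse(s == "+", "-", "+"))

# strand-aware token equality; NA strand matches anything
.tokEq <- function(l1, s1, l2, s2) {
  l1 == l2 & (is.na(s1) | is.na(s2) | s1 == s2)
}

# keep, per label, the first min(count_a, count_b) occurrences (greedy
# left-to-right); labels private to one order are transparent
.sharedFilter <- function(la, lb) {
  shared <- intersect(la, lb)
  keepFirstK <- function(l, k) {
    keep <- logical(length(l))
    seen <- integer(0)
    names(seen) <- character(0)
    for (i in seq_along(l)) {
      if (!l[i] %in% shared) next
      got <- if (l[i] %in% names(seen)) seen[[l[i]]] else 0L
      if (got < k[[l[i]]]) {
        keep[i] <- TRUE
        seen[[l[i]]] <- got + 1L
      }
    }
    which(keep)
  }
  k <- sapply(shared, function(s) min(sum(la == s), sum(lb == s)))
  if (!length(shared)) return(list(ia = integer(0), ib = integer(0)))
  names(k) <- shared
  list(ia = keepFirstK(la, k), ib = keepFirstK(lb, k))
}

# all maximal common runs between token sequences (same orientation);
# returns data.frame(i, j, len) of start positions (1-based) and length
.maximalRuns <- function(la, sa, lb, sb, circular) {
  n <- length(la); m <- length(lb)
  if (!n || !m) return(data.frame(i = integer(), j = integer(), len = integer()))
  M <- outer(seq_len(n), seq_len(m),
             function(i, j) .tokEq(la[i], sa[i], lb[j], sb[j]))
  if (!any(M)) return(data.frame(i = integer(), j = integer(), len = integer()))
  maxLen <- min(n, m)
  wrap <- function(x, nn) ((x - 1L) %% nn) + 1L
  runs <- list()
  starts <- which(M, arr.ind = TRUE)
  isStart <- apply(starts, 1L, function(ij) {
    i <- ij[1]; j <- ij[2]
    if (circular) {
      !M[wrap(i - 1L, n), wrap(j - 1L, m)]
    } else {
      i == 1L || j == 1L || !M[i - 1L, j - 1L]
    }
  })
  if (!any(isStart)) {
    # circular full cover: every diagonal through a match closes on itself
    i0 <- min(starts[, 1])
    for (j0 in starts[starts[, 1] == i0, 2])
      runs[[length(runs) + 1L]] <- c(i0, j0, maxLen)
  } else {
    st <- starts[isStart, , drop = FALSE]
    for (r in seq_len(nrow(st))) {
      i <- st[r, 1]; j <- st[r, 2]
      len <- 1L
      while (len < maxLen) {
        ni <- i + len; nj <- j + len
        if (circular) { ni <- wrap(ni, n); nj <- wrap(nj, m) }
        else if (ni > n || nj > m) break
        if (!M[ni, nj]) break
        len <- len + 1L
      }
      runs[[length(runs) + 1L]] <- c(i, j, len)
    }
  }
  out <- as.data.frame(do.call(rbind, runs))
  names(out) <- c("i", "j", "len")
  unique(out)
}

# greedy left-to-right selection of non-overlapping runs
.selectRuns <- function(runs, n, m, minLen, circular) {
  runs <- runs[runs$len >= minLen, , drop = FALSE]
  if (!nrow(runs)) return(runs)
  runs <- runs[order(runs$i, -runs$len), , drop = FALSE]
  wrap <- function(x, nn) ((x - 1L) %% nn) + 1L
  usedA <- logical(n); usedB <- logical(m)
  keep <- logical(nrow(runs))
  posOf <- function(start, len, nn) {
    p <- start + 0:(len - 1L)
    if (circular) wrap(p, nn) else p
  }
  for (r in seq_len(nrow(runs))) {
    pa <- posOf(runs$i[r], runs$len[r], n)
    pb <- posOf(runs$j[r], runs$len[r], m)
    if (any(usedA[pa]) || any(usedB[pb])) next
    usedA[pa] <- TRUE; usedB[pb] <- TRUE
    keep[r] <- TRUE
  }
  runs[keep, , drop = FALSE]
}

.clusterFromRun <- function(run, la, ia, ib, m, orientation, circular, nF, mF) {
  wrap <- function(x, nn) ((x - 1L) %% nn) + 1L
  pa <- run$i + 0:(run$len - 1L)
  pb <- run$j + 0:(run$len - 1L)
  if (circular) { pa <- wrap(pa, nF); pb <- wrap(pb, mF) }
  posB <- if (orientation == "reversed") ib[mF - pb + 1L] else ib[pb]
  list(labels = la[pa],
       posA = ia[pa],
       posB = posB,
       orientation = orientation)
}

#' Maximal gene clusters shared by two gene orders
#'
#' Finds all maximal runs of genes that appear contiguously and in the
#' same relative order (and compatible strand) in both orders, after
#' making genes private to one order transparent: a cluster may span
#' positions where the other genome interleaves its own private tRNAs.
#' Duplicated labels are matched greedily left-to-right; circular orders
#' are compared over all rotations.
#'
#' @param a,b [GeneOrder-class] objects.
#' @param minLen minimum cluster length (genes).
#' @return list of cluster matches; each has `labels`, `posA`, `posB`
#'   (positions in the original orders) and `orientation = "same"`.
#' @export
sharedClusters <- function(a, b, minLen = 2L) {
  la <- a@labels; lb <- b@labels
  if (!length(la) || !length(lb)) stop("empty gene order")
  f <- .sharedFilter(la, lb)
  if (!length(f$ia)) return(list())
  circ <- a@circular && b@circular
  runs <- .maximalRuns(la[f$ia], a@strand[f$ia], lb[f$ib], b@strand[f$ib], circ)
  sel <- .selectRuns(runs, length(f$ia), length(f$ib), minLen, circ)
  lapply(seq_len(nrow(sel)), function(r)
    .clusterFromRun(sel[r, ], la[f$ia], f$ia, f$ib, length(f$ib),
                    "same", circ, length(f$ia), length(f$ib)))
}

#' Maximal reversed gene clusters between two gene orders
#'
#' As [sharedClusters()], but the occurrence in `b` is the exact reverse
#' of the occurrence in `a` (with flipped strand where strands are
#' recorded; NA strands match either way).  Runs that already qualify as
#' same-orientation clusters are excluded.
#'
#' @inheritParams sharedClusters
#' @return list of cluster matches with `orientation = "reversed"`.
#' @export
reversedClusters <- function(a, b, minLen = 2L) {
  la <- a@labels; lb <- b@labels
  if (!length(la) || !length(lb)) stop("empty gene order")
  f <- .sharedFilter(la, lb)
  if (!length(f$ia)) return(list())
  circ <- a@circular && b@circular
  fb <- lb[f$ib]; sb <- b@strand[f$ib]
  mF <- length(fb)
  rb <- rev(fb); rs <- .flipStrand(rev(sb))
  runs <- .maximalRuns(la[f$ia], a@strand[f$ia], rb, rs, circ)
  sel <- .selectRuns(runs, length(f$ia), mF, minLen, circ)
  out <- lapply(seq_len(nrow(sel)), function(r)
    .clusterFromRun(sel[r, ], la[f$ia], f$ia, f$ib, mF,
                    "reversed", circ, length(f$ia), mF))
  # drop runs whose positions coincide with a same-orientation cluster
  same <- sharedClusters(a, b, minLen)
  if (length(same)) {
    sameSets <- lapply(same, function(cl) list(A = sort(cl$posA), B = sort(cl$posB)))
    out <- Filter(function(cl) {
      !any(vapply(sameSets, function(ss)
        all(sort(cl$posA) %in% ss$A) && all(sort(cl$posB) %in% ss$B),
        logical(1)))
    }, out)
  }
  out
}

#' Validate a cluster match by direct replay
#'
#' Checks that the cluster's genes are contiguous (under the
#' transparency rule) at the reported positions in both orders and that
#' the `b` occurrence is the exact reverse for reversed matches.
#'
#' @param a,b the compared [GeneOrder-class] objects.
#' @param cluster one element of the [sharedClusters()] /
#'   [reversedClusters()] output.
#' @return TRUE, or FALSE with attribute "reason".
#' @export
validateClusterMatch <- function(a, b, cluster) {
  fail <- function(why) structure(FALSE, reason = why)
  f <- .sharedFilter(a@labels, b@labels)
  contiguous <- function(pos, idx, circular) {
    r <- match(pos, idx)
    if (anyNA(r)) return(FALSE)
    n <- length(idx)
    d <- diff(r)
    if (all(d == 1L)) return(TRUE)
    circular && sum(d != 1L) == 1L && all(d[d != 1L] == 1L - n)
  }
  if (!identical(unname(a@labels[cluster$posA]), unname(cluster$labels)))
    return(fail("labels mismatch in a"))
  # posB is stored in a-run order (descending in b for reversed matches)
  if (!identical(unname(b@labels[cluster$posB]), unname(cluster$labels)))
    return(fail("labels mismatch in b"))
  circ <- a@circular && b@circular
  if (!contiguous(cluster$posA, f$ia, circ)) return(fail("not contiguous in a"))
  posBrun <- if (cluster$orientation == "reversed") rev(cluster$posB) else cluster$posB
  if (!contiguous(posBrun, f$ib, circ)) return(fail("not contiguous in b"))
  TRUE
}

#' Genes present in only one of two orders
#'
#' Multiset-aware difference: copy counts are respected, so a gene with
#' two copies in `a` and one in `b` contributes one copy to the a-only
#' side.
#' @param a,b [GeneOrder-class] objects.
#' @return list with `only_a` and `only_b` (character vectors, one entry
#'   per surplus copy).
#' @export
noncommonGenes <- function(a, b) {
  ta <- table(a@labels); tb <- table(b@labels)
  alls <- union(names(ta), names(tb))
  onlyA <- onlyB <- character(0)
  for (l in alls) {
    ca <- if (l %in% names(ta)) ta[[l]] else 0L
    cb <- if (l %in% names(tb)) tb[[l]] else 0L
    if (ca > cb) onlyA <- c(onlyA, rep(l, ca - cb))
    if (cb > ca) onlyB <- c(onlyB, rep(l, cb - ca))
  }
  list(only_a = onlyA, only_b = onlyB)
}

#' Duplicated genes in an order
#' @param order a [GeneOrder-class].
#' @return named integer vector of labels with count >= 2 (empty if none).
#' @export
findDuplicates <- function(order) {
  tab <- table(order@labels)
  tab <- tab[tab >= 2L]
  structure(as.integer(tab), names = names(tab))
}

## ---- TDRL ---------------------------------------------------------------

#' Apply a single TDRL event to a label sequence
#'
#' Duplicates the contiguous block in tandem, then keeps, for each block
#' position, the first copy, the second copy, or both.
#'
#' @param labels character vector (source order).
#' @param event list with `blockStart`, `blockEnd` (1-based indices into
#'   `labels`) and `retention` (character vector over block positions,
#'   each "first", "second" or "both").
#' @return character vector, the resulting order.
#' @export
applyTdrl <- function(labels, event) {
  i <- event$blockStart; j <- event$blockEnd
  stopifnot(i >= 1L, j >= i, j <= length(labels),
            length(event$retention) == j - i + 1L)
  pre <- if (i > 1L) labels[1:(i - 1L)] else character(0)
  post <- if (j < length(labels)) labels[(j + 1L):length(labels)] else character(0)
  blk <- labels[i:j]
  first <- event$retention %in% c("first", "both")
  second <- event$retention %in% c("second", "both")
  c(pre, blk[first], blk[second], post)
}

#' Single-TDRL events explaining one order from another
#'
#' Exhaustive search over single tandem-duplication-random-loss events:
#' duplicate one contiguous block of at most `maxBlock` genes of `a`,
#' then lose one copy of each duplicated gene (optionally keeping both
#' copies of genes that are duplicated in `b`), such that the result
#' equals `b` on the shared label set.  Genes private to one order are
#' transparent.  Returns an empty list when no single event explains `b`
#' (including when a = b, where no event is needed).
#'
#' @param a,b [GeneOrder-class] objects sharing at least 2 labels.
#' @param maxBlock maximum duplicated block length.
#' @param maxEvals search-space cap; exceeding it is an error advising a
#'   smaller window.
#' @return list of events; each has `blockStart`, `blockEnd`,
#'   `blockLabels`, `retention` and `result` (the replayed order), with
#'   indices referring to the shared-label subsequence of `a` (also
#'   returned as `sourceShared`).
#' @export
tdrlCandidates <- function(a, b, maxBlock = 6L, maxEvals = 2e5) {
  la <- a@labels; lb <- b@labels
  shared <- intersect(la, lb)
  if (length(shared) < 2L) stop("orders share fewer than 2 labels")
  fa <- la[la %in% shared]
  fb <- lb[lb %in% shared]
  if (identical(fa, fb)) return(list())
  n <- length(fa)
  countB <- table(fb); countA <- table(fa)
  blocks <- list()
  for (i in seq_len(n)) {
    for (j in i:min(n, i + maxBlock - 1L)) blocks[[length(blocks) + 1L]] <- c(i, j)
  }
  totalEvals <- sum(vapply(blocks, function(bk) 3^(bk[2] - bk[1] + 1), numeric(1)))
  if (totalEvals > maxEvals)
    stop("TDRL search space too large (", format(totalEvals, big.mark = ","),
         " candidate events); reduce maxBlock or the window size")
  out <- list()
  seen <- character(0)
  for (bk in blocks) {
    i <- bk[1]; j <- bk[2]
    blk <- fa[i:j]
    choiceList <- lapply(blk, function(l) {
      cb <- if (l %in% names(countB)) countB[[l]] else 0L
      ca <- countA[[l]]
      if (cb > ca) c("first", "second", "both") else c("first", "second")
    })
    grid <- expand.grid(choiceList, stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      retention <- as.character(grid[g, ])
      if (n + sum(retention == "both") != length(fb)) next
      ev <- list(blockStart = i, blockEnd = j, retention = retention)
      res <- applyTdrl(fa, ev)
      if (!identical(res, fb)) next
      key <- paste(i, j, paste(retention, collapse = ","))
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(blockStart = i, blockEnd = j,
                                      blockLabels = blk,
                                      retention = retention,
                                      result = res, sourceShared = fa)
    }
  }
  out
}

#' Gene-order comparison report
#'
#' Bundles shared clusters, reversed clusters, noncommon genes,
#' duplicates, and TDRL candidates for two orders.
#' @param a,b [GeneOrder-class] objects.
#' @param minLen minimum cluster length.
#' @param maxBlock maximum TDRL block length.
#' @return list with components `shared_clusters`, `reversed_clusters`,
#'   `noncommon`, `duplicates_a`, `duplicates_b`, `tdrl_candidates`.
#' @export
compareGeneOrders <- function(a, b, minLen = 2L, maxBlock = 6L) {
  tdrl <- tryCatch(tdrlCandidates(a, b, maxBlock),
                   error = function(e) list())
  list(shared_clusters = sharedClusters(a, b, minLen),
       reversed_clusters = reversedClusters(a, b, minLen),
       noncommon = noncommonGenes(a, b),
       duplicates_a = findDuplicates(a),
       duplicates_b = findDuplicates(b),
       tdrl_candidates = tdrl)
}
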