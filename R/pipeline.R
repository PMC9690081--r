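# Orchestration: run the full two-genome comparison from a config into a
# report bundle of TSV/JSON files plus a run log.

#' Read a flat key=value config file
#'
#' Lines of the form `key = value`; blank lines and lines starting with
#' `#` are ignored.  Keys taking multiple values (e.g. `references`)
#' separate them with commas.
#' @param path config file.
#' @return named list of character values.
#' @export
readRunConfig <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !grepl("^#", ln)]
  kv <- strsplit(ln, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("unparseable config line(s): ", paste(ln[bad], collapse = "; "))
  out <- lapply(kv, `[`, 2L)
  names(out) <- vapply(kv, `[`, "", 1L)
  out
}

.loadGenomeFile <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^LOCUS", first)) readGenBank(path)
  else if (grepl("^>", first)) {
    s <- readFastaSeqs(path)
    annotatedGenome(id = names(s)[1], sequence = s[[1]],
                    circular = TRUE, sourceFormat = "fasta")
  } else stop("unrecognised genome file format: ", path)
}

#' Run the full two-genome comparison pipeline
#'
#' Stages: per-genome composition and feature-class tables, start/stop
#' profiles, codon-usage tables with RSCU, pairwise Ka/Ks of the query
#' pair against each other and against the references, and the
#' gene-order comparison (clusters, noncommon genes, duplicates, TDRL
#' candidates).  Each stage's outputs are written as TSV/JSON into the
#' output directory together with `summary.json` (headline numbers) and
#' `run.log`.  Stage errors are logged with the stage name; stages that
#' can proceed do.  Outputs are deterministic for fixed inputs and
#' config (timestamps confined to the log).
#'
#' @param config named list (or path to a key=value file, see
#'   [readRunConfig()]) with entries: `query1`, `query2` (paths to
#'   GenBank/FASTA genomes) or `genome1`, `genome2`
#'   ([AnnotatedGenome-class] objects); optional `references` (paths or
#'   list of genomes), `code` (1/5), `rscu_partition`
#'   ("table8-standard"/"table5-mito"), `method` ("YN00"/"NG86"),
#'   `min_cluster_len`, `max_tdrl_block`, `outdir`.
#' @return invisibly, the summary list; side effect: the report bundle
#'   in `outdir`.
#' @export
runCompare <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- readRunConfig(config)
  cfg <- list(code = 5L, rscu_partition = "table8-standard", method = "YN00",
              min_cluster_len = 2L, max_tdrl_block = 6L,
              outdir = file.path(tempdir(), "mitocompare_run"),
              references = NULL)
  cfg[names(config)] <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outdir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  logMsg <- function(stage, ...) {
    writeLines(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                       stage, paste0(...)), logCon)
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, message = function(m) {
      logMsg(name, "note: ", conditionMessage(m))
      invokeRestart("muffleMessage")
    }, warning = function(w) {
      logMsg(name, "warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      logMsg(name, "ERROR: ", conditionMessage(e))
      NULL
    })
  }
  code <- geneticCode(as.integer(cfg$code), cfg$rscu_partition)

  g1 <- if (!is.null(cfg$genome1)) cfg$genome1 else .loadGenomeFile(cfg$query1)
  g2 <- if (!is.null(cfg$genome2)) cfg$genome2 else .loadGenomeFile(cfg$query2)
  refs <- list()
  if (!is.null(cfg$references)) {
    refs <- if (is.character(cfg$references))
      lapply(strsplit(cfg$references, ",")[[1]], .loadGenomeFile)
    else cfg$references
  }
  logMsg("load", sprintf("query %s (%d bp), %s (%d bp), %d reference(s)",
                         g1@id, nchar(g1@sequence), g2@id, nchar(g2@sequence),
                         length(refs)))
  summary <- list(query1 = g1@id, query2 = g2@id,
                  references = vapply(refs, genomeId, ""))

  for (g in list(g1, g2)) {
    comp <- stage(paste0("composition/", g@id), featureClassSummary(g))
    if (!is.null(comp)) {
      writeCompositionTable(comp, file.path(cfg$outdir,
                                            paste0("composition_", g@id, ".tsv")))
      summary[[paste0("size_bp_", g@id)]] <- nchar(g@sequence)
      summary[[paste0("AT_pct_", g@id)]] <-
        round(comp$AT_pct[comp$class == "whole_genome"], 2)
    }
    ss <- stage(paste0("startstop/", g@id), startStopTable(g, code))
    if (!is.null(ss))
      utils::write.table(ss, file.path(cfg$outdir, paste0("startstop_", g@id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    cu <- stage(paste0("codonusage/", g@id), codonUsage(g, code))
    if (!is.null(cu)) {
      writeCodonUsageTable(cu, file.path(cfg$outdir,
                                         paste0("codon_usage_", g@id, ".tsv")))
      summary[[paste0("total_codons_", g@id)]] <- cu@totalCodons
    }
  }

  kk <- stage("kaks", {
    targets <- c(list(g2), refs)
    do.call(rbind, lapply(targets, function(r)
      pairwiseKaKsMatrix(g1, r, method = cfg$method, code = code)))
  })
  if (!is.null(kk)) {
    num <- vapply(kk, is.numeric, logical(1))
    kk[num] <- lapply(kk[num], function(x) round(x, 6))
    utils::write.table(kk, file.path(cfg$outdir, "kaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ok <- is.finite(kk$KaKs)
    if (any(ok)) {
      top <- kk[ok, ][which.max(kk$KaKs[ok]), ]
      summary$max_kaks <- list(gene = top$gene, pair = top$pair,
                               value = round(top$KaKs, 3))
    }
    summary$n_kaks_rows <- nrow(kk)
  }

  go <- stage("geneorder", {
    oa <- geneOrderOf(g1); ob <- geneOrderOf(g2)
    compareGeneOrders(oa, ob, minLen = as.integer(cfg$min_cluster_len),
                      maxBlock = as.integer(cfg$max_tdrl_block))
  })
  if (!is.null(go)) {
    rep <- list(
      shared_clusters = lapply(go$shared_clusters, function(cl)
        list(labels = cl$labels, posA = cl$posA, posB = cl$posB)),
      reversed_clusters = lapply(go$reversed_clusters, function(cl)
        list(labels = cl$labels, posA = cl$posA, posB = cl$posB)),
      noncommon = go$noncommon,
      duplicates_a = as.list(go$duplicates_a),
      duplicates_b = as.list(go$duplicates_b),
      n_tdrl_candidates = length(go$tdrl_candidates))
    jsonlite::write_json(rep, file.path(cfg$outdir, "gene_order.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    summary$n_shared_clusters <- length(go$shared_clusters)
    summary$n_reversed_clusters <- length(go$reversed_clusters)
    summary$n_only_query1 <- length(go$noncommon$only_a)
    summary$n_only_query2 <- length(go$noncommon$only_b)
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logMsg("done", "bundle written to ", cfg$outdir)
  invisible(summary)
}
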