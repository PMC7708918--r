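# End-to-end pipeline: markers -> identity -> popgen -> parentage, writing
# versioned CSV/JSON outputs with a MANIFEST of content digests and a run log.

#' Run the analysis pipeline
#'
#' Executes the configured stages over a genotype table (and optionally an
#' SV VCF), writing CSV/JSON outputs, a run log and a MANIFEST listing every
#' output file with its MD5 content digest and the run status. Idempotent
#' for fixed inputs and seed. On a stage failure, partial outputs are
#' preserved, the MANIFEST is marked incomplete, and the error is re-raised.
#'
#' @param config a list or path to a YAML file with fields:
#'   `genotype_table` (path or `genotype_table` object), optional `sv_vcf`,
#'   `outdir` (required), `stages` (subset of "markers", "identity",
#'   "popgen", "parentage"; default all applicable), `seed` (default 1),
#'   and optional parameter blocks `markers` (`min_len`, `max_len`,
#'   `per_chrom`, `dyes`, `size_gap`, `max_group_size`), `identity`
#'   (`match_mode`), `popgen` (`grouping`, `k_patterns`, `estimator`),
#'   `parentage` (`mode`, `min_confidence`, `threshold`).
#' @return list of class `pipeline_result` with per-stage results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stop("config$outdir is required")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, "w")
  # no timestamps: report bundles must be byte-identical across re-runs
  logmsg <- function(...) writeLines(paste0("INFO ", ...), log_con)
  on.exit(close(log_con), add = TRUE)
  logmsg("gikit ", as.character(utils::packageVersion("gikit")),
         " pipeline start; seed = ", seed)

  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)
  results <- list()
  stages_run <- character(0)
  status <- "complete"

  tab <- NULL
  if (!is.null(config$genotype_table)) {
    tab <- if (inherits(config$genotype_table, "genotype_table"))
      config$genotype_table else read_genotype_table(config$genotype_table)
  }
  stages <- config$stages
  if (is.null(stages))
    stages <- c(if (!is.null(config$sv_vcf)) "markers",
                if (!is.null(tab)) c("identity", "popgen", "parentage"))

  write_manifest <- function(status, skipped) {
    manifest <- data.frame(
      file = basename(outputs),
      md5 = unname(tools::md5sum(outputs)),
      stringsAsFactors = FALSE)
    mpath <- file.path(outdir, "MANIFEST.tsv")
    con <- file(mpath, "w")
    writeLines(c(paste0("# status: ", status),
                 paste0("# stages_run: ", paste(stages_run, collapse = ",")),
                 paste0("# stages_skipped: ", paste(skipped, collapse = ",")),
                 paste0("# seed: ", seed)), con)
    utils::write.table(manifest, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    manifest
  }

  run_stage <- function(name, fn) {
    logmsg("stage ", name, " start")
    results[[name]] <<- fn()
    stages_run <<- c(stages_run, name)
    logmsg("stage ", name, " done")
  }

  all_stages <- c("markers", "identity", "popgen", "parentage")
  tryCatch({
    if ("markers" %in% stages) run_stage("markers", function() {
      mp <- config$markers
      recs <- read_sv_vcf(config$sv_vcf)
      sv_sum <- summarize_svs(recs)
      cand <- filter_indel_candidates(
        recs,
        min_len = mp$min_len %||% 50, max_len = mp$max_len %||% 400)
      panel <- select_panel(cand, per_chrom = mp$per_chrom %||% 10)
      panel <- design_multiplex(
        panel, dyes = mp$dyes %||% c("FAM", "HEX", "NED", "PET"),
        size_gap = mp$size_gap %||% 20,
        max_group_size = mp$max_group_size %||% 24)
      emit(write_panel_tsv(panel, file.path(outdir, "marker_panel.tsv")))
      emit(write_panel_bed(panel, file.path(outdir, "marker_panel.bed")))
      counts_path <- file.path(outdir, "sv_summary.csv")
      utils::write.csv(data.frame(svtype = names(sv_sum$counts),
                                  n = as.integer(sv_sum$counts),
                                  fraction_50_400 = sv_sum$fraction_in_range),
                       counts_path, row.names = FALSE)
      emit(counts_path)
      list(summary = sv_sum, panel = panel)
    })
    if ("identity" %in% stages) run_stage("identity", function() {
      mode <- (config$identity$match_mode) %||% "exact"
      groups <- group_by_signature(tab, match_mode = mode)
      cls <- classify_names(groups, tab$accessions,
                            alias_map = config$identity$alias_map)
      gpath <- file.path(outdir, "identity_groups.csv")
      utils::write.csv(data.frame(
        accession_id = names(groups$membership),
        group = unname(groups$membership),
        group_size = lengths(groups$groups)[groups$membership],
        name_class = unname(cls$labels[names(groups$membership)])),
        gpath, row.names = FALSE)
      emit(gpath)
      sports <- sport_discrimination(tab)
      if (!is.null(sports)) {
        spath <- file.path(outdir, "sport_discrimination.csv")
        utils::write.csv(as.data.frame(sports), spath, row.names = FALSE)
        emit(spath)
      }
      list(groups = groups, names = cls, sports = sports)
    })
    if ("popgen" %in% stages) run_stage("popgen", function() {
      pg <- config$popgen
      grouping <- pg$grouping %||% "species"
      rec <- recode_biallelic(tab)
      div <- summarize_population(tab, grouping = grouping)
      dpath <- file.path(outdir, "diversity.csv")
      utils::write.csv(as.data.frame(div), dpath, row.names = FALSE)
      emit(dpath)
      fm <- fst_matrix(tab, grouping = grouping,
                       estimator = pg$estimator %||% "wc84")
      fpath <- file.path(outdir, "fst_matrix.csv")
      utils::write.csv(fm$fst, fpath, row.names = TRUE)
      emit(fpath)
      ppath <- file.path(outdir, "fst_pvalues.csv")
      utils::write.csv(fm$p_value, ppath, row.names = TRUE)
      emit(ppath)
      hwe <- hwe_test(rec, grouping = grouping)
      hpath <- file.path(outdir, "hwe_pvalues.csv")
      utils::write.csv(hwe, hpath, row.names = TRUE)
      emit(hpath)
      gm <- genotype_frequency_matrix(rec, grouping = grouping)
      gmpath <- file.path(outdir, "genotype_frequency_matrix.csv")
      utils::write.csv(gm, gmpath, row.names = TRUE)
      emit(gmpath)
      pat <- classify_patterns(gm, k = pg$k_patterns %||% 5)
      papath <- file.path(outdir, "genotype_patterns.csv")
      utils::write.csv(pat$assignment, papath, row.names = FALSE)
      emit(papath)
      list(diversity = div, fst = fm, hwe = hwe, patterns = pat)
    })
    if ("parentage" %in% stages) run_stage("parentage", function() {
      pp <- config$parentage
      scan <- scan_parentage(tab, focal = pp$focal,
                             mode = pp$mode %||% "trio",
                             min_confidence = pp$min_confidence %||% 0.98,
                             threshold = pp$threshold %||% 1)
      emit(write_parentage_csv(scan, file.path(outdir, "parentage.csv")))
      scan
    })
  }, error = function(e) {
    status <<- "incomplete"
    logmsg("ERROR: ", conditionMessage(e))
    write_manifest("incomplete", setdiff(intersect(stages, all_stages),
                                         stages_run))
    stop(e)
  })
  flush(log_con)
  emit(log_path)
  manifest <- write_manifest(status, setdiff(all_stages, stages_run))
  logmsg("pipeline complete")
  structure(list(results = results, manifest = manifest, outdir = outdir,
                 status = status, stages_run = stages_run),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run (", x$status, "): stages ",
      paste(x$stages_run, collapse = ", "), "\n", sep = "")
  cat("  outputs in ", x$outdir, ":\n", sep = "")
  cat(paste0("    ", x$manifest$file, collapse = "\n"), "\n")
  invisible(x)
}

#' Verify a pipeline output directory against its MANIFEST
#'
#' @param outdir directory written by [run_pipeline()].
#' @return TRUE invisibly when every listed digest matches; errors otherwise.
#' @export
verify_manifest <- function(outdir) {
  mpath <- file.path(outdir, "MANIFEST.tsv")
  if (!file.exists(mpath)) stop("no MANIFEST.tsv in ", outdir)
  man <- utils::read.table(mpath, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  man <- man[man$file != "run.log", , drop = FALSE]  # log carries timestamps
  now <- unname(tools::md5sum(file.path(outdir, man$file)))
  bad <- man$file[is.na(now) | now != man$md5]
  if (length(bad)) stop("digest mismatch for: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
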