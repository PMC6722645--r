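#' Pipeline configuration
#'
#' All tunables of the analysis in one flat list: significance filter
#' thresholds, proximal-window half-width, intersection flags, enrichment
#' test options, sponge significance level and clustering linkage. The
#' resolved configuration is written as JSON next to every run's outputs
#' and round-trips through [jsonlite].
#'
#' @param fdr_max,pvalue_max Significance filter (see [filter_config()]).
#' @param window Proximal-window half-width in bp.
#' @param min_overlap Minimum overlap in bp for a binding hit.
#' @param stranded Strand-aware intersection.
#' @param strict Reject mixed chromosome-naming conventions.
#' @param alternative Fisher sidedness (`"greater"` default).
#' @param method p-adjustment method (`"BH"`, `"bonferroni"`, `"BY"`).
#' @param per_gene Gene-level instead of region-level contingency counts.
#' @param alpha Adjusted-p significance level for sponge breadth.
#' @param linkage Clustering linkage (`"average"` default).
#' @param event_types Event types carried through the pipeline.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr_max = 0.1, pvalue_max = 0.05, window = 500,
                            min_overlap = 1, stranded = FALSE,
                            strict = TRUE, alternative = "greater",
                            method = "BH", per_gene = FALSE, alpha = 0.05,
                            linkage = "average",
                            event_types = c("SE", "RI")) {
  cfg <- as.list(environment())
  stopifnot(all(event_types %in% .event_types))
  structure(cfg, class = "pipeline_config")
}

.stage_order <- c("filter", "matrix", "regions", "intersect", "enrich",
                  "sponge", "correlate")

.need <- function(path, stage, wanted_by) {
  if (!file.exists(path))
    stop("missing '", path, "': run stage '", stage, "' before '",
         wanted_by, "'")
  path
}

#' Run the knockdown-splicing analysis pipeline
#'
#' Executes the stages `filter -> matrix -> regions -> intersect ->
#' enrich -> sponge -> correlate` (or any contiguous subset) over a study
#' directory containing `sample_sheet.tsv` and `peaks/manifest.tsv`
#' (the layout [simulate_splicing_study()] writes). Every stage reads its
#' inputs from, and writes plain TSV outputs to, `out_dir`, so any stage
#' can be inspected or re-run; re-running a stage on unchanged inputs is
#' byte-identical. The resolved configuration is saved as
#' `config.json`.
#'
#' @param input_dir Study directory (sample sheet, rMATS tables, peaks).
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run, or `"all"`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results of the stages run.
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config(),
                         stages = "all", quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- .stage_order
  stopifnot(all(stages %in% .stage_order))
  stages <- .stage_order[.stage_order %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say <- function(...) if (!quiet) message(...)
  res <- list()
  sheet <- read_sample_sheet(file.path(input_dir, "sample_sheet.tsv"))
  fc <- filter_config(fdr_max = config$fdr_max,
                      pvalue_max = config$pvalue_max)

  read_filtered <- function() {
    dirp <- .need(file.path(out_dir, "filtered"), "filter",
                  "a downstream stage")
    out <- lapply(sheet$comparison_id, function(id) {
      do.call(rbind, lapply(config$event_types, function(ty) {
        p <- file.path(dirp, paste0(id, "_", ty, ".txt"))
        if (file.exists(p)) read_rmats_table(p, ty) else .empty_events()
      }))
    })
    stats::setNames(out, sheet$comparison_id)
  }

  if ("filter" %in% stages) {
    dir.create(file.path(out_dir, "filtered"), showWarnings = FALSE)
    n_in <- 0L; n_out <- 0L
    for (i in seq_len(nrow(sheet))) {
      for (ty in config$event_types) {
        pc <- paste0(tolower(ty), "_path")
        if (!pc %in% names(sheet) || is.na(sheet[[pc]][i])) next
        ev <- read_rmats_table(sheet[[pc]][i], ty)
        keep <- filter_events(ev, fc)
        n_in <- n_in + nrow(ev); n_out <- n_out + nrow(keep)
        write_rmats_table(keep, file.path(out_dir, "filtered",
                                          paste0(sheet$comparison_id[i],
                                                 "_", ty, ".txt")),
                          event_type = ty)
      }
    }
    say("filter: ", n_out, "/", n_in, " events significant (fdr < ",
        config$fdr_max, ", p < ", config$pvalue_max, ")")
  }

  if ("matrix" %in% stages) {
    filtered <- read_filtered()
    res$matrices <- list()
    for (ty in config$event_types) {
      m <- build_frequency_matrix(filtered, sheet, ty)
      res$matrices[[ty]] <- m
      write_matrix_tsv(m, file.path(out_dir, paste0("matrix_", ty, ".tsv")))
      if (length(unique(sheet$cell_line)) >= 1L) {
        sp <- specificity_summary(m)
        jsonlite::write_json(
          list(n_genes = sp$n_genes,
               genes_per_cell_line = lapply(sp$gene_sets, length),
               exclusive_counts = as.list(sp$exclusive_counts),
               intersection_counts = as.list(sp$intersection_counts),
               shared_genes = sp$shared_genes,
               shared_fraction = sp$shared_fraction,
               note = sp$note),
          file.path(out_dir, paste0("specificity_", ty, ".json")),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
        res$specificity[[ty]] <- sp
      }
      say("matrix: ", ty, " ", nrow(m$counts), " genes x ",
          ncol(m$counts), " knockdowns")
    }
  }

  if ("regions" %in% stages) {
    filtered <- read_filtered()
    regs <- do.call(rbind, lapply(sheet$comparison_id, function(id) {
      regions_for_comparison(filtered[[id]],
                             lncrna = sheet$lncrna[sheet$comparison_id == id],
                             cell_line = sheet$cell_line[
                               sheet$comparison_id == id],
                             window = config$window)
    }))
    utils::write.table(regs, file.path(out_dir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_bed(regs, file.path(out_dir, "regions.bed"))
    res$regions <- regs
    say("regions: ", nrow(regs), " proximal windows (+/-", config$window,
        " bp) from ", nrow(regs) / 6L, " events")
  }

  if ("intersect" %in% stages) {
    regs <- utils::read.delim(.need(file.path(out_dir, "regions.tsv"),
                                    "regions", "intersect"),
                              stringsAsFactors = FALSE)
    manifest_path <- file.path(input_dir, "peaks", "manifest.tsv")
    if (!file.exists(manifest_path))
      stop("no peaks/manifest.tsv in ", input_dir)
    manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
    peaks <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
      read_peaks_bed(file.path(input_dir, manifest$path[i]),
                     rbp = manifest$rbp[i],
                     cell_line = manifest$cell_line[i])
    }))
    bfs <- bound_flags(regs, peaks, min_overlap = config$min_overlap,
                       stranded = config$stranded, strict = config$strict)
    # only cell lines with peak data carry flags downstream
    bfs <- Filter(function(bf) ncol(bf$flags) > 0L, bfs)
    for (cl in names(bfs)) {
      fl <- bfs[[cl]]$flags
      utils::write.table(
        data.frame(region_uid = rownames(fl), fl, check.names = FALSE),
        file.path(out_dir, paste0("flags_", cl, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      say("intersect: ", cl, " ", sum(fl), " bound (region, RBP) pairs of ",
          length(fl))
    }
    res$flags <- bfs
  }

  if ("enrich" %in% stages) {
    flag_files <- list.files(out_dir, pattern = "^flags_.*\\.tsv$",
                             full.names = TRUE)
    if (length(flag_files) == 0L)
      stop("no flags_<cell_line>.tsv in ", out_dir,
           ": run stage 'intersect' before 'enrich'")
    regs <- utils::read.delim(.need(file.path(out_dir, "regions.tsv"),
                                    "regions", "enrich"),
                              stringsAsFactors = FALSE)
    res$enrichment <- list()
    for (ff in flag_files) {
      cl <- sub("^flags_(.*)\\.tsv$", "\\1", basename(ff))
      tab <- utils::read.delim(ff, check.names = FALSE,
                               stringsAsFactors = FALSE)
      fl <- as.matrix(tab[, -1, drop = FALSE])
      storage.mode(fl) <- "logical"
      rownames(fl) <- tab$region_uid
      reg_cl <- regs[regs$cell_line == cl, , drop = FALSE]
      if (!identical(.region_uid(reg_cl), rownames(fl)))
        stop("flags and regions out of sync for ", cl,
             ": re-run 'regions' and 'intersect'")
      bf <- structure(list(cell_line = cl, regions = reg_cl, flags = fl),
                      class = "binding_flags")
      er <- run_enrichment(bf, alternative = config$alternative,
                           method = config$method, alpha = config$alpha,
                           per_gene = config$per_gene)
      write_enrichment_tsv(er, file.path(out_dir,
                                         paste0("enrichment_", cl, ".tsv")))
      hm <- enrichment_heatmap_matrix(er, cluster = TRUE,
                                      linkage = config$linkage)
      utils::write.table(
        data.frame(lncrna = rownames(hm), hm, check.names = FALSE),
        file.path(out_dir, paste0("heatmap_", cl, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
      res$enrichment[[cl]] <- er
      say("enrich: ", cl, " ", sum(!is.na(er$p_adjusted)),
          " tests performed, ",
          sum(er$p_adjusted < config$alpha, na.rm = TRUE),
          " significant at adjusted p < ", config$alpha)
    }
  }

  if ("sponge" %in% stages) {
    enr_files <- list.files(out_dir, pattern = "^enrichment_.*\\.tsv$",
                            full.names = TRUE)
    if (length(enr_files) == 0L)
      stop("no enrichment_<cell_line>.tsv in ", out_dir,
           ": run stage 'enrich' before 'sponge'")
    results <- do.call(rbind, lapply(enr_files, function(f)
      utils::read.delim(f, stringsAsFactors = FALSE)))
    prof <- sponge_scores(results, alpha = config$alpha)
    utils::write.table(prof, file.path(out_dir, "sponge_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    res$sponge <- prof
    say("sponge: top breadth ",
        if (nrow(prof) > 0L) sprintf("%.2f (%s in %s)", prof$breadth[1L],
                                     prof$lncrna[1L], prof$cell_line[1L])
        else "none")
  }

  if ("correlate" %in% stages) {
    prof_path <- .need(file.path(out_dir, "sponge_profiles.tsv"), "sponge",
                       "correlate")
    prof <- utils::read.delim(prof_path, stringsAsFactors = FALSE)
    m_path <- .need(file.path(out_dir, "matrix_SE.tsv"), "matrix",
                    "correlate")
    counts <- read_matrix_tsv(m_path)
    fm <- structure(list(event_type = "SE", counts = counts,
                         samples = sheet[, c("comparison_id", "lncrna",
                                             "cell_line")]),
                    class = "event_frequency_matrix")
    corr <- binding_splicing_correlation(fm, prof)
    utils::write.table(corr, file.path(out_dir, "correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    res$correlation <- corr
    say("correlate: ", paste(unique(corr$status), collapse = "; "))
  }

  invisible(res)
}
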