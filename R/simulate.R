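# Seeded generator for a synthetic lncRNA-knockdown splicing study:
# rMATS-dialect event tables per comparison, eCLIP-style BED peaks per
# (cell line, RBP), a sample sheet, an annotation GMT, and a ground-truth
# record of everything planted. Significance is planted by construction
# (p/fdr drawn on the correct side of the thresholds): the statistics of
# interest begin downstream of event calling, so the generator emulates
# event-caller output, not sequencing reads.
#
# Event geometry: each gene owns a territory of evenly spaced "slots"; a
# slot deterministically encodes the six exon coordinates of one event
# (exon length 1200 bp, inter-exon gap 1200 bp). All six anchors of an
# event are therefore >= 1200 bp apart and slots are 8000 bp apart, so
# +/-500 bp proximal windows never overlap and a peak planted at one
# anchor binds exactly one region — the planted flag table is exact.

.slot_stride <- 8000
.exon_len <- 1200
# Per-comparison slot block within a gene territory. Slots are unique per
# (gene, comparison-within-cell-line), so two knockdowns of the same cell
# line never report the same genomic event and planted binding flags stay
# independent across lncRNAs; the same gene and comparison index in a
# DIFFERENT cell line reuses the same coordinates, so shared genes yield
# genuine duplicate events across cell lines.
.comp_block <- 60L
.block_ranges <- list(sig_SE = 1:20, sig_RI = 21:34,
                      ns_SE = 35:48, ns_RI = 49:60)

#' Configuration for the synthetic knockdown study
#'
#' Defaults emulate the structure of the real study: 3 cell lines
#' (HeLa, K562, U87) with 13 lncRNA knockdowns each (39 comparisons),
#' eCLIP peaks available for HeLa and K562 only (U87 exercises the
#' no-binding-data path), ~7% of alternatively spliced genes shared
#' between cell lines, and one planted sponge lncRNA per peak-bearing
#' cell line binding 80% of its proximal windows per RBP against a 10%
#' background.
#'
#' @param seed Integer RNG seed; the whole simulation is a deterministic
#'   function of the config including the seed.
#' @param cell_lines Cell-line names.
#' @param peak_cell_lines Cell lines with eCLIP peaks (subset).
#' @param n_lncrnas_per_cell_line Knockdowns per cell line.
#' @param n_genes Size of the gene universe.
#' @param n_as_genes_per_cell_line Genes eligible for significant events
#'   per cell line.
#' @param n_events_per_comparison Events reported per comparison.
#' @param n_events_jitter Relative spread of per-comparison event counts:
#'   each comparison reports `round(n * U(1 - j, 1 + j))` events, so
#'   knockdowns differ in splicing burden as they do in real studies. Set
#'   to 0 for exactly `n` events in every comparison.
#' @param frac_significant Fraction of events passing the default filters;
#'   exactly `round(frac * n_comparison)` per comparison by construction.
#' @param se_fraction Fraction of events that are SE (rest RI).
#' @param cross_cell_line_sharing Target fraction of AS genes shared by
#'   >= 2 cell lines.
#' @param n_rbps Number of RBPs with peak files per peak cell line.
#' @param n_sponges_per_cell_line Planted sponge lncRNAs per peak cell
#'   line.
#' @param sponge_density Per-(window, RBP) binding probability for sponge
#'   lncRNAs.
#' @param background_density Same for all other lncRNAs.
#' @param saturated_rbps RBP names planted to bind every window
#'   (probability 1) — produce all-null heatmap columns.
#' @param window Proximal window half-width (bp).
#' @param n_chromosomes,chrom_length Genome model (defaults: 3 chromosomes
#'   of 250 Mb, the scale of large human chromosomes).
#' @param fdr_max,pvalue_max Filter thresholds the planted significance is
#'   keyed to.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       cell_lines = c("HeLa", "K562", "U87"),
                       peak_cell_lines = c("HeLa", "K562"),
                       n_lncrnas_per_cell_line = 13,
                       n_genes = 60,
                       n_as_genes_per_cell_line = 15,
                       n_events_per_comparison = 100,
                       n_events_jitter = 0.2,
                       frac_significant = 0.4,
                       se_fraction = 0.6,
                       cross_cell_line_sharing = 0.07,
                       n_rbps = 20,
                       n_sponges_per_cell_line = 1,
                       sponge_density = 0.8,
                       background_density = 0.1,
                       saturated_rbps = character(0),
                       window = 500,
                       n_chromosomes = 3,
                       chrom_length = 2.5e8,
                       fdr_max = 0.1,
                       pvalue_max = 0.05) {
  cfg <- as.list(environment())
  stopifnot(length(cell_lines) >= 1L,
            all(peak_cell_lines %in% cell_lines),
            frac_significant >= 0, frac_significant <= 1,
            n_events_jitter >= 0, n_events_jitter < 1,
            se_fraction >= 0, se_fraction <= 1,
            cross_cell_line_sharing >= 0, cross_cell_line_sharing <= 1,
            sponge_density >= 0, sponge_density <= 1,
            background_density >= 0, background_density <= 1,
            window > 0)
  if (cfg$n_sponges_per_cell_line > 0 &&
      cfg$sponge_density <= cfg$background_density)
    stop("planted designs need sponge_density > background_density")
  # genome feasibility: genes per chromosome at the territory spacing
  gene_stride <- (.comp_block * n_lncrnas_per_cell_line + 1L) * .slot_stride
  genes_per_chrom <- ceiling(n_genes / n_chromosomes)
  if (1e5 + genes_per_chrom * gene_stride > chrom_length)
    stop("infeasible geometry: ", n_genes, " gene territories of ",
         gene_stride, " bp do not fit on ", n_chromosomes,
         " chromosome(s) of length ", chrom_length)
  cfg$gene_stride <- gene_stride
  n_cl <- length(cell_lines)
  f <- cross_cell_line_sharing
  n_shared <- if (n_cl >= 2L) round(f * n_cl * n_as_genes_per_cell_line /
                                      (1 + f)) else 0L
  union_size <- n_cl * n_as_genes_per_cell_line - n_shared
  if (union_size > n_genes)
    stop("infeasible gene sets: need ", union_size,
         " distinct AS genes but n_genes = ", n_genes)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study config: ", length(x$cell_lines), " cell lines x ",
      x$n_lncrnas_per_cell_line, " knockdowns, ",
      x$n_events_per_comparison, " events/comparison (",
      round(100 * x$frac_significant), "% significant), ",
      x$n_rbps, " RBPs, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# slot -> six event coordinates within a gene territory
.slot_coords <- function(base, slot) {
  s0 <- base + (slot - 1L) * .slot_stride
  list(upstream_start = s0, upstream_end = s0 + .exon_len,
       target_start = s0 + 2L * .exon_len, target_end = s0 + 3L * .exon_len,
       downstream_start = s0 + 4L * .exon_len,
       downstream_end = s0 + 5L * .exon_len)
}

# Draw per-comparison gene multisets for one cell line guaranteeing that
# every gene of the set appears at least once across the cell line
# (when the total draw count allows it). n_per_comp is a vector, one
# count per comparison.
.coverage_draws <- function(gene_set, n_per_comp) {
  n_comp <- length(n_per_comp)
  total <- sum(n_per_comp)
  out <- replicate(n_comp, character(0), simplify = FALSE)
  if (total == 0L) return(out)
  pool <- if (total >= length(gene_set)) {
    c(gene_set, sample(gene_set, total - length(gene_set), replace = TRUE))
  } else sample(gene_set, total)
  pool <- sample(pool)
  idx <- rep(seq_len(n_comp), times = n_per_comp)
  for (ci in seq_len(n_comp)) out[[ci]] <- pool[idx == ci]
  out
}

.build_events_for_comparison <- function(genes_df, draws, slot_range,
                                         event_type, significant, cfg) {
  if (length(draws) == 0L) return(.empty_events())
  tab <- table(draws)
  if (any(tab > length(slot_range)))
    stop("infeasible geometry: ", max(tab), " ", event_type,
         " events drawn for one gene exceed its ", length(slot_range),
         " slots")
  gene <- rep(names(tab), times = tab)
  slot <- unlist(lapply(as.integer(tab),
                        function(k) slot_range[seq_len(k)]),
                 use.names = FALSE)
  gi <- match(gene, genes_df$gene_symbol)
  co <- .slot_coords(genes_df$base[gi], slot)
  n <- length(gene)
  if (significant) {
    p <- stats::runif(n, 0, cfg$pvalue_max / 2)
    fdr <- stats::runif(n, 0, cfg$fdr_max / 2)
  } else {
    p <- stats::runif(n, cfg$pvalue_max, 1)
    fdr <- stats::runif(n, cfg$fdr_max, 1)
  }
  ev <- data.frame(event_type = event_type,
                   gene_id = genes_df$gene_id[gi],
                   gene_symbol = gene,
                   chrom = genes_df$chrom[gi],
                   strand = genes_df$strand[gi],
                   target_start = co$target_start,
                   target_end = co$target_end,
                   upstream_start = co$upstream_start,
                   upstream_end = co$upstream_end,
                   downstream_start = co$downstream_start,
                   downstream_end = co$downstream_end,
                   pvalue = round(p, 10), fdr = round(fdr, 10),
                   inc_level_diff = round(stats::runif(n, -1, 1), 4),
                   stringsAsFactors = FALSE)
  ev$event_id <- .event_key(ev$event_type, ev$chrom, ev$strand,
                            ev$target_start, ev$target_end,
                            ev$upstream_start, ev$upstream_end,
                            ev$downstream_start, ev$downstream_end)
  ev[, .event_columns]
}

#' Simulate a synthetic lncRNA-knockdown splicing study
#'
#' Writes, under `out_dir`: `sample_sheet.tsv`, per-comparison rMATS-style
#' tables (`rmats/<comparison>_SE.txt`, `_RI.txt`), per-(cell line, RBP)
#' BED peak files plus `peaks/manifest.tsv`, a small `annotation.gmt`, and
#' `truth.json`. Returns (invisibly) the full ground-truth record used by
#' the test oracles: planted per-gene event counts, per-(region, RBP)
#' binding flags, sponge identities and shared-gene assignments. The same
#' config (including seed) always produces byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of class `sim_truth`.
#' @export
simulate_splicing_study <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(file.path(out_dir, "rmats"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  set.seed(cfg$seed)

  ## gene universe with territories
  genes_df <- data.frame(
    gene_symbol = sprintf("GENE%03d", seq_len(cfg$n_genes)),
    gene_id = sprintf("ENSG%08d", seq_len(cfg$n_genes)),
    chrom = paste0("chr", ((seq_len(cfg$n_genes) - 1L) %%
                             cfg$n_chromosomes) + 1L),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    base = 1e5 + ((seq_len(cfg$n_genes) - 1L) %/% cfg$n_chromosomes) *
      cfg$gene_stride,
    stringsAsFactors = FALSE)

  ## AS gene sets with planted cross-cell-line sharing
  n_cl <- length(cfg$cell_lines)
  per_cl <- cfg$n_as_genes_per_cell_line
  f <- cfg$cross_cell_line_sharing
  n_shared <- if (n_cl >= 2L) round(f * n_cl * per_cl / (1 + f)) else 0L
  union_size <- n_cl * per_cl - n_shared
  as_pool <- sample(genes_df$gene_symbol, union_size)
  shared_genes <- if (n_shared > 0L) as_pool[seq_len(n_shared)] else
    character(0)
  exclusive_pool <- setdiff(as_pool, shared_genes)
  pairs <- if (n_cl >= 2L) utils::combn(n_cl, 2L, simplify = FALSE) else
    list()
  gene_sets <- stats::setNames(
    replicate(n_cl, character(0), simplify = FALSE), cfg$cell_lines)
  for (j in seq_along(shared_genes)) {
    pr <- pairs[[((j - 1L) %% length(pairs)) + 1L]]
    for (ci in pr)
      gene_sets[[ci]] <- c(gene_sets[[ci]], shared_genes[j])
  }
  offset <- 0L
  for (ci in seq_len(n_cl)) {
    need <- per_cl - length(gene_sets[[ci]])
    if (need < 0L)
      stop("infeasible sharing: cell line receives more shared genes than ",
           "its set size")
    gene_sets[[ci]] <- c(gene_sets[[ci]],
                         exclusive_pool[offset + seq_len(need)])
    offset <- offset + need
  }

  ## sample sheet
  lnc_names <- sprintf("LNC%03d",
                       seq_len(n_cl * cfg$n_lncrnas_per_cell_line))
  sheet <- data.frame(
    comparison_id = character(0), lncrna = character(0),
    cell_line = character(0), stringsAsFactors = FALSE)
  idx <- 0L
  for (cl in cfg$cell_lines) {
    for (k in seq_len(cfg$n_lncrnas_per_cell_line)) {
      idx <- idx + 1L
      sheet <- rbind(sheet, data.frame(
        comparison_id = paste0(lnc_names[idx], "_", cl),
        lncrna = lnc_names[idx], cell_line = cl, stringsAsFactors = FALSE))
    }
  }
  sponges <- stats::setNames(
    lapply(cfg$peak_cell_lines, function(cl) {
      cand <- sheet$lncrna[sheet$cell_line == cl]
      cand[seq_len(min(cfg$n_sponges_per_cell_line, length(cand)))]
    }), cfg$peak_cell_lines)

  ## events per comparison (per-comparison totals jittered, significance
  ## fraction exact within each comparison)
  n_base <- cfg$n_events_per_comparison
  j <- cfg$n_events_jitter
  n_ev_comp <- stats::setNames(
    if (j > 0) pmax(1L, round(n_base * stats::runif(nrow(sheet),
                                                    1 - j, 1 + j)))
    else rep(n_base, nrow(sheet)),
    sheet$comparison_id)
  events_by_comp <- list()
  for (cl in cfg$cell_lines) {
    comp_ids <- sheet$comparison_id[sheet$cell_line == cl]
    gs <- gene_sets[[cl]]
    n_sig_c <- round(n_ev_comp[comp_ids] * cfg$frac_significant)
    n_sig_se_c <- round(n_sig_c * cfg$se_fraction)
    n_sig_ri_c <- n_sig_c - n_sig_se_c
    n_ns_c <- n_ev_comp[comp_ids] - n_sig_c
    n_ns_se_c <- round(n_ns_c * cfg$se_fraction)
    n_ns_ri_c <- n_ns_c - n_ns_se_c
    se_draws <- .coverage_draws(gs, n_sig_se_c)
    for (ci in seq_along(comp_ids)) {
      id <- comp_ids[ci]
      block <- (ci - 1L) * .comp_block
      sig_se <- .build_events_for_comparison(
        genes_df, se_draws[[ci]], block + .block_ranges$sig_SE,
        "SE", TRUE, cfg)
      sig_ri <- .build_events_for_comparison(
        genes_df, if (n_sig_ri_c[ci] > 0L)
          sample(gs, n_sig_ri_c[ci], replace = TRUE) else character(0),
        block + .block_ranges$sig_RI, "RI", TRUE, cfg)
      ns_se <- .build_events_for_comparison(
        genes_df, if (n_ns_se_c[ci] > 0L)
          sample(genes_df$gene_symbol, n_ns_se_c[ci], replace = TRUE)
        else character(0),
        block + .block_ranges$ns_SE, "SE", FALSE, cfg)
      ns_ri <- .build_events_for_comparison(
        genes_df, if (n_ns_ri_c[ci] > 0L)
          sample(genes_df$gene_symbol, n_ns_ri_c[ci], replace = TRUE)
        else character(0),
        block + .block_ranges$ns_RI, "RI", FALSE, cfg)
      ev <- rbind(cbind(sig_se, is_significant = TRUE),
                  cbind(sig_ri, is_significant = TRUE),
                  cbind(ns_se, is_significant = FALSE),
                  cbind(ns_ri, is_significant = FALSE))
      ev$comparison_id <- rep(id, nrow(ev))
      events_by_comp[[id]] <- ev
    }
  }

  ## write rMATS tables + sheet
  sheet$se_path <- file.path("rmats", paste0(sheet$comparison_id, "_SE.txt"))
  sheet$ri_path <- file.path("rmats", paste0(sheet$comparison_id, "_RI.txt"))
  for (i in seq_len(nrow(sheet))) {
    ev <- events_by_comp[[sheet$comparison_id[i]]]
    write_rmats_table(ev[ev$event_type == "SE", .event_columns],
                      file.path(out_dir, sheet$se_path[i]),
                      event_type = "SE")
    write_rmats_table(ev[ev$event_type == "RI", .event_columns],
                      file.path(out_dir, sheet$ri_path[i]),
                      event_type = "RI")
  }
  utils::write.table(sheet, file.path(out_dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## planted per-gene counts (unique significant events per comparison)
  all_events <- do.call(rbind, events_by_comp)
  planted_counts <- lapply(c(SE = "SE", RI = "RI"), function(ty) {
    sig <- all_events[all_events$is_significant &
                        all_events$event_type == ty, , drop = FALSE]
    if (nrow(sig) == 0L)
      return(matrix(0L, 0L, nrow(sheet),
                    dimnames = list(NULL, sheet$comparison_id)))
    tab <- table(sig$gene_symbol, factor(sig$comparison_id,
                                         levels = sheet$comparison_id))
    m <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
    m[order(rownames(m)), , drop = FALSE]
  })

  ## peaks + planted binding flags
  rbps <- sprintf("RBP%02d", seq_len(cfg$n_rbps))
  bad_sat <- setdiff(cfg$saturated_rbps, rbps)
  if (length(bad_sat) > 0L)
    stop("saturated_rbps not among generated RBP names: ",
         paste(bad_sat, collapse = ", "))
  flags_truth <- list()
  regions_truth <- list()
  manifest <- data.frame(path = character(0), rbp = character(0),
                         cell_line = character(0), stringsAsFactors = FALSE)
  for (cl in cfg$peak_cell_lines) {
    comp_ids <- sheet$comparison_id[sheet$cell_line == cl]
    regs <- do.call(rbind, lapply(comp_ids, function(id) {
      ev <- events_by_comp[[id]]
      sig <- ev[ev$is_significant, .event_columns]
      regions_for_comparison(sig, lncrna = sheet$lncrna[match(id,
                               sheet$comparison_id)],
                             cell_line = cl, window = cfg$window)
    }))
    anchors <- (regs$start + regs$end) / 2  # never clipped by construction
    dens <- ifelse(regs$lncrna %in% sponges[[cl]],
                   cfg$sponge_density, cfg$background_density)
    fl <- matrix(FALSE, nrow(regs), length(rbps),
                 dimnames = list(.region_uid(regs), rbps))
    for (r in rbps) {
      p_bind <- if (r %in% cfg$saturated_rbps) rep(1, nrow(regs)) else dens
      bound <- stats::runif(nrow(regs)) < p_bind
      fl[, r] <- bound
      pk <- data.frame(chrom = regs$chrom[bound],
                       start = as.integer(anchors[bound] - 30L),
                       end = as.integer(anchors[bound] + 30L),
                       rbp = r, cell_line = cl, score = 100,
                       strand = regs$strand[bound],
                       stringsAsFactors = FALSE)
      rel <- file.path("peaks", paste0(cl, "_", r, ".bed"))
      write_bed(pk, file.path(out_dir, rel))
      manifest <- rbind(manifest, data.frame(path = rel, rbp = r,
                                             cell_line = cl,
                                             stringsAsFactors = FALSE))
    }
    flags_truth[[cl]] <- fl
    regions_truth[[cl]] <- regs
  }
  utils::write.table(manifest, file.path(out_dir, "peaks", "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## annotation GMT: random terms + one term per planted AS gene set
  n_random_terms <- 10L
  terms <- data.frame(
    term_id = c(sprintf("TERM%02d", seq_len(n_random_terms)),
                paste0("TERM_AS_", cfg$cell_lines)),
    term_name = c(sprintf("random gene set %d", seq_len(n_random_terms)),
                  paste0("planted AS genes of ", cfg$cell_lines)),
    stringsAsFactors = FALSE)
  terms$genes <- I(c(
    lapply(seq_len(n_random_terms), function(i)
      sort(sample(genes_df$gene_symbol, 8L))),
    lapply(cfg$cell_lines, function(cl) sort(gene_sets[[cl]]))))
  write_gmt(terms, file.path(out_dir, "annotation.gmt"))

  ## realized SE sharing (what the pipeline should recover)
  sig_se <- all_events[all_events$is_significant &
                         all_events$event_type == "SE", , drop = FALSE]
  cl_of <- sheet$cell_line[match(sig_se$comparison_id, sheet$comparison_id)]
  realized_sets <- lapply(stats::setNames(cfg$cell_lines, cfg$cell_lines),
                          function(cl)
                            sort(unique(sig_se$gene_symbol[cl_of == cl])))
  realized_genes <- sort(unique(unlist(realized_sets)))
  n_in <- vapply(realized_genes, function(g)
    sum(vapply(realized_sets, function(s) g %in% s, logical(1))),
    numeric(1))
  realized_shared_fraction <- if (length(realized_genes) > 0L)
    sum(n_in >= 2) / length(realized_genes) else NA_real_

  truth <- structure(list(
    config = cfg,
    out_dir = out_dir,
    genes = genes_df,
    gene_sets = gene_sets,
    shared_genes = shared_genes,
    sponges = sponges,
    sheet = sheet,
    events = all_events,
    planted_counts = planted_counts,
    regions = regions_truth,
    flags = flags_truth,
    annotation = terms,
    realized_se_gene_sets = realized_sets,
    realized_shared_fraction = realized_shared_fraction
  ), class = "sim_truth")

  ## compact truth.json for inspection / external tooling
  tj <- list(
    seed = cfg$seed,
    cell_lines = cfg$cell_lines,
    sponges = sponges,
    shared_genes = shared_genes,
    gene_sets = gene_sets,
    n_events_per_comparison = as.list(n_ev_comp),
    n_significant_per_comparison = as.list(round(n_ev_comp *
                                                   cfg$frac_significant)),
    planted_counts = lapply(planted_counts, function(m)
      list(genes = rownames(m), comparisons = colnames(m),
           counts = unname(m))),
    bound_region_uids = lapply(flags_truth, function(fl)
      apply(fl, 2L, function(col) rownames(fl)[col], simplify = FALSE)),
    realized_shared_fraction = realized_shared_fraction
  )
  jsonlite::write_json(tj, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic study in ", x$out_dir, ": ", nrow(x$sheet),
      " comparisons, ", nrow(x$events), " events (",
      sum(x$events$is_significant), " significant), sponges: ",
      paste(unlist(x$sponges), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Verify simulated files against their ground truth
#'
#' Re-reads everything the generator wrote and asserts field-by-field
#' agreement with the in-memory ground truth: sample sheet rows, every
#' rMATS table (coordinates, p, fdr, genes), and per-(region, RBP)
#' binding flags recomputed from the BED files by a naive
#' containment scan (independent of the package's sweep engine). Any
#' tampering with the files — a dropped peak line, a truncated event
#' table — is reported.
#'
#' @param out_dir Directory that [simulate_splicing_study()] wrote.
#' @param truth The `sim_truth` object it returned.
#' @return List with `ok` (logical) and `mismatches` (character vector of
#'   itemized failures, empty when everything agrees).
#' @export
verify_ground_truth <- function(out_dir, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  bad <- character(0)
  note <- function(...) bad <<- c(bad, paste0(...))
  sheet <- tryCatch(
    read_sample_sheet(file.path(out_dir, "sample_sheet.tsv")),
    error = function(e) {
      note("sample sheet unreadable: ", conditionMessage(e)); NULL
    })
  if (!is.null(sheet)) {
    if (!identical(sheet$comparison_id, truth$sheet$comparison_id))
      note("sample sheet comparisons differ from truth")
    for (i in seq_len(nrow(sheet))) {
      for (ty in c("SE", "RI")) {
        pc <- if (ty == "SE") "se_path" else "ri_path"
        got <- tryCatch(read_rmats_table(sheet[[pc]][i], ty),
                        error = function(e) NULL)
        want <- truth$events[truth$events$comparison_id ==
                               sheet$comparison_id[i] &
                               truth$events$event_type == ty,
                             .event_columns]
        if (is.null(got)) {
          note("unreadable ", ty, " table for ", sheet$comparison_id[i])
          next
        }
        if (nrow(got) != nrow(want)) {
          note("event-count mismatch in ", ty, " table of ",
               sheet$comparison_id[i], ": ", nrow(got), " vs ", nrow(want))
          next
        }
        rownames(want) <- NULL
        same_ids <- identical(got$event_id, want$event_id)
        same_stats <- isTRUE(all.equal(got$pvalue, want$pvalue,
                                       tolerance = 1e-9)) &&
          isTRUE(all.equal(got$fdr, want$fdr, tolerance = 1e-9))
        if (!same_ids || !same_stats)
          note("field mismatch in ", ty, " table of ",
               sheet$comparison_id[i])
      }
    }
  }
  manifest_path <- file.path(out_dir, "peaks", "manifest.tsv")
  if (!file.exists(manifest_path)) {
    note("missing peaks manifest")
  } else {
    manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
    for (cl in names(truth$flags)) {
      regs <- truth$regions[[cl]]
      fl_want <- truth$flags[[cl]]
      for (r in colnames(fl_want)) {
        row <- manifest[manifest$cell_line == cl & manifest$rbp == r, ,
                        drop = FALSE]
        if (nrow(row) != 1L) {
          note("manifest entry missing for ", cl, "/", r)
          next
        }
        pk <- tryCatch(read_peaks_bed(file.path(out_dir, row$path),
                                      rbp = r, cell_line = cl),
                       error = function(e) NULL)
        if (is.null(pk)) {
          note("unreadable peak file for ", cl, "/", r)
          next
        }
        got <- vapply(seq_len(nrow(regs)), function(i) {
          any(pk$chrom == regs$chrom[i] & pk$start < regs$end[i] &
                pk$end > regs$start[i])
        }, logical(1))
        if (!identical(unname(got), unname(fl_want[, r])))
          note("binding-flag mismatch for ", cl, "/", r, " (",
               sum(got != fl_want[, r]), " region(s))")
      }
    }
  }
  list(ok = length(bad) == 0L, mismatches = bad)
}
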