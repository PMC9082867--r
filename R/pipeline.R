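## End-to-end orchestration: find -> annotate -> project -> lengths ->
## expansions -> classify -> characterize -> compare, with a machine-readable
## report. All stage computations live in the module functions; this file
## only wires them together.

#' Pipeline configuration
#'
#' @param bundle_dir directory holding the standard bundle files
#'   (`assembly.fasta`, `coverage.tsv`, `template.fasta`, `segments.tsv`,
#'   `msa.fasta`, `helix_map.tsv`, `registry.tsv`, `tree.nwk`), e.g. from
#'   [generate_bundle()]. Individual paths can be overridden.
#' @param e_max,cov_factor,exp_factor,min_abs,orf_min_aa thresholds: E-value
#'   ceiling (1e-5), coverage enrichment (5x), expansion fold-change (4x),
#'   minimum absolute excess (30 nt), ORF report length (20 aa).
#' @param template_id MSA row holding the helix-map template.
#' @param focal,background explicit species sets; by default every species
#'   is tested as focal against all remaining species.
#' @param stat background summary statistic for [detect_expansions()].
#' @param ... individual path overrides (assembly_fasta, coverage_tsv,
#'   reference_fasta, segments_tsv, msa_fasta, helix_map_tsv, registry_tsv,
#'   tree_nwk).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(bundle_dir, e_max = 1e-5, cov_factor = 5,
                            exp_factor = 4, min_abs = 30, orf_min_aa = 20L,
                            template_id = "Reference", focal = NULL,
                            background = NULL, stat = "median", ...) {
  stopifnot(e_max > 0, cov_factor > 0, exp_factor > 0, min_abs >= 0)
  paths <- list(
    assembly_fasta = file.path(bundle_dir, "assembly.fasta"),
    coverage_tsv = file.path(bundle_dir, "coverage.tsv"),
    reference_fasta = file.path(bundle_dir, "template.fasta"),
    segments_tsv = file.path(bundle_dir, "segments.tsv"),
    msa_fasta = file.path(bundle_dir, "msa.fasta"),
    helix_map_tsv = file.path(bundle_dir, "helix_map.tsv"),
    registry_tsv = file.path(bundle_dir, "registry.tsv"),
    tree_nwk = file.path(bundle_dir, "tree.nwk"))
  over <- list(...)
  paths[names(over)] <- over
  structure(c(paths, list(e_max = e_max, cov_factor = cov_factor,
                          exp_factor = exp_factor, min_abs = min_abs,
                          orf_min_aa = orf_min_aa, template_id = template_id,
                          focal = focal, background = background,
                          stat = stat)),
            class = "pipeline_config")
}

#' Run the full detection pipeline
#'
#' Executes every stage on the configured inputs and returns a run report;
#' with `outdir` set, writes the intermediate tables (hits, GFF3,
#' expansions, calls, homology matrix), the report JSON, and the schematic
#' SVG. Fully deterministic given the inputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param params `scoring_params` for the homology searches.
#' @return list of class `run_report`; see Details.
#' @details The report carries: `n_contigs`, `rdna_contigs`, `annotations`,
#'   `expansions`, `calls`, `fragment_counts` (per species),
#'   `shared_pairs`, `scenarios` (per-site and for the pooled "any 28S ITS"
#'   character), `homology` (max off-diagonal identity), and the effective
#'   thresholds.
#' @export
run_pipeline <- function(config, outdir = NULL, params = scoring_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  ## --- find ---
  contigs <- stage("find", read_fasta(config$assembly_fasta))
  cov <- stage("find", parse_coverage(
    contigs, tsv = if (file.exists(config$coverage_tsv)) config$coverage_tsv
                   else NULL))
  reference <- stage("find", read_fasta(config$reference_fasta))
  ref_segments <- stage("find", read_segments(config$segments_tsv))
  rseg <- ref_segments[ref_segments$segment %in% c("SSU", "5.8S", "LSU"), ]
  queries <- setNames(substring(reference[[1]], rseg$start, rseg$end),
                      rseg$segment)
  hits <- stage("find", search_homologs(queries, contigs, params))
  rdna_ids <- stage("find", filter_rdna_contigs(hits, cov,
                                                e_max = config$e_max,
                                                factor = config$cov_factor))
  ## --- annotate ---
  annotations <- stage("annotate", lapply(rdna_ids, function(id)
    annotate_operon(contigs[id], reference, ref_segments, params,
                    e_max = config$e_max,
                    depth = cov$depth[match(id, cov$contig)],
                    hits = hits)))
  ## --- project / lengths ---
  msa <- stage("project", read_msa(config$msa_fasta))
  hm <- stage("project", read_helix_map(config$helix_map_tsv,
                                        template_id = config$template_id))
  proj <- stage("project", project_anchors(msa, hm))
  domains <- stage("project", region_domains(hm, ref_segments))
  regions <- stage("lengths", interanchor_lengths(proj, msa, domains))
  ## --- expansions ---
  species <- setdiff(names(msa), config$template_id)
  focal_set <- if (is.null(config$focal)) species else config$focal
  expansions <- stage("expansions", {
    res <- lapply(focal_set, function(sp) {
      bg <- if (is.null(config$background)) setdiff(species, sp)
            else setdiff(config$background, sp)
      suppressWarnings(detect_expansions(
        regions, focal = sp, background = bg, factor = config$exp_factor,
        min_abs = config$min_abs, stat = config$stat))
    })
    do.call(rbind, res)
  })
  ## --- classify ---
  registry <- stage("classify", if (file.exists(config$registry_tsv))
    read_its_registry(config$registry_tsv)
    else data.frame(site_id = character(0), lineage = character(0),
                    left_anchor = character(0), right_anchor = character(0),
                    region_id = character(0), domain = character(0)))
  calls <- stage("classify", classify_expansions(expansions, registry,
                                                 domains))
  ## --- characterize ---
  seqs <- degap(msa)
  its_ids <- which(calls$classification %in% c("known_ITS", "novel_candidate"))
  its_seqs <- setNames(
    vapply(its_ids, function(i)
      substring(seqs[[calls$species[i]]], calls$start[i], calls$end[i]), ""),
    vapply(its_ids, function(i)
      paste0(calls$species[i], ":", calls$region_id[i]), ""))
  characterization <- stage("characterize", {
    orf_counts <- vapply(its_seqs, function(s)
      nrow(orf_scan(s, min_aa = config$orf_min_aa)), 0L)
    fold_density <- vapply(its_seqs, function(s) {
      f <- fold_region(s)
      if (nchar(s) > 0) f$pairs * 2 / nchar(s) else 0
    }, 0)
    hom <- cross_its_homology(its_seqs)
    list(orf_counts = orf_counts, fold_density = fold_density,
         homology = hom,
         max_cross_identity = if (length(its_seqs) >= 2)
           max(hom, na.rm = TRUE) else NA_real_)
  })
  ## --- compare ---
  tree <- stage("compare", read_newick(config$tree_nwk))
  pm <- stage("compare", presence_matrix(calls, taxa = tree$tip.label))
  pairs <- stage("compare", shared_sites(registry))
  any28s <- stage("compare", {
    lsu_calls <- calls[calls$classification %in%
                         c("known_ITS", "novel_candidate") &
                         calls$domain == "LSU", , drop = FALSE]
    pres <- setNames(tree$tip.label %in% lsu_calls$species, tree$tip.label)
    gain_scenarios(tree, pres)
  })
  per_site <- stage("compare", {
    if (ncol(pm)) lapply(setNames(colnames(pm), colnames(pm)), function(rid)
      gain_scenarios(tree, setNames(pm[, rid], rownames(pm))))
    else list()
  })
  frag <- vapply(species, function(sp) fragment_count(calls, sp), 0L)
  report <- structure(list(
    n_contigs = length(contigs), rdna_contigs = rdna_ids,
    n_hits = nrow(hits), annotations = annotations,
    n_regions = nrow(regions), expansions = expansions, calls = calls,
    fragment_counts = frag, presence = pm, shared_pairs = pairs,
    scenarios = c(list(any_28S_ITS = any28s), per_site),
    characterization = characterization,
    thresholds = list(e_max = config$e_max, cov_factor = config$cov_factor,
                      exp_factor = config$exp_factor,
                      min_abs = config$min_abs,
                      orf_min_aa = config$orf_min_aa,
                      stat = config$stat)),
    class = "run_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(hits, file.path(outdir, "hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(annotations))
      write_gff3(annotations, file.path(outdir, "operons.gff3"))
    write.table(expansions, file.path(outdir, "expansions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(calls, file.path(outdir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pairs, file.path(outdir, "shared_sites.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(n_contigs = report$n_contigs, rdna_contigs = report$rdna_contigs,
           n_hits = report$n_hits, n_expansions = nrow(expansions),
           calls = calls, fragment_counts = as.list(frag),
           shared_pairs = pairs, scenarios = report$scenarios,
           thresholds = report$thresholds),
      file.path(outdir, "report.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA)
    svg <- render_schematic(calls, domains,
                            taxa_order = tree$tip.label)
    writeLines(svg, file.path(outdir, "schematic.svg"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("rDNA fragmentation run report\n")
  cat("  contigs searched:   ", x$n_contigs, "\n")
  cat("  rDNA contigs kept:  ", length(x$rdna_contigs), "\n")
  cat("  ITS calls:          ",
      sum(x$calls$classification %in% c("known_ITS", "novel_candidate")),
      "\n")
  cat("  shared site pairs:  ", nrow(x$shared_pairs), "\n")
  frag <- paste(names(x$fragment_counts), x$fragment_counts, sep = "=",
                collapse = ", ")
  cat("  28S fragments:      ", frag, "\n")
  s <- x$scenarios$any_28S_ITS
  cat("  any-28S-ITS character: fitch=", s$fitch_changes,
      " gains(no loss)=", s$gains_no_loss,
      " dollo losses=", s$dollo_losses_single_gain, "\n", sep = "")
  invisible(x)
}

#' Render a Fig-1-style fragmentation schematic
#'
#' One horizontal bar per taxon (5.8S + 28S portion of the operon), a tick
#' per ITS call at its region's relative template position; ticks at the
#' same region share an x position, which visually links shared sites.
#' Deterministic layout; plain SVG text.
#'
#' @param calls data.frame from [classify_expansions()].
#' @param domains data.frame from [region_domains()].
#' @param taxa_order bar order (e.g. tree tip labels).
#' @return character vector of SVG lines.
#' @export
render_schematic <- function(calls, domains, taxa_order) {
  lsu <- domains[domains$domain %in% c("5.8S", "LSU"), , drop = FALSE]
  t0 <- min(lsu$t_start); t1 <- max(lsu$t_end)
  width <- 640; bar_x0 <- 140; bar_x1 <- 620; row_h <- 26
  relx <- function(t) bar_x0 + (t - t0) / max(1, (t1 - t0)) * (bar_x1 - bar_x0)
  n <- length(taxa_order)
  out <- c(sprintf("<svg xmlns='http://www.w3.org/2000/svg' width='%d' height='%d'>",
                   width, 40 + n * row_h),
           "<style>text{font:11px sans-serif}</style>")
  keep <- calls$classification %in% c("known_ITS", "novel_candidate") &
    calls$domain %in% c("5.8S", "LSU")
  calls <- calls[keep, , drop = FALSE]
  for (i in seq_len(n)) {
    sp <- taxa_order[i]
    y <- 20 + i * row_h
    out <- c(out,
             sprintf("<text x='8' y='%d'>%s</text>", y + 4, sp),
             sprintf("<rect x='%d' y='%d' width='%d' height='8' fill='#9ecae1'/>",
                     bar_x0, y - 4, bar_x1 - bar_x0))
    cc <- calls[calls$species == sp, , drop = FALSE]
    cc <- cc[order(cc$region_id), , drop = FALSE]
    for (j in seq_len(nrow(cc))) {
      d <- domains[domains$region_id == cc$region_id[j], , drop = FALSE]
      if (!nrow(d)) next
      x <- relx((d$t_start[1] + d$t_end[1]) / 2)
      out <- c(out,
               sprintf("<line x1='%.1f' y1='%d' x2='%.1f' y2='%d' stroke='#d62728' stroke-width='3'/>",
                       x, y - 8, x, y + 8),
               sprintf("<title>%s %s</title>",
                       ifelse(is.na(cc$site_id[j]), cc$classification[j],
                              cc$site_id[j]), cc$region_id[j]))
    }
  }
  c(out, "</svg>")
}
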