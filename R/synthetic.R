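## Synthetic operon bundles: a conserved-core / divergent-region template
## evolving on a tree, lineage-specific ITSs of arbitrary sequence planted
## at inter-helix sites, and an assembly in which rDNA contigs carry
## several-fold the baseline coverage -- with ground truth for every stage.

.default_tree <- paste0(
  "(Outgroup:0.08,((DiplonemidA:0.04,DiplonemidB:0.04):0.03,",
  "((EuglenidA:0.04,EuglenidB:0.04):0.03,(Prokinetoplastid:0.05,",
  "(MetakinetoplastidA:0.03,MetakinetoplastidB:0.03):0.03):0.02):0.02):0.02);")

.default_planted <- function() {
  eug <- c("EuglenidA", "EuglenidB")
  meta <- c("MetakinetoplastidA", "MetakinetoplastidB")
  eug_regions <- c("L4-L5", "L10-L11", "L16-L17", "L22-L23", "L28-L29")
  meta_regions <- c("L16-L17", "L22-L23", "L28-L29", "L34-L35", "L40-L41")
  rbind(
    data.frame(site_id = paste0("eITS", seq_along(eug_regions)),
               lineage = "euglenid", region_id = eug_regions,
               taxa = paste(eug, collapse = ","),
               len_min = 200L, len_max = 500L, stringsAsFactors = FALSE),
    data.frame(site_id = paste0("kITS", seq_along(meta_regions)),
               lineage = "kinetoplastid", region_id = meta_regions,
               taxa = paste(meta, collapse = ","),
               len_min = 200L, len_max = 500L, stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is meant to detect: a
#' 5-segment operon (SSU 2000, ITS1 300, 5.8S 160, ITS2 400, LSU 3500 nt)
#' with compact hairpin helix anchors; an 8-taxon tree mirroring the taxon
#' structure of the euglenozoan problem (outgroup; a diplonemid clade and a
#' prokinetoplastid lineage without ITSs; euglenid and metakinetoplastid
#' clades with 5 planted LSU sites each, 3 of them shared); per-class
#' substitution-rate multipliers core 0.1, ES 2.0, spacer 3.0 with pairwise
#' background divergence kept below ~0.2 substitutions/site; ES/spacer-only
#' indels; and an assembly model in which rDNA contigs carry 20x the
#' baseline depth among random decoy contigs.
#'
#' @param seed integer seed; the same config yields a byte-identical bundle.
#' @param tree newick string or `phylo` with branch lengths
#'   (substitutions/site).
#' @param layout named segment lengths (SSU, ITS1, `5.8S`, ITS2, LSU).
#' @param anchor_plan per-rRNA-segment anchor counts,
#'   `list(SSU = c(core, ES), ...)`.
#' @param helix_len,loop_len nt per helix strand and hairpin loop.
#' @param rates per-class substitution multipliers (core, ES, spacer).
#' @param indel_rate indel events per eligible site per unit branch length.
#' @param indel_mean mean indel length (geometric).
#' @param planted_its data.frame(site_id, lineage, region_id, taxa
#'   (comma-separated), len_min, len_max); `NULL` for a no-ITS bundle.
#' @param assembly list(baseline_depth, rdna_multiplier, n_decoys,
#'   decoy_len, fragment_len, revcomp_alternate).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       tree = .default_tree,
                       layout = c(SSU = 2000L, ITS1 = 300L, `5.8S` = 160L,
                                  ITS2 = 400L, LSU = 3500L),
                       anchor_plan = list(SSU = c(core = 20L, ES = 5L),
                                          `5.8S` = c(core = 2L, ES = 0L),
                                          LSU = c(core = 40L, ES = 6L)),
                       helix_len = 12L, loop_len = 12L,
                       rates = c(core = 0.1, ES = 2.0, spacer = 3.0),
                       indel_rate = 0.01, indel_mean = 8,
                       planted_its = .default_planted(),
                       assembly = list(baseline_depth = 10,
                                       rdna_multiplier = 20,
                                       n_decoys = 40L,
                                       decoy_len = c(2000L, 6000L),
                                       fragment_len = Inf,
                                       revcomp_alternate = TRUE)) {
  if (is.character(tree)) tree <- read_newick(tree)
  stopifnot(all(c("SSU", "ITS1", "5.8S", "ITS2", "LSU") %in% names(layout)))
  structure(list(seed = as.integer(seed), tree = tree, layout = layout,
                 anchor_plan = anchor_plan, helix_len = as.integer(helix_len),
                 loop_len = as.integer(loop_len), rates = rates,
                 indel_rate = indel_rate, indel_mean = indel_mean,
                 planted_its = planted_its, assembly = assembly),
            class = "sim_config")
}

.rand_bases <- function(n) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

#' Build the template operon and its helix map
#'
#' Core anchors are compact hairpins (5' strand, loop, reverse-complementary
#' 3' strand) so that folding the anchor subsequence recovers at least
#' helix-length base pairs; ES anchors are single-strand divergent
#' landmarks. Anchors are spread evenly inside their rRNA segment. ITS1/ITS2
#' carry no anchors. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list: `template` (length-1 named vector, id `Reference`),
#'   `helix_map`, `segments` (data.frame), `classes` (per-position
#'   core/ES/spacer vector).
#' @export
build_template <- function(config) {
  set.seed(config$seed)
  seg_order <- c("SSU", "ITS1", "5.8S", "ITS2", "LSU")
  prefix <- c(SSU = "S", `5.8S` = "F", LSU = "L")
  bases <- character(0); classes <- character(0)
  segments <- data.frame(segment = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  hm_rows <- list()
  pos <- 0L
  for (seg in seg_order) {
    seg_len <- as.integer(config$layout[[seg]])
    seg_start <- pos + 1L
    if (seg %in% c("ITS1", "ITS2")) {
      bases <- c(bases, .rand_bases(seg_len))
      classes <- c(classes, rep("spacer", seg_len))
      pos <- pos + seg_len
    } else {
      plan <- config$anchor_plan[[seg]]
      n_core <- plan[["core"]]; n_es <- plan[["ES"]]
      n_anc <- n_core + n_es
      # interleave ES anchors evenly among cores
      cls <- rep("core", n_anc)
      if (n_es > 0)
        cls[round(seq(2, n_anc - 0.49, length.out = n_es))] <- "ES"
      span <- ifelse(cls == "core",
                     2L * config$helix_len + config$loop_len,
                     config$helix_len)
      gap <- (seg_len - sum(span)) %/% (n_anc + 1L)
      if (gap < 20L)
        stop("anchors exceed segment bounds for ", seg,
             " (inter-anchor gap ", gap, " < 20 nt)")
      extra <- seg_len - sum(span) - gap * (n_anc + 1L)
      ai <- 0L
      for (i in seq_len(n_anc)) {
        g <- gap + if (i == 1L) extra else 0L
        bases <- c(bases, .rand_bases(g))
        classes <- c(classes, rep("ES", g))
        pos <- pos + g
        ai <- ai + 1L
        nm <- paste0(prefix[[seg]], ai)
        if (cls[i] == "core") {
          fp <- .rand_bases(config$helix_len)
          loop <- .rand_bases(config$loop_len)
          tp <- rev(chartr("ACGT", "TGCA", fp))
          bases <- c(bases, fp, loop, tp)
          classes <- c(classes, rep("core", span[i]))
          hm_rows[[length(hm_rows) + 1]] <- data.frame(
            helix = nm, class = "core",
            fp_start = pos + 1L, fp_end = pos + config$helix_len,
            tp_start = pos + config$helix_len + config$loop_len + 1L,
            tp_end = pos + span[i], stringsAsFactors = FALSE)
        } else {
          bases <- c(bases, .rand_bases(config$helix_len))
          classes <- c(classes, rep("core", span[i]))
          hm_rows[[length(hm_rows) + 1]] <- data.frame(
            helix = nm, class = "ES",
            fp_start = pos + 1L, fp_end = pos + span[i],
            tp_start = NA_integer_, tp_end = NA_integer_,
            stringsAsFactors = FALSE)
        }
        pos <- pos + span[i]
      }
      tail_gap <- seg_len - (pos - seg_start + 1L)
      bases <- c(bases, .rand_bases(tail_gap))
      classes <- c(classes, rep("ES", tail_gap))
      pos <- pos + tail_gap
    }
    segments <- rbind(segments,
                      data.frame(segment = seg, start = seg_start, end = pos))
  }
  template <- setNames(paste(bases, collapse = ""), "Reference")
  hm <- as_helix_map(do.call(rbind, hm_rows), template_id = "Reference")
  list(template = template, helix_map = hm, segments = segments,
       classes = classes)
}

## node state: parallel vectors key (ordered doubles), base, class
.mutate_branch <- function(state, bl, rates, indel_rate, indel_mean) {
  n <- length(state$base)
  if (n == 0 || bl <= 0) return(state)
  r <- unname(rates[state$class])
  p <- 0.75 * (1 - exp(-4 / 3 * r * bl))
  hit <- runif(n) < p
  if (any(hit)) {
    # substitute with one of the three other bases, uniformly
    alphabet <- c("A", "C", "G", "T")
    cur <- match(state$base[hit], alphabet)
    off <- sample.int(3L, sum(hit), replace = TRUE)
    state$base[hit] <- alphabet[(cur + off - 1L) %% 4L + 1L]
  }
  elig <- state$class %in% c("ES", "spacer")
  n_ev <- rpois(1L, indel_rate * bl * sum(elig))
  for (ev in seq_len(n_ev)) {
    where <- which(elig)
    if (!length(where)) break
    pos <- where[sample.int(length(where), 1L)]
    len <- rgeom(1L, 1 / indel_mean) + 1L
    if (runif(1) < 0.5) { # deletion: consecutive eligible run from pos
      j <- pos
      while (j <= length(state$base) && (j - pos) < len &&
               state$class[j] %in% c("ES", "spacer")) j <- j + 1L
      drop <- pos:(j - 1L)
      state$key <- state$key[-drop]
      state$base <- state$base[-drop]
      state$class <- state$class[-drop]
    } else { # insertion after pos
      k1 <- state$key[pos]
      k2 <- if (pos < length(state$key)) state$key[pos + 1L] else k1 + 1
      newkeys <- sort(runif(len, k1, k2))
      idx <- seq_len(pos)
      state$key <- c(state$key[idx], newkeys, state$key[-idx])
      state$base <- c(state$base[idx], .rand_bases(len), state$base[-idx])
      state$class <- c(state$class[idx], rep(state$class[pos], len),
                       state$class[-idx])
    }
    elig <- state$class %in% c("ES", "spacer")
  }
  state
}

#' Evolve the template along a tree
#'
#' A single-parameter substitution process (equal exchangeabilities,
#' Jukes-Cantor transition probability per branch) with per-class rate
#' multipliers; indels (geometric lengths) only in ES/spacer classes, so
#' helix anchors keep their template coordinates in every descendant. The
#' output carries the true alignment implied by the indel history.
#'
#' @param template_obj from [build_template()].
#' @param tree `phylo` with branch lengths.
#' @param rates per-class multipliers.
#' @param indel_rate,indel_mean indel model.
#' @param seed RNG seed.
#' @return list of class `sim_alignment`: `leaves` (named list of key/base/
#'   class states), `root` state, `tree`, `template_obj`.
#' @export
evolve_on_tree <- function(template_obj, tree, rates = c(core = 0.1,
                           ES = 2.0, spacer = 3.0), indel_rate = 0.01,
                           indel_mean = 8, seed = 1L) {
  set.seed(seed)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  root_state <- list(
    key = as.numeric(seq_len(nchar(template_obj$template))),
    base = strsplit(template_obj$template[[1]], "")[[1]],
    class = template_obj$classes)
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  leaves <- vector("list", ntip)
  recurse <- function(node, state) {
    kid_edges <- children[[as.character(node)]]
    if (is.null(kid_edges)) {
      leaves[[node]] <<- state
      return(invisible())
    }
    for (e in kid_edges) {
      child <- tree$edge[e, 2]
      st <- .mutate_branch(state, tree$edge.length[e], rates,
                           indel_rate, indel_mean)
      recurse(child, st)
    }
  }
  root <- ntip + 1L
  recurse(root, root_state)
  names(leaves) <- tree$tip.label
  structure(list(leaves = leaves, root = root_state, tree = tree,
                 template_obj = template_obj),
            class = "sim_alignment")
}

#' Plant ITS insertions at inter-helix sites
#'
#' For each (site, taxon) a uniform-random-composition insert of sampled
#' length is placed at the midpoint of the target inter-anchor region
#' (planted ITSs have no conserved structure, matching the biology they
#' emulate). Non-target taxa are untouched. The truth table records every
#' planted interval.
#'
#' @param sim a `sim_alignment`.
#' @param specs data.frame like `sim_config()$planted_its` (or NULL).
#' @param seed RNG seed.
#' @return the `sim_alignment` with inserts applied and a `truth` element
#'   (data.frame: species, site_id, lineage, region_id, length).
#' @export
plant_its <- function(sim, specs, seed = 1L) {
  set.seed(seed)
  hm <- sim$template_obj$helix_map
  truth <- list()
  if (!is.null(specs) && nrow(specs)) {
    for (i in seq_len(nrow(specs))) {
      rid <- specs$region_id[i]
      anchors <- strsplit(rid, "-", fixed = TRUE)[[1]]
      li <- match(anchors[1], hm$helix); ri <- match(anchors[2], hm$helix)
      if (is.na(li) || is.na(ri))
        stop("planted region ", rid, " not in helix map")
      left_key <- hm$span_end[li]; right_key <- hm$span_start[ri]
      taxa <- strsplit(specs$taxa[i], ",", fixed = TRUE)[[1]]
      for (taxon in taxa) {
        if (!taxon %in% names(sim$leaves))
          stop("planted taxon ", taxon, " not a tree leaf")
        st <- sim$leaves[[taxon]]
        len <- if (specs$len_min[i] == specs$len_max[i]) specs$len_min[i]
               else sample(specs$len_min[i]:specs$len_max[i], 1L)
        in_region <- which(st$key > left_key & st$key < right_key)
        # insert at the region midpoint
        pos <- if (length(in_region))
                 in_region[max(1L, length(in_region) %/% 2L)]
               else max(which(st$key <= left_key))
        k1 <- st$key[pos]
        k2 <- if (pos < length(st$key)) st$key[pos + 1L] else k1 + 1
        newkeys <- sort(runif(len, k1, k2))
        idx <- seq_len(pos)
        st$key <- c(st$key[idx], newkeys, st$key[-idx])
        st$base <- c(st$base[idx], .rand_bases(len), st$base[-idx])
        st$class <- c(st$class[idx], rep("its", len), st$class[-idx])
        sim$leaves[[taxon]] <- st
        truth[[length(truth) + 1]] <- data.frame(
          species = taxon, site_id = specs$site_id[i],
          lineage = specs$lineage[i], region_id = rid, length = len,
          stringsAsFactors = FALSE)
      }
    }
  }
  sim$truth <- if (length(truth)) do.call(rbind, truth)
               else data.frame(species = character(0), site_id = character(0),
                               lineage = character(0),
                               region_id = character(0), length = integer(0),
                               stringsAsFactors = FALSE)
  sim
}

#' Extract the true MSA and unaligned sequences from a simulation
#'
#' The alignment includes the `Reference` template row; de-gapping any row
#' reproduces that species' unaligned sequence exactly.
#'
#' @param sim a `sim_alignment` (after [plant_its()] or not).
#' @return list: `msa` ([as_msa()]), `sequences` (named vector, leaves only).
#' @export
sim_msa <- function(sim) {
  states <- c(list(Reference = sim$root), sim$leaves)
  all_keys <- sort(unique(unlist(lapply(states, `[[`, "key"))))
  rows <- vapply(states, function(st) {
    chars <- rep("-", length(all_keys))
    chars[match(st$key, all_keys)] <- st$base
    paste(chars, collapse = "")
  }, "")
  msa <- as_msa(rows)
  seqs <- vapply(sim$leaves, function(st) paste(st$base, collapse = ""), "")
  list(msa = msa, sequences = seqs)
}

#' Emit an assembly with SPAdes-style coverage headers
#'
#' Each operon becomes one contig (or several overlapping fragments when
#' `fragment_len` is finite) at `baseline_depth * rdna_multiplier` depth;
#' alternating rDNA contigs are reverse-complemented when
#' `revcomp_alternate` to exercise strand handling. Decoy contigs of random
#' sequence sit at baseline depth.
#'
#' @param sequences named operon sequences.
#' @param model `sim_config()$assembly` list.
#' @param seed RNG seed.
#' @return list: `contigs` (named vector), `coverage` (data.frame),
#'   `rdna_contigs` (data.frame contig/species/strand).
#' @export
make_assembly <- function(sequences, model, seed = 1L) {
  set.seed(seed)
  stopifnot(model$baseline_depth > 0, model$rdna_multiplier > 0)
  contigs <- character(0)
  rdna <- list()
  idx <- 0L
  depth_r <- model$baseline_depth * model$rdna_multiplier
  frag <- if (is.null(model$fragment_len)) Inf else model$fragment_len
  for (i in seq_along(sequences)) {
    sp <- names(sequences)[i]
    s <- sequences[[i]]
    pieces <- if (!is.finite(frag) || nchar(s) <= frag) list(s) else {
      starts <- seq(1L, nchar(s), by = max(1L, frag - 500L))
      lapply(starts, function(a) substr(s, a, min(nchar(s), a + frag - 1L)))
    }
    for (p in pieces) {
      idx <- idx + 1L
      strand <- "+"
      if (isTRUE(model$revcomp_alternate) && idx %% 2L == 0L) {
        p <- revcomp(p); strand <- "-"
      }
      nm <- paste0("NODE_", idx, "_length_", nchar(p), "_cov_", depth_r)
      contigs[nm] <- p
      rdna[[length(rdna) + 1]] <- data.frame(contig = nm, species = sp,
                                             strand = strand,
                                             stringsAsFactors = FALSE)
    }
  }
  for (d in seq_len(model$n_decoys)) {
    idx <- idx + 1L
    len <- sample(model$decoy_len[1]:model$decoy_len[2], 1L)
    nm <- paste0("NODE_", idx, "_length_", len, "_cov_",
                 model$baseline_depth)
    contigs[nm] <- paste(.rand_bases(len), collapse = "")
  }
  list(contigs = contigs,
       coverage = parse_coverage(contigs),
       rdna_contigs = do.call(rbind, rdna))
}

#' Generate a complete synthetic bundle on disk
#'
#' Writes per-species operon FASTA, the true MSA (with the `Reference`
#' row), helix map and segment TSVs, a registry of the planted sites, the
#' tree, the assembly FASTA + coverage TSV, the truth JSON, and a config
#' echo. Byte-identical under a fixed seed.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created).
#' @return invisibly, the in-memory bundle (list).
#' @export
generate_bundle <- function(config, outdir = NULL) {
  bundle <- simulate_bundle(config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(bundle$template, file.path(outdir, "template.fasta"))
    write_helix_map(bundle$helix_map, file.path(outdir, "helix_map.tsv"))
    write_segments(bundle$segments, file.path(outdir, "segments.tsv"))
    write_fasta(bundle$sequences, file.path(outdir, "operons.fasta"))
    write_fasta(unclass(bundle$msa), file.path(outdir, "msa.fasta"))
    ape::write.tree(config$tree, file.path(outdir, "tree.nwk"))
    write_fasta(bundle$assembly$contigs, file.path(outdir, "assembly.fasta"))
    write.table(bundle$assembly$coverage[, c("contig", "depth", "length")],
                file.path(outdir, "coverage.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    reg <- bundle$registry
    write.table(reg[, c("site_id", "lineage", "left_anchor", "right_anchor",
                        "domain")],
                file.path(outdir, "registry.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      list(planted = bundle$truth, rdna_contigs = bundle$assembly$rdna_contigs),
      file.path(outdir, "truth.json"), dataframe = "rows", auto_unbox = TRUE,
      digits = NA)
    cfg_echo <- list(seed = config$seed,
                     tree = ape::write.tree(config$tree),
                     layout = as.list(config$layout),
                     rates = as.list(config$rates),
                     indel_rate = config$indel_rate,
                     indel_mean = config$indel_mean,
                     assembly = config$assembly[
                       vapply(config$assembly, length, 0L) > 0])
    jsonlite::write_json(cfg_echo, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(bundle)
}

#' Run the whole simulation in memory
#' @param config a [sim_config()].
#' @return list: template, helix_map, segments, msa, sequences, truth,
#'   registry, assembly (contigs/coverage/rdna_contigs), tree.
#' @export
simulate_bundle <- function(config) {
  tpl <- build_template(config)
  sim <- evolve_on_tree(tpl, config$tree, config$rates, config$indel_rate,
                        config$indel_mean, seed = config$seed + 1L)
  sim <- plant_its(sim, config$planted_its, seed = config$seed + 2L)
  ms <- sim_msa(sim)
  asm <- make_assembly(ms$sequences, config$assembly,
                       seed = config$seed + 3L)
  registry <- if (!is.null(config$planted_its) && nrow(config$planted_its)) {
    anchors <- strsplit(config$planted_its$region_id, "-", fixed = TRUE)
    data.frame(site_id = config$planted_its$site_id,
               lineage = config$planted_its$lineage,
               left_anchor = vapply(anchors, `[`, "", 1),
               right_anchor = vapply(anchors, `[`, "", 2),
               domain = "LSU",
               region_id = config$planted_its$region_id,
               stringsAsFactors = FALSE)
  } else {
    data.frame(site_id = character(0), lineage = character(0),
               left_anchor = character(0), right_anchor = character(0),
               domain = character(0), region_id = character(0),
               stringsAsFactors = FALSE)
  }
  # truth intervals on the unaligned sequence
  truth <- sim$truth
  if (nrow(truth)) {
    truth$start <- NA_integer_; truth$end <- NA_integer_
    for (i in seq_len(nrow(truth))) {
      st <- sim$leaves[[truth$species[i]]]
      its_pos <- which(st$class == "its")
      # restrict to this region's keys
      hm <- tpl$helix_map
      a <- strsplit(truth$region_id[i], "-", fixed = TRUE)[[1]]
      lk <- hm$span_end[match(a[1], hm$helix)]
      rk <- hm$span_start[match(a[2], hm$helix)]
      pos <- its_pos[st$key[its_pos] > lk & st$key[its_pos] < rk]
      truth$start[i] <- min(pos); truth$end[i] <- max(pos)
    }
  }
  list(template = tpl$template, helix_map = tpl$helix_map,
       segments = tpl$segments, classes = tpl$classes, msa = ms$msa,
       sequences = ms$sequences, truth = truth, registry = registry,
       assembly = asm, tree = config$tree)
}
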