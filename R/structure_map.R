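## Projecting template helix anchors through the structure-aware MSA onto
## every sequence, measuring inter-anchor region lengths, and flagging
## expansions by the ">4x longer than in background species" rule.

#' Project helix anchors through an alignment
#'
#' Each anchor's template interval (full span: 5' strand through 3' strand
#' where present) is converted to an alignment column interval via the
#' template row's gap pattern, then to every row's unaligned coordinates
#' (first to last non-gap position within those columns). An anchor fully
#' gapped in a row is ABSENT (`present = FALSE`). Projecting the template
#' onto itself reproduces the map spans exactly.
#'
#' @param msa an [as_msa()] alignment containing the template row.
#' @param hm a `helix_map` whose `template_id` names a row of `msa`.
#' @return data.frame: seq_id, anchor, start, end, present (unaligned
#'   1-based inclusive coordinates; NA when absent).
#' @export
project_anchors <- function(msa, hm) {
  template_id <- attr(hm, "template_id")
  if (is.na(template_id) || !template_id %in% names(msa))
    stop("helix map template row '", template_id, "' absent from alignment")
  tmpl <- strsplit(msa[[template_id]], "")[[1]]
  cols_nongap <- which(tmpl != "-")
  tlen <- length(cols_nongap)
  if (any(hm$span_end > tlen))
    stop("helix map coordinates exceed de-gapped template length (", tlen, ")")
  rows <- lapply(names(msa), function(id) {
    ch <- strsplit(msa[[id]], "")[[1]]
    nongap <- ch != "-"
    cum <- cumsum(nongap)
    res <- data.frame(seq_id = id, anchor = hm$helix,
                      start = NA_integer_, end = NA_integer_,
                      present = FALSE, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(hm))) {
      c1 <- cols_nongap[hm$span_start[i]]
      c2 <- cols_nongap[hm$span_end[i]]
      n_in <- cum[c2] - (if (c1 > 1) cum[c1 - 1] else 0L)
      if (n_in == 0) next
      res$end[i] <- cum[c2]
      res$start[i] <- cum[c2] - n_in + 1L
      res$present[i] <- TRUE
    }
    pres <- res[res$present, , drop = FALSE]
    if (nrow(pres) > 1 && any(diff(pres$start) <= 0))
      stop("anchor projection not monotone for row ", id)
    res
  })
  do.call(rbind, rows)
}

#' Template-level inter-anchor regions and their domains
#'
#' Regions are the template intervals between consecutive anchors of the map
#' (plus 5'/3' virtual termini). A region intersecting an ITS1/ITS2 segment
#' is domain `spacer`; otherwise it takes the rRNA segment (SSU, 5.8S, LSU)
#' containing it.
#'
#' @param hm a `helix_map`.
#' @param segments template segment data.frame (segment, start, end).
#' @return data.frame: region_id, left_anchor, right_anchor, t_start, t_end,
#'   domain.
#' @export
region_domains <- function(hm, segments) {
  left <- c("TER5", hm$helix)
  right <- c(hm$helix, "TER3")
  t_start <- c(1L, hm$span_end + 1L)
  t_end <- c(hm$span_start - 1L, max(segments$end))
  out <- data.frame(region_id = paste0(left, "-", right),
                    left_anchor = left, right_anchor = right,
                    t_start = t_start, t_end = t_end,
                    domain = NA_character_, stringsAsFactors = FALSE)
  spacers <- segments[segments$segment %in% c("ITS1", "ITS2"), , drop = FALSE]
  rrna <- segments[segments$segment %in% c("SSU", "5.8S", "LSU"), , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    a <- out$t_start[i]; b <- out$t_end[i]
    if (b < a) { # empty region between abutting anchors: use flanking point
      a <- out$t_end[i] + 1L; b <- a
    }
    in_spacer <- any(spacers$start <= b & spacers$end >= a)
    if (nrow(spacers) && in_spacer) { out$domain[i] <- "spacer"; next }
    j <- which(rrna$start <= a & rrna$end >= b)
    out$domain[i] <- if (length(j)) rrna$segment[j[1]] else "spacer"
  }
  out
}

#' Per-sequence inter-anchor region lengths
#'
#' For consecutive present anchors the region length is the gap between the
#' projected anchor intervals in unaligned coordinates. Anchors absent in a
#' row are bridged to the next present anchor (helix deletions occur in real
#' LSUs) with the skipped anchors recorded. Virtual 5'/3' termini are
#' included, so per row: anchor lengths + region lengths = unaligned
#' sequence length.
#'
#' @param proj projection from [project_anchors()].
#' @param msa the same alignment.
#' @param domains optional [region_domains()] table used to label regions.
#' @return data.frame: seq_id, region_id, left_anchor, right_anchor, start,
#'   end, length, skipped, domain. `start`/`end` delimit the region on the
#'   unaligned sequence (start > end means an empty region).
#' @export
interanchor_lengths <- function(proj, msa, domains = NULL) {
  seqs <- degap(msa)
  rows <- lapply(unique(proj$seq_id), function(id) {
    p <- proj[proj$seq_id == id, , drop = FALSE]
    pres <- p[p$present, , drop = FALSE]
    n <- nrow(pres)
    slen <- nchar(seqs[[id]])
    all_anchors <- p$anchor
    bound_l <- c("TER5", pres$anchor)
    bound_r <- c(pres$anchor, "TER3")
    start <- c(1L, pres$end + 1L)
    end <- c(pres$start - 1L, slen)
    skipped <- character(n + 1)
    for (i in seq_len(n + 1)) {
      li <- if (bound_l[i] == "TER5") 0L else match(bound_l[i], all_anchors)
      ri <- if (bound_r[i] == "TER3") length(all_anchors) + 1L
            else match(bound_r[i], all_anchors)
      if (ri - li > 1)
        skipped[i] <- paste(all_anchors[(li + 1):(ri - 1)], collapse = ",")
    }
    data.frame(seq_id = id, region_id = paste0(bound_l, "-", bound_r),
               left_anchor = bound_l, right_anchor = bound_r,
               start = start, end = end, length = pmax(end - start + 1L, 0L),
               skipped = skipped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(domains))
    out$domain <- domains$domain[match(out$region_id, domains$region_id)]
  out
}

#' Flag expansion segments by the fold-change rule
#'
#' A focal species is flagged in a region iff its region length exceeds
#' `factor` times the background summary statistic AND the absolute excess
#' is at least `min_abs` nt (guards the scale-free rule against near-zero
#' backgrounds). The background statistic defaults to the median, which is
#' robust to one other lineage also carrying an ITS at the same site; `max`
#' gives the strictest reading of "longer than in other species".
#'
#' @param regions data.frame from [interanchor_lengths()].
#' @param focal character vector of focal species.
#' @param background character vector of background species (disjoint from
#'   `focal`, at least 2 per region).
#' @param factor fold-change threshold (default 4).
#' @param min_abs minimum absolute excess in nt (default 30).
#' @param stat background summary: `"median"` or `"max"`, or a function.
#' @param include_termini also test the virtual 5'/3' terminus regions
#'   (default `FALSE`: an internal spacer must be flanked by structure on
#'   both sides; beyond the outermost helix the molecule simply ends, so
#'   length variation there is end heterogeneity, not a candidate ITS).
#' @return data.frame of expansion segments: species, region_id,
#'   left_anchor, right_anchor, start, end, length, background_stat, factor,
#'   domain; attribute `skipped_regions` lists regions with insufficient
#'   background.
#' @export
detect_expansions <- function(regions, focal, background, factor = 4,
                              min_abs = 30, stat = "median",
                              include_termini = FALSE) {
  if (length(intersect(focal, background)))
    stop("focal and background species sets must be disjoint")
  statf <- if (is.function(stat)) stat
           else switch(match.arg(stat, c("median", "max")),
                       median = stats::median, max = max)
  out <- list(); skipped <- character(0)
  if (!include_termini)
    regions <- regions[regions$left_anchor != "TER5" &
                         regions$right_anchor != "TER3", , drop = FALSE]
  foc <- regions[regions$seq_id %in% focal, , drop = FALSE]
  for (i in seq_len(nrow(foc))) {
    rid <- foc$region_id[i]
    bg <- regions$length[regions$seq_id %in% background &
                           regions$region_id == rid]
    if (length(bg) < 2) {
      skipped <- union(skipped, rid)
      warning("region ", rid, ": fewer than 2 background species; skipped",
              call. = FALSE)
      next
    }
    b <- statf(bg)
    len <- foc$length[i]
    if (len > factor * b && (len - b) >= min_abs) {
      row <- foc[i, c("seq_id", "region_id", "left_anchor", "right_anchor",
                      "start", "end", "length"), drop = FALSE]
      names(row)[1] <- "species"
      row$background_stat <- b
      row$factor <- if (b > 0) len / b else Inf
      if ("domain" %in% names(foc)) row$domain <- foc$domain[i]
      out[[length(out) + 1]] <- row
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(species = character(0), region_id = character(0),
                         left_anchor = character(0), right_anchor = character(0),
                         start = integer(0), end = integer(0),
                         length = integer(0), background_stat = numeric(0),
                         factor = numeric(0), domain = character(0),
                         stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped_regions") <- skipped
  res
}

#' Fold a sequence by base-pair maximization
#'
#' Internal engine: Nussinov-style maximization of Watson-Crick + GU pairs
#' with a minimum hairpin loop of 3 and deterministic traceback. This is a
#' sanity/annotation aid for helix anchors, not a thermodynamic model;
#' external engines can be plugged in behind the same contract.
#'
#' @param seq a single sequence (T treated as U).
#' @param engine `"internal"` or a function `(seq) -> list(structure, pairs)`.
#' @param min_loop minimum unpaired loop length.
#' @return list: `structure` (dot-bracket, same length as input), `pairs`.
#' @export
fold_region <- function(seq, engine = "internal", min_loop = 3L) {
  s <- normalize_residues(seq[[1]])
  if (grepl("[^ACGTN]", s)) stop("non-nucleotide residues in fold input")
  if (is.function(engine)) return(engine(s))
  .nussinov_cpp(s, as.integer(min_loop))
}
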