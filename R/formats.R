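## File formats and conventions shared by every stage.
##
## Internal coordinates are 1-based inclusive throughout (the native GFF3 /
## IRanges convention). The helix-map and segment-boundary TSV formats are
## 0-based half-open on disk and are converted here, at the single read/write
## point, so that a written file re-read reproduces the internal intervals.

#' Normalize nucleotide residues
#'
#' Uppercases, converts RNA `U` to `T`, and validates the alphabet. Only
#' `A`, `C`, `G`, `T`, `N` (and `-` when `allow_gaps = TRUE`) are accepted;
#' other IUPAC ambiguity codes are rejected so that silent miscoding of
#' assembly consensus sequences cannot propagate.
#'
#' @param x character vector of sequences.
#' @param allow_gaps allow `-` (alignment rows).
#' @return normalized character vector (names preserved).
#' @export
normalize_residues <- function(x, allow_gaps = FALSE) {
  out <- chartr("u", "t", tolower(x))
  out <- toupper(out)
  pat <- if (allow_gaps) "^[ACGTN-]*$" else "^[ACGTN]*$"
  bad <- !grepl(pat, out)
  if (any(bad)) {
    offending <- gsub(if (allow_gaps) "[ACGTN-]" else "[ACGTN]", "", out[bad][1])
    stop("non-nucleotide or ambiguous residues not supported: '",
         substr(offending, 1, 10), "' in sequence ",
         if (!is.null(names(out))) names(out)[bad][1] else which(bad)[1])
  }
  names(out) <- names(x)
  out
}

#' Read sequences from a FASTA file
#'
#' Multi-line records are concatenated; residues are normalized
#' (uppercase, `U` converted to `T`). Returns a named character vector
#' (names are the first whitespace-delimited header token); full header
#' descriptions are kept in the `"description"` attribute.
#'
#' @param path FASTA file.
#' @param allow_gaps accept `-` residues (for alignment FASTA).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    out <- character(0)
    attr(out, "description") <- character(0)
    return(out)
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: sequence data before first '>' header at line ",
         nonblank[1])
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("malformed FASTA: empty record id")
  seqs <- normalize_residues(seqs, allow_gaps = allow_gaps)
  names(seqs) <- ids
  attr(seqs, "description") <- setNames(headers, ids)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a multiple sequence alignment from FASTA
#'
#' All rows must have identical aligned width; gaps are `-`.
#'
#' @param path alignment FASTA.
#' @return named character vector of aligned rows with attribute `width`.
#' @export
read_msa <- function(path) {
  rows <- read_fasta(path, allow_gaps = TRUE)
  as_msa(rows)
}

#' Validate aligned rows as an MSA
#' @param rows named character vector of equal-width gapped sequences.
#' @return the rows, with `width` attribute, class `msa`.
#' @export
as_msa <- function(rows) {
  w <- unique(nchar(rows))
  if (length(rows) > 0 && length(w) != 1)
    stop("alignment rows have unequal widths: ", paste(w, collapse = ", "))
  if (anyDuplicated(names(rows))) stop("duplicate alignment row ids")
  attr(rows, "width") <- if (length(rows)) w else 0L
  class(rows) <- "msa"
  rows
}

#' Remove gaps from alignment rows
#' @param msa an `msa` (or any character vector with `-` gaps).
#' @return named character vector of unaligned sequences.
#' @export
degap <- function(msa) {
  out <- gsub("-", "", unclass(msa), fixed = TRUE)
  attributes(out) <- list(names = names(msa))
  out
}

#' Parse per-contig coverage
#'
#' Coverage comes either from SPAdes-style contig headers
#' (`NODE_<i>_length_<L>_cov_<c>`) or from a 2/3-column TSV
#' (contig, depth\[, length\]). An explicit TSV takes precedence over headers.
#'
#' @param seqs named character vector of contigs (may be `NULL` if `tsv` has
#'   lengths).
#' @param tsv optional path or data.frame with columns contig, depth, length.
#' @return data.frame with columns `contig`, `length`, `depth`.
#' @export
parse_coverage <- function(seqs = NULL, tsv = NULL) {
  if (is.null(seqs) && is.null(tsv)) stop("supply contigs and/or a coverage TSV")
  tab <- NULL
  if (!is.null(tsv)) {
    tab <- if (is.data.frame(tsv)) tsv
           else read.delim(tsv, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
    if (ncol(tab) < 2) stop("coverage TSV needs >= 2 columns (contig, depth)")
    tab <- data.frame(contig = as.character(tab[[1]]),
                      depth = as.numeric(tab[[2]]),
                      length = if (ncol(tab) >= 3) as.numeric(tab[[3]]) else NA_real_,
                      stringsAsFactors = FALSE)
  }
  ids <- if (!is.null(seqs)) names(seqs) else tab$contig
  res <- data.frame(contig = ids, length = NA_real_, depth = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(seqs)) res$length <- nchar(seqs)
  m <- regmatches(ids, regexec("^NODE_\\d+_length_(\\d+)_cov_([0-9.eE+-]+)$", ids))
  hdr_len <- vapply(m, function(x) if (length(x)) as.numeric(x[2]) else NA_real_, 0)
  hdr_cov <- vapply(m, function(x) if (length(x)) as.numeric(x[3]) else NA_real_, 0)
  res$depth <- hdr_cov
  res$length[is.na(res$length)] <- hdr_len[is.na(res$length)]
  if (!is.null(tab)) {
    i <- match(res$contig, tab$contig)
    res$depth[!is.na(i)] <- tab$depth[i[!is.na(i)]]
    has_len <- !is.na(i) & !is.na(tab$length[i])
    res$length[has_len] <- tab$length[i[has_len]]
    extra <- setdiff(tab$contig, res$contig)
    if (length(extra)) {
      j <- match(extra, tab$contig)
      res <- rbind(res, data.frame(contig = extra, length = tab$length[j],
                                   depth = tab$depth[j]))
    }
  }
  bad <- res$contig[is.na(res$depth)]
  if (length(bad))
    stop("no parsable coverage (header or TSV) for contig(s): ",
         paste(bad, collapse = ", "))
  if (any(!is.na(res$length) & res$length <= 0)) stop("non-positive contig length")
  rownames(res) <- NULL
  res
}

#' Read a helix anchor map
#'
#' TSV columns: `helix_name`, `class` (`core`/`ES`), `fp_start`, `fp_end`,
#' `tp_start`, `tp_end`; coordinates 0-based half-open on the template,
#' `tp_*` empty for single-strand anchors. Converted to 1-based inclusive
#' internal intervals and validated.
#'
#' @param path TSV file (header row required, `#` comments allowed).
#' @param template_id id of the template sequence the coordinates index.
#' @return a `helix_map` data.frame.
#' @export
read_helix_map <- function(path, template_id = NA_character_) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("helix_name", "class", "fp_start", "fp_end", "tp_start", "tp_end")
  if (!all(need %in% names(tab)))
    stop("helix map must have columns: ", paste(need, collapse = ", "))
  hm <- data.frame(
    helix = as.character(tab$helix_name),
    class = as.character(tab$class),
    fp_start = as.integer(tab$fp_start) + 1L,
    fp_end = as.integer(tab$fp_end),
    tp_start = ifelse(is.na(tab$tp_start) | tab$tp_start == "",
                      NA_integer_, as.integer(tab$tp_start) + 1L),
    tp_end = suppressWarnings(as.integer(tab$tp_end)),
    stringsAsFactors = FALSE)
  as_helix_map(hm, template_id = template_id)
}

#' Validate a helix map
#'
#' @param hm data.frame with columns helix, class, fp_start, fp_end,
#'   tp_start, tp_end (1-based inclusive; tp_* may be NA).
#' @param template_id template sequence id.
#' @return validated `helix_map` sorted by `fp_start`.
#' @export
as_helix_map <- function(hm, template_id = NA_character_) {
  if (anyDuplicated(hm$helix)) stop("duplicate helix names in map")
  if (!all(hm$class %in% c("core", "ES")))
    stop("helix class must be 'core' or 'ES'")
  if (any(hm$fp_end < hm$fp_start))
    stop("invalid helix 5' interval (end < start): ",
         paste(hm$helix[hm$fp_end < hm$fp_start], collapse = ", "))
  has_tp <- !is.na(hm$tp_start)
  if (any(has_tp & (hm$tp_end < hm$tp_start)))
    stop("invalid helix 3' interval (end < start)")
  if (any(has_tp & (hm$tp_start <= hm$fp_end)))
    stop("helix 3' strand overlaps or precedes its 5' strand")
  hm <- hm[order(hm$fp_start), , drop = FALSE]
  span_start <- hm$fp_start
  span_end <- ifelse(is.na(hm$tp_end), hm$fp_end, hm$tp_end)
  if (nrow(hm) > 1 && any(span_start[-1] <= span_end[-nrow(hm)]))
    stop("overlapping helix anchors in map")
  hm$span_start <- span_start
  hm$span_end <- span_end
  rownames(hm) <- NULL
  attr(hm, "template_id") <- template_id
  class(hm) <- c("helix_map", "data.frame")
  hm
}

#' Write a helix map TSV (0-based half-open on disk)
#' @param hm a `helix_map`.
#' @param path output TSV.
#' @export
write_helix_map <- function(hm, path) {
  out <- data.frame(helix_name = hm$helix, class = hm$class,
                    fp_start = hm$fp_start - 1L, fp_end = hm$fp_end,
                    tp_start = ifelse(is.na(hm$tp_start), "", hm$tp_start - 1L),
                    tp_end = ifelse(is.na(hm$tp_end), "", hm$tp_end))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read template segment boundaries
#'
#' TSV columns `segment`, `start`, `end` (0-based half-open on disk).
#' @param path TSV file.
#' @return data.frame segment/start/end, 1-based inclusive.
#' @export
read_segments <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("segment", "start", "end") %in% names(tab)))
    stop("segment TSV must have columns segment, start, end")
  data.frame(segment = as.character(tab$segment),
             start = as.integer(tab$start) + 1L,
             end = as.integer(tab$end), stringsAsFactors = FALSE)
}

#' Write template segment boundaries (0-based half-open on disk)
#' @param segments data.frame segment/start/end (1-based inclusive).
#' @param path output TSV.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(segment = segments$segment,
                    start = segments$start - 1L, end = segments$end)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.gff3_type <- c(SSU = "rRNA_18S_rRNA", ITS1 = "internal_transcribed_spacer",
                `5.8S` = "rRNA_5_8S_rRNA", ITS2 = "internal_transcribed_spacer",
                LSU = "rRNA_28S_rRNA", IGR = "intergenic_region")

#' Write operon annotations as GFF3
#'
#' Each annotation becomes a parent `operon` feature spanning its segments,
#' with child rRNA/ITS features. Output ordering is deterministic
#' (contig, then start).
#'
#' @param annotations a list of `operon_annotation` objects (see
#'   [annotate_operon()]).
#' @param path output GFF3 file.
#' @export
write_gff3 <- function(annotations, path) {
  if (inherits(annotations, "operon_annotation")) annotations <- list(annotations)
  ord <- order(vapply(annotations, function(a) a$contig, ""),
               vapply(annotations, function(a) min(a$segments$start), 0))
  annotations <- annotations[ord]
  rows <- list()
  for (k in seq_along(annotations)) {
    a <- annotations[[k]]
    seg <- a$segments[order(a$segments$start), , drop = FALSE]
    if (any(seg$end < seg$start))
      stop("empty or inverted interval for segment ",
           seg$segment[which(seg$end < seg$start)[1]], " on ", a$contig)
    op_id <- paste0("operon_", a$contig, "_", k)
    rows[[length(rows) + 1]] <- data.frame(
      seqnames = a$contig, start = min(seg$start), end = max(seg$end),
      strand = a$strand, type = "operon", ID = op_id, Parent = NA_character_,
      Name = op_id, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(seg))) {
      rows[[length(rows) + 1]] <- data.frame(
        seqnames = a$contig, start = seg$start[i], end = seg$end[i],
        strand = a$strand, type = unname(.gff3_type[seg$segment[i]]),
        ID = paste0(op_id, "_", seg$segment[i]), Parent = op_id,
        Name = seg$segment[i], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqnames,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$ID <- tab$ID
  S4Vectors::mcols(gr)$Name <- tab$Name
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(tab$Parent), "", tab$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read operon annotations back from GFF3
#'
#' Inverse of [write_gff3()] (used for coordinate round-trip checks and for
#' consuming externally produced annotations).
#'
#' @param path GFF3 file.
#' @return list of `operon_annotation` objects.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  parents <- df[df$type == "operon", , drop = FALSE]
  seg_names <- setNames(names(.gff3_type), .gff3_type)
  out <- lapply(seq_len(nrow(parents)), function(k) {
    pid <- parents$ID[k]
    kids <- df[vapply(df$Parent, function(p) pid %in% p, TRUE), , drop = FALSE]
    structure(list(
      contig = as.character(parents$seqnames[k]),
      strand = as.character(parents$strand[k]),
      complete = all(c("SSU", "ITS1", "5.8S", "ITS2", "LSU") %in% kids$Name),
      depth = NA_real_,
      segments = data.frame(segment = kids$Name, start = kids$start,
                            end = kids$end, stringsAsFactors = FALSE)),
      class = "operon_annotation")
  })
  out
}

#' Read a newick tree
#'
#' Standard newick via \pkg{ape}; polytomies allowed, duplicate leaf labels
#' rejected.
#'
#' @param path newick file (or a literal newick string).
#' @return an \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- if (file.exists(path)) tryCatch(ape::read.tree(path), error = function(e) NULL)
        else tryCatch(ape::read.tree(text = path), error = function(e) NULL)
  if (is.null(tr)) stop("failed to parse newick: ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) stop("expected a single newick tree")
    tr <- tr[[1]]
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Read a known-ITS site registry
#'
#' TSV columns: `site_id`, `lineage`, `left_anchor`, `right_anchor`, and
#' optionally `domain` (`LSU`, `5.8S`, `SSU`). `region_id` is derived as
#' `left_anchor-right_anchor`.
#'
#' @param path TSV file (`#` comments allowed).
#' @return data.frame registry.
#' @export
read_its_registry <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("site_id", "lineage", "left_anchor", "right_anchor")
  if (!all(need %in% names(tab)))
    stop("registry must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$site_id)) stop("duplicate site_id in registry")
  tab$region_id <- if (nrow(tab)) paste0(tab$left_anchor, "-",
                                         tab$right_anchor) else character(0)
  if (!"domain" %in% names(tab)) tab$domain <- NA_character_
  tab
}
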