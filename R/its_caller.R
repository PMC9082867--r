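## Classifying expansion segments: known additional ITSs (registry sites),
## novel ITS candidates (5.8S/LSU divergent regions), or SSU expansion
## segments (retained in the mature 18S rRNA, hence never ITS calls);
## plus ORF screening, cross-ITS homology, and fragment-count arithmetic.

#' Classify expansion segments
#'
#' Rules, in fixed order: (1) the region matches a registry site ->
#' `known_ITS` with that site id; (2) else the region lies in the SSU domain
#' -> `ssu_expansion` (SSU expansions are retained in the mature 18S rRNA);
#' (3) else (5.8S/LSU domain) -> `novel_candidate`. Classification is total
#' and deterministic; every call carries its evidence (length, fold factor,
#' background statistic).
#'
#' @param expansions data.frame from [detect_expansions()].
#' @param registry data.frame from [read_its_registry()] (may have 0 rows).
#' @param domains data.frame from [region_domains()] mapping region_id to
#'   domain; every expansion region must be mapped (directly, or via its
#'   flanking-anchor pair when bridging skipped absent anchors).
#' @return data.frame of calls: species, classification, site_id, region_id,
#'   start, end, length, background_stat, factor, domain.
#' @export
classify_expansions <- function(expansions, registry, domains) {
  n <- nrow(expansions)
  out <- expansions[, intersect(c("species", "region_id", "start", "end",
                                  "length", "background_stat", "factor"),
                                names(expansions)), drop = FALSE]
  out$site_id <- rep(NA_character_, n)
  out$classification <- rep(NA_character_, n)
  dom <- domains$domain[match(expansions$region_id, domains$region_id)]
  if (any(is.na(dom))) {
    bad <- unique(expansions$region_id[is.na(dom)])
    stop("expansion region(s) not in domain map: ", paste(bad, collapse = ", "))
  }
  out$domain <- dom
  for (i in seq_len(n)) {
    j <- which(registry$region_id == expansions$region_id[i])
    if (length(j)) {
      out$classification[i] <- "known_ITS"
      out$site_id[i] <- paste(registry$site_id[j], collapse = "/")
    } else if (dom[i] == "SSU") {
      out$classification[i] <- "ssu_expansion"
    } else if (dom[i] %in% c("5.8S", "LSU")) {
      out$classification[i] <- "novel_candidate"
    } else {
      out$classification[i] <- "spacer_variation"
    }
  }
  rownames(out) <- NULL
  out[, c("species", "classification", "site_id", "region_id", "start",
          "end", "length", "background_stat", "factor", "domain")]
}

.GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

.orf_scan_frame <- function(codons, min_aa) {
  ## maximal ORFs: first ATG after the previous stop, through the stop codon
  ## (or sequence end -> partial). Returns codon-index intervals.
  stops <- which(codons %in% .GENETIC_CODE_STOPS)
  starts_all <- which(codons == "ATG")
  res <- list()
  seg_begin <- 1L
  for (st in c(stops, length(codons) + 1L)) {
    partial <- st > length(codons)
    cand <- starts_all[starts_all >= seg_begin & starts_all < st]
    if (length(cand)) {
      a <- cand[1]
      aa_len <- st - a # codons from ATG to (stop - 1), i.e. aa incl. Met
      if (partial) aa_len <- length(codons) - a + 1L
      if (aa_len > min_aa)
        res[[length(res) + 1]] <- c(from = a,
                                    to = if (partial) length(codons) else st,
                                    aa = aa_len, partial = as.integer(partial))
    }
    seg_begin <- st + 1L
  }
  res
}

#' Six-frame ORF scan
#'
#' An ORF starts at the first ATG after the previous in-frame stop and runs
#' to the stop codon (or to the sequence end, flagged `partial`). Reported
#' iff its length in amino acids (including the initiator Met, excluding the
#' stop) is strictly greater than `min_aa`. Standard genetic code.
#' Alternatively (`mode = "stop_to_stop"`) maximal open frames between stops
#' are reported without requiring ATG.
#'
#' @param seq single normalized sequence.
#' @param min_aa report ORFs longer than this many amino acids (default 20).
#' @param both_strands scan the reverse complement too.
#' @param mode `"atg"` (default) or `"stop_to_stop"`.
#' @return data.frame: frame (+1..+3, -1..-3), start, end (interval on the
#'   input forward strand, including the stop codon), aa, partial.
#' @export
orf_scan <- function(seq, min_aa = 20L, both_strands = TRUE, mode = c("atg",
                     "stop_to_stop")) {
  mode <- match.arg(mode)
  s <- seq[[1]]
  n <- nchar(s)
  empty <- data.frame(frame = character(0), start = integer(0),
                      end = integer(0), aa = integer(0), partial = logical(0),
                      stringsAsFactors = FALSE)
  if (n < 3) return(empty)
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    ss <- if (strand == "+") s else revcomp(s)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3
      if (ncod < 1) next
      pos <- off + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(ss, pos, pos + 2L)
      hits <- if (mode == "atg") .orf_scan_frame(codons, min_aa)
              else .orf_scan_stop_to_stop(codons, min_aa)
      for (h in hits) {
        nt_from <- off + 1L + 3L * (h[["from"]] - 1L)
        nt_to <- off + 3L * h[["to"]]
        nt_to <- min(nt_to, n)
        if (strand == "-") {
          tmp <- nt_from
          nt_from <- n - nt_to + 1L
          nt_to <- n - tmp + 1L
        }
        rows[[length(rows) + 1]] <- data.frame(
          frame = paste0(strand, off + 1L), start = nt_from, end = nt_to,
          aa = h[["aa"]], partial = as.logical(h[["partial"]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.orf_scan_stop_to_stop <- function(codons, min_aa) {
  stops <- which(codons %in% .GENETIC_CODE_STOPS)
  res <- list()
  seg_begin <- 1L
  for (st in c(stops, length(codons) + 1L)) {
    partial <- st > length(codons)
    a <- seg_begin
    to <- if (partial) length(codons) else st
    aa_len <- (if (partial) length(codons) else st - 1L) - a + 1L
    if (aa_len > min_aa && aa_len > 0)
      res[[length(res) + 1]] <- c(from = a, to = to, aa = aa_len,
                                  partial = as.integer(partial))
    seg_begin <- st + 1L
  }
  res
}

#' All-vs-all cross-ITS homology
#'
#' Best local alignment identity between ITS sequences, within and between
#' lineages. The matrix is symmetric with an excluded (NA) diagonal. A pair
#' is reported "homologous" when best local identity >= `id_min` over an
#' alignment of >= `len_min` aligned columns (report threshold only, not a
#' classification input).
#'
#' @param its_seqs named character vector of ITS sequences.
#' @param params `scoring_params`.
#' @param id_min,len_min report thresholds for the `homologous` attribute.
#' @return numeric identity matrix with attributes `score` (matrix) and
#'   `homologous` (logical matrix).
#' @export
cross_its_homology <- function(its_seqs, params = scoring_params(),
                               id_min = 0.7, len_min = 50L) {
  n <- length(its_seqs)
  ids <- names(its_seqs)
  idm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  scm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  hom <- matrix(NA, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      al <- align_local(its_seqs[[i]], its_seqs[[j]], params)
      alen <- al$nmatch + al$nmismatch + al$ngap
      idm[i, j] <- idm[j, i] <- al$identity
      scm[i, j] <- scm[j, i] <- al$score
      hom[i, j] <- hom[j, i] <- (al$identity >= id_min && alen >= len_min)
    }
  }
  attr(idm, "score") <- scm
  attr(idm, "homologous") <- hom
  idm
}

#' Number of mature 28S-derived rRNA fragments
#'
#' Each additional ITS inside the 28S (LSU) domain splits the mature rRNA
#' once, so fragments = 28S-domain ITS calls (known or novel) + 1. Five
#' kinetoplastid ITSs give the six kinetoplastid fragments; twelve euglenid
#' ITSs give thirteen; zero gives a contiguous 28S.
#'
#' @param calls data.frame from [classify_expansions()] (one species, or use
#'   `species` to restrict).
#' @param species optional species to restrict to.
#' @param domain which domain's fragmentation to count (`"28S"`/`"LSU"`).
#' @return integer fragment count.
#' @export
fragment_count <- function(calls, species = NULL, domain = "28S") {
  dom <- if (domain %in% c("28S", "LSU")) "LSU" else domain
  if (!is.null(species)) calls <- calls[calls$species %in% species, , drop = FALSE]
  n_its <- sum(calls$classification %in% c("known_ITS", "novel_candidate") &
                 calls$domain == dom)
  n_its + 1L
}
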