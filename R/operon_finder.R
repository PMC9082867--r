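## Locating rRNA operon contigs in an assembly: seed-and-extend local homology
## search with Karlin-Altschul E-values, the multi-copy coverage filter, and
## segment annotation against an annotated reference operon.

#' Reverse complement
#' @param x character vector of normalized sequences.
#' @return reverse-complemented sequences (names preserved).
#' @export
revcomp <- function(x) {
  out <- vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

#' Karlin-Altschul parameters for ungapped match/mismatch scoring
#'
#' Solves \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1} for \eqn{\lambda}
#' under uniform base composition, and computes \eqn{K} by the classical
#' lattice formula (score distributions convolved term by term). For the
#' +1/-2 default this reproduces the published ungapped BLASTN constants
#' (\eqn{\lambda = 1.3327}, \eqn{K = 0.621}).
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param iterations number of convolution terms in the K sum.
#' @return list with `lambda`, `K`, `H` (relative entropy, nats).
#' @export
karlin_altschul <- function(match = 1L, mismatch = -2L, iterations = 80L) {
  stopifnot(match > 0, mismatch < 0)
  p_match <- 0.25
  f <- function(l) p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  lambda <- stats::uniroot(f, c(1e-8, 20), tol = 1e-12)$root
  lo <- mismatch; hi <- match
  p <- numeric(hi - lo + 1)
  p[match - lo + 1] <- p_match
  p[mismatch - lo + 1] <- 1 - p_match
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  d <- gcd2(abs(match), abs(mismatch))
  s <- lo:hi
  H <- lambda * sum(s * p * exp(lambda * s))
  Pj <- p; loj <- lo; sigma <- 0
  for (j in seq_len(iterations)) {
    sj <- loj:(loj + length(Pj) - 1)
    sigma <- sigma + sum(ifelse(sj < 0, Pj * exp(lambda * sj), Pj)) / j
    Pn <- numeric(length(Pj) + (hi - lo))
    for (k in seq_along(p))
      Pn[k:(k + length(Pj) - 1)] <- Pn[k:(k + length(Pj) - 1)] + p[k] * Pj
    Pj <- Pn; loj <- loj + lo
  }
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K, H = H)
}

#' Scoring parameters for the local homology search
#'
#' @param match,mismatch,gap_open,gap_extend integer alignment scores; a gap
#'   of length g scores `gap_open + (g-1)*gap_extend`.
#' @param seed_k exact-match word length used for seeding.
#' @param xdrop reserved extension drop-off knob (extension is currently an
#'   exact local DP within the seeded window, which dominates x-drop).
#' @param window_pad subject padding (nt) around a seed cluster.
#' @return list of class `scoring_params` with `lambda`/`K` recomputed for
#'   the ungapped scores.
#' @export
scoring_params <- function(match = 1L, mismatch = -2L, gap_open = -5L,
                           gap_extend = -2L, seed_k = 12L, xdrop = 20L,
                           window_pad = 100L) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0, seed_k >= 4)
  ka <- karlin_altschul(match, mismatch)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 seed_k = as.integer(seed_k), xdrop = as.integer(xdrop),
                 window_pad = as.integer(window_pad),
                 lambda = ka$lambda, K = ka$K),
            class = "scoring_params")
}

#' Karlin-Altschul E-value
#' @param score alignment score.
#' @param m,n query and subject lengths.
#' @param params `scoring_params`.
#' @return E-value `K * m * n * exp(-lambda * score)`.
#' @export
evalue <- function(score, m, n, params) {
  params$K * as.numeric(m) * as.numeric(n) * exp(-params$lambda * score)
}

#' Best local alignment between two sequences
#'
#' Affine-gap Smith-Waterman (exact DP). Identity is computed over aligned
#' columns excluding gap columns.
#'
#' @param q,s normalized sequences (single strings).
#' @param params `scoring_params`.
#' @param band optional integer pair `c(dlo, dhi)`: restrict the DP to
#'   diagonals `dlo <= j - i <= dhi` (subject minus query position). `NULL`
#'   computes the full matrix.
#' @return list: score, qstart/qend, sstart/send (1-based inclusive),
#'   nmatch, nmismatch, ngap, identity.
#' @export
align_local <- function(q, s, params = scoring_params(), band = NULL) {
  if (is.null(band)) band <- c(NA_integer_, NA_integer_)
  r <- .sw_align_cpp(q, s, params$match, params$mismatch,
                     params$gap_open, params$gap_extend,
                     as.integer(band[1]), as.integer(band[2]))
  denom <- r$nmatch + r$nmismatch
  r$identity <- if (denom > 0) r$nmatch / denom else 0
  r
}

.kmer_positions <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

## Seed subject positions (starts) whose k-mer occurs anywhere in the query,
## clustered into windows. Clusters break on large subject gaps or large
## diagonal jumps: colinear homologies (diagonal drift bounded by indel
## totals) stay in one window, while scattered spurious matches (e.g. the
## reverse strand of self-complementary hairpins) fall into many small
## windows instead of one gene-sized one. `sk` is the subject's precomputed
## k-mer vector.
.seed_clusters <- function(qk, sk, k, gap_max = 600L, diag_max = 700L) {
  hit <- which(sk %in% qk)
  if (length(hit) == 0) return(list())
  qpos <- match(sk[hit], qk)
  diag <- hit - qpos
  # break on subject gaps, diagonal jumps, or backward query jumps: a true
  # homology (in the strand under test) advances through the query, whereas
  # reverse-strand hairpin artifacts walk it backwards and tandem copies
  # restart it -- both belong in separate windows
  breaks <- which(diff(hit) > gap_max | abs(diff(diag)) > diag_max |
                    diff(qpos) < -50L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(hit))
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    list(from = hit[starts[i]], to = hit[ends[i]] + k - 1L,
         qmin = min(qpos[idx]), qmax = max(qpos[idx]) + k - 1L,
         dmin = min(diag[idx]), dmax = max(diag[idx]),
         seeds = hit[idx])
  })
}

#' Seed-and-extend local homology search
#'
#' Exact k-mer seeds on both strands are clustered by subject position; each
#' cluster window is resolved by exact affine local DP. Every exact shared
#' substring of length >= `seed_k` is guaranteed to seed a window. Hits are
#' reported on the subject forward strand, minus-strand hits with
#' `strand == "-"`; E-values use the ungapped Karlin-Altschul constants with
#' m = query length, n = subject length.
#'
#' @param queries,subjects named character vectors of normalized sequences.
#' @param params `scoring_params`.
#' @param e_max optional E-value ceiling on reported hits (default `Inf`).
#' @return data.frame of hits sorted by (evalue asc, score desc, subject id):
#'   query, subject, qstart, qend, sstart, send, strand, score, evalue,
#'   identity.
#' @export
search_homologs <- function(queries, subjects, params = scoring_params(),
                            e_max = Inf) {
  empty <- data.frame(query = character(0), subject = character(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      strand = character(0), score = integer(0),
                      evalue = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(queries) == 0 || length(subjects) == 0) return(empty)
  if (any(grepl("[^ACGTN]", c(queries, subjects))))
    stop("sequences must be normalized (A/C/G/T/N) before searching")
  if (is.null(names(queries)) || is.null(names(subjects)))
    stop("queries and subjects must be named")
  k <- params$seed_k
  if (any(nchar(queries) < k))
    stop("seed_k (", k, ") exceeds shortest query length")
  qk_fwd <- lapply(queries, .kmer_positions, k = k)
  qk_rev <- lapply(revcomp(queries), .kmer_positions, k = k)
  rows <- list()
  for (si in seq_along(subjects)) {
    sname <- names(subjects)[si]
    subj <- subjects[[si]]
    n_s <- nchar(subj)
    sk <- .kmer_positions(subj, k)
    for (qi in seq_along(queries)) {
      qname <- names(queries)[qi]
      for (strand in c("+", "-")) {
        q <- if (strand == "+") queries[[qi]] else revcomp(queries[[qi]])
        qk <- if (strand == "+") qk_fwd[[qi]] else qk_rev[[qi]]
        # iterate with masking so that tandem/nearby copies of a query each
        # yield their own hit: later rounds only revisit seeds not yet
        # covered by an accepted alignment
        masked <- subj
        all_seeds <- .seed_clusters(qk, sk, k)
        seed_pos <- unlist(lapply(all_seeds, `[[`, "seeds"))
        covered <- logical(length(seed_pos))
        sk_cur <- sk
        for (round in 1:6) {
          clusters <- .seed_clusters(qk, sk_cur, k)
          if (!length(clusters)) break
          found <- FALSE
          n_cov_before <- sum(covered)
          for (cl in clusters) {
            if (round > 1 &&
                  !any(!covered & seed_pos >= cl[["from"]] &
                         seed_pos <= cl[["to"]])) next
            from <- max(1L, cl[["from"]] - params$window_pad)
            to <- min(n_s, cl[["to"]] + params$window_pad)
            win <- substr(masked, from, to)
            # restrict the query to the seeded range (padded); spurious
            # clusters then cost a small DP, not a full-query one
            qpad <- 2L * params$window_pad
            q_from <- max(1L, cl[["qmin"]] - qpad)
            q_to <- min(nchar(q), cl[["qmax"]] + qpad)
            # band the DP around the seeded diagonals (converted to the
            # sliced coordinates), padded for indel drift between seeds
            bpad <- 2L * params$window_pad
            band <- c(cl[["dmin"]] - from + q_from - bpad,
                      cl[["dmax"]] - from + q_from + bpad)
            al <- align_local(substr(q, q_from, q_to), win, params,
                              band = band)
            if (al$score <= 0) next
            found <- TRUE
            sstart <- from + al$sstart - 1L
            send <- from + al$send - 1L
            qstart <- q_from + al$qstart - 1L
            qend <- q_from + al$qend - 1L
            if (strand == "-") {
              m_q <- nchar(q)
              tmp <- qstart
              qstart <- m_q - qend + 1L
              qend <- m_q - tmp + 1L
            }
            rows[[length(rows) + 1]] <- data.frame(
              query = qname, subject = sname, qstart = qstart, qend = qend,
              sstart = sstart, send = send, strand = strand,
              score = al$score,
              evalue = evalue(al$score, nchar(queries[[qi]]), n_s, params),
              identity = al$identity, stringsAsFactors = FALSE)
            substr(masked, sstart, send) <- strrep("N", send - sstart + 1L)
            covered <- covered | (seed_pos + k - 1L <= send &
                                    seed_pos >= sstart)
          }
          if (!found || all(covered)) break
          if (sum(covered) == n_cov_before) break # no progress on seeds
          sk_cur <- .kmer_positions(masked, k)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  hits <- hits[order(hits$evalue, -hits$score, hits$subject, hits$query), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Genome-average sequencing depth
#'
#' Default is the length-weighted median of per-contig depths: a handful of
#' deep multi-copy contigs (the rDNA itself) would inflate a mean and make a
#' "k-fold above average" rule self-defeating on small assemblies. Mean modes
#' are selectable.
#'
#' @param cov coverage data.frame (contig, length, depth).
#' @param method `"weighted_median"` (default), `"weighted_mean"`, `"mean"`.
#' @return scalar depth.
#' @export
genome_average_depth <- function(cov, method = c("weighted_median",
                                                 "weighted_mean", "mean")) {
  method <- match.arg(method)
  if (nrow(cov) == 0) stop("empty coverage table")
  w <- cov$length
  if (method == "mean" || any(is.na(w))) {
    if (method != "mean" && any(is.na(w)))
      stop("contig lengths required for length-weighted statistics")
  }
  switch(method,
    mean = mean(cov$depth),
    weighted_mean = sum(cov$depth * w) / sum(w),
    weighted_median = {
      o <- order(cov$depth)
      d <- cov$depth[o]; ww <- w[o]
      cum <- cumsum(ww) / sum(ww)
      # lower weighted median: smallest depth with cumulative weight >= 1/2
      i <- which(cum >= 0.5)[1]
      if (!is.na(i) && abs(cum[i] - 0.5) < 1e-12 && i < length(d))
        (d[i] + d[i + 1]) / 2
      else d[i]
    })
}

#' Filter candidate rDNA contigs by homology and coverage
#'
#' A contig is retained iff it carries at least one hit with
#' `evalue < e_max` and its depth exceeds `factor` times the genome-average
#' depth (multi-copy rDNA enrichment; also excludes mitochondrial rRNA and
#' low-coverage misassemblies).
#'
#' @param hits data.frame from [search_homologs()] (subjects are contigs).
#' @param cov coverage data.frame.
#' @param e_max E-value ceiling (default `1e-5`).
#' @param factor coverage enrichment factor (default `5`).
#' @param method average-depth method passed to [genome_average_depth()].
#' @return character vector of retained contig ids, ordered by best evalue
#'   then id.
#' @export
filter_rdna_contigs <- function(hits, cov, e_max = 1e-5, factor = 5,
                                method = "weighted_median") {
  if (nrow(hits) == 0) return(character(0))
  missing <- setdiff(unique(hits$subject), cov$contig)
  if (length(missing))
    stop("hit subject(s) missing from coverage table: ",
         paste(missing, collapse = ", "))
  avg <- genome_average_depth(cov, method)
  good <- hits[hits$evalue < e_max, , drop = FALSE]
  if (nrow(good) == 0) return(character(0))
  best <- tapply(good$evalue, good$subject, min)
  ids <- names(best)
  depth <- cov$depth[match(ids, cov$contig)]
  keep <- depth > factor * avg
  ids <- ids[keep]; best <- best[keep]
  ids[order(best, ids)]
}

#' Annotate rRNA operon segments on a contig
#'
#' Maps each reference rRNA segment (SSU, 5.8S, LSU) to the contig via its
#' best local hit, chooses the strand by majority score, normalizes all
#' coordinates to the contig forward strand, and infers ITS1/ITS2 as the
#' gaps between flanking rRNA segments. Segment layouts inconsistent with a
#' single strand raise a structured "inconsistent layout" error (the
#' automated counterpart of manual misassembly screening).
#'
#' @param contig single named normalized sequence (character of length 1,
#'   name = contig id) or a named vector of length 1.
#' @param reference named reference operon sequence (length-1 named vector).
#' @param ref_segments data.frame segment/start/end (1-based inclusive) with
#'   rows for SSU, 5.8S, LSU on the reference.
#' @param params `scoring_params`.
#' @param e_max E-value ceiling for accepting a segment mapping.
#' @param depth optional contig coverage to record.
#' @param hits optional precomputed hit table for this contig (queries named
#'   SSU/5.8S/LSU); searched here when omitted.
#' @return an `operon_annotation`: list(contig, strand, complete, depth,
#'   segments = data.frame(segment, start, end)).
#' @export
annotate_operon <- function(contig, reference, ref_segments,
                            params = scoring_params(), e_max = 1e-5,
                            depth = NA_real_, hits = NULL) {
  stopifnot(length(contig) == 1, length(reference) == 1)
  contig_id <- names(contig)
  if (is.null(contig_id)) stop("contig must be named")
  rseg <- ref_segments[ref_segments$segment %in% c("SSU", "5.8S", "LSU"), ,
                       drop = FALSE]
  if (nrow(rseg) == 0) stop("reference segments must include SSU, 5.8S, LSU")
  queries <- setNames(substring(reference[[1]], rseg$start, rseg$end),
                      rseg$segment)
  if (is.null(hits)) hits <- search_homologs(queries, contig, params)
  else hits <- hits[hits$subject == contig_id, , drop = FALSE]
  hits <- hits[hits$evalue < e_max, , drop = FALSE]
  best <- do.call(rbind, lapply(split(hits, hits$query), function(h)
    h[order(h$evalue, -h$score)[1], , drop = FALSE]))
  found <- if (is.null(best)) character(0) else best$query
  absent <- setdiff(rseg$segment, found)
  if (length(found) == 0) {
    return(structure(list(contig = contig_id, strand = "+", complete = FALSE,
                          depth = depth, absent = absent,
                          segments = data.frame(segment = character(0),
                                                start = integer(0),
                                                end = integer(0))),
                     class = "operon_annotation"))
  }
  strand_score <- tapply(best$score, best$strand, sum)
  strand <- names(strand_score)[which.max(strand_score)]
  len <- nchar(contig[[1]])
  seg <- data.frame(segment = best$query, start = best$sstart, end = best$send,
                    strand = best$strand, stringsAsFactors = FALSE)
  if (any(seg$strand != strand))
    stop("inconsistent layout: segments map to both strands of ", contig_id,
         " (possible misassembly)")
  # order along the operon (5'->3' of the transcript)
  op_order <- c("SSU", "5.8S", "LSU")
  seg <- seg[match(op_order[op_order %in% seg$segment], seg$segment), ,
             drop = FALSE]
  along <- if (strand == "+") seg$start else -seg$start
  if (is.unsorted(along, strictly = TRUE))
    stop("inconsistent layout: segment order on ", contig_id,
         " incompatible with strand ", strand, " (possible misassembly)")
  # overlap check on forward-strand coordinates
  fw <- seg[order(seg$start), , drop = FALSE]
  if (nrow(fw) > 1 && any(fw$start[-1] <= fw$end[-nrow(fw)]))
    stop("inconsistent layout: overlapping segments on ", contig_id)
  # infer spacers between consecutive present rRNA segments
  spacer_name <- function(a, b) {
    if (a == "SSU" && b == "5.8S") "ITS1"
    else if (a == "5.8S" && b == "LSU") "ITS2"
    else NA_character_
  }
  segs <- data.frame(segment = seg$segment, start = seg$start, end = seg$end,
                     stringsAsFactors = FALSE)
  if (nrow(seg) > 1) {
    for (i in seq_len(nrow(seg) - 1)) {
      nm <- spacer_name(seg$segment[i], seg$segment[i + 1])
      if (is.na(nm)) next
      if (strand == "+") {
        s0 <- seg$end[i] + 1L; e0 <- seg$start[i + 1] - 1L
      } else {
        s0 <- seg$end[i + 1] + 1L; e0 <- seg$start[i] - 1L
      }
      if (e0 >= s0)
        segs <- rbind(segs, data.frame(segment = nm, start = s0, end = e0))
    }
  }
  segs <- segs[order(segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  structure(list(contig = contig_id, strand = strand,
                 complete = all(c("SSU", "ITS1", "5.8S", "ITS2", "LSU") %in%
                                  segs$segment),
                 depth = depth, absent = absent, segments = segs),
            class = "operon_annotation")
}

#' Read externally produced tabular hits (outfmt-6-style)
#'
#' Adapter for parity runs with an external search tool: a 12-column TSV
#' (query, subject, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore) is converted to the internal hit table. Subject
#' coordinates with sstart > send are normalized to the forward strand with
#' `strand == "-"`.
#'
#' @param path TSV file.
#' @return hits data.frame compatible with [filter_rdna_contigs()].
#' @export
read_external_hits <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) < 12) stop("expected 12-column tabular hits")
  names(tab)[1:12] <- c("query", "subject", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore")
  minus <- tab$sstart > tab$send
  s1 <- pmin(tab$sstart, tab$send); s2 <- pmax(tab$sstart, tab$send)
  data.frame(query = tab$query, subject = tab$subject,
             qstart = tab$qstart, qend = tab$qend, sstart = s1, send = s2,
             strand = ifelse(minus, "-", "+"), score = tab$bitscore,
             evalue = tab$evalue, identity = tab$pident / 100,
             stringsAsFactors = FALSE)
}
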