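# Independent oracles used to verify the package's own implementations.
# These deliberately take different routes (brute force, enumeration,
# external library) from the code under test.

# weighted median by explicit expansion: each contig repeated `length` times
oracle_weighted_median <- function(depth, len) {
  stats::median(rep(depth, times = len))
}

# six-frame ORF scan via Biostrings translation + stop-split bookkeeping
oracle_orf_scan <- function(seq, min_aa = 20L) {
  n <- nchar(seq)
  out <- list()
  # translate all six frames in one batch call
  fwd <- seq
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  frames <- list()
  for (strand in c("+", "-")) for (off in 0:2) {
    s <- if (strand == "+") fwd else rev
    ncod <- (n - off) %/% 3
    frames[[paste0(strand, off)]] <-
      if (ncod < 1) "" else substr(s, off + 1, off + 3 * ncod)
  }
  keep <- nzchar(unlist(frames))
  prots <- rep("", length(frames))
  names(prots) <- names(frames)
  if (any(keep))
    prots[keep] <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAStringSet(unlist(frames)[keep]),
      if.fuzzy.codon = "X", no.init.codon = TRUE)))
  for (strand in c("+", "-")) {
    for (off in 0:2) {
      aa <- prots[[paste0(strand, off)]]
      if (!nzchar(aa)) next
      chunks <- strsplit(aa, "*", fixed = TRUE)[[1]]
      # trailing stop yields no empty last chunk from strsplit; detect it
      ends_with_stop <- substring(aa, nchar(aa)) == "*"
      cum <- 0L
      for (ci in seq_along(chunks)) {
        chunk <- chunks[ci]
        m <- regexpr("M", chunk, fixed = TRUE)
        partial <- (ci == length(chunks)) && !ends_with_stop
        if (m > 0) {
          aa_len <- nchar(chunk) - m + 1L
          if (aa_len > min_aa) {
            cod_from <- cum + m
            cod_to <- cum + nchar(chunk) + (if (partial) 0L else 1L)
            nt_from <- off + 1L + 3L * (cod_from - 1L)
            nt_to <- off + 3L * cod_to
            if (strand == "-") {
              tmp <- nt_from
              nt_from <- n - nt_to + 1L
              nt_to <- n - tmp + 1L
            }
            out[[length(out) + 1]] <- data.frame(
              frame = paste0(strand, off + 1L), start = nt_from, end = nt_to,
              aa = aa_len, partial = partial, stringsAsFactors = FALSE)
          }
        }
        cum <- cum + nchar(chunk) + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = character(0), start = integer(0),
                      end = integer(0), aa = integer(0),
                      partial = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# minimum binary changes by exhaustive enumeration of internal labelings
oracle_fitch <- function(tree, presence) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  states <- integer(ntip + nint)
  states[seq_len(ntip)] <-
    as.integer(vapply(tree$tip.label, function(l) isTRUE(presence[[l]]), TRUE))
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    states[ntip + seq_len(nint)] <- bitwAnd(mask %/% 2^(seq_len(nint) - 1), 1)
    changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# exhaustive enumeration of all nested structures (max pair count)
oracle_max_pairs <- function(seq, min_loop = 3L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  pairable <- function(a, b)
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j) # i unpaired: enumerate the rest
    for (k in (i + min_loop + 1L):j) {
      if (!pairable(chars[i], chars[k])) next
      best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  if (length(chars) < 2) return(0L)
  rec(1L, length(chars))
}

# full local DP via Biostrings; gap cost mapping: our gap_open (-5) is the
# cost of a 1-nt gap, so Biostrings gapOpening = 3, gapExtension = 2
oracle_local_alignment <- function(a, b, match = 1, mismatch = -2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 3, gapExtension = 2,
    scoreOnly = FALSE)
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  list(score = pa@score,
       identity = if (nm + nmm > 0) nm / (nm + nmm) else 0)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
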