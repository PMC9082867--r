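test_that("projection: identity on gapless MSA, ABSENT on gapped anchors", {
  hm <- hand_helix_map()
  gapless <- as_msa(c(Reference = "AACCGGTTAAACGTACGT",
                      rowB = "AACCGGTTAAACGTACGT"))
  proj <- project_anchors(gapless, hm)
  for (id in names(gapless)) for (i in seq_len(nrow(hm))) {
    r <- proj[proj$seq_id == id & proj$anchor == hm$helix[i], ]
    expect_equal(c(r$start, r$end), c(hm$span_start[i], hm$span_end[i]))
  }

  gapped <- as_msa(c(Reference = "AACCGGTTAAACGTACGT",
                     rowB = "AA----TTAAACGTACGT"))
  proj2 <- project_anchors(gapped, hm)
  r <- proj2[proj2$seq_id == "rowB" & proj2$anchor == "H1", ]
  expect_false(r$present)
  expect_error(project_anchors(as_msa(c(other = "ACGT")), hm), "template")
})

test_that("projection of a staggered-gap MSA matches a column-walk oracle", {
  msa <- hand_msa()
  hm <- hand_helix_map()
  proj <- project_anchors(msa, hm)
  # oracle: walk alignment columns, mapping template positions to columns
  # and per-row unaligned indices one character at a time
  tmpl <- strsplit(msa[["Reference"]], "")[[1]]
  for (id in names(msa)) {
    row <- strsplit(msa[[id]], "")[[1]]
    for (i in seq_len(nrow(hm))) {
      tpos <- 0; upos <- 0; hits <- integer(0)
      for (col in seq_along(tmpl)) {
        if (tmpl[col] != "-") tpos <- tpos + 1
        if (row[col] != "-") upos <- upos + 1
        if (tmpl[col] != "-" && tpos >= hm$span_start[i] &&
              tpos <= hm$span_end[i] && row[col] != "-")
          hits <- c(hits, upos)
        if (row[col] != "-" && tmpl[col] == "-" &&
              tpos >= hm$span_start[i] && tpos < hm$span_end[i])
          hits <- c(hits, upos) # insertions inside the anchor columns
      }
      r <- proj[proj$seq_id == id & proj$anchor == hm$helix[i], ]
      if (length(hits)) {
        expect_true(r$present)
        expect_equal(c(r$start, r$end), range(hits))
      } else {
        expect_false(r$present)
      }
    }
  }
})

test_that("inter-anchor arithmetic: abutting and separated anchors", {
  # anchors [11,20] and [51,60] on a 100 nt gapless row -> region length 30
  hm <- as_helix_map(data.frame(
    helix = c("A1", "A2"), class = "core",
    fp_start = c(11L, 51L), fp_end = c(20L, 60L),
    tp_start = NA_integer_, tp_end = NA_integer_), template_id = "Reference")
  s <- strrep("A", 100)
  msa <- as_msa(c(Reference = s))
  reg <- interanchor_lengths(project_anchors(msa, hm), msa)
  expect_equal(reg$length[reg$region_id == "A1-A2"], 30)
  expect_equal(reg$length[reg$region_id == "TER5-A1"], 10)
  expect_equal(reg$length[reg$region_id == "A2-TER3"], 40)

  hm2 <- as_helix_map(data.frame(
    helix = c("A1", "A2"), class = "core",
    fp_start = c(11L, 21L), fp_end = c(20L, 30L),
    tp_start = NA_integer_, tp_end = NA_integer_), template_id = "Reference")
  reg2 <- interanchor_lengths(project_anchors(msa, hm2), msa)
  expect_equal(reg2$length[reg2$region_id == "A1-A2"], 0)
})

test_that("per-row length conservation holds on simulated alignments", {
  b <- simulate_bundle(small_config(seed = 4))
  proj <- project_anchors(b$msa, b$helix_map)
  reg <- interanchor_lengths(proj, b$msa)
  seqs <- degap(b$msa)
  for (id in names(b$msa)) {
    p <- proj[proj$seq_id == id & proj$present, ]
    anchor_total <- sum(p$end - p$start + 1)
    region_total <- sum(reg$length[reg$seq_id == id])
    expect_equal(anchor_total + region_total, nchar(seqs[[id]]))
  }
})

test_that("expansion rule: fold threshold, absolute guard, degenerate background", {
  mk <- function(lens) {
    sp <- c("focal", paste0("bg", seq_along(lens) - 1))[seq_along(lens)]
    data.frame(seq_id = c("focal", paste0("bg", seq_len(length(lens) - 1))),
               region_id = "A-B", left_anchor = "A", right_anchor = "B",
               start = 1, end = lens, length = lens,
               skipped = "", domain = "LSU", stringsAsFactors = FALSE)
  }
  bg <- paste0("bg", 1:3)
  r <- mk(c(250, 50, 55, 60))
  out <- detect_expansions(r, "focal", bg)
  expect_equal(nrow(out), 1)          # 250 > 4*55 and 250-55 >= 30
  expect_equal(out$background_stat, 55)
  expect_equal(out$factor, 250 / 55)

  expect_equal(nrow(detect_expansions(mk(c(200, 50, 55, 60)), "focal", bg)),
               0)                     # 200 < 4*55 = 220

  expect_equal(nrow(detect_expansions(mk(c(40, 0, 0, 0)), "focal", bg)), 1)
  expect_equal(nrow(detect_expansions(mk(c(20, 0, 0, 0)), "focal", bg)), 0)

  # background smaller than 2 -> warning, region skipped
  r2 <- mk(c(250, 50))
  expect_warning(out2 <- detect_expansions(r2, "focal", "bg1"),
                 "fewer than 2")
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "skipped_regions"), "A-B")
  expect_error(detect_expansions(r, "focal", c("focal", bg)), "disjoint")
})

test_that("expansion rule is order-invariant and scale-free above the guard", {
  set.seed(31)
  for (i in 1:10) {
    lens <- sample(30:80, 5)
    foc_len <- sample(400:900, 1)
    r <- data.frame(seq_id = c("f", paste0("b", 1:5)),
                    region_id = "A-B", left_anchor = "A", right_anchor = "B",
                    start = 1, end = 1, length = c(foc_len, lens),
                    skipped = "", stringsAsFactors = FALSE)
    out1 <- detect_expansions(r, "f", paste0("b", 1:5))
    r_shuf <- r[sample(nrow(r)), ]
    out2 <- detect_expansions(r_shuf, "f", sample(paste0("b", 1:5)))
    expect_equal(nrow(out1), nrow(out2))
    r_scaled <- r; r_scaled$length <- r$length * 3L
    out3 <- detect_expansions(r_scaled, "f", paste0("b", 1:5))
    expect_equal(nrow(out3), nrow(out1))
  }
})

test_that("folding: loop constraint, known optimum, and contract properties", {
  expect_equal(fold_region("AAAA")$structure, "....")
  f <- fold_region("GGGAAAACCC")
  expect_equal(f$pairs, 3)
  expect_equal(f$structure, "(((....)))")
  expect_error(fold_region("ACGT-ACGT"), "residues")
})

test_that("folding pair count equals exhaustive enumeration for short sequences", {
  set.seed(13)
  for (i in 1:40) {
    s <- random_dna(sample(5:16, 1))
    f <- fold_region(s)
    expect_equal(f$pairs, oracle_max_pairs(s), info = s)
    # structural validity: balanced, nested, pairable, loop >= 3
    db <- strsplit(f$structure, "")[[1]]
    stack <- integer(0); pairs <- list()
    for (pos in seq_along(db)) {
      if (db[pos] == "(") stack <- c(stack, pos)
      else if (db[pos] == ")") {
        expect_gt(length(stack), 0)
        pairs[[length(pairs) + 1]] <- c(stack[length(stack)], pos)
        stack <- stack[-length(stack)]
      }
    }
    expect_length(stack, 0)
    ch <- strsplit(s, "")[[1]]
    for (p in pairs) {
      expect_gte(p[2] - p[1] - 1, 3)
      expect_true(paste0(ch[p[1]], ch[p[2]]) %in%
                    c("AT", "TA", "GC", "CG", "GT", "TG"))
    }
  }
})
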