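test_that("Karlin-Altschul lambda satisfies its defining equation", {
  for (sc in list(c(1, -2), c(1, -3), c(2, -3))) {
    ka <- karlin_altschul(sc[1], sc[2])
    # lambda solves sum p_i p_j exp(lambda s_ij) = 1, uniform composition
    lhs <- 0.25 * exp(ka$lambda * sc[1]) + 0.75 * exp(ka$lambda * sc[2])
    expect_equal(lhs, 1, tolerance = 1e-9)
    expect_gt(ka$K, 0)
    expect_lt(ka$K, 1)
  }
  # published ungapped BLASTN constants for the default +1/-2 scores
  ka <- karlin_altschul(1, -2)
  expect_equal(ka$lambda, 1.33271, tolerance = 1e-4)
  expect_equal(ka$K, 0.620991, tolerance = 1e-4)
})

test_that("E-value formula matches K*m*n*exp(-lambda*S) and is monotone", {
  p <- scoring_params()
  e <- evalue(50, 1000, 1000, p)
  expect_equal(e, p$K * 1e6 * exp(-50 * p$lambda))
  scores <- seq(20, 200, by = 10)
  es <- evalue(scores, 1000, 1000, p)
  expect_true(all(diff(es) < 0))
})

test_that("self-alignment and strand symmetry behave as local search contracts", {
  set.seed(3)
  s <- setNames(random_dna(100), "q")
  p <- scoring_params()
  hits <- search_homologs(s, s, p)
  top <- hits[1, ]
  expect_equal(top$score, 100)
  expect_equal(c(top$qstart, top$qend, top$sstart, top$send),
               c(1, 100, 1, 100))
  expect_equal(top$strand, "+")
  expect_equal(top$identity, 1.0)

  rc <- setNames(revcomp(s), "rc")
  hits2 <- search_homologs(s, rc, p)
  expect_equal(hits2$score[1], 100)
  expect_equal(hits2$strand[1], "-")
  expect_equal(c(hits2$sstart[1], hits2$send[1]), c(1, 100))

  expect_equal(nrow(search_homologs(character(0), s, p)), 0)
  expect_error(search_homologs(setNames("ACRT", "b"), s, p), "normalized")
})

test_that("every planted exact repeat of seed length or more is found", {
  set.seed(7)
  p <- scoring_params()
  for (trial in 1:10) {
    motif <- random_dna(sample(p$seed_k:40, 1))
    backbone <- random_dna(3000)
    at <- sort(sample(seq(1, 2500, by = 600), 3))
    subj <- backbone
    for (a in at) subj <- paste0(substr(subj, 1, a - 1), motif,
                                 substr(subj, a + nchar(motif), nchar(subj)))
    hits <- search_homologs(setNames(motif, "m"), setNames(subj, "s"), p)
    covered <- vapply(at, function(a) {
      any(hits$sstart <= a & hits$send >= a + nchar(motif) - 1)
    }, TRUE)
    expect_true(all(covered))
  }
})

test_that("local alignment agrees with an independent full-DP oracle", {
  set.seed(5)
  p <- scoring_params()
  for (i in 1:20) {
    a <- random_dna(sample(50:250, 1))
    b <- random_dna(sample(50:250, 1))
    mine <- align_local(a, b, p)
    orc <- oracle_local_alignment(a, b)
    expect_equal(mine$score, orc$score)
  }
  # related pair: oracle must agree on score for homologs too
  a <- random_dna(300)
  b <- paste0(substr(a, 1, 120), random_dna(40), substr(a, 160, 300))
  mine <- align_local(a, b, p)
  orc <- oracle_local_alignment(a, b)
  expect_equal(mine$score, orc$score)
})

test_that("genome average depth: median semantics and expansion oracle", {
  cov <- data.frame(contig = c("a", "b", "c"), length = c(100, 100, 100),
                    depth = c(10, 12, 300))
  expect_equal(genome_average_depth(cov), 12)
  expect_equal(genome_average_depth(data.frame(contig = "a", length = 5,
                                               depth = 7)), 7)
  expect_error(genome_average_depth(cov[0, ]), "empty")

  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    cov <- data.frame(contig = paste0("c", 1:n),
                      length = sample(1:50, n, replace = TRUE),
                      depth = sample(1:500, n, replace = TRUE))
    expect_equal(genome_average_depth(cov),
                 oracle_weighted_median(cov$depth, cov$length))
  }
})

test_that("rDNA contig filter applies both the E-value and coverage gates", {
  # genome average (weighted median) is 10 here
  cov <- data.frame(contig = c("big", paste0("bg", 1:5)),
                    length = rep(5000, 6), depth = c(80, rep(10, 5)))
  hit <- function(e, subj = "big")
    data.frame(query = "SSU", subject = subj, qstart = 1, qend = 50,
               sstart = 1, send = 50, strand = "+", score = 50,
               evalue = e, identity = 1)
  expect_equal(genome_average_depth(cov), 10)
  expect_equal(filter_rdna_contigs(hit(1e-6), cov), "big")    # 80 > 5*10
  expect_equal(filter_rdna_contigs(hit(1e-3), cov), character(0))
  cov2 <- cov; cov2$depth[1] <- 40
  expect_equal(filter_rdna_contigs(hit(1e-6), cov2), character(0)) # 40 < 50
  expect_error(filter_rdna_contigs(hit(1e-6, "missing"), cov), "missing")
})

test_that("operon annotation: identity, strand involution, and insertions", {
  cfg <- small_config(seed = 9, planted = FALSE)
  tpl <- build_template(cfg)
  ref <- tpl$template
  p <- scoring_params()

  contig <- setNames(ref, "contig1")
  ann <- annotate_operon(contig, ref, tpl$segments, p)
  expect_true(ann$complete)
  expect_equal(ann$strand, "+")
  for (seg in c("SSU", "5.8S", "LSU")) {
    got <- ann$segments[ann$segments$segment == seg, ]
    want <- tpl$segments[tpl$segments$segment == seg, ]
    expect_equal(c(got$start, got$end), c(want$start, want$end))
  }

  rc <- setNames(revcomp(ref), "contig1rc")
  ann_rc <- annotate_operon(rc, ref, tpl$segments, p)
  expect_equal(ann_rc$strand, "-")
  L <- nchar(ref[[1]])
  # involution: intervals map to the same positions after flipping
  for (seg in c("SSU", "ITS1", "5.8S", "ITS2", "LSU")) {
    a <- ann$segments[ann$segments$segment == seg, ]
    b <- ann_rc$segments[ann_rc$segments$segment == seg, ]
    expect_equal(c(b$start, b$end), c(L - a$end + 1, L - a$start + 1))
  }

  # 100 nt inserted mid-LSU lengthens LSU by exactly 100, others unchanged
  lsu <- tpl$segments[tpl$segments$segment == "LSU", ]
  mid <- (lsu$start + lsu$end) %/% 2
  set.seed(1)
  ins <- paste0(substr(ref, 1, mid), random_dna(100),
                substr(ref, mid + 1, nchar(ref)))
  ann_ins <- annotate_operon(setNames(ins, "c2"), ref, tpl$segments, p)
  g <- function(a, seg) {
    r <- a$segments[a$segments$segment == seg, ]
    r$end - r$start + 1
  }
  expect_equal(g(ann_ins, "LSU"), g(ann, "LSU") + 100)
  for (seg in c("SSU", "ITS1", "5.8S", "ITS2"))
    expect_equal(g(ann_ins, seg), g(ann, seg))
})

test_that("external tabular hits adapter normalizes minus-strand intervals", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SSU\tc1\t98.5\t100\t1\t0\t1\t100\t500\t401\t1e-30\t180"), f)
  h <- read_external_hits(f)
  expect_equal(h$strand, "-")
  expect_equal(c(h$sstart, h$send), c(401, 500))
  expect_equal(h$identity, 0.985)
})
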