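test_that("template building is deterministic and respects the anchor plan", {
  cfg <- small_config(seed = 1)
  a <- build_template(cfg)
  b <- build_template(cfg)
  expect_identical(a, b)
  expect_equal(nchar(a$template[[1]]), sum(cfg$layout))
  expect_equal(a$segments$segment, c("SSU", "ITS1", "5.8S", "ITS2", "LSU"))

  # zero ES anchors -> only core-class anchors in the map
  cfg2 <- sim_config(seed = 2, anchor_plan = list(
    SSU = c(core = 6L, ES = 0L), `5.8S` = c(core = 2L, ES = 0L),
    LSU = c(core = 16L, ES = 0L)), planted_its = NULL)
  tpl2 <- build_template(cfg2)
  expect_true(all(tpl2$helix_map$class == "core"))

  # anchors that cannot fit raise a config error
  cfg3 <- small_config(seed = 1)
  cfg3$layout["LSU"] <- 300L
  expect_error(build_template(cfg3), "exceed")
})

test_that("core helix anchors fold back on themselves", {
  tpl <- build_template(small_config(seed = 5))
  hm <- tpl$helix_map
  core <- hm[hm$class == "core", ][1:5, ]
  for (i in seq_len(nrow(core))) {
    sub <- substring(tpl$template[[1]], core$span_start[i], core$span_end[i])
    f <- fold_region(sub)
    expect_gte(f$pairs, core$fp_end[i] - core$fp_start[i] + 1)
  }
})

test_that("evolution: zero branch lengths reproduce the template exactly", {
  cfg <- small_config(seed = 3, planted = FALSE)
  tr <- cfg$tree
  tr$edge.length[] <- 0
  tpl <- build_template(cfg)
  sim <- evolve_on_tree(tpl, tr, seed = 3)
  ms <- sim_msa(sim)
  expect_true(all(ms$sequences == tpl$template[[1]]))
  expect_false(any(grepl("-", unclass(ms$msa), fixed = TRUE)))
})

test_that("observed core substitutions match the process expectation", {
  # one branch of length 0.1; core rate multiplier 0.1 -> d = 0.01
  cfg <- sim_config(seed = 8,
                    tree = "(A:0.1,B:0.0);",
                    layout = c(SSU = 6000L, ITS1 = 100L, `5.8S` = 160L,
                               ITS2 = 100L, LSU = 4000L),
                    anchor_plan = list(SSU = c(core = 10L, ES = 0L),
                                       `5.8S` = c(core = 1L, ES = 0L),
                                       LSU = c(core = 10L, ES = 0L)),
                    planted_its = NULL, indel_rate = 0)
  tpl <- build_template(cfg)
  sim <- evolve_on_tree(tpl, cfg$tree, rates = cfg$rates, indel_rate = 0,
                        seed = 8)
  tchars <- strsplit(tpl$template[[1]], "")[[1]]
  achars <- strsplit(paste(sim$leaves[["A"]]$base, collapse = ""), "")[[1]]
  core_sites <- which(tpl$classes == "core")
  n <- length(core_sites)
  observed <- sum(tchars[core_sites] != achars[core_sites])
  p <- 0.75 * (1 - exp(-4 / 3 * 0.1 * 0.1))
  expect_lt(abs(observed - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  # ES sites evolve faster than core under the multipliers
  es_sites <- which(tpl$classes == "ES")
  obs_es <- mean(tchars[es_sites] != achars[es_sites])
  expect_gt(obs_es, observed / n)
})

test_that("doubling ES rates increases ES divergence, core unchanged", {
  cfg <- small_config(seed = 12, planted = FALSE)
  tpl <- build_template(cfg)
  div <- function(rates) {
    sim <- evolve_on_tree(tpl, cfg$tree, rates = rates,
                          indel_rate = 0, seed = 99)
    tchars <- strsplit(tpl$template[[1]], "")[[1]]
    vapply(c(core = "core", ES = "ES"), function(cl) {
      idx <- which(tpl$classes == cl)
      mean(vapply(sim$leaves, function(st)
        mean(st$base[idx] != tchars[idx]), 0))
    }, 0)
  }
  d1 <- div(c(core = 0.1, ES = 1.0, spacer = 3.0))
  d2 <- div(c(core = 0.1, ES = 2.0, spacer = 3.0))
  expect_gt(d2[["ES"]], d1[["ES"]])
  # core divergence is statistically unchanged (same rate, same tree)
  expect_lt(abs(d2[["core"]] - d1[["core"]]), 0.01)
})

test_that("planted ITS bookkeeping: lengths, untouched rows, empty spec", {
  cfg <- small_config(seed = 6, planted = FALSE)
  tpl <- build_template(cfg)
  sim <- evolve_on_tree(tpl, cfg$tree, cfg$rates, cfg$indel_rate,
                        cfg$indel_mean, seed = 6)
  before <- sim_msa(sim)$sequences

  spec <- data.frame(site_id = "X1", lineage = "euglenid",
                     region_id = "L4-L5", taxa = "EuglenidA",
                     len_min = 500L, len_max = 500L, stringsAsFactors = FALSE)
  sim2 <- plant_its(sim, spec, seed = 6)
  after <- sim_msa(sim2)$sequences
  expect_equal(nchar(after[["EuglenidA"]]),
               nchar(before[["EuglenidA"]]) + 500)
  for (sp in setdiff(names(before), "EuglenidA"))
    expect_identical(after[[sp]], before[[sp]])
  expect_equal(sim2$truth$length, 500)

  sim0 <- plant_its(sim, NULL, seed = 6)
  expect_identical(sim_msa(sim0)$sequences, before)
  expect_equal(nrow(sim0$truth), 0)

  bad <- spec; bad$region_id <- "L98-L99"
  expect_error(plant_its(sim, bad, seed = 1), "not in helix map")
})

test_that("de-gapping the true MSA reproduces the unaligned sequences", {
  b <- simulate_bundle(small_config(seed = 14))
  un <- degap(b$msa)
  for (sp in names(b$sequences))
    expect_identical(un[[sp]], b$sequences[[sp]])
  expect_identical(un[["Reference"]], b$template[[1]])
})

test_that("assembly model: depths, headers, decoys, strand alternation", {
  seqs <- setNames(c(strrep("ACGT", 500), strrep("GATC", 500)), c("A", "B"))
  model <- list(baseline_depth = 10, rdna_multiplier = 20, n_decoys = 3L,
                decoy_len = c(500L, 800L), fragment_len = Inf,
                revcomp_alternate = TRUE)
  asm <- make_assembly(seqs, model, seed = 2)
  expect_equal(nrow(asm$coverage), 5)
  rdna_cov <- asm$coverage$depth[match(asm$rdna_contigs$contig,
                                       asm$coverage$contig)]
  expect_true(all(rdna_cov == 200))
  decoy <- setdiff(asm$coverage$contig, asm$rdna_contigs$contig)
  expect_true(all(asm$coverage$depth[match(decoy, asm$coverage$contig)] == 10))
  expect_true(all(grepl("^NODE_\\d+_length_\\d+_cov_", asm$coverage$contig)))
  expect_equal(asm$rdna_contigs$strand, c("+", "-"))
  # single contig per operon when fragment length exceeds operon length
  expect_equal(nrow(asm$rdna_contigs), 2)
})

test_that("bundles are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_bundle(small_config(seed = 20), d1)
  generate_bundle(small_config(seed = 20), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 9)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  d3 <- withr::local_tempdir()
  generate_bundle(small_config(seed = 21), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "operons.fasta"))),
                         unname(tools::md5sum(file.path(d3, "operons.fasta")))))
})

test_that("coverage filter recovers exactly the planted rDNA contigs", {
  for (seed in c(2, 3)) {
    b <- simulate_bundle(small_config(seed = seed))
    rseg <- b$segments[b$segments$segment %in% c("SSU", "5.8S", "LSU"), ]
    queries <- setNames(substring(b$template[[1]], rseg$start, rseg$end),
                        rseg$segment)
    hits <- search_homologs(queries, b$assembly$contigs)
    kept <- filter_rdna_contigs(hits, b$assembly$coverage)
    expect_setequal(kept, b$assembly$rdna_contigs$contig)
  }
})
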