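test_that("shared sites: vacuous, constructed, and curated-registry cases", {
  reg0 <- data.frame(site_id = c("eITS1", "kITS1"),
                     lineage = c("euglenid", "kinetoplastid"),
                     left_anchor = c("A", "C"), right_anchor = c("B", "D"),
                     stringsAsFactors = FALSE)
  reg0$region_id <- paste0(reg0$left_anchor, "-", reg0$right_anchor)
  expect_equal(nrow(shared_sites(reg0)), 0)

  reg1 <- reg0
  reg1$left_anchor <- "H54"; reg1$right_anchor <- "H58"
  reg1$region_id <- "H54-H58"
  ss <- shared_sites(reg1)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$site_a, "eITS1")
  expect_equal(ss$site_b, "kITS1")

  # same-lineage sites at one region never pair
  reg2 <- reg1; reg2$lineage <- "euglenid"
  expect_equal(nrow(shared_sites(reg2)), 0)

  # the curated euglenozoan registry yields exactly the three published pairs
  reg <- read_its_registry(registry_fixture_path())
  ss <- shared_sites(reg)
  expect_equal(nrow(ss), 3)
  got <- sort(paste(ss$site_a, ss$site_b, sep = "/"))
  expect_equal(got, sort(c("eITS10/kITS5", "eITS11/kITS6", "eITS13/kITS7")))
})

test_that("parsimony: constant and single-autapomorphy characters", {
  tr <- read_newick("((A,B),(C,D));")
  expect_equal(min_state_changes(tr, c(A = TRUE, B = TRUE, C = TRUE,
                                       D = TRUE)), 0)
  expect_equal(min_state_changes(tr, c(A = TRUE, B = FALSE, C = FALSE,
                                       D = FALSE)), 1)
  expect_error(min_state_changes(tr, c(A = TRUE, B = TRUE, C = TRUE)),
               "leaf without state")
})

test_that("parsimony equals exhaustive enumeration on random trees", {
  set.seed(17)
  for (trial in 1:40) {
    ntip <- sample(4:9, 1)
    tr <- random_topology(ntip)
    pres <- setNames(sample(c(TRUE, FALSE), ntip, replace = TRUE),
                     tr$tip.label)
    expect_equal(min_state_changes(tr, pres), oracle_fitch(tr, pres),
                 info = paste("trial", trial))
  }
  # including polytomies
  for (trial in 1:10) {
    tr <- ape::di2multi(ape::rtree(7), tol = 0.5)
    tr$edge.length <- NULL
    pres <- setNames(sample(c(TRUE, FALSE), 7, replace = TRUE), tr$tip.label)
    expect_equal(min_state_changes(tr, pres), oracle_fitch(tr, pres))
  }
})

test_that("parsimony count is invariant under re-rooting", {
  set.seed(23)
  for (trial in 1:15) {
    tr <- random_topology(7)
    pres <- setNames(sample(c(TRUE, FALSE), 7, replace = TRUE), tr$tip.label)
    base <- min_state_changes(tr, pres)
    for (og in sample(tr$tip.label, 3))
      expect_equal(min_state_changes(ape::root(tr, og), pres), base)
  }
})

test_that("parsimony agrees with phangorn on random binary characters", {
  skip_if_not_installed("phangorn")
  set.seed(29)
  for (trial in 1:20) {
    ntip <- sample(5:12, 1)
    tr <- random_topology(ntip)
    pres <- setNames(sample(c(TRUE, FALSE), ntip, replace = TRUE),
                     tr$tip.label)
    dat <- phangorn::phyDat(matrix(as.character(as.integer(pres)),
                                   ncol = 1,
                                   dimnames = list(names(pres), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(min_state_changes(tr, pres),
                 as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("gain scenarios: nested, disjoint, and constant characters", {
  tr <- read_newick("((A,B),((C,D),(E,F)));")
  # presence in one clade only
  s <- gain_scenarios(tr, c(A = TRUE, B = TRUE, C = FALSE, D = FALSE,
                            E = FALSE, F = FALSE))
  expect_equal(s$gains_no_loss, 1)
  expect_equal(s$dollo_losses_single_gain, 0)
  # two non-sister clades separated by an absent clade
  s2 <- gain_scenarios(tr, c(A = TRUE, B = TRUE, C = FALSE, D = FALSE,
                             E = TRUE, F = TRUE))
  expect_equal(s2$gains_no_loss, 2)
  expect_equal(s2$fitch_changes, 1) # a single loss on the (C,D) clade
  expect_equal(s2$dollo_losses_single_gain, 1)
  # presence everywhere
  s3 <- gain_scenarios(tr, setNames(rep(TRUE, 6), tr$tip.label))
  expect_equal(s3, list(fitch_changes = 0L, gains_no_loss = 1L,
                        dollo_losses_single_gain = 0L))
  # no presence
  s4 <- gain_scenarios(tr, setNames(rep(FALSE, 6), tr$tip.label))
  expect_equal(s4, list(fitch_changes = 0L, gains_no_loss = 0L,
                        dollo_losses_single_gain = 0L))
})

test_that("gains_no_loss counts maximal all-present subtrees (oracle check)", {
  set.seed(41)
  for (trial in 1:20) {
    ntip <- sample(4:9, 1)
    tr <- random_topology(ntip)
    pres <- setNames(sample(c(TRUE, FALSE), ntip, replace = TRUE),
                     tr$tip.label)
    s <- gain_scenarios(tr, pres)
    # oracle: for each present leaf find its largest all-present clade, then
    # count distinct maximal clades
    clades <- list()
    for (leaf in tr$tip.label[pres[tr$tip.label]]) {
      best <- leaf
      for (node in (ntip + 1):(ntip + tr$Nnode)) {
        tips <- ape::extract.clade(tr, node)$tip.label
        if (leaf %in% tips && all(pres[tips]))
          if (length(tips) > length(best)) best <- tips
      }
      clades[[length(clades) + 1]] <- sort(best)
    }
    expect_equal(s$gains_no_loss, length(unique(clades)))
    # structural inequalities
    expect_lte(s$fitch_changes, s$gains_no_loss)
    expect_lte(s$fitch_changes, 1 + s$dollo_losses_single_gain)
  }
})

test_that("the euglenozoan fragmentation character needs two gains on both topologies", {
  pres <- euglenozoa_presence()
  for (tr in euglenozoa_trees()) {
    s <- gain_scenarios(tr, pres)
    expect_gte(s$gains_no_loss, 2)
    expect_gte(s$fitch_changes, 2)
  }
})
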