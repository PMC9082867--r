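# Small in-code fixtures shared across test files.

# a compact config for fast end-to-end tests (full defaults are exercised in
# the acceptance tests)
small_config <- function(seed = 1L, planted = TRUE) {
  sim_config(
    seed = seed,
    layout = c(SSU = 600L, ITS1 = 120L, `5.8S` = 160L, ITS2 = 150L,
               LSU = 1400L),
    anchor_plan = list(SSU = c(core = 6L, ES = 1L),
                       `5.8S` = c(core = 2L, ES = 0L),
                       LSU = c(core = 16L, ES = 2L)),
    planted_its = if (planted)
      data.frame(site_id = c("eITS1", "kITS1"),
                 lineage = c("euglenid", "kinetoplastid"),
                 region_id = c("L4-L5", "L4-L5"),
                 taxa = c("EuglenidA,EuglenidB",
                          "MetakinetoplastidA,MetakinetoplastidB"),
                 len_min = 200L, len_max = 300L, stringsAsFactors = FALSE)
      else NULL,
    assembly = list(baseline_depth = 10, rdna_multiplier = 20,
                    n_decoys = 12L, decoy_len = c(1500L, 4000L),
                    fragment_len = Inf, revcomp_alternate = TRUE))
}

# hand-built 3-row MSA with staggered gaps around two anchors
hand_msa <- function() {
  as_msa(c(
    Reference = "AACCGGTT--ACGTACGT",
    rowB      = "AAC-GGTTAAACGT--GT",
    rowC      = "--CCGG--AAACGTACGT"))
}

hand_helix_map <- function() {
  as_helix_map(data.frame(
    helix = c("H1", "H2"), class = c("core", "core"),
    fp_start = c(3L, 11L), fp_end = c(6L, 14L),
    tp_start = NA_integer_, tp_end = NA_integer_,
    stringsAsFactors = FALSE), template_id = "Reference")
}

# the two candidate deep topologies for Euglenozoa (euglenids sister to
# kinetoplastids vs euglenids sister to diplonemids+kinetoplastids), with
# kinetoplastids always split into pro- and metakinetoplastids
euglenozoa_trees <- function() {
  list(
    own = read_newick(
      "(Outgroup,(Diplonemids,(Euglenids,(Prokinetoplastids,Metakinetoplastids))));"),
    kostygov = read_newick(
      "(Outgroup,(Euglenids,(Diplonemids,(Prokinetoplastids,Metakinetoplastids))));"))
}

euglenozoa_presence <- function() {
  c(Outgroup = FALSE, Diplonemids = FALSE, Euglenids = TRUE,
    Prokinetoplastids = FALSE, Metakinetoplastids = TRUE)
}

random_topology <- function(ntip) {
  ape::rtree(ntip, rooted = TRUE, br = NULL)
}

registry_fixture_path <- function() {
  system.file("extdata", "its_registry_schematic.tsv", package = "rdnafrag")
}
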