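make_tax <- function(otus, genera) {
  taxonomy_map(data.frame(otu_id = otus, domain = "Bacteria",
                          genus = genera, stringsAsFactors = FALSE))
}

test_that("OTUs inherit pathways from their genus annotation", {
  tax <- make_tax(c("O1", "O2", "O3"),
                  c("Acidothermus", "Planctomyces", NA))
  ann <- guild_annotation(c("Acidothermus", "Planctomyces", "Planctomyces"),
                          c("nirK", "nrfA", "narG"))
  gm <- suppressMessages(assign_guilds(tax, ann))
  expect_equal(gm$O1, "denitrification")
  expect_equal(gm$O2, c("DNRA", "nitrate_reduction"))
  expect_equal(gm$O3, character(0))
})

test_that("guild quantification counts membership, not genes", {
  tax <- make_tax(c("A", "B", "C"), c("gA", "gB", "gC"))
  ann <- guild_annotation(c("gA", "gB", "gB", "gC"),
                          c("nirK", "nirK", "nosZ", "nrfA"))
  gm <- suppressMessages(assign_guilds(tax, ann))
  abs_tab <- toy_table(matrix(c(100, 50, 30), 3, 1), scale = "absolute",
                       otus = c("A", "B", "C"))
  pa <- quantify_guilds(abs_tab, gm, annotation = ann, taxonomy = tax)
  expect_equal(unname(pa$pathways["denitrification", 1]), 150)  # B once
  expect_equal(unname(pa$pathways["DNRA", 1]), 30)
  # adding a second denitrification gene to an already-denitrifying OTU
  # changes nothing
  ann2 <- guild_annotation(c("gA", "gA", "gB", "gB", "gC"),
                           c("nirK", "nirS", "nirK", "nosZ", "nrfA"))
  gm2 <- suppressMessages(assign_guilds(tax, ann2))
  pa2 <- quantify_guilds(abs_tab, gm2)
  expect_equal(pa2$pathways["denitrification", ],
               pa$pathways["denitrification", ])
  expect_error(quantify_guilds(toy_table(matrix(1, 1, 1)), gm),
               "to_absolute")
})

test_that("pathway sums equal the sum over their provenance", {
  set.seed(12)
  sim <- generate_community(50, 8, guild_spec = c(denitrification = 0.3,
                                                  DNRA = 0.1),
                            depth = 5000, seed = 12)
  gm <- suppressMessages(assign_guilds(sim$taxonomy, sim$annotation))
  pa <- quantify_guilds(sim$absolute, gm)
  for (p in rownames(pa$pathways)) {
    members <- names(pa$provenance)[vapply(pa$provenance,
                                           function(s) p %in% s, TRUE)]
    manual <- if (length(members) > 0)
      colSums(sim$absolute$values[members, , drop = FALSE])
    else setNames(rep(0, 8), colnames(sim$absolute$values))
    expect_equal(pa$pathways[p, ], manual)
  }
})

test_that("denitrification:DNRA ratio works on group means", {
  pw <- matrix(0, 5, 4, dimnames = list(names(gene_pathways()),
                                        paste0("S", 1:4)))
  pw["denitrification", ] <- c(300, 300, 140, 140)
  pw["DNRA", ] <- c(100, 100, 100, 100)
  pa <- structure(list(pathways = pw, genes = NULL, provenance = list(),
                       group = setNames(c("spruce", "spruce", "beech",
                                          "beech"), colnames(pw))),
                  class = "pathway_abundance")
  r <- denit_dnra_ratio(pa)
  expect_equal(unname(r["spruce"]), 3)
  expect_equal(unname(r["beech"]), 1.4)
  # equal abundances give ratio one
  pw["denitrification", ] <- pw["DNRA", ]
  pa$pathways <- pw
  expect_equal(as.vector(unname(denit_dnra_ratio(pa))), c(1, 1))
  # zero DNRA reports +Inf with a warning, not an error
  pw["DNRA", ] <- 0
  pa$pathways <- pw
  expect_warning(r0 <- denit_dnra_ratio(pa), "Inf")
  expect_true(all(is.infinite(r0)))
})

test_that("guild abundances are linear in the table", {
  set.seed(3)
  sim <- generate_community(40, 6, guild_spec = c(denitrification = 0.3,
                                                  DNRA = 0.1),
                            depth = 2000, seed = 3)
  gm <- suppressMessages(assign_guilds(sim$taxonomy, sim$annotation))
  pa1 <- quantify_guilds(sim$absolute, gm)
  scaled <- sample_table(sim$absolute$values * 7, scale = "absolute")
  pa7 <- quantify_guilds(scaled, gm)
  expect_equal(pa7$pathways, pa1$pathways * 7)
  expect_equal(denit_dnra_ratio(pa7), denit_dnra_ratio(pa1))
})

test_that("flux scheme weights are group-mean guild abundances", {
  pw <- matrix(1:10, 5, 2, dimnames = list(names(gene_pathways()),
                                           c("S1", "S2")))
  pa <- structure(list(pathways = pw, genes = NULL, provenance = list(),
                       group = NULL), class = "pathway_abundance")
  fs <- flux_scheme(pa)
  expect_setequal(fs$pathway, names(gene_pathways()))
  expect_equal(fs$weight[fs$pathway == "denitrification"],
               mean(pw["denitrification", ]))
  expect_equal(fs$from[fs$pathway == "DNRA"], "NO2-")
  expect_equal(fs$to[fs$pathway == "DNRA"], "NH4+")
  # doubling all abundances doubles all weights
  pa2 <- pa; pa2$pathways <- pw * 2
  expect_equal(flux_scheme(pa2)$weight, fs$weight * 2)
  # all-zero pathways give all-zero arrows
  pa0 <- pa; pa0$pathways <- pw * 0
  expect_true(all(flux_scheme(pa0)$weight == 0))
})
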