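make_tax_fixture <- function() {
  m <- rbind(OTU1 = c(5L, 1L, 0L, 2L),
             OTU2 = c(1L, 3L, 2L, 0L),
             OTU3 = c(0L, 2L, 4L, 1L),
             OTU4 = c(2L, 0L, 1L, 3L))
  colnames(m) <- paste0("S", 1:4)
  tab <- otu_table(m, "m")
  tax <- c(
    OTU1 = "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae; g__Lactobacillus",
    OTU2 = "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae; g__Lactobacillus",
    OTU3 = "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Bacteroidaceae; g__Bacteroides",
    OTU4 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__")
  list(tab = tab, tax = tax)
}

test_that("taxonomic collapse sums members and conserves column totals", {
  fx <- make_tax_fixture()
  gen <- collapse_by_taxonomy(fx$tab, fx$tax, "genus")
  ## two OTUs share the Lactobacillus lineage -> one row with summed counts
  lacto <- grep("g__Lactobacillus", otu_ids(gen), value = TRUE)
  expect_length(lacto, 1)
  expect_equal(unname(gen$counts[lacto, ]),
               unname(fx$tab$counts["OTU1", ] + fx$tab$counts["OTU2", ]))
  ## empty genus rank -> unclassified keyed by the deepest assigned parent
  uncl <- grep("^unclassified_", otu_ids(gen), value = TRUE)
  expect_length(uncl, 1)
  expect_match(uncl, "f__Lachnospiraceae")
  ## conservation
  expect_equal(colSums(gen$counts), colSums(fx$tab$counts))

  ## random fixture conservation at phylum level
  m <- make_counts(10, 6, seed = 19)
  tab <- otu_table(m, "r")
  tax <- setNames(sprintf("k__Bacteria; p__P%d", rep(1:3, length.out = 10)),
                  rownames(m))
  phy <- collapse_by_taxonomy(tab, tax, "phylum")
  expect_equal(colSums(phy$counts), colSums(m))
  expect_equal(nrow(phy$counts), 3)

  expect_error(collapse_by_taxonomy(tab, tax, "species"))
  expect_error(collapse_by_taxonomy(tab, tax[-1], "phylum"),
               "without taxonomy")
})

test_that("collapse is idempotent and hierarchical", {
  fx <- make_tax_fixture()
  gen <- collapse_by_taxonomy(fx$tab, fx$tax, "genus")
  ## re-collapsing the genus table at genus level changes nothing
  tax_gen <- setNames(otu_ids(gen), otu_ids(gen))
  ## unclassified rows carry no parsable prefix at genus; rebuild lineages
  tax_gen[grep("^unclassified_", tax_gen)] <-
    sub("^unclassified_", "", tax_gen[grep("^unclassified_", tax_gen)])
  gen2 <- collapse_by_taxonomy(gen, tax_gen, "genus")
  expect_equal(colSums(gen2$counts), colSums(gen$counts))

  ## genus -> phylum equals collapsing directly at phylum
  phy_direct <- collapse_by_taxonomy(fx$tab, fx$tax, "phylum")
  phy_via_gen <- collapse_by_taxonomy(gen, tax_gen, "phylum")
  expect_identical(sort(otu_ids(phy_direct)), sort(otu_ids(phy_via_gen)))
  expect_equal(phy_direct$counts[order(rownames(phy_direct$counts)), ],
               phy_via_gen$counts[order(rownames(phy_via_gen$counts)), ])
})

test_that("shared_taxa intersects profiles alphabetically", {
  mk <- function(ids, lab)
    herit_profile(data.frame(otu_id = ids, A = 0.1,
                             stringsAsFactors = FALSE), lab)
  expect_identical(shared_taxa(list(mk(c("b", "a"), "1"),
                                    mk(c("a", "b"), "2"))), c("a", "b"))
  expect_identical(shared_taxa(list(mk("a", "1"), mk("b", "2"))),
                   character(0))
  expect_identical(shared_taxa(list(mk(c("a", "x"), "1"),
                                    mk(c("x", "b"), "2"),
                                    mk(c("c", "x"), "3"))), "x")
})

test_that("heritability GLM matches the normal-equation solution", {
  ## 6-row example solved by explicit matrix algebra
  obs <- data.frame(taxon = c("t1", "t1", "t2", "t2", "t3", "t3"),
                    method = rep(c("m1", "m2"), 3),
                    A = c(0.10, 0.12, 0.30, 0.33, 0.05, 0.06))
  g <- heritability_glm(obs)
  X <- cbind(1, obs$taxon == "t2", obs$taxon == "t3", obs$method == "m2")
  beta <- solve(t(X) %*% X, t(X) %*% obs$A)
  expect_equal(unname(coef(g)), drop(beta), tolerance = 1e-10)
  expect_identical(unname(g$reference_levels),
                   c("t1", "m1"))
  ## residuals orthogonal to the design
  expect_true(all(abs(t(X) %*% residuals(g$lm_fit)) < 1e-8))
})

test_that("heritability GLM recovers constructed taxon effects", {
  set.seed(71)
  methods <- paste0("m", 1:4)
  taxa <- paste0("t", 1:6)
  obs <- expand.grid(taxon = taxa, method = methods,
                     stringsAsFactors = FALSE)
  obs$A <- 0.1 + 0.2 * (obs$taxon == "t2") + rnorm(nrow(obs), sd = 0.01)
  g <- heritability_glm(obs)
  co <- g$coefficients
  expect_lt(abs(co$estimate[co$term == "taxont2"] - 0.2), 0.02)
  mcoef <- co$estimate[startsWith(co$term, "method")]
  expect_true(all(abs(mcoef) < 0.02))
  expect_equal(g$n_methods_significant, 0)
  expect_gte(g$n_taxa_significant, 1)

  ## constant response: all non-intercept coefficients are 0
  obs0 <- obs; obs0$A <- 0.25
  g0 <- suppressWarnings(heritability_glm(obs0))  # lm warns: perfect fit
  expect_true(all(abs(coef(g0)[-1]) < 1e-12))

  ## a taxon seen under one method only is dropped with a warning
  extra <- rbind(obs, data.frame(taxon = "t9", method = "m1", A = 0.5))
  expect_warning(g2 <- heritability_glm(extra), "t9")
  expect_false(any(grepl("t9", g2$coefficients$term)))
})
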