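feat_row <- function(...) {
  base <- data.frame(taxon = "t1", genome = "g1", source_spring = "Jinze",
                     identity_16S = 99, completeness = 0.95,
                     contamination = 0.02, size_obs = 2.5e6,
                     gltI = FALSE, peb1A = FALSE, aapJ = FALSE,
                     abc_pa_s = FALSE, gltP = FALSE, gltT = FALSE,
                     gltTK = FALSE, gltPh = FALSE, ybeC = FALSE,
                     actP = FALSE, atcase = FALSE, ack_pta = FALSE,
                     acs = FALSE, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("aspartate primary utilizers need transporter AND pathway", {
  pri <- classify_utilizer("aspartate", 0.15,
                           features = feat_row(abc_pa_s = TRUE, atcase = TRUE))
  expect_equal(pri$class, "primary")
  cf <- classify_utilizer("aspartate", 0.15, features = feat_row(atcase = TRUE))
  expect_equal(cf$class, "cross-feeder")
  cf2 <- classify_utilizer("aspartate", 0.15,
                           features = feat_row(gltP = TRUE))
  expect_equal(cf2$class, "cross-feeder")   # transporter without pathway
  non <- classify_utilizer("aspartate", -0.01,
                           features = feat_row(abc_pa_s = TRUE, atcase = TRUE))
  expect_equal(non$class, "non-utilizer")
})

test_that("acetate waives the transporter requirement", {
  pri <- classify_utilizer("acetate", 0.05,
                           features = feat_row(actP = FALSE, acs = TRUE))
  expect_equal(pri$class, "primary")
  pri2 <- classify_utilizer("acetate", 0.05,
                            features = feat_row(ack_pta = TRUE))
  expect_equal(pri2$class, "primary")
  cf <- classify_utilizer("acetate", 0.05,
                          features = feat_row(actP = TRUE))
  expect_equal(cf$class, "cross-feeder")    # transporter alone is not a pathway
})

test_that("emergent and genome-less taxa get their own classes", {
  expect_equal(classify_utilizer("aspartate", NA, emergent = TRUE)$class,
               "emergent-unscored")
  expect_equal(classify_utilizer("aspartate", 0.2, features = NULL)$class,
               "no-genome")
  expect_error(classify_utilizer("glucose", 0.2), "arg")
})

test_that("CI-based positivity is available as an option", {
  f <- feat_row(abc_pa_s = TRUE, atcase = TRUE)
  med <- classify_utilizer("aspartate", 0.1, features = f,
                           ci_low = -0.02, positive = "median")
  expect_equal(med$class, "primary")
  ci <- classify_utilizer("aspartate", 0.1, features = f,
                          ci_low = -0.02, positive = "ci")
  expect_equal(ci$class, "non-utilizer")
})

test_that("genome size estimation follows the completeness/contamination formula", {
  expect_equal(estimate_genome_size(2e6, 0.95, 0.05), 2e6)
  expect_equal(estimate_genome_size(123456, 1, 0), 123456)
  expect_equal(estimate_genome_size(3e6, 0.90, 0.10), 3e6)
  # linear in size_obs
  expect_equal(estimate_genome_size(2 * 1.7e6, 0.8, 0.04),
               2 * estimate_genome_size(1.7e6, 0.8, 0.04))
  expect_error(estimate_genome_size(2e6, 0, 0.05), "completeness")
  expect_error(estimate_genome_size(2e6, 0.9, 1), "contamination")
})

test_that("representative selection prioritizes location over quality", {
  cands <- rbind(
    feat_row(genome = "gJ", source_spring = "Jinze", identity_16S = 99,
             completeness = 0.90, contamination = 0),
    feat_row(genome = "gR", source_spring = "Rehai", identity_16S = 100,
             completeness = 0.99, contamination = 0))
  expect_equal(select_representative(cands)$genome, "gJ")
  cands2 <- rbind(cands, feat_row(genome = "gG", source_spring = "Gongxiaoshe",
                                  identity_16S = 97, completeness = 0.75,
                                  contamination = 0.05))
  expect_equal(select_representative(cands2)$genome, "gG")
  # identity filter is strict
  low <- feat_row(genome = "gLow", identity_16S = 94)
  expect_null(select_representative(low, identity_min = 95))
  # same spring: quality score completeness - 5*contamination decides
  q <- rbind(feat_row(genome = "gA", completeness = 0.96, contamination = 0.05),
             feat_row(genome = "gB", completeness = 0.90, contamination = 0.01))
  expect_equal(select_representative(q)$genome, "gB")  # 0.85 vs 0.71
  # full tie: lexicographically smaller genome id
  tie <- rbind(feat_row(genome = "gB"), feat_row(genome = "gA"))
  expect_equal(select_representative(tie)$genome, "gA")
})

test_that("duplicate AFE values on one genome keep the maximum", {
  calls <- data.frame(taxon = c("t1", "t2", "t3"),
                      genome = c("g1", "g1", "g2"),
                      afe_median = c(0.1, 0.3, 0.2),
                      stringsAsFactors = FALSE)
  out <- resolve_duplicate_afe(calls)
  expect_equal(nrow(out), 2)
  expect_equal(out$afe_median[out$genome == "g1"], 0.3)
  one <- resolve_duplicate_afe(calls[3, ])
  expect_equal(one$afe_median, 0.2)
  tie <- data.frame(taxon = c("a", "b"), genome = "g", afe_median = 0.2)
  expect_equal(nrow(resolve_duplicate_afe(tie)), 1)
})

test_that("classification is a pure function of its inputs", {
  f <- feat_row(abc_pa_s = TRUE, atcase = TRUE)
  a <- classify_utilizer("aspartate", 0.12, features = f)
  b <- classify_utilizer("aspartate", 0.12, features = f)
  expect_identical(a, b)
})

test_that("no primary call ever has nonpositive AFE across synthetic runs", {
  sim <- simulate_experiment(sim_config(n_taxa = 50, seed = 31,
                                        reads_per_fraction = 20000,
                                        emergent_taxa = 3))
  feats <- simulate_genome_features(sim$truth, seed = 5)
  afe <- rbind(qsip_afe(sim$fractions, "acetate", n_boot = 100, seed = 1),
               qsip_afe(sim$fractions, "aspartate", n_boot = 100, seed = 1))
  calls <- classify_utilizers(afe, feats)
  pri <- calls[calls$class == "primary", ]
  expect_true(all(pri$afe_median > 0))
  expect_true(all(calls$class %in% c("primary", "cross-feeder", "non-utilizer",
                                     "emergent-unscored", "no-genome")))
  # dedupe keeps one call per genome
  dd <- classify_utilizers(afe, feats, dedupe_genomes = TRUE)
  with_g <- dd[!is.na(dd$genome), ]
  expect_false(any(duplicated(with_g$genome)))
})
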