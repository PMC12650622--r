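toy_model <- function() {
  new_metabolic_model(
    metabolites = data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                             compartment = "c", stringsAsFactors = FALSE),
    reactions = list(
      list(id = "r1", stoichiometry = c(A = -1, B = 1), gpr = "g1 or g2",
           subsystem = "s1"),
      list(id = "r2", stoichiometry = c(B = -1, C = 1), gpr = "g3 and g4",
           subsystem = "s2"),
      list(id = "r3", stoichiometry = c(A = -1, C = 1), gpr = "g5",
           subsystem = "s1")),
    genes = paste0("g", 1:5))
}

test_that("model construction validates its invariants", {
  m <- toy_model()
  expect_s3_class(m, "pdmr_metabolic_model")
  expect_length(m$reactions, 3)
  expect_error(new_metabolic_model(
    data.frame(id = "A", name = "A", compartment = "c"),
    list(list(id = "r1", stoichiometry = c(A = -1, ZZ = 1), gpr = "",
              subsystem = "")), character(0)),
    "undeclared metabolite.*ZZ|ZZ")
  expect_error(new_metabolic_model(
    data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    list(list(id = "r1", stoichiometry = c(A = -1, B = 1),
              gpr = "g1 or or g2", subsystem = "")), "g1"),
    "r1")
  # a metabolite with no reactions is a degenerate network
  expect_error(new_metabolic_model(
    data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
               compartment = "c"),
    list(list(id = "r1", stoichiometry = c(A = -1, B = 1), gpr = "",
              subsystem = "")), character(0)),
    "no reactions")
})

test_that("JSON and SBML round trips preserve the model", {
  m <- toy_model()
  fj <- tempfile(fileext = ".json")
  write_model(m, fj)
  mj <- load_model(fj)
  expect_equal(mj$metabolites, m$metabolites)
  expect_equal(lapply(mj$reactions, `[[`, "stoichiometry"),
               lapply(m$reactions, `[[`, "stoichiometry"))
  expect_equal(vapply(mj$reactions, `[[`, "", "gpr"),
               vapply(m$reactions, `[[`, "", "gpr"))
  expect_setequal(mj$genes, m$genes)

  fs <- tempfile(fileext = ".xml")
  write_model(m, fs, format = "sbml")
  ms <- load_model(fs)
  expect_equal(ms$metabolites$id, m$metabolites$id)
  expect_equal(lapply(ms$reactions, `[[`, "stoichiometry"),
               lapply(m$reactions, `[[`, "stoichiometry"))
  # GPRs may gain redundant parentheses; compare parsed gene content and
  # linkage semantics instead of strings
  for (i in seq_along(m$reactions)) {
    expect_setequal(pdmr:::gpr_genes(parse_gpr(ms$reactions[[i]]$gpr)),
                    pdmr:::gpr_genes(parse_gpr(m$reactions[[i]]$gpr)))
  }
  expect_equal(vapply(ms$reactions, `[[`, "", "subsystem"),
               vapply(m$reactions, `[[`, "", "subsystem"))
})

test_that("GPR parsing and evaluation respect the linkage policy", {
  flags <- c(g1 = TRUE, g2 = FALSE, g3 = TRUE, g4 = FALSE)
  expect_true(evaluate_gpr("g1 or g2", flags))
  # OR-collapse: an AND rule is linked if any member is flagged
  expect_true(evaluate_gpr("g3 and g4", flags))
  expect_false(evaluate_gpr("g3 and g4", flags, policy = "boolean"))
  expect_true(evaluate_gpr("(g1 and g2) or g3", flags, policy = "boolean"))
  expect_false(evaluate_gpr("g2 or g4", flags))
  # unknown genes count as not-DE
  expect_false(evaluate_gpr("gX and gY", flags))
  expect_error(parse_gpr("g1 or (g2"), "\\)")
  expect_error(parse_gpr("g1 g2"), "trailing")
  parsed <- parse_gpr("(g1 and g2) or g3")
  expect_equal(parsed$op, "or")
  expect_setequal(pdmr:::gpr_genes(parsed), c("g1", "g2", "g3"))
})

test_that("reporter_scores: flat input, k = 1 limit, invariants", {
  m <- toy_model()
  # all p = 0.5 -> all Z = 0, corrected scores ~ 0, nothing significant
  p_flat <- setNames(rep(0.5, 5), paste0("g", 1:5))
  rs <- reporter_scores(m, p_flat, n_background = 500, seed = 1)
  expect_true(all(abs(rs$z_corrected) < 1e-6 | !is.finite(rs$z_corrected)))
  expect_true(all(rs$fdr >= 0.05))

  # k = 1 metabolite with Z = 3 against a null background
  m2 <- new_metabolic_model(
    data.frame(id = c("X", "Y"), name = c("X", "Y"), compartment = "c"),
    list(list(id = "r1", stoichiometry = c(X = -1, Y = 1), gpr = "hot",
              subsystem = "s")),
    genes = "hot")
  big <- gen_toy_metabolic_model(seed = 2)   # provides a wide gene pool
  # embed: one-reaction model scores only its own gene; background draws
  # come from the scored model genes, here many nulls plus the hot gene
  m3 <- new_metabolic_model(
    rbind(big$model$metabolites, data.frame(id = "X", name = "X",
                                            compartment = "c")),
    c(big$model$reactions,
      list(list(id = "rX", stoichiometry = c(m01 = -1, X = 1), gpr = "hot",
                subsystem = "s"))),
    genes = c(big$model$genes, "hot"))
  p3 <- c(setNames(pdmr:::with_seed(44, runif(length(big$model$genes))),
                   big$model$genes),
          hot = 1 - pnorm(3))
  rs3 <- reporter_scores(m3, p3, n_background = 4000, seed = 3)
  zx <- rs3$z_corrected[rs3$metabolite == "X"]
  # closed-form k = 1 background: mean/sd of the scored pool's Z values
  pool_z <- qnorm(p3, lower.tail = FALSE)
  expected <- (3 - mean(pool_z)) / sd(pool_z)
  expect_lt(abs(zx - expected), 0.15)
  expect_lt(abs(zx - 3), 1)     # mu_1 ~ 0, sigma_1 ~ 1 under a null pool

  # p = 0 clipped with a message; k >= 1 and fdr in (0, 1]
  expect_message(reporter_scores(m, c(p_flat[1:4], g5 = 0),
                                 n_background = 200, seed = 1), "clipped")
  expect_true(all(rs$k >= 1))
  expect_true(all(rs$fdr > 0 & rs$fdr <= 1))
  # rows sorted by corrected score, descending
  expect_true(all(diff(rs3$z_corrected) <= 1e-12))
  expect_error(reporter_scores(m, c(zz = 0.5), n_background = 10, seed = 1),
               "maps into")
})

test_that("background correction removes the k-dependence of null scores", {
  tm <- gen_toy_metabolic_model(n_metabolites = 20, n_reactions = 40,
                                contrast = 1, seed = 14)
  p_null <- setNames(pdmr:::with_seed(45, runif(length(tm$model$genes))),
                     tm$model$genes)
  rs <- reporter_scores(tm$model, p_null, n_background = 2000, seed = 4)
  # regression of corrected score on k: slope ~ 0
  fit <- lm(z_corrected ~ k, data = rs)
  expect_lt(abs(coef(fit)[["k"]]), 0.2)
  expect_lt(abs(mean(rs$z_corrected)), 0.5)
})

test_that("reporter score is monotone in neighbour evidence", {
  m <- toy_model()
  p_lo <- setNames(c(0.5, 0.5, 0.5, 0.5, 0.5), paste0("g", 1:5))
  p_hi <- p_lo; p_hi["g5"] <- 1 - 1e-12   # near-certain null evidence
  rs_lo <- reporter_scores(m, p_lo, n_background = 1000, seed = 6)
  rs_hi <- reporter_scores(m, p_hi, n_background = 1000, seed = 6)
  # metabolite A neighbours g1, g2 (r1) and g5 (r3): weakening g5's
  # evidence can only lower A's raw aggregate under a fixed background
  expect_lte(rs_hi$z_raw[rs_hi$metabolite == "A"],
             rs_lo$z_raw[rs_lo$metabolite == "A"])
})

test_that("subsystem enrichment matches Fisher and handles edge cases", {
  m <- toy_model()
  # DE genes hit r1 (s1) and r2 (s2) but not r3 (s1)
  res <- subsystem_enrichment(m, c("g1", "g3"))
  expect_setequal(res$subsystem, c("s1", "s2"))
  s1 <- res[res$subsystem == "s1", ]
  # universe 3 reactions, 2 linked; s1 has 2 reactions, 1 linked
  expect_equal(s1$n_reactions, 2L)
  expect_equal(s1$n_de_linked, 1L)
  expect_equal(s1$pval, enum_hyper_tail(1, 2, 3, 2), tolerance = 1e-12)
  fis <- fisher.test(matrix(c(1, 1, 1, 0), 2), alternative = "greater")
  expect_equal(s1$pval, fis$p.value, tolerance = 1e-10)
  # every reaction linked -> all p = 1
  res_all <- subsystem_enrichment(m, paste0("g", 1:5))
  expect_true(all(res_all$pval == 1))
  # reactions without GPR are excluded from the universe
  m2 <- new_metabolic_model(
    data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    list(list(id = "r1", stoichiometry = c(A = -1, B = 1), gpr = "g1",
              subsystem = "s1"),
         list(id = "r2", stoichiometry = c(B = -1, A = 1), gpr = "",
              subsystem = "bare")),
    genes = "g1")
  res2 <- subsystem_enrichment(m2, "g1")
  expect_false("bare" %in% res2$subsystem)
  expect_error(subsystem_enrichment(m, "nope"), "maps into")
})

test_that("run_contrasts labels shared and subtype-specific findings", {
  tm <- gen_toy_metabolic_model(n_metabolites = 15, n_reactions = 25,
                                contrast = 10000, seed = 19)
  de <- data.frame(gene = names(tm$gene_pvals),
                   pval = unname(tm$gene_pvals),
                   log2fc = ifelse(tm$gene_pvals < 0.01, 3, 0.1))
  # identical inputs: everything shared or neither
  res <- run_contrasts(tm$model, list(GBA1_PD = de, sporadic_PD = de),
                       seed = 3, n_background = 1000)
  expect_true(all(res$reporter_comparison$label %in% c("shared", "neither")))
  expect_true(all(res$subsystem_comparison$label %in% c("shared", "neither")))
  expect_true(tm$truth$hot_metabolite %in%
                res$reporter_comparison$id[res$reporter_comparison$label ==
                                             "shared"])
  # empty DE in one contrast leaves the other unaffected
  de_null <- de; de_null$pval <- runif(nrow(de_null), 0.5, 1)
  de_null$log2fc <- 0
  res2 <- run_contrasts(tm$model, list(GBA1_PD = de, sporadic_PD = de_null),
                        seed = 3, n_background = 1000)
  lab <- res2$reporter_comparison
  expect_true(tm$truth$hot_metabolite %in% lab$id[lab$label == "GBA1_specific"])
  expect_error(run_contrasts(tm$model, list(GBA1_PD = de), seed = 1),
               "both contrasts")
})
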