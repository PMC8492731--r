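test_that("ternary sign vector matches a cor.test oracle gene by gene", {
  set.seed(10)
  n <- 6
  anchor <- rnorm(n)
  vals <- rbind(anchor, anchor + rnorm(n, 0, 0.05),
                -anchor + rnorm(n, 0, 0.05), rnorm(n))
  expr <- named_expr(vals, genes = c("IGF1", "POS1", "NEG1", "NOISE1"))
  signs <- ternary_sign_vector(expr, c("POS1", "NEG1", "NOISE1"))
  oracle <- sapply(c("POS1", "NEG1", "NOISE1"), function(g) {
    ct <- cor.test(expr[g, ], expr["IGF1", ])
    if (ct$p.value <= 0.01) as.integer(sign(ct$estimate)) else 0L
  })
  expect_equal(unname(signs), unname(oracle))
})

test_that("genes identical or opposite to the anchor get signs +1 / -1", {
  set.seed(11)
  anchor <- rnorm(8)
  expr <- named_expr(rbind(anchor, anchor, -anchor),
                     genes = c("IGF1", "SAME", "OPP"))
  signs <- ternary_sign_vector(expr, c("SAME", "OPP"))
  expect_equal(unname(signs), c(1L, -1L))
  # zero-variance gene: correlation undefined, sign 0 with warning
  expr2 <- named_expr(rbind(anchor, rep(1, 8)), genes = c("IGF1", "FLAT"))
  expect_warning(s2 <- ternary_sign_vector(expr2, "FLAT"),
                 "zero-variance")
  expect_equal(unname(s2), 0L)
})

test_that("ligand score is the per-patient correlation with the signs", {
  set.seed(12)
  g <- 10
  signs <- setNames(sample(c(-1L, 1L), g, replace = TRUE),
                    sprintf("G%03d", 1:g))
  vals <- matrix(rnorm(g * 5), g, 5)
  vals[, 1] <- signs          # patient 1 equals the sign vector
  vals[, 2] <- -signs         # patient 2 is its negation
  expr <- named_expr(vals)
  sc <- igf1_ligand_score(expr, signs, center = FALSE)
  expect_equal(unname(sc[1]), 1)
  expect_equal(unname(sc[2]), -1)
  expect_true(all(sc >= -1 & sc <= 1))
  # brute-force Pearson oracle per patient, with population centering
  sc_c <- igf1_ligand_score(expr, signs, center = TRUE)
  ctr <- expr - rowMeans(expr)
  oracle <- apply(ctr, 2, function(x) cor(as.numeric(signs), x))
  expect_equal(sc_c, oracle, tolerance = 1e-10)
})

test_that("ligand score is invariant to gene/patient order and scaling", {
  set.seed(13)
  sim <- simulate_expression(scenario_config(expression = list(
    n_patients = 30L, ligand_size = 40L, creighton_size = 20L,
    n_other = 10L)), seed = 14)
  expr <- sim$expr
  signs <- ternary_sign_vector(expr, sim$ligand_signature$genes)
  sc <- igf1_ligand_score(expr, signs)
  perm <- expr[sample(nrow(expr)), sample(ncol(expr))]
  sc_perm <- igf1_ligand_score(perm, signs)
  expect_equal(sc_perm[names(sc)], sc, tolerance = 1e-10)
  # positive rescaling of a patient's centered expression keeps its score
  ctr <- center_expression(expr, "mean")
  ctr2 <- ctr; ctr2[, 3] <- 5 * ctr2[, 3]
  sc2 <- igf1_ligand_score(ctr2, signs, center = FALSE)
  sc1 <- igf1_ligand_score(ctr, signs, center = FALSE)
  expect_equal(sc2[3], sc1[3], tolerance = 1e-10)
})

test_that("signed-signature score matches a per-patient lm oracle", {
  set.seed(15)
  g <- 8; n <- 12
  signs <- c(rep(1L, 4), rep(-1L, 4))
  sig <- signed_signature("toy", sprintf("G%03d", 1:g), signs)
  expr <- named_expr(matrix(rnorm(g * n), g, n))
  raw <- igfr_creighton_score(expr, sig, zscore = FALSE)
  med <- apply(expr, 1, median)
  ctr <- expr - med
  oracle_raw <- sapply(seq_len(n), function(j) {
    -summary(lm(ctr[, j] ~ signs))$coefficients["signs", "t value"]
  })
  expect_equal(unname(raw), oracle_raw, tolerance = 1e-10)
  z <- igfr_creighton_score(expr, sig)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(unname(z), unname((raw - mean(raw)) / sd(raw)),
               tolerance = 1e-12)
})

test_that("flipping every signature sign negates the raw scores", {
  set.seed(16)
  g <- 20; n <- 9
  sig <- signed_signature("toy", sprintf("G%03d", 1:g),
                          sample(c(-1L, 1L), g, replace = TRUE))
  flip <- signed_signature("toy-flip", sig$genes, -unname(sig$signs))
  expr <- named_expr(matrix(rnorm(g * n), g, n))
  raw <- igfr_creighton_score(expr, sig, zscore = FALSE)
  raw_f <- igfr_creighton_score(expr, flip, zscore = FALSE)
  expect_equal(raw_f, -raw, tolerance = 1e-10)
  expect_equal(igfr_creighton_score(expr, flip),
               -igfr_creighton_score(expr, sig), tolerance = 1e-10)
})

test_that("tertile classification splits at the empirical thirds", {
  cls <- tertile_class(c(5, 9, 1, 3, 7, 2, 8, 4, 6))
  expect_equal(as.vector(table(cls)), c(3, 3, 3))
  expect_equal(as.character(cls[3]), "low")
  expect_equal(as.character(cls[2]), "high")
  expect_warning(flat <- tertile_class(rep(2, 5)), "all scores equal")
  expect_true(all(flat == "low"))
  # sort-based oracle on 10 values
  set.seed(17)
  x <- rnorm(10)
  cls10 <- tertile_class(x)
  q <- quantile(x, c(1, 2) / 3, names = FALSE)
  oracle <- cut(x, c(-Inf, q, Inf),
                labels = c("low", "intermediate", "high"))
  expect_equal(as.character(cls10), as.character(oracle))
})

test_that("gene-level biomarkers pass through expression plus the ratio", {
  set.seed(18)
  genes <- c("IGF1", "IGF2", "IGF1R", "INSR", "IGFBP2", "IRS1", "IRS2",
             "IGFBP3", "IGFBP4", "IGFBP5", "CDH1")
  vals <- matrix(rnorm(11 * 4), 11, 4)
  vals[10, ] <- vals[9, ]  # IGFBP5 == IGFBP4
  expr <- named_expr(vals, genes = genes)
  tab <- gene_level_biomarkers(expr)
  expect_equal(tab$IGFBP5_IGFBP4_ratio, rep(0, 4))
  expect_equal(tab$IRS1, unname(expr["IRS1", ]))
  # log-scale ratio equals the difference oracle
  vals[10, ] <- vals[9, ] + c(1, -2, 0.5, 0)
  tab2 <- gene_level_biomarkers(named_expr(vals, genes = genes))
  expect_equal(tab2$IGFBP5_IGFBP4_ratio, c(1, -2, 0.5, 0))
  expect_warning(out <- gene_level_biomarkers(expr[-1, ]), "IGF1")
  expect_false("IGF1" %in% names(out))
})
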