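make_weights <- function(ids, ref, alt, w, gene = "geneA", h2 = 0.2) {
  structure(data.frame(variant_id = ids, ref = ref, alt = alt, weight = w,
                       stringsAsFactors = FALSE),
            class = c("blue_weights", "data.frame"),
            gene_id = gene, lambda_hat = h2 / (1 - h2), h2 = h2)
}

test_that("harmonization matches, flips and drops as specified", {
  g <- toy_genotypes(n = 10, p = 5, seed = 90)
  g$variants$ref <- c("A", "C", "A", "C", "A")
  g$variants$alt <- c("G", "T", "T", "G", "G")
  # identical panel: identity mapping
  w_id <- make_weights(g$variants$id, g$variants$ref, g$variants$alt,
                       w = seq(0.1, 0.5, by = 0.1))
  h <- harmonize_weights(w_id, g)
  expect_identical(h$n_matched, 5L)
  expect_identical(h$n_dropped_ambiguous + h$n_dropped_mismatch +
                     h$n_unmatched, 0L)
  expect_equal(h$weights, w_id$weight)

  # rs1 swapped (A/G -> G/A, unambiguous): weight sign flips; imputed
  # expression shifts by an additive constant only
  w_sw <- w_id
  w_sw$ref[1] <- "G"; w_sw$alt[1] <- "A"
  h_sw <- harmonize_weights(w_sw, g)
  expect_identical(h_sw$n_flipped, 1L)
  expect_equal(h_sw$weights[1], -w_id$weight[1])
  # the training weight refers to the opposite allele, whose dosage is
  # 2 - g: the harmonized imputation equals that orientation up to the
  # additive constant 2 * beta_1
  e_manual <- as.numeric(g$dosages[, -1] %*% w_id$weight[-1]) +
    w_id$weight[1] * (2 - g$dosages[, 1])
  diff <- e_manual - impute_expression(h_sw)
  expect_equal(unname(diff), rep(2 * w_id$weight[1], 10), tolerance = 1e-12)

  # rs3 is A/T: a swap is strand-ambiguous and must be dropped
  w_amb <- w_id
  w_amb$ref[3] <- "T"; w_amb$alt[3] <- "A"
  h_amb <- harmonize_weights(w_amb, g)
  expect_identical(h_amb$n_matched, 4L)
  expect_identical(h_amb$n_dropped_ambiguous, 1L)
  # allele mismatch dropped; unknown ID unmatched
  w_mis <- w_id
  w_mis$ref[2] <- "A"; w_mis$alt[2] <- "C"
  w_mis$variant_id[5] <- "rs_nope"
  h_mis <- harmonize_weights(w_mis, g)
  expect_identical(h_mis$n_dropped_mismatch, 1L)
  expect_identical(h_mis$n_unmatched, 1L)
  expect_identical(h_mis$n_matched, 3L)
  w_none <- make_weights("zzz", "A", "G", 1)
  expect_error(harmonize_weights(w_none, g), "zero matched")
})

test_that("imputation is the dosage-weight product", {
  g <- toy_genotypes(n = 10, p = 4, seed = 91)
  w0 <- make_weights(g$variants$id, g$variants$ref, g$variants$alt,
                     w = rep(0, 4))
  expect_equal(impute_expression(harmonize_weights(w0, g)), rep(0, 10))
  w1 <- make_weights(g$variants$id[2], g$variants$ref[2], g$variants$alt[2], 1)
  expect_equal(impute_expression(harmonize_weights(w1, g)),
               unname(g$dosages[, 2]))
  wv <- make_weights(g$variants$id, g$variants$ref, g$variants$alt,
                     w = c(0.3, -0.2, 0.5, 1.1))
  expect_equal(impute_expression(harmonize_weights(wv, g)),
               as.numeric(g$dosages %*% c(0.3, -0.2, 0.5, 1.1)))
})

test_that("association Wald p matches an IRLS oracle and calibrates", {
  set.seed(92)
  n <- 200
  ehat <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * ehat))
  at <- association_test(ehat, y)
  orc <- oracle_logistic(ehat, y)
  expect_equal(unname(at$effect), unname(orc$coef[2]), tolerance = 1e-6)
  expect_equal(unname(at$p), unname(orc$p[2]), tolerance = 1e-4)
  expect_false(at$firth)
  # continuous phenotype route
  yc <- 0.5 * ehat + rnorm(n)
  atc <- association_test(ehat, yc)
  fit <- lm(yc ~ ehat)
  expect_equal(unname(atc$p), summary(fit)$coefficients[2, 4], tolerance = 1e-10)
  # strong effect: tiny p (odds ratio e^3 per unit of imputed expression)
  ys <- rbinom(n, 1, plogis(3 * ehat))
  expect_lt(association_test(ehat, ys)$p, 1e-6)
  expect_error(association_test(rep(1, n), y), "constant")
  expect_error(association_test(ehat, rep(1, n)), "distinct")
})

test_that("association test is calibrated under the null", {
  set.seed(93)
  R <- 2000; n <- 150
  pv <- vapply(seq_len(R), function(i) {
    association_test(rnorm(n), rbinom(n, 1, 0.4))$p
  }, numeric(1))
  t1 <- mean(pv < 0.05)
  expect_lt(abs(t1 - 0.05), 2.576 * sqrt(0.05 * 0.95 / R) + 0.005)
})

test_that("complete separation falls back to the Firth fit", {
  set.seed(94)
  ehat <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  at <- association_test(ehat, y)
  expect_true(at$firth)
  expect_true(is.finite(at$p) && at$p > 0 && at$p <= 1)
  expect_lt(at$p, 0.01)
})

test_that("in-sample imputation with trained BLUE equals Z beta_hat", {
  set.seed(95)
  g <- simulate_genotypes(80, 8, seed = 95)
  e <- simulate_expression(g, tau2 = 0.1, seed = 96)
  fit <- fit_reml(spectral_decompose(g, e = e))
  w <- blue_weights(fit)
  w$variant_id <- g$variants$id
  h <- harmonize_weights(w, g)
  expect_equal(impute_expression(h),
               as.numeric(g$dosages %*% w$weight), tolerance = 1e-12)
})

test_that("run_predixcan filters on heritability and controls the null", {
  set.seed(97)
  n <- 400
  g <- simulate_genotypes(n, 30, seed = 97)
  ids <- g$variants$id
  mk <- function(h2, gene) {
    set.seed(match(gene, paste0("gene", 1:50)) + 1000)
    make_weights(ids, g$variants$ref, g$variants$alt,
                 rnorm(30, 0, 0.05), gene = gene, h2 = h2)
  }
  db <- list(gene1 = mk(0.01, "gene1"),    # boundary: excluded (strict >)
             gene2 = mk(0.010001, "gene2"),
             gene3 = mk(0.3, "gene3"),
             gene4 = mk(0.0, "gene4"))
  y <- rbinom(n, 1, 0.5)
  res <- run_predixcan(db, g, y)
  expect_setequal(res$gene_id, c("gene2", "gene3"))
  expect_identical(attr(res, "bonferroni"), 0.05 / 2)
  # all-null cohort: no significant genes expected
  expect_lte(sum(res$significant), 1L)
})

test_that("causal genes drive recovery in a synthetic cohort", {
  set.seed(98)
  n <- 4000
  g <- simulate_genotypes(n, 40, seed = 98)
  ids <- g$variants$id
  db <- list(); truth <- character(0)
  for (k in 1:10) {
    gene <- sprintf("gene%02d", k)
    set.seed(2000 + k)
    w <- rnorm(40, 0, 0.08)
    db[[gene]] <- make_weights(ids, g$variants$ref, g$variants$alt, w,
                               gene = gene, h2 = 0.2)
  }
  causal <- sprintf("gene%02d", 1:5)
  eta <- rep(-0.2, n)
  for (gene in causal) {
    ehat <- as.numeric(g$dosages %*% db[[gene]]$weight)
    eta <- eta + 0.8 * scale(ehat)[, 1]
  }
  set.seed(99)
  y <- rbinom(n, 1, plogis(eta))
  res <- run_predixcan(db, g, y)
  hits <- res$gene_id[res$significant]
  expect_gte(sum(causal %in% hits), 4L)
})

test_that("significance is monotone in the Bonferroni family size", {
  p <- c(0.001, 0.01, 0.04)
  expect_gte(sum(p <= 0.05 / 3), sum(p <= 0.05 / 30))
})
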