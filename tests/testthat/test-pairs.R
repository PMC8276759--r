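test_that("negative-correlation test matches its closed form and cor.test", {
  # perfect negative correlation
  z <- rnorm(10)
  r1 <- neg_correlation_test(-z, z)
  expect_equal(r1$r, -1)
  expect_lt(r1$p, 1e-12)

  # exactly orthogonal vectors give p = 0.5 by t symmetry
  z2 <- c(-1, 0, 1, -1, 0, 1)
  x2 <- c(1, -2, 1, 1, -2, 1)        # centered, orthogonal to z2
  expect_equal(sum(x2 * z2), 0)
  r2 <- neg_correlation_test(x2, z2)
  expect_equal(r2$r, 0)
  expect_equal(r2$p, 0.5)

  # fixed n = 5 instance against an independent evaluation of r and the
  # t-tail (cor.test's one-sided Pearson test)
  x <- c(1, 2, 3, 4, 5)
  z <- c(5, 4, 4, 2, 1)
  got <- neg_correlation_test(x, z)
  ct <- cor.test(x, z, alternative = "less")
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)

  expect_error(neg_correlation_test(rep(1, 5), rnorm(5)), "variance")
})

test_that("microarray filter keeps planted pairs and matches per-pair oracle", {
  pan <- toy_panel(n = 95, n_planted = 4, n_null = 6, seed = 7)
  sets <- filter_pairs_microarray(pan$pairs, pan$mirna, pan$mrna, alpha = 0.05)

  # the 4 strongly negative planted pairs must be retained
  expect_true(all(pan$planted$gene %in% sets$gene))

  # exact retention equals the brute-force per-pair one-sided test
  keep_oracle <- vapply(seq_len(nrow(pan$pairs)), function(i) {
    cor.test(pan$mrna[, pan$pairs$gene[i]], pan$mirna[, pan$pairs$miRNA[i]],
             alternative = "less")$p.value < 0.05
  }, logical(1))
  expect_setequal(sets$gene, pan$pairs$gene[keep_oracle])

  # a positively correlated pair is dropped (wrong tail)
  z <- rnorm(50)
  d <- list(Z = cbind(mA = z), X = cbind(gA = 0.9 * z + rnorm(50, sd = 0.3)))
  rownames(d$Z) <- rownames(d$X) <- paste0("s", 1:50)
  out <- filter_pairs_microarray(tibble::tibble(miRNA = "mA", gene = "gA"),
                                 d$Z, d$X)
  expect_equal(nrow(out), 0)
})

test_that("unknown feature ids are skipped with a warning, not an error", {
  pan <- toy_panel(n = 30, seed = 2)
  pairs <- rbind(pan$pairs, tibble::tibble(miRNA = "mZZ", gene = "gZZ"))
  expect_warning(out <- filter_pairs_microarray(pairs, pan$mirna, pan$mrna),
                 "unknown feature")
  expect_false("gZZ" %in% out$gene)
})

test_that("retention is monotone in alpha", {
  pan <- toy_panel(n = 60, n_planted = 3, n_null = 12, strength = 0.5, seed = 5)
  s1 <- filter_pairs_microarray(pan$pairs, pan$mirna, pan$mrna, alpha = 0.01)
  s2 <- filter_pairs_microarray(pan$pairs, pan$mirna, pan$mrna, alpha = 0.10)
  key <- function(s) paste(s$miRNA, s$gene)
  expect_true(all(key(s1) %in% key(s2)))
})

test_that("null pairs are retained at about the nominal rate", {
  set.seed(11)
  n <- 40
  npairs <- 600
  Z <- matrix(rnorm(n * npairs), n, npairs,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:npairs)))
  X <- matrix(rnorm(n * npairs), n, npairs,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:npairs)))
  pairs <- tibble::tibble(miRNA = colnames(Z), gene = colnames(X))
  out <- filter_pairs_microarray(pairs, Z, X, alpha = 0.05)
  rate <- nrow(out) / npairs
  tol <- 3 * sqrt(0.05 * 0.95 / npairs)
  expect_lt(abs(rate - 0.05), tol)
})

test_that("sequencing two-step filter matches a brute-force evaluation", {
  set.seed(13)
  n <- 80
  npairs <- 20
  planted <- 1:6
  Z <- matrix(rpois(n * npairs, lambda = 8), n, npairs,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:npairs)))
  X <- matrix(rnorm(n * npairs), n, npairs,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:npairs)))
  for (j in seq_len(npairs)) {
    zero <- rbinom(n, 1, 0.3) == 1
    Z[zero, j] <- 0
    if (j %in% planted) {
      # zero-miRNA samples express high; elsewhere anti-correlated
      X[zero, j] <- 2 + rnorm(sum(zero), sd = 0.5)
      X[!zero, j] <- -0.08 * Z[!zero, j] + rnorm(sum(!zero), sd = 0.5)
    }
  }
  pairs <- tibble::tibble(miRNA = colnames(Z), gene = colnames(X))
  out <- filter_pairs_sequencing(pairs, Z, X, alpha = 0.05)

  keep_oracle <- vapply(seq_len(npairs), function(j) {
    z <- Z[, j]; x <- X[, j]
    zero <- z == 0
    if (sum(zero) < 2 || sum(!zero) < 2) return(FALSE)
    p1 <- t.test(x[zero], x[!zero], alternative = "greater")$p.value
    if (p1 >= 0.05) return(FALSE)
    cor.test(x[!zero], z[!zero], alternative = "less")$p.value < 0.05
  }, logical(1))
  expect_setequal(out$gene, colnames(X)[keep_oracle])
  expect_true(all(paste0("g", planted) %in% out$gene) ||
                sum(keep_oracle[planted]) >= 5)  # construction is strong

  # constant mRNA can never pass either step
  Xc <- X
  Xc[, 7] <- 1
  out2 <- filter_pairs_sequencing(pairs, Z, Xc)
  expect_false("g7" %in% out2$gene)
})

test_that("TargetScan flat files reduce to unique two-column pair lists", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ts.txt")
  writeLines(c("miR Family\tGene Symbol\tGene Tax ID\tSite Type",
               "miR-1\tGENE1\t9606\t2",
               "miR-1\tGENE1\t9606\t3",       # duplicate pair, extra site
               "miR-2\tGENE2\t9606\t1"), f)
  pairs <- read_targetscan(f)
  expect_equal(nrow(pairs), 2)
  expect_equal(names(pairs), c("miRNA", "gene"))
  expect_error(read_targetscan(f, mirna_col = "nope"), "not found")
})

test_that("integration set summary and TSV output are consistent", {
  pan <- toy_panel(n = 95, seed = 7)
  sets <- filter_pairs_microarray(pan$pairs, pan$mirna, pan$mrna)
  summ <- integration_sets(sets)
  expect_true(all(summ$n_mRNAs >= 1))
  expect_equal(sum(summ$n_mRNAs), nrow(sets))
  dir <- withr::local_tempdir()
  write_integration_sets(sets, file.path(dir, "sets.tsv"))
  expect_true(file.exists(file.path(dir, "sets.tsv")))
  expect_true(file.exists(file.path(dir, "sets.log.tsv")))
})
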