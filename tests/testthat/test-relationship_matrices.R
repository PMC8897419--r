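# VanRaden G, Vitezica D, combined G_ad, conditioning helpers

test_that("additive G matches hand computation on one locus", {
  g <- gm(c(0L), c(2L))
  G <- build_additive_G(g)  # p = 0.5, M = (-1, 1), denom = 0.5
  expect_equal(unname(unclass(G)), matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(G, "denominator"), 0.5)
  # all-monomorphic loci: zero denominator is an error
  expect_error(build_additive_G(gm(c(0L), c(0L))), "monomorphic")
})

test_that("heterozygote-only locus at p=0.5 yields the zero matrix", {
  g3 <- gm(c(1L), c(1L))
  G3 <- build_additive_G(g3)  # centered heterozygote code is 0 at p = 0.5
  expect_equal(unname(unclass(G3)), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("duplicate individuals give identical G rows", {
  g <- random_gm(10, 30, seed = 21)
  codes <- g$codes
  codes[2, ] <- codes[1, ]
  g2 <- genotype_matrix(codes)
  G <- build_additive_G(g2)
  expect_equal(unclass(G)[1, ], unclass(G)[2, ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("dominance D matches hand computations", {
  # one locus, p = q = 0.5: H coefficients (-0.5, 0.5, -0.5), denom 0.25
  g <- gm(c(1L, 0L), c(1L, 2L))  # two heterozygotes at locus 1... build exact
  gh <- gm(c(1L), c(1L), ids = c("A", "B"))
  # p = 0.5 here; both heterozygous
  D <- build_dominance_D(gh)
  expect_equal(unname(unclass(D)), matrix(1, 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  # homozygous-everywhere vs heterozygous-everywhere: off-diagonal -1
  m <- 6
  codes <- rbind(rep(0L, m), rep(1L, m), rep(2L, m), rep(1L, m))
  gd <- genotype_matrix(codes)  # p = 0.5 each locus
  D2 <- build_dominance_D(gd)
  expect_equal(unclass(D2)[1, 2], -1, tolerance = 1e-12)
})

test_that("combined G_ad reduces to G when C_d = 1 with no flips", {
  g <- random_gm(30, 50, seed = 23)
  cod <- estimate_dominance(
    genotype_class_means(g, cp(rnorm(30), rownames(g$codes))),
    min_class_count = Inf)  # all fallback: C_d = 1, no flips
  G <- build_additive_G(g)
  Gad <- cadm_grm(g, cod)
  expect_lt(max(abs(unclass(Gad) - unclass(G))), 1e-12)
  expect_equal(attr(Gad, "denominator"), attr(G, "denominator"))
})

test_that("G_ad hand case: complete dominance separates het from low homozygote", {
  g <- gm(c(1L), c(0L))  # p = 0.25; force p = 0.5 by explicit freqs
  cod <- estimate_dominance(means_fixture(10, 20, 20))  # C_d = 2, no flip
  coded <- apply_coding(g, cod)
  Gad <- build_combined_Gad(coded, 0.5)
  expect_equal(unname(unclass(Gad)), matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  # C_d = 0 makes heterozygote and low homozygote indistinguishable
  cod0 <- estimate_dominance(means_fixture(10, 8, 20))  # C_d = 0
  g2 <- gm(c(1L), c(0L), c(2L))
  Gad0 <- cadm_grm(g2, cod0)
  expect_equal(unclass(Gad0)[1, ], unclass(Gad0)[2, ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("brute-force oracle: entries equal explicit per-locus double sums", {
  for (seed in 1:3) {
    g <- random_gm(8, 15, seed = seed)
    p <- unname(allele_frequencies(g))
    G <- build_additive_G(g)
    D <- build_dominance_D(g)
    z <- impute_missing(g)
    # scalar-by-scalar reference
    Gref <- matrix(0, 8, 8)
    Dref <- matrix(0, 8, 8)
    hcoef <- function(code, pi) {
      if (code == 0) -2 * pi^2 else if (code == 1) 2 * pi * (1 - pi)
      else -2 * (1 - pi)^2
    }
    for (i in 1:8) for (j in 1:8) {
      sg <- 0; sd <- 0
      for (l in 1:15) {
        sg <- sg + (z[i, l] - 2 * p[l]) * (z[j, l] - 2 * p[l])
        sd <- sd + hcoef(g$codes[i, l], p[l]) * hcoef(g$codes[j, l], p[l])
      }
      Gref[i, j] <- sg
      Dref[i, j] <- sd
    }
    expect_equal(unname(unclass(G)), Gref / sum(2 * p * (1 - p)),
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(unname(unclass(D)), Dref / sum((2 * p * (1 - p))^2),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("HWE sanity: mean diagonal near 1, mean off-diagonal near 0", {
  g <- random_gm(500, 2000, seed = 29, maf = c(0.05, 0.5))
  G <- build_additive_G(g)
  v <- unclass(G)
  expect_gt(mean(diag(v)), 0.9); expect_lt(mean(diag(v)), 1.1)
  off <- mean(v[upper.tri(v)])
  expect_gt(off, -0.05); expect_lt(off, 0.05)
  # with weights concentrated near 1 (the additive regime the invariant
  # conditions on) G_ad obeys the same bounds; constructed coding, since a
  # per-locus estimate from a polygenic trait is individually noisy
  set.seed(29)
  cod <- structure(data.frame(locus = colnames(g$codes),
                              raw_d = NA_real_,
                              C_d = runif(2000, 0.95, 1.05),
                              flip = sample(c(TRUE, FALSE), 2000, TRUE),
                              fallback = FALSE),
                   class = c("dominance_coding", "data.frame"))
  Gad <- unclass(cadm_grm(g, cod))
  expect_gt(mean(diag(Gad)), 0.9); expect_lt(mean(diag(Gad)), 1.1)
  offad <- mean(Gad[upper.tri(Gad)])
  expect_gt(offad, -0.05); expect_lt(offad, 0.05)
})

test_that("column centering: M columns have mean ~ 0; H under exact HWE", {
  g <- random_gm(50, 20, seed = 31)
  p <- allele_frequencies(g)
  M <- sweep(impute_missing(g), 2, 2 * as.numeric(p))
  expect_lt(max(abs(colMeans(M))), 1e-10)
  # exact HWE class proportions at p = 0.5: 1:2:1
  gh <- genotype_matrix(cbind(c(0L, 1L, 1L, 2L)))
  ph <- 0.5; qh <- 0.5
  h <- c(-2 * ph^2, 2 * ph * qh, 2 * ph * qh, -2 * qh^2)
  expect_equal(mean(h), 0, tolerance = 1e-12)
})

test_that("paper-literal centering is exposed and differs when p != 0.5", {
  g <- random_gm(20, 10, seed = 37, maf = c(0.05, 0.3))
  G1 <- build_additive_G(g)
  G2 <- build_additive_G(g, centering = "paper_literal")
  expect_gt(max(abs(unclass(G1) - unclass(G2))), 1e-6)
})

test_that("ensure_invertible ridges singular matrices minimally", {
  # well-conditioned simulated G: no ridge needed
  g <- random_gm(50, 500, seed = 41)
  G <- build_additive_G(g)
  expect_equal(attr(ensure_invertible(G), "ridge_added"), 0)
  # duplicated individuals: exactly singular, ridge > 0
  codes <- g$codes; codes[2, ] <- codes[1, ]
  Gs <- build_additive_G(genotype_matrix(codes))
  expect_gt(attr(ensure_invertible(Gs), "ridge_added"), 0)
  # identity passes through untouched
  I5 <- ensure_invertible(diag(5))
  expect_equal(attr(I5, "ridge_added"), 0)
  expect_equal(unname(unclass(I5)), diag(5), ignore_attr = TRUE)
  # hopeless matrix errors out
  expect_error(ensure_invertible(matrix(-1, 3, 3) + diag(0, 3), 1e-8, 1e-4),
               "ridge")
})

test_that("grm text serialization round-trips the lower triangle", {
  g <- random_gm(6, 20, seed = 43)
  G <- build_additive_G(g)
  path <- withr::local_tempfile(fileext = ".txt")
  write_grm(G, path)
  lines <- readLines(path)
  expect_equal(strsplit(lines[1], "\t")[[1]], rownames(G))
  row3 <- as.numeric(strsplit(lines[4], "\t")[[1]])
  expect_equal(row3, unname(unclass(G)[3, 1:3]), tolerance = 1e-12)
})
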