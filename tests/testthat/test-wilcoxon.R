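# Independent brute-force enumerator: materializes all 2^n sign vectors.
# Deliberately different from the generating-function implementation.
enumerate_wilcoxon <- function(d, alternative) {
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  p_le <- mean(v_all <= v_obs + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

test_that("the minimum attainable p at n = 4 is 1/16 one-sided", {
  expect_equal(wilcoxon_exact(c(1, 2, 3, 4))$p.value, 0.0625)
  expect_equal(wilcoxon_exact(-c(1, 2, 3, 4), "less")$p.value, 0.0625)
  expect_equal(wilcoxon_exact(c(1, 2, 3, 4), "two.sided")$p.value, 0.125)
  expect_equal(wilcoxon_exact(rep(1, 6))$p.value, 1 / 64)
})

test_that("exact p-values match brute-force enumeration for n <= 10", {
  set.seed(11)
  for (rep_i in 1:40) {
    n <- sample(2:10, 1)
    d <- round(rnorm(n), 2)
    d <- d[d != 0]
    if (length(d) < 2) next
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(wilcoxon_exact(d, alt)$p.value,
                   enumerate_wilcoxon(d, alt),
                   tolerance = 1e-12,
                   info = paste(alt, paste(d, collapse = ",")))
    }
  }
})

test_that("exact p-values agree with the reference implementation", {
  set.seed(12)
  for (rep_i in 1:25) {
    n <- sample(3:12, 1)
    d <- signif(rnorm(n), 3)
    d <- d[d != 0 & !duplicated(abs(d))]   # wilcox.test exact needs no ties
    if (length(d) < 3) next
    expect_equal(wilcoxon_exact(d, "two.sided")$p.value,
                 suppressWarnings(
                   stats::wilcox.test(d, exact = TRUE)$p.value),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_exact(d, "greater")$p.value,
                 suppressWarnings(
                   stats::wilcox.test(d, exact = TRUE,
                                      alternative = "greater")$p.value),
                 tolerance = 1e-12)
  }
})

test_that("p-values always lie in (0, 1] and zeros are handled", {
  set.seed(13)
  for (rep_i in 1:20) {
    d <- rnorm(sample(1:8, 1))
    p <- wilcoxon_exact(d, "two.sided")$p.value
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
  expect_warning(wilcoxon_exact(c(0, 1, 2)), "zero difference")
  expect_error(wilcoxon_exact(c(0, 0)), "all differences are zero")
  expect_error(suppressWarnings(wilcoxon_exact(numeric(0))), "no finite")
})

test_that("tied absolute differences use average ranks", {
  d <- c(1, 1, -1, 2)
  expect_equal(wilcoxon_exact(d, "greater")$p.value,
               enumerate_wilcoxon(d, "greater"), tolerance = 1e-12)
})
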