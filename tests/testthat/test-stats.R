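test_that("ART ANOVA detects a pure group shift and nothing else", {
  set.seed(13)
  ps <- replicate(10, {
    d <- factorial_data(15, group_shift = -2)
    a <- art_anova_two_way(d, "y")
    a$p
  })
  # population effect overwhelming; age and interaction behave as nulls
  expect_lt(median(ps[1, ]), 1e-3)
  expect_gte(mean(ps[2, ] > 0.05), 0.7)
  expect_gte(mean(ps[3, ] > 0.05), 0.7)
})

test_that("ART statistics are invariant to positive affine response transforms", {
  # the alignment step works on cell means, so only order-and-spacing
  # preserving (affine) transforms leave the aligned ranks unchanged;
  # nonlinear monotone maps alter the alignment by construction
  set.seed(14)
  d <- factorial_data(8, group_shift = -1)
  a1 <- art_anova_two_way(d, "y")
  d$y <- 3.7 * d$y + 12
  a2 <- art_anova_two_way(d, "y")
  expect_equal(a1$F, a2$F, tolerance = 1e-9)
  expect_equal(a1$partial_eta2, a2$partial_eta2, tolerance = 1e-9)
})

test_that("with one age level ART collapses to the rank one-way ANOVA", {
  set.seed(15)
  d <- factorial_data(12, group_shift = -1)
  d <- d[d$age_band == "a", ]
  a <- art_anova_two_way(d, "y")
  expect_equal(nrow(a), 1)
  oracle <- anova(lm(rank(y) ~ group, data = d))
  expect_equal(a$F, oracle["group", "F value"], tolerance = 0.05 * a$F)
})

test_that("empty design cells are a design error", {
  d <- factorial_data(5)
  d <- d[!(d$group == "ASD" & d$age_band == "b"), ]
  expect_error(art_anova_two_way(d, "y"), "empty cell")
})

test_that("ART-C contrasts separate disjoint groups and count pairs", {
  d <- factorial_data(10)
  d$y <- ifelse(d$group == "ASD", d$y, d$y + 50)
  ph <- artc_posthoc(d, "y", "group", "age_band")
  expect_equal(nrow(ph), 1)
  expect_equal(ph$contrast, "ASD - TD")
  expect_lt(ph$p_adjusted, 1e-3)
  expect_lt(ph$cohens_d, 0)
  # three age levels -> three contrasts
  ph2 <- artc_posthoc(d, "y", "age_band", "group")
  expect_equal(nrow(ph2), 3)
  expect_true(all(ph2$p_adjusted <= 1))
})

test_that("ART-C familywise error stays controlled under the null", {
  set.seed(16)
  fw <- vapply(1:300, function(i) {
    d <- factorial_data(8)
    ph <- artc_posthoc(d, "y", "age_band", "group")
    any(ph$p_adjusted < 0.05)
  }, logical(1))
  # Bonferroni bound 5% plus three MC standard errors
  expect_lte(mean(fw), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("Cohen's d matches hand-computed cases", {
  expect_equal(cohens_d(1:3, 4:6), -3)
  expect_equal(cohens_d(c(0, 2), c(-1, 1)), abs(cohens_d(c(-1, 1), c(0, 2))))
  set.seed(17)
  a <- rnorm(50, 1, 1); b <- rnorm(50, 0, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "degenerate")
})

test_that("Spearman screen matches hand ranks and keeps NA rules", {
  ft <- data.frame(participant_id = paste0("P", 1:5),
                   trt_s = c(1, 2, 3, 4, 5), roa_deg = 5:1,
                   symmetry = c(1, 3, 2, 5, 4))
  sc <- data.frame(id = paste0("P", 1:5), s1 = 1:5,
                   s2 = c(NA, NA, 1, 2, NA))
  m <- spearman_matrix(ft, sc)
  expect_equal(m$rho["trt_s", "s1"], 1)
  expect_equal(m$rho["roa_deg", "s1"], -1)
  expect_equal(m$rho["symmetry", "s1"], 0.8)
  expect_true(is.na(m$rho["trt_s", "s2"]))   # < 4 complete pairs
  expect_equal(m$n["trt_s", "s2"], 2)
})

test_that("chi-square matches hand computation and is permutation invariant", {
  r <- chi_square_independence(rbind(c(10, 20), c(20, 10)))
  expect_equal(r$chi2, 20 / 3, tolerance = 1e-9)
  expect_equal(r$df, 1)
  prop <- rbind(c(10, 20), c(20, 40))
  expect_equal(chi_square_independence(prop)$chi2, 0, tolerance = 1e-12)
  tab <- rbind(c(15, 19), c(15, 20), c(19, 20))
  r1 <- chi_square_independence(tab)
  r2 <- chi_square_independence(tab[c(3, 1, 2), c(2, 1)])
  expect_equal(r1$chi2, r2$chi2, tolerance = 1e-12)
  expect_error(chi_square_independence(rbind(c(0, 0), c(3, 4))), "margin")
})
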