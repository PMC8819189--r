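test_that("frustum volume matches closed forms and limits", {
  # equal diameters: cylinder pi r^2 h
  expect_equal(frustum_volume(10, 10, 5), pi * 5 * 0.25)
  # mixed diameters: direct formula
  expect_equal(frustum_volume(10, 6, 5), pi * 5 / 3 * (0.25 + 0.15 + 0.09))
  # vanishing lower diameter approaches the cone pi r^2 h / 3
  expect_equal(frustum_volume(10, 1e-9, 5), pi * 0.25 * 5 / 3,
               tolerance = 1e-6)
  expect_equal(frustum_volume(4, 7), frustum_volume(7, 4))
  expect_true(frustum_volume(10, 6) < frustum_volume(10, 6.5))
  expect_error(frustum_volume(0, 5), "positive")
})

test_that("pool statistics flag the designed phenotype contrasts", {
  phen <- simulate_phenotypes(seed = 101)
  st <- pool_stats(phen)
  tt <- st$tests
  get_p <- function(v, p1, p2)
    tt$p[tt$variable == v & tt$pool1 == p1 & tt$pool2 == p2]
  expect_lt(get_p("volume_cm3", "A", "B"), 0.001)
  expect_lt(get_p("volume_cm3", "A", "C"), 0.001)
  expect_lt(get_p("length_cm", "A", "B"), 0.001)
  expect_lt(get_p("length_cm", "B", "C"), 0.001)
  # similar pools do not separate: B vs C volume
  expect_gt(get_p("volume_cm3", "B", "C"), 0.05)
  expect_true(all(st$normality$n >= 21 & st$normality$n <= 36))

  # identical pools: t = 0, p = 1
  same <- data.frame(pool = rep(c("A", "B", "C"), each = 4),
                     length_cm = rep(c(10, 11, 12, 13), 3),
                     volume_cm3 = rep(c(1, 2, 3, 4), 3))
  st2 <- pool_stats(same)
  expect_true(all(st2$tests$p == 1))
  expect_true(all(abs(st2$tests$t) < 1e-12))
  expect_error(pool_stats(data.frame(pool = c("A", "A", "A", "B", "B", "C"),
                                     length_cm = 1:6, volume_cm3 = 1:6)),
               "at least 3")
})

test_that("significance stars map the usual thresholds", {
  expect_identical(macetrait:::.p_stars(c(0.2, 0.04, 0.004, 0.0004)),
                   c("n.s.", "*", "**", "***"))
})

test_that("primer efficiency recovers the standard-curve slope exactly", {
  # perfect doubling: slope -1/log10(2), 100% efficiency
  ld <- c(0, -1, -2, -3)
  eff <- primer_efficiency(ld, 20 - ld / log10(2))
  expect_equal(eff$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(eff$amplification_base, 2, tolerance = 1e-9)
  expect_equal(eff$percent_efficiency, 100, tolerance = 1e-6)

  eff <- primer_efficiency(ld, 22 - 3.6 * ld)
  expect_equal(eff$slope, -3.6, tolerance = 1e-9)
  expect_equal(eff$amplification_base, 10^(1 / 3.6), tolerance = 1e-9)
  expect_equal(eff$percent_efficiency, (10^(1 / 3.6) - 1) * 100,
               tolerance = 1e-6)
  expect_error(primer_efficiency(c(0, 0, 0), c(1, 2, 3)), "constant")
  expect_error(primer_efficiency(c(0, -1), c(1, 2)), "at least 3")
})

test_that("normalization is an efficiency-corrected calibrated ratio", {
  effs <- data.frame(assay = c("tg", "ref1", "ref2"),
                     amplification_base = c(2, 2, 2))
  cq <- rbind(
    data.frame(plant_id = c("p1", "p2", "p3"), assay = "tg",
               Cq = c(25, 24, 25)),
    data.frame(plant_id = c("p1", "p2", "p3"), assay = "ref1",
               Cq = c(20, 20, 20)),
    data.frame(plant_id = c("p1", "p2", "p3"), assay = "ref2",
               Cq = c(18, 18, 18)))
  ne <- qpcr_normalize(cq, effs, "tg", c("ref1", "ref2"), calibrator = "p1")
  expect_equal(ne$normalized_expression[ne$plant_id == "p1"], 1)
  # one cycle below calibrator at perfect efficiency = 2-fold
  expect_equal(ne$normalized_expression[ne$plant_id == "p2"], 2)
  expect_equal(ne$normalized_expression[ne$plant_id == "p3"], 1)
  # default calibrator (median target Cq) only rescales
  ne2 <- qpcr_normalize(cq, effs, "tg", c("ref1", "ref2"))
  expect_equal(ne2$normalized_expression / ne$normalized_expression,
               rep(1, 3))
  expect_error(qpcr_normalize(cq[cq$plant_id != "p3" | cq$assay != "ref1", ],
                              effs, "tg", c("ref1", "ref2")), "lacks Cq")
})

test_that("Grubbs removal drops a gross outlier and stops at clean data", {
  x <- c(8.0, 8.1, 7.9, 8.2, 25.0)
  # independent computation: G = 1.789 exceeds G_crit(5, 0.05) = 1.715
  g_obs <- max(abs(x - mean(x))) / sd(x)
  tq <- qt(1 - 0.05 / 10, 3)
  g_crit <- (4 / sqrt(5)) * sqrt(tq^2 / (3 + tq^2))
  expect_gt(g_obs, g_crit)
  out <- grubbs_remove(x)
  expect_equal(out$removed, 25.0)
  expect_equal(out$values, c(8.0, 8.1, 7.9, 8.2))

  expect_equal(grubbs_remove(rep(1, 5))$values, rep(1, 5))
  sym <- c(1, 2, 3, 4, 5, 6, 7)
  expect_length(grubbs_remove(sym)$removed, 0)
  # never below n = 3
  wild <- c(0, 1000, -1000, 5e5, -7e5)
  expect_gte(length(grubbs_remove(wild)$values), 3)
  expect_error(grubbs_remove(c(1, 2)), "at least 3")
})

test_that("correlation pipeline recovers exact and null relationships", {
  x <- seq(1, 5, length.out = 20)
  rep1 <- correlate(x, 2 * x)
  expect_equal(rep1$r, 1)
  expect_equal(rep1$r_squared, 1)
  expect_equal(rep1$slope, 2)

  # affine invariance: R unchanged, sign flips with negative scale
  set.seed(40)
  y <- x + rnorm(20, 0, 0.5)
  r0 <- correlate(x, y)$r
  expect_equal(correlate(10 * x - 3, y)$r, r0)
  expect_equal(correlate(-2 * x, y)$r, -r0)

  # independent variables rarely fake a strong correlation at n = 35
  hits <- 0
  for (s in 1:200) {
    set.seed(s)
    r <- cor(rnorm(35), rnorm(35))  # oracle for the base rate
    if (abs(r) < 0.5) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
  set.seed(77)
  rep2 <- correlate(rnorm(35), rnorm(35))
  expect_lt(abs(rep2$r), 0.5)
})

test_that("noise-free qPCR simulation closes the loop at R = 1", {
  phen <- simulate_phenotypes(n_per_pool = 12, seed = 3)
  targets <- data.frame(gene = "cand1", relation = "positive",
                        against = "volume_cm3")
  qp <- simulate_qpcr(phen, targets, noise_sd = 0, seed = 4)
  ne <- qpcr_normalize(qp$cq, qp$efficiencies, "cand1")
  v <- phen$volume_cm3[match(ne$plant_id, phen$plant_id)]
  rep <- correlate(v, ne$normalized_expression)
  expect_equal(rep$r, 1, tolerance = 1e-9)

  qp_neg <- simulate_qpcr(phen, data.frame(gene = "cand2",
                                           relation = "negative",
                                           against = "volume_cm3"),
                          noise_sd = 0, seed = 4)
  ne <- qpcr_normalize(qp_neg$cq, qp_neg$efficiencies, "cand2")
  rep <- correlate(phen$volume_cm3[match(ne$plant_id, phen$plant_id)],
                   ne$normalized_expression)
  expect_equal(rep$r, -1, tolerance = 1e-6)
})

test_that("expression-phenotype sign is recovered at default noise", {
  phen <- simulate_phenotypes(n_per_pool = 12, seed = 9)
  targets <- data.frame(gene = "cand1", relation = "positive",
                        against = "length_cm")
  ok <- 0
  for (s in 1:60) {
    qp <- simulate_qpcr(phen, targets, seed = s)
    ne <- qpcr_normalize(qp$cq, qp$efficiencies, "cand1")
    v <- phen$length_cm[match(ne$plant_id, phen$plant_id)]
    if (correlate(v, ne$normalized_expression)$r > 0) ok <- ok + 1
  }
  expect_equal(ok, 60)
})
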