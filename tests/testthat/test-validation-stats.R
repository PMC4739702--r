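test_that("one-way ANOVA matches hand-computed decomposition", {
  # groups {1,2,3} and {2,3,4}: SSb = 1.5, SSw = 4, F = 1.5
  a <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(a$F, 1.5)
  expect_equal(a$ms_between, 1.5)
  expect_equal(a$ms_within, 1.0)
  expect_identical(c(a$df_between, a$df_within), c(1L, 4L))
  expect_equal(a$F, a$ms_between / a$ms_within, tolerance = 1e-9)
  # identical group means: F = 0
  z <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(z$F, 0)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "at least 2 observations")
  expect_error(one_way_anova(1:4, rep("a", 4)), "at least 2 groups")
})

test_that("ANOVA sums of squares are additive on random data", {
  set.seed(99)
  for (k in 1:10) {
    v <- stats::rnorm(30)
    g <- sample(letters[1:3], 30, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    if (min(table(g)) < 2) next
    a <- one_way_anova(v, g)
    sst <- sum((v - mean(v))^2)
    expect_equal(a$ms_between * a$df_between + a$ms_within * a$df_within,
                 sst, tolerance = 1e-9 * max(1, sst))
  }
})

test_that("Tukey HSD agrees with a direct Tukey-Kramer computation", {
  # identical groups: zero difference, p = 1
  tk <- tukey_hsd(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(tk$diff, 0)
  expect_equal(tk$p_adj, 1, tolerance = 1e-9)

  # unbalanced three-group data against the studentized-range formula
  set.seed(7)
  v <- c(stats::rnorm(5, 0), stats::rnorm(8, 1.2), stats::rnorm(6, 2.5))
  g <- rep(c("a", "b", "c"), c(5, 8, 6))
  res <- tukey_hsd(v, g)
  a <- one_way_anova(v, g)
  means <- tapply(v, g, mean)
  ns <- table(g)
  for (i in seq_len(nrow(res))) {
    g1 <- res$group1[i]; g2 <- res$group2[i]
    d <- abs(means[[g1]] - means[[g2]])
    se <- sqrt(a$ms_within / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    p <- stats::ptukey(d / se, nmeans = 3, df = a$df_within, lower.tail = FALSE)
    expect_equal(res$diff[i], d, tolerance = 1e-6)
    expect_equal(res$p_adj[i], p, tolerance = 1e-3)
  }
  expect_true(all(res$p_adj >= 0 & res$p_adj <= 1))
})

test_that("Tukey p values fall as group separation grows", {
  set.seed(11)
  base <- stats::rnorm(10)
  ps <- vapply(c(0.5, 1.5, 3), function(shift) {
    tukey_hsd(c(base, base + shift), rep(c("a", "b"), each = 10))$p_adj
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("linear fit recovers exact lines and rejects constant x", {
  f <- suppressWarnings(linear_fit(1:10, 2 * (1:10) + 1))  # perfect fit warns
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  expect_error(linear_fit(rep(1, 5), stats::rnorm(5)), "zero variance")
})

test_that("synthetic specimen table is moment-matched to the published sample", {
  tab <- synthetic_specimen_table()
  expect_identical(nrow(tab), 36L)
  counts <- table(tab$species)
  expect_identical(as.integer(counts[c("Cercocebus atys", "Cercopithecus mitis",
                                       "Colobus guereza", "Theropithecus gelada")]),
                   c(7L, 10L, 10L, 9L))
  expect_equal(tab$delta_opcr, tab$td_opcr - tab$dem_opcr)
  mom <- dentaltopo:::species_opcr_moments()
  for (i in seq_len(nrow(mom))) {
    sub <- tab[tab$species == mom$species[i], ]
    expect_equal(mean(sub$td_opcr), mom$td_mean[i], tolerance = 0.01)
    expect_equal(stats::sd(sub$td_opcr), mom$td_sd[i], tolerance = 0.01)
    expect_equal(mean(sub$dem_opcr), mom$dem_mean[i], tolerance = 0.01)
    expect_equal(stats::sd(sub$dem_opcr), mom$dem_sd[i], tolerance = 0.01)
    expect_equal(stats::sd(sub$delta_opcr), mom$delta_sd[i], tolerance = 0.01)
  }
  # deterministic
  expect_identical(tab, synthetic_specimen_table())
})

test_that("specimen tables round-trip through the TSV loader", {
  tab <- synthetic_specimen_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- data.frame(specimen = tab$specimen, species = tab$species,
                    DEM_OPCR = tab$dem_opcr, OPCR3D = tab$td_opcr,
                    delta = 0)  # a stale difference column must be ignored
  utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- load_specimen_table(f)
  expect_equal(back$td_opcr, tab$td_opcr, tolerance = 1e-9)
  expect_equal(back$delta_opcr, tab$delta_opcr, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(out[, 1:3], bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_specimen_table(bad), "missing column")
})

test_that("treatment validation reproduces the published comparison", {
  v <- validate_opcr_treatments()
  # mesh OPCR differs between species; grid OPCR does not
  expect_equal(v$anova_td$F, 5.486, tolerance = 0.01 * 5.486)
  expect_equal(v$anova_td$ms_between, 533.285, tolerance = 0.005 * 533.285)
  expect_equal(v$anova_td$ms_within, 97.202, tolerance = 0.005 * 97.202)
  expect_lt(v$anova_td$p, 0.05)
  expect_equal(v$anova_dem$F, 0.819, tolerance = 0.01)
  expect_gt(v$anova_dem$p, 0.05)
  # treatment difference varies by species
  expect_equal(v$anova_delta$F, 9.440, tolerance = 0.01 * 9.440)

  # exactly two significant pairs, both involving Theropithecus gelada
  sig <- v$tukey_td[v$tukey_td$significant, ]
  expect_identical(nrow(sig), 2L)
  pair_of <- function(row) sort(c(row$group1, row$group2))
  pairs <- apply(sig, 1, function(r) paste(sort(c(r[["group1"]], r[["group2"]])),
                                           collapse = " / "))
  expect_setequal(pairs, c("Cercopithecus mitis / Theropithecus gelada",
                           "Colobus guereza / Theropithecus gelada"))
  gm <- sig[grepl("mitis", paste(sig$group1, sig$group2)), ]
  gg <- sig[grepl("guereza", paste(sig$group1, sig$group2)), ]
  expect_equal(gm$diff, 16.597, tolerance = 0.011)
  expect_lt(abs(gm$p_adj - 0.005), 0.002)   # published p to within +/-0.002
  expect_equal(gg$diff, 15.435, tolerance = 0.011)
  expect_lt(abs(gg$p_adj - 0.009), 0.002)

  # regressions of the treatment difference
  expect_equal(v$fit_delta_on_td$slope, 0.736, tolerance = 0.002)
  expect_equal(v$fit_delta_on_td$intercept, -35.972, tolerance = 0.05)
  expect_equal(v$fit_delta_on_td$r_squared, 0.864, tolerance = 0.002)
  expect_lt(v$fit_delta_on_td$p, 0.001)
  expect_equal(v$fit_delta_on_dem$slope, 0.703, tolerance = 0.005)
  expect_equal(v$fit_delta_on_dem$r_squared, 0.122, tolerance = 0.002)
})
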