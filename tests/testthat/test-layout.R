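test_that("group ranking reproduces the published group-lasso ordering", {
  pc <- published_group_coefs()
  s <- summarize_groups(pc$beta, pc$group, sort_type = "max")
  expect_identical(s$table$group, c("CD3D", "HLA-DPB1", "TRDC"))
  expect_equal(s$table$feature, c(0.225, 0.038, 0.037))
  expect_identical(as.integer(s$table$size), c(1L, 2L, 1L))
})

test_that("ranking sorts by feature with lexicographic tie-break and
           drops all-zero groups", {
  b <- c(a1 = 0.9, b1 = 0.5, c1 = 0, c2 = 0, d1 = 0.5)
  g <- c("A", "B", "C", "C", "D")
  s <- summarize_groups(b, g)
  expect_identical(s$table$group, c("A", "B", "D"))  # C absent, B before D
  expect_false("C" %in% s$members$group)
  expect_error(summarize_groups(c(x = 0, y = 0), c("a", "b")),
               "all coefficients are zero")
})

test_that("mean and max sort types compute different features", {
  b <- c(p1 = 1.0, p2 = 0.2, q1 = 0.7)
  g <- c("P", "P", "Q")
  smax <- summarize_groups(b, g, "max")
  smean <- summarize_groups(b, g, "mean")
  expect_identical(smax$table$group[1], "P")   # max 1.0 beats 0.7
  expect_identical(smean$table$group[1], "Q")  # mean 0.6 loses to 0.7
  expect_equal(smean$table$feature[smean$table$group == "P"], 0.6)
})

test_that("max_shown truncates the weakest groups", {
  b <- stats::setNames(seq(1, 0.02, length.out = 50), paste0("v", 1:50))
  s <- summarize_groups(b, paste0("G", 1:50))
  expect_identical(nrow(suppressMessages(apply_max_shown(s, 30))$table), 30L)
  expect_identical(nrow(suppressMessages(apply_max_shown(s, 60))$table), 50L)
  expect_identical(nrow(apply_max_shown(s, NULL)$table), 50L)
  expect_message(apply_max_shown(s, 30), "20 hidden")
  expect_error(apply_max_shown(s, 0), "positive")
})

test_that("sectors partition the circle with rank 1 at zero degrees", {
  b <- stats::setNames(runif(16, 0.1, 1), paste0("v", 1:16))
  g <- rep(paste0("G", 1:8), each = 2)
  lay <- compute_layout(summarize_groups(b, g), jitter_seed = 1)
  s <- lay$sectors
  expect_identical(nrow(s), 8L)
  expect_equal(s$end_deg - s$start_deg, rep(45, 8))
  expect_equal(s$start_deg[1], 0)
  expect_equal(sum(s$end_deg - s$start_deg), 360)
  expect_equal(s$start_deg[-1], s$end_deg[-8])  # disjoint, contiguous
  expect_equal(max(s$radius), 1)
  expect_true(all(diff(s$radius) <= 0))         # nonincreasing with rank
})

test_that("sector radii are proportional to the ranking feature", {
  b <- c(x1 = 1.0, y1 = 0.5)
  lay <- compute_layout(summarize_groups(b, c("X", "Y")))
  expect_equal(lay$sectors$radius, c(1.0, 0.5))
})

test_that("inner points sit inside their sector at relative magnitude radius", {
  pc <- published_group_coefs()
  lay <- compute_layout(summarize_groups(pc$beta, pc$group), jitter_seed = 3)
  pts <- lay$points
  s <- lay$sectors
  for (i in seq_len(nrow(pts))) {
    sec <- s[s$group == pts$group[i], ]
    expect_gt(pts$angle_deg[i], sec$start_deg)
    expect_lt(pts$angle_deg[i], sec$end_deg)
  }
  expect_true(all(pts$rel_radius > 0 & pts$rel_radius <= 1))
  # the 0.036 member of HLA-DPB1 scales against the group max 0.038
  expect_equal(pts$rel_radius[pts$variable == "HLA-DPB1.2"], 0.036 / 0.038)
  # one point per group attains radius 1 under sort_type max
  for (g in s$group)
    expect_identical(sum(pts$rel_radius[pts$group == g] == 1), 1L)
  # a constructed single-group pair: 0.037 against max 0.038
  lay2 <- compute_layout(summarize_groups(
    c(m1 = 0.038, m2 = 0.037), c("H", "H")))
  expect_equal(sort(lay2$points$rel_radius), c(0.037 / 0.038, 1))
})

test_that("point symbols record the coefficient sign", {
  pc <- published_group_coefs()
  lay <- compute_layout(summarize_groups(pc$beta, pc$group))
  expect_identical(lay$points$symbol[lay$points$variable == "CD3D"],
                   "negative")
  expect_identical(lay$points$symbol[lay$points$variable == "TRDC"],
                   "positive")
  expect_true(all((lay$points$coefficient < 0) ==
                    (lay$points$symbol == "negative")))
  expect_match(lay$points$tooltip[lay$points$variable == "CD3D"],
               "CD3D / CD3D / -0.2250")
})

test_that("layout is deterministic in the jitter seed", {
  b <- stats::setNames(rnorm(12), paste0("v", 1:12))
  b[b == 0] <- 0.1
  g <- rep(paste0("G", 1:4), each = 3)
  l1 <- compute_layout(summarize_groups(b, g), jitter_seed = 42)
  l2 <- compute_layout(summarize_groups(b, g), jitter_seed = 42)
  expect_identical(l1, l2)
  l3 <- compute_layout(summarize_groups(b, g), jitter_seed = 43)
  expect_false(identical(l1$points$angle_deg, l3$points$angle_deg))
})

test_that("styles map larger groups to darker colors over displayed groups", {
  b <- c(a = 1, b1 = 0.9, b2 = 0.8, c1 = 0.7, c2 = 0.6, c3 = 0.5,
         c4 = 0.4, c5 = 0.3)
  g <- c("A", "B", "B", "C", "C", "C", "C", "C")
  lay <- assign_styles(compute_layout(summarize_groups(b, g)))
  s <- lay$sectors[order(lay$sectors$size), ]
  expect_true(all(diff(s$color_value) > 0))  # sizes 1, 2, 5 darken
  lum <- function(col) colMeans(grDevices::col2rgb(col))
  expect_true(all(diff(lum(s$color)) < 0))   # brightness decreasing in size
  # equal sizes share one color
  lay2 <- assign_styles(compute_layout(summarize_groups(
    c(x = 1, y = 0.5), c("X", "Y"))))
  expect_identical(unique(lay2$sectors$color_value), 0.5)
})

test_that("lasso mode gives one single-point sector per selected variable", {
  pl <- published_lasso_coefs()
  lay <- lasso_layout(pl)
  expect_identical(nrow(lay$sectors), 3L)
  expect_equal(lay$sectors$end_deg - lay$sectors$start_deg, rep(120, 3))
  expect_identical(lay$sectors$group, c("CD3D", "TNNI3", "ACAP1"))
  expect_equal(lay$sectors$radius, c(1, 0.107 / 0.121, 0.097 / 0.121))
  expect_true(all(lay$points$rel_radius == 1))
  expect_identical(nrow(lay$points), 3L)
  expect_true(lay$lasso_mode)

  one <- lasso_layout(c(only = 0.5))
  expect_identical(nrow(one$sectors), 1L)
  expect_equal(one$sectors$end_deg - one$sectors$start_deg, 360)
  expect_equal(one$sectors$radius, 1)

  many <- stats::setNames(runif(40, 0.1, 1), paste0("w", 1:40))
  expect_identical(nrow(suppressMessages(
    lasso_layout(many, max_shown = 30))$sectors), 30L)
  expect_error(lasso_layout(c(a = 0, b = 0)), "all coefficients are zero")
})

test_that("chart_layout dispatches on coefficient tables and CV results", {
  pc <- published_group_coefs()
  tab <- data.frame(variable = names(pc$beta), group = pc$group,
                    coefficient = unname(pc$beta))
  lay <- chart_layout(tab)
  expect_identical(lay$sectors$group[1], "CD3D")
  expect_false(lay$lasso_mode)
  # a table whose groups are the variables themselves -> lasso mode
  tl <- data.frame(variable = names(published_lasso_coefs()),
                   group = names(published_lasso_coefs()),
                   coefficient = unname(published_lasso_coefs()))
  expect_true(chart_layout(tl)$lasso_mode)

  sim <- generate_dataset(sim_config(n = 80, n_groups = 5, group_size = 3,
                                     n_active = 2, seed = 4))
  cv <- cv_pl_fit(sim$data, group = sim$groups, method = "grouplasso",
                  k = 5, seed = 1, nlambda = 30)
  lay_min <- chart_layout(cv, lambda_type = "min")
  expect_equal(lay_min$lambda_used, cv$lambda.min)
  lay_1se <- chart_layout(cv, lambda_type = "1se")
  expect_lte(nrow(lay_1se$points), nrow(lay_min$points))
})
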