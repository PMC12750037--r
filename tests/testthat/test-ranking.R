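test_that("two-round z-scores reproduce the worked cases", {
  # {10, 20, 30}: population sd 8.165, no outliers
  z <- two_round_z(c(A = 10, B = 20, C = 30))
  expect_equal(z$z, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_false(any(z$imputed_missing))

  # {0, 90 x 5}: the 0 is a round-1 outlier (z = -2.236); round-2 sd is 0
  # so the five members get z = 0 and the outlier floors to -2
  z2 <- two_round_z(setNames(c(0, rep(90, 5)), LETTERS[1:6]))
  expect_equal(z2$z, c(-2, 0, 0, 0, 0, 0))
  expect_true(z2$excluded_round1[1])
  expect_false(any(z2$excluded_round1[-1]))

  # a group with no submission gets -2 with the imputed_missing flag
  z3 <- two_round_z(c(A = 10, B = 20, C = 30), groups = c("A", "B", "C", "D"))
  expect_equal(z3$z[z3$group == "D"], -2)
  expect_true(z3$imputed_missing[z3$group == "D"])

  # lower-is-better metrics are negated before standardization
  z4 <- two_round_z(c(A = 1.2, B = 3.5), orientation = "lower_better")
  expect_gt(z4$z[z4$group == "A"], z4$z[z4$group == "B"])

  expect_warning(z5 <- two_round_z(c(A = 50)), "fewer than 2")
  expect_equal(z5$z, 0)
})

test_that("final z-scores never drop below the floor", {
  set.seed(99)
  for (rep in 1:20) {
    v <- setNames(rnorm(12, 50, 20), paste0("G", 1:12))
    v[sample(12, 2)] <- NA
    z <- two_round_z(v, groups = paste0("G", 1:12))
    expect_true(all(z$z >= -2))
  }
})

test_that("composite weights follow the printed scheme and sum to 1", {
  w <- default_weight_scheme()
  expect_equal(sum(w$weight), 1, tolerance = 1e-15)
  expect_equal(w$weight[w$metric == "gdt_ha"], 1 / 6)
  expect_equal(w$weight[w$metric == "sphgr"], 1 / 8)
  expect_equal(w$weight[w$metric == "molprobity"], 1 / 16)
  expect_equal(w$orientation[w$metric == "molprobity"], "lower_better")

  z0 <- setNames(rep(0, 9), w$metric)
  expect_equal(composite_z(z0, w), 0)
  z1 <- setNames(rep(1, 9), w$metric)
  expect_equal(composite_z(z1, w), 1)
  zg <- z0; zg["gdt_ha"] <- 1
  expect_equal(composite_z(zg, w), 1 / 6)
  expect_error(composite_z(z1[-1], w), "missing")
})

test_that("unscored metrics impute to the worst observed value per EU", {
  t <- toy_score_table(groups = c("A", "B", "C"), models = 1,
                       metrics = c("gdt_ha", "molprobity"),
                       value_fun = function(g, e, m, met) {
                         if (met == "gdt_ha") c(A = 80, B = 90, C = NA)[g]
                         else c(A = 1.2, B = 3.5, C = NA)[g]
                       })
  out <- impute_unscored(t)
  expect_equal(out$value[out$group == "C" & out$metric == "gdt_ha"], 80)
  expect_equal(out$value[out$group == "C" & out$metric == "molprobity"], 3.5)

  complete <- toy_score_table()
  expect_identical(impute_unscored(complete), complete)
})

test_that("model selection applies first / best / model6 rules", {
  sch <- single_metric_scheme("gdt_ha")
  t <- toy_score_table(groups = "A", models = c(1, 3), metrics = "gdt_ha",
                       value_fun = function(g, e, m, met) if (m == 1) 10 else 90)
  first <- select_models(t, "first", sch)
  expect_equal(unique(first$model), 1)
  best <- select_models(t, "best", sch)
  expect_equal(unique(best$model), 3)

  # lowest-ID rule when model 1 is absent
  t2 <- toy_score_table(groups = "A", models = c(2, 4), metrics = "gdt_ha")
  expect_equal(unique(select_models(t2, "first", sch)$model), 2)

  # model6 mode keeps only index 6, silently absent otherwise
  t3 <- rbind(t, transform(t[t$model == 1, ], model = 6, value = 50))
  m6 <- select_models(t3, "model6", sch)
  expect_equal(unique(m6$model), 6)
  expect_equal(nrow(select_models(t, "model6", sch)), 0)
})

test_that("EU-weighted aggregation ranks a dominating group first", {
  sch <- default_weight_scheme()
  eus <- data.frame(eu = c("T1-D1", "T1-D2", "T1-D3", "T1-D4"),
                    weight = 0.25)
  t <- toy_score_table(groups = c("A", "B", "C"), eus = eus$eu, models = 1,
                       metrics = sch$metric,
                       value_fun = function(g, e, m, met) {
                         base <- c(A = 80, B = 60, C = 40)[g]
                         if (met == "molprobity") (100 - base) / 20 else base
                       })
  r <- aggregate_ranking(t, eus, sch, mode = "first")
  expect_equal(r$group[1], "A")
  expect_equal(r$group[3], "C")
  # EU weights of one target sum to 1, so totals stay on the z scale
  expect_lt(max(abs(r$total_z)), 3)

  # permuting the record order changes nothing
  set.seed(1)
  t_perm <- t[sample(nrow(t)), ]
  r_perm <- aggregate_ranking(t_perm, eus, sch, mode = "first")
  expect_equal(r_perm$total_z, r$total_z)
  expect_equal(r_perm$group, r$group)

  # a single-metric scheme reproduces the plain per-metric z ranking
  r_gdt <- aggregate_ranking(t, eus, single_metric_scheme("gdt_ha"),
                             mode = "first")
  expect_equal(r_gdt$group, c("A", "B", "C"))

  # the floor-at-0 alternative keeps the dominant group on top
  r0 <- aggregate_ranking(t, eus, sch, mode = "first", floor = 0)
  expect_equal(r0$group[1], "A")
  expect_true(all(r0$total_z >= 0))
})

test_that("groups missing every EU rank last at the floor", {
  sch <- single_metric_scheme("gdt_ha")
  eus <- data.frame(eu = c("T1-D1", "T2-D1"), weight = 1)
  t <- toy_score_table(groups = c("A", "B", "C"), eus = eus$eu, models = 1,
                       metrics = "gdt_ha",
                       value_fun = function(g, e, m, met)
                         c(A = 80, B = 60, C = 40)[g])
  t <- t[t$group != "C", ]
  r <- aggregate_ranking(t, eus, sch, mode = "first",
                         groups = c("A", "B", "C"))
  expect_equal(r$group[3], "C")
  expect_equal(r$total_z[3], sum(eus$weight) * -2)
})

test_that("first-model-best frequency counts strict maxima with tie credit", {
  # group A: first model always best; group B: never
  t <- toy_score_table(groups = c("A", "B"), eus = paste0("T", 1:4, "-D1"),
                       models = 1:5, metrics = "gdt_ha",
                       value_fun = function(g, e, m, met)
                         if (g == "A") 100 - m else 50 + m)
  r <- first_model_best_frequency(t)
  expect_equal(r$ratio[r$group == "A"], 1)
  expect_equal(r$ratio[r$group == "B"], 0)
  expect_equal(r$n_targets, c(4, 4))

  # ties are credited to the first model
  t2 <- toy_score_table(groups = "A", eus = "T1-D1", models = 1:2,
                        metrics = "gdt_ha",
                        value_fun = function(g, e, m, met) 70)
  expect_equal(first_model_best_frequency(t2)$ratio, 1)

  expect_error(first_model_best_frequency(
    toy_score_table(models = 1, metrics = "gdt_ha")), ">= 2 models")
})

test_that("renormalization keeps weights summing to 1", {
  w <- default_weight_scheme()
  expect_warning(
    w2 <- renormalize_weights(w, c("gdt_ha", "ase", "gdc_sc", "al0_p", "lddt")),
    "renormalized")
  expect_equal(sum(w2$weight), 1, tolerance = 1e-15)
  expect_setequal(w2$metric, c("gdt_ha", "ase", "gdc_sc", "al0_p", "lddt"))
})

test_that("latent-model ranking recovers the skill order", {
  x <- latent_experiment(n_groups = 12, n_targets = 20, seed = 7)
  tab <- simulate_experiment(x)
  r <- aggregate_ranking(tab, attr(tab, "eus"), mode = "best")
  skill <- attr(tab, "skill")
  rho <- cor(skill[r$group], seq_len(nrow(r)), method = "spearman")
  expect_lt(rho, -0.9)  # rank 1 = highest skill
})
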