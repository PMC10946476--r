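# deterministic metric table with known structure
fixture_table <- function(n_per = 12, sd = 0.05, habitat_shift = 0,
                          seed = 1) {
  set.seed(seed)
  habs <- rep(HABITAT_LEVELS, each = n_per)
  n <- length(habs)
  shift <- ifelse(habs == "Agricultural", -habitat_shift, 0)
  df <- data.frame(
    network_id = sprintf("N%02d", seq_len(n)),
    study_id = sprintf("N%02d", seq_len(n)),
    habitat = habs,
    latitude = runif(n, -30, 60),
    dominant_family = sample(c("Culicidae", "Ceratopogonidae",
                               "Psychodidae"), n, replace = TRUE),
    n_diptera = sample(5:12, n, replace = TRUE),
    n_hosts = sample(8:20, n, replace = TRUE),
    m = sample(120:260, n, replace = TRUE),
    L = sample(15:40, n, replace = TRUE),
    flags = "", stringsAsFactors = FALSE)
  df$abs_latitude <- abs(df$latitude)
  df$S <- df$n_diptera + df$n_hosts
  df$IE <- pmin(pmax(0.7 + shift + rnorm(n, 0, sd), 0), 1)
  df$H2prime <- pmin(pmax(0.4 + rnorm(n, 0, sd), 0), 1)
  df$H2 <- df$H2min <- df$H2max <- 1
  df$ie_mode <- "realized_links"
  metrics_table(df)
}

test_that("metrics_table excludes flagged networks and logs them", {
  sim <- generate_dataset(default_scenario(5), records = FALSE)
  met <- do.call(rbind, lapply(sim$networks, network_summary, h2 = FALSE))
  met$H2prime <- 0.4
  met$flags[1] <- "ie_undefined"
  tbl <- metrics_table(met)
  expect_equal(nrow(tbl), nrow(met) - 1)
  expect_equal(nrow(attr(tbl, "exclusions")), 1)
  expect_equal(tbl$log_m, log(tbl$n_bloodmeals))
})

test_that("gaussian GLM deviance equals the residual sum of squares", {
  tbl <- fixture_table()
  fit <- fit_metric_model(tbl, "IE")
  expect_equal(deviance(fit), sum(residuals(fit)^2))
  # constant response: all slopes zero, zero deviance
  tbl0 <- tbl
  tbl0$IE <- 0.5
  fit0 <- fit_metric_model(tbl0, "IE", interactions = FALSE)
  cf <- coef(fit0)
  expect_true(all(abs(cf[-1][!is.na(cf[-1])]) < 1e-10))
  expect_lt(deviance(fit0), 1e-20)
})

test_that("an injected habitat effect is recovered with the right sign", {
  tbl <- fixture_table(n_per = 20, habitat_shift = 0.12, seed = 2)
  fit <- fit_metric_model(tbl, "IE", interactions = FALSE)
  cf <- coef(fit)
  # Agricultural is the reference level: the other two sit higher
  expect_gt(cf[["habitatNearNatural"]], 0.06)
  expect_gt(cf[["habitatVillageUrban"]], 0.06)
  ts <- term_significance(tbl, "IE", "habitat")
  expect_lt(ts$p_value, 0.01)
  expect_equal(ts$df, 2)
})

test_that("adding a term never increases deviance, and df reconcile", {
  tbl <- fixture_table(seed = 3)
  for (term in c("habitat", "abs_latitude", "S", "log_m",
                 "dominant_family", "dominant_family:habitat",
                 "dominant_family:abs_latitude")) {
    ts <- term_significance(tbl, "IE", term)
    expect_gte(ts$deviance_change, 0)
    expect_gte(ts$df, 1)
    expect_true(ts$p_value >= 0 && ts$p_value <= 1)
    expect_true(ts$p_raw >= 0 && ts$p_raw <= 1)
  }
})

test_that("Tukey HSD behaves at the extremes and matches TukeyHSD", {
  # identical group means: adjusted p near 1
  tbl <- fixture_table(seed = 4)
  tbl$IE <- 0.6 + rep(c(0.01, -0.01), length.out = nrow(tbl))
  tk <- tukey_habitat(tbl, "IE", method = "raw")
  expect_equal(nrow(tk), 3)
  expect_true(all(tk$p_adj > 0.9))

  # huge separation: p below 0.001
  tbl2 <- fixture_table(habitat_shift = 0.5, sd = 0.01, seed = 5)
  tk2 <- tukey_habitat(tbl2, "IE", method = "raw")
  agr <- grepl("Agricultural", tk2$contrast)
  expect_true(all(tk2$p_adj[agr] < 1e-3))

  # model-based contrasts agree with the raw mode when covariates are
  # orthogonal to habitat by construction (large balanced fixture)
  tk_model <- tukey_habitat(tbl2, "IE", method = "model")
  expect_equal(nrow(tk_model), 3)
  expect_true(all(tk_model$p_adj[grepl("Agricultural",
                                       tk_model$contrast)] < 1e-3))

  # cross-check the raw mode against an independent studentized-range
  # computation via ptukey
  grp <- split(tbl2$IE, tbl2$habitat)
  mse <- sum(vapply(grp, function(x) sum((x - mean(x))^2), numeric(1))) /
    (nrow(tbl2) - 3)
  n_per <- lengths(grp)
  qstat <- abs(mean(grp[["NearNatural"]]) - mean(grp[["Agricultural"]])) /
    sqrt(mse / 2 * (1 / n_per[["Agricultural"]] + 1 / n_per[["NearNatural"]]))
  p_manual <- ptukey(qstat, nmeans = 3, df = nrow(tbl2) - 3,
                     lower.tail = FALSE)
  row <- tk2[tk2$contrast == "NearNatural-Agricultural", ]
  expect_equal(row$p_adj, p_manual, tolerance = 1e-6)
})

test_that("richness-latitude model controls for effort and flags the slope", {
  tbl <- fixture_table(seed = 6)
  # perfect linear structure: R^2 = 1
  tbl$n_hosts <- 2 + 0.5 * tbl$abs_latitude + 0.01 * tbl$n_bloodmeals
  # a perfect linear fixture triggers R's perfect-fit warning by design
  fit <- suppressWarnings(richness_latitude_model(tbl, "host_richness"))
  expect_equal(suppressWarnings(summary(fit)$r.squared), 1)
  lt <- attr(fit, "latitude_test")
  expect_equal(lt$estimate, 0.5, tolerance = 1e-8)
  expect_lt(lt$p, 1e-10)

  # no latitude structure: slope CI covers 0 at roughly the nominal rate
  cover <- vapply(1:60, function(s) {
    t2 <- fixture_table(seed = 100 + s)
    t2$n_hosts <- 10 + 0.02 * t2$n_bloodmeals + rnorm(nrow(t2), 0, 2)
    f <- richness_latitude_model(t2, "host_richness")
    attr(f, "latitude_test")$p > 0.05
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})
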