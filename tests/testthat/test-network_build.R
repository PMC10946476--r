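test_that("matrices are built by summation with lexicographic ordering", {
  df <- data.frame(study_id = "S01", site_id = "S01", latitude = 5,
                   habitat = "Agricultural",
                   diptera_taxon = c("A", "A", "B"),
                   diptera_rank = "species", diptera_family = "Culicidae",
                   host_taxon = c("x", "y", "x"), host_rank = "species",
                   count = c(2L, 1L, 3L), stringsAsFactors = FALSE)
  m <- build_matrix(df)
  expect_equal(unname(m$weights), matrix(c(2, 3, 1, 0), 2, 2))
  expect_equal(sum(m$weights), 6)
  expect_equal(sum(m$weights > 0), 3)

  # duplicate rows accumulate
  df2 <- rbind(df, df[1, ])
  m2 <- build_matrix(df2)
  expect_equal(m2$weights["A", "x"], 4)

  # order invariance
  m3 <- build_matrix(df[sample(nrow(df)), ])
  expect_identical(m$weights, m3$weights)

  # conflicting latitudes are an error
  df$latitude[2] <- 6
  expect_error(build_matrix(df), "latitude")
})

test_that("networks split by (study, habitat) and single-Diptera nets drop", {
  rec <- rbind(make_records(study = "S01", habitat = "Agricultural"),
               make_records(study = "S01", habitat = "NearNatural"),
               make_records(study = "S02", habitat = "VillageUrban",
                            diptera = "Culex pipiens"))
  ns <- split_networks(rec)
  expect_length(ns$networks, 2)
  expect_setequal(names(ns$networks),
                  c("S01::Agricultural", "S01::NearNatural"))
  expect_equal(nrow(ns$exclusions), 1)
  expect_match(ns$exclusions$reason, "fewer than 2")

  expect_warning(empty <- split_networks(make_records()[0, ]), "empty")
  expect_length(empty$networks, 0)
})

test_that("matrix sizes reconcile with retained record counts", {
  rec <- rbind(make_records(study = "S01", habitat = "Agricultural",
                            counts = c(5, 1, 2, 7)),
               make_records(study = "S03", habitat = "NearNatural",
                            counts = c(4, 4, 1, 1)))
  ns <- split_networks(rec)
  total <- sum(vapply(ns$networks, function(n) sum(n$weights), numeric(1)))
  expect_equal(total, sum(rec$count))
  expect_equal(sum(aggregate_global(ns)$weights), sum(rec$count))
})

test_that("dominant family follows the interaction count with alpha tie-break", {
  w <- matrix(c(6, 4, 3), 3, 1, dimnames = list(c("a", "b", "c"), "h"))
  m <- interaction_matrix(w, row_family = c("Culicidae", "Culicidae",
                                            "Simuliidae"))
  expect_equal(as.character(dominant_family(m)), "Culicidae")

  m2 <- interaction_matrix(w, row_family = c("Simuliidae", "Culicidae",
                                             "Ceratopogonidae"))
  # Simuliidae 6 vs Culicidae 4 vs Cerato 3
  expect_equal(as.character(dominant_family(m2)), "Simuliidae")

  w3 <- matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "h"))
  m3 <- interaction_matrix(w3, row_family = c("Simuliidae", "Culicidae"))
  dom <- dominant_family(m3)
  expect_equal(as.character(dom), "Culicidae")
  expect_true(attr(dom, "tie"))
})

test_that("aggregation unions labels and sums shared cells", {
  m1 <- interaction_matrix(matrix(2, 1, 1, dimnames = list("A", "x")),
                           study_id = "s1", habitat = "Agricultural")
  m2 <- interaction_matrix(matrix(3, 1, 1, dimnames = list("B", "y")),
                           study_id = "s2", habitat = "Agricultural")
  agg <- aggregate_global(list(m1, m2))
  expect_equal(dim(agg$weights), c(2, 2))
  expect_equal(sum(agg$weights > 0), 2)

  m3 <- interaction_matrix(matrix(3, 1, 1, dimnames = list("A", "x")),
                           study_id = "s3", habitat = "NearNatural")
  agg2 <- aggregate_global(list(m1, m3))
  expect_equal(agg2$weights["A", "x"], 5)

  expect_identical(aggregate_global(list(m1))$weights, m1$weights)
})
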