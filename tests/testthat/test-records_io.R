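test_that("well-formed files read back with validated types", {
  df <- make_records()
  path <- write_temp_records(df)
  rec <- read_records(path)
  expect_equal(nrow(rec), 4)
  expect_type(rec$count, "integer")
  expect_type(rec$latitude, "double")
  expect_equal(sum(rec$count), sum(df$count))
})

test_that("schema and row-level validation reject bad input", {
  df <- make_records()
  df$habitat <- "Urban"
  expect_error(read_records(write_temp_records(df)), "Urban")

  df <- make_records()
  df$count[2] <- "2.5"
  expect_error(read_records(write_temp_records(df)), "count")

  df <- make_records()
  df$latitude[1] <- 123
  expect_error(read_records(write_temp_records(df)), "latitude")

  df <- make_records()[, -3]  # drop latitude column entirely
  expect_error(read_records(write_temp_records(df)), "missing required")
})

test_that("zero counts are dropped and duplicates summed, with warnings", {
  df <- make_records(counts = c(3, 0, 2, 1))
  expect_warning(rec <- read_records(write_temp_records(df)), "count = 0")
  expect_equal(nrow(rec), 3)

  df <- rbind(make_records(counts = c(1, 1, 1, 1)),
              make_records(counts = c(2, 2, 2, 2)))
  expect_warning(rec <- read_records(write_temp_records(df)), "duplicate")
  expect_equal(nrow(rec), 4)
  expect_equal(sort(rec$count), c(3, 3, 3, 3))
})

test_that("write/read round-trips preserve tables including unicode labels", {
  df <- make_records(latitude = -23.456789012345)
  df$host_taxon[1] <- "Grue cendrée"
  path <- tempfile(fileext = ".csv")
  write_records(df, path)
  back <- read_records(path)
  expect_equal(back$host_taxon, df$host_taxon)
  expect_equal(back$latitude, df$latitude)
  expect_equal(back$count, df$count)

  empty <- df[0, , drop = FALSE]
  write_records(empty, path)
  expect_equal(nrow(read_records(path)), 0)
})

test_that("a single unresolved taxon becomes a genus node", {
  df <- make_records(diptera = c("Culicoides sp.", "Culex pipiens"),
                     counts = c(2, 1, 1, 3))
  df$diptera_rank[df$diptera_taxon == "Culicoides sp."] <- "genus"
  res <- resolve_taxa(df)
  expect_true("Culicoides spp." %in% res$records$diptera_taxon)
  expect_equal(res$log$removed_interactions, 0)
  expect_equal(nrow(res$records), 4)
})

test_that("ambiguous multi-species genus nodes follow the sympatry rule", {
  df <- make_records(diptera = c("Culicoides sp. A", "Culicoides sp. B",
                                 "Culex pipiens"),
                     counts = rep(1, 6))
  df$diptera_rank[grepl("Culicoides", df$diptera_taxon)] <- "genus"

  # sympatric congeners possible -> all ambiguous rows removed
  sym <- data.frame(taxon = "Culicoides", study_id = "S01",
                    n_sympatric_species = 3)
  res <- resolve_taxa(df, sym)
  expect_false(any(grepl("Culicoides", res$records$diptera_taxon)))
  expect_equal(res$log$removed_interactions, 4)
  expect_equal(res$log$removed_diptera, 2)

  # no sympatric congeners -> collapsed into one genus node
  sym$n_sympatric_species <- 1
  res2 <- resolve_taxa(df, sym)
  expect_true("Culicoides spp." %in% res2$records$diptera_taxon)
  expect_equal(res2$log$removed_interactions, 0)
  expect_equal(sum(res2$records$count), sum(df$count))

  # genus absent from the table -> unresolvable, removed and logged
  res3 <- resolve_taxa(df, sym[0, ])
  expect_equal(res3$log$removed_interactions, 4)
  expect_true(any(grepl("unresolvable",
                        res3$log$dispositions$reason)))
})

test_that("resolution conserves rows and is idempotent", {
  df <- make_records(diptera = c("Culicoides sp. A", "Culicoides sp. B",
                                 "Anopheles sp.", "Culex pipiens"),
                     hosts = c("Human", "Anas sp.", "Turdus merula"),
                     counts = rep(2, 12))
  df$diptera_rank[grepl("sp\\.", df$diptera_taxon)] <- "genus"
  df$host_rank[df$host_taxon == "Anas sp."] <- "genus"
  sym <- data.frame(taxon = c("Culicoides", "Anas"),
                    study_id = "S01", n_sympatric_species = c(2, 1))

  res <- resolve_taxa(df, sym)
  expect_equal(res$log$n_input,
               res$log$n_output + res$log$removed_interactions +
                 res$log$rows_merged)
  again <- resolve_taxa(res$records, sym)
  expect_equal(again$records, res$records)
  expect_equal(again$log$removed_interactions, 0)

  # fully species-resolved input passes through untouched
  clean <- make_records()
  res_clean <- resolve_taxa(clean)
  expect_equal(res_clean$records, clean)
  expect_equal(nrow(res_clean$log$collapsed_nodes), 0)
})

test_that("labels above family rank are removed", {
  df <- make_records(hosts = c("Aves", "Human"), counts = c(1, 2, 3, 4))
  df$host_rank[df$host_taxon == "Aves"] <- "class"
  res <- resolve_taxa(df)
  expect_false("Aves" %in% res$records$host_taxon)
  expect_equal(res$log$removed_interactions, 2)
})
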