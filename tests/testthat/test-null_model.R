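make_net <- function(w, habitat = "Agricultural", study = "s1") {
  interaction_matrix(w, study_id = study, habitat = habitat, latitude = 10)
}

test_that("host removal deletes columns and emptied rows", {
  w <- matrix(c(3, 0, 2, 4), 2, 2,
              dimnames = list(c("A", "B"), c("Human", "Turdus merula")))
  red <- remove_hosts(make_net(w), "Turdus merula")
  expect_equal(colnames(red$weights), "Human")
  expect_true(all(rowSums(red$weights) > 0))
  expect_equal(rownames(red$weights), "A")  # B fed only on the bird

  expect_warning(same <- remove_hosts(make_net(w), "Vulpes vulpes"),
                 "not present")
  expect_identical(same$weights, w)

  emptied <- remove_hosts(make_net(w), c("Human", "Turdus merula"))
  expect_true(isTRUE(attr(emptied, "empty")))
})

test_that("null model is exactly reproducible and matches a re-run oracle", {
  set.seed(99)
  w <- matrix(rpois(20, 3) + 1, 4, 5,
              dimnames = list(paste0("D", 1:4),
                              c("Human", "Cattle", "Turdus merula",
                                "Vulpes vulpes", "Apodemus sylvaticus")))
  net <- make_net(w)
  r1 <- run_null_model(net, n_reps = 100, seed = 1)
  r2 <- run_null_model(net, n_reps = 100, seed = 1)
  expect_identical(r1$ie_random, r2$ie_random)
  expect_equal(r1$z, r2$z, tolerance = 1e-12)

  # independent replay of the documented sampling scheme
  set.seed(1)
  labels <- colnames(w)
  replay <- replicate(100, {
    pick <- sample(labels, 2)  # Human + Cattle are the 2 domestic hosts
    keep <- w[, !(labels %in% pick), drop = FALSE]
    keep <- keep[rowSums(keep) > 0, , drop = FALSE]
    p <- keep[keep > 0] / sum(keep)
    -sum(p * log(p)) / log(sum(keep > 0))
  })
  expect_equal(r1$ie_random, replay, tolerance = 1e-12)
  z_oracle <- (r1$ie_targeted - mean(replay)) / sd(replay)
  expect_equal(r1$z, z_oracle, tolerance = 1e-12)
})

test_that("host-permutation-symmetric networks give z = 0", {
  # identical totals and link pattern in every column; one domestic host
  w <- matrix(2, 3, 4,
              dimnames = list(paste0("D", 1:3),
                              c("Human", "Turdus merula", "Vulpes vulpes",
                                "Apodemus sylvaticus")))
  res <- run_null_model(make_net(w), n_reps = 50, seed = 3)
  expect_false(res$skipped)
  expect_lt(abs(res$z), 1e-9)
  expect_true(all(abs(res$ie_random - res$ie_targeted) < 1e-12))
})

test_that("skip logic covers degenerate networks", {
  w_wild <- matrix(c(1, 2, 3, 4), 2, 2,
                   dimnames = list(c("A", "B"),
                                   c("Turdus merula", "Vulpes vulpes")))
  res <- run_null_model(make_net(w_wild))
  expect_true(res$skipped)
  expect_match(res$reason, "no domestic hosts")

  w_dom <- matrix(c(1, 2, 3, 4), 2, 2,
                  dimnames = list(c("A", "B"), c("Human", "Cattle")))
  res2 <- run_null_model(make_net(w_dom))
  expect_true(res2$skipped)
  expect_match(res2$reason, "all hosts domestic")

  empty_list <- list(hosts = character(), synonyms = character())
  res3 <- run_null_model(make_net(w_dom), domestic = empty_list)
  expect_true(res3$skipped)
})

test_that("domestic matching is case-insensitive and synonym-aware", {
  labs <- c("CATTLE", "Bos taurus", "homo sapiens", "Sus scrofa",
            "Turdus merula")
  expect_equal(is_domestic(labs), c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("habitat summary recomputes means and standard errors", {
  mk <- function(id, hab, ie) {
    structure(list(network_id = id, habitat = hab, k_removed = 1,
                   ie_observed = ie, ie_targeted = ie,
                   ie_random = rep(ie, 10), z = 0, n_redraws = 0L,
                   seed = 1L, skipped = FALSE, reason = ""),
              class = "null_model_result")
  }
  res <- list(mk("a", "Agricultural", 0.4), mk("b", "Agricultural", 0.6),
              mk("c", "NearNatural", 0.5))
  s <- summarise_null_by_habitat(res)
  agr <- s[s$habitat == "Agricultural", ]
  expect_equal(agr$mean_ie_targeted, 0.5)
  expect_equal(agr$n, 2)
  expect_equal(agr$se, sd(c(0.4, 0.6)) / sqrt(2))
  expect_true(is.na(s$se[s$habitat == "NearNatural"]))

  skipped <- structure(c(mk("d", "VillageUrban", 0.1), list()),
                       class = "null_model_result")
  skipped$skipped <- TRUE
  expect_warning(summarise_null_by_habitat(c(res, list(skipped))),
                 "VillageUrban")
})
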