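test_that("nearest-marker classification matches a brute-force argmax and breaks ties canonically", {
  d <- c(10, 1, 1)
  mask <- full_mask(d)
  basis <- function(i) {
    v <- array(0, dim = d); v[i, 1, 1] <- 1
    v <- v - mean(v)
    v
  }
  markers <- list(WR = fake_map(basis(1), mask, "WR"),
                  PV = fake_map(basis(2), mask, "PV"),
                  FT = fake_map(basis(3), mask, "FT"))
  test <- fake_map(0.9 * basis(3), mask, "FT")
  pred <- classify_trial(test, markers, mask)
  expect_equal(as.character(pred), "FT")
  expect_false(attr(pred, "tie"))
  # brute-force check of all three correlations
  Rs <- attr(pred, "R")
  for (l in names(markers))
    expect_equal(unname(Rs[l]),
                 pearson_oracle(test$r[mask$inside], markers[[l]]$r[mask$inside]),
                 tolerance = 1e-12)
  expect_equal(names(which.max(Rs)), "FT")

  # exact tie (two markers with identical maps) -> first label in canonical
  # order, flagged
  tied <- list(WR = markers$PV, PV = markers$PV, FT = markers$FT)
  pred2 <- classify_trial(fake_map(basis(2), mask), tied, mask)
  expect_equal(as.character(pred2), "WR")
  expect_true(attr(pred2, "tie"))
})

test_that("exhaustive identification enumerates 512 combinations and 10752 tests", {
  d <- c(8, 4, 2)
  mask <- full_mask(d)
  with_seed(14, {
    protos <- list(WR = array(rnorm(prod(d)), dim = d),
                   PV = array(rnorm(prod(d)), dim = d),
                   FT = array(rnorm(prod(d)), dim = d))
  })
  maps <- toy_trial_maps(protos, mask, noise_sd = 0.5, seed = 15)
  res <- run_identification(maps, mask, task_levels = c("WR", "PV", "FT"))
  expect_equal(res$n_combinations, 512L)
  expect_equal(res$n_tests, 10752L)
  expect_equal(res$n_tests / res$n_combinations, 21)
  expect_equal(unname(res$n_total), rep(512 * 7, 3))
  expect_true(all(res$correct_rate >= 0 & res$correct_rate <= 100))
})

test_that("perfectly separable categories are identified at 100%", {
  d <- c(9, 3, 1)
  mask <- full_mask(d)
  protos <- list(WR = array(0, dim = d), PV = array(0, dim = d),
                 FT = array(0, dim = d))
  protos$WR[1:9] <- c(1, rep(0, 8)); protos$PV[1:9] <- c(0, 1, rep(0, 7))
  protos$FT[1:9] <- c(0, 0, 1, rep(0, 6))
  maps <- toy_trial_maps(protos, mask, noise_sd = 0)
  res <- run_identification(maps, mask, task_levels = c("WR", "PV", "FT"))
  expect_equal(unname(res$correct_rate), rep(100, 3))
})

test_that("pooled rates are invariant to trial order within categories", {
  d <- c(6, 4, 2)
  mask <- full_mask(d)
  with_seed(44, {
    protos <- list(WR = array(rnorm(prod(d)), dim = d),
                   PV = array(rnorm(prod(d)), dim = d),
                   FT = array(rnorm(prod(d)), dim = d))
  })
  maps <- toy_trial_maps(protos, mask, noise_sd = 1, seed = 45)
  res1 <- run_identification(maps, mask, task_levels = c("WR", "PV", "FT"))
  # shuffle trials within each category
  perm <- with_seed(46, {
    unlist(lapply(split(seq_along(maps),
                        vapply(maps, function(m) m$window$task_label, character(1))),
                  sample), use.names = FALSE)
  })
  res2 <- run_identification(maps[perm], mask, task_levels = c("WR", "PV", "FT"))
  expect_equal(res2$correct_rate, res1$correct_rate)
})

test_that("chance rate is 100 / k", {
  expect_equal(round(chance_rate(3), 1), 33.3)
  expect_equal(chance_rate(2), 50)
  expect_error(chance_rate(1), "n_categories")
})

test_that("the test against chance matches a hand computation", {
  rates <- c(50, 60, 70)
  res <- test_vs_chance(rates, chance = 100 / 3)
  m <- mean(rates) - 100 / 3
  s <- sqrt(sum((rates - mean(rates))^2) / 2)
  t_hand <- m / (s / sqrt(3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pt(t_hand, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # centred on chance: t = 0, one-sided p = 0.5
  res0 <- test_vs_chance(c(23, 33, 43), chance = 33)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 0.5, tolerance = 1e-12)

  expect_error(test_vs_chance(rep(50, 5)), "variance")
  expect_error(test_vs_chance(60), "2 subjects")
})

test_that("the similarity/correct-rate association recovers exact linear relations", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  up <- associate_similarity_rate(x, 50 + 100 * x)
  expect_equal(up$r, 1)
  expect_equal(up$n, 4)
  down <- associate_similarity_rate(c(0.1, 0.2, 0.3), c(90, 70, 50))
  expect_equal(down$r, -1)
  expect_error(associate_similarity_rate(c(0.1, 0.1, 0.1), c(1, 2, 3)), "constant")
  expect_error(associate_similarity_rate(c(0.1, 0.2), c(1, 2)), "3 points")
})
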