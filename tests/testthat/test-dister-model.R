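test_that("geometric prior closed form and inverse relation hold", {
  expect_equal(estimate_prior_geometric(2.1277), 0.53, tolerance = 5e-3)
  expect_equal(estimate_prior_geometric(1), 0)
  expect_equal(estimate_prior_geometric(2), 0.5)
  for (p in c(0, 0.25, 0.5, 0.53, 0.9)) {
    expect_equal(estimate_prior_geometric(1 / (1 - p)), p,
                 tolerance = 1e-12)
  }
  expect_error(estimate_prior_geometric(0.9),
               class = "dister_domain_error")
})

test_that("mean training TU length uses experimental non-leader TUs only", {
  # lengths 3 and 1; computational (2) and leader (2) excluded
  expect_equal(mean_tu_length(toy_tus()), 2)
})

eight_pairs <- function() {
  feature_pairs(rep(1, 8), c(rep(FALSE, 4), rep(TRUE, 4)),
                c(rep("STU", 4), rep("DTU", 4)))
}

test_that("add-one smoothing over the joint grid matches hand computation", {
  model <- dister_fit(eight_pairs(), config = 2, alpha = 1,
                      prior = "empirical")
  expect_equal(model$p_stu_prior, 0.5)
  expect_equal(model$tables$STU["1", "FALSE"], 5 / 6)
  expect_equal(model$tables$STU["1", "TRUE"], 1 / 6)
  expect_equal(model$tables$DTU["1", "FALSE"], 1 / 6)
  expect_equal(model$tables$DTU["1", "TRUE"], 5 / 6)
  # conditional tables always sum to one
  expect_equal(sum(model$tables$STU), 1, tolerance = 1e-12)
  expect_equal(sum(model$tables$DTU), 1, tolerance = 1e-12)
})

test_that("independence configuration uses smoothed marginals", {
  model <- dister_fit(eight_pairs(), config = 1, alpha = 1,
                      prior = "empirical")
  expect_equal(unname(model$tables$STU$bin["1"]), 1)
  expect_equal(unname(model$tables$STU$term["FALSE"]), 5 / 6)
  expect_equal(unname(model$tables$DTU$term["TRUE"]), 5 / 6)
})

test_that("posterior matches the hand Bayes computation and normalizes", {
  model <- dister_fit(eight_pairs(), config = 2, alpha = 1,
                      prior = "empirical")
  q <- feature_pairs(1, FALSE, "unlabeled")
  post <- predict(model, q)$p_stu
  expect_equal(post, (0.5 * 5 / 6) / (0.5 * 5 / 6 + 0.5 * 1 / 6),
               tolerance = 1e-12)
  # complements: P(STU) + P(DTU) = 1 by construction of the two-class rule
  q2 <- feature_pairs(1, TRUE, "unlabeled")
  expect_equal(predict(model, q2)$p_stu, 1 - post, tolerance = 1e-12)
})

test_that("identical class tables give posterior equal to the prior", {
  train <- feature_pairs(c(0, 1, 0, 1), c(FALSE, TRUE, FALSE, TRUE),
                         c("STU", "STU", "DTU", "DTU"))
  model <- dister_fit(train, config = 2, alpha = 1, prior = "geometric",
                      mean_tu_len = 1 / (1 - 0.53))
  qs <- feature_pairs(c(0, 1, 5), c(TRUE, FALSE, FALSE), "unlabeled")
  expect_equal(predict(model, qs)$p_stu, rep(0.53, 3), tolerance = 1e-12)
})

test_that("fitted posteriors equal the brute-force oracle to 1e-12", {
  for (config in 1:3) {
    for (seed in 1:8) {
      train <- random_training_set(30, seed = seed)
      query <- random_training_set(20, seed = seed + 100)
      for (alpha in c(0.5, 1, 2)) {
        model <- dister_fit(train, config = config, alpha = alpha,
                            prior = "empirical")
        got <- predict(model, query)$p_stu
        want <- brute_posterior(train, query, config, alpha,
                                model$p_stu_prior)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("as alpha shrinks, a class-pure cell's posterior approaches 1", {
  train <- feature_pairs(c(rep(-1, 5), rep(5, 5)),
                         rep(FALSE, 10),
                         c(rep("STU", 5), rep("DTU", 5)))
  q <- feature_pairs(-1, FALSE, "unlabeled")
  post <- vapply(c(1, 0.1, 0.01, 1e-4), function(a) {
    m <- dister_fit(train, config = 2, alpha = a, prior = "empirical")
    predict(m, q)$p_stu
  }, numeric(1))
  expect_true(all(diff(post) > 0))
  expect_gt(post[4], 1 - 1e-3)
})

test_that("configs 2 and 3 coincide when one score class carries all calls", {
  train <- random_training_set(60, seed = 3)
  train$term_confidence[train$term_present] <- 95  # all "high"
  train$term_score_class <- terminator_score_class(
    ifelse(train$term_present, 95, NA_real_))
  q <- random_training_set(30, seed = 4)
  q$term_confidence[q$term_present] <- 95
  q$term_score_class <- terminator_score_class(
    ifelse(q$term_present, 95, NA_real_))
  m2 <- dister_fit(train, config = 2, alpha = 0, prior = "empirical")
  m3 <- dister_fit(train, config = 3, alpha = 0, prior = "empirical")
  expect_equal(predict(m2, q)$p_stu, predict(m3, q)$p_stu,
               tolerance = 1e-12)
})

test_that("classification is strict at the threshold, ties go to DTU", {
  model <- dister_fit(eight_pairs(), config = 2, alpha = 1,
                      prior = "empirical")
  q <- feature_pairs(1, FALSE, "unlabeled")
  expect_equal(dister_classify(model, q, threshold = 0.5)$call, "STU")
  post <- predict(model, q)$p_stu
  expect_equal(dister_classify(model, q, threshold = post)$call, "DTU")
  expect_equal(dister_classify(model, q, threshold = 1)$call, "DTU")
  expect_error(dister_classify(model, q, threshold = 1.5),
               class = "dister_domain_error")
})

test_that("posterior refuses non-same-strand pairs", {
  model <- dister_fit(eight_pairs(), config = 2, prior = "empirical")
  q <- feature_pairs(1, FALSE, "unlabeled")
  q$orientation <- "convergent"
  expect_error(predict(model, q), class = "dister_contract_error")
})

test_that("fit guards: missing class, bad alpha, NK labels", {
  all_stu <- feature_pairs(c(0, 1), c(FALSE, FALSE), c("STU", "STU"))
  expect_error(dister_fit(all_stu, prior = "empirical"),
               class = "dister_unfittable_error")
  tr <- eight_pairs()
  expect_error(dister_fit(tr, alpha = -1, prior = "empirical"),
               class = "dister_domain_error")
  tr$label[1] <- "NK"
  expect_error(dister_fit(tr, prior = "empirical"))
})

test_that("JSON serialization reloads to identical posteriors", {
  for (config in 1:3) {
    train <- random_training_set(50, seed = 11)
    model <- dister_fit(train, config = config, alpha = 1,
                        prior = "geometric", mean_tu_len = 2.3)
    path <- withr::local_tempfile(fileext = ".json")
    dister_write(model, path)
    back <- dister_read(path)
    query <- random_training_set(100, seed = 12)
    expect_equal(predict(back, query)$p_stu, predict(model, query)$p_stu,
                 tolerance = 1e-12)
    expect_equal(back$p_stu_prior, model$p_stu_prior)
    expect_equal(back$bins, model$bins)
  }
})

test_that("out-of-range bins clamp to the trained edge", {
  train <- eight_pairs()  # trained on bin 1 only
  model <- dister_fit(train, config = 2, alpha = 1, prior = "empirical")
  inside <- predict(model, feature_pairs(1, FALSE, "x"))$p_stu
  outside <- predict(model, feature_pairs(30, FALSE, "x"))$p_stu
  below <- predict(model, feature_pairs(-5, FALSE, "x"))$p_stu
  expect_equal(outside, inside)
  expect_equal(below, inside)
})

test_that("fitting recovers the generating tables as n grows", {
  config <- simulation_config()
  tv_dist <- function(n, seed) {
    sim <- simulate_genome(simulation_config(n_genes = n), seed = seed)
    train <- dplyr::filter(sim$pairs, orientation == "same_strand")
    model <- dister_fit(train, config = 2, alpha = 0, prior = "empirical")
    # total variation between fitted STU table and the generating law
    fitted <- tidy(model) %>%
      dplyr::filter(class == "STU")
    truth <- purrr::map2_dbl(
      fitted$distance_bin, fitted$term_state,
      function(b, s) {
        pb <- config$stu_distance[as.character(b)]
        pb <- ifelse(is.na(pb), 0, pb)
        pt <- if (b >= 0) config$p_term_stu else 0
        pb * (if (s == "TRUE") pt else 1 - pt)
      })
    sum(abs(fitted$probability - truth)) / 2
  }
  tvs <- c(tv_dist(200, 21), tv_dist(2000, 22), tv_dist(20000, 23))
  expect_true(all(diff(tvs) < 0))
  expect_lt(tvs[3], 0.05)
})

test_that("tidy and glance expose the model coherently", {
  model <- dister_fit(eight_pairs(), config = 2, alpha = 1,
                      prior = "empirical")
  td <- tidy(model)
  expect_equal(nrow(td), 2 * 1 * 2)  # 2 classes x 1 bin x 2 states
  sums <- td %>%
    dplyr::group_by(class) %>%
    dplyr::summarise(s = sum(probability))
  expect_equal(sums$s, c(1, 1), tolerance = 1e-12)
  gl <- glance(model)
  expect_equal(gl$config, 2L)
  expect_equal(gl$n_stu, 4L)
  expect_equal(gl$threshold, 0.5)
})
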