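#' Sensitivity and specificity from confusion counts
#'
#' With co-transcribed (`STU`) pairs as the positive class: sensitivity is
#' the proportion of true STU pairs called STU, specificity the proportion
#' of true DTU pairs called DTU.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.
#' @return A one-row tibble with columns `se`, `sp`.
#' @export
#' @examples
#' sensitivity_specificity(tp = 79, fn = 21, tn = 83, fp = 17)
sensitivity_specificity <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) {
    stop_dister("confusion counts must be non-negative.")
  }
  if (tp + fn == 0 || tn + fp == 0) {
    stop_dister("a class with zero evaluated pairs has no defined rate.",
                class = "dister_undefined_rate")
  }
  tibble(se = tp / (tp + fn), sp = tn / (tn + fp))
}

# Se/Sp at each threshold from posteriors + truth labels; strict ">" call.
scan_posteriors <- function(posterior, truth, grid) {
  n_pos <- sum(truth == "STU")
  n_neg <- sum(truth == "DTU")
  purrr::map_dfr(grid, function(th) {
    call_stu <- posterior > th
    tibble(
      threshold = th,
      se = sum(call_stu & truth == "STU") / n_pos,
      sp = sum(!call_stu & truth == "DTU") / n_neg
    )
  }) %>%
    mutate(cost = (1 - .data$se)^2 + (1 - .data$sp)^2)
}

#' Scan decision thresholds under an evaluation scheme
#'
#' Evaluates the classifier over a grid of decision thresholds in
#' `[0.05, 1]` under one of three schemes:
#' * `resubstitution` -- fit once on all pairs and score those same pairs
#'   (an optimistic bound on generalization);
#' * `holdout` -- fit on a seeded, label-stratified 80% split and score the
#'   held-out 20%;
#' * `loo` -- leave-one-out: refit N times, classify each held-out pair
#'   once, and pool the N single-pair outcomes into one confusion table per
#'   threshold.
#'
#' The geometric prior, when used, is re-estimated from the supplied mean TU
#' length in every fold; with the empirical prior each fold uses its own
#' training fraction, so no information leaks from held-out pairs.
#'
#' @param pairs Labeled same-strand pairs (`label` in `STU`/`DTU`).
#' @param config Model configuration (1, 2 or 3).
#' @param scheme `"resubstitution"`, `"holdout"` or `"loo"`.
#' @param grid Strictly increasing thresholds within `[0.05, 1]`
#'   (default `seq(0.05, 1, by = 0.05)`).
#' @param seed Integer seed for the holdout split.
#' @param train_frac Training fraction for the holdout scheme (0.8).
#' @param alpha,prior,mean_tu_len Passed to [dister_fit()].
#' @return A `dister_scan`: the per-threshold tibble (`threshold`, `se`,
#'   `sp`, `cost`) with the scheme, the chosen threshold
#'   (see [best_threshold()]) and the number of model fits as attributes.
#' @export
threshold_scan <- function(pairs, config = 2,
                           scheme = c("resubstitution", "holdout", "loo"),
                           grid = seq(0.05, 1, by = 0.05), seed = 1L,
                           train_frac = 0.8, alpha = 1,
                           prior = c("empirical", "geometric"),
                           mean_tu_len = NULL) {
  scheme <- match.arg(scheme)
  prior <- match.arg(prior)
  if (any(grid < 0.05 - 1e-12) || any(grid > 1 + 1e-12) ||
      any(diff(grid) <= 0)) {
    stop_dister("grid must be strictly increasing within [0.05, 1].",
                class = "dister_domain_error")
  }
  pairs <- filter(pairs, .data$orientation == "same_strand")
  fit_one <- function(train) {
    dister_fit(train, config = config, alpha = alpha, prior = prior,
               mean_tu_len = mean_tu_len)
  }
  n_fits <- 0L
  if (scheme == "resubstitution") {
    model <- fit_one(pairs)
    n_fits <- 1L
    post <- predict(model, pairs)$p_stu
    truth <- pairs$label
  } else if (scheme == "holdout") {
    idx <- withr::with_seed(seed, {
      unlist(lapply(c("STU", "DTU"), function(cl) {
        rows <- which(pairs$label == cl)
        sample(rows, size = floor(length(rows) * train_frac))
      }))
    })
    train <- pairs[idx, , drop = FALSE]
    test <- pairs[-idx, , drop = FALSE]
    if (length(unique(train$label)) < 2 || length(unique(test$label)) < 2) {
      stop_dister(paste0("holdout split left a class empty; use a ",
                         "different stratification seed."),
                  class = "dister_unfittable_error")
    }
    model <- fit_one(train)
    n_fits <- 1L
    post <- predict(model, test)$p_stu
    truth <- test$label
  } else {
    n <- nrow(pairs)
    post <- numeric(n)
    for (i in seq_len(n)) {
      model <- fit_one(pairs[-i, , drop = FALSE])
      n_fits <- n_fits + 1L
      post[i] <- predict(model, pairs[i, , drop = FALSE])$p_stu
    }
    truth <- pairs$label
  }
  scan <- scan_posteriors(post, truth, grid)
  structure(
    scan,
    scheme = scheme,
    seed = if (scheme == "holdout") seed else NA_integer_,
    n_fits = n_fits,
    chosen_threshold = best_threshold(scan),
    class = c("dister_scan", class(scan))
  )
}

#' Threshold nearest the perfect-classification corner
#'
#' Picks the grid threshold minimizing `(1 - Se)^2 + (1 - Sp)^2`, the
#' squared distance to the (Se = 1, Sp = 1) corner of the ROC plane. Ties
#' are broken toward 0.5 and then toward the smaller threshold, so the
#' choice is deterministic.
#'
#' @param scan A `dister_scan` or any tibble with `threshold`, `se`, `sp`.
#' @return The chosen threshold.
#' @export
best_threshold <- function(scan) {
  if (nrow(scan) == 0) {
    stop_dister("empty threshold scan.")
  }
  cost <- (1 - scan$se)^2 + (1 - scan$sp)^2
  cand <- which(cost <= min(cost) + 1e-12)
  d_half <- abs(scan$threshold[cand] - 0.5)
  cand <- cand[d_half <= min(d_half) + 1e-12]
  scan$threshold[min(cand)]
}

#' @export
print.dister_scan <- function(x, ...) {
  cat(sprintf("<dister_scan> scheme %s, %d thresholds, chosen %.2f\n",
              attr(x, "scheme"), nrow(x), attr(x, "chosen_threshold")))
  NextMethod()
}

#' @rdname glance.dister_model
#' @exportS3Method generics::glance
glance.dister_scan <- function(x, ...) {
  best <- x[x$threshold == attr(x, "chosen_threshold"), , drop = FALSE]
  tibble(
    scheme = attr(x, "scheme"),
    n_thresholds = nrow(x),
    n_fits = attr(x, "n_fits"),
    chosen_threshold = attr(x, "chosen_threshold"),
    se = best$se[1],
    sp = best$sp[1],
    cost = best$cost[1]
  )
}

#' Export a threshold scan as TSV
#'
#' Writes the per-threshold table (`threshold`, `se`, `sp`, `cost`),
#' suitable for ROC plotting.
#'
#' @param scan A `dister_scan`.
#' @param path Output path.
#' @return The scan, invisibly.
#' @export
write_scan <- function(scan, path) {
  readr::write_tsv(as_tibble(scan), path)
  invisible(scan)
}
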