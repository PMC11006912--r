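make_md <- function(breeds, n_per, doc_mean = 10, doc = NULL) {
  n <- sum(n_per)
  md <- tibble::tibble(
    sample_id = sprintf("H%03d", seq_len(n)),
    breed = rep(breeds, n_per))
  md$doc <- if (is.null(doc)) rep(doc_mean, n) else doc
  md$breed_group <- md$breed
  md
}

test_that("breed inclusion applies both thresholds", {
  md <- dplyr::bind_rows(
    make_md("Small", 16, doc_mean = 6),     # too few
    make_md("Shallow", 17, doc_mean = 4),   # mean DOC not > 5
    make_md("Big", 104, doc_mean = 12))     # qualifies
  md$sample_id <- sprintf("H%03d", seq_len(nrow(md)))
  sel <- select_target_breeds(md)
  expect_identical(sel$targets, "Big")
  expect_setequal(unique(sel$metadata$breed_group[sel$metadata$breed != "Big"]),
                  "Other")
  # boundary: exactly 17 samples qualifies, mean DOC exactly 5 does not
  md2 <- dplyr::bind_rows(make_md("Edge", 17, doc_mean = 5),
                          make_md("Ok", 17, doc_mean = 5.01))
  md2$sample_id <- sprintf("G%03d", seq_len(nrow(md2)))
  expect_identical(select_target_breeds(md2)$targets, "Ok")
  expect_warning(select_target_breeds(make_md("Tiny", 3)), "no breed meets")
})

test_that("count model equals normal-equations oracle; DOC handled", {
  withr::local_seed(21)
  md <- make_md(paste0("B", 1:12), rep(20, 12),
                doc = runif(240, 5, 18))
  resp <- tibble::tibble(sample_id = md$sample_id,
                         n_burden = round(500 + 10 * md$doc +
                                            rnorm(240, 0, 20)))
  fit <- fit_count_model(resp, md, "n_burden")
  # independent solve of the normal equations
  X <- model.matrix(~ breed_group + doc,
                    data.frame(breed_group = factor(md$breed_group),
                               doc = md$doc))
  beta <- solve(t(X) %*% X, t(X) %*% resp$n_burden)
  expect_equal(unname(coef(fit$fit)), unname(drop(beta)), tolerance = 1e-8)
  expect_true(fit$doc_p < 0.05)

  # constant DOC: covariate dropped, coefficients are group-mean contrasts
  md_c <- make_md(c("A", "B"), c(10, 10), doc_mean = 7)
  resp_c <- tibble::tibble(sample_id = md_c$sample_id,
                           n_burden = c(rnorm(10, 100), rnorm(10, 150)))
  expect_warning(fit_c <- fit_count_model(resp_c, md_c, "n_burden"),
                 "constant")
  mA <- mean(resp_c$n_burden[1:10]); mB <- mean(resp_c$n_burden[11:20])
  expect_equal(unname(coef(fit_c$fit)), c(mA, mB - mA), tolerance = 1e-10)
})

test_that("planted DOC effect is detected reliably", {
  withr::local_seed(90)
  hits <- 0
  for (r in 1:200) {
    doc <- runif(80, 5, 18)
    md <- make_md(c("A", "B"), c(40, 40), doc = doc)
    md$sample_id <- sprintf("H%03d", 1:80)
    resp <- tibble::tibble(sample_id = md$sample_id,
                           n_burden = 400 + 15 * doc + rnorm(80, 0, 10))
    fit <- fit_count_model(resp, md, "n_burden")
    if (fit$doc_p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("EMMEAN reduces to the group mean in balanced equal-DOC designs", {
  withr::local_seed(3)
  md <- make_md(c("A", "B", "C"), c(15, 15, 15), doc_mean = 9)
  resp <- tibble::tibble(sample_id = md$sample_id,
                         n_burden = rnorm(45, rep(c(600, 700, 800), each = 15),
                                          30))
  expect_warning(fit <- fit_count_model(resp, md, "n_burden"), "constant")
  emm <- estimate_emmeans(fit)
  raw <- tapply(resp$n_burden, md$breed_group, mean)
  expect_equal(emm$emmean, as.numeric(raw[emm$breed]), tolerance = 1e-8)
  expect_true(all(emm$ci_low <= emm$emmean & emm$emmean <= emm$ci_high))
})

test_that("EMMEANs are invariant to centering the DOC covariate", {
  withr::local_seed(4)
  md <- make_md(c("A", "B"), c(20, 20), doc = runif(40, 5, 15))
  resp <- tibble::tibble(sample_id = md$sample_id,
                         n_burden = 500 + 8 * md$doc + rnorm(40, 0, 15))
  fit <- fit_count_model(resp, md, "n_burden")
  emm <- estimate_emmeans(fit)
  md2 <- md; md2$doc <- md$doc - mean(md$doc)
  fit2 <- fit_count_model(resp, md2, "n_burden")
  emm2 <- estimate_emmeans(fit2)
  expect_equal(emm$emmean, emm2$emmean, tolerance = 1e-8)
  expect_equal(emm$se, emm2$se, tolerance = 1e-8)
})

test_that("EMMEANs agree with the emmeans package on an unbalanced design", {
  skip_if_not_installed("emmeans")
  withr::local_seed(5)
  md <- make_md(c("A", "B", "C"), c(12, 25, 18), doc = runif(55, 5, 18))
  resp <- tibble::tibble(sample_id = md$sample_id,
                         n_burden = 450 + 12 * md$doc +
                           rep(c(0, 60, 120), c(12, 25, 18)) +
                           rnorm(55, 0, 20))
  fit <- fit_count_model(resp, md, "n_burden")
  emm <- estimate_emmeans(fit)
  ref <- summary(emmeans::emmeans(fit$fit, "breed_group",
                                  at = list(doc = mean(fit$data$doc))))
  expect_equal(emm$emmean, ref$emmean, tolerance = 1e-10)
  expect_equal(emm$se, ref$SE, tolerance = 1e-10)
  expect_equal(emm$ci_low, ref$lower.CL, tolerance = 1e-10)
})

test_that("breed-share-weighted EMMEANs reproduce the fitted grand mean", {
  withr::local_seed(6)
  md <- make_md(c("A", "B", "C"), c(10, 30, 20), doc = runif(60, 5, 15))
  resp <- tibble::tibble(sample_id = md$sample_id,
                         n_burden = 500 + 9 * md$doc + rnorm(60, 0, 10))
  fit <- fit_count_model(resp, md, "n_burden")
  emm <- estimate_emmeans(fit)
  w <- table(md$breed_group)[emm$breed] / nrow(md)
  # prediction at mean DOC, weighted by breed shares, equals the mean
  # prediction of the fitted model at mean DOC
  grand <- mean(predict(fit$fit, newdata = transform(fit$data,
                                                     doc = mean(fit$data$doc))))
  expect_equal(sum(emm$emmean * as.numeric(w)), grand, tolerance = 1e-8)
})

test_that("Ne correlation: exact line, errors, CI behavior", {
  md <- make_md(c("A", "B", "C"), c(5, 5, 5), doc_mean = 10)
  ne <- tibble::tibble(breed = c("A", "B", "C"), ne = c(100, 200, 300),
                       source = "array54K")
  sb <- tibble::tibble(sample_id = md$sample_id,
                       n_burden = rep(c(10, 20, 30), each = 5))
  res <- correlate_burden_ne(sb, md, ne, responses = "n_burden")
  expect_equal(res$r, 1)
  expect_equal(res$n, 15)

  ne_const <- tibble::tibble(breed = c("A", "B", "C"), ne = 100,
                             source = "array54K")
  expect_error(correlate_burden_ne(sb, md, ne_const, responses = "n_burden"),
               "constant")
  sb_const <- tibble::tibble(sample_id = md$sample_id, n_burden = 5)
  expect_error(correlate_burden_ne(sb_const, md, ne, responses = "n_burden"),
               "constant")
  # horses of breeds without an Ne are excluded and counted
  ne_part <- ne[ne$breed != "C", ]
  sbj <- tibble::tibble(sample_id = md$sample_id,
                        n_burden = c(rnorm(5, 10), rnorm(5, 20), rnorm(5, 30)))
  res2 <- correlate_burden_ne(sbj, md, ne_part, responses = "n_burden")
  expect_equal(res2$n, 10)
  expect_equal(res2$n_excluded, 5)
})

test_that("Fisher-z CI contains r and narrows with n", {
  withr::local_seed(8)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  md <- tibble::tibble(sample_id = sprintf("H%02d", 1:30),
                       breed = "A", doc = 10, breed_group = "A")
  # direct check through cor.test-backed implementation on two sizes
  widths <- sapply(c(30, 300), function(n) {
    xx <- rnorm(n); yy <- 0.5 * xx + sqrt(1 - 0.25) * rnorm(n)
    ct <- cor.test(xx, yy)
    expect_true(ct$conf.int[1] <= ct$estimate &&
                  ct$estimate <= ct$conf.int[2])
    diff(ct$conf.int)
  })
  expect_lt(widths[2], widths[1])
})

test_that("frequency comparison is a Welch test with sane degenerate cases", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  same <- compare_frequencies(x, x)
  expect_equal(same$p, 1)
  expect_equal(same$mean_diff, 0)
  withr::local_seed(9)
  a <- rnorm(500, 0.10, 0.02)
  b <- rnorm(500, 0.12, 0.02)
  res <- compare_frequencies(a, b)
  expect_lt(res$p, 1e-6)
  expect_true(res$ci_low <= 0.02 && 0.02 <= res$ci_high)
  # one group constant still yields a finite Welch statistic
  const <- compare_frequencies(rep(0.1, 5), rnorm(50, 0.3, 0.05))
  expect_true(is.finite(const$p))
  expect_error(compare_frequencies(0.1, c(0.1, 0.2)), "at least 2")
})

test_that("Welch CI covers a planted shift at near-nominal rate", {
  withr::local_seed(14)
  cover <- 0
  for (r in 1:200) {
    a <- rnorm(200, 0.05, 0.03)
    b <- rnorm(200, 0.02, 0.01)
    res <- compare_frequencies(b, a)
    if (res$ci_low <= 0.03 && 0.03 <= res$ci_high) cover <- cover + 1
  }
  expect_gte(cover / 200, 0.9)
})
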