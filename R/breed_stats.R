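#' Select target breeds for breed-level analysis
#'
#' A breed is a target when it has at least `min_n` samples and a breed-mean
#' depth of coverage strictly above `min_mean_doc` X. All other samples are
#' pooled into the `"Other"` group.
#'
#' @param metadata Sample metadata tibble (`sample_id`, `breed`, `doc`).
#' @param min_n Minimum samples per target breed (default 17).
#' @param min_mean_doc Minimum breed-mean DOC in X (default 5, strict).
#' @return List: `targets` (character vector of target breeds) and
#'   `metadata` with an added `breed_group` column (target breed or "Other").
#' @export
select_target_breeds <- function(metadata, min_n = 17, min_mean_doc = 5) {
  stopifnot(nrow(metadata) > 0)
  by_breed <- metadata |>
    dplyr::group_by(.data$breed) |>
    dplyr::summarise(n = dplyr::n(), mean_doc = mean(.data$doc),
                     .groups = "drop")
  targets <- by_breed$breed[by_breed$n >= min_n &
                              by_breed$mean_doc > min_mean_doc]
  targets <- setdiff(targets, "Other")
  if (length(targets) == 0) {
    warning("no breed meets the inclusion criteria; all samples pooled as ",
            "\"Other\"", call. = FALSE)
  }
  metadata$breed_group <- ifelse(metadata$breed %in% targets,
                                 metadata$breed, "Other")
  list(targets = sort(targets), metadata = metadata)
}

#' Fit the per-sample count model: count ~ breed + DOC
#'
#' Ordinary least squares with treatment coding (reference level = first
#' breed group alphabetically). If DOC is (numerically) constant across
#' samples it is dropped with a warning and the model reduces to group means.
#'
#' @param responses Tibble with `sample_id` and the response column.
#' @param metadata Metadata with `sample_id`, `breed_group`, `doc`.
#' @param response Name of the response column in `responses`.
#' @return A `burden_count_fit`: the `lm` fit plus bookkeeping (response
#'   label, breed levels, whether DOC entered, the model data).
#' @export
fit_count_model <- function(responses, metadata, response = "n_burden") {
  stopifnot(response %in% names(responses),
            all(c("sample_id", "breed_group", "doc") %in% names(metadata)))
  df <- dplyr::inner_join(responses[c("sample_id", response)], metadata,
                          by = "sample_id")
  df$count <- df[[response]]
  df$breed_group <- factor(df$breed_group)
  if (nlevels(df$breed_group) < 2) {
    stop("need at least two breed groups to fit the count model",
         call. = FALSE)
  }
  doc_varies <- stats::sd(df$doc) > 1e-10
  if (!doc_varies) {
    warning("DOC is constant; covariate dropped from the count model",
            call. = FALSE)
    fit <- stats::lm(count ~ breed_group, data = df)
  } else {
    fit <- stats::lm(count ~ breed_group + doc, data = df)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("singular design: could not estimate ",
         paste(sub("^breed_group", "", bad), collapse = ", "), call. = FALSE)
  }
  doc_p <- NA_real_
  if (doc_varies) {
    doc_p <- stats::summary.lm(fit)$coefficients["doc", "Pr(>|t|)"]
  }
  structure(
    list(fit = fit, response = response, data = df,
         levels = levels(df$breed_group), has_doc = doc_varies,
         doc_p = doc_p, r_squared = stats::summary.lm(fit)$r.squared),
    class = "burden_count_fit"
  )
}

#' @export
print.burden_count_fit <- function(x, ...) {
  cat(sprintf("<burden_count_fit> %s ~ breed%s; %d samples, %d breed groups\n",
              x$response, if (x$has_doc) " + DOC" else "",
              nrow(x$data), length(x$levels)))
  invisible(x)
}

#' DOC-adjusted estimated marginal means per breed
#'
#' Predicts each breed group's mean response at a fixed reference depth of
#' coverage (by default the grand-mean DOC over the modeled samples),
#' adjusting breed comparisons for DOC. The standard error comes from the
#' linear form's variance under the coefficient covariance and the 95% CI
#' uses the t distribution on the residual degrees of freedom.
#'
#' @param fit A `burden_count_fit`.
#' @param at_doc Reference DOC in X; default = grand-mean DOC.
#' @param level Confidence level (default 0.95).
#' @return Tibble: `breed`, `response`, `emmean`, `se`, `df`, `ci_low`,
#'   `ci_high`.
#' @export
estimate_emmeans <- function(fit, at_doc = NULL, level = 0.95) {
  stopifnot(inherits(fit, "burden_count_fit"))
  if (is.null(at_doc)) at_doc <- mean(fit$data$doc)
  lv <- fit$levels
  grid <- data.frame(breed_group = factor(lv, lv), doc = at_doc)
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit$fit)),
                           grid)
  beta <- stats::coef(fit$fit)
  V <- stats::vcov(fit$fit)
  est <- unname(drop(X %*% beta))
  se <- unname(sqrt(rowSums((X %*% V) * X)))
  dfres <- stats::df.residual(fit$fit)
  tq <- stats::qt(1 - (1 - level) / 2, dfres)
  tibble::tibble(
    breed = lv, response = fit$response,
    emmean = est, se = se, df = dfres,
    ci_low = est - tq * se, ci_high = est + tq * se
  )
}

#' Correlate per-sample burden with breed effective population size
#'
#' Pairs each horse's response with its breed's published Ne estimate and
#' computes Pearson's correlation with a Fisher-z 95% confidence interval
#' (via [stats::cor.test()]); horses of breeds without an Ne for the given
#' source are excluded and counted.
#'
#' @param sample_burden Per-sample burden tibble ([per_sample_burden()]).
#' @param metadata Metadata with `sample_id` and `breed_group`.
#' @param ne_table Tibble `breed`, `ne`, `source`.
#' @param responses Response columns to correlate.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble: `response`, `source`, `r`, `p`, `ci_low`, `ci_high`, `n`,
#'   `n_excluded`.
#' @export
correlate_burden_ne <- function(sample_burden, metadata, ne_table,
                                responses = c("n_burden", "n_burden_hom",
                                              "n_lof", "n_lof_hom"),
                                conf_level = 0.95) {
  df <- dplyr::inner_join(sample_burden, metadata, by = "sample_id")
  out <- list()
  for (src in unique(ne_table$source)) {
    ne_src <- ne_table[ne_table$source == src, ]
    ne <- ne_src$ne[match(df$breed_group, ne_src$breed)]
    keep <- !is.na(ne)
    if (sum(keep) < 3) {
      stop("fewer than 3 samples have a breed Ne for source ", src,
           call. = FALSE)
    }
    if (stats::sd(ne[keep]) == 0) {
      stop("Ne is constant across paired samples for source ", src,
           "; correlation undefined", call. = FALSE)
    }
    for (resp in responses) {
      y <- df[[resp]][keep]
      if (stats::sd(y) == 0) {
        stop("response ", resp, " is constant; correlation undefined",
             call. = FALSE)
      }
      ct <- stats::cor.test(ne[keep], y, method = "pearson",
                            conf.level = conf_level)
      out[[length(out) + 1]] <- tibble::tibble(
        response = resp, source = src,
        r = unname(ct$estimate), p = ct$p.value,
        ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
        n = sum(keep), n_excluded = sum(!keep)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Compare variant-frequency distributions between two variant groups
#'
#' Welch two-sample t-test on per-variant frequencies (e.g. burden vs
#' non-burden variants), with the mean difference, its 95% CI, and the
#' medians/IQRs of both groups.
#'
#' @param freqs_burden,freqs_other Numeric vectors of per-variant
#'   frequencies; each of length >= 2.
#' @return List: `p`, `mean_diff`, `ci_low`, `ci_high`, and per-group
#'   median/IQR summaries.
#' @export
compare_frequencies <- function(freqs_burden, freqs_other) {
  if (length(freqs_burden) < 2 || length(freqs_other) < 2) {
    stop("each group needs at least 2 frequencies", call. = FALSE)
  }
  tt <- stats::t.test(freqs_other, freqs_burden)
  list(
    p = tt$p.value,
    mean_diff = unname(tt$estimate[1] - tt$estimate[2]),
    ci_low = tt$conf.int[1],
    ci_high = tt$conf.int[2],
    burden = median_iqr(freqs_burden),
    other = median_iqr(freqs_other)
  )
}
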