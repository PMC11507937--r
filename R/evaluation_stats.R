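# Inference and model evaluation: bootstrap standard errors, Wald
# z-tests with Bonferroni correction, likelihood-ratio testing of nested
# models, expected per-sequence log loss, mean absolute error against the
# empirical scenario distribution, and annotation-ranking comparison
# between models with and without microhomology terms.

#' Empirical (weighted) scenario distribution
#'
#' Weighted counts per (pair, trimming, ligation) cell, with fractional
#' assignment of multi-annotation sequences by their E-step posterior
#' weights (consistent with the latent-annotation framework), normalised
#' per observed pair.
#'
#' @param dataset an [annotate_records()] result.
#' @param params a [model_params()] used to compute E-step weights when
#'   `weights` is not supplied.
#' @param q productivity conditioning.
#' @param weights optional explicit weight vector over `dataset$amap`
#'   rows (overrides `params`).
#' @param multiplicity optional per-sequence integer weights.
#' @return an object of class `empirical_distribution`: list with
#'   `counts` (per global cell), `pair_totals`, and `p_emp` (per-cell
#'   empirical probabilities, normalised within pair).
#' @export
empirical_distribution <- function(dataset, params = NULL, q = "both",
                                   weights = NULL, multiplicity = NULL) {
  stopifnot(inherits(dataset, "annotated_dataset"))
  if (is.null(weights)) {
    if (is.null(params))
      stop("supply either `params` or explicit `weights`", call. = FALSE)
    weights <- e_step(dataset, params, q)
  }
  counts <- aggregate_counts(dataset, weights, multiplicity)
  pair_of_cell <- rep(seq_along(dataset$tables),
                      vapply(dataset$tables, function(pt) nrow(pt$cells),
                             integer(1)))
  pair_totals <- as.vector(rowsum(counts, pair_of_cell))
  p_emp <- counts / ifelse(pair_totals[pair_of_cell] > 0,
                           pair_totals[pair_of_cell], NA_real_)
  structure(list(counts = counts, pair_totals = pair_totals,
                 p_emp = p_emp, pair_of_cell = pair_of_cell),
            class = "empirical_distribution")
}

#' Expected per-sequence log loss
#'
#' Negative observed-data log-likelihood divided by the number of
#' sequences; lower is better. Evaluation freezes the supplied
#' parameters (no refitting on the evaluation data).
#'
#' @inheritParams observed_loglik
#' @return scalar log loss (natural log).
#' @export
per_sequence_log_loss <- function(dataset, params, q = "both",
                                  multiplicity = NULL) {
  n <- if (is.null(multiplicity)) dataset$n_seq else sum(multiplicity)
  -observed_loglik(dataset, params, q, multiplicity) / n
}

#' Mean absolute error against the empirical scenario distribution
#'
#' Builds the weighted [empirical_distribution()] and returns the
#' unweighted mean over all (pair, T, m) cells in the choice sets of
#' observed pairs of `|P_model - P_emp|`.
#'
#' @inheritParams empirical_distribution
#' @return scalar MAE.
#' @export
mean_absolute_error <- function(dataset, params, q = "both",
                                weights = NULL, multiplicity = NULL) {
  stopifnot(inherits(dataset, "annotated_dataset"))
  check_params(params, dataset$config)
  emp <- empirical_distribution(dataset, params, q, weights, multiplicity)
  model_p <- dataset_joint(dataset, params, q)
  observed <- emp$pair_totals[emp$pair_of_cell] > 0
  if (!any(observed)) stop("no observed pairs", call. = FALSE)
  mean(abs(model_p[observed] - emp$p_emp[observed]))
}

#' Bootstrap standard errors of the fitted parameters
#'
#' Resamples sequences with replacement `B` times and refits the model on
#' each replicate (warm-started from the full-data estimate with a
#' reduced iteration cap, which preserves the estimator since the M-step
#' objective is concave). The standard error of each parameter is the
#' sample standard deviation of its `B` estimates. Fully reproducible
#' given `seed`. A replicate failing to converge is retried once and then
#' dropped with a warning; more than 10% drops is an error.
#'
#' @param dataset an [annotate_records()] result.
#' @param fit a [fit_em()] result on the full dataset.
#' @param B number of bootstrap replicates (the reference analysis uses
#'   1000).
#' @param seed integer seed.
#' @param max_iter EM iteration cap per replicate (default 10).
#' @return named numeric vector of standard errors (trimming
#'   coefficients, then `mh_lig_count` when present), with the `B x p`
#'   estimate matrix attached as attribute `"estimates"`.
#' @export
bootstrap_se <- function(dataset, fit, B = 1000L, seed = 1L,
                         max_iter = 10L) {
  stopifnot(inherits(dataset, "annotated_dataset"),
            inherits(fit, "vdjmh_fit"), B >= 2L)
  cfg <- em_config(max_iter = max_iter)
  set.seed(seed)
  n <- dataset$n_seq
  est <- matrix(NA_real_, nrow = B,
                ncol = length(params_to_theta(fit$params)),
                dimnames = list(NULL, names(params_to_theta(fit$params))))
  dropped <- 0L
  for (b in seq_len(B)) {
    mult <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    rep_fit <- tryCatch(
      suppressWarnings(fit_em(dataset, q = fit$q, em_config = cfg,
                              ablation = fit$ablation, init = fit$params,
                              multiplicity = mult)),
      error = function(e) NULL)
    if (is.null(rep_fit))  # retry once with a fresh resample
      rep_fit <- tryCatch(
        suppressWarnings(fit_em(dataset, q = fit$q, em_config = cfg,
                                ablation = fit$ablation, init = fit$params,
                                multiplicity = tabulate(
                                  sample.int(n, n, replace = TRUE),
                                  nbins = n))),
        error = function(e) NULL)
    if (is.null(rep_fit)) {
      dropped <- dropped + 1L
      next
    }
    est[b, ] <- params_to_theta(rep_fit$params)
  }
  if (dropped > 0L)
    warning(sprintf("%d bootstrap replicate(s) dropped", dropped),
            call. = FALSE)
  if (dropped > 0.1 * B)
    stop("more than 10% of bootstrap replicates failed to converge",
         call. = FALSE)
  ses <- apply(est, 2L, stats::sd, na.rm = TRUE)
  attr(ses, "estimates") <- est
  ses
}

#' Wald z-tests with Bonferroni correction
#'
#' Tests each coefficient against zero: `z = estimate / SE`, two-sided
#' p-value from the standard normal, significance at the Bonferroni
#' threshold `alpha / (number of parameters)` (0.05 / 32 = 0.0016 for the
#' default full model).
#'
#' @param params a [model_params()] (or `vdjmh_fit`).
#' @param ses named standard errors from [bootstrap_se()].
#' @param alpha family-wise error rate (default 0.05).
#' @return an object of class `wald_report`: data.frame `parameter`,
#'   `estimate`, `se`, `z`, `p_value`, `significant`, with the threshold
#'   as attribute `"threshold"`.
#' @export
wald_report <- function(params, ses, alpha = 0.05) {
  if (inherits(params, "vdjmh_fit")) params <- params$params
  stopifnot(inherits(params, "model_params"))
  theta <- params_to_theta(params)
  if (!all(names(theta) %in% names(ses)))
    stop("`ses` does not cover all parameters", call. = FALSE)
  ses <- ses[names(theta)]
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("standard errors must be positive and finite", call. = FALSE)
  z <- theta / ses
  p <- 2 * stats::pnorm(-abs(z))
  threshold <- alpha / length(theta)
  out <- data.frame(parameter = names(theta), estimate = unname(theta),
                    se = unname(ses), z = unname(z), p_value = unname(p),
                    significant = unname(p < threshold))
  rownames(out) <- NULL
  structure(out, threshold = threshold, class = c("wald_report",
                                                  "data.frame"))
}

#' @export
print.wald_report <- function(x, ...) {
  cat(sprintf("Wald report (%d parameters, Bonferroni threshold %.4g)\n",
              nrow(x), attr(x, "threshold")))
  NextMethod()
  invisible(x)
}

#' Likelihood-ratio test of nested choice models
#'
#' `LR = 2 (loglik_full - loglik_reduced)`, compared to a chi-square
#' distribution with degrees of freedom equal to the number of extra
#' parameters in the full model (2 for the microhomology ablation: the
#' trimming and the ligation microhomology coefficients).
#'
#' @param full,reduced [fit_em()] results on the same dataset; the
#'   reduced model's terms must be a strict subset of the full model's.
#' @param dataset optional [annotate_records()] result on which to
#'   re-evaluate both log-likelihoods; defaults to the stored training
#'   log-likelihoods.
#' @return an object of class `vdjmh_lrt`: list `statistic`, `df`,
#'   `p_value`, `loglik_full`, `loglik_reduced`.
#' @export
likelihood_ratio_test <- function(full, reduced, dataset = NULL) {
  stopifnot(inherits(full, "vdjmh_fit"), inherits(reduced, "vdjmh_fit"))
  full_terms <- names(params_to_theta(full$params))
  red_terms <- names(params_to_theta(reduced$params))
  if (!all(red_terms %in% full_terms))
    stop("models are not nested: reduced model has terms absent from the full model",
         call. = FALSE)
  if (is.null(dataset)) {
    ll_f <- full$loglik; ll_r <- reduced$loglik
  } else {
    ll_f <- observed_loglik(dataset, full$params, full$q)
    ll_r <- observed_loglik(dataset, reduced$params, reduced$q)
  }
  lr <- 2 * (ll_f - ll_r)
  if (lr < -1e-6 * (1 + abs(ll_f)))
    stop(sprintf(
      "negative LR statistic (%.6g): the full model fits worse; fitting failure",
      lr), call. = FALSE)
  lr <- max(lr, 0)
  df <- length(full_terms) - length(red_terms)
  p <- if (df == 0L) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  structure(list(statistic = lr, df = df, p_value = p,
                 loglik_full = ll_f, loglik_reduced = ll_r),
            class = "vdjmh_lrt")
}

#' @export
print.vdjmh_lrt <- function(x, ...) {
  cat(sprintf("LRT: statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# argmax with deterministic tie-break: highest posterior, then lower t_v,
# lower t_j, higher m.
top_annotation_idx <- function(post, t_v, t_j, m) {
  ord <- order(-post, t_v, t_j, -m)
  ord[1L]
}

#' Compare top-ranked annotations between two models
#'
#' Restricted to sequences with at least two annotations. For each
#' sequence the top annotation under each model is found (posterior
#' argmax; ties broken by lower `t_v`, lower `t_j`, higher `m`). Reports,
#' per V-J pair, the proportion of sequences whose top annotation
#' differs, the per-sequence relative confidence (absolute difference,
#' under the full model, between the probabilities of the two models' top
#' annotations), the per-pair mean of the per-sequence average annotation
#' microhomology, and the Pearson correlation between per-pair proportion
#' and mean microhomology.
#'
#' @param dataset an [annotate_records()] result.
#' @param params_full,params_nomh the two [model_params()] (typically the
#'   full model and the microhomology ablation).
#' @param q productivity conditioning.
#' @return an object of class `ranking_comparison`: list `per_sequence`,
#'   `per_pair`, `mean_relative_confidence` (over sequences whose top
#'   annotation differs), `pearson_r`, `pearson_p`.
#' @export
compare_top_annotations <- function(dataset, params_full, params_nomh,
                                    q = "both") {
  stopifnot(inherits(dataset, "annotated_dataset"))
  if (inherits(params_full, "vdjmh_fit")) params_full <- params_full$params
  if (inherits(params_nomh, "vdjmh_fit")) params_nomh <- params_nomh$params
  check_params(params_full, dataset$config)
  check_params(params_nomh, dataset$config)

  jp_full <- dataset_joint(dataset, params_full, q)
  jp_nomh <- dataset_joint(dataset, params_nomh, q)
  am <- dataset$amap
  n_ann <- tabulate(am$seq_id, dataset$n_seq)
  multi <- which(n_ann >= 2L)
  if (length(multi) == 0L)
    stop("no sequences with multiple annotations", call. = FALSE)

  cell_tv <- unlist(lapply(dataset$tables, function(pt) pt$cells$t_v),
                    use.names = FALSE)
  cell_tj <- unlist(lapply(dataset$tables, function(pt) pt$cells$t_j),
                    use.names = FALSE)
  cell_m <- unlist(lapply(dataset$tables, function(pt) pt$cells$m),
                   use.names = FALSE)

  rows_of_seq <- split(seq_len(nrow(am)), am$seq_id)
  per_seq <- lapply(multi, function(i) {
    r <- rows_of_seq[[i]]
    g <- am$gcell[r]
    pf <- jp_full[g]; pn <- jp_nomh[g]
    if (sum(pf) <= 0 || sum(pn) <= 0) return(NULL)
    pf <- pf / sum(pf); pn <- pn / sum(pn)
    tv <- cell_tv[g]; tj <- cell_tj[g]; mm <- cell_m[g]
    i_f <- top_annotation_idx(pf, tv, tj, mm)
    i_n <- top_annotation_idx(pn, tv, tj, mm)
    data.frame(seq_id = i, pair_id = am$pair_id[r[1L]],
               differs = i_f != i_n,
               relative_confidence = abs(pf[i_f] - pf[i_n]),
               mean_annotation_mh = mean(mm))
  })
  per_seq <- do.call(rbind, per_seq)
  if (is.null(per_seq) || nrow(per_seq) == 0L)
    stop("no usable multi-annotation sequences under `q` conditioning",
         call. = FALSE)

  agg <- split(per_seq, per_seq$pair_id)
  per_pair <- do.call(rbind, lapply(agg, function(d) {
    pt <- dataset$tables[[d$pair_id[1L]]]
    data.frame(v_name = pt$pair$v$name, j_name = pt$pair$j$name,
               n_multi = nrow(d),
               prop_differing = mean(d$differs),
               mean_annotation_mh = mean(d$mean_annotation_mh))
  }))
  rownames(per_pair) <- NULL

  r <- p <- NA_real_
  if (nrow(per_pair) >= 3L &&
      stats::sd(per_pair$prop_differing) > 0 &&
      stats::sd(per_pair$mean_annotation_mh) > 0) {
    ct <- stats::cor.test(per_pair$prop_differing,
                          per_pair$mean_annotation_mh)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  mean_rc <- if (any(per_seq$differs))
    mean(per_seq$relative_confidence[per_seq$differs]) else 0
  structure(list(per_sequence = per_seq, per_pair = per_pair,
                 mean_relative_confidence = mean_rc,
                 pearson_r = r, pearson_p = p),
            class = "ranking_comparison")
}

#' @export
print.ranking_comparison <- function(x, ...) {
  cat(sprintf(
    "<ranking_comparison> %d multi-annotation sequences over %d pairs\n",
    nrow(x$per_sequence), nrow(x$per_pair)))
  cat(sprintf("  mean proportion with differing top annotation: %.4f\n",
              mean(x$per_pair$prop_differing)))
  cat(sprintf("  mean relative confidence (differing): %.4f\n",
              x$mean_relative_confidence))
  if (is.finite(x$pearson_r))
    cat(sprintf("  Pearson r (proportion vs mean MH): %.4f (p = %.3g)\n",
                x$pearson_r, x$pearson_p))
  invisible(x)
}
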