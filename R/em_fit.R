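# Expectation-maximization over latent annotation assignments.
#
# The true (trimming, ligation) annotation of each observed junction is
# latent: the E-step assigns each candidate annotation its posterior
# weight under the current parameters, and the M-step maximises the
# weight-aggregated conditional-logit log-likelihood. Because the
# aggregated objective only depends on weighted counts per (pair, T, m)
# cell, both steps run on sufficient statistics rather than on sequences,
# and the M-step objective is the standard concave conditional-logit
# likelihood (up to the per-motif-position gauge) when no productivity
# restriction is applied.

#' EM configuration
#'
#' @param max_iter maximum EM iterations (default 50).
#' @param tol_loglik relative log-likelihood change declaring
#'   convergence (default 1e-8).
#' @param tol_param maximum absolute parameter change declaring
#'   convergence (default 1e-6); both tolerances must be met.
#' @param mstep_maxit,mstep_reltol BFGS settings for the M-step.
#' @param mstep_grad_tol maximum permitted infinity-norm of the
#'   per-observation gradient at the M-step optimum.
#' @return an object of class `em_config`.
#' @export
em_config <- function(max_iter = 50L, tol_loglik = 1e-8, tol_param = 1e-6,
                      mstep_maxit = 500L, mstep_reltol = 1e-12,
                      mstep_grad_tol = 1e-5) {
  stopifnot(max_iter >= 1L, tol_loglik > 0, tol_param > 0,
            mstep_reltol > 0, mstep_grad_tol > 0)
  structure(list(max_iter = as.integer(max_iter), tol_loglik = tol_loglik,
                 tol_param = tol_param, mstep_maxit = as.integer(mstep_maxit),
                 mstep_reltol = mstep_reltol,
                 mstep_grad_tol = mstep_grad_tol),
            class = "em_config")
}

#' E-step: posterior annotation weights
#'
#' One weight per (sequence, annotation) row of the dataset's annotation
#' map, equal to [annotation_posteriors()] under the current parameters;
#' weights sum to one within each sequence.
#'
#' @param dataset an [annotate_records()] result.
#' @param params current [model_params()].
#' @param q productivity conditioning.
#' @return numeric vector aligned with `dataset$amap`.
#' @export
e_step <- function(dataset, params, q = "both") {
  stopifnot(inherits(dataset, "annotated_dataset"))
  jp <- dataset_joint(dataset, params, q)
  val <- jp[dataset$amap$gcell]
  tot <- as.vector(rowsum(val, dataset$amap$seq_id))
  if (any(tot <= 0))
    stop("degenerate posterior mass in E-step", call. = FALSE)
  val / tot[dataset$amap$seq_id]
}

# Weighted counts per global cell (the M-step sufficient statistics).
aggregate_counts <- function(dataset, weights, multiplicity = NULL) {
  w <- if (is.null(multiplicity)) weights
       else weights * multiplicity[dataset$amap$seq_id]
  agg <- rowsum(w, dataset$amap$gcell)  # one row per observed cell
  counts <- numeric(dataset$n_cells_total)
  counts[as.integer(rownames(agg))] <- agg
  counts
}

# Log-likelihood and gradient of the aggregated objective for one pair.
pair_ll_grad <- function(pt, counts, params, q, want_grad = TRUE) {
  bt <- params$beta_trim
  X <- if (length(bt)) pt$X_trim[, names(bt), drop = FALSE] else NULL
  cl <- cell_log_joint(pt, params, q)
  cells <- pt$cells
  pos <- counts > 0
  if (any(pos & !is.finite(cl$log_joint)))
    return(list(ll = -Inf, grad_t = NULL, grad_l = NULL))
  ll <- sum(counts[pos] * cl$log_joint[pos])
  if (!want_grad) return(list(ll = ll))
  N <- sum(counts)
  c_scen <- as.vector(rowsum(counts, cells$scen_id))
  j_scen <- as.vector(rowsum(cl$joint, cells$scen_id))
  grad_t <- if (is.null(X)) NULL
            else LN10 * drop(crossprod(X, c_scen - N * j_scen))
  grad_l <- NULL
  if (!is.null(params$beta_lig)) {
    ebar <- as.vector(rowsum(cl$p_lig * cells$m, cells$scen_id))
    dev <- cells$m - ebar[cells$scen_id]
    grad_l <- LN10 * (sum(counts * dev) - N * sum(cl$joint * dev))
  }
  list(ll = ll, grad_t = grad_t, grad_l = grad_l)
}

params_to_theta <- function(params) {
  c(params$beta_trim,
    if (!is.null(params$beta_lig)) c(mh_lig_count = params$beta_lig))
}

theta_to_params <- function(theta, template) {
  k <- length(template$beta_trim)
  bt <- theta[seq_len(k)]
  names(bt) <- names(template$beta_trim)
  model_params(bt, beta_lig = if (is.null(template$beta_lig)) NULL
                              else unname(theta[k + 1L]))
}

#' M-step: maximise the weighted conditional-logit objective
#'
#' Maximises `sum_i sum_a w_ia log P(T_a, m_a | pair_i, q)` over the
#' active coefficients by BFGS with analytic gradients, warm-started from
#' `init`. Errors if the optimiser stops with a per-observation gradient
#' infinity-norm above `config$mstep_grad_tol`.
#'
#' @param dataset an [annotate_records()] result.
#' @param weights E-step weight vector (rows of `dataset$amap`).
#' @param init starting [model_params()] (also fixes which terms are
#'   active).
#' @param q productivity conditioning.
#' @param config an [em_config()].
#' @param multiplicity optional per-sequence integer weights.
#' @return a [model_params()] with attributes `objective` (mean
#'   log-likelihood) and `grad_norm`.
#' @export
m_step <- function(dataset, weights, init, q = "both",
                   config = em_config(), multiplicity = NULL) {
  stopifnot(inherits(dataset, "annotated_dataset"),
            inherits(init, "model_params"))
  counts <- aggregate_counts(dataset, weights, multiplicity)
  N <- sum(counts)
  if (N <= 0) stop("zero total weight in M-step", call. = FALSE)

  # stacked evaluation: all pairs share the scenario grid, so the
  # objective and gradient reduce to a few block-matrix operations
  st <- dataset$stack
  k_trim <- length(init$beta_trim)
  has_lig <- !is.null(init$beta_lig)
  Xa <- if (k_trim) st$X_all[, names(init$beta_trim), drop = FALSE]
        else NULL
  m_cells <- st$cell_m
  scen_g <- st$cell_scen_g
  keep <- if (q == "both") NULL else st$cell_prod == q
  N_pair <- as.vector(rowsum(counts, st$pair_of_cell))
  c_scen <- numeric(st$n_pairs * st$n_scen)
  agg <- rowsum(counts, scen_g)
  c_scen[as.integer(rownames(agg))] <- agg
  obs_x <- if (k_trim) drop(crossprod(Xa[c_scen > 0, , drop = FALSE],
                                      c_scen[c_scen > 0])) else NULL
  pos <- counts > 0

  eval_all <- function(theta, want_grad) {
    bt <- theta[seq_len(k_trim)]
    bl <- if (has_lig) theta[k_trim + 1L] else NULL
    # trimming step: per-pair softmax over the shared grid
    s <- if (k_trim) LN10 * drop(Xa %*% bt)
         else numeric(st$n_pairs * st$n_scen)
    S <- matrix(s, st$n_scen, st$n_pairs)
    mx <- apply(S, 2L, max)
    E <- exp(sweep(S, 2L, mx))
    Z <- colSums(E)
    log_ptrim <- as.vector(sweep(S, 2L, mx)) -
      rep(log(Z), each = st$n_scen)
    # ligation step within each scenario's feasible set
    lw <- if (has_lig) LN10 * bl * m_cells else numeric(length(m_cells))
    wv <- exp(lw)
    totw <- as.vector(rowsum(wv, scen_g))  # every scenario has an m=0 cell
    log_plig <- lw - log(totw)[scen_g]
    log_joint <- log_ptrim[scen_g] + log_plig
    joint <- exp(log_joint)
    if (!is.null(keep)) {
      mass <- as.vector(rowsum(joint * keep, st$pair_of_cell))
      if (any(mass[N_pair > 0] <= 0))
        stop("degenerate productivity conditioning in M-step",
             call. = FALSE)
      mass[mass <= 0] <- 1  # unobserved pairs: avoid 0/0, they carry no weight
      joint <- ifelse(keep, joint, 0) / mass[st$pair_of_cell]
      log_joint <- log_joint - log(mass)[st$pair_of_cell]
      if (any(pos & !keep)) return(list(ll = -Inf, grad = NULL))
    }
    ll <- sum(counts[pos] * log_joint[pos])
    if (!want_grad) return(list(ll = ll))
    grad <- NULL
    j_scen <- as.vector(rowsum(joint * N_pair[st$pair_of_cell], scen_g))
    if (k_trim)
      grad <- LN10 * (obs_x - drop(crossprod(Xa, j_scen)))
    if (has_lig) {
      ebar <- as.vector(rowsum((wv / totw[scen_g]) * m_cells, scen_g))
      dev <- m_cells - ebar[scen_g]
      gl <- LN10 * (sum(counts * dev) -
                      sum(N_pair[st$pair_of_cell] * joint * dev))
      grad <- c(grad, gl)
    }
    list(ll = ll, grad = grad)
  }
  # optim calls fn and gr back-to-back at the same point: cache one eval
  cache <- new.env(parent = emptyenv())
  cached_eval <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta))
      return(cache$val)
    val <- eval_all(theta, TRUE)
    cache$theta <- theta
    cache$val <- val
    val
  }
  fn <- function(theta) -cached_eval(theta)$ll / N
  gr <- function(theta) -cached_eval(theta)$grad / N
  theta0 <- params_to_theta(init)
  # restart BFGS (fresh Hessian approximation) until the gradient
  # criterion is met; each restart tightens reltol so a warm start that
  # satisfies the objective-change test but not the gradient test still
  # makes progress. The objective is smooth and, without productivity
  # restriction, concave, so restarts converge quickly.
  opt <- list(par = theta0)
  gnorm <- Inf
  reltol <- config$mstep_reltol
  for (attempt in seq_len(5L)) {
    opt <- stats::optim(opt$par, fn, gr, method = "BFGS",
                        control = list(maxit = config$mstep_maxit,
                                       reltol = reltol))
    gnorm <- max(abs(gr(opt$par)))
    if (gnorm <= config$mstep_grad_tol) break
    reltol <- max(reltol * 1e-3, 1e-15)
  }
  if (gnorm > config$mstep_grad_tol)
    stop(sprintf(
      "M-step did not converge: |grad|_inf = %.3e (> %.1e), optim code %d after %d evals",
      gnorm, config$mstep_grad_tol, opt$convergence, opt$counts[1]),
      call. = FALSE)
  out <- theta_to_params(opt$par, init)
  attr(out, "objective") <- -opt$value
  attr(out, "grad_norm") <- gnorm
  out
}

#' Fit the choice model by EM
#'
#' Alternates [e_step()] and [m_step()] from all-zero parameters (the
#' uniform model, making results deterministic) until both the relative
#' log-likelihood change and the maximum absolute parameter change fall
#' below their tolerances, or `max_iter` is reached (warning; the
#' best-so-far result is returned flagged unconverged). The observed-data
#' log-likelihood is checked to be non-decreasing across iterations
#' within a small slack.
#'
#' @param dataset an [annotate_records()] result.
#' @param q productivity conditioning used for fitting.
#' @param em_config an [em_config()].
#' @param ablation term groups to drop structurally, subset of
#'   `c("mh_trim", "mh_lig", "motif", "base_5p", "base_3p")`.
#' @param init optional warm-start [model_params()] (overrides the
#'   all-zero initialisation; must match the ablation).
#' @param multiplicity optional per-sequence integer weights
#'   (bootstrap resampling).
#' @return an object of class `vdjmh_fit`: `params`, `config`, `q`,
#'   `ablation`, `loglik`, `em_trace` (per-iteration log-likelihood and
#'   maximum parameter change), `converged`, `n_iter`.
#' @export
fit_em <- function(dataset, q = "both", em_config = vdjmh::em_config(),
                   ablation = character(), init = NULL,
                   multiplicity = NULL) {
  stopifnot(inherits(dataset, "annotated_dataset"))
  q <- match.arg(q, c("both", "productive", "nonproductive"))
  stopifnot(all(ablation %in% ablation_groups))
  params <- if (is.null(init)) zero_params(dataset$config, ablation)
            else check_params(init, dataset$config)
  ll_prev <- observed_loglik(dataset, params, q, multiplicity)
  trace <- vector("list", em_config$max_iter)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(em_config$max_iter)) {
    w <- e_step(dataset, params, q)
    new_params <- m_step(dataset, w, params, q, em_config, multiplicity)
    dpar <- max(abs(params_to_theta(new_params) - params_to_theta(params)))
    params <- new_params
    ll <- observed_loglik(dataset, params, q, multiplicity)
    if (ll < ll_prev - 1e-6 * (1 + abs(ll_prev)))
      warning(sprintf(
        "EM log-likelihood decreased at iteration %d (%.8g -> %.8g)",
        it, ll_prev, ll), call. = FALSE)
    trace[[it]] <- data.frame(iteration = it, loglik = ll,
                              max_param_change = dpar)
    rel <- abs(ll - ll_prev) / (abs(ll_prev) + 1e-12)
    if (rel < em_config$tol_loglik && dpar < em_config$tol_param) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  if (!converged)
    warning(sprintf("EM did not meet both tolerances within %d iterations",
                    em_config$max_iter), call. = FALSE)
  structure(
    list(params = params, config = dataset$config, q = q,
         ablation = ablation,
         loglik = trace[[it]]$loglik,
         em_trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
         converged = converged, n_iter = it),
    class = "vdjmh_fit")
}

#' @export
print.vdjmh_fit <- function(x, ...) {
  cat(sprintf(
    "<vdjmh_fit> %d parameter(s), log-likelihood %.4f, %d EM iteration(s)%s\n",
    length(x$params$beta_trim) + !is.null(x$params$beta_lig),
    x$loglik, x$n_iter, if (x$converged) "" else " (unconverged)"))
  if (length(x$ablation))
    cat("  ablated:", paste(x$ablation, collapse = ", "), "\n")
  mh <- c(trimming = unname(x$params$beta_trim["mh_trim_avg"]),
          ligation = if (!is.null(x$params$beta_lig)) x$params$beta_lig)
  mh <- mh[!is.na(mh)]
  if (length(mh))
    cat("  microhomology coefficients (log10-odds):",
        paste(sprintf("%s %.4f", names(mh), mh), collapse = ", "), "\n")
  invisible(x)
}
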