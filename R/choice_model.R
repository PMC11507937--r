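# Two-step conditional-logit choice model of trimming and ligation.
#
# Step 1 chooses a trimming scenario T over the full scenario grid with
# probability proportional to 10^(x(T) . beta_trim); step 2 chooses a
# ligation scenario m among the feasible microhomology counts for T with
# probability proportional to 10^(beta_lig . m). All coefficients are on
# the log10-odds scale, so a parameter is directly the change in the
# log10 odds of a scenario per unit change of its feature. Productivity
# conditioning, when requested, restricts the joint distribution to the
# scenarios of the requested class and renormalises.

#' Model parameters
#'
#' @param beta_trim named numeric vector of trimming-step coefficients;
#'   names must be a subset of `trim_feature_names(config)`. Ablated term
#'   groups are structurally absent, not zero.
#' @param beta_lig scalar ligation coefficient, or `NULL` when the
#'   ligation step is ablated (uniform over feasible counts).
#' @return an object of class `model_params` (scale tag `"log10-odds"`).
#' @export
model_params <- function(beta_trim, beta_lig = NULL) {
  if (!is.numeric(beta_trim) || is.null(names(beta_trim)) ||
      any(!nzchar(names(beta_trim))))
    stop("`beta_trim` must be a named numeric vector", call. = FALSE)
  if (any(!is.finite(beta_trim)))
    stop("`beta_trim` must be finite", call. = FALSE)
  if (!is.null(beta_lig)) {
    if (length(beta_lig) != 1L || !is.finite(beta_lig))
      stop("`beta_lig` must be a finite scalar or NULL", call. = FALSE)
    beta_lig <- as.numeric(beta_lig)
  }
  structure(list(beta_trim = beta_trim, beta_lig = beta_lig,
                 scale = "log10-odds"),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %d trimming coefficient(s), ligation %s (log10-odds)\n",
              length(x$beta_trim),
              if (is.null(x$beta_lig)) "absent" else sprintf("%.4f", x$beta_lig)))
  invisible(x)
}

ablation_groups <- c("mh_trim", "mh_lig", "motif", "base_5p", "base_3p")

group_of_feature <- function(names) {
  out <- rep(NA_character_, length(names))
  out[names == "mh_trim_avg"] <- "mh_trim"
  out[names == "mh_lig_count"] <- "mh_lig"
  out[grepl("_motif_", names)] <- "motif"
  out[grepl("_5p_(at|gc)_count$", names)] <- "base_5p"
  out[grepl("_3p_(at|gc)_count$", names)] <- "base_3p"
  out
}

#' All-zero parameters, optionally with term groups ablated
#'
#' @param config a [feature_config()].
#' @param ablation subset of
#'   `c("mh_trim", "mh_lig", "motif", "base_5p", "base_3p")` to drop
#'   structurally.
#' @return a [model_params()] object.
#' @export
zero_params <- function(config = feature_config(), ablation = character()) {
  stopifnot(all(ablation %in% ablation_groups))
  tn <- trim_feature_names(config)
  tn <- tn[!(group_of_feature(tn) %in% ablation)]
  model_params(stats::setNames(numeric(length(tn)), tn),
               beta_lig = if ("mh_lig" %in% ablation) NULL else 0)
}

check_params <- function(params, config) {
  stopifnot(inherits(params, "model_params"))
  unknown <- setdiff(names(params$beta_trim), trim_feature_names(config))
  if (length(unknown))
    stop(sprintf("beta_trim name(s) not in feature configuration: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  invisible(params)
}

# log10 softmax with max-shift; returns probabilities
softmax10 <- function(s) {
  e <- exp(LN10 * (s - max(s)))
  e / sum(e)
}

# Per-cell natural-log joint probabilities for a pair table, with
# optional productivity restriction. Returns list(log_joint, p_trim,
# p_lig, joint) where joint is the (restricted, renormalised) probability
# vector over cells.
cell_log_joint <- function(pt, params, q = "both") {
  bt <- params$beta_trim
  s <- if (length(bt)) drop(pt$X_trim[, names(bt), drop = FALSE] %*% bt)
       else numeric(nrow(pt$grid))
  p_trim <- softmax10(s)
  cells <- pt$cells
  if (is.null(params$beta_lig)) {
    lw <- numeric(nrow(cells))
  } else {
    lw <- LN10 * params$beta_lig * cells$m
  }
  w <- exp(lw)  # m <= m_cap keeps this well within range
  tot <- as.vector(rowsum(w, cells$scen_id))  # scenarios all have an m = 0 cell
  log_plig <- lw - log(tot)[cells$scen_id]
  log_joint <- log(p_trim)[cells$scen_id] + log_plig
  joint <- exp(log_joint)
  if (q != "both") {
    keep <- cells$productivity == q
    mass <- sum(joint[keep])
    if (mass <= 0)
      stop(sprintf("degenerate conditioning: no probability mass on %s scenarios",
                   q), call. = FALSE)
    joint <- ifelse(keep, joint / mass, 0)
    log_joint <- ifelse(keep, log_joint - log(mass), -Inf)
  }
  list(log_joint = log_joint, joint = joint, p_trim = p_trim,
       p_lig = exp(log_plig))
}

#' Trimming-scenario choice probabilities
#'
#' `P(T | S) = 10^(x(T) . beta_trim)` normalised over the full scenario
#' grid (289 scenarios at the default bounds), regardless of which
#' scenarios can explain any particular junction.
#'
#' @param pair a [gene_pair()] or a prebuilt [build_pair_table()].
#' @param params a [model_params()].
#' @param config a [feature_config()] (ignored when `pair` is a table).
#' @return data.frame with `t_v`, `t_j`, `prob`, summing to one.
#' @export
trim_probabilities <- function(pair, params, config = feature_config()) {
  pt <- if (inherits(pair, "pair_table")) pair else build_pair_table(pair, config)
  check_params(params, pt$config)
  bt <- params$beta_trim
  s <- if (length(bt)) drop(pt$X_trim[, names(bt), drop = FALSE] %*% bt)
       else numeric(nrow(pt$grid))
  data.frame(t_v = pt$grid$t_v, t_j = pt$grid$t_j, prob = softmax10(s))
}

#' Ligation-scenario choice probabilities
#'
#' `P(m | T, S) = 10^(beta_lig . m)` normalised over the feasible
#' microhomology counts of the trimming scenario. An absent (`NULL`)
#' `beta_lig` yields the uniform distribution over feasible counts.
#'
#' @param pair a [gene_pair()].
#' @param t_v,t_j trimming scenario.
#' @param params a [model_params()].
#' @param m_cap maximum microhomology considered.
#' @return data.frame with `m`, `prob`, summing to one.
#' @export
ligation_probabilities <- function(pair, t_v, t_j, params, m_cap = 10L) {
  ms <- feasible_ligations(pair, t_v, t_j, m_cap)
  w <- if (is.null(params$beta_lig)) rep(1, length(ms))
       else 10^(params$beta_lig * ms)
  data.frame(m = ms, prob = w / sum(w))
}

#' Joint probability of a trimming and ligation scenario
#'
#' Product of the two step probabilities; when `q` names a single
#' productivity class the joint distribution is restricted to scenarios
#' of that class and renormalised.
#'
#' @param pair a [gene_pair()] or [build_pair_table()].
#' @param t_v,t_j,m the annotation.
#' @param params a [model_params()].
#' @param q `"both"`, `"productive"` or `"nonproductive"`.
#' @param config a [feature_config()] (ignored when `pair` is a table).
#' @return numeric probability.
#' @export
joint_probability <- function(pair, t_v, t_j, m, params, q = "both",
                              config = feature_config()) {
  pt <- if (inherits(pair, "pair_table")) pair else build_pair_table(pair, config)
  check_params(params, pt$config)
  q <- match.arg(q, c("both", "productive", "nonproductive"))
  hit <- which(pt$cells$t_v == t_v & pt$cells$t_j == t_j & pt$cells$m == m)
  if (length(hit) != 1L)
    stop(sprintf("annotation (t_v=%s, t_j=%s, m=%s) is not feasible for %s/%s",
                 t_v, t_j, m, pt$pair$v$name, pt$pair$j$name), call. = FALSE)
  cell_log_joint(pt, params, q)$joint[hit]
}

#' Posterior weights over an annotation set
#'
#' Each annotation of an observed junction is weighted by its joint
#' scenario probability under the model, normalised within the set.
#'
#' @param aset an [enumerate_annotations()] result.
#' @param params a [model_params()].
#' @param q productivity conditioning.
#' @param config a [feature_config()].
#' @return data.frame `t_v`, `t_j`, `m`, `posterior` summing to one.
#' @export
annotation_posteriors <- function(aset, params, q = "both",
                                  config = feature_config()) {
  stopifnot(inherits(aset, "annotation_set"))
  pt <- build_pair_table(aset$pair, config)
  check_params(params, config)
  q <- match.arg(q, c("both", "productive", "nonproductive"))
  jp <- cell_log_joint(pt, params, q)$joint
  key_cells <- paste(pt$cells$t_v, pt$cells$t_j, pt$cells$m)
  idx <- match(paste(aset$annotations$t_v, aset$annotations$t_j,
                     aset$annotations$m), key_cells)
  if (anyNA(idx))
    stop("annotation set contains cells outside the configured scenario space",
         call. = FALSE)
  w <- jp[idx]
  if (sum(w) <= 0)
    stop("all annotations have zero probability mass under `q` conditioning",
         call. = FALSE)
  out <- aset$annotations
  out$posterior <- w / sum(w)
  out
}

# Internal: per-cell joint probability vectors for every pair table of a
# dataset, concatenated in global-cell order.
dataset_joint <- function(dataset, params, q) {
  unlist(lapply(dataset$tables, function(pt)
    cell_log_joint(pt, params, q)$joint), use.names = FALSE)
}

#' Observed-data log-likelihood
#'
#' Sum over sequences of the log of the total joint probability of the
#' sequence's annotation set (natural log).
#'
#' @param dataset an [annotate_records()] result.
#' @param params a [model_params()].
#' @param q productivity conditioning.
#' @param multiplicity optional per-sequence integer weights (bootstrap
#'   resampling); defaults to one per sequence.
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(dataset, params, q = "both",
                            multiplicity = NULL) {
  stopifnot(inherits(dataset, "annotated_dataset"))
  check_params(params, dataset$config)
  q <- match.arg(q, c("both", "productive", "nonproductive"))
  jp <- dataset_joint(dataset, params, q)
  val <- jp[dataset$amap$gcell]
  tot <- as.vector(rowsum(val, dataset$amap$seq_id))
  if (any(tot <= 0))
    stop(sprintf("%d sequence(s) have zero total probability mass",
                 sum(tot <= 0)), call. = FALSE)
  if (is.null(multiplicity)) sum(log(tot))
  else sum(multiplicity * log(tot))
}
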