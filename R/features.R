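# Covariates of the trimming and ligation choice models.
#
# Each trimming scenario is scored from, per gene: a one-hot "trimming
# motif" around the trim site (by default 1 retained + 2 removed
# positions, i.e. a three-nucleotide window), GC/AT base counts beyond the
# motif on each side, and the average microhomology available between the
# two trimmed sequences. The ligation step has a single covariate: the
# number of microhomologous nucleotides used in the join.

#' Feature configuration
#'
#' @param window_5p retained-side motif positions (default 1).
#' @param window_3p removed-side motif positions (default 2). The default
#'   split covers a three-nucleotide window around each trimming site.
#' @param include_5p_AT also count AT nucleotides on the retained side
#'   beyond the motif (off by default).
#' @param m_cap maximum microhomology count considered (default 10, a
#'   safe superset of the 1-4 nt stretches typical of germline genes).
#' @param trim_bounds inclusive trim-amount bounds for both genes;
#'   default `c(-2, 14)`, a 17 x 17 = 289-scenario grid.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(window_5p = 1L, window_3p = 2L,
                           include_5p_AT = FALSE, m_cap = 10L,
                           trim_bounds = c(-2L, 14L)) {
  window_5p <- assert_scalar_int(window_5p, "window_5p", 0L)
  window_3p <- assert_scalar_int(window_3p, "window_3p", 0L)
  m_cap <- assert_scalar_int(m_cap, "m_cap", 0L)
  stopifnot(length(trim_bounds) == 2L, trim_bounds[1] <= trim_bounds[2])
  trim_bounds <- as.integer(trim_bounds)
  if (trim_bounds[1] < -2L)
    stop("trim_bounds cannot extend below -2 (full P-extension)", call. = FALSE)
  structure(list(window_5p = window_5p, window_3p = window_3p,
                 include_5p_AT = isTRUE(include_5p_AT), m_cap = m_cap,
                 trim_bounds = trim_bounds),
            class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  cat(sprintf(
    "<feature_config> motif %d+%d, 5' AT %s, m_cap %d, trims [%d, %d]\n",
    x$window_5p, x$window_3p, if (x$include_5p_AT) "on" else "off",
    x$m_cap, x$trim_bounds[1], x$trim_bounds[2]))
  invisible(x)
}

motif_positions <- function(config) {
  c(if (config$window_5p > 0) -seq.int(config$window_5p, 1L),
    if (config$window_3p > 0) seq_len(config$window_3p))
}

gene_feature_names <- function(gene_tag, config) {
  bases <- c("A", "C", "G", "T")
  motif <- as.vector(t(outer(motif_positions(config), bases,
                             function(p, b) sprintf("%s_motif_p%d_%s",
                                                    gene_tag, p, b))))
  counts <- c(if (config$include_5p_AT) sprintf("%s_5p_at_count", gene_tag),
              sprintf("%s_5p_gc_count", gene_tag),
              sprintf("%s_3p_at_count", gene_tag),
              sprintf("%s_3p_gc_count", gene_tag))
  c(motif, counts)
}

#' Feature labels implied by a configuration
#'
#' Deterministic, stable ordering: V motif block, V base counts, J motif
#' block, J base counts, the average-microhomology trimming covariate,
#' and the ligation microhomology covariate. The default configuration
#' yields 32 labels.
#'
#' @param config a [feature_config()].
#' @return character vector of labels.
#' @export
feature_names <- function(config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  c(gene_feature_names("v", config), gene_feature_names("j", config),
    "mh_trim_avg", "mh_lig_count")
}

#' Labels of the trimming-step features (everything except `mh_lig_count`)
#' @param config a [feature_config()].
#' @return character vector.
#' @export
trim_feature_names <- function(config = feature_config()) {
  setdiff(feature_names(config), "mh_lig_count")
}

# Per-gene trimming features for every trim value, in trimming
# orientation (V as-is; J reverse-complemented so its trimmed end is
# rightmost). Returns a length(t_vals) x (4 * motif positions + counts)
# matrix. Motif one-hots are read from the P-extended sequence; positions
# falling outside it contribute all-zero one-hots and are excluded from
# the base counts.
gene_trim_feature_matrix <- function(gene, t_vals, config) {
  oriented <- if (gene$end == "V_3prime") gene$extended_sequence
              else revcomp(gene$extended_sequence)
  L2 <- nchar(oriented)
  L <- L2 - 2L
  chars <- strsplit(oriented, "", fixed = TRUE)[[1]]
  gc <- cumsum(chars %in% c("G", "C"))
  at <- cumsum(chars %in% c("A", "T"))
  cum_gc <- function(lo, hi) { # counts in [lo, hi] clamped to [1, L2]
    lo <- pmax(lo, 1L); hi <- pmin(hi, L2)
    ifelse(hi < lo, 0L, gc[hi] - c(0L, gc)[lo])
  }
  cum_at <- function(lo, hi) {
    lo <- pmax(lo, 1L); hi <- pmin(hi, L2)
    ifelse(hi < lo, 0L, at[hi] - c(0L, at)[lo])
  }
  pos <- motif_positions(config)
  nms <- gene_feature_names(if (gene$end == "V_3prime") "v" else "j", config)
  out <- matrix(0, nrow = length(t_vals), ncol = length(nms),
                dimnames = list(NULL, nms))
  r <- L - t_vals  # index of the last retained nucleotide in oriented coords
  if (any(r < 0L | r > L2))
    stop("trim values outside the available sequence", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(pos)) {
    p <- pos[k]
    idx <- if (p < 0) r + p + 1L else r + p  # absolute oriented position
    inside <- idx >= 1L & idx <= L2
    b <- rep(NA_character_, length(t_vals))
    b[inside] <- chars[idx[inside]]
    for (bb in bases)
      out[, 4L * (k - 1L) + match(bb, bases)] <- as.numeric(!is.na(b) & b == bb)
  }
  off <- 4L * length(pos)
  w5 <- config$window_5p; w3 <- config$window_3p
  col <- off
  if (config$include_5p_AT) {
    col <- col + 1L
    out[, col] <- cum_at(rep(1L, length(r)), r - w5)
  }
  out[, col + 1L] <- cum_gc(rep(1L, length(r)), r - w5)
  out[, col + 2L] <- cum_at(r + w3 + 1L, rep(L2, length(r)))
  out[, col + 3L] <- cum_gc(r + w3 + 1L, rep(L2, length(r)))
  out
}

# Design matrix over the full trimming-scenario grid of a pair:
# n_scenarios x length(trim_feature_names(config)). `avg_mh` is the
# per-scenario average microhomology (computed by the scenario-space
# layer and passed in to avoid recomputation).
trim_design_matrix <- function(pair, config, avg_mh, grid) {
  vfeat <- gene_trim_feature_matrix(pair$v, sort(unique(grid$t_v)), config)
  jfeat <- gene_trim_feature_matrix(pair$j, sort(unique(grid$t_j)), config)
  tv_vals <- sort(unique(grid$t_v)); tj_vals <- sort(unique(grid$t_j))
  X <- cbind(vfeat[match(grid$t_v, tv_vals), , drop = FALSE],
             jfeat[match(grid$t_j, tj_vals), , drop = FALSE],
             mh_trim_avg = avg_mh)
  stopifnot(identical(colnames(X), trim_feature_names(config)))
  X
}

#' Trimming-step feature vector for one scenario
#'
#' Concatenates, for each gene in its trimming orientation, the motif
#' one-hots around the trim site and the GC/AT base counts beyond the
#' motif, then appends the average microhomology available under the
#' trimming scenario.
#'
#' @param pair a [gene_pair()].
#' @param t_v,t_j trim amounts.
#' @param config a [feature_config()].
#' @return named numeric vector with labels `trim_feature_names(config)`.
#' @export
trimming_feature_vector <- function(pair, t_v, t_j,
                                    config = feature_config()) {
  t_v <- assert_scalar_int(t_v, "t_v", config$trim_bounds[1],
                           config$trim_bounds[2])
  t_j <- assert_scalar_int(t_j, "t_j", config$trim_bounds[1],
                           config$trim_bounds[2])
  grid <- data.frame(t_v = t_v, t_j = t_j)
  amh <- average_mh(pair, t_v, t_j, m_cap = config$m_cap)
  drop(trim_design_matrix(pair, config, amh, grid)[1L, ])
}

#' Ligation-step feature of an annotation
#'
#' The single ligation covariate: the number of microhomologous
#' nucleotides appearing (counted once) in the joined sequence.
#'
#' @param m microhomology count (or an annotation row with an `m` field).
#' @return numeric.
#' @export
ligation_feature <- function(m) {
  if (is.list(m)) m <- m$m
  as.numeric(m)
}
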