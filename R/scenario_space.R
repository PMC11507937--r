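# Scenario space: feasible ligations, average microhomology, exhaustive
# enumeration of microhomology-adapted annotations, record filters, and
# germline microhomology summaries.
#
# A "trimming scenario" is a pair (t_v, t_j) of trim amounts; a "ligation
# scenario" is the number m of microhomologous nucleotides shared (counted
# once) in the joined sequence. Microhomology is top-strand identity
# between the trimmed V suffix and the trimmed J prefix; the
# double-stranded complementarity of the overhangs reduces to identity in
# top-strand coordinates.

trim_grid <- function(trim_bounds) {
  vals <- seq.int(trim_bounds[1], trim_bounds[2])
  expand.grid(t_v = vals, t_j = vals, KEEP.OUT.ATTRS = FALSE)
}

#' Feasible ligation scenarios for a trimming scenario
#'
#' The blunt join `m = 0` is always feasible; `m >= 1` is feasible iff the
#' last `m` nucleotides of the trimmed V equal the first `m` of the
#' trimmed J, bounded by `m_cap` and both trimmed lengths.
#'
#' @param pair a [gene_pair()].
#' @param t_v,t_j trim amounts.
#' @param m_cap maximum microhomology considered.
#' @return ascending integer vector of feasible `m` values.
#' @examples
#' v <- germline_gene("Vt", "CATTGA", end = "V_3prime")
#' j <- germline_gene("Jt", "GATCAC", end = "J_5prime")
#' feasible_ligations(gene_pair(v, j), 0, 0)  # c(0, 2)
#' @export
feasible_ligations <- function(pair, t_v, t_j, m_cap = 10L) {
  stopifnot(inherits(pair, "gene_pair"))
  m_cap <- assert_scalar_int(m_cap, "m_cap", 0L)
  vtr <- trimmed_sequence(pair$v, t_v)
  jtr <- trimmed_sequence(pair$j, t_j)
  nv <- nchar(vtr); nj <- nchar(jtr)
  top <- min(m_cap, nv, nj)
  ms <- 0L
  if (top >= 1L) {
    cand <- seq_len(top)
    ok <- substring(vtr, nv - cand + 1L, nv) == substring(jtr, 1L, cand)
    ms <- c(0L, cand[ok])
  }
  ms
}

#' Average microhomology available under a trimming scenario
#'
#' Arithmetic mean of [feasible_ligations()] (the blunt `m = 0` scenario
#' included). This is the trimming-step microhomology covariate.
#'
#' @inheritParams feasible_ligations
#' @return numeric.
#' @export
average_mh <- function(pair, t_v, t_j, m_cap = 10L) {
  mean(feasible_ligations(pair, t_v, t_j, m_cap))
}

#' Precomputed scenario table for a gene pair
#'
#' Enumerates every joint (trimming, ligation) outcome of a pair over the
#' configured trim grid: one row per feasible `(t_v, t_j, m)` cell, with
#' the merged junction it produces and its productivity label. Also
#' carries the trimming design matrix over the full scenario grid and a
#' junction-to-cell lookup used to annotate observed sequences. This is
#' the workhorse structure shared by the model, the EM fitter and the
#' simulator.
#'
#' @param pair a [gene_pair()].
#' @param config a [feature_config()].
#' @return an object of class `pair_table`.
#' @export
build_pair_table <- function(pair, config = feature_config()) {
  stopifnot(inherits(pair, "gene_pair"), inherits(config, "feature_config"))
  grid <- trim_grid(config$trim_bounds)
  tv_vals <- seq.int(config$trim_bounds[1], config$trim_bounds[2])
  tj_vals <- tv_vals
  v_tr <- vapply(tv_vals, function(t) trimmed_sequence(pair$v, t), character(1))
  j_tr <- vapply(tj_vals, function(t) trimmed_sequence(pair$j, t), character(1))
  iv <- match(grid$t_v, tv_vals); ij <- match(grid$t_j, tj_vals)
  vg <- v_tr[iv]; jg <- j_tr[ij]
  nv <- nchar(vg); nj <- nchar(jg)
  n_scen <- nrow(grid)

  # feasible m per scenario, vectorised over the grid one m at a time
  scen_id <- seq_len(n_scen)
  cell_scen <- scen_id          # m = 0 cells
  cell_m <- integer(n_scen)
  for (m in seq_len(config$m_cap)) {
    can <- nv >= m & nj >= m
    hit <- can & substring(vg, nv - m + 1L, nv) == substring(jg, 1L, m)
    if (any(hit)) {
      cell_scen <- c(cell_scen, scen_id[hit])
      cell_m <- c(cell_m, rep.int(m, sum(hit)))
    }
  }
  ord <- order(cell_scen, cell_m)
  cell_scen <- cell_scen[ord]; cell_m <- cell_m[ord]

  junction <- paste0(vg[cell_scen], substring(jg[cell_scen], cell_m + 1L))
  net_change <- -(grid$t_v[cell_scen] + grid$t_j[cell_scen] + cell_m)
  prod <- vapply(seq_along(junction), function(i)
    productivity_of_junction(junction[i], nv[cell_scen[i]], net_change[i],
                             pair$v$frame_offset), character(1))

  n_lig <- tabulate(cell_scen, nbins = n_scen)
  avg_mh <- as.vector(rowsum(as.numeric(cell_m), cell_scen)) / n_lig
  X <- trim_design_matrix(pair, config, avg_mh, grid)

  cells <- data.frame(scen_id = cell_scen,
                      t_v = grid$t_v[cell_scen], t_j = grid$t_j[cell_scen],
                      m = cell_m, junction = junction,
                      productivity = prod, stringsAsFactors = FALSE)
  structure(
    list(pair = pair, config = config, grid = grid, cells = cells,
         avg_mh = avg_mh, n_lig = n_lig, X_trim = X,
         junction_index = split(seq_len(nrow(cells)), cells$junction)),
    class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("<pair_table> %s / %s: %d scenarios, %d joint cells\n",
              x$pair$v$name, x$pair$j$name, nrow(x$grid), nrow(x$cells)))
  invisible(x)
}

#' Enumerate all microhomology-adapted annotations of a junction
#'
#' For every trimming scenario in bounds the overlap is length-forced:
#' `m = len(trimmed V) + len(trimmed J) - len(x)`. The annotation
#' `(t_v, t_j, m)` is included iff `0 <= m <= m_cap`, the last `m`
#' nucleotides of the trimmed V equal the first `m` of the trimmed J, and
#' the merge (overlap counted once) reproduces `x` exactly. Unlike
#' annotation tools that assign shared nucleotides to a single gene, this
#' enumeration includes every microhomology-bearing explanation.
#'
#' @param x observed zero-insertion junction string over `{A,C,G,T}`.
#' @param pair a [gene_pair()].
#' @param trim_bounds inclusive trim bounds (default `c(-2, 14)`).
#' @param m_cap maximum microhomology considered.
#' @return an object of class `annotation_set`: list with `sequence`,
#'   `pair`, and `annotations` (data.frame `t_v`, `t_j`, `m`).
#' @export
enumerate_annotations <- function(x, pair, trim_bounds = c(-2L, 14L),
                                  m_cap = 10L) {
  stopifnot(inherits(pair, "gene_pair"))
  x <- toupper(x)
  if (length(x) != 1L || !nzchar(x) || !is_dna(x))
    stop("junction must be a non-empty string over {A,C,G,T}", call. = FALSE)
  grid <- trim_grid(as.integer(trim_bounds))
  tv_vals <- seq.int(trim_bounds[1], trim_bounds[2])
  v_tr <- vapply(tv_vals, function(t) trimmed_sequence(pair$v, t), character(1))
  j_tr <- vapply(tv_vals, function(t) trimmed_sequence(pair$j, t), character(1))
  vg <- v_tr[match(grid$t_v, tv_vals)]; jg <- j_tr[match(grid$t_j, tv_vals)]
  nv <- nchar(vg); nj <- nchar(jg)
  m <- nv + nj - nchar(x)
  cand <- which(m >= 0L & m <= m_cap & m <= nv & m <= nj)
  keep <- cand[substring(vg[cand], nv[cand] - m[cand] + 1L, nv[cand]) ==
                 substring(jg[cand], 1L, m[cand]) &
               paste0(vg[cand], substring(jg[cand], m[cand] + 1L)) == x]
  if (length(keep) == 0L) {
    cnd <- structure(
      class = c("vdjmh_unexplainable", "error", "condition"),
      list(message = sprintf(
             "unexplainable junction for pair %s/%s: %s",
             pair$v$name, pair$j$name, x),
           call = sys.call(-1), pair = pair, sequence = x))
    stop(cnd)
  }
  ann <- data.frame(t_v = grid$t_v[keep], t_j = grid$t_j[keep],
                    m = as.integer(m[keep]))
  ann <- ann[order(ann$t_v, ann$t_j, ann$m), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(sequence = x, pair = pair, annotations = ann),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s (%s/%s): %d annotation(s)\n",
              x$sequence, x$pair$v$name, x$pair$j$name, nrow(x$annotations)))
  print(x$annotations)
  invisible(x)
}

#' Filter repertoire records for the zero-insertion analysis
#'
#' Keeps records with zero N-insertions, productivity in `q_keep`, and at
#' least one annotation whose trims are both at most `max_trim` (deeper
#' trimming is uncommon and may reflect a different mechanism). Counts
#' removed per criterion are attached as attribute `"filter_log"`.
#'
#' @param records data.frame with columns `sequence`, `v_gene`, `j_gene`,
#'   `productivity` (`"productive"`/`"nonproductive"`), `n_insertions`.
#' @param panel a [germline_panel()] resolving the gene calls.
#' @param q_keep productivity classes to keep.
#' @param max_trim maximum nucleotides trimmed from either gene.
#' @param m_cap maximum microhomology considered when testing
#'   explainability.
#' @return the filtered data.frame (possibly empty, with a warning).
#' @export
filter_records <- function(records, panel,
                           q_keep = c("productive", "nonproductive"),
                           max_trim = 14L, m_cap = 10L) {
  stopifnot(is.data.frame(records), inherits(panel, "germline_panel"))
  need <- c("sequence", "v_gene", "j_gene", "productivity", "n_insertions")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop(sprintf("records lack column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  q_keep <- match.arg(q_keep, several.ok = TRUE)
  n0 <- nrow(records)
  ins_drop <- records$n_insertions != 0L
  records <- records[!ins_drop, , drop = FALSE]
  q_drop <- !(records$productivity %in% q_keep)
  records <- records[!q_drop, , drop = FALSE]

  # explainability within [-2, max_trim] on both genes
  ok <- logical(nrow(records))
  if (nrow(records)) {
    key <- paste(trimws(records$v_gene), trimws(records$j_gene), sep = "\r")
    for (k in unique(key)) {
      idx <- which(key == k)
      vg <- panel$v[[trimws(records$v_gene[idx[1]])]]
      jg <- panel$j[[trimws(records$j_gene[idx[1]])]]
      if (is.null(vg) || is.null(jg)) next  # unknown gene call: drop
      pr <- gene_pair(vg, jg)
      for (i in idx) {
        ok[i] <- tryCatch({
          enumerate_annotations(records$sequence[i], pr,
                                trim_bounds = c(-2L, as.integer(max_trim)),
                                m_cap = m_cap)
          TRUE
        }, vdjmh_unexplainable = function(e) FALSE)
      }
    }
  }
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- data.frame(
    criterion = c("n_insertions", "productivity", "no_annotation_within_bounds"),
    removed = c(sum(ins_drop), sum(q_drop), sum(!ok)))
  if (nrow(out) == 0L)
    warning("all records removed by filtering", call. = FALSE)
  message(sprintf(
    "filter_records: kept %d of %d (removed %d with insertions, %d by productivity, %d unexplainable within max_trim)",
    nrow(out), n0, sum(ins_drop), sum(q_drop), sum(!ok)))
  out
}

#' Germline microhomology summary of a gene-pair panel
#'
#' For each pair, the mean over all trimming scenarios of (a) the average
#' microhomology and (b) the feasible-ligation-set size, plus the medians
#' across pairs. A median set size of exactly 1 would mean every
#' annotation is microhomology-free; values above 1 indicate trimming
#' scenarios with multiple possible ligation outcomes.
#'
#' @param pairs list of [gene_pair()] objects (e.g. [panel_pairs()]).
#' @param trim_bounds inclusive trim bounds.
#' @param m_cap maximum microhomology considered.
#' @return list with `per_pair` (data.frame) and scalar
#'   `median_avg_mh`, `median_n_ligation`.
#' @export
germline_mh_summary <- function(pairs, trim_bounds = c(-2L, 14L),
                                m_cap = 10L) {
  if (length(pairs) == 0L) stop("empty pair collection", call. = FALSE)
  config <- feature_config(m_cap = m_cap, trim_bounds = trim_bounds)
  rows <- lapply(pairs, function(pr) {
    pt <- build_pair_table(pr, config)
    data.frame(v_name = pr$v$name, j_name = pr$j$name,
               mean_avg_mh = mean(pt$avg_mh),
               mean_n_ligation = mean(pt$n_lig))
  })
  per_pair <- do.call(rbind, rows)
  list(per_pair = per_pair,
       median_avg_mh = stats::median(per_pair$mean_avg_mh),
       median_n_ligation = stats::median(per_pair$mean_n_ligation))
}
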