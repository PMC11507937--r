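# Annotated dataset: repertoire records joined to their microhomology-
# adapted annotation sets through precomputed pair tables. Everything the
# EM fitter and the evaluation statistics need is indexed here once:
# `amap` holds one row per (sequence, annotation) with the global cell id
# of the annotation in the concatenated pair tables, and `stack` holds
# the pair tables stacked into block matrices so the M-step evaluates the
# likelihood with a handful of vectorised operations.

pair_key <- function(v_gene, j_gene) {
  paste(trimws(v_gene), trimws(j_gene), sep = "\r")
}

#' Precompute pair tables for every V-J pair of a panel
#'
#' Convenience cache for workflows that annotate several datasets (or
#' many simulation replicates) against the same panel: pass the result to
#' [annotate_records()] or [simulate_repertoire()] to avoid rebuilding
#' the tables.
#'
#' @param panel a [germline_panel()].
#' @param config a [feature_config()].
#' @return named list of [build_pair_table()] objects keyed by V/J name.
#' @export
build_panel_tables <- function(panel, config = feature_config()) {
  stopifnot(inherits(panel, "germline_panel"))
  out <- list()
  for (vn in names(panel$v)) for (jn in names(panel$j))
    out[[pair_key(vn, jn)]] <-
      build_pair_table(gene_pair(panel$v[[vn]], panel$j[[jn]]), config)
  out
}

# Stacked representation of a list of pair tables (shared scenario grid).
stack_tables <- function(tables) {
  n_scen <- nrow(tables[[1]]$grid)
  n_cells <- vapply(tables, function(pt) nrow(pt$cells), integer(1))
  n_pairs <- length(tables)
  list(
    n_scen = n_scen, n_pairs = n_pairs, n_cells = n_cells,
    X_all = do.call(rbind, lapply(tables, `[[`, "X_trim")),
    cell_m = unlist(lapply(tables, function(pt) pt$cells$m),
                    use.names = FALSE),
    cell_prod = unlist(lapply(tables, function(pt) pt$cells$productivity),
                       use.names = FALSE),
    # global scenario index of each cell, and owners of cells/scenarios
    cell_scen_g = unlist(lapply(seq_along(tables), function(k)
      tables[[k]]$cells$scen_id + (k - 1L) * n_scen), use.names = FALSE),
    pair_of_cell = rep(seq_len(n_pairs), n_cells),
    pair_of_scen = rep(seq_len(n_pairs), each = n_scen))
}

#' Annotate filtered records against a germline panel
#'
#' Builds one [build_pair_table()] per observed V-J pair and maps every
#' record's junction to its annotation cells by exact lookup. Columns
#' prefixed `truth_` (simulator ground truth) are carried along but never
#' used. Records whose junction cannot be explained raise an
#' `vdjmh_unexplainable` error unless `skip_unexplainable = TRUE`.
#'
#' @param records filtered data.frame (see [filter_records()]); must have
#'   `n_insertions == 0` throughout.
#' @param panel a [germline_panel()].
#' @param config a [feature_config()].
#' @param skip_unexplainable drop unexplainable records with a warning
#'   instead of erroring.
#' @param tables optional [build_panel_tables()] cache (must match
#'   `config`).
#' @return an object of class `annotated_dataset`.
#' @export
annotate_records <- function(records, panel, config = feature_config(),
                             skip_unexplainable = FALSE, tables = NULL) {
  stopifnot(is.data.frame(records), inherits(panel, "germline_panel"),
            inherits(config, "feature_config"))
  need <- c("sequence", "v_gene", "j_gene")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop(sprintf("records lack column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (!is.null(records$n_insertions) && any(records$n_insertions != 0L))
    stop("records with N-insertions present; run filter_records() first",
         call. = FALSE)
  if (nrow(records) == 0L) stop("no records to annotate", call. = FALSE)

  pkey <- pair_key(records$v_gene, records$j_gene)
  upairs <- unique(pkey)
  pair_tabs <- vector("list", length(upairs))
  names(pair_tabs) <- upairs
  for (k in upairs) {
    i <- match(k, pkey)
    vn <- trimws(records$v_gene[i]); jn <- trimws(records$j_gene[i])
    if (is.null(panel$v[[vn]]))
      stop(sprintf("V-gene call '%s' not in panel", vn), call. = FALSE)
    if (is.null(panel$j[[jn]]))
      stop(sprintf("J-gene call '%s' not in panel", jn), call. = FALSE)
    pair_tabs[[k]] <- if (!is.null(tables) && !is.null(tables[[k]]))
      tables[[k]]
    else build_pair_table(gene_pair(panel$v[[vn]], panel$j[[jn]]), config)
  }
  n_cells <- vapply(pair_tabs, function(pt) nrow(pt$cells), integer(1))
  offset <- c(0L, cumsum(n_cells))[seq_along(pair_tabs)]
  names(offset) <- upairs

  # vectorised junction -> cells lookup, one list subset per pair
  pair_id <- match(pkey, upairs)
  rec_cells <- vector("list", nrow(records))
  for (k in seq_along(upairs)) {
    idx <- which(pair_id == k)
    hits <- pair_tabs[[k]]$junction_index[toupper(records$sequence[idx])]
    rec_cells[idx] <- hits
  }
  n_ann <- lengths(rec_cells)  # missing junctions have length 0
  if (any(n_ann == 0L)) {
    bad <- which(n_ann == 0L)
    msg <- sprintf("%d record(s) with unexplainable junctions (first: %s)",
                   length(bad), records$sequence[bad[1]])
    if (!skip_unexplainable)
      stop(structure(class = c("vdjmh_unexplainable", "error", "condition"),
                     list(message = msg, call = sys.call())))
    warning(msg, call. = FALSE)
    records <- records[-bad, , drop = FALSE]
    rownames(records) <- NULL
    pair_id <- pair_id[-bad]
    rec_cells <- rec_cells[-bad]
    n_ann <- n_ann[-bad]
    if (nrow(records) == 0L)
      stop("no explainable records left", call. = FALSE)
  }
  amap <- data.frame(
    seq_id = rep.int(seq_len(nrow(records)), n_ann),
    pair_id = rep.int(pair_id, n_ann),
    cell_id = unlist(rec_cells, use.names = FALSE))
  amap$gcell <- offset[amap$pair_id] + amap$cell_id

  structure(
    list(records = records, tables = pair_tabs, amap = amap,
         config = config, n_seq = nrow(records),
         n_cells_total = sum(n_cells), offset = offset,
         stack = stack_tables(pair_tabs)),
    class = "annotated_dataset")
}

#' @export
print.annotated_dataset <- function(x, ...) {
  cat(sprintf(
    "<annotated_dataset> %d sequences, %d V-J pairs, %d (sequence, annotation) rows\n",
    x$n_seq, length(x$tables), nrow(x$amap)))
  multi <- sum(tabulate(x$amap$seq_id, x$n_seq) > 1L)
  cat(sprintf("  sequences with multiple annotations: %d (%.1f%%)\n",
              multi, 100 * multi / x$n_seq))
  invisible(x)
}

#' Annotation set of one dataset record
#' @param dataset an [annotate_records()] result.
#' @param i record index.
#' @return an `annotation_set` for record `i`.
#' @export
dataset_annotation_set <- function(dataset, i) {
  stopifnot(inherits(dataset, "annotated_dataset"))
  i <- assert_scalar_int(i, "i", 1L, dataset$n_seq)
  rows <- dataset$amap[dataset$amap$seq_id == i, , drop = FALSE]
  pt <- dataset$tables[[rows$pair_id[1]]]
  ann <- pt$cells[rows$cell_id, c("t_v", "t_j", "m"), drop = FALSE]
  ann <- ann[order(ann$t_v, ann$t_j, ann$m), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(sequence = toupper(dataset$records$sequence[i]),
                 pair = pt$pair, annotations = ann),
            class = "annotation_set")
}
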