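# Germline gene handling: P-nucleotide extension, trimming, productivity.

#' Construct a germline gene
#'
#' A germline V or J segment together with its P-nucleotide-extended
#' sequence. Hairpin opening is modelled at position +2, so exactly two
#' P-nucleotides (the reverse complement of the terminal two bases) are
#' appended at the trimmed end: the 3' end for V genes, the 5' end for J
#' genes. Trim amounts are indexed so that a trim of -2 leaves the
#' extension intact and a trim of 0 deletes exactly the two P-nucleotides,
#' i.e. stops at the germline gene boundary.
#'
#' @param name gene/allele identifier, e.g. `"TRAV41*01"`.
#' @param sequence top-strand 5'->3' nucleotide string over `{A,C,G,T}`.
#' @param end which end is trimmed: `"V_3prime"` or `"J_5prime"`.
#' @param locus locus tag (e.g. `"TRA"`, `"TRG"`, `"toy"`).
#' @param frame_offset integer 0-2, the reading-frame phase at the gene's
#'   trimmed end; used only when deciding productivity of a joined
#'   sequence (the V-side offset anchors the frame of the junction).
#' @return an object of class `germline_gene`.
#' @examples
#' g <- germline_gene("Vt", "CATTGA", end = "V_3prime")
#' g$extended_sequence  # "CATTGATC"
#' @export
germline_gene <- function(name, sequence, end = c("V_3prime", "J_5prime"),
                          locus = "toy", frame_offset = 0L) {
  end <- match.arg(end)
  if (length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  if (length(sequence) != 1L || !nzchar(sequence) || !is_dna(sequence))
    stop(sprintf("sequence of gene '%s' must be non-empty over {A,C,G,T}", name),
         call. = FALSE)
  frame_offset <- assert_scalar_int(frame_offset, "frame_offset", 0L, 2L)
  n <- nchar(sequence)
  extended <- if (end == "V_3prime") {
    paste0(sequence, revcomp(substr(sequence, n - 1L, n)))
  } else {
    paste0(revcomp(substr(sequence, 1L, 2L)), sequence)
  }
  structure(
    list(name = name, locus = locus, end = end, sequence = sequence,
         frame_offset = frame_offset, extended_sequence = extended),
    class = "germline_gene"
  )
}

#' @export
print.germline_gene <- function(x, ...) {
  cat(sprintf("<germline_gene> %s (%s, %s, %d nt + 2 P-nt)\n",
              x$name, x$locus, x$end, nchar(x$sequence)))
  invisible(x)
}

#' Read germline genes from a FASTA file
#'
#' Accepts plain or IMGT-style headers; the token before the first `|` or
#' whitespace is taken as the gene name. Sequences are uppercased; records
#' containing characters outside `{A,C,G,T}` are rejected with a warning.
#'
#' @param path FASTA file path.
#' @param end trimmed end for all records (`"V_3prime"` or `"J_5prime"`).
#' @param locus locus tag applied to all records.
#' @return a named list of [germline_gene()] objects, input order preserved.
#' @export
read_germline_fasta <- function(path, end = c("V_3prime", "J_5prime"),
                                locus = "toy") {
  end <- match.arg(end)
  if (!file.exists(path))
    stop(sprintf("germline FASTA not found: %s", path), call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L)
    stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  nms <- sub("[|[:space:]].*$", "", names(seqs))
  chr <- toupper(as.character(seqs))
  ok <- is_dna(chr)
  if (any(!ok)) {
    warning(sprintf("rejecting %d record(s) with non-ACGT characters: %s",
                    sum(!ok), paste(nms[!ok], collapse = ", ")),
            call. = FALSE)
    nms <- nms[ok]; chr <- chr[ok]
  }
  if (length(chr) == 0L)
    stop(sprintf("no usable records in %s", path), call. = FALSE)
  dup <- nms[duplicated(nms)]
  if (length(dup))
    stop(sprintf("duplicate gene name(s) in %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  genes <- mapply(germline_gene, name = nms, sequence = chr,
                  MoreArgs = list(end = end, locus = locus),
                  SIMPLIFY = FALSE)
  names(genes) <- nms
  genes
}

#' Pair a V gene with a J gene
#'
#' @param v a [germline_gene()] with `end = "V_3prime"`.
#' @param j a [germline_gene()] with `end = "J_5prime"`.
#' @return an object of class `gene_pair`.
#' @export
gene_pair <- function(v, j) {
  if (!inherits(v, "germline_gene") || v$end != "V_3prime")
    stop("`v` must be a germline_gene with end = 'V_3prime'", call. = FALSE)
  if (!inherits(j, "germline_gene") || j$end != "J_5prime")
    stop("`j` must be a germline_gene with end = 'J_5prime'", call. = FALSE)
  if (!identical(v$locus, j$locus))
    stop(sprintf("locus mismatch: %s (%s) vs %s (%s)",
                 v$name, v$locus, j$name, j$locus), call. = FALSE)
  structure(list(v = v, j = j), class = "gene_pair")
}

#' @export
print.gene_pair <- function(x, ...) {
  cat(sprintf("<gene_pair> %s / %s (%s)\n", x$v$name, x$j$name, x$v$locus))
  invisible(x)
}

#' A panel of germline V and J genes
#'
#' Container for the gene pool a repertoire draws from. Gene-call strings
#' in repertoire tables are matched against the panel names exactly after
#' stripping whitespace (no allele collapsing).
#'
#' @param v_genes named list of V-side [germline_gene()] objects.
#' @param j_genes named list of J-side [germline_gene()] objects.
#' @return an object of class `germline_panel`.
#' @export
germline_panel <- function(v_genes, j_genes) {
  chk <- function(genes, end, side) {
    if (length(genes) == 0L)
      stop(sprintf("empty %s-gene list", side), call. = FALSE)
    ok <- vapply(genes, function(g)
      inherits(g, "germline_gene") && g$end == end, logical(1))
    if (!all(ok))
      stop(sprintf("all %s genes must be germline_gene with end = '%s'",
                   side, end), call. = FALSE)
    names(genes) <- vapply(genes, `[[`, character(1), "name")
    if (anyDuplicated(names(genes)))
      stop(sprintf("duplicate %s-gene names in panel", side), call. = FALSE)
    genes
  }
  structure(list(v = chk(v_genes, "V_3prime", "V"),
                 j = chk(j_genes, "J_5prime", "J")),
            class = "germline_panel")
}

#' @export
print.germline_panel <- function(x, ...) {
  cat(sprintf("<germline_panel> %d V genes x %d J genes\n",
              length(x$v), length(x$j)))
  invisible(x)
}

#' All V-J pairs of a panel
#' @param panel a [germline_panel()].
#' @return list of [gene_pair()] objects, J varying fastest.
#' @export
panel_pairs <- function(panel) {
  stopifnot(inherits(panel, "germline_panel"))
  out <- vector("list", length(panel$v) * length(panel$j))
  k <- 0L
  for (v in panel$v) for (j in panel$j) {
    k <- k + 1L
    out[[k]] <- gene_pair(v, j)
  }
  out
}

#' Trimmed gene sequence under the IGoR-compatible trim index
#'
#' Removes `t + 2` nucleotides from the trimmed end of the P-extended
#' sequence: `t = -2` returns the extension unchanged, `t = 0` the
#' unextended germline sequence, positive `t` deletes into the gene body.
#'
#' @param gene a [germline_gene()].
#' @param t integer trim amount in `[-2, 14]`.
#' @return nucleotide string.
#' @examples
#' g <- germline_gene("Vt", "CATTGA", end = "V_3prime")
#' trimmed_sequence(g, -2)  # "CATTGATC"
#' trimmed_sequence(g, 0)   # "CATTGA"
#' @export
trimmed_sequence <- function(gene, t) {
  stopifnot(inherits(gene, "germline_gene"))
  t <- assert_scalar_int(t, "t", -2L, 14L)
  L2 <- nchar(gene$extended_sequence)
  if (t + 2L > L2)
    stop(sprintf("over-trim: t = %d removes %d nt but %s has only %d", t,
                 t + 2L, gene$name, L2), call. = FALSE)
  if (gene$end == "V_3prime") substr(gene$extended_sequence, 1L, L2 - (t + 2L))
  else substring(gene$extended_sequence, t + 3L)
}

# Junction productivity rule used for synthetic data and choice-set
# restriction: in-frame iff the net length change relative to the
# (t_v = 0, t_j = 0, m = 0) join is 0 mod 3, and no stop codon occurs in
# the junction window (last 30 nt of trimmed V through first 30 nt of
# trimmed J) in the frame anchored by the V gene's frame_offset.
# Real-data records carry their own productivity flag, which takes
# precedence over this rule.
productivity_of_junction <- function(junction, len_v_trim, net_change,
                                     frame_offset) {
  if (net_change %% 3L != 0L) return("nonproductive")
  L <- nchar(junction)
  win_lo <- max(1L, len_v_trim - 29L)
  win_hi <- min(L, len_v_trim + 30L)
  # complete codons in the V-anchored frame that overlap the window
  first <- frame_offset + 1L
  starts <- if (first + 2L > L) integer(0)
            else seq.int(first, L - 2L, by = 3L)
  if (length(starts)) {
    keep <- (starts + 2L) >= win_lo & starts <= win_hi
    starts <- starts[keep]
  }
  if (length(starts)) {
    codons <- substring(junction, starts, starts + 2L)
    if (any(codons %in% stop_codons)) return("nonproductive")
  }
  "productive"
}

#' Productivity of a trimming/ligation scenario
#'
#' Deterministic frame-plus-stop-codon rule on the joined junction: the
#' scenario is productive iff its net length change relative to the
#' `(t_v = 0, t_j = 0, m = 0)` join is a multiple of three and the
#' junction window (last 30 nt of the trimmed V through the first 30 nt of
#' the trimmed J) contains no stop codon in the frame implied by the V
#' gene's `frame_offset`. Because every annotation of a given junction
#' reconstructs the same observed sequence, productivity is a property of
#' the junction, shared by all of its annotations.
#'
#' @param pair a [gene_pair()].
#' @param t_v,t_j trim amounts.
#' @param m microhomology count; must be feasible for the trims.
#' @return `"productive"` or `"nonproductive"`.
#' @export
productivity <- function(pair, t_v, t_j, m) {
  stopifnot(inherits(pair, "gene_pair"))
  m <- assert_scalar_int(m, "m", 0L)
  vtr <- trimmed_sequence(pair$v, t_v)
  jtr <- trimmed_sequence(pair$j, t_j)
  nv <- nchar(vtr); nj <- nchar(jtr)
  if (m > min(nv, nj))
    stop(sprintf("infeasible scenario: m = %d exceeds trimmed lengths", m),
         call. = FALSE)
  if (m > 0L &&
      substr(vtr, nv - m + 1L, nv) != substr(jtr, 1L, m))
    stop(sprintf(
      "infeasible scenario for %s/%s: trimmed ends do not share %d nt",
      pair$v$name, pair$j$name, m), call. = FALSE)
  junction <- paste0(vtr, substring(jtr, m + 1L))
  productivity_of_junction(junction, nv, -(t_v + t_j + m),
                           pair$v$frame_offset)
}

#' Write a germline gene list as FASTA
#' @param genes named list of [germline_gene()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(genes, path) {
  ss <- Biostrings::DNAStringSet(vapply(genes, `[[`, character(1), "sequence"))
  names(ss) <- vapply(genes, `[[`, character(1), "name")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
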