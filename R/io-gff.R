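#' Read gene models from a GFF3 file
#'
#' Builds one gene model per mRNA from a GFF3 gene/mRNA/exon hierarchy linked
#' by `ID`/`Parent` attributes. Exon intervals are stored sorted ascending by
#' start regardless of strand, 1-based inclusive as in GFF3. When an mRNA has
#' no `exon` features, its `CDS` features are used instead (some annotation
#' dialects omit exon rows).
#'
#' Exon (or CDS) features whose `Parent` does not resolve to an mRNA are
#' skipped with a single warning reporting the count. Overlapping exons within
#' one mRNA are a hard error.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with one row per exon and columns `gene_id`,
#'   `mrna_id`, `seq_id`, `strand`, `start`, `end`, sorted by `mrna_id` then
#'   `start`.
#' @export
read_gff3_gene_models <- function(path) {
  if (!file.exists(path)) stop2("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent  # CharacterList

  is_mrna <- type %in% c("mRNA", "transcript")
  mrna_ids <- ids[is_mrna]
  mrna_parent <- vapply(parents[is_mrna], function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  gene_of_mrna <- setNames(mrna_parent, mrna_ids)

  pick <- function(feature_type) {
    sel <- which(type == feature_type)
    if (length(sel) == 0L) return(NULL)
    par <- vapply(parents[sel], function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    data.frame(
      mrna_id = par,
      seq_id = as.character(GenomicRanges::seqnames(gr))[sel],
      strand = as.character(GenomicRanges::strand(gr))[sel],
      start = GenomicRanges::start(gr)[sel],
      end = GenomicRanges::end(gr)[sel],
      stringsAsFactors = FALSE)
  }

  exons <- pick("exon")
  cds <- pick("CDS")

  resolve <- function(tab) {
    if (is.null(tab)) return(list(ok = NULL, skipped = 0L))
    orphan <- is.na(tab$mrna_id) | !(tab$mrna_id %in% mrna_ids)
    list(ok = tab[!orphan, , drop = FALSE], skipped = sum(orphan))
  }
  ex <- resolve(exons)
  cd <- resolve(cds)
  skipped <- ex$skipped + cd$skipped
  if (skipped > 0L)
    warning(skipped, " exon/CDS feature(s) without resolvable Parent skipped",
            call. = FALSE)

  # CDS fallback only for mRNAs lacking exon rows
  tab <- ex$ok
  if (!is.null(cd$ok)) {
    missing_mrnas <- setdiff(mrna_ids, unique(tab$mrna_id))
    tab <- rbind(tab, cd$ok[cd$ok$mrna_id %in% missing_mrnas, , drop = FALSE])
  }
  if (is.null(tab) || nrow(tab) == 0L)
    stop2("no exon or CDS features resolvable to an mRNA in ", path)

  tab$gene_id <- unname(gene_of_mrna[tab$mrna_id])
  tab <- tab[order(tab$mrna_id, tab$start), , drop = FALSE]

  # overlap check per mRNA on the sorted intervals
  by_mrna <- split(seq_len(nrow(tab)), tab$mrna_id)
  for (idx in by_mrna) {
    s <- tab$start[idx]; e <- tab$end[idx]
    if (any(e < s)) stop2("exon with end < start in mRNA ", tab$mrna_id[idx[1]])
    if (length(idx) > 1L && any(s[-1] <= e[-length(e)]))
      stop2("overlapping exons within mRNA ", tab$mrna_id[idx[1]])
  }

  rownames(tab) <- NULL
  tab[, c("gene_id", "mrna_id", "seq_id", "strand", "start", "end")]
}
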