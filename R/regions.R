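# Age-modified region calling: a gene harbouring at least two significant
# CpGs with the same direction of change configures a region; its span is
# the base-pair distance between the outermost member probes.

#' Call age-modified regions from significant CpGs
#'
#' Groups significant probes by (annotated gene, direction) using all gene
#' annotations of each probe — a probe annotated to two genes can belong
#' to two regions — and emits a region for every group of at least
#' `min_cpgs` probes. Region length is `max(position) - min(position)`
#' over member probes (0 only for co-located annotations). Intergenic
#' probes never form regions. A gene whose probes change in both
#' directions can yield one region per direction. Probes lacking a
#' position are excluded and reported via the `n_no_position` attribute.
#'
#' @param sig a `diffmeth_table` restricted (or not) to significant rows;
#'   only rows with `direction != "not_significant"` are used.
#' @param manifest probe annotation data.frame (see [read_manifest()]).
#' @param min_cpgs minimum probes per region (default 2).
#' @return data.frame ordered by chromosome then start: `gene`,
#'   `direction`, `chromosome`, `n_cpgs`, `start`, `end`,
#'   `region_length_bp`, `probe_ids` (semicolon-joined).
#' @export
call_regions <- function(sig, manifest, min_cpgs = 2) {
  called <- sig[sig$direction != "not_significant", , drop = FALSE]
  long <- expand_gene_annotations(manifest)
  long <- long[!is.na(long$gene), , drop = FALSE]
  pos <- manifest$position[match(long$probe_id, manifest$probe_id)]
  chr <- manifest$chromosome[match(long$probe_id, manifest$probe_id)]
  no_pos <- is.na(pos)
  long <- long[!no_pos, , drop = FALSE]
  pos <- pos[!no_pos]; chr <- chr[!no_pos]

  hit <- long$probe_id %in% called$probe_id
  ann <- data.frame(probe_id = long$probe_id[hit], gene = long$gene[hit],
                    position = pos[hit], chromosome = chr[hit],
                    stringsAsFactors = FALSE)
  ann$direction <- called$direction[match(ann$probe_id, called$probe_id)]
  # a probe can carry the same gene twice (two transcripts); regions count
  # distinct probes
  ann <- unique(ann)

  empty <- data.frame(gene = character(0), direction = character(0),
                      chromosome = character(0), n_cpgs = integer(0),
                      start = integer(0), end = integer(0),
                      region_length_bp = integer(0),
                      probe_ids = character(0), stringsAsFactors = FALSE)
  key <- paste(ann$gene, ann$direction, sep = "\r")
  groups <- split(ann, key)
  groups <- groups[vapply(groups, nrow, integer(1)) >= min_cpgs]
  if (length(groups) == 0) {
    attr(empty, "n_no_position") <- sum(no_pos)
    return(empty)
  }
  rows <- lapply(groups, function(g) {
    g <- g[order(g$position, g$probe_id), , drop = FALSE]
    data.frame(gene = g$gene[1], direction = g$direction[1],
               chromosome = g$chromosome[1], n_cpgs = nrow(g),
               start = min(g$position), end = max(g$position),
               region_length_bp = max(g$position) - min(g$position),
               probe_ids = paste(g$probe_id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  chrnum <- suppressWarnings(as.integer(sub("^chr", "", out$chromosome)))
  out <- out[order(chrnum, out$start, out$gene, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_no_position") <- sum(no_pos)
  out
}
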