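# Readers and writers for the pipeline's plain-text interchange formats.

.OUTFMT6 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' @param path TSV without header, standard 12-column order.
#' @param metadata optional copy table used to annotate `qspecies`,
#'   `sspecies`, `superfamily` from the copy ids.
#' @return hit data frame (with `hit_id`).
#' @export
read_outfmt6 <- function(path, metadata = NULL) {
  hits <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = .OUTFMT6,
                            stringsAsFactors = FALSE, quote = "")
  hits$hit_id <- sprintf("h%06d", seq_len(nrow(hits)))
  if (!is.null(metadata)) {
    iq <- match(hits$qseqid, metadata$copy_id)
    is_ <- match(hits$sseqid, metadata$copy_id)
    hits$qspecies <- metadata$species[iq]
    hits$sspecies <- metadata$species[is_]
    hits$qsuperfamily <- metadata$superfamily[iq]
    hits$ssuperfamily <- metadata$superfamily[is_]
    hits$superfamily <- hits$qsuperfamily
  }
  hits
}

#' Write hits in BLAST outfmt-6 column order
#' @param hits hit data frame; @param path output TSV.
#' @export
write_outfmt6 <- function(hits, path) {
  utils::write.table(hits[, .OUTFMT6], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a copy metadata table
#'
#' TSV with header: `copy_id`, `species`, `superfamily`, `te_class`,
#' `family`, and frame segments as `frame_start`, `frame_end`,
#' `frame_phase` (one row per segment; copies repeat).
#'
#' @param path metadata TSV; @param fasta optional FASTA of copy sequences.
#' @return copy table with a `frames` list-column (and `sequence` when
#'   `fasta` is given).
#' @export
read_copy_table <- function(path, fasta = NULL) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  first <- !duplicated(m$copy_id)
  copies <- m[first, c("copy_id", "species", "superfamily", "te_class",
                       "family"), drop = FALSE]
  copies$frames <- lapply(copies$copy_id, function(id) {
    seg <- m[m$copy_id == id & !is.na(m$frame_start), , drop = FALSE]
    data.frame(start = seg$frame_start, end = seg$frame_end,
               phase = seg$frame_phase)
  })
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    copies$sequence <- as.character(ss)[copies$copy_id]
  }
  rownames(copies) <- NULL
  copies
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits `copies.fasta`, `copies.tsv` (metadata + frames), `hits.tsv`
#' (outfmt 6), `identities.tsv`, `core_ks.tsv`, `tree.nwk` and `truth.tsv`.
#'
#' @param ds `htt_dataset`; @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(ds$copies$sequence)
  names(seqs) <- ds$copies$copy_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "copies.fasta"))
  meta <- do.call(rbind, lapply(seq_len(nrow(ds$copies)), function(i) {
    fr <- ds$copies$frames[[i]]
    data.frame(copy_id = ds$copies$copy_id[i],
               species = ds$copies$species[i],
               superfamily = ds$copies$superfamily[i],
               te_class = ds$copies$te_class[i],
               family = ds$copies$family[i],
               frame_start = fr$start, frame_end = fr$end,
               frame_phase = fr$phase, stringsAsFactors = FALSE)
  }))
  utils::write.table(meta, file.path(dir, "copies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_outfmt6(ds$hits, file.path(dir, "hits.tsv"))
  utils::write.table(ds$identities, file.path(dir, "identities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$core_ks, file.path(dir, "core_ks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(ds$tree$phylo, file.path(dir, "tree.nwk"))
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
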