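## File writers/readers for the plain-text exchange formats the pipeline
## uses. Reading goes through rtracklayer; writers emit exactly the columns
## downstream stages consume. Internal interval frames are 0-based
## half-open (BED semantics); GFF3 is converted at the boundary.

#' Write gene models as GFF3
#'
#' @param genes data.frame (chrom, start, end, strand, gene_id; 0-based
#'   half-open)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    lines <- sprintf("%s\tchroma3d\tgene\t%s\t%s\t.\t%s\t.\tID=%s",
                     genes$chrom,
                     format(genes$start + 1, scientific = FALSE, trim = TRUE),
                     format(genes$end, scientific = FALSE, trim = TRUE),
                     genes$strand, genes$gene_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 path
#' @return data.frame (chrom, start, end, strand, gene_id; 0-based half-open)
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = gr$ID,
             stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param df data.frame (chrom, start, end; optional peak_id, score)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom,
                    start = format(df$start, scientific = FALSE, trim = TRUE),
                    end = format(df$end, scientific = FALSE, trim = TRUE),
                    name = df$peak_id %||% sprintf("peak%05d", seq_len(nrow(df))),
                    score = df$score %||% 0,
                    strand = ".")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of peaks
#'
#' @param path BED path
#' @return data.frame (chrom, start, end, peak_id; 0-based half-open)
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             peak_id = if (!is.null(gr$name)) gr$name
                       else sprintf("peak%05d", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Write a signal track as bedGraph
#'
#' @param track data.frame (chrom, start, end, value)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(track, path) {
  out <- data.frame(chrom = track$chrom,
                    start = format(track$start, scientific = FALSE, trim = TRUE),
                    end = format(track$end, scientific = FALSE, trim = TRUE),
                    value = format(track$value, scientific = FALSE,
                                   trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph path
#' @return data.frame (chrom, start, end, value; 0-based half-open)
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             value = gr$score,
             stringsAsFactors = FALSE)
}
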