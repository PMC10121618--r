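#' Write / read the per-site count table
#'
#' Columns: `site_id`, `gene`, `chrom`, `pos` (0-based), `strand`, then
#' `ref_<sample>` / `alt_<sample>` per sample; sample names start with the
#' condition (`S_ADAR_1`, `EV_2`, ...).
#'
#' @param counts count table.
#' @param path file path.
#' @return the path (write) or the table (read).
#' @export
write_counts_tsv <- function(counts, path) {
  write_tsv(counts, path, meta = "per-site editing counts; pos is 0-based")
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  x <- read_tsv(path)
  parse_count_columns(x)  # validates structure
  x
}

#' Write / read transcript models as BED-like TSV
#'
#' 0-based, half-open intervals; columns `chrom`, `start`, `end`, `gene`,
#' `transcript_id`, `region`, `strand`.
#'
#' @param transcripts transcript-model data frame.
#' @param path file path.
#' @export
write_transcripts_bed <- function(transcripts, path) {
  write_tsv(transcripts[c("chrom", "start", "end", "gene", "transcript_id",
                          "region", "strand")],
            path, meta = "transcript regions; 0-based half-open")
}

#' @rdname write_transcripts_bed
#' @export
read_transcripts_bed <- function(path) read_tsv(path)

#' Write / read sequences as FASTA
#'
#' Sequences are held internally in the DNA alphabet and written with `T`;
#' `read_fasta` returns DNA-alphabet character vectors (motif-level code
#' converts to RNA).
#'
#' @param sequences named character vector (DNA alphabet).
#' @param path file path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write edit calls as a VCF-like text file
#'
#' One record per called site with 1-based POS on write; REF/ALT follow the
#' A-to-I convention (A>G on `+`, T>C on `-`); INFO carries F_ADAR, F_EV,
#' DELTA_F, Q, REGION, GENE.
#'
#' @param calls `edit_calls` data frame.
#' @param path file path.
#' @export
write_calls_vcf <- function(calls, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=F_ADAR,Number=1,Type=Float,Description=\"Mean S-ADAR editing frequency\">",
               "##INFO=<ID=F_EV,Number=1,Type=Float,Description=\"Mean EV editing frequency\">",
               "##INFO=<ID=DELTA_F,Number=1,Type=Float,Description=\"Differential editing frequency\">",
               "##INFO=<ID=Q,Number=1,Type=Float,Description=\"BH-adjusted p-value\">",
               "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Genic region\">",
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    minus <- calls$strand == "-"
    region <- if ("region" %in% names(calls)) calls$region else "."
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tF_ADAR=%.6g;F_EV=%.6g;DELTA_F=%.6g;Q=%.6g;REGION=%s;GENE=%s",
                       calls$chrom, calls$pos + 1L, calls$site_id,
                       ifelse(minus, "T", "A"), ifelse(minus, "C", "G"),
                       calls$f_adar, calls$f_ev, calls$delta_f, calls$q_value,
                       region, calls$gene), con)
  }
  invisible(path)
}
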