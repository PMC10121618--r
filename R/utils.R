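#' @keywords internal
"_PACKAGE"

# Deterministic per-stage child seeds from one master seed.  Kept below
# .Machine$integer.max so they are valid arguments to set.seed() everywhere.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stage <- as.integer(stage)
  as.integer((as.double(abs(seed)) + 104729 * as.double(stage)) %% 2147483629)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, closed_top = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (if (closed_top) x > 1 else x >= 1)) {
    stop_config(field, sprintf("must be a fraction in [0,%s]", if (closed_top) "1" else "1)"))
  }
  invisible(x)
}

#' Write a data frame as tab-separated values
#'
#' Plain TSV with a header row; optional `#`-prefixed metadata lines are
#' written before the header so downstream readers can skip them.
#'
#' @param x data frame.
#' @param path output path.
#' @param meta optional character vector of metadata lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# sample names encode condition as "<condition>_<replicate>"
condition_of <- function(sample_names) sub("_[0-9]+$", "", sample_names)
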