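# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Build a residue key
#'
#' Residues are identified throughout the package by a compact key
#' `"<chain>:<resno><icode>"`, e.g. `"A:131"` or `"R:52A"`. Numbering is
#' carried exactly as authored in the coordinate file; insertion codes are
#' part of the key.
#'
#' @param chain chain identifier(s)
#' @param resno residue number(s)
#' @param insert insertion code(s); `NA` or `""` for none
#' @return character vector of keys
#' @export
res_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, insert)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

stop_if_missing_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Deterministic per-stage seed derivation, kept inside 32-bit integer range.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 113L + offset * 7919L) %% 2147483629)
}
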