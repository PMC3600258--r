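# Internal helpers shared across modules.

GENOTYPES <- c("hom_wt", "het", "hom_var", "no_call")
PHENOTYPES <- c("normal", "intermediate", "poor", "indeterminate")
CHANNELS <- c("TARGET", "IPC")
PRIMER_ALLELES <- c("wt", "var")

stop_input <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("tpmt_input_error", "error")))
}

stop_panel <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("tpmt_panel_error", "error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom utils read.csv write.csv packageVersion
read_table_checked <- function(path, required, sep = ",", what = "file") {
  if (!file.exists(path)) stop_input(what, " not found: ", path)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_input(what, " ", path, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  }
  df
}

# Atomic write: write to a temp file in the same directory, then rename.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

# Comma-joined flag sets used in flat report tables.
join_flags <- function(flags) {
  if (length(flags) == 0) "" else paste(sort(unique(flags)), collapse = ",")
}
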