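# Internal helpers shared across modules.

#' Derive a reproducible stage seed from a master seed
#'
#' Stages of the pipeline draw from stage-specific seeds derived from one
#' master seed, so each stage is independently reproducible. The derivation is
#' a small polynomial string hash, stable across platforms and R sessions.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "train")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# validate a character vector of unique ids
check_unique_ids <- function(x, what) {
  if (anyDuplicated(x)) {
    dup <- unique(x[duplicated(x)])
    abort(sprintf("duplicate %s ids: %s", what, paste(head(dup, 5), collapse = ", ")))
  }
  invisible(x)
}

# path to a shipped data table
extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "dtiscreen", mustWork = TRUE)
  p
}

# read a shipped TSV with an md5 integrity check
read_versioned_tsv <- function(file, md5 = NULL) {
  p <- extdata_path(file)
  if (!is.null(md5)) {
    got <- unname(tools::md5sum(p))
    if (!identical(got, md5)) {
      warn(sprintf("checksum mismatch for %s (expected %s, got %s)", file, md5, got))
    }
  }
  readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
}
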